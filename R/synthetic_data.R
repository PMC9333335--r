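# Synthetic input generator with planted ground truth: block-structured
# HMM hit tables for K families, fragment sequences with >95%-identity HSPs,
# structural hit tables straddling the acceptance cutoffs, and birth-death
# gene trees along the fixed species tree. Every generator is deterministic
# under its seed, so the whole pipeline is testable against the planted
# truth without any database download.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: planted
#' families whose members score far above the 50-bit search threshold
#' (bit scores ~ Normal(200, 15) truncated at 51), sparse cross-family
#' noise hits straddling the 25-bit fingerprint threshold, a fifth of genes
#' with fragment copies, and moderate duplication/loss rates per species
#' branch.
#'
#' @param n_families Number of planted families.
#' @param proteins_per_family Members per family (scalar or length-2 range).
#' @param models_per_family HMMs dedicated to each family.
#' @param family_score_mean,family_score_sd Bit-score distribution of
#'   within-family hits (truncated at 51 bits).
#' @param noise_hit_rate Probability that a protein also hits one random
#'   foreign model.
#' @param noise_score_range Bit-score range of noise hits (straddles 25).
#' @param fragment_rate Fraction of genes receiving fragment copies.
#' @param label_missing_rate Probability a fragment loses its gene labels.
#' @param dup_rate,loss_rate Per-branch duplication/loss probabilities for
#'   gene-family evolution.
#' @param seed Integer seed; all generators are deterministic under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 20L, proteins_per_family = 10L,
                       models_per_family = 3L,
                       family_score_mean = 200, family_score_sd = 15,
                       noise_hit_rate = 0.02, noise_score_range = c(20, 30),
                       fragment_rate = 0.2, label_missing_rate = 0.3,
                       dup_rate = 0.1, loss_rate = 0.05, seed = 1L) {
  stopifnot(n_families >= 1, models_per_family >= 1,
            family_score_mean > 50,
            noise_hit_rate >= 0, noise_hit_rate <= 1,
            fragment_rate >= 0, fragment_rate <= 1,
            label_missing_rate >= 0, label_missing_rate <= 1,
            dup_rate >= 0, loss_rate >= 0,
            length(noise_score_range) == 2,
            noise_score_range[1] < noise_score_range[2])
  structure(list(n_families = as.integer(n_families),
                 proteins_per_family = proteins_per_family,
                 models_per_family = as.integer(models_per_family),
                 family_score_mean = family_score_mean,
                 family_score_sd = family_score_sd,
                 noise_hit_rate = noise_hit_rate,
                 noise_score_range = noise_score_range,
                 fragment_rate = fragment_rate,
                 label_missing_rate = label_missing_rate,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.study_taxa <- function() c("human", "mouse", "rat", "chicken", "zebrafish",
                            "fly", "worm")

.n_per_family <- function(config) {
  p <- config$proteins_per_family
  if (length(p) == 2) sample(p[1]:p[2], 1) else as.integer(p)
}

#' Simulate per-domain HMM hits with planted family structure
#'
#' Each family owns a dedicated model subset; members hit every family
#' model with bit score ~ Normal(mean, sd) truncated at 51 bits. With
#' probability `noise_hit_rate` a protein additionally hits one random
#' foreign model with a score drawn uniformly from `noise_score_range`.
#'
#' @param config A [sim_config()].
#' @return List: `hits` (per-domain data.frame in the [parse_domtblout()]
#'   layout) and `truth` (list with `protein_family`, a named character
#'   vector).
#' @export
simulate_hits <- function(config = sim_config()) {
  set.seed(config$seed)
  rows <- list()
  fam_of <- character(0)
  model_len <- 220L
  for (f in seq_len(config$n_families)) {
    models <- sprintf("FAM%02d_M%d", f, seq_len(config$models_per_family))
    n_p <- .n_per_family(config)
    for (p in seq_len(n_p)) {
      acc <- sprintf("F%02dP%03d", f, p)
      fam_of[acc] <- sprintf("FAM%02d", f)
      sc <- pmax(51, stats::rnorm(length(models), config$family_score_mean,
                                  config$family_score_sd))
      for (k in seq_along(models)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = acc, model_id = models[k],
          bit_score = round(sc[k], 1), evalue = 10^(-sc[k] / 5),
          model_from = 3L, model_to = model_len,
          target_from = 10L, target_to = 10L + model_len,
          stringsAsFactors = FALSE)
      }
      if (config$n_families > 1 &&
          stats::runif(1) < config$noise_hit_rate) {
        foreign_fam <- sample(setdiff(seq_len(config$n_families), f), 1)
        fm <- sprintf("FAM%02d_M%d", foreign_fam,
                      sample(config$models_per_family, 1))
        ns <- stats::runif(1, config$noise_score_range[1],
                           config$noise_score_range[2])
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = acc, model_id = fm,
          bit_score = round(ns, 1), evalue = 10^(-ns / 5),
          model_from = 20L, model_to = 90L,
          target_from = 30L, target_to = 100L,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(hits = do.call(rbind, rows), truth = list(protein_family = fam_of))
}

# segments at fixed spacing: k helices of width 21 separated by loops
.make_tm_segments <- function(k, offset = 15L) {
  if (k == 0L) return(NULL)
  start <- offset + 35L * (seq_len(k) - 1L)
  cbind(start = start, end = start + 20L)
}

#' Simulate protein metadata records for planted proteins
#'
#' One gene per protein: species assigned round-robin over the seven study
#' taxa, lengths 300-900, a reviewed (curated) flag with probability 0.6,
#' gene labels in the GN and GeneID namespaces, and 3-14 TM helices.
#'
#' @param truth Truth list from [simulate_hits()].
#' @param config A [sim_config()].
#' @return Record table ([protein_records()] layout).
#' @export
simulate_records <- function(truth, config = sim_config()) {
  set.seed(config$seed + 1L)
  acc <- names(truth$protein_family)
  n <- length(acc)
  taxa <- .study_taxa()
  species <- taxa[(seq_len(n) - 1L) %% length(taxa) + 1L]
  len <- sample(300:900, n, replace = TRUE)
  reviewed <- stats::runif(n) < 0.6
  labels <- lapply(seq_len(n), function(i)
    c(paste0("GN:", acc[i], "g"), paste0("GeneID:", 100000L + i)))
  tms <- lapply(sample(3:14, n, replace = TRUE), .make_tm_segments)
  protein_records(acc, species, len, reviewed, labels, tms)
}

#' Add fragment copies and an HSP table to a record set
#'
#' For a fraction `fragment_rate` of genes, 1-3 truncated copies (30-90% of
#' the parent length) are added: each shares the parent's HMM hits with
#' scores scaled by its length fraction, carries an HSP against the parent
#' with identity uniform in (95, 100], is never reviewed, and loses its
#' gene labels with probability `label_missing_rate`. Adversarial
#' distractor HSPs with identity in (80, 95] connect unrelated genes and
#' must never cause a merge.
#'
#' @param records Parent record table.
#' @param hits Per-domain hit data.frame for the parents.
#' @param config A [sim_config()].
#' @return List: `records` (expanded), `hits` (expanded), `hsps`, and
#'   `truth` (named character vector fragment/protein -> parent gene).
#' @export
simulate_fragments <- function(records, hits, config = sim_config()) {
  set.seed(config$seed + 2L)
  gene_of <- stats::setNames(records$accession, records$accession)
  new_records <- records
  new_hits <- hits
  hsps <- list()
  n_parent <- nrow(records)
  frag_parents <- records$accession[stats::runif(n_parent) <
                                      config$fragment_rate]
  for (parent in frag_parents) {
    pi <- match(parent, records$accession)
    n_frag <- sample(1:3, 1)
    for (k in seq_len(n_frag)) {
      frac <- stats::runif(1, 0.3, 0.9)
      facc <- sprintf("%s_FR%d", parent, k)
      gene_of[facc] <- parent
      flen <- max(50L, as.integer(round(frac * records$sequence_length[pi])))
      keep_labels <- stats::runif(1) >= config$label_missing_rate
      labs <- if (keep_labels) records$gene_labels[[pi]] else character(0)
      ptm <- records$tm_segments[[pi]]
      ftm <- if (is.null(ptm)) NULL else {
        sub <- ptm[ptm[, 2] <= flen, , drop = FALSE]
        if (nrow(sub)) sub else NULL
      }
      new_records <- rbind(new_records, protein_records(
        facc, records$species[pi], flen, FALSE, list(labs), list(ftm)))
      ph <- hits[hits$protein_id == parent, , drop = FALSE]
      if (nrow(ph)) {
        ph$protein_id <- facc
        ph$bit_score <- round(ph$bit_score * frac, 1)
        ph$target_to <- pmin(ph$target_to, flen)
        ph$target_from <- pmin(ph$target_from, ph$target_to)
        new_hits <- rbind(new_hits, ph)
      }
      hsps[[length(hsps) + 1L]] <- data.frame(
        query_id = facc, subject_id = parent,
        pct_identity = round(stats::runif(1, 95.01, 100), 2),
        aln_length = flen, stringsAsFactors = FALSE)
    }
  }
  # distractors: pairs of distinct parent genes, identity in (80, 95]
  n_distract <- max(1L, as.integer(round(0.1 * n_parent)))
  if (n_parent >= 2) {
    for (k in seq_len(n_distract)) {
      pr <- sample(records$accession, 2)
      hsps[[length(hsps) + 1L]] <- data.frame(
        query_id = pr[1], subject_id = pr[2],
        pct_identity = round(stats::runif(1, 80.01, 95), 2),
        aln_length = sample(100:300, 1), stringsAsFactors = FALSE)
    }
  }
  hsp_df <- if (length(hsps)) do.call(rbind, hsps) else
    data.frame(query_id = character(0), subject_id = character(0),
               pct_identity = numeric(0), aln_length = integer(0),
               stringsAsFactors = FALSE)
  list(records = new_records, hits = new_hits, hsps = hsp_df,
       truth = gene_of)
}

#' Simulate structural hits with planted accept flags
#'
#' Per protein, 0-3 candidate PDB-chain hits: E-values log-uniform in
#' [1e-12, 1e-2]; each chain carries TM segments of which a known number
#' (0-6) is fully contained in the aligned region. The planted flag is the
#' acceptance rule: at least 3 contained segments and E strictly below
#' 1e-4.
#'
#' @param proteins Character vector of protein accessions.
#' @param config A [sim_config()].
#' @return List: `hits` (data.frame `protein_id`, `pdb_chain_id`, `evalue`,
#'   `target_aln_from`, `target_aln_to`), `tm` (named list of segment
#'   matrices), `truth` (logical vector per hit row).
#' @export
simulate_structural_hits <- function(proteins, config = sim_config()) {
  set.seed(config$seed + 3L)
  rows <- list(); tm <- list(); flags <- logical(0)
  chain_i <- 0L
  for (p in proteins) {
    for (h in seq_len(sample(0:3, 1))) {
      chain_i <- chain_i + 1L
      chain <- sprintf("%04d_A", chain_i)
      n_cov <- sample(0:6, 1)
      n_total <- n_cov + sample(0:3, 1)
      seg <- .make_tm_segments(n_total, offset = 10L)
      if (is.null(seg)) seg <- cbind(start = integer(0), end = integer(0))
      tm[[chain]] <- seg
      if (n_cov > 0) {
        aln_from <- 1L
        aln_to <- seg[n_cov, 2] + 4L   # next segment starts later: not covered
      } else {
        aln_from <- 1L
        aln_to <- 5L
      }
      ev <- 10^stats::runif(1, -12, -2)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, pdb_chain_id = chain, evalue = ev,
        target_aln_from = aln_from, target_aln_to = aln_to,
        stringsAsFactors = FALSE)
      flags <- c(flags, n_cov >= 3 && ev < 1e-4)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), pdb_chain_id = character(0),
               evalue = numeric(0), target_aln_from = integer(0),
               target_aln_to = integer(0), stringsAsFactors = FALSE)
  list(hits = hits, tm = tm, truth = flags)
}

# ---- birth-death gene trees --------------------------------------------------

# evolve one gene lineage along the branch entering species node `v`;
# returns a nested-list gene tree node or NULL (lineage lost)
.evolve_branch <- function(v, idx, dup_rate, loss_rate, state) {
  if (stats::runif(1) < dup_rate) {
    state$planted_dup <- state$planted_dup + 1L
    left <- .evolve_after_dup(v, idx, dup_rate, loss_rate, state)
    right <- .evolve_after_dup(v, idx, dup_rate, loss_rate, state)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) return(right)
    if (is.null(right)) return(left)
    return(list(event = "D", children = list(left, right)))
  }
  .evolve_after_dup(v, idx, dup_rate, loss_rate, state)
}

.evolve_after_dup <- function(v, idx, dup_rate, loss_rate, state) {
  if (stats::runif(1) < loss_rate) {
    state$n_loss <- state$n_loss + 1L
    return(NULL)
  }
  .evolve_node(v, idx, dup_rate, loss_rate, state)
}

.evolve_node <- function(v, idx, dup_rate, loss_rate, state) {
  if (v <= idx$n_tip) {
    state$leaf_i <- state$leaf_i + 1L
    sp <- idx$tree$tip.label[v]
    return(list(leaf = paste0(state$prefix, "g", state$leaf_i, "__", sp)))
  }
  kids <- idx$children[[as.character(v)]]
  sub <- lapply(kids, .evolve_branch, idx = idx, dup_rate = dup_rate,
                loss_rate = loss_rate, state = state)
  sub <- sub[!vapply(sub, is.null, logical(1))]
  if (!length(sub)) return(NULL)
  if (length(sub) == 1L) return(sub[[1]])
  list(event = "S", children = sub)
}

.tree_to_newick <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  paste0("(", paste(vapply(node$children, .tree_to_newick, character(1)),
                    collapse = ","), ")", node$event)
}

.count_events <- function(node) {
  if (!is.null(node$leaf)) return(c(D = 0L, S = 0L, leaves = 1L))
  sub <- Reduce(`+`, lapply(node$children, .count_events))
  sub[node$event] <- sub[node$event] + 1L
  sub
}

#' Simulate gene trees by birth-death evolution along the species tree
#'
#' One gene lineage enters the root; on every branch it duplicates with
#' probability `dup_rate` and each copy is lost with probability
#' `loss_rate`. Surviving leaves are genes named `geneN__species`. The
#' planted rooted tree carries `D`/`S` node labels; trees are also emitted
#' unrooted (root edge dissolved) to exercise parsimony rooting. Families
#' going extinct or surviving with fewer than 2 genes are resampled
#' (bounded retries).
#'
#' @param species_tree Rooted species tree ([study_species_tree()]).
#' @param config A [sim_config()].
#' @param n_trees Number of gene families to simulate.
#' @param root_duplication Force one duplication at the root of every tree.
#' @return List of per-tree lists: `rooted` (phylo with `D`/`S` node
#'   labels), `unrooted` (phylo), `n_duplications`, `n_losses`.
#' @export
simulate_gene_trees <- function(species_tree = study_species_tree(),
                                config = sim_config(), n_trees = 10L,
                                root_duplication = FALSE) {
  set.seed(config$seed + 4L)
  idx <- .species_index(species_tree)
  out <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    for (try in 1:50) {
      state <- new.env()
      state$leaf_i <- 0L
      state$n_loss <- 0L
      state$planted_dup <- 0L
      state$prefix <- sprintf("t%02d", t)
      root <- if (root_duplication) {
        l <- .evolve_node(idx$root, idx, config$dup_rate, config$loss_rate,
                          state)
        r <- .evolve_node(idx$root, idx, config$dup_rate, config$loss_rate,
                          state)
        if (is.null(l) || is.null(r)) NULL
        else list(event = "D", children = list(l, r))
      } else {
        .evolve_node(idx$root, idx, config$dup_rate, config$loss_rate,
                     state)
      }
      if (!is.null(root) && is.null(root$leaf)) break
      root <- NULL
    }
    if (is.null(root)) {
      stop("gene-family simulation failed after 50 retries (tree ", t, ")")
    }
    nwk <- paste0(.tree_to_newick(root), ";")
    rooted <- ape::read.tree(text = nwk)
    counts <- .count_events(root)
    unrooted <- if (length(rooted$tip.label) >= 3) ape::unroot(rooted)
                else rooted
    out[[t]] <- list(rooted = rooted, unrooted = unrooted,
                     n_duplications = unname(counts["D"]),
                     n_losses = state$n_loss)
  }
  out
}

# ---- bundle writer -----------------------------------------------------------

.random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Generate and write a complete synthetic input bundle
#'
#' Produces every pipeline input under `dir`: proteome FASTA, domtblout
#' hit table, HSP TSV, protein metadata TSV, structural hits + PDB TM
#' annotations, Newick gene trees, the species tree, and a JSON truth file
#' (planted families, gene map, structural flags, per-tree event counts).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_trees Gene families to simulate for the orthology stage.
#' @return Invisibly, a list with all generated objects, the truth and the
#'   file paths.
#' @export
simulate_bundle <- function(config = sim_config(), dir, n_trees = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_hits(config)
  records <- simulate_records(sim$truth, config)
  fr <- simulate_fragments(records, sim$hits, config)
  st <- simulate_structural_hits(records$accession, config)
  trees <- simulate_gene_trees(study_species_tree(), config, n_trees)

  set.seed(config$seed + 5L)
  seqs <- stats::setNames(
    vapply(fr$records$sequence_length, .random_sequence, character(1)),
    fr$records$accession)
  # fragments are literal substrings of their parents
  frag <- grepl("_FR\\d+$", fr$records$accession)
  for (i in which(frag)) {
    parent <- sub("_FR\\d+$", "", fr$records$accession[i])
    seqs[i] <- substr(seqs[parent], 1L, fr$records$sequence_length[i])
  }

  paths <- list(
    fasta = file.path(dir, "proteins.fasta"),
    hits = file.path(dir, "hits.domtbl"),
    hsps = file.path(dir, "hsps.tsv"),
    records = file.path(dir, "records.tsv"),
    structural = file.path(dir, "structural_hits.tsv"),
    tm = file.path(dir, "pdb_tm.tsv"),
    species_tree = file.path(dir, "species_tree.nwk"),
    tree_dir = file.path(dir, "gene_trees"),
    truth = file.path(dir, "truth.json"))
  write_fasta(seqs, paths$fasta)
  write_domtblout(fr$hits, paths$hits)
  write_table(fr$hsps, paths$hsps)
  write_records(fr$records, paths$records)
  write_table(st$hits, paths$structural)
  write_tm_annotations(st$tm, paths$tm)
  ape::write.tree(study_species_tree(), file = paths$species_tree)
  dir.create(paths$tree_dir, showWarnings = FALSE)
  for (t in seq_along(trees)) {
    ape::write.tree(trees[[t]]$unrooted,
                    file = file.path(paths$tree_dir,
                                     sprintf("tree%02d.nwk", t)))
  }
  truth <- list(
    protein_family = as.list(sim$truth$protein_family),
    gene_map = as.list(fr$truth),
    structural_accept = st$truth,
    tree_events = lapply(trees, function(x)
      list(n_duplications = x$n_duplications, n_losses = x$n_losses)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, hits = fr$hits, records = fr$records,
                 hsps = fr$hsps, structural = st, trees = trees,
                 truth = truth, paths = paths))
}
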