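# End-to-end orchestration: fingerprint -> collapse -> sanitize ->
# cluster(+constraints) -> structural filter -> orthology, with a JSON
# run manifest (input hashes, parameters, stage counts, warnings).

#' Pipeline configuration
#'
#' @param hits,records,hsps,structural,tm,species_tree,gene_trees Input
#'   paths: domtblout hit table, protein metadata TSV, BLAST tabular or
#'   HSP TSV, structural hit TSV, PDB TM-annotation TSV, species-tree
#'   Newick, and a directory of gene-tree Newick files (`gene_trees` and
#'   the structural inputs may be `NULL` to skip those stages).
#' @param out_dir Output directory.
#' @param thresholds A [threshold_config()].
#' @param collapse A [collapse_config()].
#' @param cluster A [cluster_config()].
#' @param struct_min_tm,struct_max_e Structural filter parameters.
#' @param focal_species Focal species for the ortholog matrix.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(hits, records, hsps, out_dir,
                            structural = NULL, tm = NULL,
                            species_tree = NULL, gene_trees = NULL,
                            thresholds = threshold_config(),
                            collapse = collapse_config(),
                            cluster = cluster_config(),
                            struct_min_tm = 3L, struct_max_e = 1e-4,
                            focal_species = "human", seed = 1L) {
  structure(list(hits = hits, records = records, hsps = hsps,
                 structural = structural, tm = tm,
                 species_tree = species_tree, gene_trees = gene_trees,
                 out_dir = out_dir, thresholds = thresholds,
                 collapse = collapse, cluster = cluster,
                 struct_min_tm = as.integer(struct_min_tm),
                 struct_max_e = struct_max_e,
                 focal_species = focal_species, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; nested
#' `thresholds`, `collapse` and `cluster` maps override the corresponding
#' sub-config defaults (constraint pairs as lists of two-element lists).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$thresholds)) y$thresholds <- list()
  thr <- do.call(threshold_config, c(
    y$thresholds[setdiff(names(y$thresholds), "region_exclusions")],
    if (!is.null(y$thresholds$region_exclusions))
      list(region_exclusions = do.call(rbind, lapply(
        y$thresholds$region_exclusions, as.data.frame)))))
  pairs_df <- function(p) {
    if (is.null(p)) return(NULL)                  # absent: fall back to defaults
    if (!length(p)) {                             # explicit empty list: none
      return(data.frame(a = character(0), b = character(0)))
    }
    do.call(rbind, lapply(p, function(q)
      data.frame(a = q[[1]], b = q[[2]], stringsAsFactors = FALSE)))
  }
  cl <- y$cluster
  clu <- cluster_config(
    cut_height = cl$cut_height %||% 0.7,
    scan_heights = unlist(cl$scan_heights) %||% c(0.6, 0.7, 0.8),
    joins = pairs_df(cl$joins) %||% default_join_pairs(),
    splits = pairs_df(cl$splits) %||% default_split_pairs())
  col <- do.call(collapse_config, y$collapse %||% list())
  pipeline_config(
    hits = y$hits, records = y$records, hsps = y$hsps,
    out_dir = y$out_dir, structural = y$structural, tm = y$tm,
    species_tree = y$species_tree, gene_trees = y$gene_trees,
    thresholds = thr, collapse = col, cluster = clu,
    struct_min_tm = y$struct_min_tm %||% 3L,
    struct_max_e = y$struct_max_e %||% 1e-4,
    focal_species = y$focal_species %||% "human",
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Returns every problem found (never just the first); an empty character
#' vector means the configuration is valid.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- c("hits", "records", "hsps")
  for (f in need) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      problems <- c(problems, paste0("missing input file for '", f, "'"))
    }
  }
  for (f in c("structural", "tm", "species_tree")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      problems <- c(problems, paste0("input file for '", f,
                                     "' does not exist"))
    }
  }
  if (!is.null(config$gene_trees) && !dir.exists(config$gene_trees)) {
    problems <- c(problems, "gene_trees directory does not exist")
  }
  th <- config$thresholds
  if (!(th$search_min_bits >= th$fingerprint_min_bits &&
        th$fingerprint_min_bits > 0)) {
    problems <- c(problems,
                  "thresholds must satisfy search >= fingerprint > 0")
  }
  cl <- config$cluster
  if (!(cl$cut_height > 0 && cl$cut_height < 2)) {
    problems <- c(problems, "cut_height outside (0, 2)")
  }
  both <- intersect(.pair_keys(cl$joins), .pair_keys(cl$splits))
  if (length(both)) {
    problems <- c(problems, paste0("pair(s) in both joins and splits: ",
                                   paste(both, collapse = ", ")))
  }
  co <- config$collapse
  if (!(co$min_hsp_identity > 0 && co$min_hsp_identity < 100)) {
    problems <- c(problems, "min_hsp_identity outside (0, 100)")
  }
  if (co$min_tmh < 0) problems <- c(problems, "min_tmh negative")
  if (!(config$struct_max_e > 0)) {
    problems <- c(problems, "struct_max_e must be positive")
  }
  problems
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# constraint pairs restricted to accessions present in the dendrogram
.present_pairs <- function(pairs, labels, warnings, what) {
  if (!nrow(pairs)) return(list(pairs = pairs, warnings = warnings))
  ok <- pairs$a %in% labels & pairs$b %in% labels
  if (any(!ok)) {
    warnings <- c(warnings, paste0(
      what, " constraint(s) skipped (accession absent): ",
      paste(paste(pairs$a[!ok], pairs$b[!ok], sep = "-"), collapse = ", ")))
  }
  list(pairs = pairs[ok, , drop = FALSE], warnings = warnings)
}

#' Run the whole pipeline
#'
#' Stages: parse and merge hits, region exclusions, candidate selection,
#' fragment collapse, TMH sanitization, fingerprint construction,
#' cosine-UPGMA clustering with constrained cutting and a threshold scan,
#' structural-homolog filtering, and orthology extraction. Every
#' intermediate is written as TSV under `out_dir`, plus `manifest.json`.
#' Output is deterministic given identical inputs and seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the run manifest (also written as JSON).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid pipeline config: ", paste(problems, collapse = "; "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  warnings_log <- character(0)
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    message("[slcpipe] ", msg)
  }
  counts <- list()

  hits_raw <- .stage("parse-hits", parse_domtblout(config$hits))
  records <- .stage("parse-records", read_records(config$records))
  hsps <- .stage("parse-hsps", {
    first <- readLines(config$hsps, n = 1)
    if (grepl("query_id", first)) read_table(config$hsps)
    else parse_blast_tab(config$hsps)
  })
  counts$domain_rows <- nrow(hits_raw)
  counts$records_in <- nrow(records)

  merged <- .stage("merge-hits", merge_hits(hits_raw))
  merged <- .stage("region-exclusions", withCallingHandlers(
    apply_region_exclusions(merged, config$thresholds$region_exclusions),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }))
  counts$merged_hits <- nrow(merged)

  candidates <- .stage("select-candidates",
                       select_candidates(merged, config$thresholds))
  counts$candidates <- length(candidates)
  writeLines(candidates, out("candidates.txt"))

  cand_records <- records[records$accession %in% candidates, , drop = FALSE]
  missing_meta <- setdiff(candidates, records$accession)
  if (length(missing_meta)) {
    note(paste0("candidate(s) without metadata dropped: ",
                paste(missing_meta, collapse = ", ")))
    candidates <- setdiff(candidates, missing_meta)
  }
  collapsed <- .stage("collapse", withCallingHandlers(
    collapse_fragments(cand_records, hsps, config$collapse),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }))
  counts$gene_clusters <- length(collapsed$clusters)
  counts$representatives <- length(collapsed$representatives)
  cluster_rows <- data.frame(
    representative = vapply(collapsed$clusters, function(cl)
      if (is.na(cl$representative)) "REVIEW" else cl$representative,
      character(1)),
    members = vapply(collapsed$clusters, function(cl)
      paste(cl$members, collapse = ";"), character(1)),
    evidence = vapply(collapsed$clusters, function(cl)
      paste(sort(cl$evidence), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  write_table(cluster_rows, out("gene_clusters.tsv"))
  write_table(collapsed$review, out("collapse_review.tsv"))

  rep_records <- cand_records[
    cand_records$accession %in% collapsed$representatives, , drop = FALSE]
  san <- .stage("sanitize-tmh", sanitize_by_tmh(rep_records, config$collapse))
  counts$kept_after_tmh <- length(san$kept)
  counts$excluded_tmh <- length(san$excluded)
  counts$tmh_review <- length(san$review)
  writeLines(san$kept, out("kept.txt"))
  writeLines(san$excluded, out("excluded_tmh.txt"))

  fp <- .stage("fingerprints", withCallingHandlers(
    build_fingerprints(merged, san$kept, config$thresholds),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }))
  counts$fingerprint_proteins <- nrow(fp)
  counts$fingerprint_models <- ncol(fp)
  write_fingerprints(fp, out("fingerprints.tsv"))

  fam <- NULL
  if (nrow(fp) >= 2) {
    d <- .stage("cosine-distance", cosine_distance_matrix(fp))
    dend <- .stage("upgma", upgma(d))
    base <- .stage("cut", cut_dendrogram(dend, config$cluster$cut_height))
    jp <- .present_pairs(config$cluster$joins, dend$labels, warnings_log,
                         "join")
    warnings_log <- jp$warnings
    sp <- .present_pairs(config$cluster$splits, dend$labels, warnings_log,
                         "split")
    warnings_log <- sp$warnings
    fam <- .stage("constraints",
                  apply_constraints(dend, base, jp$pairs, sp$pairs))
    counts$families <- length(fam$families)
    write_table(data.frame(
      protein_id = names(fam$membership),
      family = names(fam$families)[fam$membership],
      stringsAsFactors = FALSE), out("families.tsv"))
    write_table(data.frame(
      family = names(fam$families),
      provenance = unname(fam$provenance),
      members = vapply(fam$families, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE), out("family_members.tsv"))
    scan <- .stage("threshold-scan",
                   threshold_scan(dend, config$cluster$scan_heights,
                                  jp$pairs, sp$pairs))
    write_table(scan, out("threshold_scan.tsv"))
    writeLines(dendrogram_newick(dend), out("dendrogram.nwk"))
    write_table(polar_layout(dend, fam), out("polar_layout.tsv"))
  } else {
    note("fewer than 2 fingerprint rows; clustering skipped")
  }

  if (!is.null(config$structural) && !is.null(config$tm)) {
    shits <- .stage("parse-structural", read_structural_hits(config$structural))
    tm <- .stage("parse-tm", read_tm_annotations(config$tm))
    best <- .stage("structural-filter", withCallingHandlers(
      best_structural_homolog(shits, tm, config$struct_min_tm,
                              config$struct_max_e),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      }))
    counts$structural_hits_in <- nrow(shits)
    counts$proteins_with_structure <- nrow(best)
    write_table(best, out("best_structural_homologs.tsv"))
    if (!is.null(fam)) {
      orphans <- structural_orphans(fam, best)
      counts$structural_orphan_families <- length(orphans)
      writeLines(orphans, out("structural_orphans.txt"))
    }
  }

  if (!is.null(config$gene_trees) && !is.null(config$species_tree)) {
    sp_tree <- .stage("parse-species-tree",
                      parse_newick(config$species_tree, is_file = TRUE))
    files <- sort(list.files(config$gene_trees, pattern = "\\.nwk$",
                             full.names = TRUE))
    recs <- .stage("orthology", lapply(files, function(f) {
      root_by_dl(parse_newick(f, is_file = TRUE), sp_tree)
    }))
    names(recs) <- sub("\\.nwk$", "", basename(files))
    counts$gene_trees <- length(recs)
    counts$total_duplications <- sum(vapply(recs, `[[`, integer(1),
                                            "n_duplications"))
    counts$total_losses <- sum(vapply(recs, `[[`, integer(1), "n_losses"))
    mat <- .stage("focal-matrix", focal_matrix(recs, config$focal_species))
    write_table(mat, out("orthology_matrix.tsv"))
  }

  inputs <- Filter(Negate(is.null),
                   config[c("hits", "records", "hsps", "structural", "tm",
                            "species_tree")])
  manifest <- list(
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    parameters = list(
      search_min_bits = config$thresholds$search_min_bits,
      fingerprint_min_bits = config$thresholds$fingerprint_min_bits,
      min_hsp_identity = config$collapse$min_hsp_identity,
      min_tmh = config$collapse$min_tmh,
      cut_height = config$cluster$cut_height,
      scan_heights = config$cluster$scan_heights,
      struct_min_tm = config$struct_min_tm,
      struct_max_e = config$struct_max_e,
      focal_species = config$focal_species,
      seed = config$seed),
    counts = counts,
    warnings = warnings_log)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
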