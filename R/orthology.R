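# Gene-tree / species-tree LCA reconciliation, duplication-loss parsimony
# rooting, and ortholog relation extraction for a focal lineage.

#' The fixed seven-species study tree
#'
#' Rooted binary topology over human, mouse, rat, chicken, zebrafish, fly
#' and worm, with fly and worm as successive outgroups and named ancestral
#' nodes.
#'
#' @return An [ape::phylo] object.
#' @export
study_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((human,(mouse,rat)Rodentia)Mammalia,chicken)Amniota,",
    "zebrafish)Vertebrata,fly)Bilateria,worm)Metazoa;"))
}

# ---- species-tree index ------------------------------------------------------

# parent array, depths and labels for fast LCA queries
.species_index <- function(sp) {
  n <- length(sp$tip.label)
  m <- n + sp$Nnode
  parent <- integer(m)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  root <- setdiff(sp$edge[, 1], sp$edge[, 2])[1]
  parent[root] <- 0L
  depth <- integer(m)
  ord <- ape::reorder.phylo(sp, "postorder")$edge
  for (i in rev(seq_len(nrow(ord)))) {
    depth[ord[i, 2]] <- depth[ord[i, 1]] + 1L
  }
  labels <- c(sp$tip.label,
              if (is.null(sp$node.label)) paste0("anc", seq_len(sp$Nnode))
              else sp$node.label)
  kids <- split(sp$edge[, 2], sp$edge[, 1])
  list(tree = sp, parent = parent, depth = depth, root = root,
       labels = labels, children = kids, n_tip = n)
}

.sp_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

# TRUE when a is an ancestor of b or equal to it
.sp_ancestor_of <- function(idx, a, b) .sp_lca(idx, a, b) == a

# species nodes on the path from `from` (exclusive) down to `to` (exclusive)
.sp_between <- function(idx, from, to) {
  out <- integer(0)
  v <- idx$parent[to]
  while (v != from && v != 0L) {
    out <- c(out, v)
    v <- idx$parent[v]
  }
  rev(out)
}

# child of species node v that is NOT on the path towards descendant d
.sp_offpath_child <- function(idx, v, d) {
  kids <- idx$children[[as.character(v)]]
  on_path <- vapply(kids, function(k) .sp_ancestor_of(idx, k, d), logical(1))
  kids[!on_path]
}

# ---- reconciliation ----------------------------------------------------------

#' Reconcile a rooted gene tree with the species tree (LCA mapping)
#'
#' Each gene-tree node is mapped to the lowest species-tree node containing
#' all its descendant species. An internal node is a duplication when the
#' mapped species subtrees of two of its children overlap (for a binary
#' node: a child maps to the same species node as the parent); otherwise it
#' is a speciation. Losses are inferred per gene-tree edge: one loss for
#' every species node strictly between the parent and child maps, plus one
#' at the parent's node when the parent is a duplication whose child maps
#' strictly below it.
#'
#' @param gene_tree Rooted [ape::phylo]; leaf labels `gene<delim>species`.
#' @param species_tree Rooted [ape::phylo] over the species.
#' @param delim Delimiter in composite leaf labels.
#' @return A `reconciled_gene_tree`: list with the trees, `leaf_info`,
#'   `map` (gene node -> species node), `events` (internal nodes:
#'   `"duplication"`/`"speciation"`), `losses` (data.frame `edge_child`,
#'   `species_node`, `species_label`), `n_duplications`, `n_losses`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, delim = "__") {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  idx <- .species_index(species_tree)
  info <- split_leaf_labels(gene_tree$tip.label, delim)
  sp_of_leaf <- match(info$species, species_tree$tip.label)
  if (anyNA(sp_of_leaf)) {
    stop("species not in species tree: ",
         paste(unique(info$species[is.na(sp_of_leaf)]), collapse = ", "))
  }
  ng <- length(gene_tree$tip.label)
  mg <- ng + gene_tree$Nnode
  map <- integer(mg)
  map[seq_len(ng)] <- sp_of_leaf
  post <- ape::reorder.phylo(gene_tree, "postorder")$edge
  kids <- split(post[, 2], post[, 1])
  # accumulate maps edge by edge: postorder guarantees a child's subtree is
  # complete before its parent edge is seen
  for (i in seq_len(nrow(post))) {
    u <- post[i, 1]; v <- post[i, 2]
    map[u] <- if (map[u] == 0L) map[v] else .sp_lca(idx, map[u], map[v])
  }
  events <- rep(NA_character_, mg)
  for (v in unique(post[, 1])) {
    ch <- kids[[as.character(v)]]
    dup <- FALSE
    for (i in seq_along(ch)) {
      for (j in seq_along(ch)) {
        if (i < j && (.sp_ancestor_of(idx, map[ch[i]], map[ch[j]]) ||
                      .sp_ancestor_of(idx, map[ch[j]], map[ch[i]]))) {
          dup <- TRUE
        }
      }
    }
    events[v] <- if (dup) "duplication" else "speciation"
  }
  losses <- data.frame(edge_child = integer(0), species_node = integer(0),
                       species_label = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    if (map[u] == map[v]) next
    lost_at <- integer(0)
    for (s in .sp_between(idx, map[u], map[v])) {
      lost_at <- c(lost_at, .sp_offpath_child(idx, s, map[v]))
    }
    if (events[u] == "duplication") {
      lost_at <- c(.sp_offpath_child(idx, map[u], map[v]), lost_at)
    }
    if (length(lost_at)) {
      losses <- rbind(losses, data.frame(
        edge_child = v, species_node = lost_at,
        species_label = idx$labels[lost_at], stringsAsFactors = FALSE))
    }
  }
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 leaf_info = info, map = map, events = events,
                 losses = losses,
                 n_duplications = sum(events == "duplication", na.rm = TRUE),
                 n_losses = nrow(losses)),
            class = "reconciled_gene_tree")
}

#' @export
print.reconciled_gene_tree <- function(x, ...) {
  cat("reconciled gene tree:", length(x$gene_tree$tip.label), "leaves,",
      x$n_duplications, "duplication(s),", x$n_losses, "inferred loss(es)\n")
  invisible(x)
}

# tips below each edge's child node of an unrooted tree
.edge_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (i in seq_len(nrow(post))) {
    u <- post[i, 1]; v <- post[i, 2]
    below[[u]] <- c(below[[u]], below[[v]])
  }
  lapply(seq_len(nrow(tree$edge)), function(i)
    sort(tree$tip.label[below[[tree$edge[i, 2]]]]))
}

#' Root a gene tree by duplication-loss parsimony
#'
#' Every edge of the unrooted tree is evaluated as a root position; the
#' rooting minimizing duplications + losses wins, with ties broken by
#' fewest duplications and then by the lexicographically smallest split
#' (the sorted tip set of the root child not containing the overall
#' smallest leaf label).
#'
#' @param gene_tree Unrooted (or rooted) [ape::phylo].
#' @param species_tree Rooted species tree.
#' @param delim Leaf-label delimiter.
#' @return The selected rooted `reconciled_gene_tree`.
#' @export
root_by_dl <- function(gene_tree, species_tree, delim = "__") {
  n <- length(gene_tree$tip.label)
  if (n < 3) {
    rt <- if (ape::is.rooted(gene_tree)) gene_tree
          else ape::root(gene_tree, outgroup = gene_tree$tip.label[1],
                         resolve.root = TRUE)
    return(lca_reconcile(rt, species_tree, delim))
  }
  ut <- if (ape::is.rooted(gene_tree)) ape::unroot(gene_tree) else gene_tree
  tipsets <- .edge_tipsets(ut)
  smallest <- min(ut$tip.label)
  best <- NULL
  for (ts in unique(tipsets)) {
    if (length(ts) == n) next
    rt <- ape::root(ut, outgroup = ts, resolve.root = TRUE)
    rec <- lca_reconcile(rt, species_tree, delim)
    side <- if (smallest %in% ts) sort(setdiff(ut$tip.label, ts)) else ts
    key <- paste(side, collapse = "|")
    score <- c(rec$n_duplications + rec$n_losses, rec$n_duplications)
    if (is.null(best) ||
        score[1] < best$score[1] ||
        (score[1] == best$score[1] && score[2] < best$score[2]) ||
        (all(score == best$score) && key < best$key)) {
      best <- list(rec = rec, score = score, key = key)
    }
  }
  best$rec
}

#' Ortholog pairs of a reconciled gene tree
#'
#' Two genes from different species are orthologs iff their gene-tree LCA
#' is a speciation node.
#'
#' @param rec A `reconciled_gene_tree`.
#' @return Data.frame `gene1`, `gene2`, `species1`, `species2` (pairs
#'   ordered lexicographically by label).
#' @export
ortholog_pairs <- function(rec) {
  tr <- rec$gene_tree
  n <- length(tr$tip.label)
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      species1 = character(0), species2 = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  lca <- ape::mrca(tr)
  info <- rec$leaf_info
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (info$species[i] == info$species[j]) next
      if (rec$events[lca[i, j]] != "speciation") next
      a <- tr$tip.label[i]; b <- tr$tip.label[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp
                   si <- info$species[j]; sj <- info$species[i]
      } else { si <- info$species[i]; sj <- info$species[j] }
      out[[length(out) + 1L]] <- data.frame(
        gene1 = a, gene2 = b, species1 = si, species2 = sj,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$gene1, res$gene2), , drop = FALSE]
}

#' Ortholog relation matrix for a focal lineage
#'
#' For each focal-species gene g and each other species S, let k be the
#' number of S-orthologs of g and m the number of focal genes sharing at
#' least one of those orthologs. Categories: `none` (k = 0), `one_to_one`
#' (k = 1, m = 1), `one_to_many` (k > 1, m = 1: the focal gene has several
#' orthologs), `many_to_one` (k = 1, m > 1: several focal genes share one
#' ortholog), `many_to_many` otherwise (duplications in both lineages;
#' flagged). Clusters with no surviving focal gene yield a
#' `lost_in_focal` row.
#'
#' @param rec_trees Named list of `reconciled_gene_tree` objects (one per
#'   gene cluster).
#' @param focal_species Focal species name (default `"human"`).
#' @return Data.frame `cluster`, `focal_gene`, `species`, `category`,
#'   `n_orthologs`.
#' @export
focal_matrix <- function(rec_trees, focal_species = "human") {
  if (is.null(names(rec_trees))) {
    names(rec_trees) <- sprintf("cluster%03d", seq_along(rec_trees))
  }
  rows <- list()
  for (cl in names(rec_trees)) {
    rec <- rec_trees[[cl]]
    info <- rec$leaf_info
    other_species <- setdiff(unique(rec$species_tree$tip.label),
                             focal_species)
    focal <- info$label[info$species == focal_species]
    if (!length(focal)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, focal_gene = NA_character_, species = NA_character_,
        category = "lost_in_focal", n_orthologs = 0L,
        stringsAsFactors = FALSE)
      next
    }
    op <- ortholog_pairs(rec)
    orth_of <- function(g, S) {
      a <- op$gene2[op$gene1 == g & op$species2 == S]
      b <- op$gene1[op$gene2 == g & op$species1 == S]
      unique(c(a, b))
    }
    for (g in sort(focal)) {
      for (S in other_species) {
        mine <- orth_of(g, S)
        k <- length(mine)
        if (k == 0L) {
          cat_ <- "none"
        } else {
          sharers <- vapply(focal, function(g2)
            length(intersect(orth_of(g2, S), mine)) > 0, logical(1))
          m <- sum(sharers)
          cat_ <- if (k == 1L && m == 1L) "one_to_one"
                  else if (k > 1L && m == 1L) "one_to_many"
                  else if (k == 1L && m > 1L) "many_to_one"
                  else "many_to_many"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, focal_gene = g, species = S, category = cat_,
          n_orthologs = k, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
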