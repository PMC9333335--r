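# Cosine-distance UPGMA over HMM fingerprints, threshold cutting with
# join/split constraints, threshold scans and the radial layout transform.
# This is the analytical core of the pipeline and is implemented here rather
# than delegated: merge heights are the unhalved average inter-cluster
# distances so that "cut at 0.7 cosine distance" compares like with like,
# and merge ties are broken lexicographically for cross-platform determinism.

#' Clustering configuration
#'
#' Defaults encode the study settings: cosine distance, tree cut at 0.7,
#' scan heights 0.6/0.7/0.8, plus the eight join and five split constraint
#' pairs used to keep known transporter families together or apart. The
#' constraint pairs are given as gene symbols; when clustering other data
#' sets supply pairs of your own accessions (or empty data.frames).
#'
#' @param cut_height Tree cut height in cosine distance (strict `<`).
#' @param scan_heights Heights for [threshold_scan()].
#' @param joins,splits Two-column data.frames (or 2-col matrices) of
#'   accession pairs forced together / apart.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(cut_height = 0.7,
                           scan_heights = c(0.6, 0.7, 0.8),
                           joins = default_join_pairs(),
                           splits = default_split_pairs()) {
  stopifnot(cut_height > 0, cut_height < 2)
  joins <- .as_pairs(joins)
  splits <- .as_pairs(splits)
  both <- intersect(.pair_keys(joins), .pair_keys(splits))
  if (length(both)) {
    stop("pair(s) present in both joins and splits: ",
         paste(both, collapse = ", "))
  }
  structure(list(metric = "cosine", cut_height = cut_height,
                 scan_heights = scan_heights, joins = joins, splits = splits),
            class = "cluster_config")
}

.as_pairs <- function(p) {
  if (is.null(p)) return(data.frame(a = character(0), b = character(0)))
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  stopifnot(ncol(p) == 2)
  names(p) <- c("a", "b")
  p$a <- as.character(p$a); p$b <- as.character(p$b)
  p
}

.pair_keys <- function(p) {
  if (!nrow(p)) return(character(0))
  apply(p, 1, function(r) paste(sort(r), collapse = "|"))
}

#' Default join constraint pairs (gene symbols)
#' @return Two-column data.frame of gene-symbol pairs forced together.
#' @export
default_join_pairs <- function() {
  data.frame(
    a = c("SLC5A1", "SLC9A1", "SLC10A1", "SLC25A1", "SLC30A1", "SLC35C1",
          "SLC39A1", "SLC66A1"),
    b = c("SLC5A7", "SLC9B1", "SLC10A7", "SLC25A46", "SLC30A9", "SLC35G1",
          "SLC39A9", "SLC66A5"),
    stringsAsFactors = FALSE)
}

#' Default split constraint pairs (gene symbols)
#' @return Two-column data.frame of gene-symbol pairs forced apart.
#' @export
default_split_pairs <- function() {
  data.frame(
    a = c("SLC2A1", "SLC17A1", "SLC17A1", "SLC32A1", "SLC32A1"),
    b = c("SLC22A1", "SLC18A1", "SLC37A1", "SLC36A1", "SLC38A1"),
    stringsAsFactors = FALSE)
}

#' Cosine distance matrix of fingerprint rows
#'
#' d(i, j) = 1 - x_i.x_j / (||x_i|| ||x_j||). All fingerprint entries are
#' nonnegative, so distances lie in [0, 1].
#'
#' @param fp Fingerprint matrix (rows = proteins).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
cosine_distance_matrix <- function(fp) {
  fp <- as.matrix(fp)
  nrm <- sqrt(rowSums(fp^2))
  if (any(nrm == 0)) {
    stop("zero-norm fingerprint row(s): ",
         paste(rownames(fp)[nrm == 0], collapse = ", "))
  }
  s <- tcrossprod(fp / nrm)
  d <- 1 - s
  d[d < 0] <- 0          # guard rounding
  diag(d) <- 0
  (d + t(d)) / 2
}

#' UPGMA (average linkage) agglomeration
#'
#' Merge heights are the unhalved average inter-cluster distance at the
#' merge. When several pairs tie at the minimal distance, the pair whose
#' clusters have the lexicographically smallest minimum-member labels is
#' merged (smallest first label, then smallest second), giving a
#' deterministic tree on any input.
#'
#' @param d Symmetric distance matrix with zero diagonal (labelled).
#' @return Object of class `fp_dendrogram`: list with `merges` (two-column
#'   matrix in hclust convention: negative = leaf index, positive = earlier
#'   merge row), `heights`, and `labels`. A single leaf yields zero merges.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  dend <- structure(list(merges = matrix(integer(0), 0, 2),
                         heights = numeric(0), labels = labels),
                    class = "fp_dendrogram")
  if (n < 2) return(dend)

  # active clusters: id (negative leaf / positive merge row), size, min label
  work <- d
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minlab <- labels
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(ids)
    dm <- min(work[upper.tri(work)])
    cand <- which(upper.tri(work) & work <= dm + 0, arr.ind = TRUE)
    cand <- cand[work[cand] == dm, , drop = FALSE]
    # order each candidate pair by member labels, pick lexicographic smallest
    key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- min(cand[pick, ]); j <- max(cand[pick, ])

    merges[step, ] <- c(ids[i], ids[j])
    heights[step] <- dm
    # Lance-Williams average-linkage update
    new_row <- (sizes[i] * work[i, ] + sizes[j] * work[j, ]) /
      (sizes[i] + sizes[j])
    work[i, ] <- new_row
    work[, i] <- new_row
    work[i, i] <- 0
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
    keep <- setdiff(seq_len(m), j)
    work <- work[keep, keep, drop = FALSE]
    ids <- ids[keep]; sizes <- sizes[keep]; minlab <- minlab[keep]
  }
  dend$merges <- merges
  dend$heights <- heights
  dend
}

#' @export
print.fp_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram:", length(x$labels), "leaves,",
      nrow(x$merges), "merges\n")
  if (length(x$heights)) {
    cat("merge heights:", paste(signif(head(x$heights, 5), 4),
                                collapse = ", "),
        if (length(x$heights) > 5) "...\n" else "\n")
  }
  invisible(x)
}

#' Convert an fp_dendrogram to an hclust object
#' @param dend An `fp_dendrogram`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(dend) {
  n <- length(dend$labels)
  stopifnot(n >= 2)
  structure(list(merge = dend$merges, height = dend$heights,
                 order = .dend_order(dend), labels = dend$labels,
                 method = "average", dist.method = "cosine"),
            class = "hclust")
}

.dend_order <- function(dend) {
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(dend$merges[node, 1]), leaves_of(dend$merges[node, 2]))
  }
  if (!nrow(dend$merges)) return(seq_along(dend$labels))
  leaves_of(nrow(dend$merges))
}

# leaf indices under a merge row (or a single leaf for negative ids)
.leaves_under <- function(dend, node) {
  if (node < 0) return(-node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd < 0) out <- c(out, -nd)
    else stack <- c(dend$merges[nd, 1], dend$merges[nd, 2], stack)
  }
  out
}

#' Cut a dendrogram at a height
#'
#' Families are the groups connected by merges with height strictly below
#' `h`; merges at exactly `h` are not applied.
#'
#' @param dend An `fp_dendrogram`.
#' @param h Cut height.
#' @return A `family_assignment`: list with `membership` (named integer
#'   vector protein -> family id), `families` (list of member vectors) and
#'   `provenance` (per family: `"base"`, `"join"` or `"split"`).
#' @export
cut_dendrogram <- function(dend, h) {
  n <- length(dend$labels)
  comp <- seq_len(n)
  applied <- which(dend$heights < h)
  for (s in applied) {
    kids <- dend$merges[s, ]
    l1 <- .leaves_under(dend, kids[1])[1]
    l2 <- .leaves_under(dend, kids[2])[1]
    c1 <- comp[l1]; c2 <- comp[l2]
    comp[comp == c2] <- c1
  }
  .make_assignment(dend$labels, comp, "base")
}

.make_assignment <- function(labels, comp, prov_default,
                             prov_by_comp = NULL) {
  fam_ids <- match(comp, sort(unique(comp)))
  # renumber by smallest member label for determinism
  first_label <- tapply(labels, fam_ids, min)
  remap <- match(names(sort(first_label)), names(first_label))
  fam_ids <- match(fam_ids, remap)
  membership <- stats::setNames(fam_ids, labels)
  families <- split(labels, fam_ids)
  names(families) <- paste0("F", sprintf("%03d", as.integer(names(families))))
  names(membership) <- labels
  prov <- rep(prov_default, length(families))
  if (!is.null(prov_by_comp)) prov <- prov_by_comp
  structure(list(membership = membership, families = families,
                 provenance = stats::setNames(prov, names(families))),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("family assignment:", length(x$families), "families,",
      length(x$membership), "proteins\n")
  invisible(x)
}

# merge-row LCA of two leaves (by label)
.dend_lca <- function(dend, a, b) {
  ia <- match(a, dend$labels); ib <- match(b, dend$labels)
  if (is.na(ia) || is.na(ib)) {
    stop("constraint accession(s) not in dendrogram: ",
         paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  }
  for (s in seq_len(nrow(dend$merges))) {
    lv <- .leaves_under(dend, s)
    if (ia %in% lv && ib %in% lv) return(s)
  }
  stop("no common ancestor for ", a, " and ", b)   # unreachable on one tree
}

#' Apply join/split constraints to a base family assignment
#'
#' A join on (p, q) already co-clustered is a no-op; otherwise the whole
#' leaf set under their dendrogram LCA becomes one family (the cut is
#' raised just above that node). A split on (p, q) already separated is a
#' no-op; otherwise the family containing both is re-cut strictly below the
#' LCA's merge height, separating the LCA's two child clades (and any
#' family members attached above them). All splits are applied first, then
#' all joins, then every constraint is verified; violations raise an error
#' listing the offending pairs.
#'
#' @param dend The `fp_dendrogram` the base assignment was cut from.
#' @param base A `family_assignment` from [cut_dendrogram()].
#' @param joins,splits Two-column data.frames of accession pairs.
#' @return A `family_assignment` with provenance `"join"`/`"split"` on
#'   modified families.
#' @export
apply_constraints <- function(dend, base, joins = NULL, splits = NULL) {
  joins <- .as_pairs(joins)
  splits <- .as_pairs(splits)
  labels <- dend$labels
  comp <- base$membership[labels]          # working component ids
  touched <- stats::setNames(rep("base", length(labels)), labels)

  for (k in seq_len(nrow(splits))) {
    p <- splits$a[k]; q <- splits$b[k]
    if (comp[p] != comp[q]) next
    lca <- .dend_lca(dend, p, q)
    h_lca <- dend$heights[lca]
    fam_members <- which(comp == comp[p])
    # re-cut this family's members at the LCA height (strict <)
    local <- stats::setNames(seq_along(fam_members), labels[fam_members])
    for (s in which(dend$heights < h_lca)) {
      lv <- .leaves_under(dend, s)
      lv <- lv[labels[lv] %in% names(local)]
      if (length(lv) < 2) next
      tgt <- local[labels[lv[1]]]
      local[labels[lv]] <- tgt
    }
    offset <- max(comp)
    comp[fam_members] <- offset + match(local, unique(local))
    touched[fam_members] <- "split"
  }

  for (k in seq_len(nrow(joins))) {
    p <- joins$a[k]; q <- joins$b[k]
    if (comp[p] == comp[q]) next
    lca <- .dend_lca(dend, p, q)
    lv <- .leaves_under(dend, lca)
    # absorb every component intersecting the LCA clade
    comps_in <- unique(comp[lv])
    sel <- comp %in% comps_in
    comp[sel] <- comp[lv[1]]
    touched[sel] <- "join"
  }

  # verification
  bad <- character(0)
  for (k in seq_len(nrow(joins))) {
    if (comp[joins$a[k]] != comp[joins$b[k]]) {
      bad <- c(bad, paste0("join ", joins$a[k], "-", joins$b[k]))
    }
  }
  for (k in seq_len(nrow(splits))) {
    if (comp[splits$a[k]] == comp[splits$b[k]]) {
      bad <- c(bad, paste0("split ", splits$a[k], "-", splits$b[k]))
    }
  }
  if (length(bad)) {
    stop("constraint conflict; unsatisfied after application: ",
         paste(bad, collapse = "; "))
  }
  out <- .make_assignment(labels, comp, "base")
  # provenance keyed by each family's smallest member, robust to renumbering
  prov_by_first <- stats::setNames(
    vapply(split(touched, comp[labels]), function(tt) {
      if (any(tt == "join")) "join"
      else if (any(tt == "split")) "split" else "base"
    }, character(1)),
    vapply(split(labels, comp[labels]), min, character(1)))
  first_member <- vapply(out$families, min, character(1))
  out$provenance[] <- prov_by_first[first_member]
  out
}

#' Family counts across a set of cut heights
#'
#' @param dend An `fp_dendrogram`.
#' @param heights Numeric vector of cut heights.
#' @param joins,splits Constraint pairs applied at every height.
#' @return Data.frame with columns `height` and `n_families`. Counts are
#'   non-increasing in height when no constraints are given.
#' @export
threshold_scan <- function(dend, heights, joins = NULL, splits = NULL) {
  if (!length(heights)) {
    return(data.frame(height = numeric(0), n_families = integer(0)))
  }
  n <- vapply(heights, function(h) {
    fa <- cut_dendrogram(dend, h)
    fa <- apply_constraints(dend, fa, joins, splits)
    length(fa$families)
  }, integer(1))
  data.frame(height = heights, n_families = n)
}

#' Radial layout transform for polar dendrogram plots
#'
#' d' = 0.5 + arcsin(2d - 1) / pi, a strictly increasing bijection of
#' [0, 1] that magnifies detail near d = 0 and d = 1.
#'
#' @param d Numeric vector in [0, 1].
#' @return Transformed values in [0, 1].
#' @export
radial_transform <- function(d) {
  if (any(d < 0 | d > 1, na.rm = TRUE)) {
    stop("radial_transform: input outside [0, 1]")
  }
  0.5 + asin(2 * d - 1) / pi
}

#' Inverse of [radial_transform()]
#' @param dp Numeric vector in [0, 1].
#' @return Values d with `radial_transform(d) == dp`.
#' @export
radial_inverse <- function(dp) {
  if (any(dp < 0 | dp > 1, na.rm = TRUE)) {
    stop("radial_inverse: input outside [0, 1]")
  }
  (1 + sin(pi * (dp - 0.5))) / 2
}

#' Export a dendrogram as Newick with merge heights as node depths
#'
#' @param dend An `fp_dendrogram`.
#' @return Newick string.
#' @export
dendrogram_newick <- function(dend) {
  n <- length(dend$labels)
  if (n == 1) return(paste0(dend$labels, ";"))
  height_of <- function(node) if (node < 0) 0 else dend$heights[node]
  build <- function(node) {
    if (node < 0) return(dend$labels[-node])
    h <- dend$heights[node]
    kids <- dend$merges[node, ]
    paste0("(",
           build(kids[1]), ":", format(h - height_of(kids[1]), digits = 10),
           ",",
           build(kids[2]), ":", format(h - height_of(kids[2]), digits = 10),
           ")")
  }
  paste0(build(nrow(dend$merges)), ";")
}

#' Polar layout coordinates for a cut dendrogram
#'
#' Leaves are placed at equal angles in dendrogram order; the radial
#' coordinate is `1 - h` (leaves at radius 1) transformed by
#' [radial_transform()].
#'
#' @param dend An `fp_dendrogram`.
#' @param assignment Optional `family_assignment` to attach family ids.
#' @return Data.frame `label`, `angle` (radians), `radius`, `family`.
#' @export
polar_layout <- function(dend, assignment = NULL) {
  ord <- .dend_order(dend)
  n <- length(dend$labels)
  ang <- stats::setNames(2 * pi * (seq_len(n) - 1) / n, dend$labels[ord])
  out <- data.frame(label = dend$labels[ord],
                    angle = as.numeric(ang),
                    radius = radial_transform(rep(1, n)),
                    stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    out$family <- names(assignment$families)[assignment$membership[out$label]]
  }
  out
}
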