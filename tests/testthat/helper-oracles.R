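# Independent oracles used across the suite. These deliberately recompute
# quantities from first principles (naive averaging, transitive closure,
# pairwise LCA lookups) rather than sharing code with the implementation.

# Exhaustive average-linkage agglomeration: at every step the inter-cluster
# distance is recomputed from the raw matrix by averaging over all member
# pairs (no Lance-Williams update). Tie-break mirrors the documented rule.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  clusters <- lapply(seq_len(n), function(i) i)   # member leaf indices
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  avg_dist <- function(a, b) {
    mean(d[clusters[[a]], clusters[[b]], drop = FALSE])
  }
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dv <- avg_dist(i, j)
        k1 <- min(labels[clusters[[i]]][1], labels[clusters[[j]]][1])
        lab_i <- min(labels[clusters[[i]]])
        lab_j <- min(labels[clusters[[j]]])
        key <- c(min(lab_i, lab_j), max(lab_i, lab_j))
        if (is.null(best) || dv < best$d - 1e-12 ||
            (abs(dv - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dv, key = key)
        }
      }
    }
    merges[step, ] <- c(ids[best$i], ids[best$j])
    heights[step] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(merges = merges, heights = heights, labels = labels)
}

# Warshall-style transitive closure of an undirected edge list
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  if (nrow(edges)) {
    ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
    reach[cbind(ia, ib)] <- TRUE
    reach[cbind(ib, ia)] <- TRUE
  }
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  out <- lapply(split(nodes, comp), sort)
  unname(out[order(vapply(out, `[`, character(1), 1L))])
}

# brute-force structural acceptance: literal re-count of contained segments
oracle_accept <- function(evalue, aln_from, aln_to, seg, min_tm = 3,
                          max_e = 1e-4) {
  if (is.null(seg)) return(FALSE)
  cov <- 0L
  for (r in seq_len(nrow(seg))) {
    if (seg[r, 1] >= aln_from && seg[r, 2] <= aln_to) cov <- cov + 1L
  }
  cov >= min_tm && evalue < max_e
}

# brute-force ortholog pairs: for every leaf pair, walk to the root from
# both leaves to find the LCA, then look up its event label
oracle_ortholog_pairs <- function(rec) {
  tr <- rec$gene_tree
  n <- length(tr$tip.label)
  parent <- integer(n + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  ancestors <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  info <- rec$leaf_info
  pairs <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j || info$species[i] == info$species[j]) next
      anc_i <- ancestors(i)
      lca <- anc_i[match(TRUE, anc_i %in% ancestors(j))]
      if (rec$events[lca] == "speciation") {
        a <- sort(c(tr$tip.label[i], tr$tip.label[j]))
        pairs <- c(pairs, paste(a, collapse = "~"))
      }
    }
  }
  sort(pairs)
}

# exhaustive loss enumeration for a reconciled tree: for each gene-tree
# edge, enumerate the full species path and count skipped branches
oracle_loss_count <- function(rec) {
  sp <- rec$species_tree
  m <- length(sp$tip.label) + sp$Nnode
  parent <- integer(m)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  depth <- function(v) {
    d <- 0L
    while (parent[v] != 0L) { v <- parent[v]; d <- d + 1L }
    d
  }
  total <- 0L
  for (i in seq_len(nrow(rec$gene_tree$edge))) {
    u <- rec$gene_tree$edge[i, 1]; v <- rec$gene_tree$edge[i, 2]
    steps <- depth(rec$map[v]) - depth(rec$map[u])
    if (steps <= 0) next
    dup <- rec$events[u] == "duplication"
    total <- total + steps - 1L + as.integer(dup)
  }
  total
}

# random distance matrix with labelled rows
random_dist <- function(n, labels = sprintf("P%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  v <- runif(n * (n - 1) / 2, 0.05, 1)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  d
}

# random satisfiable join/split constraint set for a dendrogram + base cut:
# the join is chosen first and the split pair is drawn from a family fully
# disjoint from the join pair's LCA clade, so neither operation can cascade
# into the other
build_satisfiable_constraints <- function(dd, base) {
  fams <- base$families
  joins <- splits <- NULL
  join_leaves <- character(0)
  if (length(fams) >= 2) {
    pick <- sample(length(fams), 2)
    joins <- data.frame(a = sample(fams[[pick[1]]], 1),
                        b = sample(fams[[pick[2]]], 1))
    lca <- slcpipe:::.dend_lca(dd, joins$a, joins$b)
    join_leaves <- dd$labels[slcpipe:::.leaves_under(dd, lca)]
  }
  big <- fams[lengths(fams) >= 2 &
                !vapply(fams, function(m) any(m %in% join_leaves),
                        logical(1))]
  if (length(big)) {
    mem <- sample(big, 1)[[1]]
    pr <- sample(mem, 2)
    splits <- data.frame(a = pr[1], b = pr[2])
  }
  list(joins = joins, splits = splits)
}

# random gene tree over a species set, as a Newick string with unique genes
random_gene_tree <- function(n_leaves, species, prefix = "g") {
  labs <- sprintf("%s%02d__%s", prefix, seq_len(n_leaves),
                  sample(species, n_leaves, replace = TRUE))
  tr <- ape::rtree(n_leaves, tip.label = labs, br = NULL)
  tr$node.label <- NULL
  tr
}
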