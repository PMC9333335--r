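test_that("cosine distance matches hand-evaluated cases", {
  fp <- rbind(a = c(3, 4), b = c(4, 3), c = c(3, 4), d = c(1, 0),
              e = c(0, 1))
  d <- cosine_distance_matrix(fp)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["d", "e"], 1)
  expect_equal(d["a", "b"], 1 - 24 / 25)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 5), rownames(fp)))
  expect_error(cosine_distance_matrix(rbind(a = c(1, 1), z = c(0, 0))),
               "zero-norm.*z")
})

test_that("UPGMA agglomerates the documented 3-leaf example", {
  d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d)
  expect_equal(dd$heights, c(0.2, 0.8))
  expect_equal(dd$merges[1, ], c(-1L, -2L))
  expect_equal(sort(dd$merges[2, ]), c(-3L, 1L))
})

test_that("UPGMA recovers ultrametric heights and matches brute force", {
  # ultrametric 4x4: ((A,B):0.1, (C,D):0.3):0.6
  lab <- c("A", "B", "C", "D")
  d <- matrix(0.6, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["C", "D"] <- d["D", "C"] <- 0.3
  diag(d) <- 0
  dd <- upgma(d)
  expect_equal(sort(dd$heights), c(0.1, 0.3, 0.6))

  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    dm <- random_dist(n)
    got <- upgma(dm)
    want <- oracle_upgma(dm)
    expect_equal(got$merges, want$merges)
    expect_equal(got$heights, want$heights, tolerance = 1e-12)
  }
})

test_that("UPGMA cophenetic heights agree with hclust average linkage", {
  set.seed(31)
  for (rep in 1:10) {
    dm <- random_dist(7)
    got <- as_hclust(upgma(dm))
    ref <- stats::hclust(stats::as.dist(dm), method = "average")
    expect_equal(sort(got$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(
      as.matrix(stats::cophenetic(got))[rownames(dm), rownames(dm)],
      as.matrix(stats::cophenetic(ref))[rownames(dm), rownames(dm)],
      tolerance = 1e-12)
  }
})

test_that("cutting applies merges strictly below the threshold", {
  d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d)
  expect_equal(cut_dendrogram(dd, 0.7)$families,
               list(F001 = c("A", "B"), F002 = "C"))
  expect_length(cut_dendrogram(dd, 0)$families, 3)
  expect_length(cut_dendrogram(dd, 0.2)$families, 3)  # merge AT h not applied
  expect_length(cut_dendrogram(dd, 1)$families, 1)
})

test_that("join raises and split lowers the cut at the pair's LCA", {
  d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d)
  base <- cut_dendrogram(dd, 0.7)

  joined <- apply_constraints(dd, base, joins = data.frame(a = "A", b = "C"))
  expect_equal(joined$families, list(F001 = c("A", "B", "C")))
  expect_equal(unname(joined$provenance["F001"]), "join")

  split_ <- apply_constraints(dd, base, splits = data.frame(a = "A", b = "B"))
  expect_equal(split_$families, list(F001 = "A", F002 = "B", F003 = "C"))
  expect_equal(unname(split_$provenance[c("F001", "F002")]),
               c("split", "split"))

  # no-op branches
  expect_equal(apply_constraints(dd, base,
                                 joins = data.frame(a = "A", b = "B"))$families,
               base$families)
  expect_equal(apply_constraints(dd, base,
                                 splits = data.frame(a = "A", b = "C"))$families,
               base$families)

  # conflicting set raises with the offending constraint named
  expect_error(
    apply_constraints(dd, base, joins = data.frame(a = "A", b = "B"),
                      splits = data.frame(a = "A", b = "B")),
    "conflict.*A-B")
})

test_that("random satisfiable constraints end co-assigned/separated", {
  set.seed(57)
  for (rep in 1:50) {
    n <- sample(6:12, 1)
    dm <- random_dist(n)
    dd <- upgma(dm)
    h <- stats::median(dd$heights)
    base <- cut_dendrogram(dd, h)
    cs <- build_satisfiable_constraints(dd, base)
    joins <- cs$joins; splits <- cs$splits
    fa <- apply_constraints(dd, base, joins, splits)
    if (!is.null(joins)) {
      expect_equal(fa$membership[joins$a], fa$membership[joins$b],
                   ignore_attr = TRUE)
    }
    if (!is.null(splits)) {
      expect_false(fa$membership[splits$a] == fa$membership[splits$b])
    }
    # provenance recorded and partition preserved
    expect_setequal(unlist(fa$families), dd$labels)
    expect_true(all(fa$provenance %in% c("base", "join", "split")))
  }
})

test_that("family counts are non-increasing in the cut height", {
  set.seed(73)
  for (rep in 1:10) {
    dm <- random_dist(sample(5:10, 1))
    dd <- upgma(dm)
    tab <- threshold_scan(dd, c(0.6, 0.7, 0.8))
    expect_true(all(diff(tab$n_families) <= 0))
  }
  expect_equal(nrow(threshold_scan(upgma(random_dist(4)), numeric(0))), 0)
})

test_that("noise-free synthetic data yields the planted family count at all scan heights", {
  cfg <- sim_config(n_families = 6, proteins_per_family = 4,
                    noise_hit_rate = 0, seed = 8)
  sim <- simulate_hits(cfg)
  m <- merge_hits(sim$hits)
  fp <- build_fingerprints(m, select_candidates(m))
  dd <- upgma(cosine_distance_matrix(fp))
  tab <- threshold_scan(dd, c(0.6, 0.7, 0.8))
  expect_equal(tab$n_families, rep(6L, 3))
})

test_that("radial transform has the exact fixed points and is monotone", {
  expect_identical(radial_transform(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(radial_transform(0.25), 1 / 3, tolerance = 1e-12)
  g <- seq(0, 1, length.out = 1000)
  expect_true(all(diff(radial_transform(g)) > 0))
  expect_equal(radial_inverse(radial_transform(g)), g, tolerance = 1e-12)
  expect_error(radial_transform(1.01), "outside")
  expect_error(radial_inverse(-0.01), "outside")
})

test_that("UPGMA heights are monotone along the merge sequence", {
  set.seed(91)
  for (rep in 1:20) {
    dd <- upgma(random_dist(sample(4:9, 1)))
    expect_true(all(diff(dd$heights) >= -1e-12))
  }
})

test_that("dendrogram Newick export preserves cophenetic structure", {
  set.seed(13)
  dm <- random_dist(6)
  dd <- upgma(dm)
  tr <- ape::read.tree(text = dendrogram_newick(dd))
  # root-to-tip depth equals half... depths here are merge heights directly
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(depths), rep(max(dd$heights), 6), tolerance = 1e-8)
})
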