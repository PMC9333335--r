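.make_tm <- function(k) {
  if (k == 0) return(NULL)
  start <- 10L + 35L * (seq_len(k) - 1L)
  cbind(start = start, end = start + 20L)
}

mk_records <- function(acc, reviewed = rep(FALSE, length(acc)),
                       len = rep(400L, length(acc)),
                       labels = rep(list(character(0)), length(acc)),
                       tm = rep(list(NULL), length(acc))) {
  protein_records(acc, rep("human", length(acc)), len, reviewed, labels, tm)
}

test_that("label edges require an identical (namespace, value) pair", {
  rec <- mk_records(c("P1", "P2", "P3"),
                    labels = list("GN:MFSD8", "GN:MFSD8", "GN:OTHER"))
  e <- build_redundancy_graph(rec, data.frame(query_id = character(0),
                                              subject_id = character(0),
                                              pct_identity = numeric(0),
                                              aln_length = integer(0)))
  expect_equal(nrow(e), 1)
  expect_equal(c(e$a, e$b, e$reason), c("P1", "P2", "shared-label"))
})

test_that("HSP edges require identity strictly above 95%", {
  rec <- mk_records(c("P3", "P4", "P5", "P6"))
  hsps <- data.frame(query_id = c("P3", "P5"), subject_id = c("P4", "P6"),
                     pct_identity = c(95.0, 95.1), aln_length = c(300L, 300L))
  e <- build_redundancy_graph(rec, hsps)
  expect_equal(nrow(e), 1)
  expect_equal(c(e$a, e$b, e$reason), c("P5", "P6", "hsp"))

  # unknown accession: warning, HSP skipped
  hsps2 <- data.frame(query_id = "P3", subject_id = "NOPE",
                      pct_identity = 99, aln_length = 100L)
  expect_warning(e2 <- build_redundancy_graph(rec, hsps2), "unknown")
  expect_equal(nrow(e2), 0)

  # neither labels nor HSPs: empty edge list
  expect_equal(nrow(build_redundancy_graph(
    mk_records(c("A", "B")), hsps[0, ])), 0)
})

test_that("connected components include singletons and match closure oracle", {
  nodes <- c("A", "B", "C", "D")
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"))
  expect_equal(connected_components(nodes, edges),
               list(c("A", "B", "C"), "D"), ignore_attr = TRUE)
  expect_equal(connected_components(character(0), edges[0, ]), list())

  set.seed(17)
  for (rep in 1:50) {
    n <- sample(4:14, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    n_e <- sample(0:(2 * n), 1)
    edges <- data.frame(a = sample(nodes, n_e, replace = TRUE),
                        b = sample(nodes, n_e, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    expect_equal(unname(connected_components(nodes, edges)),
                 oracle_components(nodes, edges))
  }
})

test_that("representative rules: single reviewed, none reviewed, multiple reviewed", {
  rec <- mk_records(c("P1", "P2", "P3", "P4"),
                    reviewed = c(TRUE, FALSE, FALSE, TRUE),
                    len = c(400L, 600L, 300L, 500L))
  r1 <- select_representative(c("P1", "P2"), rec)
  expect_equal(r1$representative, "P1")      # the single curated member
  r2 <- select_representative(c("P2", "P3"), rec)
  expect_equal(r2$representative, "P2")      # longest when none curated
  r3 <- select_representative(c("P1", "P4"), rec)
  expect_true(r3$review)                     # >= 2 curated: manual review
  expect_true(is.na(r3$representative))

  # equal-length unreviewed tie -> smallest accession
  rec2 <- mk_records(c("Q2", "Q1"), len = c(500L, 500L))
  expect_equal(select_representative(c("Q2", "Q1"), rec2)$representative,
               "Q1")
})

test_that("TMH sanitization keeps >=3 helices, rescues listed accessions", {
  rec <- mk_records(c("K1", "X1", "R1", "U1"),
                    tm = list(.make_tm(4), .make_tm(2), .make_tm(1), NULL))
  cfg <- collapse_config(rescue_list = "R1")
  s <- sanitize_by_tmh(rec, cfg)
  expect_equal(s$kept, c("K1", "R1"))
  expect_equal(s$excluded, "X1")
  expect_equal(s$review, "U1")
})

test_that("annotation conflicts within a namespace are routed to review", {
  rec <- mk_records(c("P1", "P2"),
                    labels = list(c("GN:AAA", "GeneID:1"),
                                  c("GN:BBB", "GeneID:1")))
  out <- collapse_fragments(rec, data.frame(query_id = character(0),
                                            subject_id = character(0),
                                            pct_identity = numeric(0),
                                            aln_length = integer(0)))
  # one cluster via shared GeneID, but conflicting GN values
  expect_equal(length(out$clusters), 1)
  expect_equal(out$review$reason, "annotation-conflict")
  expect_length(out$representatives, 0)
})

test_that("planted fragments collapse onto their parents; distractors never merge", {
  cfg <- sim_config(n_families = 8, proteins_per_family = 5,
                    fragment_rate = 0.4, label_missing_rate = 0.5, seed = 23)
  sim <- simulate_hits(cfg)
  rec <- simulate_records(sim$truth, cfg)
  fr <- simulate_fragments(rec, sim$hits, cfg)
  out <- collapse_fragments(fr$records, fr$hsps)
  # one representative per planted gene, total membership conserved
  genes <- unique(fr$truth)
  expect_equal(length(out$clusters), length(genes))
  expect_equal(sum(lengths(lapply(out$clusters, `[[`, "members"))),
               nrow(fr$records))
  # every cluster is exactly one planted gene group and the parent is chosen
  for (cl in out$clusters) {
    expect_length(unique(fr$truth[cl$members]), 1)
    parent <- unique(fr$truth[cl$members])
    if (!cl$review && !cl$conflict) {
      expect_equal(cl$representative, unname(parent))
    }
  }
})
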