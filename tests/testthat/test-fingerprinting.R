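mk_hits <- function(...) {
  # ... = lists(protein, model, score, mfrom, mto)
  rows <- lapply(list(...), function(x)
    data.frame(protein_id = x[[1]], model_id = x[[2]],
               bit_score = as.numeric(x[[3]]), evalue = 1e-10,
               model_from = as.integer(x[[4]]), model_to = as.integer(x[[5]]),
               target_from = 1L, target_to = 100L,
               stringsAsFactors = FALSE))
  merge_hits(do.call(rbind, rows))
}

test_that("duplicate (protein, model) rows merge to the best score with all domains", {
  raw <- rbind(
    data.frame(protein_id = "P1", model_id = "M1", bit_score = 80,
               evalue = 1e-20, model_from = 1L, model_to = 50L,
               target_from = 1L, target_to = 50L),
    data.frame(protein_id = "P1", model_id = "M1", bit_score = 75,
               evalue = 1e-18, model_from = 60L, model_to = 120L,
               target_from = 60L, target_to = 120L))
  m <- merge_hits(raw)
  expect_equal(nrow(m), 1)
  expect_equal(m$bit_score, 80)
  expect_equal(m$evalue, 1e-20)
  expect_equal(nrow(m$domains[[1]]), 2)
})

test_that("candidate selection uses a strict 50-bit threshold", {
  expect_equal(select_candidates(mk_hits(list("P", "M", 50.0, 1, 100))),
               character(0))
  expect_equal(select_candidates(mk_hits(list("P", "M", 50.1, 1, 100))),
               "P")
  expect_equal(select_candidates(merge_hits(slcpipe:::empty_hits())),
               character(0))
})

test_that("region exclusions drop hits confined to the excluded window", {
  rules <- region_exclusion_rules()
  # entirely above 400 on RBP_receptor: removed
  h1 <- mk_hits(list("P1", "RBP_receptor", 90, 420, 500))
  expect_equal(nrow(suppressWarnings(apply_region_exclusions(h1, rules))), 0)
  # spanning the boundary: retained
  h2 <- mk_hits(list("P2", "RBP_receptor", 90, 350, 450))
  expect_equal(nrow(suppressWarnings(apply_region_exclusions(h2, rules))), 1)
  # one domain inside, one outside: retained (not ONLY within the window)
  h3 <- merge_hits(rbind(
    data.frame(protein_id = "P3", model_id = "2.A.19.3", bit_score = 90,
               evalue = 1e-9, model_from = 300L, model_to = 400L,
               target_from = 1L, target_to = 100L),
    data.frame(protein_id = "P3", model_id = "2.A.19.3", bit_score = 88,
               evalue = 1e-9, model_from = 1L, model_to = 100L,
               target_from = 1L, target_to = 100L)))
  expect_equal(nrow(suppressWarnings(apply_region_exclusions(h3, rules))), 1)
  # all domains inside 250-725: removed
  h4 <- mk_hits(list("P4", "2.A.19.3", 90, 300, 700))
  expect_equal(nrow(suppressWarnings(apply_region_exclusions(h4, rules))), 0)
  # below-200 window
  h5 <- mk_hits(list("P5", "OST3_OST6", 90, 20, 150))
  expect_equal(nrow(suppressWarnings(apply_region_exclusions(h5, rules))), 0)
  # no rules: unchanged
  expect_identical(apply_region_exclusions(h1, NULL), h1)
  # unknown model in a rule: warning, rule ignored
  expect_warning(
    apply_region_exclusions(mk_hits(list("P", "M", 60, 1, 10)), rules),
    "unknown model")
})

test_that("fingerprint columns need > 25 bits; cells keep reported scores", {
  h <- mk_hits(list("P", "M1", 60, 1, 100), list("P", "M2", 30, 1, 100),
               list("P", "M3", 20, 1, 100))
  fp <- build_fingerprints(h, "P")
  expect_equal(sort(colnames(fp)), c("M1", "M2"))
  expect_equal(fp["P", "M2"], 30)

  # best score exactly 25 -> column dropped (strict)
  h2 <- mk_hits(list("P", "M1", 60, 1, 100), list("P", "M4", 25.0, 1, 100))
  expect_false("M4" %in% colnames(build_fingerprints(h2, "P")))

  # sub-threshold scores to retained columns are kept unless cells_min_bits
  h3 <- mk_hits(list("P", "M1", 60, 1, 100), list("Q", "M1", 10, 1, 100),
                list("Q", "M2", 55, 1, 100))
  fp3 <- build_fingerprints(h3, c("P", "Q"))
  expect_equal(fp3["Q", "M1"], 10)
  fp3s <- build_fingerprints(h3, c("P", "Q"),
                             threshold_config(cells_min_bits = TRUE))
  expect_equal(fp3s["Q", "M1"], 0)
})

test_that("identical hit profiles give identical fingerprint rows", {
  h <- mk_hits(list("A", "M1", 60, 1, 100), list("A", "M2", 40, 1, 100),
               list("B", "M1", 60, 1, 100), list("B", "M2", 40, 1, 100))
  fp <- build_fingerprints(h, c("A", "B"))
  expect_equal(unname(fp["A", ]), unname(fp["B", ]))
})

test_that("column-max invariant holds on fuzzed random hit sets", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    raw <- data.frame(
      protein_id = sample(sprintf("P%d", 1:6), n, replace = TRUE),
      model_id = sample(sprintf("M%d", 1:5), n, replace = TRUE),
      bit_score = round(runif(n, 5, 120), 1), evalue = 1e-8,
      model_from = 1L, model_to = 90L, target_from = 1L, target_to = 90L,
      stringsAsFactors = FALSE)
    m <- merge_hits(raw)
    cand <- select_candidates(m)
    if (!length(cand)) next
    fp <- suppressWarnings(build_fingerprints(m, cand))
    if (!ncol(fp)) next
    expect_true(all(apply(fp, 2, max) > 25))
    expect_true(all(fp >= 0))
    # idempotence wrt re-merging
    expect_identical(suppressWarnings(build_fingerprints(merge_hits(raw),
                                                         cand)), fp)
  }
})

test_that("noise-free planted families give a block-structured matrix", {
  cfg <- sim_config(n_families = 5, proteins_per_family = 3,
                    noise_hit_rate = 0, seed = 5)
  sim <- simulate_hits(cfg)
  m <- merge_hits(sim$hits)
  fp <- build_fingerprints(m, select_candidates(m))
  fam_of_protein <- sim$truth$protein_family[rownames(fp)]
  fam_of_model <- sub("_M\\d+$", "", colnames(fp))
  for (i in seq_len(nrow(fp))) {
    off_block <- fam_of_model != fam_of_protein[i]
    expect_true(all(fp[i, off_block] == 0))
    expect_true(all(fp[i, !off_block] > 50))
  }
})
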