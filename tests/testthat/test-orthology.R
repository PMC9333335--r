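sp3 <- parse_newick("((human,mouse)hm,fly)root;")

test_that("congruent gene trees reconcile with all-speciation and no loss", {
  rec <- lca_reconcile(parse_newick("((h1__human,m1__mouse),f1__fly);"), sp3)
  expect_true(all(rec$events[!is.na(rec$events)] == "speciation"))
  expect_equal(rec$n_losses, 0)
  op <- ortholog_pairs(rec)
  expect_equal(nrow(op), 3)
})

test_that("within-species cherries are duplications; losses counted on gaps", {
  rec <- lca_reconcile(parse_newick("((h1__human,h2__human),m1__mouse);"), sp3)
  lab <- rec$gene_tree$tip.label
  cherry <- ape::getMRCA(rec$gene_tree, match(c("h1__human", "h2__human"), lab))
  expect_equal(rec$events[cherry], "duplication")
  expect_equal(rec$n_duplications, 1)
  expect_equal(rec$n_losses, 0)

  rec2 <- lca_reconcile(parse_newick("(h1__human,f1__fly);"), sp3)
  expect_equal(rec2$n_losses, 1)
  expect_equal(rec2$losses$species_label, "mouse")

  # duplication with one copy surviving only in human: sibling-lineage loss
  rec3 <- lca_reconcile(
    parse_newick("((h1__human,m1__mouse),h2__human);"), sp3)
  root <- length(rec3$gene_tree$tip.label) + 1L
  expect_equal(rec3$events[root], "duplication")
  expect_equal(rec3$n_losses, 1)
  expect_equal(rec3$losses$species_label, "mouse")
})

test_that("unknown species and unrooted input are rejected", {
  expect_error(lca_reconcile(parse_newick("(h1__human,x1__yeti);"), sp3),
               "yeti")
  ut <- ape::unroot(parse_newick(
    "((h1__human,m1__mouse),(f1__fly,f2__fly));"))
  expect_error(lca_reconcile(ut, sp3), "rooted")
})

test_that("ortholog pairs equal brute-force pairwise-LCA classification", {
  set.seed(61)
  sp <- study_species_tree()
  for (rep in 1:60) {
    gt <- random_gene_tree(sample(4:10, 1), sp$tip.label)
    rec <- lca_reconcile(gt, sp)
    got <- ortholog_pairs(rec)
    got_keys <- if (nrow(got)) sort(paste(got$gene1, got$gene2, sep = "~"))
                else character(0)
    expect_equal(got_keys, oracle_ortholog_pairs(rec))
  }
})

test_that("loss counts equal exhaustive enumeration on small gene trees", {
  set.seed(67)
  species <- c("human", "mouse", "fly")
  for (n_leaves in 2:5) {
    for (rep in 1:20) {
      gt <- random_gene_tree(n_leaves, species)
      rec <- lca_reconcile(gt, sp3)
      expect_equal(rec$n_losses, oracle_loss_count(rec))
    }
  }
})

test_that("DL-parsimony rooting recovers the congruent rooting", {
  gt <- parse_newick(
    "(((h1__human,(m1__mouse,r1__rat)),c1__chicken),(z1__zebrafish,f1__fly));")
  ut <- ape::unroot(gt)
  rec <- root_by_dl(ut, study_species_tree())
  expect_equal(rec$n_duplications, 0)
  # worm is outside the root map's subtree, so no loss is inferred for it
  expect_equal(rec$n_losses, 0)

  # 3-leaf tree: all rootings enumerated, congruent one chosen
  ut3 <- ape::unroot(parse_newick("((h1__human,m1__mouse),f1__fly);"))
  rec3 <- root_by_dl(ut3, sp3)
  expect_equal(rec3$n_duplications + rec3$n_losses, 0)
})

test_that("rooting recovers planted events on loss-free birth-death trees", {
  cfg <- sim_config(dup_rate = 0.2, loss_rate = 0, seed = 71)
  trees <- simulate_gene_trees(study_species_tree(), cfg, n_trees = 12)
  for (tr in trees) {
    rec <- root_by_dl(tr$unrooted, study_species_tree())
    expect_equal(rec$n_duplications, tr$n_duplications)
    expect_equal(rec$n_losses, 0)
    # and the rooted reconciliation of the planted tree agrees
    rec_planted <- lca_reconcile(tr$rooted, study_species_tree())
    expect_equal(rec_planted$n_duplications, tr$n_duplications)
  }
})

test_that("with losses, recovered duplications lower-bound planted ones", {
  cfg <- sim_config(dup_rate = 0.15, loss_rate = 0.1, seed = 73)
  trees <- simulate_gene_trees(study_species_tree(), cfg, n_trees = 10)
  for (tr in trees) {
    rec <- lca_reconcile(tr$rooted, study_species_tree())
    expect_lte(rec$n_duplications, tr$n_duplications)
  }
})

test_that("focal matrix classifies 1:1, 1:many, many:1 and lost clusters", {
  sp <- sp3
  recs <- list(
    a = lca_reconcile(parse_newick("((h1__human,m1__mouse),f1__fly);"), sp),
    b = lca_reconcile(parse_newick("((h1__human,h2__human),m1__mouse);"), sp),
    c = lca_reconcile(parse_newick("((m1__mouse,m2__mouse),h1__human);"), sp),
    d = lca_reconcile(parse_newick("(m1__mouse,f1__fly);"), sp))
  mat <- focal_matrix(recs, "human")
  pick <- function(cl, g, s)
    mat$category[mat$cluster == cl & mat$focal_gene == g & mat$species == s]
  expect_equal(pick("a", "h1__human", "mouse"), "one_to_one")
  expect_equal(pick("a", "h1__human", "fly"), "one_to_one")
  expect_equal(pick("b", "h1__human", "mouse"), "many_to_one")
  expect_equal(pick("b", "h2__human", "mouse"), "many_to_one")
  expect_equal(pick("b", "h1__human", "fly"), "none")
  expect_equal(pick("c", "h1__human", "mouse"), "one_to_many")
  expect_equal(mat$category[mat$cluster == "d"], "lost_in_focal")
})

test_that("single-species trees yield no ortholog pairs", {
  rec <- lca_reconcile(parse_newick("(h1__human,h2__human);"), sp3)
  expect_equal(nrow(ortholog_pairs(rec)), 0)
})
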