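test_that("Jaccard co-regulation is strict at the threshold", {
  net <- grn(c("A", "B", "A", "B", "A", "A", "B", "C", "A", "B", "D"),
             c("g1", "g1", "g2", "g2", "g3", "g4", "g4", "g4",
               "g5", "g5", "g5"),
             rep(0.9, 11))
  cp <- coregulated_pairs(net, 0.5)
  df <- pairs_to_df(cp)
  key <- paste(df$gene_a, df$gene_b)
  # identical sets {A,B}: Jaccard 1 -> co-regulated
  expect_true("g1 g2" %in% key)
  # {A,B} vs {A,B,C}: 2/3 > 0.5 -> co-regulated
  expect_true("g1 g4" %in% key)
  # {A,B,C} vs {A,B,D}: 2/4 = 0.5 -> NOT co-regulated (strict)
  expect_false("g4 g5" %in% key)
  # {A,B} vs {A} is Jaccard 0.5 -> not co-regulated
  net2 <- grn(c("A", "B", "A"), c("g1", "g1", "g2"), rep(0.9, 3))
  expect_length(coregulated_pairs(net2, 0.5), 0)

  # nestedness: co-regulated pairs never involve genes outside the network
  b <- simulate_weighted_grn(seed = 21)
  cp2 <- coregulated_pairs(b$network)
  genes <- unique(b$network$target)
  d2 <- pairs_to_df(cp2)
  expect_true(all(c(d2$gene_a, d2$gene_b) %in% genes))
})

test_that("regulatory precision counts gold-evaluable hits", {
  gold <- toy_gold()
  # predicted entirely inside the gold standard
  expect_equal(precision_regulatory(grn(c("A", "B"), c("g1", "g3"),
                                        c(1, 1)),
                                    gold$regulatory), 1)
  # no overlap
  expect_equal(precision_regulatory(grn("A", "g9", 1), gold$regulatory), 0)
  # 2 hits of 5 evaluable
  pred <- grn(c("A", "A", "A", "B", "B"),
              c("g1", "g2", "g7", "g8", "g9"), rep(1, 5))
  expect_equal(precision_regulatory(pred, gold$regulatory), 0.4)
  # predictions for regulators unknown to the gold standard drop out of
  # the denominator unless restriction is disabled
  pred2 <- grn(c("A", "Z"), c("g1", "g9"), c(1, 1))
  expect_equal(precision_regulatory(pred2, gold$regulatory), 1)
  expect_equal(precision_regulatory(pred2, gold$regulatory,
                                    restrict_to_gold_regulators = FALSE),
               0.5)
  expect_warning(p0 <- precision_regulatory(grn("Z", "g1", 1),
                                            gold$regulatory), "evaluable")
  expect_equal(p0, 0)
})

test_that("co-functional recall is anchored to the initial network", {
  # initial network: regulator pair {A,B} co-regulates g1..g4 (all Jaccard 1)
  initial <- grn(rep(c("A", "B"), each = 4),
                 rep(paste0("g", 1:4), 2), rep(0.9, 8))
  gold_cof <- data.frame(gene_a = c("g1", "g1", "g2", "g3"),
                         gene_b = c("g2", "g3", "g3", "g4"))
  gold <- list(cofunction = gold_cof)
  # identity pruning -> recall 1
  expect_equal(recall_cofunctional(initial, initial, gold_cof), 1)
  # empty prediction -> 0
  expect_equal(suppressWarnings(
    recall_cofunctional(initial[0, ], initial, gold_cof)), 0)
  # dropping g4 removes exactly one of four co-annotated pairs; both
  # denominator anchors agree on this fixture
  pruned <- initial[initial$target != "g4", , drop = FALSE]
  expect_equal(recall_cofunctional(pruned, initial, gold_cof), 0.75)
  expect_equal(recall_cofunctional(pruned, initial, gold_cof,
                                   anchor = "initial"), 0.75)
  # initial anchoring is capped at 1 even when pruning creates
  # co-regulated pairs (a decoy regulator dilutes the initial Jaccard)
  with_decoy <- rbind(initial, grn("D", "g1", 0.9))
  expect_lte(recall_cofunctional(initial, with_decoy, gold_cof,
                                 anchor = "initial"), 1)
})

test_that("f-beta arithmetic and symmetry", {
  expect_equal(f_beta_score(1, 1), 1)
  expect_equal(f_beta_score(1, 0), 0)
  expect_equal(f_beta_score(0.5, 0.5), 0.5)
  expect_equal(f_beta_score(0, 0), 0)
  # symmetric iff beta = 1; increasing in each argument
  expect_equal(f_beta_score(0.3, 0.8), f_beta_score(0.8, 0.3))
  expect_false(isTRUE(all.equal(f_beta_score(0.3, 0.8, beta = 2),
                                f_beta_score(0.8, 0.3, beta = 2))))
  expect_gt(f_beta_score(0.6, 0.5), f_beta_score(0.4, 0.5))
  expect_gt(f_beta_score(0.5, 0.6), f_beta_score(0.5, 0.4))
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  expect_equal(fisher_enrichment(10, 100, 100, 1000)$fold_change, 1.0)
  expect_equal(fisher_enrichment(10, 100, 10, 1000)$fold_change, 10.0)
  # table (5,5;5,85): p equals the exhaustive hypergeometric tail sum
  fe <- fisher_enrichment(5, 10, 10, 100)
  expect_equal(fe$p_value, oracle_fisher_p(5, 10, 10, 100),
               tolerance = 1e-12)
  # random small tables
  set.seed(31)
  for (i in 1:20) {
    n_bg <- sample(20:50, 1)
    n_pred <- sample(2:(n_bg - 1), 1)
    hits_bg <- sample(1:n_bg, 1)
    hits_pred <- sample(0:min(n_pred, hits_bg), 1)
    if ((n_bg - n_pred) < (hits_bg - hits_pred)) next
    fe <- fisher_enrichment(hits_pred, n_pred, hits_bg, n_bg)
    expect_equal(fe$p_value,
                 oracle_fisher_p(hits_pred, n_pred, hits_bg, n_bg),
                 tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(0, 10, 0, 100), "undefined")
})
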