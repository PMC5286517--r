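test_that("meta edge weights follow the product combination rule", {
  expect_equal(meta_edge_weight(0.8, 0.8, 1.0), 1.0)
  expect_equal(meta_edge_weight(0.3, 0.9, 0.0), 0.0)
  expect_equal(meta_edge_weight(0.9, 0.7, 0.5), 0.4)
  # symmetry, monotonicity in distance and in co-function weight
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1); w <- runif(1)
    expect_equal(meta_edge_weight(a, b, w), meta_edge_weight(b, a, w))
    expect_true(meta_edge_weight(a, b, w) >= 0,
                meta_edge_weight(a, b, w) <= 1)
  }
  # strictly decreasing in |distance| for w_ff > 0
  expect_gt(meta_edge_weight(0.5, 0.6, 0.8), meta_edge_weight(0.5, 0.9, 0.8))
  # increasing in w_ff
  expect_gt(meta_edge_weight(0.5, 0.6, 0.9), meta_edge_weight(0.5, 0.6, 0.3))
  # the alternative ratio rule shares the monotonicities
  expect_gt(meta_edge_weight(0.5, 0.6, 0.8, rule = "ratio"),
            meta_edge_weight(0.5, 0.9, 0.8, rule = "ratio"))
})

test_that("meta network pairs same-regulator links only", {
  net <- grn(c("r", "r", "r", "s", "s"),
             c("g1", "g2", "g3", "g2", "g4"),
             c(0.9, 0.8, 0.7, 0.6, 0.5))
  cofn <- data.frame(gene_a = "g1", gene_b = "g2", weight = 1.0)
  me <- build_meta_network(net, cofn)
  # C(3,2) for r plus C(2,2) for s
  expect_equal(nrow(me), 4)
  expect_equal(sum(me$regulator == "r"), 3)
  expect_equal(sum(me$regulator == "s"), 1)
  # known pair weight: w_ff = 1, |0.9 - 0.8| = 0.1
  w12 <- me$weight[me$regulator == "r" & me$target_a == "g1" &
                     me$target_b == "g2"]
  expect_equal(w12, 0.9)
  # absent co-function pairs contribute zero coupling but are emitted
  expect_true(all(me$weight[!(me$target_a == "g1" & me$target_b == "g2")] == 0))
  # links with distinct regulators never pair
  two <- build_meta_network(grn(c("r", "s"), c("g1", "g2"), c(0.5, 0.5)),
                            cofn)
  expect_equal(nrow(two), 0)
})

test_that("modules partition the links and trees are maximal", {
  # triangle: MST keeps the 0.9 and 0.5 edges
  net3 <- grn(rep("r", 3), c("g1", "g2", "g3"), c(0.9, 0.8, 0.7))
  cofn <- data.frame(gene_a = c("g1", "g1", "g2"),
                     gene_b = c("g2", "g3", "g3"),
                     weight = c(0.9 / (1 - 0.1), 0.5 / (1 - 0.2),
                                0.2 / (1 - 0.1)))
  me <- build_meta_network(net3, cofn)
  expect_equal(sort(me$weight), c(0.2, 0.5, 0.9))
  mods <- extract_modules(me, net3)
  expect_length(mods, 1)
  expect_equal(sort(mods[[1]]$edges$weight), c(0.5, 0.9))

  # isolated link -> singleton module with no tree edges
  net4 <- grn(c("r", "r", "s"), c("g1", "g2", "g9"), c(0.9, 0.8, 0.7))
  mods4 <- extract_modules(build_meta_network(net4, cofn), net4)
  sizes <- sapply(mods4, function(m) nrow(m$links))
  expect_equal(sort(sizes), c(1, 2))
  expect_equal(nrow(mods4[[which(sizes == 1)]]$edges), 0)

  # partition property on a simulated network
  b <- simulate_weighted_grn(seed = 5)
  mods5 <- extract_modules(build_meta_network(b$network, b$cofn), b$network)
  lk <- module_links(mods5)
  expect_equal(nrow(lk), nrow(b$network))
  expect_false(anyDuplicated(paste(lk$regulator, lk$target)) > 0)
  # |edges| = |nodes| - 1 in every module
  for (m in mods5) expect_equal(nrow(m$edges), nrow(m$links) - 1)
})

test_that("spanning trees match exhaustive enumeration on random graphs", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:7, 1)
    # random connected graph: random tree plus extra random edges
    base <- random_tree_edges(n)
    extra_n <- sample(0:4, 1)
    all_pairs <- t(utils::combn(n, 2))
    have <- paste(pmin(base$a, base$b), pmax(base$a, base$b))
    pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), ,
                      drop = FALSE]
    if (extra_n > 0 && nrow(pool) > 0) {
      pick <- pool[sample.int(nrow(pool), min(extra_n, nrow(pool))), ,
                   drop = FALSE]
      base <- rbind(base, data.frame(a = pick[, 1], b = pick[, 2],
                                     weight = runif(nrow(pick))))
    }
    # express as a meta network over one regulator
    targets <- sprintf("G%03d", seq_len(n))
    net <- grn(rep("r", n), targets, runif(n))
    me <- data.frame(regulator = "r",
                     target_a = pmin(targets[base$a], targets[base$b]),
                     target_b = pmax(targets[base$a], targets[base$b]),
                     weight = base$weight, stringsAsFactors = FALSE)
    mods <- extract_modules(me, net)
    expect_length(mods, 1)
    expect_equal(sum(mods[[1]]$edges$weight),
                 oracle_max_spanning_tree(n, base), tolerance = 1e-12)
  }
})

test_that("path graphs are their own spanning tree and ties break deterministically", {
  targets <- c("g1", "g2", "g3", "g4")
  net <- grn(rep("r", 4), targets, c(0.9, 0.8, 0.7, 0.6))
  path <- data.frame(regulator = "r", target_a = c("g1", "g2", "g3"),
                     target_b = c("g2", "g3", "g4"),
                     weight = c(0.5, 0.4, 0.3), stringsAsFactors = FALSE)
  mods <- extract_modules(path, net)
  expect_equal(sort(mods[[1]]$edges$weight), c(0.3, 0.4, 0.5))
  # equal-weight triangle: lexicographically smaller pairs win
  tri <- data.frame(regulator = "r",
                    target_a = c("g1", "g1", "g2"),
                    target_b = c("g2", "g3", "g3"),
                    weight = rep(0.5, 3), stringsAsFactors = FALSE)
  mods2 <- extract_modules(tri, net[1:3, ])
  kept <- mods2[[1]]$edges
  kept_pairs <- sort(paste(mods2[[1]]$links$target[kept$a],
                           mods2[[1]]$links$target[kept$b]))
  expect_equal(kept_pairs, c("g1 g2", "g1 g3"))
  # identical call twice -> identical modules
  expect_identical(extract_modules(tri, net[1:3, ]),
                   extract_modules(tri, net[1:3, ]))
})
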