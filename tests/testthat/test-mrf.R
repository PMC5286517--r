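test_that("energy matches hand evaluation and decouples without coupling", {
  # singleton at the threshold: both states have zero energy
  m1 <- make_module(0.4)
  expect_equal(module_energy(m1, 1, gamma = 0.4, lambda = 1), 0)
  expect_equal(module_energy(m1, 0, gamma = 0.4, lambda = 1), 0)

  # two links, (upsilon - gamma) = (+0.2, -0.1), lambda 1, coupling 0.5,
  # state (1,1): E = -(0.2) - (-0.1) - 0.5 = -0.6
  m2 <- make_module(c(0.6, 0.3),
                    data.frame(a = 1L, b = 2L, weight = 0.5))
  expect_equal(module_energy(m2, c(1, 1), gamma = 0.4, lambda = 1), -0.6)

  # zero coupling: energy is the sum of the two unary energies
  m0 <- make_module(c(0.6, 0.3), data.frame(a = 1L, b = 2L, weight = 0))
  for (x1 in 0:1) for (x2 in 0:1) {
    expect_equal(module_energy(m0, c(x1, x2), 0.4, 2),
                 module_energy(make_module(0.6), x1, 0.4, 2) +
                   module_energy(make_module(0.3), x2, 0.4, 2))
  }
  expect_error(module_energy(m2, c(1, NA), 0.4, 1), "assign")
})

test_that("joint probabilities normalize and match enumeration", {
  # singleton at the threshold: both states equally likely
  m1 <- make_module(0.4)
  expect_equal(joint_probability(m1, 1, 0.4, 1), 0.5)
  expect_equal(joint_probability(m1, 0, 0.4, 1), 0.5)

  # 3-node chain: sums to one, matches independent enumeration
  m3 <- make_module(c(0.2, 0.5, 0.7),
                    data.frame(a = c(1L, 2L), b = c(2L, 3L),
                               weight = c(0.6, 0.3)))
  gamma <- 0.9; lambda <- 1.3  # nothing clamped
  states <- as.matrix(expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1))
  ps <- apply(states, 1, function(x) joint_probability(m3, x, gamma, lambda))
  expect_equal(sum(ps), 1, tolerance = 1e-12)
  loge <- apply(states, 1, function(x) {
    -oracle_energy(m3$links$weight, m3$edges, x, gamma, lambda)
  })
  expect_equal(ps, exp(loge) / sum(exp(loge)), tolerance = 1e-12)

  # clamped configurations: states violating evidence have probability 0
  expect_equal(joint_probability(m3, c(0, 0, 0), gamma = 0.4, lambda = 1), 0)
})

test_that("belief propagation equals enumeration on random trees", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    weights <- runif(n)
    edges <- random_tree_edges(n)
    gamma <- runif(1)
    lambda <- runif(1, 0, 2.5)
    mod <- make_module(weights, edges)
    bp <- bp_marginals(mod, gamma, lambda)
    expect_equal(bp$p, oracle_marginals(weights, edges, gamma, lambda),
                 tolerance = 1e-9)
    # and without clamping
    bp0 <- bp_marginals(mod, gamma, lambda, clamp = FALSE)
    expect_equal(bp0$p,
                 oracle_marginals(weights, edges, gamma, lambda,
                                  clamp = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("free singletons follow the logistic closed form", {
  set.seed(7)
  for (rep in 1:100) {
    u <- runif(1); g <- runif(1)
    p <- bp_marginals(make_module(u), g, runif(1, 0, 2), clamp = FALSE)$p
    expect_equal(p, plogis(2 * (u - g)), tolerance = 1e-12)
  }
  # upsilon - gamma = 0.5 -> sigma(1)
  expect_equal(bp_marginals(make_module(0.9), 0.4, 1, clamp = FALSE)$p,
               plogis(1), tolerance = 1e-12)
})

test_that("clamping is strict and rescues coupled sub-threshold links", {
  # upsilon exactly gamma is NOT clamped and is removed (p = 0.5)
  m <- make_module(0.4)
  bp <- bp_marginals(m, 0.4, 1)
  expect_false(bp$clamped)
  expect_equal(bp$p, 0.5)
  expect_false(prune_module(m, 0.4, 1))

  # all links above gamma: whole module clamped, marginals all 1
  m2 <- make_module(c(0.8, 0.9), data.frame(a = 1L, b = 2L, weight = 0.5))
  bp2 <- bp_marginals(m2, 0.5, 1)
  expect_true(all(bp2$clamped))
  expect_equal(bp2$p, c(1, 1))

  # chain low-high-low: middle clamped, flanks match conditioned enumeration
  wts <- c(0.3, 0.9, 0.35)
  edges <- data.frame(a = c(1L, 2L), b = c(2L, 3L), weight = c(0.7, 0.6))
  m3 <- make_module(wts, edges)
  bp3 <- bp_marginals(m3, 0.5, 1.2)
  expect_equal(bp3$clamped, c(FALSE, TRUE, FALSE))
  expect_equal(bp3$p, oracle_marginals(wts, edges, 0.5, 1.2),
               tolerance = 1e-9)

  # a weak link tied to a clamped neighbor is rescued when the coupling
  # outweighs the unary deficit (lambda * upsilon_delta > gamma - upsilon)
  m4 <- make_module(c(0.45, 0.9), data.frame(a = 1L, b = 2L, weight = 0.8))
  expect_true(all(prune_module(m4, 0.5, lambda = 2)))
  # but an isolated link below gamma is removed
  expect_false(prune_module(make_module(0.45), 0.5, 2))
})

test_that("marginals are monotone in lambda next to clamped evidence", {
  m <- make_module(c(0.4, 0.9), data.frame(a = 1L, b = 2L, weight = 0.6))
  lams <- seq(0, 2.5, length.out = 26)
  ps <- sapply(lams, function(l) bp_marginals(m, 0.5, l)$p[1])
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("the decoupled limit reduces to thresholding at gamma", {
  set.seed(13)
  b <- simulate_weighted_grn(seed = 13)
  mods <- extract_modules(build_meta_network(b$network, b$cofn), b$network)
  gamma <- median(b$network$weight)
  kept <- prune_network(mods, gamma, lambda = 0)
  expected <- b$network[b$network$weight > gamma, , drop = FALSE]
  expect_equal(kept, grn(expected$regulator, expected$target,
                         expected$weight))
  # same with all co-function weights zeroed, lambda arbitrary
  cof0 <- b$cofn; cof0$weight <- 0
  mods0 <- extract_modules(build_meta_network(b$network, cof0), b$network)
  kept0 <- prune_network(mods0, gamma, lambda = 1.7)
  expect_equal(kept0, grn(expected$regulator, expected$target,
                          expected$weight))
  # retained-set size is non-increasing in gamma at lambda = 0
  sizes <- sapply(quantile(b$network$weight, c(0.1, 0.3, 0.5, 0.7, 0.9)),
                  function(g) nrow(prune_network(mods, g, 0)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cyclic edge sets are rejected", {
  bad <- make_module(c(0.5, 0.6, 0.7),
                     data.frame(a = c(1L, 2L, 1L), b = c(2L, 3L, 3L),
                                weight = rep(0.5, 3)))
  expect_error(bp_marginals(bad, 0.4, 1), "tree")
})
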