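#' Simulate a planted-truth expression benchmark
#'
#' Generates every input the refinement pipeline consumes, with a known
#' ground-truth network: a planted TF -> target network; an expression
#' matrix in which each target is a linear combination of its regulators'
#' profiles plus Gaussian noise (so tree-ensemble regression has
#' recoverable signal); a binding network equal to the true links plus
#' random decoy links; a co-function network assigning high weights
#' (Beta(5, 2)) to pairs sharing a true regulator and low weights
#' (Beta(1.5, 5)) to background pairs; and sparse gold standards covering
#' stated fractions of the truth. Fully deterministic per seed.
#'
#' Gene identifiers are synthetic (`TF0001`, `G00042`); they do not refer
#' to real loci.
#'
#' @param n_tfs Number of transcription factors (>= 2; default 20).
#' @param n_genes Total number of genes including TFs (>= 10; default
#'   300).
#' @param n_conditions Number of expression conditions (default 40).
#' @param targets_per_tf Mean number of targets per TF; actual counts are
#'   `2 + Poisson(targets_per_tf - 2)` (default 8).
#' @param noise_sd Standard deviation of the additive expression noise
#'   (default 0.5; regulator effect sizes are drawn from `U(0.5, 1.5)`
#'   with random sign).
#' @param decoy_rate Decoy binding links per true link (default 1).
#' @param cofn_coverage Fraction of true co-regulon pairs present in the
#'   co-function network (default 0.8).
#' @param gold_reg_fraction Fraction of true links in the regulatory gold
#'   standard (default 0.3).
#' @param gold_cofn_coverage Fraction of true co-regulon pairs in the
#'   co-functional gold standard (default 0.5).
#' @param seed Integer seed.
#' @return List with `truth` (network `data.frame`), `expression`
#'   (matrix), `tf_list`, `binding`, `cofn`, `gold` (list `regulatory`,
#'   `cofunction`) and `params`.
#' @export
simulate_benchmark <- function(n_tfs = 20, n_genes = 300, n_conditions = 40,
                               targets_per_tf = 8, noise_sd = 0.5,
                               decoy_rate = 1, cofn_coverage = 0.8,
                               gold_reg_fraction = 0.3,
                               gold_cofn_coverage = 0.5, seed = 1) {
  stopifnot(n_tfs >= 2, n_genes >= 10, n_genes > n_tfs, n_conditions >= 2,
            targets_per_tf >= 2, noise_sd >= 0, decoy_rate >= 0,
            cofn_coverage > 0, cofn_coverage <= 1,
            gold_reg_fraction > 0, gold_reg_fraction <= 1,
            gold_cofn_coverage > 0, gold_cofn_coverage <= 1)
  set.seed(seed)
  tfs <- sprintf("TF%04d", seq_len(n_tfs))
  others <- sprintf("G%05d", seq_len(n_genes - n_tfs))
  genes <- c(tfs, others)

  # planted network: each TF regulates a Poisson-sized set of non-TF genes
  truth <- do.call(rbind, lapply(tfs, function(tf) {
    k <- min(2 + stats::rpois(1, targets_per_tf - 2), length(others))
    data.frame(regulator = tf, target = sample(others, k),
               stringsAsFactors = FALSE)
  }))
  truth <- unique(truth)

  # expression: TFs are independent profiles, targets linear responses
  expr <- matrix(stats::rnorm(length(genes) * n_conditions),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("C%03d", seq_len(n_conditions))))
  by_target <- split(truth$regulator, truth$target)
  for (tg in names(by_target)) {
    regs <- by_target[[tg]]
    beta <- stats::runif(length(regs), 0.5, 1.5) *
      sample(c(-1, 1), length(regs), replace = TRUE)
    expr[tg, ] <- drop(beta %*% expr[regs, , drop = FALSE]) +
      stats::rnorm(n_conditions, sd = noise_sd)
  }

  # binding: truth plus decoys
  n_decoy <- round(decoy_rate * nrow(truth))
  true_ids <- link_id(truth$regulator, truth$target)
  decoys <- data.frame(regulator = character(0), target = character(0))
  if (n_decoy > 0) {
    pool_r <- sample(tfs, 4 * n_decoy, replace = TRUE)
    pool_t <- sample(others, 4 * n_decoy, replace = TRUE)
    ok <- !(link_id(pool_r, pool_t) %in% true_ids)
    cand <- unique(data.frame(regulator = pool_r[ok], target = pool_t[ok],
                              stringsAsFactors = FALSE))
    decoys <- cand[seq_len(min(n_decoy, nrow(cand))), , drop = FALSE]
  }
  binding <- rbind(truth, decoys)

  # co-regulon pairs of the truth
  cr <- unique(unlist(lapply(split(truth$target, truth$regulator),
                             function(tg) {
    tg <- unique(tg)
    if (length(tg) < 2) return(character(0))
    cmb <- utils::combn(sort(tg), 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))

  # co-function network: covered co-regulon pairs high, background low
  n_cov <- max(1, round(cofn_coverage * length(cr)))
  covered <- sample(cr, n_cov)
  n_bg <- 2 * n_cov
  bg_a <- sample(genes, 3 * n_bg, replace = TRUE)
  bg_b <- sample(genes, 3 * n_bg, replace = TRUE)
  ok <- bg_a != bg_b & !(pair_id(bg_a, bg_b) %in% cr)
  bg <- unique(pair_id(bg_a[ok], bg_b[ok]))
  bg <- bg[seq_len(min(n_bg, length(bg)))]
  cof_pairs <- pairs_to_df(c(covered, bg))
  cofn <- data.frame(cof_pairs,
                     weight = c(stats::rbeta(length(covered), 5, 2),
                                stats::rbeta(length(bg), 1.5, 5)),
                     stringsAsFactors = FALSE)

  # gold standards: sparse subsets of the truth
  gold_reg <- truth[sample.int(nrow(truth),
                               max(1, round(gold_reg_fraction * nrow(truth)))), ,
                    drop = FALSE]
  gold_cof <- pairs_to_df(sample(cr, max(1, round(gold_cofn_coverage *
                                                    length(cr)))))

  list(truth = grn(truth$regulator, truth$target, rep(1, nrow(truth))),
       expression = expr, tf_list = tfs, binding = binding, cofn = cofn,
       gold = list(regulatory = gold_reg, cofunction = gold_cof),
       params = list(n_tfs = n_tfs, n_genes = n_genes,
                     n_conditions = n_conditions,
                     targets_per_tf = targets_per_tf, noise_sd = noise_sd,
                     decoy_rate = decoy_rate, cofn_coverage = cofn_coverage,
                     gold_reg_fraction = gold_reg_fraction,
                     gold_cofn_coverage = gold_cofn_coverage, seed = seed))
}

#' Simulate a weighted network with a planted confidence threshold
#'
#' Direct fixture for the coupling, pruning and hyperparameter-learning
#' stages, bypassing the expression stage: true links receive confidence
#' weights biased above a planted threshold `t`, decoy links weights
#' biased below it. With `separation = "wide"` the two weight
#' distributions do not overlap (`t + (1 - t) Beta(5, 2)` vs.
#' `t Beta(2, 5)`), so a learner recovering the threshold can prune
#' perfectly; with `"overlap"` they cross the threshold
#' (`Beta(6, 3)` vs. `Beta(3, 6)`), the regime where coupling information
#' can improve over pure thresholding. Co-function network and gold
#' standards are built as in [simulate_benchmark()].
#'
#' @param n_tfs Number of regulators (default 10).
#' @param n_genes Number of candidate target genes (default 120).
#' @param targets_per_tf Mean true targets per TF (default 8).
#' @param decoy_rate Decoy links per true link (default 1).
#' @param threshold Planted weight threshold `t` in `(0, 1)` (default
#'   0.5).
#' @param separation `"wide"` or `"overlap"`.
#' @param cofn_coverage,gold_reg_fraction,gold_cofn_coverage Coverage
#'   fractions as in [simulate_benchmark()] (defaults 0.8, 0.5, 0.5).
#' @param seed Integer seed.
#' @return List with `network` (true + decoy links with weights), `truth`,
#'   `cofn`, `gold`, `params`.
#' @export
simulate_weighted_grn <- function(n_tfs = 10, n_genes = 120,
                                  targets_per_tf = 8, decoy_rate = 1,
                                  threshold = 0.5,
                                  separation = c("wide", "overlap"),
                                  cofn_coverage = 0.8,
                                  gold_reg_fraction = 0.5,
                                  gold_cofn_coverage = 0.5, seed = 1) {
  separation <- match.arg(separation)
  stopifnot(n_tfs >= 2, n_genes >= 10, threshold > 0, threshold < 1)
  set.seed(seed)
  tfs <- sprintf("TF%04d", seq_len(n_tfs))
  others <- sprintf("G%05d", seq_len(n_genes))

  truth <- do.call(rbind, lapply(tfs, function(tf) {
    k <- min(2 + stats::rpois(1, targets_per_tf - 2), length(others))
    data.frame(regulator = tf, target = sample(others, k),
               stringsAsFactors = FALSE)
  }))
  truth <- unique(truth)
  true_ids <- link_id(truth$regulator, truth$target)

  n_decoy <- round(decoy_rate * nrow(truth))
  decoys <- data.frame(regulator = character(0), target = character(0))
  if (n_decoy > 0) {
    pool_r <- sample(tfs, 4 * n_decoy, replace = TRUE)
    pool_t <- sample(others, 4 * n_decoy, replace = TRUE)
    ok <- !(link_id(pool_r, pool_t) %in% true_ids)
    cand <- unique(data.frame(regulator = pool_r[ok], target = pool_t[ok],
                              stringsAsFactors = FALSE))
    decoys <- cand[seq_len(min(n_decoy, nrow(cand))), , drop = FALSE]
  }

  t <- threshold
  w_true <- switch(separation,
                   wide = t + (1 - t) * stats::rbeta(nrow(truth), 5, 2),
                   overlap = stats::rbeta(nrow(truth), 6, 3))
  w_decoy <- switch(separation,
                    wide = t * stats::rbeta(nrow(decoys), 2, 5),
                    overlap = stats::rbeta(nrow(decoys), 3, 6))
  network <- grn(c(truth$regulator, decoys$regulator),
                 c(truth$target, decoys$target),
                 pmin(pmax(c(w_true, w_decoy), 0), 1))

  cr <- unique(unlist(lapply(split(truth$target, truth$regulator),
                             function(tg) {
    tg <- unique(tg)
    if (length(tg) < 2) return(character(0))
    cmb <- utils::combn(sort(tg), 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))
  n_cov <- max(1, round(cofn_coverage * length(cr)))
  covered <- sample(cr, n_cov)
  n_bg <- 2 * n_cov
  bg_a <- sample(others, 3 * n_bg, replace = TRUE)
  bg_b <- sample(others, 3 * n_bg, replace = TRUE)
  ok <- bg_a != bg_b & !(pair_id(bg_a, bg_b) %in% cr)
  bg <- unique(pair_id(bg_a[ok], bg_b[ok]))
  bg <- bg[seq_len(min(n_bg, length(bg)))]
  cofn <- data.frame(pairs_to_df(c(covered, bg)),
                     weight = c(stats::rbeta(length(covered), 5, 2),
                                stats::rbeta(length(bg), 1.5, 5)),
                     stringsAsFactors = FALSE)

  gold_reg <- truth[sample.int(nrow(truth),
                               max(1, round(gold_reg_fraction * nrow(truth)))), ,
                    drop = FALSE]
  gold_cof <- pairs_to_df(sample(cr, max(1, round(gold_cofn_coverage *
                                                    length(cr)))))

  list(network = network,
       truth = grn(truth$regulator, truth$target, rep(1, nrow(truth))),
       cofn = cofn,
       gold = list(regulatory = gold_reg, cofunction = gold_cof),
       params = list(n_tfs = n_tfs, n_genes = n_genes,
                     targets_per_tf = targets_per_tf,
                     decoy_rate = decoy_rate, threshold = threshold,
                     separation = separation, seed = seed))
}
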