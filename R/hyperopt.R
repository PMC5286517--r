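#' Evaluate one hyperparameter pair on a module set
#'
#' Prunes every module at `(gamma, lambda)` (same hyperparameters for all
#' modules), unions the retained links into a candidate network, and
#' scores it against the gold standards. The initial network anchoring the
#' recall is the union of the modules' links unless supplied explicitly.
#'
#' @param gamma,lambda Hyperparameters.
#' @param modules Module list from [extract_modules()].
#' @param gold Gold-standard list (`regulatory`, `cofunction`).
#' @param initial Optional initial network for recall anchoring; defaults
#'   to all module links.
#' @param beta,jaccard_threshold,p_max Passed to [score_network()].
#' @return List with `precision_raw`, `precision_scaled`, `recall`,
#'   `f_beta`, `n_retained`.
#' @export
evaluate_theta <- function(gamma, lambda, modules, gold, initial = NULL,
                           beta = 1, jaccard_threshold = 0.5, p_max = 1,
                           recall_anchor = "gold") {
  all_links <- module_links(modules)
  if (is.null(initial)) {
    initial <- grn(all_links$regulator, all_links$target, all_links$weight)
  }
  candidate <- prune_network(modules, gamma, lambda)
  sc <- score_network(candidate, initial, gold, beta, jaccard_threshold,
                      p_max, recall_anchor)
  c(sc, list(n_retained = nrow(candidate)))
}

#' Hyperparameter search space from the observed weight distribution
#'
#' The threshold `gamma` ranges over the observed link-weight range
#' (0 percent to 100 percent quantiles of weights over the module links);
#' the coupling penalty `lambda` ranges over a user band, by default
#' `[0.001, 2.5]`, whose upper limit caps the influence of co-functional
#' coupling and guards against over-predicting master regulators.
#'
#' @param modules Module list.
#' @param lambda_range Length-2 numeric, `lambda_min > 0`.
#' @return List with `gamma_range`, `lambda_range`, `weights` (sorted link
#'   weights, used to place grid levels at empirical quantiles).
#' @export
search_space <- function(modules, lambda_range = c(0.001, 2.5)) {
  stopifnot(length(lambda_range) == 2, lambda_range[1] > 0,
            lambda_range[2] > lambda_range[1])
  w <- sort(module_links(modules)$weight)
  list(gamma_range = range(w), lambda_range = lambda_range, weights = w)
}

# Grid levels: gamma at empirical weight quantiles (scale-free in the
# weight distribution), lambda log-spaced across its band.
grid_levels <- function(space, resolution = c(10, 10)) {
  gam <- unique(stats::quantile(space$weights,
                                seq(0, 1, length.out = resolution[1]),
                                names = FALSE, type = 7))
  lam <- exp(seq(log(space$lambda_range[1]), log(space$lambda_range[2]),
                 length.out = resolution[2]))
  list(gamma = gam, lambda = lam)
}

#' Coarse grid search over the hyperparameter space
#'
#' Evaluates the objective on a Cartesian grid — `gamma` at empirical
#' weight quantiles, `lambda` log-spaced — and returns the best cell plus
#' a sub-space of one grid step around it (clipped to the space) for the
#' annealing stage. The precision scale `P_max` (the maximum raw precision
#' observed on the grid) is fixed here and reused, frozen, by the
#' annealing stage so the objective stays stationary. Ties are broken
#' toward the lowest `lambda`, then the lowest `gamma` (the conservative
#' preference for weak coupling).
#'
#' @param modules,gold,initial,beta,jaccard_threshold As in
#'   [evaluate_theta()].
#' @param space Search space from [search_space()].
#' @param resolution Integer 2-vector: grid points per axis (default
#'   `c(10, 10)`; at least 2 each).
#' @return List with `trace` (data.frame: gamma, lambda, precision_raw,
#'   recall, f_beta), `best` (gamma, lambda, f_beta), `sub_space`
#'   (gamma_range, lambda_range), `p_max`.
#' @export
grid_search <- function(modules, gold, space = search_space(modules),
                        resolution = c(10, 10), initial = NULL, beta = 1,
                        jaccard_threshold = 0.5, recall_anchor = "gold") {
  stopifnot(all(resolution >= 2))
  lv <- grid_levels(space, resolution)
  cells <- expand.grid(gamma = lv$gamma, lambda = lv$lambda,
                       KEEP.OUT.ATTRS = FALSE)
  raw <- lapply(seq_len(nrow(cells)), function(i) {
    evaluate_theta(cells$gamma[i], cells$lambda[i], modules, gold, initial,
                   beta, jaccard_threshold, p_max = 1,
                   recall_anchor = recall_anchor)
  })
  P <- vapply(raw, `[[`, 0, "precision_raw")
  R <- vapply(raw, `[[`, 0, "recall")
  p_max <- max(P)
  Ph <- if (p_max > 0) pmin(1, P / p_max) else rep(0, length(P))
  f <- mapply(f_beta_score, Ph, R, MoreArgs = list(beta = beta))
  trace <- data.frame(gamma = cells$gamma, lambda = cells$lambda,
                      precision_raw = P, recall = R, f_beta = f)
  # best cell: max f, ties to lowest lambda then lowest gamma
  best_i <- order(-f, cells$lambda, cells$gamma)[1]
  gi <- match(cells$gamma[best_i], lv$gamma)
  li <- match(cells$lambda[best_i], lv$lambda)
  sub <- list(
    gamma_range = c(lv$gamma[max(1, gi - 1)],
                    lv$gamma[min(length(lv$gamma), gi + 1)]),
    lambda_range = c(lv$lambda[max(1, li - 1)],
                     lv$lambda[min(length(lv$lambda), li + 1)])
  )
  list(trace = trace,
       best = list(gamma = cells$gamma[best_i], lambda = cells$lambda[best_i],
                   f_beta = f[best_i]),
       sub_space = sub, p_max = p_max, grid = lv)
}

#' Simulated annealing refinement within a sub-space
#'
#' Metropolis search on the negative objective with geometric cooling.
#' Proposals are per-axis Gaussian steps with scale 10 percent of the
#' sub-space width, reflected at the boundaries. After cooling, the final
#' estimate is chosen conservatively: among all visited points whose
#' objective is within a relative tolerance `delta_f` of the best visited
#' value, the one with the smallest `lambda` (then smallest `gamma`) wins
#' — near-equivalent optima are resolved toward the weakest coupling,
#' which avoids over-predicting master regulators. Deterministic given
#' `seed`.
#'
#' @param modules,gold,initial,beta,jaccard_threshold As in
#'   [evaluate_theta()].
#' @param sub_space List with `gamma_range`, `lambda_range`.
#' @param theta_init List with `gamma`, `lambda` (e.g. the grid best).
#' @param p_max Frozen precision scale from [grid_search()].
#' @param t0 Initial temperature (default 1).
#' @param cooling Geometric cooling factor (default 0.9).
#' @param n_levels Temperature levels (default 50).
#' @param n_per_level Proposals per level (default 4).
#' @param delta_f Relative near-optimality tolerance (default 0.01).
#' @param seed Integer seed.
#' @return List with `theta` (gamma, lambda), `f_beta`, `trace`
#'   (data.frame of visited points).
#' @export
simulated_annealing <- function(modules, gold, sub_space, theta_init,
                                p_max = 1, initial = NULL, beta = 1,
                                jaccard_threshold = 0.5,
                                recall_anchor = "gold", t0 = 1,
                                cooling = 0.9, n_levels = 50,
                                n_per_level = 4, delta_f = 0.01, seed = 1) {
  gr <- sub_space$gamma_range
  lr <- sub_space$lambda_range
  stopifnot(theta_init$gamma >= gr[1] - 1e-12,
            theta_init$gamma <= gr[2] + 1e-12,
            theta_init$lambda >= lr[1] - 1e-12,
            theta_init$lambda <= lr[2] + 1e-12)
  reflect <- function(x, lo, hi) {
    if (hi <= lo) return(lo)
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    lo + ifelse(y > span, 2 * span - y, y)
  }
  obj <- function(gamma, lambda) {
    evaluate_theta(gamma, lambda, modules, gold, initial, beta,
                   jaccard_threshold, p_max = p_max,
                   recall_anchor = recall_anchor)$f_beta
  }
  set.seed(seed)
  cur <- c(theta_init$gamma, theta_init$lambda)
  f_cur <- obj(cur[1], cur[2])
  visited_g <- cur[1]; visited_l <- cur[2]; visited_f <- f_cur
  sd_g <- 0.1 * (gr[2] - gr[1])
  sd_l <- 0.1 * (lr[2] - lr[1])
  temp <- t0
  for (lev in seq_len(n_levels)) {
    for (it in seq_len(n_per_level)) {
      prop <- c(reflect(cur[1] + stats::rnorm(1, 0, max(sd_g, 1e-12)),
                        gr[1], gr[2]),
                reflect(cur[2] + stats::rnorm(1, 0, max(sd_l, 1e-12)),
                        lr[1], lr[2]))
      f_prop <- obj(prop[1], prop[2])
      if (f_prop >= f_cur ||
          stats::runif(1) < exp((f_prop - f_cur) / temp)) {
        cur <- prop
        f_cur <- f_prop
      }
      visited_g <- c(visited_g, prop[1])
      visited_l <- c(visited_l, prop[2])
      visited_f <- c(visited_f, f_prop)
    }
    temp <- temp * cooling
  }
  f_best <- max(visited_f)
  near <- which(visited_f >= (1 - delta_f) * f_best)
  pick <- near[order(visited_l[near], visited_g[near])[1]]
  list(theta = list(gamma = visited_g[pick], lambda = visited_l[pick]),
       f_beta = visited_f[pick],
       trace = data.frame(gamma = visited_g, lambda = visited_l,
                          f_beta = visited_f))
}

#' Learn hyperparameters by coarse-to-fine optimization
#'
#' Runs [grid_search()] to localize a promising sub-space and fix the
#' precision scale, then [simulated_annealing()] within it. The returned
#' pair maximizes the combined f-beta objective up to the conservative
#' lowest-lambda selection rule.
#'
#' @inheritParams grid_search
#' @param anneal List of annealing settings overriding the defaults of
#'   [simulated_annealing()] (`t0`, `cooling`, `n_levels`, `n_per_level`,
#'   `delta_f`).
#' @param seed Integer seed for the annealing stage.
#' @return List with `theta` (gamma, lambda), `f_beta`, `p_max`,
#'   `grid_trace`, `anneal_trace`.
#' @export
learn_theta <- function(modules, gold, lambda_range = c(0.001, 2.5),
                        resolution = c(10, 10), initial = NULL, beta = 1,
                        jaccard_threshold = 0.5, recall_anchor = "gold",
                        anneal = list(), seed = 1) {
  space <- search_space(modules, lambda_range)
  gs <- grid_search(modules, gold, space, resolution, initial, beta,
                    jaccard_threshold, recall_anchor)
  args <- utils::modifyList(
    list(modules = modules, gold = gold, sub_space = gs$sub_space,
         theta_init = gs$best, p_max = gs$p_max, initial = initial,
         beta = beta, jaccard_threshold = jaccard_threshold,
         recall_anchor = recall_anchor, seed = seed),
    anneal
  )
  sa <- do.call(simulated_annealing, args)
  # the grid best seeds the visited set, so the conservative pick can
  # never trail the grid optimum beyond the delta_f tolerance
  list(theta = sa$theta, f_beta = sa$f_beta, p_max = gs$p_max,
       grid_trace = gs$trace, anneal_trace = sa$trace)
}
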