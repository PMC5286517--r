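#' Split modules into a train and test set
#'
#' Uniformly samples `round(fraction * M)` modules without replacement as
#' the training set (default fraction 0.632, the classic hold-out
#' convention) and leaves the remainder as test set. The gold standards
#' are partitioned along with the modules: a regulatory gold pair follows
#' the module containing its link (pairs matching no module link are
#' dropped); a co-function gold pair belongs to a split when both genes
#' occur as targets of that split's modules.
#'
#' @param modules Module list.
#' @param gold Gold-standard list (`regulatory`, `cofunction`).
#' @param fraction Training fraction in `(0, 1)` (default 0.632).
#' @param seed Integer seed.
#' @return List with `train`, `test`; each has `modules`, `gold`.
#' @export
holdout_split <- function(modules, gold, fraction = 0.632, seed = 1) {
  M <- length(modules)
  if (M < 2) stop("need at least 2 modules to split")
  n_train <- round(fraction * M)
  if (n_train < 1 || n_train >= M) stop("split leaves an empty train or test set")
  set.seed(seed)
  idx <- sort(sample.int(M, n_train))
  split_gold <- function(mods) {
    lk <- module_links(mods)
    ids <- link_id(lk$regulator, lk$target)
    reg <- gold$regulatory[link_id(gold$regulatory$regulator,
                                   gold$regulatory$target) %in% ids, ,
                           drop = FALSE]
    targets <- unique(lk$target)
    cof <- gold$cofunction[gold$cofunction$gene_a %in% targets &
                             gold$cofunction$gene_b %in% targets, ,
                           drop = FALSE]
    list(regulatory = reg, cofunction = cof)
  }
  train_mod <- modules[idx]
  test_mod <- modules[-idx]
  list(train = list(modules = train_mod, gold = split_gold(train_mod)),
       test = list(modules = test_mod, gold = split_gold(test_mod)))
}

#' Train one hold-out round
#'
#' Learns hyperparameters on the training modules and training gold
#' standard, applies them to ALL modules (so the ensemble vote is defined
#' for every link), and reports the test-set enrichment: gold recovery in
#' the pruned test modules versus the unpruned test modules as
#' background.
#'
#' @param round_index Round number (used to derive the round seed).
#' @param modules Full module list.
#' @param gold Full gold-standard list.
#' @param seed Global integer seed; the round seed is
#'   `derive_seed(seed, round_index)`.
#' @param fraction Training fraction.
#' @param hyperopt List of settings forwarded to [learn_theta()]
#'   (`lambda_range`, `resolution`, `beta`, `jaccard_threshold`,
#'   `anneal`).
#' @return List with `round`, `theta`, `f_beta`, `retained` (network
#'   `data.frame` over all modules), `test_enrichment` (list with
#'   `fold_change`, `p_value`, or `NULL` when the test split has no gold
#'   hits).
#' @export
train_round <- function(round_index, modules, gold, seed = 1,
                        fraction = 0.632, hyperopt = list()) {
  rseed <- derive_seed(seed, round_index)
  sp <- holdout_split(modules, gold, fraction, seed = rseed)
  args <- utils::modifyList(
    list(modules = sp$train$modules, gold = sp$train$gold,
         seed = derive_seed(rseed, "anneal")),
    hyperopt
  )
  fit <- do.call(learn_theta, args)
  retained <- prune_network(modules, fit$theta$gamma, fit$theta$lambda)

  # test enrichment: pruned vs. unpruned test modules
  test_links <- module_links(sp$test$modules)
  test_ids <- link_id(test_links$regulator, test_links$target)
  gold_ids <- link_id(sp$test$gold$regulatory$regulator,
                      sp$test$gold$regulatory$target)
  ret_test <- link_id(retained$regulator, retained$target)
  ret_test <- ret_test[ret_test %in% test_ids]
  enr <- NULL
  if (length(gold_ids) && length(ret_test)) {
    enr <- tryCatch(
      fisher_enrichment(sum(ret_test %in% gold_ids), length(ret_test),
                        sum(test_ids %in% gold_ids), length(test_ids)),
      error = function(e) NULL
    )
  }
  list(round = round_index, theta = fit$theta, f_beta = fit$f_beta,
       retained = retained, test_enrichment = enr)
}

#' Aggregate hold-out rounds into an ensemble network
#'
#' The ensemble likelihood of a link is the unweighted vote fraction —
#' the share of rounds whose model retained it. A link enters the final
#' network only when its likelihood strictly exceeds `epsilon` (default
#' 0.5: more than half of the models must retain it; exactly half is not
#' enough).
#'
#' @param rounds List of round results from [train_round()].
#' @param epsilon Strict vote threshold in `[0, 1)` (default 0.5).
#' @return List with `likelihood` (`data.frame`: `regulator`, `target`,
#'   `likelihood`) and `final` (network `data.frame` of selected links
#'   with the likelihood as weight).
#' @export
aggregate_rounds <- function(rounds, epsilon = 0.5) {
  stopifnot(length(rounds) >= 1)
  N <- length(rounds)
  votes <- table(unlist(lapply(rounds, function(r) {
    link_id(r$retained$regulator, r$retained$target)
  })))
  L <- as.numeric(votes) / N
  parts <- strsplit(names(votes), "\r", fixed = TRUE)
  lik <- data.frame(regulator = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    likelihood = L, stringsAsFactors = FALSE)
  lik <- lik[order(lik$regulator, lik$target), , drop = FALSE]
  rownames(lik) <- NULL
  sel <- lik[lik$likelihood > epsilon, , drop = FALSE]
  list(likelihood = lik,
       final = grn(sel$regulator, sel$target, sel$likelihood))
}

#' Run the full hold-out ensemble
#'
#' Trains `n_rounds` independent models on resampled module subsets and
#' aggregates them by majority vote. Per-round seeds are derived from the
#' global seed and the round index, so the result does not depend on
#' execution order and is reproducible.
#'
#' @param modules Module list.
#' @param gold Gold-standard list.
#' @param n_rounds Number of hold-out rounds (default 100).
#' @param fraction Training fraction (default 0.632).
#' @param epsilon Vote threshold (default 0.5).
#' @param seed Global integer seed.
#' @param hyperopt Settings forwarded to [learn_theta()].
#' @return List with `final`, `likelihood` (see [aggregate_rounds()]),
#'   `rounds` (per-round summaries: theta, f_beta, test enrichment) and
#'   `n_rounds`.
#' @export
run_ensemble <- function(modules, gold, n_rounds = 100, fraction = 0.632,
                         epsilon = 0.5, seed = 1, hyperopt = list()) {
  rounds <- lapply(seq_len(n_rounds), function(n) {
    train_round(n, modules, gold, seed = seed, fraction = fraction,
                hyperopt = hyperopt)
  })
  agg <- aggregate_rounds(rounds, epsilon)
  summaries <- do.call(rbind, lapply(rounds, function(r) {
    data.frame(round = r$round, gamma = r$theta$gamma,
               lambda = r$theta$lambda, f_beta = r$f_beta,
               n_retained = nrow(r$retained),
               test_fold_change = if (is.null(r$test_enrichment)) NA_real_
                                  else r$test_enrichment$fold_change,
               test_p_value = if (is.null(r$test_enrichment)) NA_real_
                              else r$test_enrichment$p_value)
  }))
  list(final = agg$final, likelihood = agg$likelihood, rounds = summaries,
       round_details = rounds, n_rounds = n_rounds)
}
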