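#' Average replicates and filter low-variance genes
#'
#' Collapses experimental replicates to their per-group mean and removes
#' genes whose across-condition variance falls below a sample quantile of
#' all gene variances. This is the standard preprocessing applied before
#' expression-based network inference: replicate averaging reduces
#' technical noise, and variance filtering removes genes with no usable
#' expression signal.
#'
#' @param expr Numeric matrix, genes x conditions, with rownames (gene IDs)
#'   and colnames (condition IDs). No missing values.
#' @param replicate_map Named character vector mapping every condition ID to
#'   a replicate-group label. Conditions sharing a label are averaged.
#' @param variance_quantile Fraction in `[0, 1)`; genes with variance
#'   strictly below this quantile of all gene variances are dropped.
#'   `0` retains every gene.
#' @return Numeric matrix with one column per replicate group (in order of
#'   first appearance) and surviving genes in their original order.
#' @export
preprocess_expression <- function(expr, replicate_map = NULL,
                                  variance_quantile = 0) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene IDs in expression matrix")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!(variance_quantile >= 0 && variance_quantile < 1)) {
    stop("variance_quantile must lie in [0, 1)")
  }
  if (is.null(replicate_map)) {
    replicate_map <- stats::setNames(colnames(expr), colnames(expr))
  }
  missing_cond <- setdiff(colnames(expr), names(replicate_map))
  if (length(missing_cond)) {
    stop("conditions missing from replicate_map: ",
         paste(missing_cond, collapse = ", "))
  }
  groups <- unique(unname(replicate_map[colnames(expr)]))
  if (!length(groups)) stop("replicate_map defines no groups")
  avg <- vapply(groups, function(g) {
    members <- colnames(expr)[replicate_map[colnames(expr)] == g]
    if (!length(members)) stop("replicate group with zero members: ", g)
    rowMeans(expr[, members, drop = FALSE])
  }, numeric(nrow(expr)))
  avg <- matrix(avg, nrow = nrow(expr),
                dimnames = list(rownames(expr), groups))
  if (ncol(avg) < 2) stop("need at least 2 conditions after replicate averaging")
  v <- apply(avg, 1, stats::var)
  if (variance_quantile > 0) {
    cut <- stats::quantile(v, variance_quantile, names = FALSE)  # type 7
    avg <- avg[v >= cut, , drop = FALSE]
  }
  if (!nrow(avg)) stop("no genes left after variance filtering")
  avg
}

#' Infer regulator-to-target importance scores by tree-ensemble regression
#'
#' Decomposes network inference into one regression problem per target
#' gene: the target's expression profile is regressed on the profiles of
#' all transcription factors (excluding the target itself when it is a TF)
#' with a random forest, and each TF's importance — total impurity
#' (variance) reduction accumulated over splits — becomes the raw evidence
#' for a directed regulatory link TF -> target.
#'
#' Each target uses a seed derived from `seed` and the target's ID via
#' [derive_seed()], so results do not depend on target iteration order and
#' are bitwise reproducible.
#'
#' @param expr Numeric matrix, genes x conditions (preprocessed).
#' @param tf_list Character vector of regulator gene IDs; must be a subset
#'   of `rownames(expr)`.
#' @param n_trees Number of trees per target regression (default 1000).
#' @param seed Integer global seed.
#' @return `data.frame` with columns `regulator`, `target`, `importance`
#'   (non-negative raw importances), one row per TF-target pair.
#' @export
infer_importance_network <- function(expr, tf_list, n_trees = 1000, seed = 1) {
  stopifnot(is.matrix(expr), n_trees >= 1)
  tf_list <- unique(as.character(tf_list))
  if (!length(tf_list)) stop("tf_list is empty")
  missing_tf <- setdiff(tf_list, rownames(expr))
  if (length(missing_tf)) {
    stop("TFs absent from expression matrix: ",
         paste(missing_tf, collapse = ", "))
  }
  targets <- rownames(expr)
  X <- t(expr[tf_list, , drop = FALSE])  # conditions x TFs
  res <- lapply(targets, function(tg) {
    preds <- setdiff(tf_list, tg)
    if (!length(preds)) return(NULL)
    y <- expr[tg, ]
    if (stats::var(y) == 0) {
      imp <- stats::setNames(rep(0, length(preds)), preds)
    } else {
      dat <- data.frame(..y = y, X[, preds, drop = FALSE], check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = "..y", data = dat,
        num.trees = n_trees, importance = "impurity",
        seed = derive_seed(seed, tg), num.threads = 1
      )
      imp <- pmax(fit$variable.importance[preds], 0)
    }
    data.frame(regulator = preds, target = tg, importance = unname(imp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank-normalize importances and keep the top fraction
#'
#' Maps every raw importance to its empirical cumulative distribution value
#' over all scores, `ECDF(x) = #(scores <= x) / n`, and keeps links whose
#' ECDF value strictly exceeds `1 - keep_fraction`. The ECDF value itself
#' becomes the normalized link weight, so output weights lie in `(0, 1]`
#' and preserve the raw-importance ordering. Tied scores share one ECDF
#' value and are kept or dropped together, so the returned count can
#' slightly exceed `keep_fraction * n` in the presence of ties.
#'
#' @param scores `data.frame` with columns `regulator`, `target`,
#'   `importance` as returned by [infer_importance_network()].
#' @param keep_fraction Fraction in `(0, 1]` of top-ranked links to keep
#'   (default 0.05, i.e. the top 5 percent).
#' @return Network `data.frame` (`regulator`, `target`, `weight`) of the
#'   retained links with ECDF weights.
#' @export
ecdf_filter <- function(scores, keep_fraction = 0.05) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (!nrow(scores)) stop("empty score list")
  n <- nrow(scores)
  # #(scores <= x)/n; ties share a value
  ec <- vapply(scores$importance,
               function(x) sum(scores$importance <= x), 0L) / n
  keep <- ec > 1 - keep_fraction
  grn(scores$regulator[keep], scores$target[keep], ec[keep])
}

#' Intersect expression-based links with a binding network
#'
#' Retains exactly the expression-derived links whose (regulator, target)
#' pair also has transcription-factor binding evidence; ECDF weights are
#' preserved. This is the integrative step producing the initial network
#' that the downstream refinement prunes.
#'
#' @param expr_links Network `data.frame` from [ecdf_filter()].
#' @param binding `data.frame` with columns `regulator`, `target` (an
#'   unweighted edge list of binding evidence).
#' @return Network `data.frame` of the intersection. Warns when empty.
#' @export
intersect_with_binding <- function(expr_links, binding) {
  keep <- link_id(expr_links$regulator, expr_links$target) %in%
    link_id(binding$regulator, binding$target)
  if (!any(keep)) warning("binding intersection is empty")
  grn(expr_links$regulator[keep], expr_links$target[keep],
      expr_links$weight[keep])
}

#' Build the initial integrative gene regulatory network
#'
#' Convenience wrapper chaining [infer_importance_network()],
#' [ecdf_filter()] and [intersect_with_binding()].
#'
#' @inheritParams infer_importance_network
#' @inheritParams ecdf_filter
#' @param binding Binding edge list (`regulator`, `target`).
#' @return Network `data.frame` (`regulator`, `target`, `weight`).
#' @export
infer_initial_grn <- function(expr, tf_list, binding, keep_fraction = 0.05,
                              n_trees = 1000, seed = 1) {
  scores <- infer_importance_network(expr, tf_list, n_trees, seed)
  intersect_with_binding(ecdf_filter(scores, keep_fraction), binding)
}
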