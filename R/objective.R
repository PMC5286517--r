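#' Gene pairs co-regulated under the Jaccard criterion
#'
#' A gene pair (g, g') counts as co-regulated when the Jaccard coefficient
#' of their regulator sets, `|R_g intersect R_g'| / |R_g union R_g'|`,
#' strictly exceeds the threshold (default 0.5, i.e. "higher than 50%").
#' Genes without any regulator in the network are excluded. Only pairs
#' sharing at least one regulator can exceed a positive threshold, so the
#' search is restricted to within-regulon candidate pairs.
#'
#' @param network Network `data.frame` (`regulator`, `target`, ...).
#' @param jaccard_threshold Strict lower bound on the Jaccard coefficient,
#'   in `[0, 1]` (default 0.5).
#' @return Character vector of canonical unordered pair ids (internal
#'   representation); use [pairs_to_df()] for a two-column table.
#' @export
coregulated_pairs <- function(network, jaccard_threshold = 0.5) {
  stopifnot(jaccard_threshold >= 0, jaccard_threshold <= 1)
  if (!nrow(network)) return(character(0))
  regsets <- split(network$regulator, network$target)
  regsets <- lapply(regsets, unique)
  sizes <- lengths(regsets)
  # candidate pairs: targets sharing >= 1 regulator
  by_reg <- split(network$target, network$regulator)
  cand <- unique(unlist(lapply(by_reg, function(tg) {
    tg <- unique(tg)
    if (length(tg) < 2) return(character(0))
    cmb <- utils::combn(sort(tg), 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))
  if (!length(cand)) return(character(0))
  parts <- strsplit(cand, "\r", fixed = TRUE)
  g1 <- vapply(parts, `[`, "", 1)
  g2 <- vapply(parts, `[`, "", 2)
  jac <- vapply(seq_along(g1), function(i) {
    inter <- length(intersect(regsets[[g1[i]]], regsets[[g2[i]]]))
    inter / (sizes[[g1[i]]] + sizes[[g2[i]]] - inter)
  }, 0)
  sort(cand[jac > jaccard_threshold])
}

#' Convert canonical pair ids to a two-column data frame
#'
#' @param pairs Character vector of canonical pair ids.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
pairs_to_df <- function(pairs) {
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1),
             gene_b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Precision against the regulatory gold standard
#'
#' Raw precision: gold-standard links recovered over predictions made. By
#' default the denominator is restricted to gold-evaluable predictions —
#' links whose regulator occurs in the gold standard — because with a
#' sparse curated map, predictions for regulators the gold standard never
#' saw carry no information about correctness.
#'
#' @param predicted Network `data.frame` of predicted links.
#' @param gold_regulatory `data.frame` with columns `regulator`, `target`
#'   of curated positive links.
#' @param restrict_to_gold_regulators If `TRUE` (default), only
#'   predictions whose regulator appears in the gold standard enter the
#'   denominator.
#' @return Precision in `[0, 1]`; 0 with a warning when no prediction is
#'   evaluable.
#' @export
precision_regulatory <- function(predicted, gold_regulatory,
                                 restrict_to_gold_regulators = TRUE) {
  if (restrict_to_gold_regulators) {
    evaluable <- predicted[predicted$regulator %in%
                             unique(gold_regulatory$regulator), ,
                           drop = FALSE]
  } else {
    evaluable <- predicted
  }
  if (!nrow(evaluable)) {
    warning("no gold-evaluable predictions; precision set to 0")
    return(0)
  }
  hits <- sum(link_id(evaluable$regulator, evaluable$target) %in%
                link_id(gold_regulatory$regulator, gold_regulatory$target))
  hits / nrow(evaluable)
}

#' Co-functional recall of a pruned network
#'
#' The numerator is always the number of the pruned network's co-regulated
#' gene pairs carrying co-function annotation. Two denominators ("anchors")
#' are supported:
#'
#' * `"gold"` (default): all co-annotated pairs whose genes both occur as
#'   targets of the initial network — the reachable part of the annotation
#'   universe. This anchor rewards pruning that exposes true co-regulons:
#'   removing a spurious regulator raises a pair's Jaccard coefficient
#'   above the threshold, so recall can increase under pruning.
#' * `"initial"`: the same co-annotated co-regulated count computed on the
#'   initial (unpruned) network. Because spurious regulators dilute the
#'   initial network's Jaccard sets, this denominator can be very small,
#'   in which case the recall saturates; the ratio is capped at 1.
#'
#' @param predicted Pruned network (`data.frame`); its links must be a
#'   subset of `initial`'s.
#' @param initial Initial network (`data.frame`).
#' @param gold_cofunction `data.frame` with columns `gene_a`, `gene_b` of
#'   co-annotated gene pairs.
#' @param jaccard_threshold Passed to [coregulated_pairs()].
#' @param anchor `"gold"` or `"initial"` (see above).
#' @return Recall in `[0, 1]`; 0 with a warning when the denominator is
#'   empty.
#' @export
recall_cofunctional <- function(predicted, initial, gold_cofunction,
                                jaccard_threshold = 0.5,
                                anchor = c("gold", "initial")) {
  anchor <- match.arg(anchor)
  gold_pairs <- unique(pair_id(gold_cofunction$gene_a,
                               gold_cofunction$gene_b))
  if (anchor == "gold") {
    targets <- unique(initial$target)
    gp <- pairs_to_df(gold_pairs)
    den <- sum(gp$gene_a %in% targets & gp$gene_b %in% targets)
  } else {
    den <- sum(coregulated_pairs(initial, jaccard_threshold) %in% gold_pairs)
  }
  if (den == 0) {
    warning("no co-annotated pairs to recall; recall set to 0")
    return(0)
  }
  num <- sum(coregulated_pairs(predicted, jaccard_threshold) %in% gold_pairs)
  min(1, num / den)
}

#' Combined f-beta score of scaled precision and co-functional recall
#'
#' `f_beta = (1 + beta^2) * P * R / (beta^2 * P + R)`, the weighted
#' harmonic mean; `beta = 1` gives equal emphasis, larger `beta` shifts
#' emphasis toward recall. Returns 0 when both arguments are 0.
#'
#' @param precision_scaled Scaled precision in `[0, 1]`.
#' @param recall Recall in `[0, 1]`.
#' @param beta Positive emphasis exponent (default 1).
#' @return Score in `[0, 1]`.
#' @export
f_beta_score <- function(precision_scaled, recall, beta = 1) {
  stopifnot(beta > 0,
            precision_scaled >= 0, precision_scaled <= 1,
            recall >= 0, recall <= 1)
  if (precision_scaled == 0 && recall == 0) return(0)
  (1 + beta^2) * precision_scaled * recall /
    (beta^2 * precision_scaled + recall)
}

#' Enrichment of gold-standard hits over a background
#'
#' Compares the hit rate among predictions with the hit rate in a
#' background set containing them (typically the maximum number of
#' possible links, i.e. a fully connected background). Reports the fold
#' change of rates and a one-sided (greater) Fisher's exact p-value on the
#' 2x2 table of predictions vs. the remaining background.
#'
#' @param hits_pred,n_pred Gold hits among the predictions and number of
#'   predictions.
#' @param hits_bg,n_bg Gold hits in, and size of, the full background
#'   (which includes the predictions; `n_bg >= n_pred`,
#'   `hits_bg >= hits_pred`).
#' @return List with `fold_change` and `p_value`.
#' @export
fisher_enrichment <- function(hits_pred, n_pred, hits_bg, n_bg) {
  stopifnot(hits_pred <= n_pred, hits_bg <= n_bg,
            n_bg >= n_pred, hits_bg >= hits_pred)
  if (hits_bg == 0) stop("no gold hits in background; fold change undefined")
  tab <- matrix(c(hits_pred, n_pred - hits_pred,
                  hits_bg - hits_pred,
                  (n_bg - n_pred) - (hits_bg - hits_pred)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent contingency counts")
  list(
    fold_change = (hits_pred / n_pred) / (hits_bg / n_bg),
    p_value = stats::fisher.test(tab, alternative = "greater")$p.value
  )
}

#' Score a candidate network against both gold standards
#'
#' Computes raw regulatory precision, co-functional recall anchored to the
#' initial network, and the combined f-beta score with precision scaled by
#' `p_max` (values above `p_max` are capped at scaled precision 1).
#'
#' @param predicted,initial Candidate and initial networks.
#' @param gold List with `regulatory` (`regulator`, `target`) and
#'   `cofunction` (`gene_a`, `gene_b`) data frames.
#' @param beta f-score exponent.
#' @param jaccard_threshold Jaccard co-regulation threshold.
#' @param p_max Precision scale; `P_hat = min(1, P / p_max)`. Use 1 for
#'   unscaled precision.
#' @param recall_anchor Passed to [recall_cofunctional()].
#' @return List with `precision_raw`, `precision_scaled`, `recall`,
#'   `f_beta`.
#' @export
score_network <- function(predicted, initial, gold, beta = 1,
                          jaccard_threshold = 0.5, p_max = 1,
                          recall_anchor = "gold") {
  P <- suppressWarnings(precision_regulatory(predicted, gold$regulatory))
  R <- suppressWarnings(recall_cofunctional(predicted, initial,
                                            gold$cofunction,
                                            jaccard_threshold,
                                            recall_anchor))
  Ph <- if (p_max > 0) min(1, P / p_max) else 0
  list(precision_raw = P, precision_scaled = Ph, recall = R,
       f_beta = f_beta_score(Ph, R, beta))
}
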