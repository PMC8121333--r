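#' Evaluate a ranked edge list against a gold standard
#'
#' Edge presence/absence evaluation over a candidate universe of ordered
#' non-self gene pairs (pairs missing from `scores` — e.g. discarded by sign
#' tie-breaking — re-enter with score 0 so the universe stays complete).
#'
#' `auroc()` is the rank-based estimator: the probability that a random true
#' edge outranks a random non-edge, ties counted one half — equivalent to
#' trapezoidal integration of the ROC curve. `aupr()` integrates the
#' non-interpolated precision-recall curve over descending unique score
#' thresholds, `sum_i (R_i - R_(i-1)) * P_i`. `evaluate_ranking()` bundles
#' both with the positive-fraction AUPR baseline.
#'
#' @param scores data frame with columns `regulator`, `target`, `score`.
#' @param gold a `pepn_gold` table (presence only; signs ignored).
#' @param candidates optional tibble of candidate pairs; defaults to
#'   [all_pairs()] over the genes appearing in `scores` and `gold`.
#' @return `evaluate_ranking()`: a one-row tibble of class `pepn_eval` with
#'   `auroc`, `aupr`, `baseline_aupr`, `n_candidates`, `n_positives` (and the
#'   ROC/PR curves in attributes). `auroc()`/`aupr()` return a single number,
#'   `NA` (with a warning) when a class is empty.
#' @export
evaluate_ranking <- function(scores, gold, candidates = NULL) {
  lab <- candidate_labels(scores, gold, candidates)
  out <- tibble::tibble(
    auroc = auroc_impl(lab$score, lab$label),
    aupr = aupr_impl(lab$score, lab$label),
    baseline_aupr = mean(lab$label),
    n_candidates = nrow(lab),
    n_positives = sum(lab$label)
  )
  attr(out, "curves") <- pr_roc_curves(lab$score, lab$label)
  class(out) <- c("pepn_eval", class(out))
  out
}

#' @rdname evaluate_ranking
#' @export
auroc <- function(scores, gold, candidates = NULL) {
  lab <- candidate_labels(scores, gold, candidates)
  auroc_impl(lab$score, lab$label)
}

#' @rdname evaluate_ranking
#' @export
aupr <- function(scores, gold, candidates = NULL) {
  lab <- candidate_labels(scores, gold, candidates)
  aupr_impl(lab$score, lab$label)
}

candidate_labels <- function(scores, gold, candidates = NULL) {
  if (is.null(candidates)) {
    genes <- sort(unique(c(
      scores$regulator, scores$target, gold$regulator, gold$target
    )))
    candidates <- all_pairs(genes)
  }
  candidates <- candidates[candidates$regulator != candidates$target, ]
  key <- function(r, t) paste(r, t, sep = "\r")
  s <- scores$score[match(
    key(candidates$regulator, candidates$target),
    key(scores$regulator, scores$target)
  )]
  s[is.na(s)] <- 0
  tibble::tibble(
    regulator = candidates$regulator, target = candidates$target,
    score = s,
    label = as.integer(key(candidates$regulator, candidates$target) %in%
      key(gold$regulator, gold$target))
  )
}

auroc_impl <- function(score, label) {
  np <- sum(label == 1)
  nn <- sum(label == 0)
  if (np == 0 || nn == 0) {
    warning("AUROC undefined: need both positives and negatives")
    return(NA_real_)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

aupr_impl <- function(score, label) {
  np <- sum(label == 1)
  if (np == 0 || all(label == 1)) {
    warning("AUPR undefined: need both positives and negatives")
    return(NA_real_)
  }
  cur <- pr_roc_curves(score, label)$pr
  sum(diff(c(0, cur$recall)) * cur$precision)
}

pr_roc_curves <- function(score, label) {
  np <- sum(label == 1)
  nn <- sum(label == 0)
  ord <- order(-score)
  s <- score[ord]
  l <- label[ord]
  grp_end <- cumsum(rle(s)$lengths) # last index of each unique threshold
  tp <- cumsum(l)[grp_end]
  fp <- (grp_end - cumsum(l)[grp_end])
  list(
    pr = tibble::tibble(
      threshold = s[grp_end],
      recall = tp / np,
      precision = tp / (tp + fp)
    ),
    roc = tibble::tibble(
      threshold = s[grp_end],
      fpr = c(fp / nn),
      tpr = c(tp / np)
    )
  )
}

#' Average rank of true and random edges in a ranked list
#'
#' Candidates are ranked 1..N by descending score (ties broken
#' lexicographically by regulator then target). Returns the mean rank of the
#' gold edges and the mean rank of a seeded uniform sample of candidate
#' pairs; an inferred ranking is good when true edges rank low and random
#' edges rank high.
#'
#' @inheritParams evaluate_ranking
#' @param n_random size of the random-pair sample (without replacement,
#'   capped at the number of candidates).
#' @param seed RNG seed for the random sample.
#' @return one-row tibble: `rank_true`, `rank_random`, `n_ranked`.
#' @export
average_rank <- function(scores, gold, candidates = NULL, n_random = 100, seed = 1) {
  lab <- candidate_labels(scores, gold, candidates)
  ord <- order(-lab$score, lab$regulator, lab$target, method = "radix")
  lab <- lab[ord, ]
  n <- nrow(lab)
  idx <- withr::with_seed(seed, sample.int(n, min(n_random, n)))
  tibble::tibble(
    rank_true = mean(which(lab$label == 1)),
    rank_random = mean(idx),
    n_ranked = n
  )
}

#' DREAM challenge overall score
#'
#' Given per-network p-values for AUROC and AUPR (computed externally against
#' the challenge null distributions), the per-metric score is
#' `-mean(log10(p))` and the overall score is the mean of the two.
#'
#' @param p_auroc,p_aupr numeric vectors of p-values in (0, 1].
#' @return one-row tibble: `score_auroc`, `score_aupr`, `overall`.
#' @export
dream_overall_score <- function(p_auroc, p_aupr) {
  check_p <- function(p, what) {
    if (any(p <= 0 | p > 1)) stop(what, " p-values must lie in (0, 1]", call. = FALSE)
  }
  check_p(p_auroc, "AUROC")
  check_p(p_aupr, "AUPR")
  sa <- -mean(log10(p_auroc))
  sp <- -mean(log10(p_aupr))
  tibble::tibble(score_auroc = sa, score_aupr = sp, overall = (sa + sp) / 2)
}
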