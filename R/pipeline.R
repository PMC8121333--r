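#' End-to-end network inference from a time-series expression table
#'
#' Chains the full unsupervised pipeline: discretization (skipped when `data`
#' is already a `pepn_discretized` table), evidence extraction, score
#' aggregation (`v1` or `v2`), sign selection and thresholding, returning the
#' ranked signed edge list. For the supervised variant see [run_v3()], which
#' needs a training gold standard.
#'
#' @param data a `pepn_expression` table (or pre-binned `pepn_discretized`).
#' @param variant `"v1"` (unweighted mean of evidence probabilities) or
#'   `"v2"` (count-weighted).
#' @param method discretization method passed to [discretize()].
#' @param bins number of discretization levels (2 or 3).
#' @param regulators optional TF list restricting candidate regulators.
#' @param nreg,th post-hoc thresholds (see [threshold_edges()]); the defaults
#'   `nreg = Inf`, `th = 0` keep every sign-selected pair, the setting used
#'   when ranking all gene pairs for AUROC/AUPR evaluation.
#' @param tie_tolerance passed to [select_signs()].
#' @return a ranked edge tibble (`regulator`, `target`, `sign`, `score`) with
#'   the evidence table and decay profile in attributes `evidence` and
#'   `decay`.
#' @examples
#' sim <- simulate_expression(generate_network(10, 4, seed = 3), seed = 3)
#' infer_network(sim$expression, variant = "v1", method = "efd", bins = 2)
#' @export
infer_network <- function(data, variant = c("v1", "v2"),
                          method = c("efd", "ewd", "kmeans"), bins = 2,
                          regulators = NULL, nreg = Inf, th = 0,
                          tie_tolerance = 1e-12) {
  variant <- match.arg(variant)
  disc <- if (inherits(data, "pepn_discretized")) {
    data
  } else {
    discretize(data, method = match.arg(method), bins = bins)
  }
  ev <- extract_evidence(disc, regulators = regulators)
  scored <- score_edges(ev, variant = variant)
  selected <- select_signs(scored, tolerance = tie_tolerance)
  out <- threshold_edges(selected, nreg = if (is.finite(nreg)) nreg else nrow(selected), th = th)
  attr(out, "evidence") <- ev
  attr(out, "decay") <- decay_probability(disc)
  attr(out, "variant") <- variant
  out
}
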