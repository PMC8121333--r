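#' Aggregate evidence probabilities into edge scores
#'
#' Two unsupervised aggregation variants over the four evidence types:
#'
#' * `v1` (unweighted): the score of a signed edge is the mean of its four
#'   evidence probabilities, an evidence type the target never exhibits
#'   contributing 0.
#' * `v2` (count-weighted): the score is the ratio of summed signed counts to
#'   the summed target event counts,
#'   `sum_e C_e(r,t,s) / sum_e C_e(t)` (0 when the denominator is 0), so
#'   frequent evidence types weigh more.
#'
#' @param table a [extract_evidence()] table.
#' @param variant `"v1"` or `"v2"`.
#' @return a tibble with columns `regulator`, `target`, `sign`, `score`
#'   (both signs present for every candidate pair).
#' @examples
#' x <- as_discretized(
#'   matrix(c(1, 1, 0, 0, 0, 1, 1, 0), 2,
#'     byrow = TRUE,
#'     dimnames = list(c("g1", "g2"), NULL)
#'   ),
#'   bins = 2
#' )
#' score_edges(extract_evidence(x), "v1")
#' @export
score_edges <- function(table, variant = c("v1", "v2")) {
  variant <- match.arg(variant)
  grouped <- dplyr::group_by(table, .data$regulator, .data$target, .data$sign)
  out <- if (variant == "v1") {
    dplyr::summarise(grouped, score = sum(.data$prob) / 4, .groups = "drop")
  } else {
    dplyr::summarise(grouped,
      score = if (sum(.data$total) > 0) sum(.data$count) / sum(.data$total) else 0,
      .groups = "drop"
    )
  }
  tibble::as_tibble(out)
}

#' Select one regulation sign per gene pair
#'
#' A regulator either activates or inhibits a target, never both. Per
#' (regulator, target) pair the higher-scoring sign is kept; pairs whose two
#' sign scores tie (within `tolerance`) are discarded entirely as clear false
#' positives. Pairs carrying a single sign keep it.
#'
#' @param edges signed score tibble from [score_edges()] (at most one row per
#'   (regulator, target, sign)).
#' @param tolerance absolute score difference treated as a tie.
#' @return a tibble with one row per surviving pair.
#' @export
select_signs <- function(edges, tolerance = 1e-12) {
  grouped <- dplyr::group_by(edges, .data$regulator, .data$target)
  out <- dplyr::filter(
    grouped,
    dplyr::n() == 1 |
      (abs(max(.data$score) - min(.data$score)) > tolerance &
        .data$score == max(.data$score))
  )
  tibble::as_tibble(dplyr::ungroup(out))
}

#' Per-gene decay probability
#'
#' Estimates how often each gene decays: the number of negative first
#' differences of its discretized levels (taken within each series) divided
#' by the number of time points at which the gene is above level 0.
#'
#' @param data a `pepn_discretized` table.
#' @return a tibble with columns `gene`, `decay_count`, `occurrence_count`,
#'   `decay_prob` (0 for genes never above level 0).
#' @export
decay_probability <- function(data) {
  mats <- expression_matrices(data)
  genes <- gene_names(data)
  diffs <- do.call(cbind, lapply(mats, function(m) {
    m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  }))
  levels_all <- do.call(cbind, mats)
  c_decay <- unname(rowSums(diffs < 0))
  c_occ <- unname(rowSums(levels_all > 0))
  tibble::tibble(
    gene = genes,
    decay_count = as.integer(c_decay),
    occurrence_count = as.integer(c_occ),
    decay_prob = ifelse(c_occ > 0, c_decay / c_occ, 0)
  )
}

#' Threshold a sign-selected edge list
#'
#' Applies the two post-hoc filters in a fixed order: first keep, per target,
#' the top `nreg` regulators by score (ties broken lexicographically by
#' regulator name), then drop edges scoring below `th`.
#'
#' @param edges sign-selected edge tibble.
#' @param nreg maximum regulators retained per target.
#' @param th minimum score in `[0, 1]`.
#' @return the filtered tibble.
#' @export
threshold_edges <- function(edges, nreg = 3, th = 0) {
  stopifnot(nreg >= 1, th >= 0, th <= 1)
  edges <- tibble::as_tibble(edges)
  ord <- order(edges$target, -edges$score, edges$regulator, method = "radix")
  edges <- edges[ord, ]
  keep <- stats::ave(seq_along(edges$score), edges$target, FUN = seq_along) <= nreg
  out <- edges[keep & edges$score >= th, ]
  rank_edges(out)
}

#' Likelihood of a gold-standard network under edge-presence probabilities
#'
#' Treats each candidate ordered gene pair as an independent Bernoulli
#' variable with the supplied presence probability. `edges_only` multiplies
#' the probabilities of the gold edges; `full` additionally multiplies
#' `1 - p` over all candidate non-edges. Probabilities are also returned on
#' the log10 scale to avoid underflow; a gold edge with probability 0 yields
#' `-Inf`, reported as such.
#'
#' @param edge_probs tibble with columns `regulator`, `target`, `prob`
#'   (presence probability per candidate pair; absent pairs count as 0).
#' @param gold a `pepn_gold` table.
#' @param mode `"full"` or `"edges_only"`.
#' @param candidates optional two-column tibble of candidate pairs; defaults
#'   to all ordered non-self pairs over the genes seen in `edge_probs` and
#'   `gold`.
#' @return one-row tibble: `mode`, `n_edges`, `n_candidates`,
#'   `log10_likelihood`, `likelihood`.
#' @export
network_likelihood <- function(edge_probs, gold, mode = c("full", "edges_only"),
                               candidates = NULL) {
  mode <- match.arg(mode)
  if (is.null(candidates)) {
    genes <- sort(unique(c(
      edge_probs$regulator, edge_probs$target, gold$regulator, gold$target
    )))
    candidates <- all_pairs(genes)
  }
  key <- function(r, t) paste(r, t, sep = "\r")
  p <- edge_probs$prob[match(key(candidates$regulator, candidates$target),
    key(edge_probs$regulator, edge_probs$target))]
  p[is.na(p)] <- 0
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  is_edge <- key(candidates$regulator, candidates$target) %in%
    key(gold$regulator, gold$target)
  ll <- sum(log10(p[is_edge]))
  if (mode == "full") ll <- ll + sum(log10(1 - p[!is_edge]))
  tibble::tibble(
    mode = mode, n_edges = sum(is_edge), n_candidates = nrow(candidates),
    log10_likelihood = ll, likelihood = 10^ll
  )
}

#' All ordered non-self gene pairs
#'
#' @param genes character vector of gene names.
#' @param regulators optional subset allowed on the regulator side.
#' @return tibble with columns `regulator`, `target`.
#' @export
all_pairs <- function(genes, regulators = NULL) {
  if (is.null(regulators)) regulators <- genes
  g <- tidyr::expand_grid(regulator = regulators, target = genes)
  g[g$regulator != g$target, ]
}
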