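#' Discretize expression data gene-by-gene
#'
#' Converts continuous expression values to integer levels `0..k-1`, one gene
#' row at a time, over the concatenation of all time series for that gene.
#' Three per-gene methods are available:
#'
#' * `ewd` (equal width): the range is split into `k` equal-width intervals,
#'   `Thresh = (max - min) / k`; `level(x) = min(floor((x - min)/Thresh), k-1)`
#'   so the maximum is clamped into the top bin. Constant rows map to level 0.
#' * `efd` (equal frequency): values are stable-sorted and split into `k`
#'   bins whose sizes differ by at most one, the remainder going to the
#'   lowest bins; ties at a bin boundary are separated by sort position.
#' * `kmeans`: deterministic 1-D Lloyd iterations with centres initialized at
#'   the `(2i+1)/(2k)` quantiles, run to convergence (centre movement below
#'   `1e-9`, at most 300 iterations); clusters are relabelled `0..k-1` by
#'   ascending centre. Rows with at most `k` distinct values map each
#'   distinct value to its own level in ascending order.
#'
#' All methods are monotone within a gene row.
#'
#' @param data a [as_expression()] table (or anything coercible to one via a
#'   genes-by-time matrix / list of matrices).
#' @param method `"ewd"`, `"efd"` or `"kmeans"`.
#' @param bins number of levels `k >= 2` (the shipped evidence rule tables
#'   support `k` of 2 or 3).
#' @return a `pepn_discretized` tibble with a `level` column and `n_bins`
#'   attribute.
#' @examples
#' x <- as_expression(matrix(c(0, 1, 2, 3, 3, 2, 1, 0), 2, byrow = TRUE))
#' discretize(x, "ewd", 2)
#' @export
discretize <- function(data, method = c("efd", "ewd", "kmeans"), bins = 2) {
  method <- match.arg(method)
  if (!is.data.frame(data)) data <- as_expression(data)
  k <- as.integer(bins)
  if (k < 2) stop("`bins` must be at least 2", call. = FALSE)
  rowfun <- switch(method, ewd = ewd_row, efd = efd_row, kmeans = kmeans_row)
  lev <- stats::ave(data$value, data$gene, FUN = function(v) rowfun(v, k))
  new_discretized(data, lev, k)
}

#' Mark an expression table as already discrete
#'
#' For inputs that are pre-binned (e.g. rule-table fixtures), validates the
#' values are integer levels in `0..k-1` and attaches the bin count.
#'
#' @inheritParams discretize
#' @param bins the number of levels the data uses.
#' @return a `pepn_discretized` tibble.
#' @export
as_discretized <- function(data, bins) {
  if (!is.data.frame(data)) data <- as_expression(data)
  k <- as.integer(bins)
  v <- if ("level" %in% names(data)) data$level else data$value
  if (any(v != round(v)) || any(v < 0) || any(v > k - 1)) {
    stop("values are not integer levels in 0..bins-1", call. = FALSE)
  }
  new_discretized(data, v, k)
}

ewd_row <- function(v, k) {
  lo <- min(v)
  thresh <- (max(v) - lo) / k
  if (thresh == 0) {
    return(rep(0L, length(v)))
  }
  pmin(floor((v - lo) / thresh), k - 1)
}

efd_row <- function(v, k) {
  n <- length(v)
  kk <- min(k, n)
  base <- n %/% kk
  rem <- n %% kk
  sizes <- base + (seq_len(kk) <= rem)
  lev_sorted <- rep(seq_len(kk) - 1L, sizes)
  out <- integer(n)
  out[order(v, method = "radix")] <- lev_sorted # stable sort: ties by position
  out
}

kmeans_row <- function(v, k) {
  u <- sort(unique(v))
  if (length(u) <= k) {
    return(match(v, u) - 1L)
  }
  centres <- stats::quantile(v, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  for (it in seq_len(300)) {
    # nearest centre; ties go to the lower-indexed (lower-valued) centre
    d <- abs(outer(v, centres, "-"))
    assign <- max.col(-d, ties.method = "first")
    new_c <- vapply(seq_len(k), function(j) {
      if (any(assign == j)) mean(v[assign == j]) else centres[j]
    }, 0)
    if (max(abs(new_c - centres)) < 1e-9) {
      centres <- new_c
      break
    }
    centres <- new_c
  }
  relabel <- order(order(centres)) # rank of each centre, ascending
  relabel[assign] - 1L
}
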