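#' Time-series expression tables
#'
#' pepngrn stores expression data in long ("tidy") form: one row per
#' (series, time, gene) observation. `as_expression()` builds such a table
#' from a list of gene-by-time matrices (one matrix per time series, rows in
#' a shared gene order); `expression_matrices()` is the inverse. Discretized
#' data uses the same layout with an integer `level` column and an `n_bins`
#' attribute (see [discretize()]).
#'
#' @param series a matrix (genes x time points), or a list of such matrices
#'   sharing the same row (gene) order. Row names are used as gene names;
#'   unnamed rows get `G1..Gp`.
#' @param genes optional character vector of gene names overriding row names.
#' @return `as_expression()`: a tibble of class `pepn_expression` with columns
#'   `series`, `time`, `gene`, `value` and a `genes` attribute giving the
#'   gene order.
#' @examples
#' m <- matrix(rnorm(8), 2, 4, dimnames = list(c("G1", "G2"), NULL))
#' x <- as_expression(m)
#' expression_matrices(x)
#' @export
as_expression <- function(series, genes = NULL) {
  mats <- prep_series(series, genes)
  out <- series_to_tbl(mats, value_col = "value")
  validate_expression(out)
}

#' @rdname as_expression
#' @param x a `pepn_expression` or `pepn_discretized` table.
#' @return `expression_matrices()`: a list of genes-by-time matrices, one per
#'   series, carrying the `value` (or `level`) column.
#' @export
expression_matrices <- function(x) {
  col <- if ("level" %in% names(x)) "level" else "value"
  genes <- gene_names(x)
  lapply(split(x, x$series), function(d) {
    n_t <- length(unique(d$time))
    m <- matrix(d[[col]][order(d$time, match(d$gene, genes))],
      nrow = length(genes), ncol = n_t,
      dimnames = list(genes, NULL)
    )
    m
  })
}

#' @rdname as_expression
#' @export
gene_names <- function(x) {
  g <- attr(x, "genes")
  if (is.null(g)) unique(x$gene) else g
}

#' Number of discretization levels of a table
#'
#' @param x a `pepn_discretized` table.
#' @return integer bin count `k`.
#' @export
n_bins <- function(x) {
  k <- attr(x, "n_bins")
  if (is.null(k)) stop("`x` has no `n_bins` attribute; discretize it first", call. = FALSE)
  as.integer(k)
}

# --- internal constructors ---------------------------------------------------

prep_series <- function(series, genes = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (!is.list(series) || !all(vapply(series, is.matrix, logical(1)))) {
    stop("`series` must be a matrix or a list of matrices", call. = FALSE)
  }
  p <- nrow(series[[1]])
  if (any(vapply(series, nrow, integer(1)) != p)) {
    stop("all series must have the same number of genes", call. = FALSE)
  }
  if (is.null(genes)) genes <- rownames(series[[1]])
  if (is.null(genes)) genes <- paste0("G", seq_len(p))
  if (anyDuplicated(genes)) stop("duplicate gene names", call. = FALSE)
  if (length(genes) != p) stop("`genes` length does not match rows", call. = FALSE)
  lapply(series, function(m) {
    rownames(m) <- genes
    m
  })
}

series_to_tbl <- function(mats, value_col = "value") {
  genes <- rownames(mats[[1]])
  parts <- purrr::imap(mats, function(m, s) {
    tibble::tibble(
      series = as.integer(s),
      time = rep(seq_len(ncol(m)), each = nrow(m)),
      gene = rep(genes, ncol(m)),
      !!value_col := as.vector(m)
    )
  })
  out <- dplyr::bind_rows(parts)
  structure(out,
    genes = genes,
    class = c("pepn_expression", class(tibble::tibble()))
  )
}

validate_expression <- function(x) {
  if (length(gene_names(x)) < 2) {
    stop("need at least 2 genes", call. = FALSE)
  }
  n_per <- tapply(x$time, x$series, function(t) length(unique(t)))
  if (any(n_per < 2)) stop("every series needs at least 2 time points", call. = FALSE)
  if (anyNA(x$value %||% x$level)) stop("missing values in expression data", call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_discretized <- function(x, level, k) {
  out <- dplyr::mutate(tibble::as_tibble(x), value = NULL, level = as.integer(level))
  structure(out,
    genes = gene_names(x), n_bins = as.integer(k),
    class = c("pepn_discretized", "pepn_expression", class(tibble::tibble()))
  )
}

#' @export
print.pepn_expression <- function(x, ...) {
  k <- attr(x, "n_bins")
  n_per <- tapply(x$time, x$series, function(t) length(unique(t)))
  cat(sprintf(
    "# %s: %d genes, %d series (%s time points)%s\n",
    if (is.null(k)) "expression time series" else sprintf("discretized time series (k = %d)", k),
    length(gene_names(x)), length(n_per), paste(n_per, collapse = ", "),
    ""
  ))
  NextMethod()
}
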