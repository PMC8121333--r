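#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic edge model
#'
#' @param x a `pepn_logit` object.
#' @param ... unused.
#' @return a tibble with one row per coefficient: `term`, `estimate`. Terms
#'   are `w0` (bias) and one weight per evidence type.
#' @method tidy pepn_logit
#' @export
tidy.pepn_logit <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights),
    evidence = c(NA, x$feature_names %||% paste0("x", seq_along(x$weights[-1]))),
    estimate = unname(x$weights)
  )
}

#' @rdname tidy.pepn_logit
#' @method glance pepn_logit
#' @export
glance.pepn_logit <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights) - 1, lambda = x$lambda)
}

#' Tidy a cross-validated v3 fit
#'
#' @param x a `pepn_v3_fit` object.
#' @param ... unused.
#' @return `tidy()`: learned weights, one row per (fold, model class, term);
#'   `glance()`: one row per fold with the number of held-out edges.
#' @method tidy pepn_v3_fit
#' @export
tidy.pepn_v3_fit <- function(x, ...) {
  purrr::imap(x$models, function(m, nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    dplyr::mutate(tidy(m),
      fold = as.integer(sub("fold", "", parts[1])),
      model = paste(parts[-1], collapse = "_")
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("fold", "model", "term", "evidence", "estimate")
}

#' @rdname tidy.pepn_v3_fit
#' @method glance pepn_v3_fit
#' @export
glance.pepn_v3_fit <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$edges, fold = .data$fold),
    n_edges = dplyr::n(),
    n_networks = dplyr::n_distinct(.data$network),
    .groups = "drop"
  )
}
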