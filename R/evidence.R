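#' Evidence types and logical rules
#'
#' Between two adjacent time points a target gene can exhibit one of four
#' evidence-generating events: production (`PE`, a rise to the top level),
#' decay (`DE`, a fall to the bottom level), sustained production (`SPE`, a
#' plateau at the top level) and sustained decay (`SDE`, a plateau at level
#' 0). For each event, the logical rule tables classify every candidate
#' regulator by its level at the *earlier* time point: for production-like
#' events (`PE`, `SPE`) a regulator at a non-zero level is activation
#' evidence and a regulator at level 0 inhibition evidence; for decay-like
#' events (`DE`, `SDE`) the roles swap (level 0 supports activation, non-zero
#' supports inhibition).
#'
#' With 2 bins the event patterns are 0->1 (`PE`), 1->0 (`DE`), 1->1 (`SPE`),
#' 0->0 (`SDE`). With 3 bins they are \{0,1\}->2, \{1,2\}->0, 2->2 and 0->0;
#' all other ternary transitions (0->1, 2->1, 1->1) generate no evidence.
#'
#' @param pre_level,post_level integer levels at times t-1 and t.
#' @param bins 2 or 3.
#' @return `classify_target_event()`: one of `"PE"`, `"DE"`, `"SPE"`, `"SDE"`
#'   or `NA` (no evidence), vectorized over its inputs.
#' @export
classify_target_event <- function(pre_level, post_level, bins) {
  k <- as.integer(bins)
  if (!k %in% c(2L, 3L)) stop("rule tables are defined for 2 or 3 bins", call. = FALSE)
  bad <- pre_level < 0 | pre_level > k - 1 | post_level < 0 | post_level > k - 1
  if (any(bad)) stop("level out of range for ", k, " bins", call. = FALSE)
  top <- k - 1L
  dplyr::case_when(
    pre_level < top & post_level == top ~ "PE",
    pre_level >= 1 & post_level == 0 ~ "DE",
    pre_level == top & post_level == top ~ "SPE",
    pre_level == 0 & post_level == 0 ~ "SDE",
    TRUE ~ NA_character_
  )
}

evidence_types <- c("PE", "DE", "SPE", "SDE")

#' Adjacent state pairs of a discretized data set
#'
#' Enumerates the (pre-state, post-state) vector pairs at adjacent time
#' points. Pairs never span a series boundary: adjacency across independent
#' time series is not a biological transition.
#'
#' @param data a `pepn_discretized` table.
#' @return a list with matrices `pre` and `post` (genes x pairs) and the
#'   originating `series` index of each pair.
#' @export
build_state_pairs <- function(data) {
  mats <- expression_matrices(data)
  pre <- do.call(cbind, lapply(mats, function(m) m[, -ncol(m), drop = FALSE]))
  post <- do.call(cbind, lapply(mats, function(m) m[, -1, drop = FALSE]))
  series <- rep(seq_along(mats), vapply(mats, ncol, 0L) - 1L)
  structure(list(pre = pre, post = post, series = series), class = "pepn_state_pairs")
}

#' @export
print.pepn_state_pairs <- function(x, ...) {
  cat(sprintf(
    "# state pairs: %d pairs over %d genes (%d series)\n",
    ncol(x$pre), nrow(x$pre), length(unique(x$series))
  ))
  invisible(x)
}

#' Extract signed edge evidence from discretized time series
#'
#' Applies the logical rule tables (see [classify_target_event()]) to every
#' adjacent state pair: each time a target gene exhibits one of the four
#' evidence events, every candidate regulator contributes exactly one signed
#' count for that evidence type, on the activation or inhibition side
#' according to its pre-state. Per-edge evidence probabilities are the signed
#' counts normalized by the number of times the target exhibited the event,
#' `Pr_e(r, t, s) = C_e(r, t, s) / C_e(t)` (0 when the target never exhibits
#' the event). Self edges are never emitted.
#'
#' @param data a `pepn_discretized` table (2 or 3 bins).
#' @param regulators optional character vector restricting candidate
#'   regulators (e.g. a known TF list); defaults to all genes.
#' @return a tibble of class `pepn_evidence` with one row per
#'   (regulator, target, sign, evidence) combination: columns `regulator`,
#'   `target`, `sign` (+1/-1), `evidence` (`PE`/`DE`/`SPE`/`SDE`), `count`,
#'   `total` (the target's event count) and `prob`.
#' @examples
#' x <- as_discretized(
#'   matrix(c(1, 1, 0, 0, 0, 1, 1, 0), 2,
#'     byrow = TRUE,
#'     dimnames = list(c("g1", "g2"), NULL)
#'   ),
#'   bins = 2
#' )
#' extract_evidence(x)
#' @export
extract_evidence <- function(data, regulators = NULL) {
  k <- n_bins(data)
  if (!k %in% c(2L, 3L)) stop("rule tables are defined for 2 or 3 bins", call. = FALSE)
  genes <- gene_names(data)
  if (is.null(regulators)) regulators <- genes
  if (!all(regulators %in% genes)) {
    stop("unknown regulator gene(s): ",
      paste(setdiff(regulators, genes), collapse = ", "),
      call. = FALSE
    )
  }
  sp <- build_state_pairs(data)
  pre <- sp$pre
  post <- sp$post
  top <- k - 1L

  event_mask <- list(
    PE = pre < top & post == top,
    DE = pre >= 1 & post == 0,
    SPE = pre == top & post == top,
    SDE = pre == 0 & post == 0
  )
  reg_hi <- (pre >= 1) + 0 # regulator pre-state indicator matrices
  reg_lo <- (pre == 0) + 0

  ridx <- match(regulators, genes)
  parts <- purrr::map(evidence_types, function(e) {
    m <- event_mask[[e]] + 0 # targets x pairs
    act <- if (e %in% c("PE", "SPE")) reg_hi else reg_lo
    c_plus <- act %*% t(m) # regulators x targets
    c_minus <- (1 - act) %*% t(m)
    diag(c_plus) <- 0
    diag(c_minus) <- 0
    tot <- rowSums(m)
    grid <- tidyr::expand_grid(
      regulator = genes[ridx], target = genes, sign = c(1L, -1L)
    )
    grid$evidence <- e
    grid$count <- ifelse(grid$sign > 0,
      c_plus[cbind(match(grid$regulator, genes), match(grid$target, genes))],
      c_minus[cbind(match(grid$regulator, genes), match(grid$target, genes))]
    )
    grid$total <- tot[match(grid$target, genes)]
    grid
  })
  out <- dplyr::bind_rows(parts)
  out <- out[out$regulator != out$target, ]
  out$count <- as.integer(out$count)
  out$total <- as.integer(out$total)
  out$prob <- ifelse(out$total > 0, out$count / out$total, 0)
  out$evidence <- factor(out$evidence, levels = evidence_types)
  out <- dplyr::arrange(out, .data$target, .data$regulator, .data$evidence, dplyr::desc(.data$sign))
  structure(out,
    genes = genes, regulators = regulators, n_bins = k,
    class = c("pepn_evidence", class(tibble::tibble()))
  )
}
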