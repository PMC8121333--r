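# Independent oracles and fixture builders used across the suite.

# Brute-force evidence-table oracle. Deliberately independent of the package
# implementation: the logical rule tables are restated literally per bin
# setting (target transition patterns and admissible regulator pre-states for
# each sign), and counting loops over every (state pair, target, regulator)
# triple one at a time.
brute_force_evidence <- function(series_levels, k, regulators = NULL) {
  genes <- rownames(series_levels[[1]])
  if (is.null(regulators)) regulators <- genes
  if (k == 2) {
    target_rule <- list(
      PE = function(pre, post) pre == 0 && post == 1,
      DE = function(pre, post) pre == 1 && post == 0,
      SPE = function(pre, post) pre == 1 && post == 1,
      SDE = function(pre, post) pre == 0 && post == 0
    )
    act_set <- list(PE = 1, DE = 0, SPE = 1, SDE = 0)
    inh_set <- list(PE = 0, DE = 1, SPE = 0, SDE = 1)
  } else if (k == 3) {
    target_rule <- list(
      PE = function(pre, post) pre %in% c(0, 1) && post == 2,
      DE = function(pre, post) pre %in% c(2, 1) && post == 0,
      SPE = function(pre, post) pre == 2 && post == 2,
      SDE = function(pre, post) pre == 0 && post == 0
    )
    act_set <- list(PE = c(1, 2), DE = 0, SPE = c(1, 2), SDE = 0)
    inh_set <- list(PE = 0, DE = c(1, 2), SPE = 0, SDE = c(1, 2))
  } else {
    stop("oracle defined for 2 or 3 bins")
  }
  ev_names <- c("PE", "DE", "SPE", "SDE")
  counts <- array(0L,
    dim = c(length(regulators), length(genes), 2, 4),
    dimnames = list(regulators, genes, c("plus", "minus"), ev_names)
  )
  totals <- matrix(0L, length(genes), 4, dimnames = list(genes, ev_names))
  for (m in series_levels) {
    for (t in 2:ncol(m)) {
      for (tar in genes) {
        pre <- m[tar, t - 1]
        post <- m[tar, t]
        for (e in ev_names) {
          if (!target_rule[[e]](pre, post)) next
          totals[tar, e] <- totals[tar, e] + 1L
          for (r in regulators) {
            if (r == tar) next
            rpre <- m[r, t - 1]
            if (rpre %in% act_set[[e]]) {
              counts[r, tar, "plus", e] <- counts[r, tar, "plus", e] + 1L
            } else if (rpre %in% inh_set[[e]]) {
              counts[r, tar, "minus", e] <- counts[r, tar, "minus", e] + 1L
            }
          }
        }
      }
    }
  }
  list(counts = counts, totals = totals)
}

# Compare a package evidence table against the oracle, exact integer match.
expect_matches_oracle <- function(table, oracle) {
  sign_name <- ifelse(table$sign > 0, "plus", "minus")
  got <- as.integer(table$count)
  want <- oracle$counts[cbind(
    table$regulator, table$target, sign_name, as.character(table$evidence)
  )]
  expect_identical(got, as.integer(want))
  want_tot <- oracle$totals[cbind(table$target, as.character(table$evidence))]
  expect_identical(as.integer(table$total), as.integer(want_tot))
  expect_equal(table$prob, ifelse(want_tot > 0, want / want_tot, 0))
}

# Trapezoidal ROC integration, independent of the rank-based implementation.
trapezoid_auroc <- function(score, label) {
  ord <- order(-score)
  s <- score[ord]
  l <- label[ord]
  ends <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(l)[ends] / sum(l))
  fpr <- c(0, (ends - cumsum(l)[ends]) / sum(1 - l))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Random discretized micro-dataset: p genes, n_s series of random lengths,
# i.i.d. uniform levels.
random_micro_dataset <- function(p = 3, k = 2, n_series = 2, max_len = 8) {
  genes <- paste0("G", seq_len(p))
  mats <- lapply(seq_len(n_series), function(s) {
    n <- sample(2:max_len, 1)
    matrix(sample(0:(k - 1), p * n, replace = TRUE), p, n,
      dimnames = list(genes, NULL)
    )
  })
  as_discretized(as_expression(mats, genes = genes), bins = k)
}

# Discretized table from a single genes-by-time level matrix.
levels_tbl <- function(m, k, genes = NULL) {
  if (is.null(genes)) {
    genes <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  }
  rownames(m) <- genes
  as_discretized(as_expression(m, genes = genes), bins = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
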