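#' Build the evidence feature matrix for supervised edge classification
#'
#' Each candidate edge becomes one training/test row whose four features are
#' its evidence probabilities (`Pr_PE`, `Pr_DE`, `Pr_SPE`, `Pr_SDE`). In
#' `signed` mode there is one row per (regulator, target, sign) — for a
#' 10-gene network, 90 ordered pairs and hence 180 rows — labelled 1 iff the
#' gold standard contains that edge with that sign. In `unsigned` mode (for
#' gold standards without regulation signs) there is one row per ordered
#' pair, carrying the activation-sign feature vector (the inhibition features
#' are its per-evidence complements, hence dependent), labelled 1 iff the
#' pair is a gold edge.
#'
#' @param table a [extract_evidence()] table.
#' @param gold a `pepn_gold` table over the same gene universe.
#' @param mode `"signed"` or `"unsigned"`.
#' @return a tibble with columns `regulator`, `target`, `sign` (signed mode),
#'   `Pr_PE`, `Pr_DE`, `Pr_SPE`, `Pr_SDE`, `label`.
#' @export
build_features <- function(table, gold, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  signed_gold <- isTRUE(attr(gold, "signed")) || "sign" %in% names(gold)
  if (mode == "signed" && !signed_gold) {
    stop("signed mode requires a signed gold standard", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(table, "regulator", "target", "sign", "evidence", "prob"),
    names_from = "evidence", values_from = "prob", names_prefix = "Pr_"
  )
  key <- function(...) paste(..., sep = "\r")
  if (mode == "signed") {
    wide$label <- as.integer(
      key(wide$regulator, wide$target, wide$sign) %in%
        key(gold$regulator, gold$target, gold$sign)
    )
    out <- wide
  } else {
    out <- wide[wide$sign > 0, setdiff(names(wide), "sign")]
    out$label <- as.integer(
      key(out$regulator, out$target) %in% key(gold$regulator, gold$target)
    )
  }
  tibble::as_tibble(out)
}

feature_cols <- paste0("Pr_", c("PE", "DE", "SPE", "SDE"))

#' SMOTE minority oversampling
#'
#' Balances a two-class feature set by synthesizing minority-class rows:
#' each synthetic row lies uniformly at random on the segment between a
#' minority row and one of its `k_neighbors` nearest minority neighbours
#' (Euclidean distance; `k_neighbors` is clipped to minority size minus one).
#' Deterministic given `seed`. A minority class of size 1 has no neighbours
#' and is duplicated instead, with a warning.
#'
#' @param features numeric matrix or data frame of feature columns.
#' @param labels 0/1 vector, one per row.
#' @param k_neighbors neighbour pool size (default 5).
#' @param seed integer RNG seed.
#' @return list with balanced `features` (matrix) and `labels`.
#' @export
smote_upsample <- function(features, labels, k_neighbors = 5, seed = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("SMOTE needs both classes present", call. = FALSE)
  minority <- as.integer(names(which.min(tab)))
  need <- abs(diff(as.integer(tab)))
  if (need == 0) {
    return(list(features = x, labels = labels))
  }
  xm <- x[labels == minority, , drop = FALSE]
  m0 <- nrow(xm)
  if (m0 == 1) {
    warning("minority class of size 1: duplicating instead of interpolating")
    synth <- xm[rep(1, need), , drop = FALSE]
  } else {
    k <- min(k_neighbors, m0 - 1)
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- t(matrix(apply(d, 1, function(r) order(r)[seq_len(k)]), nrow = k))
    synth <- withr::with_seed(seed, {
      base <- rep_len(seq_len(m0), need)
      pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
      gap <- stats::runif(need)
      xm[base, , drop = FALSE] + gap * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    })
  }
  list(
    features = rbind(x, synth),
    labels = c(labels, rep(minority, need))
  )
}

#' Fit a logistic edge-classification model
#'
#' Maximum penalized-likelihood logistic regression of edge presence on the
#' four evidence probabilities, with a weak ridge penalty so that weights
#' stay finite on separable data. Fitting uses glmnet at a single small
#' lambda without feature standardization; the result is deterministic.
#'
#' @param features numeric matrix/data frame (rows = edges, columns = the four
#'   evidence probabilities).
#' @param labels 0/1 vector.
#' @param lambda ridge penalty strength.
#' @return an object of class `pepn_logit` with elements `weights`
#'   (`w0` bias then one weight per feature column) and `lambda`.
#' @export
fit_logistic <- function(features, labels, lambda = 1e-4) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature value", call. = FALSE)
  # glmnet requires >= 2 columns; pad single-feature input with a zero column
  pad <- ncol(x) == 1
  xx <- if (pad) cbind(x, 0) else x
  fit <- glmnet::glmnet(xx, as.integer(labels),
    family = "binomial", alpha = 0,
    lambda = lambda, standardize = FALSE, thresh = 1e-12, maxit = 1e6
  )
  w <- as.numeric(stats::coef(fit))
  if (pad) w <- w[-length(w)]
  names(w) <- c("w0", paste0("w", seq_len(ncol(x))))
  structure(
    list(weights = w, lambda = lambda, feature_names = colnames(x)),
    class = "pepn_logit"
  )
}

#' @export
print.pepn_logit <- function(x, ...) {
  cat("# logistic edge model (ridge lambda =", format(x$lambda), ")\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @describeIn fit_logistic predicted edge-presence probabilities
#'   `sigma(w0 + sum_i w_i x_i)` for new feature rows.
#' @param object a `pepn_logit` model.
#' @param newdata feature matrix/data frame with the model's feature columns.
#' @param ... unused.
#' @export
predict.pepn_logit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  w <- object$weights
  as.numeric(stats::plogis(w[1] + x %*% w[-1]))
}

#' Supervised (v3) edge scoring with cross-validation
#'
#' The third PEPN-GRN variant learns how much each evidence type contributes
#' to activating and inhibiting regulation. Candidate edges are split into
#' `k_folds` folds (grouping `by_network`: each network is one fold, the
#' DREAM4-style protocol; `by_edge`: a seeded random partition of pairs
#' within pooled networks). Per fold, two logistic models are fitted on the
#' SMOTE-balanced training rows — one on activation-sign rows, one on
#' inhibition-sign rows — and every held-out signed edge is scored by its
#' sign's model; the reported per-pair score is the larger of the two model
#' probabilities and carries the winning model's sign. With an unsigned gold
#' standard a single model is fitted on the 4-feature unsigned rows.
#'
#' Scores estimate the probability that the edge is present in the network.
#'
#' @param tables a single [extract_evidence()] table or a list of them (one
#'   per network).
#' @param golds a `pepn_gold` table or list matching `tables`.
#' @param k_folds number of folds (default 5).
#' @param grouping `"by_network"` (requires `length(tables) >= k_folds`) or
#'   `"by_edge"`.
#' @param mode `"signed"` or `"unsigned"` (see [build_features()]).
#' @param seed RNG seed for SMOTE interpolation and `by_edge` fold
#'   assignment.
#' @param k_neighbors SMOTE neighbour pool size.
#' @param lambda ridge penalty for [fit_logistic()].
#' @return an object of class `pepn_v3_fit`: a list with `edges` (per
#'   held-out edge: `network`, `fold`, `regulator`, `target`, `sign`,
#'   `score`), `models` (per fold and sign class), and the call parameters.
#'   `tidy()` returns the model weights, `glance()` one row per fold.
#' @export
run_v3 <- function(tables, golds, k_folds = 5,
                   grouping = c("by_network", "by_edge"),
                   mode = c("signed", "unsigned"),
                   seed = 1, k_neighbors = 5, lambda = 1e-4) {
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  if (inherits(tables, "pepn_evidence")) tables <- list(tables)
  if (is.data.frame(golds)) golds <- list(golds)
  stopifnot(length(tables) == length(golds), k_folds >= 2)

  feats <- purrr::map2(tables, golds, build_features, mode = mode)
  feats <- purrr::imap(feats, function(f, i) dplyr::mutate(f, network = as.integer(i)))
  all_rows <- dplyr::bind_rows(feats)

  if (grouping == "by_network") {
    if (length(tables) < k_folds) {
      stop("by_network grouping needs at least k_folds networks", call. = FALSE)
    }
    all_rows$fold <- all_rows$network %% k_folds + 1L
  } else {
    pairs <- dplyr::distinct(all_rows, .data$network, .data$regulator, .data$target)
    pairs$fold <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), nrow(pairs))))
    all_rows <- dplyr::left_join(all_rows, pairs,
      by = c("network", "regulator", "target")
    )
  }

  sign_classes <- if (mode == "signed") c(activation = 1L, inhibition = -1L) else c(edge = 0L)
  models <- list()
  scored <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- all_rows[all_rows$fold != f, ]
    test <- all_rows[all_rows$fold == f, ]
    if (!nrow(test)) next
    fold_scores <- list()
    for (cls in names(sign_classes)) {
      tr <- if (mode == "signed") train[train$sign == sign_classes[[cls]], ] else train
      if (length(unique(tr$label)) < 2) {
        stop(sprintf("fold %d: training labels for %s model are single-class", f, cls),
          call. = FALSE
        )
      }
      bal <- smote_upsample(tr[feature_cols], tr$label,
        k_neighbors = k_neighbors, seed = seed + 1000L * f
      )
      model <- fit_logistic(bal$features, bal$labels, lambda = lambda)
      models[[sprintf("fold%d_%s", f, cls)]] <- model
      te <- if (mode == "signed") test[test$sign == sign_classes[[cls]], ] else test
      pred <- predict(model, te[feature_cols])
      fold_scores[[cls]] <- dplyr::mutate(
        te[c("network", "regulator", "target", intersect("sign", names(te)))],
        fold = f, model = cls, score = pred
      )
    }
    sc <- dplyr::bind_rows(fold_scores)
    if (mode == "signed") {
      # max-fusion: the winning model's probability and sign per pair
      sc <- dplyr::slice_max(
        dplyr::group_by(sc, .data$network, .data$regulator, .data$target),
        .data$score,
        n = 1, with_ties = FALSE
      )
      sc <- dplyr::ungroup(sc)
    } else {
      sc$sign <- 1L
    }
    scored[[f]] <- sc
  }
  edges <- dplyr::arrange(
    dplyr::bind_rows(scored),
    .data$network, dplyr::desc(.data$score), .data$regulator, .data$target
  )
  structure(
    list(
      edges = tibble::as_tibble(edges), models = models,
      k_folds = k_folds, grouping = grouping, mode = mode, seed = seed,
      lambda = lambda, k_neighbors = k_neighbors
    ),
    class = "pepn_v3_fit"
  )
}

#' @export
print.pepn_v3_fit <- function(x, ...) {
  cat(sprintf(
    "# PEPN-GRN v3 fit: %d folds (%s, %s mode), %d scored edges, %d models\n",
    x$k_folds, x$grouping, x$mode, nrow(x$edges), length(x$models)
  ))
  invisible(x)
}
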