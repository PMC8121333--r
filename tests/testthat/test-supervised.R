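# evidence tables + signed golds for n small random networks (shared fixture)
v3_fixture <- function(n_networks = 5, p = 10, seed = 101, n_series = 5) {
  nets <- lapply(seq_len(n_networks), function(i) {
    generate_network(p, max(3, p %/% 3), seed = seed + i)
  })
  tables <- lapply(seq_along(nets), function(i) {
    sim <- simulate_expression(nets[[i]],
      n_series = n_series, n_timepoints = 21, seed = seed + i
    )
    extract_evidence(discretize(sim$expression, "efd", 2))
  })
  list(tables = tables, golds = nets)
}

test_that("feature rows enumerate signed candidate edges", {
  fx <- v3_fixture(n_networks = 1)
  f <- build_features(fx$tables[[1]], fx$golds[[1]], mode = "signed")
  expect_equal(nrow(f), 180) # 90 ordered pairs x 2 signs
  expect_equal(sum(f$label), nrow(fx$golds[[1]]))
  expect_true(all(f[paste0("Pr_", c("PE", "DE", "SPE", "SDE"))] >= 0 &
    f[paste0("Pr_", c("PE", "DE", "SPE", "SDE"))] <= 1))

  un <- build_features(fx$tables[[1]], fx$golds[[1]], mode = "unsigned")
  expect_equal(nrow(un), 90)

  # unsigned gold cannot feed signed mode
  g <- as_gold(fx$golds[[1]][c("regulator", "target")])
  expect_error(build_features(fx$tables[[1]], g, mode = "signed"), "signed")
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  withr::local_seed(5)
  x <- rbind(
    matrix(stats::runif(40), 10, 4), # 10 minority
    matrix(stats::runif(360), 90, 4) # 90 majority
  )
  y <- c(rep(1, 10), rep(0, 90))
  out <- smote_upsample(x, y, seed = 9)
  expect_equal(as.vector(table(out$labels)), c(90, 90))
  expect_true(all(out$features >= 0 & out$features <= 1))
  # determinism
  out2 <- smote_upsample(x, y, seed = 9)
  expect_identical(out, out2)
  expect_false(identical(out, smote_upsample(x, y, seed = 10)))

  # two identical-coordinate minority points: synthetics inherit the segment
  xm <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1), matrix(0.5, 4, 4))
  ym <- c(1, 1, 0, 0, 0, 0)
  o <- smote_upsample(xm, ym, seed = 3)
  synth <- o$features[o$labels == 1, ][-(1:2), , drop = FALSE]
  expect_equal(nrow(synth), 2)
  apply(synth, 1, function(r) expect_equal(max(r) - min(r), 0)) # on the diagonal
  expect_true(all(synth >= 0 & synth <= 1))

  expect_error(smote_upsample(x, rep(1, 100)), "both classes")
  expect_warning(
    smote_upsample(rbind(c(0, 0), c(1, 1), c(2, 2)), c(1, 0, 0)),
    "size 1"
  )
})

test_that("logistic fit finds separation direction and stays calibrated on noise", {
  withr::local_seed(31)
  # no signal: labels independent of features
  x <- matrix(stats::runif(400), 100, 4)
  y <- rep(c(0, 1), 50)
  m <- fit_logistic(x, y)
  expect_true(all(abs(m$weights[-1]) < 1))
  expect_true(all(abs(predict(m, x) - 0.5) < 0.4))

  # perfect 1-feature separation: positive weight, correct classification
  xs <- cbind(c(stats::runif(50, 0, 0.4), stats::runif(50, 0.6, 1)))
  ys <- rep(c(0, 1), each = 50)
  ms <- fit_logistic(xs, ys)
  expect_gt(ms$weights[2], 0)
  expect_true(all((predict(ms, xs) > 0.5) == (ys == 1)))
  expect_true(all(is.finite(ms$weights)))

  expect_error(fit_logistic(matrix(c(1, NA, 0, 1), 2), c(0, 1)), "non-finite")
})

test_that("sigmoid predictions match the closed form", {
  m <- structure(
    list(weights = c(w0 = 0, w1 = 1, w2 = 0, w3 = 0, w4 = 0), lambda = 0),
    class = "pepn_logit"
  )
  x0 <- matrix(0, 1, 4)
  x1 <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(predict(m, x0), 0.5)
  expect_equal(predict(m, x1), 1 / (1 + exp(-1)))
  m$weights[1] <- 2
  expect_equal(predict(m, x0), stats::plogis(2))
})

test_that("cross-validated v3 scores every network exactly once as test", {
  fx <- v3_fixture(n_networks = 5)
  fit <- run_v3(fx$tables, fx$golds, k_folds = 5, grouping = "by_network", seed = 4)
  per_net <- table(fit$edges$network)
  expect_equal(length(per_net), 5)
  expect_true(all(per_net == 90)) # each pair scored once, max-fused over signs
  expect_equal(length(fit$models), 10) # 2 sign models per fold
  expect_true(all(fit$edges$score > 0 & fit$edges$score < 1))
  # determinism
  fit2 <- run_v3(fx$tables, fx$golds, k_folds = 5, grouping = "by_network", seed = 4)
  expect_identical(fit$edges, fit2$edges)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_setequal(unique(td$model), c("activation", "inhibition"))
  expect_equal(nrow(td), 10 * 5) # 5 weights per model
  expect_equal(nrow(glance(fit)), 5)
})

test_that("a separable evidence feature drives held-out ranking to the top", {
  # true activation edges have Pr_SDE(+) = 1, true inhibition edges
  # Pr_SPE(-) = 1, every other probability 0; same pattern in every network
  genes <- paste0("G", 1:6)
  gold <- as_gold(tibble::tibble(
    regulator = c("G1", "G2", "G1"), target = c("G3", "G4", "G5"),
    sign = c(1L, 1L, -1L)
  ), signed = TRUE)
  attr(gold, "genes") <- genes
  make_table <- function() {
    tbl <- tidyr::expand_grid(
      regulator = genes, target = genes, sign = c(1L, -1L),
      evidence = factor(c("PE", "DE", "SPE", "SDE"),
        levels = c("PE", "DE", "SPE", "SDE")
      )
    )
    tbl <- tbl[tbl$regulator != tbl$target, ]
    key <- paste(tbl$regulator, tbl$target, tbl$sign)
    gkey <- paste(gold$regulator, gold$target, gold$sign)
    tbl$total <- 4L
    tbl$count <- ifelse(
      key %in% gkey &
        ((tbl$sign == 1L & tbl$evidence == "SDE") |
          (tbl$sign == -1L & tbl$evidence == "SPE")),
      4L, 0L
    )
    tbl$prob <- tbl$count / tbl$total
    tbl
  }
  tables <- replicate(5, make_table(), simplify = FALSE)
  golds <- replicate(5, gold, simplify = FALSE)
  fit <- run_v3(tables, golds, k_folds = 5, grouping = "by_network", seed = 2)
  one <- fit$edges[fit$edges$network == 3, ]
  truth <- paste(one$regulator, one$target) %in% paste(gold$regulator, gold$target)
  expect_true(min(one$score[truth]) > max(one$score[!truth]))
  expect_equal(auroc(one, gold, candidates = all_pairs(genes)), 1)
})

test_that("by_edge folds partition pairs and single-network data works", {
  fx <- v3_fixture(n_networks = 1)
  fit <- run_v3(fx$tables[[1]], fx$golds[[1]],
    k_folds = 3, grouping = "by_edge", seed = 6
  )
  expect_equal(nrow(fit$edges), 90)
  expect_equal(sort(unique(fit$edges$fold)), 1:3)
  expect_error(
    run_v3(fx$tables, fx$golds, k_folds = 5, grouping = "by_network"),
    "at least k_folds"
  )
})

test_that("swapping gold signs swaps the two sign models' roles", {
  fx <- v3_fixture(n_networks = 5, seed = 301)
  flip <- function(g) {
    g2 <- g
    g2$sign <- -g2$sign
    g2
  }
  fit <- run_v3(fx$tables, fx$golds, k_folds = 5, seed = 8)
  fit_sw <- run_v3(fx$tables, lapply(fx$golds, flip), k_folds = 5, seed = 8)
  # evidence features are sign-complementary per evidence type, so the
  # swapped fit must reproduce the same ranked pairs with flipped signs
  a <- dplyr::arrange(fit$edges, network, regulator, target)
  b <- dplyr::arrange(fit_sw$edges, network, regulator, target)
  expect_equal(a$score, b$score, tolerance = 1e-6)
  expect_equal(a$sign, -b$sign)
})
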