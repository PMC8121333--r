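worked_evidence <- function() {
  extract_evidence(levels_tbl(
    matrix(c(1, 1, 0, 0, 0, 1, 1, 0), 2, byrow = TRUE),
    2, c("g1", "g2")
  ))
}

test_that("v1 averages the four evidence probabilities, missing evidence as zero", {
  v1 <- score_edges(worked_evidence(), "v1")
  sc <- function(r, t, s) v1$score[v1$regulator == r & v1$target == t & v1$sign == s]
  expect_equal(sc("g1", "g2", 1), 0.75) # (1 + 1 + 1 + 0) / 4
  expect_equal(sc("g1", "g2", -1), 0)
  expect_equal(sc("g2", "g1", -1), 0.75)

  # synthetic table: equal probabilities pass through the mean
  tbl <- tidyr::expand_grid(
    regulator = "a", target = "b", sign = c(1L, -1L),
    evidence = c("PE", "DE", "SPE", "SDE")
  )
  tbl$count <- 4L
  tbl$total <- 5L
  tbl$prob <- ifelse(tbl$sign == 1, 0.8, 0.2)
  expect_equal(score_edges(tbl, "v1")$score, c(0.2, 0.8))
})

test_that("v2 weights evidence by occurrence counts", {
  v2 <- score_edges(worked_evidence(), "v2")
  expect_equal(
    v2$score[v2$regulator == "g1" & v2$target == "g2" & v2$sign == 1],
    1 # counts 1+1+1+0 over totals 1+1+1+0
  )
  # constructed fixture: 10 occurrences, 7 matching the + sign
  tbl <- tidyr::expand_grid(
    regulator = "a", target = "b", sign = c(1L, -1L),
    evidence = c("PE", "DE", "SPE", "SDE")
  )
  totals <- c(PE = 4L, DE = 3L, SPE = 2L, SDE = 1L)
  plus <- c(PE = 4L, DE = 2L, SPE = 1L, SDE = 0L)
  tbl$total <- unname(totals[tbl$evidence])
  tbl$count <- unname(ifelse(tbl$sign == 1, plus[tbl$evidence],
    totals[tbl$evidence] - plus[tbl$evidence]
  ))
  tbl$prob <- ifelse(tbl$total > 0, tbl$count / tbl$total, 0)
  v2b <- score_edges(tbl, "v2")
  expect_equal(v2b$score[v2b$sign == 1], 0.7)
  expect_equal(v2b$score[v2b$sign == -1], 0.3)
  # all-zero table scores zero
  tbl$count <- 0L
  tbl$total <- 0L
  tbl$prob <- 0
  expect_equal(score_edges(tbl, "v2")$score, c(0, 0))
})

test_that("sign-score sums follow the evidence-coverage identity", {
  withr::local_seed(21)
  for (rep in 1:8) {
    d <- random_micro_dataset(p = sample(3:5, 1), k = sample(2:3, 1))
    ev <- extract_evidence(d)
    cover <- dplyr::summarise(
      dplyr::group_by(ev, regulator, target),
      n_types = sum(total[!duplicated(evidence)] > 0),
      any_total = sum(total) > 0, .groups = "drop"
    )
    for (variant in c("v1", "v2")) {
      s <- score_edges(ev, variant)
      expect_true(all(s$score >= 0 & s$score <= 1))
      sums <- dplyr::summarise(
        dplyr::group_by(s, regulator, target),
        both = sum(score), .groups = "drop"
      )
      j <- dplyr::left_join(sums, cover, by = c("regulator", "target"))
      if (variant == "v1") {
        expect_equal(j$both, j$n_types / 4)
      } else {
        expect_equal(j$both[j$any_total], rep(1, sum(j$any_total)))
        expect_equal(j$both[!j$any_total], rep(0, sum(!j$any_total)))
      }
    }
  }
})

test_that("sign selection keeps the winner and discards exact ties", {
  edges <- tibble::tibble(
    regulator = c("a", "a", "b", "b", "c"),
    target = c("t", "t", "t", "t", "t"),
    sign = c(1L, -1L, 1L, -1L, 1L),
    score = c(0.75, 0.25, 0.5, 0.5, 0.3)
  )
  out <- select_signs(edges)
  expect_equal(nrow(out), 2)
  expect_equal(out$sign[out$regulator == "a"], 1L)
  expect_equal(out$score[out$regulator == "c"], 0.3) # single sign kept
  expect_false("b" %in% out$regulator) # tie discarded
  # near-tie within tolerance is also discarded
  near <- tibble::tibble(
    regulator = "a", target = "t", sign = c(1L, -1L),
    score = c(0.5, 0.5 + 1e-13)
  )
  expect_equal(nrow(select_signs(near)), 0)
})

test_that("decay probabilities follow the difference-count rule", {
  d <- decay_probability(levels_tbl(rbind(
    g1 = c(1, 1, 0, 0),
    g2 = c(0, 0, 0, 0),
    g3 = c(1, 0, 1, 0)
  ), 2))
  expect_equal(d$decay_prob[d$gene == "g1"], 0.5) # 1 decay / 2 occupied points
  expect_equal(d$decay_prob[d$gene == "g2"], 0) # never occupied
  expect_equal(d$decay_count[d$gene == "g3"], 2)

  d3 <- decay_probability(levels_tbl(rbind(up = c(0, 1, 2), pad = c(0, 0, 0)), 3))
  expect_equal(d3$decay_prob[d3$gene == "up"], 0)

  # differences respect series boundaries: drop from end of series 1 to start
  # of series 2 is not a decay
  two <- as_discretized(as_expression(list(
    matrix(c(1, 0, 1, 0), 2, 2, dimnames = list(c("g", "pad"), NULL)),
    matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(c("g", "pad"), NULL))
  )), bins = 2)
  expect_equal(decay_probability(two)$decay_count, c(0L, 0L))
})

test_that("thresholding applies the regulator cap before the score floor", {
  edges <- tibble::tibble(
    regulator = paste0("r", 1:5), target = "t", sign = 1L,
    score = c(0.9, 0.8, 0.7, 0.6, 0.5)
  )
  expect_equal(nrow(threshold_edges(edges, nreg = 3, th = 0)), 3)
  expect_equal(nrow(threshold_edges(edges, nreg = 3, th = 0.75)), 2)
  expect_equal(nrow(threshold_edges(edges, nreg = 10, th = 0)), 5)
  # cap ties break lexicographically by regulator
  tied <- tibble::tibble(
    regulator = c("z", "a", "m"), target = "t", sign = 1L, score = 0.5
  )
  kept <- threshold_edges(tied, nreg = 2, th = 0)
  expect_setequal(kept$regulator, c("a", "m"))
})

test_that("network likelihood multiplies edge and non-edge probabilities", {
  gold <- as_gold(tibble::tibble(
    regulator = c("a", "b", "c"), target = c("b", "c", "a")
  ))
  probs <- tibble::tibble(
    regulator = c("a", "b", "c", "a"), target = c("b", "c", "a", "c"),
    prob = c(0.9, 0.8, 0.5, 0.3)
  )
  cands <- probs[c("regulator", "target")]
  full <- network_likelihood(probs, gold, "full", candidates = cands)
  expect_equal(full$likelihood, 0.9 * 0.8 * 0.5 * 0.7)
  eo <- network_likelihood(probs, gold, "edges_only", candidates = cands)
  expect_equal(eo$likelihood, 0.9 * 0.8 * 0.5)
  expect_equal(eo$log10_likelihood, log10(0.36))

  # perfect probabilities give likelihood 1; a zero on a gold edge gives -Inf
  perfect <- tibble::tibble(
    regulator = c("a", "b"), target = c("b", "c"), prob = c(1, 1)
  )
  g2 <- as_gold(tibble::tibble(regulator = c("a", "b"), target = c("b", "c")))
  c2 <- perfect[c("regulator", "target")]
  expect_equal(network_likelihood(perfect, g2, "full", candidates = c2)$likelihood, 1)
  two_half <- tibble::tibble(
    regulator = c("a", "b"), target = c("b", "c"), prob = c(0.5, 0.5)
  )
  expect_equal(
    network_likelihood(two_half, g2, "edges_only", candidates = c2)$likelihood, 0.25
  )
  zero <- tibble::tibble(regulator = "a", target = "b", prob = 0)
  expect_equal(
    network_likelihood(zero, g2, "edges_only", candidates = c2[1, ])$log10_likelihood,
    -Inf
  )
})
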