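#' Generate a random signed regulatory network
#'
#' DREAM-style sparse topology: candidate regulators are the first `n_tfs`
#' genes; every non-TF gene draws between 1 and `max_regulators` regulators
#' uniformly from the TFs, and each edge is independently signed activating
#' or inhibiting with probability one half. TFs themselves are unregulated
#' (exogenous inputs whose autonomous switching drives the network).
#' Deterministic given `seed`.
#'
#' @param p number of genes (named `G1..Gp`; the first `n_tfs` are TFs).
#' @param n_tfs number of transcription factors (`<= p`).
#' @param max_regulators maximum regulators drawn per target.
#' @param seed integer RNG seed.
#' @return a signed `pepn_gold` tibble with attributes `genes` and `tfs`.
#' @export
generate_network <- function(p = 20, n_tfs = 5, max_regulators = 2, seed = 1) {
  stopifnot(n_tfs <= p, n_tfs >= 1, max_regulators >= 1, p >= 2)
  genes <- paste0("G", seq_len(p))
  tfs <- genes[seq_len(n_tfs)]
  edges <- withr::with_seed(seed, {
    purrr::map(setdiff(genes, tfs), function(g) {
      pool <- setdiff(tfs, g)
      if (!length(pool)) {
        return(NULL)
      }
      n_r <- sample.int(min(max_regulators, length(pool)), 1)
      regs <- sample(pool, n_r)
      tibble::tibble(
        regulator = regs, target = g,
        sign = sample(c(1L, -1L), n_r, replace = TRUE)
      )
    })
  })
  out <- as_gold(dplyr::bind_rows(edges), signed = TRUE)
  attr(out, "genes") <- genes
  attr(out, "tfs") <- tfs
  out
}

#' Simulate multi-series expression data from a regulatory network
#'
#' Stochastic threshold dynamics with first-order Markov regulation and
#' separate synthesis/decay moves, mirroring the mechanism the evidence rules
#' assume (lagged threshold regulation) without implementing the rules
#' themselves. Genes hold discrete levels `0..levels-1`. Per series, initial
#' levels are uniform; then per gene and time step, with all regulator states
#' read at the previous time point:
#'
#' * *drive*: some activator is at the top level; *veto*: some inhibitor is
#'   at the top level;
#' * under veto the gene falls one level (active inhibition nets out as
#'   degradation of the target, overriding any drive);
#' * under drive without veto it rises one level (certainly);
#' * otherwise it rises one level with probability `basal_synthesis` (basal
#'   transcription), else falls one level with probability `decay_prob`,
#'   else holds.
#'
#' Regulated genes thus track their activators (time-shifted) and mirror
#' their inhibitors (inverted time-shifted) with a one-step lag, up to basal
#' and decay stochasticity.
#'
#' Each discrete observation is then independently replaced by a uniform
#' random level with probability `flip_noise` (measurement corruption), and
#' the continuous readout is the observed level plus uniform jitter of
#' amplitude `jitter` (0.3 keeps 1-unit levels separable under equal-width
#' discretization).
#'
#' @param network a signed `pepn_gold` (e.g. from [generate_network()]); its
#'   `genes` attribute, or the genes appearing in it, defines the universe.
#' @param n_series,n_timepoints series count and length (DREAM4-like defaults
#'   10 x 21).
#' @param levels number of discrete levels `k` (2 or 3).
#' @param flip_noise per-observation corruption probability in `[0, 1)`.
#' @param basal_synthesis probability of an un-driven rise.
#' @param decay_prob probability of a fall when not rising.
#' @param jitter half-width of the uniform continuous noise.
#' @param seed integer RNG seed.
#' @return list of class `pepn_simulation`: `expression` (continuous
#'   `pepn_expression`), `levels` (the noise-free `pepn_discretized` truth),
#'   `observed_levels` (after flips), and `network`.
#' @export
simulate_expression <- function(network, n_series = 10, n_timepoints = 21,
                                levels = 2, flip_noise = 0,
                                basal_synthesis = 0.3, decay_prob = 0.6,
                                jitter = 0.3, seed = 1) {
  k <- as.integer(levels)
  stopifnot(k >= 2, n_timepoints >= 2, n_series >= 1,
            flip_noise >= 0, flip_noise < 1)
  genes <- attr(network, "genes")
  if (is.null(genes)) genes <- sort(unique(c(network$regulator, network$target)))
  p <- length(genes)
  act <- lapply(genes, function(g) {
    match(network$regulator[network$target == g & network$sign > 0], genes)
  })
  inh <- lapply(genes, function(g) {
    match(network$regulator[network$target == g & network$sign < 0], genes)
  })
  top <- k - 1L

  sim <- withr::with_seed(seed, {
    true_l <- vector("list", n_series)
    obs_l <- vector("list", n_series)
    cont_l <- vector("list", n_series)
    for (s in seq_len(n_series)) {
      m <- matrix(0L, p, n_timepoints, dimnames = list(genes, NULL))
      m[, 1] <- sample(0:top, p, replace = TRUE)
      for (t in 2:n_timepoints) {
        prev <- m[, t - 1]
        rise_u <- stats::runif(p)
        fall_u <- stats::runif(p)
        for (i in seq_len(p)) {
          drive <- length(act[[i]]) > 0 && any(prev[act[[i]]] == top)
          veto <- length(inh[[i]]) > 0 && any(prev[inh[[i]]] == top)
          lev <- prev[i]
          if (veto) {
            lev <- max(lev - 1L, 0L)
          } else if (drive) {
            lev <- min(lev + 1L, top)
          } else if (rise_u[i] < basal_synthesis) {
            lev <- min(lev + 1L, top)
          } else if (fall_u[i] < decay_prob) {
            lev <- max(lev - 1L, 0L)
          }
          m[i, t] <- lev
        }
      }
      # replacement levels are drawn unconditionally so the RNG stream (and
      # hence the noise-free trajectory) is identical across flip_noise values
      flip <- matrix(stats::runif(p * n_timepoints) < flip_noise, p, n_timepoints)
      repl <- matrix(sample(0:top, p * n_timepoints, replace = TRUE), p, n_timepoints)
      obs <- m
      obs[flip] <- repl[flip]
      cont <- obs + matrix(stats::runif(p * n_timepoints, -jitter, jitter),
        p, n_timepoints)
      true_l[[s]] <- m
      obs_l[[s]] <- obs
      cont_l[[s]] <- cont
    }
    list(true = true_l, obs = obs_l, cont = cont_l)
  })

  structure(
    list(
      expression = as_expression(sim$cont, genes = genes),
      levels = as_discretized(as_expression(sim$true, genes = genes), bins = k),
      observed_levels = as_discretized(as_expression(sim$obs, genes = genes), bins = k),
      network = network
    ),
    class = "pepn_simulation"
  )
}

#' @export
print.pepn_simulation <- function(x, ...) {
  n_per <- tapply(x$expression$time, x$expression$series, function(t) length(unique(t)))
  cat(sprintf(
    "# simulated GRN data: %d genes, %d series x %d time points, %d gold edges (k = %d)\n",
    length(gene_names(x$expression)), length(n_per), n_per[1],
    nrow(x$network), n_bins(x$levels)
  ))
  invisible(x)
}
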