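# Deterministic oracles shared by the validation tests.

# A one-category 1:1 matched toy with known within-pair code differences,
# for checking the sampler against grid quadrature.  codes: list of
# per-set lists of per-member code vectors (case first).
grid_toy_study <- function(codes, manifest) {
  toy_study(codes, categories = rep("I", length(codes)), manifest = manifest)
}

# total-variation distance between a quadrature posterior and MCMC draws,
# both binned on the same grid
tv_grid_vs_draws <- function(grid, weights, draws, n_bins = 50L) {
  brk <- seq(min(grid), max(grid), length.out = n_bins + 1L)
  pg <- tapply(weights, cut(grid, brk, include.lowest = TRUE), sum)
  pg[is.na(pg)] <- 0
  eps <- diff(range(grid)) * 1e-9
  pm <- hist(pmin(pmax(draws, min(grid) + eps), max(grid) - eps),
             breaks = brk, plot = FALSE)$counts / length(draws)
  0.5 * sum(abs(pg - pm))
}

# normalized grid posterior for a 1:1 conditional-logistic toy with one
# free coefficient: within-pair code differences d, vague normal prior
grid_posterior_1p <- function(grid, diffs, prior_var = 1000) {
  lp <- vapply(grid, function(mu)
    sum(stats::plogis(diffs * mu, log.p = TRUE)) +
      stats::dnorm(mu, 0, sqrt(prior_var), log = TRUE), 0)
  w <- exp(lp - max(lp))
  w / sum(w)
}
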