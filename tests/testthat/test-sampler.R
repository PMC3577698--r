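test_that("retention follows the burn-in/thinning protocol", {
  d <- small_sim_study(sets = 5L)
  spec <- model_spec(d$manifest)
  # the analysis protocol: 50,000 post-burn-in iterations thinned by 10
  tr <- run_chain("unconditional", d, spec,
                  cfg = chain_config(n_iter = 50000L, burn_in = 5000L,
                                     thin = 10L, seed = 3L))
  expect_equal(nrow(tr$draws), 5000L)
  expect_equal(length(tr$deviance), 5000L)
  # an incomplete final thinning block is dropped
  tr2 <- run_chain("bclr", d, spec,
                   cfg = chain_config(n_iter = 100L, burn_in = 50L,
                                      thin = 7L, seed = 3L))
  expect_equal(nrow(tr2$draws), 14L)
  # variance draws are strictly positive
  expect_true(all(tr$draws[, c("tau2[1]", "tau2[2]", "var_area", "var_pair")] > 0))
})

test_that("identical seeds give identical traces", {
  d <- small_sim_study(sets = 8L)
  spec <- model_spec(d$manifest)
  cfg <- chain_config(n_iter = 400L, burn_in = 100L, thin = 2L, seed = 99L)
  t1 <- run_chain("unconditional", d, spec, cfg = cfg)
  t2 <- run_chain("unconditional", d, spec, cfg = cfg)
  expect_identical(t1$draws, t2$draws)
  expect_identical(t1$deviance, t2$deviance)
  cfg2 <- cfg; cfg2$seed <- 100L
  t3 <- run_chain("unconditional", d, spec, cfg = cfg2)
  expect_false(identical(t1$draws, t3$draws))
})

test_that("bclr traces exclude intercept, area and pair layers", {
  d <- small_sim_study(sets = 6L)
  spec <- model_spec(d$manifest)
  tr <- run_chain("bclr", d, spec,
                  cfg = chain_config(n_iter = 200L, burn_in = 100L,
                                     thin = 2L, seed = 5L))
  expect_false(any(c("alpha", "var_area", "var_pair") %in% colnames(tr$draws)))
  expect_false(any(grepl("^(a|b)\\[", colnames(tr$draws))))
  expect_true(all(sprintf("tau2[%d]", 1:2) %in% colnames(tr$draws)))

  # and the no-GE reduction removes beta/tau2 columns
  spec0 <- model_spec(d$manifest, ge_interaction = FALSE)
  tr0 <- run_chain("unconditional", d, spec0,
                   cfg = chain_config(n_iter = 200L, burn_in = 100L,
                                      thin = 2L, seed = 5L))
  expect_false(any(grepl("^(beta|tau2)\\[", colnames(tr0$draws))))
  expect_true(all(sprintf("mu[%d]", 1:2) %in% colnames(tr0$draws)))
})

test_that("metropolis_update accepts sure moves and rejects forbidden ones", {
  # zero density change -> always accepted
  set.seed(1)
  res <- replicate(50, metropolis_update(0, function(x) 0, 1)$accepted)
  expect_true(all(res))
  # proposal into a zero-density region -> always rejected
  set.seed(1)
  res2 <- replicate(50, metropolis_update(0, function(x)
    if (x == 0) 0 else -Inf, 1)$accepted)
  expect_false(any(res2))
})

test_that("adaptive scaling settles near the target acceptance rate", {
  # standard-normal target, windowed adaptation as in the chain engine
  set.seed(42)
  target <- 0.44
  lp <- function(x) -x^2 / 2
  x <- 0; scale <- 5; acc_win <- 0
  for (t in 1:4000) {
    r <- metropolis_update(x, lp, scale)
    x <- r$value
    acc_win <- acc_win + r$accepted
    if (t %% 50 == 0) {
      scale <- scale * exp(min(0.5, max(-0.5, acc_win / 50 - target)))
      acc_win <- 0
    }
  }
  acc <- 0
  for (t in 1:4000) {
    r <- metropolis_update(x, lp, scale)
    x <- r$value
    acc <- acc + r$accepted
  }
  expect_lt(abs(acc / 4000 - target), 0.1)
})

test_that("conjugate variance updates match the inverse-gamma closed form", {
  set.seed(7)
  dev <- rnorm(25, 0, 1.5)
  shape <- 0.001; rate <- 0.001
  n_draw <- 10000L
  v <- vapply(seq_len(n_draw), function(i)
    gibbs_update_variance(dev, shape, rate), 0)
  post_shape <- shape + length(dev) / 2
  post_rate <- rate + sum(dev^2) / 2
  # precision sample mean within 3 standard errors of the analytic mean
  prec <- 1 / v
  se <- sqrt(post_shape) / post_rate / sqrt(n_draw)
  expect_lt(abs(mean(prec) - post_shape / post_rate), 3 * se)
  # full-distribution agreement: KS statistic below 0.02
  ks <- suppressWarnings(ks.test(prec, stats::pgamma, shape = post_shape,
                                 rate = post_rate))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("empty deviations draw the variance from its prior", {
  set.seed(8)
  v <- vapply(1:5000, function(i) gibbs_update_variance(numeric(0), 2, 3), 0)
  ks <- suppressWarnings(ks.test(1 / v, stats::pgamma, shape = 2, rate = 3))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("scaling deviations by k scales variance draws by k^2", {
  dev <- c(0.4, -1.1, 0.7)
  k <- 3
  set.seed(5); v1 <- gibbs_update_variance(dev, 0.5, 1e-12)
  set.seed(5); v2 <- gibbs_update_variance(k * dev, 0.5, 1e-12)
  expect_equal(v2 / v1, k^2, tolerance = 1e-9)
})

test_that("traces survive a CSV round trip and summaries are unchanged", {
  d <- small_sim_study(sets = 6L)
  spec <- model_spec(d$manifest, interaction_pairs = list(c("snp1", "snp2")))
  tr <- run_chain("unconditional", d, spec,
                  cfg = chain_config(n_iter = 300L, burn_in = 100L,
                                     thin = 3L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(summarize_posterior(tr2), summarize_posterior(tr),
               tolerance = 1e-12)
  expect_equal(tr2$deviance, tr$deviance, tolerance = 1e-12)
  expect_equal(tr2$model, tr$model)
  expect_equal(tr2$interaction_pairs, tr$interaction_pairs)
  expect_equal(tr2$config$n_iter, tr$config$n_iter)
  expect_equal(dic(tr2, d, spec)$dic, dic(tr, d, spec)$dic,
               tolerance = 1e-9)
})

test_that("relabeling categories permutes effects but not heterogeneity", {
  m <- toy_manifest(1L)
  sc <- sim_scenario(m, alt_freq = 0.4, n_categories = 3L,
                     sets_per_category = 40L, true_mu = 0.5,
                     true_tau2 = 1.2, var_area = 0, var_pair = 0.2,
                     seed = 21L)
  d <- simulate_matched_study(sc)
  # relabel categories I->III, II->I, III->II (labels sort to a new order)
  relab <- c(I = "B", II = "C", III = "A")
  subj2 <- d$subjects
  subj2$category <- unname(relab[subj2$category])
  d2 <- study_data(subj2, m)
  spec <- model_spec(m)
  cfg <- chain_config(n_iter = 6000L, burn_in = 2000L, thin = 3L, seed = 4L)
  t1 <- run_chain("unconditional", d, spec, cfg = cfg)
  t2 <- run_chain("unconditional", d2, spec, cfg = cfg)
  # new category order A,B,C corresponds to old III,I,II
  perm <- match(c("III", "I", "II"), d$categories$label)
  m1 <- colMeans(t1$draws[, sprintf("beta[1,%d]", perm)])
  m2 <- colMeans(t2$draws[, sprintf("beta[1,%d]", 1:3)])
  expect_lt(max(abs(m2 - m1)), 0.35)
  md1 <- median(t1$draws[, "tau2[1]"])
  md2 <- median(t2$draws[, "tau2[1]"])
  expect_lt(abs(md2 - md1), 0.5 * max(md1, md2))
})
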