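# a one-category paper-model study whose first subject carries G/G for
# rs7799039 and A/A for rs12535708 (coded 1 under their recessive models)
# and reference genotypes elsewhere
worked_example_study <- function() {
  m <- paper_manifest()
  subjects <- data.frame(
    subject_id = c("case1", "ctrl1"), set_id = "set1", category = "I",
    status = c(1L, 0L),
    rs1801282 = "C/C", rs7799039 = c("G/G", "A/A"),
    rs12535708 = c("A/A", "C/C"), rs822390 = "T/T", rs182052 = "A/A",
    stringsAsFactors = FALSE)
  study_data(subjects, m)
}

test_that("linear predictor reproduces the combined-effect worked example", {
  d <- worked_example_study()
  spec <- paper_spec()
  st <- init_state(d, spec)
  expect_equal(linear_predictor(st, d, spec), c(0, 0))  # empty predictor

  st$beta[2, 1] <- 0.25    # rs7799039, category I
  st$beta[3, 1] <- 9.90    # rs12535708, category I
  st$gamma <- -10.70       # their interaction
  eta <- linear_predictor(st, d, spec)
  expect_equal(eta[1], 0.25 + 9.90 - 10.70)  # = -0.55
  expect_equal(eta[2], 0)
})

test_that("additive coding enters the predictor linearly", {
  m <- toy_manifest(1L)
  d <- toy_study(list(list(2L, 1L), list(0L, 1L)),
                 categories = c("I", "I"), manifest = m)
  spec <- model_spec(m)
  st <- init_state(d, spec)
  st$beta[1, 1] <- 0.7
  eta <- linear_predictor(st, d, spec)
  # codes are 2,1,0,1 -> eta = 1.4, 0.7, 0, 0.7
  expect_equal(eta, 0.7 * c(2, 1, 0, 1))
})

test_that("unconditional log-likelihood matches a per-subject Bernoulli oracle", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest,
                     interaction_pairs = list(c("snp1", "snp2")))
  st <- nontrivial_state(d, spec)

  # independent oracle: per-subject probabilities from first principles
  eta_oracle <- vapply(seq_len(nrow(d$subjects)), function(i) {
    ci <- d$cat_idx[i]
    st$alpha + sum(st$beta[, ci] * d$coded[i, ]) +
      st$gamma * d$coded[i, 1] * d$coded[i, 2] +
      st$a[ci] + st$b[d$set_idx[i]]
  }, 0)
  oracle <- sum(log(ifelse(d$y == 1, plogis(eta_oracle),
                           1 - plogis(eta_oracle))))
  expect_equal(loglik_unconditional(st, d, spec), oracle)
})

test_that("null predictor gives n log(1/2) and extremes are overflow-safe", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest)
  st <- init_state(d, spec)
  expect_equal(loglik_unconditional(st, d, spec), 6 * log(0.5))

  # a certain event contributes 0; overflow-safe far beyond exp() range
  m <- toy_manifest(1L)
  d1 <- toy_study(list(list(1L, 0L)), categories = "I", manifest = m)
  spec1 <- model_spec(m)
  st1 <- init_state(d1, spec1)
  st1$beta[1, 1] <- 1000   # case has code 1 -> eta = 1000; control eta = 0
  expect_equal(loglik_unconditional(st1, d1, spec1), log(0.5))
})

test_that("log-likelihood is invariant to subject order", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest)
  st <- nontrivial_state(d, spec)
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  d2 <- study_data(d$subjects[perm, ], d$manifest)
  st2 <- st
  st2$a <- st$a[match(d2$categories$label, d$categories$label)]
  st2$b <- st$b[match(d2$sets$set_id, d$sets$set_id)]
  expect_equal(loglik_unconditional(st2, d2, spec),
               loglik_unconditional(st, d, spec))
})

test_that("log-likelihood is monotone in a single subject's predictor", {
  m <- toy_manifest(1L)
  d <- toy_study(list(list(1L, 0L)), categories = "I", manifest = m)
  spec <- model_spec(m)
  st <- init_state(d, spec)
  lls <- vapply(c(-2, 0, 2), function(bb) {
    st$beta[1, 1] <- bb          # moves only the case's eta
    loglik_unconditional(st, d, spec)
  }, 0)
  expect_true(all(diff(lls) > 0))
})

test_that("log prior matches its closed form at the zero state", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest, interaction_pairs = list(c("snp1", "snp2")))
  pr <- prior_spec()
  st <- init_state(d, spec)
  G <- 2L; C <- nrow(d$categories); P <- nrow(d$sets)
  expected <-
    (1 + G + 1) * dnorm(0, 0, sqrt(1000), log = TRUE) +   # alpha, mu, gamma
    G * C * dnorm(0, 0, 1, log = TRUE) +                  # beta | mu, tau2=1
    (C + P) * dnorm(0, 0, 1, log = TRUE) +                # a, b
    (G + 2) * dgamma(1, 0.001, rate = 0.001, log = TRUE)  # precisions
  expect_equal(logprior(st, spec, pr), expected)
})

test_that("halving one heterogeneity variance shifts the prior analytically", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest)
  pr <- prior_spec()
  st <- init_state(d, spec)   # beta = mu: zero deviations
  C <- nrow(d$categories)
  lp1 <- logprior(st, spec, pr)
  st$tau2[1] <- 0.5
  lp2 <- logprior(st, spec, pr)
  expected_delta <-
    C * (dnorm(0, 0, sqrt(0.5), log = TRUE) - dnorm(0, 0, 1, log = TRUE)) +
    dgamma(2, 0.001, rate = 0.001, log = TRUE) -
    dgamma(1, 0.001, rate = 0.001, log = TRUE)
  expect_equal(lp2 - lp1, expected_delta)
})

test_that("non-positive variances have zero prior density", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest)
  st <- init_state(d, spec)
  st$tau2[2] <- -1
  expect_identical(logprior(st, spec, prior_spec()), -Inf)
})

test_that("log posterior is the sum of log-likelihood and log prior", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest, interaction_pairs = list(c("snp1", "snp2")))
  pr <- prior_spec()
  st <- nontrivial_state(d, spec)
  expect_equal(logposterior_unconditional(st, d, spec, pr),
               loglik_unconditional(st, d, spec) + logprior(st, spec, pr))
  expect_true(is.finite(logposterior_unconditional(init_state(d, spec),
                                                   d, spec, pr)))
})

test_that("without the GE layer the posterior ignores category-specific slots", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest, ge_interaction = FALSE)
  pr <- prior_spec()
  st <- nontrivial_state(d, spec)
  lp1 <- logposterior_unconditional(st, d, spec, pr)
  st$beta[] <- st$beta[] + 5   # unused layer
  expect_equal(logposterior_unconditional(st, d, spec, pr), lp1)
})

test_that("in the flat-prior limit posterior differences equal likelihood differences", {
  d <- six_subject_study()
  spec <- model_spec(d$manifest)
  pr <- prior_spec(location_prior_variance = 1e12)
  st1 <- nontrivial_state(d, spec, seed = 1L)
  st2 <- st1
  st2$mu <- st1$mu + 0.5
  st2$alpha <- st1$alpha - 0.3
  # shift beta along with mu so the hierarchical deviations are unchanged
  st2$beta <- sweep(st1$beta, 1L, 0.5, `+`)
  lp_diff <- logposterior_unconditional(st2, d, spec, pr) -
    logposterior_unconditional(st1, d, spec, pr)
  ll_diff <- loglik_unconditional(st2, d, spec) -
    loglik_unconditional(st1, d, spec)
  expect_equal(lp_diff, ll_diff, tolerance = 1e-6)
})
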