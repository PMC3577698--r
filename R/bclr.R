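#' Conditional log-likelihood of one matched set
#'
#' Conditioning on the set containing exactly one case, the probability that
#' the observed case is the diseased member is
#' exp(psi_case) / sum_j exp(psi_j) over the set's members, where psi is the
#' linear predictor without the set-constant intercept, area and pair terms.
#' Evaluated through log-sum-exp.
#'
#' @param state a \code{"cgx_state"}.
#' @param data a \code{"cgx_study"}.
#' @param spec a \code{"cgx_spec"}.
#' @param set_id id of the matched set.
#' @return The set's conditional log-likelihood contribution.
#' @export
set_loglik_conditional <- function(state, data, spec, set_id) {
  p <- match(set_id, data$sets$set_id)
  if (is.na(p)) stop("unknown set id: ", set_id)
  idx <- which(data$set_idx == p)
  psi <- linear_predictor(state, data, spec, conditional = TRUE)[idx]
  y <- data$y[idx]
  if (sum(y) != 1L)
    stop("set ", set_id, " does not contain exactly one case")
  m <- max(psi)
  psi[y == 1L] - (m + log(sum(exp(psi - m))))
}

#' Conditional (BCLR) log-likelihood of the full study
#'
#' Matched sets are independent; the value is the sum of per-set conditional
#' log-likelihoods.  Invariant under adding any set-constant to the
#' predictors, which is why the intercept and the area/pair random
#' intercepts are excluded: the conditional likelihood carries no
#' information on them.
#'
#' @inheritParams set_loglik_conditional
#' @return A single number.
#' @export
loglik_conditional <- function(state, data, spec) {
  psi <- linear_predictor(state, data, spec, conditional = TRUE)
  if (any(is.nan(psi))) return(-Inf)
  total <- 0
  for (p in seq_len(nrow(data$sets))) {
    idx <- which(data$set_idx == p)
    ps <- psi[idx]
    m <- max(ps)
    total <- total + ps[data$y[idx] == 1L] - (m + log(sum(exp(ps - m))))
  }
  total
}

#' Unnormalized log posterior of the conditional (BCLR) model
#'
#' Conditional log-likelihood plus the prior restricted to the retained
#' parameters (SNP effects with their hierarchical GE layer, interaction
#' gamma, covariate effects).
#'
#' @inheritParams set_loglik_conditional
#' @param priors a \code{\link{prior_spec}}.
#' @return A single number; \code{-Inf} propagates.
#' @export
logposterior_conditional <- function(state, data, spec, priors) {
  ll <- loglik_conditional(state, data, spec)
  if (!is.finite(ll)) return(-Inf)
  ll + logprior(state, spec, priors, conditional = TRUE)
}
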