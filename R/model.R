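#' Model specification for the hierarchical cross-level interaction model
#'
#' Declares which SNPs enter the linear predictor, any SNP-SNP interaction
#' pairs, covariates, and whether the cross-level gene-environment (GE)
#' interaction layer is present.  With \code{ge_interaction = TRUE} each SNP
#' g has category-specific effects beta[g,c] ~ Normal(mu[g], tau2[g]) and
#' tau2[g] measures the across-category heterogeneity (the GE interaction);
#' with \code{FALSE} the effect is a single mu[g] common to all categories
#' and tau2 leaves the parameter space.
#'
#' @param manifest a \code{\link{snp_manifest}}.
#' @param interaction_pairs list of length-2 character vectors of SNP ids
#'   whose coded-genotype product enters with one shared coefficient gamma.
#' @param covariates character vector of covariate column names.
#' @param ge_interaction logical; see above.
#' @return An object of class \code{"cgx_spec"}.
#' @export
model_spec <- function(manifest, interaction_pairs = list(),
                       covariates = character(), ge_interaction = TRUE) {
  stopifnot(inherits(manifest, "cgx_manifest"))
  if (length(interaction_pairs)) {
    for (p in interaction_pairs) {
      if (length(p) != 2L || !all(p %in% manifest$snp_id))
        stop("interaction pair must name two manifest SNPs: ",
             paste(p, collapse = " x "))
    }
  }
  structure(list(manifest = manifest,
                 interaction_pairs = interaction_pairs,
                 covariates = as.character(covariates),
                 ge_interaction = isTRUE(ge_interaction)),
            class = "cgx_spec")
}

#' The default model of the motivating study
#'
#' Five SNPs with the study's codings, one SNP-SNP interaction pair
#' (rs7799039 x rs12535708, both recessive-coded so the product term is 0/1),
#' no covariates (matching already balances sex, age, education and
#' ethnicity), and the GE layer switched on.
#'
#' @param ge_interaction include the cross-level GE layer (default
#'   \code{TRUE}); \code{FALSE} gives the no-GE comparator used for DIC
#'   model selection.
#' @return A \code{"cgx_spec"}.
#' @export
paper_spec <- function(ge_interaction = TRUE) {
  model_spec(paper_manifest(),
             interaction_pairs = list(c("rs7799039", "rs12535708")),
             ge_interaction = ge_interaction)
}

#' Prior specification
#'
#' Location parameters (intercept, SNP effect means mu, interaction gamma,
#' covariate effects) get zero-mean normal priors with one shared large
#' variance.  Each precision (1/tau2[g], 1/var_area, 1/var_pair) gets a
#' gamma prior, configurable per layer for sensitivity analysis.
#'
#' @param location_prior_variance variance of the vague normal priors.
#' @param snp_heterogeneity,area,pair length-2 numeric vectors
#'   \code{c(shape, rate)} of the gamma prior on the corresponding precision.
#' @return An object of class \code{"cgx_priors"}.
#' @export
prior_spec <- function(location_prior_variance = 1000,
                       snp_heterogeneity = c(0.001, 0.001),
                       area = c(0.001, 0.001),
                       pair = c(0.001, 0.001)) {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(x <= 0))
      stop("gamma prior for ", nm, " must be two positive numbers (shape, rate)")
    as.numeric(x)
  }
  if (location_prior_variance <= 0)
    stop("location_prior_variance must be positive")
  structure(list(location_prior_variance = as.numeric(location_prior_variance),
                 precision_gamma = list(
                   snp_heterogeneity = chk(snp_heterogeneity, "snp_heterogeneity"),
                   area = chk(area, "area"),
                   pair = chk(pair, "pair"))),
            class = "cgx_priors")
}

#' Initial parameter state
#'
#' Locations start at zero, variances at one, random intercepts at zero.
#'
#' @param data a \code{"cgx_study"}.
#' @param spec a \code{"cgx_spec"}.
#' @return A list of class \code{"cgx_state"} with elements \code{alpha},
#'   \code{beta} (G x C matrix), \code{mu} (length G), \code{tau2}
#'   (length G), \code{gamma} (one per interaction pair), \code{delta}
#'   (one per covariate), \code{a} (length C), \code{b} (one per set),
#'   \code{var_area}, \code{var_pair}.
#' @export
init_state <- function(data, spec) {
  G <- nrow(spec$manifest)
  C <- nrow(data$categories)
  P <- nrow(data$sets)
  structure(list(alpha = 0,
                 beta = matrix(0, G, C,
                               dimnames = list(spec$manifest$snp_id,
                                               data$categories$label)),
                 mu = stats::setNames(rep(0, G), spec$manifest$snp_id),
                 tau2 = stats::setNames(rep(1, G), spec$manifest$snp_id),
                 gamma = rep(0, length(spec$interaction_pairs)),
                 delta = stats::setNames(rep(0, length(spec$covariates)),
                                         spec$covariates),
                 a = rep(0, C), b = rep(0, P),
                 var_area = 1, var_pair = 1),
            class = "cgx_state")
}

# Coded-genotype product columns for the declared interaction pairs (n x K).
interaction_matrix <- function(data, spec) {
  K <- length(spec$interaction_pairs)
  M <- matrix(0, nrow(data$coded), K)
  for (k in seq_len(K)) {
    p <- spec$interaction_pairs[[k]]
    M[, k] <- data$coded[, p[1L]] * data$coded[, p[2L]]
  }
  M
}

#' Linear predictor of the hierarchical logistic model
#'
#' For subject i in category c and matched set p:
#' eta_i = alpha + sum_g beta[g,c] S_i(g) + sum_k gamma_k S_i(g1) S_i(g2)
#' + delta' x_i + a_c + b_p.  Under the conditional (BCLR) reduction the
#' set-constant terms alpha, a_c and b_p are dropped, leaving the within-set
#' predictor psi_i.
#'
#' @param state a \code{"cgx_state"}.
#' @param data a \code{"cgx_study"}.
#' @param spec a \code{"cgx_spec"}.
#' @param conditional drop intercept, area and pair terms (default
#'   \code{FALSE}).
#' @return Numeric vector, one predictor per subject (in \code{data$subjects}
#'   row order).
#' @export
linear_predictor <- function(state, data, spec, conditional = FALSE) {
  G <- nrow(spec$manifest)
  C <- nrow(data$categories)
  if (spec$ge_interaction && !all(dim(state$beta) == c(G, C)))
    stop("state/spec dimension mismatch: beta is ",
         paste(dim(state$beta), collapse = "x"), ", expected ", G, "x", C)
  S <- data$coded
  eta <- numeric(nrow(S))
  for (g in seq_len(G)) {
    eff <- if (spec$ge_interaction) state$beta[g, data$cat_idx]
           else rep(state$mu[g], length(eta))
    eta <- eta + eff * S[, g]
  }
  M <- interaction_matrix(data, spec)
  for (k in seq_along(state$gamma)) eta <- eta + state$gamma[k] * M[, k]
  if (length(spec$covariates))
    eta <- eta + as.vector(data$covariates[, spec$covariates, drop = FALSE] %*%
                             state$delta)
  if (!conditional)
    eta <- eta + state$alpha + state$a[data$cat_idx] + state$b[data$set_idx]
  unname(eta)
}

# Numerically safe Bernoulli log-likelihood terms: y*eta - log(1 + exp(eta)).
bernoulli_loglik_terms <- function(y, eta) {
  y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

#' Unconditional (full) Bernoulli log-likelihood
#'
#' Sum over subjects of y_i eta_i - log(1 + exp(eta_i)), evaluated
#' overflow-safely.
#'
#' @inheritParams linear_predictor
#' @return A single number; \code{-Inf} if any predictor is non-finite in
#'   the wrong direction for its outcome.
#' @export
loglik_unconditional <- function(state, data, spec) {
  eta <- linear_predictor(state, data, spec)
  if (any(is.nan(eta))) return(-Inf)
  sum(bernoulli_loglik_terms(data$y, eta))
}

#' Log prior density of a parameter state
#'
#' Normal log-densities for the location parameters (centered at zero with
#' the vague prior variance), Normal(mu[g], tau2[g]) for each beta[g,c],
#' zero-mean normals for the area and pair random intercepts, and gamma
#' log-densities for the three precisions 1/tau2[g], 1/var_area, 1/var_pair.
#' Under \code{conditional = TRUE} the intercept, area and pair layers are
#' absent and contribute nothing.
#'
#' @inheritParams linear_predictor
#' @param priors a \code{\link{prior_spec}}.
#' @return A single number; \code{-Inf} for non-positive variances.
#' @export
logprior <- function(state, spec, priors, conditional = FALSE) {
  v0 <- priors$location_prior_variance
  pg <- priors$precision_gamma
  if (any(state$tau2 <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(state$mu, 0, sqrt(v0), log = TRUE)) +
    sum(stats::dnorm(state$gamma, 0, sqrt(v0), log = TRUE)) +
    sum(stats::dnorm(state$delta, 0, sqrt(v0), log = TRUE))
  if (spec$ge_interaction) {
    lp <- lp + sum(stats::dnorm(state$beta, state$mu, sqrt(state$tau2),
                                log = TRUE)) +
      sum(stats::dgamma(1 / state$tau2, shape = pg$snp_heterogeneity[1L],
                        rate = pg$snp_heterogeneity[2L], log = TRUE))
  }
  if (!conditional) {
    if (state$var_area <= 0 || state$var_pair <= 0) return(-Inf)
    lp <- lp + stats::dnorm(state$alpha, 0, sqrt(v0), log = TRUE) +
      sum(stats::dnorm(state$a, 0, sqrt(state$var_area), log = TRUE)) +
      sum(stats::dnorm(state$b, 0, sqrt(state$var_pair), log = TRUE)) +
      stats::dgamma(1 / state$var_area, shape = pg$area[1L],
                    rate = pg$area[2L], log = TRUE) +
      stats::dgamma(1 / state$var_pair, shape = pg$pair[1L],
                    rate = pg$pair[2L], log = TRUE)
  }
  lp
}

#' Unnormalized log posterior of the unconditional model
#'
#' @inheritParams logprior
#' @param data a \code{"cgx_study"}.
#' @return \code{loglik_unconditional + logprior}; \code{-Inf} propagates.
#' @export
logposterior_unconditional <- function(state, data, spec, priors) {
  ll <- loglik_unconditional(state, data, spec)
  if (!is.finite(ll)) return(-Inf)
  ll + logprior(state, spec, priors)
}
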