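#' MCMC chain configuration
#'
#' Defaults follow the analysis protocol of the motivating study: 50,000
#' retained-range iterations after a burn-in of 5,000, thinned by 10, giving
#' 5,000 posterior draws.
#'
#' @param n_iter post-burn-in iterations.
#' @param burn_in burn-in iterations (discarded; adaptation happens here).
#' @param thin keep every \code{thin}-th post-burn-in draw; an incomplete
#'   final block is dropped, so \code{floor(n_iter / thin)} draws are kept.
#' @param seed integer seed for R's RNG.
#' @param adapt_window iterations per step-scale adaptation batch.
#' @param target_acceptance target acceptance rate of the scalar
#'   random-walk updates (0.44 is the standard one-dimensional choice).
#' @return An object of class \code{"cgx_chain_config"}.
#' @export
chain_config <- function(n_iter = 50000L, burn_in = 5000L, thin = 10L,
                         seed = 1L, adapt_window = 50L,
                         target_acceptance = 0.44) {
  if (n_iter < 1L || burn_in < 1L || thin < 1L)
    stop("n_iter, burn_in and thin must be positive")
  if (target_acceptance <= 0 || target_acceptance >= 1)
    stop("target_acceptance must lie in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 target_acceptance = target_acceptance),
            class = "cgx_chain_config")
}

#' Short-chain profile
#'
#' 5,000 iterations after a 500-iteration burn-in, thinned by 5 (1,000
#' retained draws): suitable for simulation studies and test suites.
#'
#' @param seed integer seed.
#' @return A \code{\link{chain_config}}.
#' @export
fast_chain_config <- function(seed = 1L) {
  chain_config(n_iter = 5000L, burn_in = 500L, thin = 5L, seed = seed)
}

# parameter column names matching the sampler's layout
trace_param_names <- function(data, spec, model) {
  conditional <- model == "bclr"
  G <- nrow(spec$manifest); C <- nrow(data$categories)
  K <- length(spec$interaction_pairs); Q <- length(spec$covariates)
  nm <- character()
  if (!conditional) nm <- "alpha"
  if (spec$ge_interaction) {
    nm <- c(nm,
            as.vector(t(outer(seq_len(G), seq_len(C),
                              function(g, c) sprintf("beta[%d,%d]", g, c)))),
            sprintf("mu[%d]", seq_len(G)), sprintf("tau2[%d]", seq_len(G)))
  } else {
    nm <- c(nm, sprintf("mu[%d]", seq_len(G)))
  }
  if (K == 1L) nm <- c(nm, "gamma")
  else if (K > 1L) nm <- c(nm, sprintf("gamma[%d]", seq_len(K)))
  if (Q) nm <- c(nm, sprintf("delta[%s]", spec$covariates))
  if (!conditional)
    nm <- c(nm, sprintf("a[%d]", seq_len(C)),
            sprintf("b[%d]", seq_len(nrow(data$sets))),
            "var_area", "var_pair")
  nm
}

# names of the random-walk Metropolis components, in sweep order
metropolis_component_names <- function(data, spec, model) {
  conditional <- model == "bclr"
  G <- nrow(spec$manifest); C <- nrow(data$categories)
  K <- length(spec$interaction_pairs); Q <- length(spec$covariates)
  nm <- character()
  if (!conditional) nm <- "alpha"
  if (spec$ge_interaction)
    nm <- c(nm, as.vector(t(outer(seq_len(G), seq_len(C),
                                  function(g, c) sprintf("beta[%d,%d]", g, c)))))
  else nm <- c(nm, sprintf("mu[%d]", seq_len(G)))
  if (K == 1L) nm <- c(nm, "gamma")
  else if (K > 1L) nm <- c(nm, sprintf("gamma[%d]", seq_len(K)))
  if (Q) nm <- c(nm, sprintf("delta[%s]", spec$covariates))
  if (!conditional)
    nm <- c(nm, sprintf("a[%d]", seq_len(C)),
            sprintf("b[%d]", seq_len(nrow(data$sets))))
  nm
}

#' Run an MCMC chain for either model
#'
#' Metropolis-within-Gibbs: the SNP-effect means mu[g], the heterogeneity
#' variances tau2[g] and the area/pair variances are drawn from their
#' conjugate full conditionals; every other parameter moves by adaptive
#' random-walk Metropolis (step scales tuned toward the target acceptance
#' rate during burn-in and frozen afterwards, preserving detailed balance in
#' the retained range).  The conditional (\code{"bclr"}) model has no
#' intercept, area or pair layer.  Identical seed and inputs give an
#' identical trace.
#'
#' @param model \code{"unconditional"} (full-likelihood GLMM) or
#'   \code{"bclr"} (conditional likelihood).
#' @param data a \code{"cgx_study"}.
#' @param spec a \code{"cgx_spec"}.
#' @param priors a \code{\link{prior_spec}}.
#' @param cfg a \code{\link{chain_config}}.
#' @return An object of class \code{"cgx_trace"}: \code{draws} (retained
#'   draws x named parameters), \code{deviance} (-2 log-likelihood of the
#'   fitted model kind at each retained draw), \code{accept} (per-component
#'   post-burn-in acceptance rates), \code{model}, \code{config},
#'   \code{ge_interaction}, \code{snp_ids}.
#' @export
run_chain <- function(model = c("unconditional", "bclr"), data, spec,
                      priors = prior_spec(), cfg = chain_config()) {
  model <- match.arg(model)
  stopifnot(inherits(data, "cgx_study"), inherits(spec, "cgx_spec"),
            inherits(priors, "cgx_priors"),
            inherits(cfg, "cgx_chain_config"))
  rep <- validate_sets(data)
  if (nrow(rep)) stop("data fails matched-set validation; see validate_sets()")
  conditional <- model == "bclr"

  state0 <- init_state(data, spec)
  lp0 <- if (conditional) logposterior_conditional(state0, data, spec, priors)
         else logposterior_unconditional(state0, data, spec, priors)
  if (!is.finite(lp0))
    stop("non-finite log posterior at initialization; try rescaling ",
         "covariates or a different starting configuration")

  X <- data$covariates[, spec$covariates, drop = FALSE]
  Inter <- interaction_matrix(data, spec)
  set.seed(cfg$seed)
  res <- .run_chain_cpp(
    S = data$coded, X = X, Inter = Inter, y = data$y,
    cat0 = data$cat_idx - 1L, set0 = data$set_idx - 1L,
    set_cat0 = data$sets$category_id - 1L,
    conditional = conditional, ge = spec$ge_interaction,
    v0 = priors$location_prior_variance,
    prior_tau = priors$precision_gamma$snp_heterogeneity,
    prior_area = priors$precision_gamma$area,
    prior_pair = priors$precision_gamma$pair,
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    adapt_window = cfg$adapt_window, target_acc = cfg$target_acceptance)

  nm <- trace_param_names(data, spec, model)
  draws <- res$draws
  colnames(draws) <- nm
  accept <- res$accept
  names(accept) <- metropolis_component_names(data, spec, model)
  structure(list(draws = draws, deviance = as.numeric(res$deviance),
                 accept = accept, model = model, config = cfg,
                 ge_interaction = spec$ge_interaction,
                 snp_ids = spec$manifest$snp_id,
                 interaction_pairs = spec$interaction_pairs,
                 covariates = spec$covariates),
            class = "cgx_trace")
}

#' @export
print.cgx_trace <- function(x, ...) {
  cat("MCMC trace (", x$model, " model): ", nrow(x$draws), " retained draws of ",
      ncol(x$draws), " parameters; mean deviance ",
      round(mean(x$deviance), 2), "\n", sep = "")
  invisible(x)
}

#' One random-walk Metropolis update of a scalar parameter
#'
#' Proposes value + Normal(0, step_scale) and accepts with probability
#' min(1, exp(delta log posterior)).  A proposal into a region of zero
#' posterior density (log posterior \code{-Inf}) is always rejected; a
#' proposal with no density change is always accepted.
#'
#' @param value current parameter value.
#' @param logpost function of one argument returning the (unnormalized) log
#'   posterior density.
#' @param step_scale proposal standard deviation (> 0).
#' @param current_logpost optional cached \code{logpost(value)}.
#' @return List with \code{value}, \code{logpost} and \code{accepted}.
#' @export
metropolis_update <- function(value, logpost, step_scale,
                              current_logpost = NULL) {
  if (step_scale <= 0) stop("step_scale must be positive")
  if (is.null(current_logpost)) current_logpost <- logpost(value)
  proposal <- value + stats::rnorm(1L, 0, step_scale)
  lp <- logpost(proposal)
  accepted <- is.finite(lp) && log(stats::runif(1L)) < lp - current_logpost
  if (accepted) list(value = proposal, logpost = lp, accepted = TRUE)
  else list(value = value, logpost = current_logpost, accepted = FALSE)
}

#' Conjugate Gibbs draw of a variance component
#'
#' With deviations e_1..e_n from their layer mean and a Gamma(shape, rate)
#' prior on the precision, the full conditional of the precision is
#' Gamma(shape + n/2, rate + sum(e^2)/2); the returned value is its inverse
#' (a variance draw).  With no deviations the draw comes from the prior.
#'
#' @param deviations numeric vector of centered effects for the layer.
#' @param shape,rate gamma prior on the precision.
#' @return One positive variance draw.
#' @export
gibbs_update_variance <- function(deviations, shape, rate) {
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  n <- length(deviations)
  1 / stats::rgamma(1L, shape = shape + n / 2,
                    rate = rate + sum(deviations^2) / 2)
}

#' Persist a trace as CSV plus JSON metadata
#'
#' The CSV holds one column per named parameter and a final \code{deviance}
#' column, one row per retained draw.  Chain configuration, model kind and
#' acceptance rates go to a \code{.meta.json} sidecar.
#'
#' @param trace a \code{"cgx_trace"}.
#' @param path output CSV path; the sidecar is \code{paste0(path, ".meta.json")}.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cgx_trace"))
  df <- as.data.frame(trace$draws, check.names = FALSE)
  df$deviance <- trace$deviance
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model = trace$model, config = unclass(trace$config),
               accept = as.list(trace$accept),
               ge_interaction = trace$ge_interaction,
               snp_ids = trace$snp_ids,
               interaction_pairs = trace$interaction_pairs,
               covariates = trace$covariates)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reload a persisted trace
#'
#' @param path CSV path written by \code{\link{write_trace}}.
#' @return A \code{"cgx_trace"}.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list(model = "unconditional", config = NULL, accept = NULL,
                    ge_interaction = any(grepl("^tau2\\[", names(df))),
                    snp_ids = NULL)
  dev <- df$deviance
  df$deviance <- NULL
  cfg <- if (!is.null(meta$config))
    do.call(chain_config, meta$config[c("n_iter", "burn_in", "thin", "seed",
                                        "adapt_window", "target_acceptance")])
  else NULL
  ip <- meta$interaction_pairs
  pairs <- if (is.null(ip) || length(ip) == 0L) list()
           else if (is.matrix(ip)) lapply(seq_len(nrow(ip)), function(i) ip[i, ])
           else if (is.character(ip)) list(ip)
           else lapply(ip, unlist)
  structure(list(draws = as.matrix(df), deviance = dev,
                 accept = unlist(meta$accept), model = meta$model,
                 config = cfg, ge_interaction = isTRUE(meta$ge_interaction),
                 snp_ids = meta$snp_ids, interaction_pairs = pairs,
                 covariates = as.character(unlist(meta$covariates))),
            class = "cgx_trace")
}
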