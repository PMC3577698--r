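#' Posterior summary table
#'
#' Sample mean, sample standard deviation, an equal-tailed credible interval
#' and the posterior probability of being positive, per parameter column of
#' a trace.
#'
#' @param trace a \code{"cgx_trace"}.
#' @param level credible level (default 0.95).
#' @return A data frame with columns \code{parameter}, \code{mean},
#'   \code{sd}, \code{lower}, \code{upper}, \code{p_positive}.
#' @export
summarize_posterior <- function(trace, level = 0.95) {
  stopifnot(inherits(trace, "cgx_trace"))
  if (nrow(trace$draws) == 0L) stop("empty trace")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  d <- trace$draws
  data.frame(
    parameter = colnames(d),
    mean = apply(d, 2L, mean),
    sd = apply(d, 2L, stats::sd),
    lower = apply(d, 2L, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(d, 2L, stats::quantile, probs = 1 - alpha, names = FALSE),
    p_positive = apply(d, 2L, function(x) mean(x > 0)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior probability that a parameter is positive
#'
#' Fraction of retained draws strictly greater than zero, the P(beta > 0 | y)
#' quantity used to compare category-specific SNP effects.
#'
#' @param trace a \code{"cgx_trace"}.
#' @param parameter parameter column name, e.g. \code{"beta[1,2]"}.
#' @return A number in [0, 1].
#' @export
prob_positive <- function(trace, parameter) {
  stopifnot(inherits(trace, "cgx_trace"))
  if (!parameter %in% colnames(trace$draws))
    stop("unknown parameter: ", parameter)
  mean(trace$draws[, parameter] > 0)
}

#' Combine log-odds components into one odds ratio
#'
#' Sums log-odds terms (e.g. two single-SNP effects for one category plus
#' their interaction coefficient) and exponentiates: the combined odds ratio
#' for carrying both exposure genotypes simultaneously.
#'
#' @param components numeric vector of log-odds terms; empty gives odds
#'   ratio 1.
#' @return List with \code{log_odds} (the sum) and \code{odds_ratio}
#'   (its exponential).
#' @examples
#' combined_odds_ratio(c(0.25, 9.90, -10.70))  # exp(-0.55) = 0.577
#' @export
combined_odds_ratio <- function(components) {
  lo <- sum(as.numeric(components))
  list(log_odds = lo, odds_ratio = exp(lo))
}

#' Cross-level heterogeneity report
#'
#' Summarizes the posterior of each SNP's across-category effect variance
#' tau2[g] - the cross-level gene-environment interaction measure - and
#' exports Gaussian kernel density curves (Silverman bandwidth) for
#' plotting.
#'
#' @param trace a \code{"cgx_trace"} from a fit with the GE layer.
#' @param level credible level for the intervals.
#' @return List with \code{summary} (data frame: snp, mean, sd, lower,
#'   upper) and \code{densities} (named list of data frames with columns
#'   \code{x}, \code{y}).
#' @export
heterogeneity_report <- function(trace, level = 0.95) {
  stopifnot(inherits(trace, "cgx_trace"))
  cols <- grep("^tau2\\[", colnames(trace$draws), value = TRUE)
  if (!length(cols))
    stop("trace has no tau2 columns: fit was run without the GE ",
         "interaction layer")
  alpha <- (1 - level) / 2
  g <- as.integer(sub("^tau2\\[(\\d+)\\]$", "\\1", cols))
  snp <- if (!is.null(trace$snp_ids)) trace$snp_ids[g] else cols
  sm <- data.frame(
    snp = snp, parameter = cols,
    mean = apply(trace$draws[, cols, drop = FALSE], 2L, mean),
    sd = apply(trace$draws[, cols, drop = FALSE], 2L, stats::sd),
    lower = apply(trace$draws[, cols, drop = FALSE], 2L, stats::quantile,
                  probs = alpha, names = FALSE),
    upper = apply(trace$draws[, cols, drop = FALSE], 2L, stats::quantile,
                  probs = 1 - alpha, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  dens <- lapply(cols, function(cl) {
    x <- trace$draws[, cl]
    if (stats::sd(x) == 0)
      return(data.frame(x = x[1L], y = Inf))
    d <- stats::density(x)
    data.frame(x = d$x, y = d$y)
  })
  names(dens) <- snp
  list(summary = sm, densities = dens)
}

# rebuild a cgx_state from the column means of a trace
state_from_trace_means <- function(trace, data, spec) {
  m <- colMeans(trace$draws)
  st <- init_state(data, spec)
  G <- nrow(spec$manifest); C <- nrow(data$categories)
  pick <- function(nm, default) if (nm %in% names(m)) m[[nm]] else default
  st$alpha <- pick("alpha", 0)
  if (spec$ge_interaction) {
    for (g in seq_len(G)) for (c in seq_len(C))
      st$beta[g, c] <- m[[sprintf("beta[%d,%d]", g, c)]]
    st$tau2[] <- m[sprintf("tau2[%d]", seq_len(G))]
  }
  st$mu[] <- m[sprintf("mu[%d]", seq_len(G))]
  K <- length(spec$interaction_pairs)
  if (K == 1L) st$gamma <- m[["gamma"]]
  else if (K > 1L) st$gamma <- unname(m[sprintf("gamma[%d]", seq_len(K))])
  if (length(spec$covariates))
    st$delta[] <- m[sprintf("delta[%s]", spec$covariates)]
  if (trace$model == "unconditional") {
    st$a <- unname(m[sprintf("a[%d]", seq_len(C))])
    st$b <- unname(m[sprintf("b[%d]", seq_len(nrow(data$sets)))])
    st$var_area <- pick("var_area", 1)
    st$var_pair <- pick("var_pair", 1)
  }
  st
}

#' Deviance information criterion
#'
#' Conditional-deviance focus: the deviance is -2 times the model's
#' log-likelihood evaluated at a draw's full state, random effects included.
#' Dbar is the mean of the per-draw deviances recorded in the trace;
#' D(at mean) re-evaluates the deviance at the posterior mean of every
#' sampled quantity; p_D = Dbar - D(at mean); DIC = Dbar + p_D.
#'
#' @param trace a \code{"cgx_trace"} (must carry per-draw deviance).
#' @param data the \code{"cgx_study"} the trace was fitted to.
#' @param spec the \code{"cgx_spec"} used for the fit.
#' @return An object of class \code{"cgx_dic"}: list with \code{dbar},
#'   \code{d_at_mean}, \code{p_d}, \code{dic}.
#' @export
dic <- function(trace, data, spec) {
  stopifnot(inherits(trace, "cgx_trace"))
  if (is.null(trace$deviance) || !length(trace$deviance))
    stop("trace carries no deviance record")
  dbar <- mean(trace$deviance)
  st <- state_from_trace_means(trace, data, spec)
  ll <- if (trace$model == "bclr") loglik_conditional(st, data, spec)
        else loglik_unconditional(st, data, spec)
  d_at_mean <- -2 * ll
  p_d <- dbar - d_at_mean
  structure(list(dbar = dbar, d_at_mean = d_at_mean, p_d = p_d,
                 dic = dbar + p_d),
            class = "cgx_dic")
}

#' @export
print.cgx_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (Dbar = %.2f, D(at mean) = %.2f, p_D = %.2f)\n",
              x$dic, x$dbar, x$d_at_mean, x$p_d))
  invisible(x)
}

#' Compare two models by DIC
#'
#' The model with the smaller DIC is preferred; equal DICs are flagged as a
#' tie with no selection.
#'
#' @param dic_a,dic_b \code{"cgx_dic"} objects.
#' @param labels length-2 character vector naming the models.
#' @return List with \code{selected} (label of the winner, or \code{NA} on a
#'   tie), \code{delta_dic} (dic_a - dic_b) and the two inputs.
#' @export
compare_models <- function(dic_a, dic_b, labels = c("model_a", "model_b")) {
  stopifnot(inherits(dic_a, "cgx_dic"), inherits(dic_b, "cgx_dic"))
  delta <- dic_a$dic - dic_b$dic
  selected <- if (delta < 0) labels[1L] else if (delta > 0) labels[2L]
              else NA_character_
  list(selected = selected, delta_dic = delta, tie = delta == 0,
       dic = stats::setNames(c(dic_a$dic, dic_b$dic), labels))
}
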