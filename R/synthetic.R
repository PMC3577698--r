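#' Simulation scenario for matched case-control studies
#'
#' Full truth specification of the generator: matched 1:1 or 1:2 sets nested
#' in contextual categories, Hardy-Weinberg genotypes per SNP, a shared
#' matched-set frailty, category-varying allelic effects
#' beta[g,c] ~ Normal(true_mu[g], true_tau2[g]) (degenerate at the mean when
#' true_tau2[g] = 0, i.e. no cross-level interaction), zero-mean area
#' effects, and an optional SNP-SNP interaction coefficient.
#'
#' @param manifest a \code{\link{snp_manifest}}.
#' @param alt_freq alternative-allele frequency per SNP, each in (0, 1).
#' @param n_categories number of contextual categories.
#' @param sets_per_category matched sets per category.
#' @param controls_per_case 1 or 2.
#' @param true_mu mean SNP effects (log odds per coded unit), length G.
#' @param true_tau2 across-category effect variances, length G,
#'   non-negative.
#' @param true_gamma coefficient of the coded-genotype product for each
#'   interaction pair.
#' @param interaction_pairs list of SNP-id pairs (as in
#'   \code{\link{model_spec}}).
#' @param true_intercept baseline log odds.
#' @param var_area,var_pair variances of the area effects and of the shared
#'   matched-set frailty; non-negative.
#' @param seed integer seed; (scenario, seed) fully determines the dataset.
#' @return An object of class \code{"cgx_scenario"}.
#' @export
sim_scenario <- function(manifest, alt_freq, n_categories = 4L,
                         sets_per_category = 100L, controls_per_case = 1L,
                         true_mu = rep(0, nrow(manifest)),
                         true_tau2 = rep(0, nrow(manifest)),
                         true_gamma = numeric(),
                         interaction_pairs = list(),
                         true_intercept = 0, var_area = 0.5,
                         var_pair = 0.25, seed = 1L) {
  stopifnot(inherits(manifest, "cgx_manifest"))
  G <- nrow(manifest)
  if (length(alt_freq) != G || any(alt_freq <= 0) || any(alt_freq >= 1))
    stop("alt_freq must give one frequency in (0, 1) per SNP")
  if (!(controls_per_case %in% c(1L, 2L)))
    stop("controls_per_case must be 1 or 2")
  if (length(true_mu) != G || length(true_tau2) != G)
    stop("true_mu and true_tau2 must have one entry per SNP")
  if (any(true_tau2 < 0) || var_area < 0 || var_pair < 0)
    stop("variances must be non-negative")
  if (length(true_gamma) != length(interaction_pairs))
    stop("true_gamma must have one entry per interaction pair")
  if (n_categories < 1L || sets_per_category < 1L)
    stop("n_categories and sets_per_category must be positive")
  structure(list(manifest = manifest, alt_freq = as.numeric(alt_freq),
                 n_categories = as.integer(n_categories),
                 sets_per_category = as.integer(sets_per_category),
                 controls_per_case = as.integer(controls_per_case),
                 true_mu = as.numeric(true_mu),
                 true_tau2 = as.numeric(true_tau2),
                 true_gamma = as.numeric(true_gamma),
                 interaction_pairs = interaction_pairs,
                 true_intercept = as.numeric(true_intercept),
                 var_area = as.numeric(var_area),
                 var_pair = as.numeric(var_pair),
                 seed = as.integer(seed)),
            class = "cgx_scenario")
}

#' The consistency-simulation preset
#'
#' Four categories of one hundred 1:1 matched sets each (100 cases and 100
#' matched controls per category, 800 subjects in total) with the five study
#' SNPs and their codings.  Alternative-allele frequencies (0.25, 0.30,
#' 0.25, 0.30, 0.35) and effect sizes are package defaults chosen to echo
#' the study's marginal genotype-class frequencies and effect pattern (one
#' SNP with across-category heterogeneity, the rest homogeneous); run the
#' replication driver (\code{\link{recovery_experiment}}) with incremented
#' seeds for a multi-replicate study.
#'
#' @param seed integer seed.
#' @param true_tau2 across-category variances (default: 1 for the first SNP,
#'   0 for the rest).
#' @param sets_per_category matched sets per category (default 100).
#' @return A \code{"cgx_scenario"}.
#' @export
paper_scenario <- function(seed = 1L, true_tau2 = c(1, 0, 0, 0, 0),
                           sets_per_category = 100L) {
  m <- paper_manifest()
  sim_scenario(manifest = m,
               alt_freq = c(0.25, 0.30, 0.25, 0.30, 0.35),
               n_categories = 4L, sets_per_category = sets_per_category,
               controls_per_case = 1L,
               true_mu = c(0.5, 0.3, 0.4, 0.3, 0.2),
               true_tau2 = true_tau2,
               true_gamma = 0,
               interaction_pairs = list(c("rs7799039", "rs12535708")),
               true_intercept = 0, var_area = 0.5, var_pair = 0.25,
               seed = seed)
}

#' Draw the realized true parameters of a scenario
#'
#' beta[g,c] ~ Normal(true_mu[g], true_tau2[g]) and a[c] ~ Normal(0,
#' var_area), both degenerate at their means when the variance is zero.
#' Seeded by \code{scenario$seed}, so the same scenario always yields the
#' same truth.
#'
#' @param scenario a \code{"cgx_scenario"}.
#' @return An object of class \code{"cgx_sim_truth"}: list with \code{beta}
#'   (G x C), \code{a} (length C) and the scenario.
#' @export
draw_true_params <- function(scenario) {
  stopifnot(inherits(scenario, "cgx_scenario"))
  set.seed(scenario$seed)
  G <- nrow(scenario$manifest); C <- scenario$n_categories
  beta <- matrix(stats::rnorm(G * C, mean = rep(scenario$true_mu, C),
                              sd = rep(sqrt(scenario$true_tau2), C)),
                 G, C)
  a <- stats::rnorm(C, 0, sqrt(scenario$var_area))
  structure(list(beta = beta, a = a, scenario = scenario),
            class = "cgx_sim_truth")
}

# genotype string for a count of alternative alleles
genotype_string <- function(n_alt, ref, alt) {
  c(paste0(ref, "/", ref), paste0(ref, "/", alt), paste0(alt, "/", alt))[n_alt + 1L]
}

# coded value from an alt-allele count under a genetic model
code_from_nalt <- function(n_alt, coding) {
  switch(coding,
         additive = n_alt,
         dominant = as.integer(n_alt >= 1L),
         recessive = as.integer(n_alt == 2L))
}

#' Simulate a matched case-control study
#'
#' Retrospective sampling by per-slot rejection: for each matched set a
#' shared frailty b ~ Normal(0, var_pair) is drawn once; the case slot
#' repeatedly draws Hardy-Weinberg genotypes, computes the disease
#' probability pi = logistic(eta) under the realized truth, and accepts the
#' draw as the case with probability pi; each control slot accepts with
#' probability 1 - pi.  This conditions correctly on case/control status
#' given the shared frailty.  Seeded by \code{scenario$seed + 1} (the truth
#' draw uses \code{scenario$seed}), so datasets are byte-reproducible.
#'
#' @param scenario a \code{"cgx_scenario"}.
#' @param truth a matching \code{"cgx_sim_truth"}; drawn from the scenario
#'   when omitted.
#' @param max_attempts rejection-sampling cap per slot before the generator
#'   aborts advising an intercept adjustment.
#' @return A \code{\link{study_data}} object that passes
#'   \code{\link{validate_sets}}.
#' @export
simulate_matched_study <- function(scenario, truth = draw_true_params(scenario),
                                   max_attempts = 1e5) {
  stopifnot(inherits(scenario, "cgx_scenario"),
            inherits(truth, "cgx_sim_truth"))
  m <- scenario$manifest
  G <- nrow(m); C <- scenario$n_categories
  pair_idx <- lapply(scenario$interaction_pairs,
                     function(p) match(p, m$snp_id))
  set.seed(scenario$seed + 1L)
  cat_labels <- as.character(utils::as.roman(seq_len(C)))

  draw_slot <- function(cat, b, want_case) {
    for (attempt in seq_len(max_attempts)) {
      n_alt <- stats::rbinom(G, 2L, scenario$alt_freq)
      code <- vapply(seq_len(G), function(g) code_from_nalt(n_alt[g], m$coding[g]),
                     0L)
      eta <- scenario$true_intercept + sum(truth$beta[, cat] * code) +
        truth$a[cat] + b
      for (k in seq_along(pair_idx))
        eta <- eta + scenario$true_gamma[k] *
          code[pair_idx[[k]][1L]] * code[pair_idx[[k]][2L]]
      pi <- stats::plogis(eta)
      p_accept <- if (want_case) pi else 1 - pi
      if (stats::runif(1L) < p_accept) return(n_alt)
    }
    stop("rejection sampling stalled after ", max_attempts, " attempts ",
         "(disease probability numerically ", if (want_case) 0 else 1,
         "); adjust true_intercept or effect sizes")
  }

  rows <- vector("list", C * scenario$sets_per_category *
                   (1L + scenario$controls_per_case))
  r <- 0L
  for (cat in seq_len(C)) {
    for (k in seq_len(scenario$sets_per_category)) {
      set_id <- sprintf("%s_set%03d", cat_labels[cat], k)
      b <- stats::rnorm(1L, 0, sqrt(scenario$var_pair))
      statuses <- c(1L, rep(0L, scenario$controls_per_case))
      for (s in seq_along(statuses)) {
        n_alt <- draw_slot(cat, b, statuses[s] == 1L)
        r <- r + 1L
        row <- list(subject_id = sprintf("%s_m%d", set_id, s),
                    set_id = set_id, category = cat_labels[cat],
                    status = statuses[s])
        for (g in seq_len(G))
          row[[m$snp_id[g]]] <- genotype_string(n_alt[g], m$ref[g], m$alt[g])
        rows[[r]] <- row
      }
    }
  }
  subjects <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  study_data(subjects, m)
}

#' Parameter-recovery experiment over replicated simulations
#'
#' For each replicate the scenario is re-seeded (seed + replicate index), a
#' study is simulated, and the requested models are fitted.  Posterior
#' means, medians and equal-tailed intervals of every tau2[g] and beta[g,c]
#' are recorded against the realized truth, and bias, RMSE and interval
#' coverage are summarized per model.
#'
#' @param scenario a \code{"cgx_scenario"}.
#' @param n_reps number of replicates (0 gives empty tables).
#' @param cfg a \code{\link{chain_config}}; its seed is offset per replicate.
#' @param models character vector among \code{"unconditional"},
#'   \code{"bclr"}.
#' @param priors a \code{\link{prior_spec}}.
#' @return List of class \code{"cgx_recovery"} with \code{records} (one row
#'   per replicate x model x parameter) and \code{summary} (bias, RMSE,
#'   coverage per model and parameter kind).
#' @export
recovery_experiment <- function(scenario, n_reps, cfg = fast_chain_config(),
                                models = c("unconditional", "bclr"),
                                priors = prior_spec()) {
  stopifnot(inherits(scenario, "cgx_scenario"))
  models <- match.arg(models, several.ok = TRUE)
  empty <- data.frame(replicate = integer(), model = character(),
                      parameter = character(), truth = numeric(),
                      post_mean = numeric(), post_median = numeric(),
                      lower = numeric(), upper = numeric(),
                      stringsAsFactors = FALSE)
  records <- list()
  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- scenario$seed + r
    truth <- draw_true_params(sc)
    data <- simulate_matched_study(sc, truth)
    spec <- model_spec(sc$manifest, interaction_pairs = sc$interaction_pairs,
                       ge_interaction = TRUE)
    for (mod in models) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r
      trace <- run_chain(mod, data, spec, priors, cfg_r)
      d <- trace$draws
      G <- nrow(sc$manifest); C <- sc$n_categories
      par <- c(sprintf("tau2[%d]", seq_len(G)),
               as.vector(t(outer(seq_len(G), seq_len(C),
                                 function(g, c) sprintf("beta[%d,%d]", g, c)))))
      tru <- c(sc$true_tau2, as.vector(t(truth$beta)))
      records[[length(records) + 1L]] <- data.frame(
        replicate = r, model = mod, parameter = par, truth = tru,
        post_mean = colMeans(d[, par, drop = FALSE]),
        post_median = apply(d[, par, drop = FALSE], 2L, stats::median),
        lower = apply(d[, par, drop = FALSE], 2L, stats::quantile,
                      probs = 0.025, names = FALSE),
        upper = apply(d[, par, drop = FALSE], 2L, stats::quantile,
                      probs = 0.975, names = FALSE),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records)) do.call(rbind, records) else empty
  summary <- if (nrow(records)) {
    records$kind <- ifelse(grepl("^tau2", records$parameter), "tau2", "beta")
    agg <- do.call(rbind, lapply(split(records, records[c("model", "kind")]),
                                 function(s) data.frame(
      model = s$model[1L], kind = s$kind[1L],
      bias = mean(s$post_mean - s$truth),
      rmse = sqrt(mean((s$post_mean - s$truth)^2)),
      coverage = mean(s$truth >= s$lower & s$truth <= s$upper),
      stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    agg
  } else data.frame(model = character(), kind = character(), bias = numeric(),
                    rmse = numeric(), coverage = numeric(),
                    stringsAsFactors = FALSE)
  structure(list(records = records, summary = summary),
            class = "cgx_recovery")
}

#' Read / write a simulation scenario as YAML
#'
#' The YAML mirrors \code{\link{sim_scenario}}: a \code{snps} block (one
#' entry per SNP with \code{alleles}, \code{coding}, \code{alt_freq},
#' \code{true_mu}, \code{true_tau2}) plus the scalar fields and optional
#' \code{interaction_pairs} with \code{true_gamma}.
#'
#' @param path YAML file.
#' @return \code{read_sim_scenario}: a \code{"cgx_scenario"}.
#' @export
read_sim_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  snps <- y$snps
  manifest <- snp_manifest(
    snp_id = names(snps),
    ref = vapply(snps, function(s) as.character(s$alleles[[1]]), ""),
    alt = vapply(snps, function(s) as.character(s$alleles[[2]]), ""),
    coding = vapply(snps, function(s) as.character(s$coding), ""))
  pairs <- if (is.null(y$interaction_pairs)) list()
           else lapply(y$interaction_pairs, unlist)
  sim_scenario(
    manifest = manifest,
    alt_freq = vapply(snps, function(s) as.numeric(s$alt_freq), 0),
    n_categories = y$n_categories %||% 4L,
    sets_per_category = y$sets_per_category %||% 100L,
    controls_per_case = y$controls_per_case %||% 1L,
    true_mu = vapply(snps, function(s) as.numeric(s$true_mu %||% 0), 0),
    true_tau2 = vapply(snps, function(s) as.numeric(s$true_tau2 %||% 0), 0),
    true_gamma = as.numeric(y$true_gamma %||% rep(0, length(pairs))),
    interaction_pairs = pairs,
    true_intercept = y$true_intercept %||% 0,
    var_area = y$var_area %||% 0.5, var_pair = y$var_pair %||% 0.25,
    seed = y$seed %||% 1L)
}

#' @rdname read_sim_scenario
#' @param scenario a \code{"cgx_scenario"}.
#' @return \code{write_sim_scenario}: \code{path}, invisibly.
#' @export
write_sim_scenario <- function(scenario, path) {
  m <- scenario$manifest
  snps <- lapply(seq_len(nrow(m)), function(g)
    list(alleles = c(m$ref[g], m$alt[g]), coding = m$coding[g],
         alt_freq = scenario$alt_freq[g], true_mu = scenario$true_mu[g],
         true_tau2 = scenario$true_tau2[g]))
  names(snps) <- m$snp_id
  yaml::write_yaml(list(
    snps = snps,
    n_categories = scenario$n_categories,
    sets_per_category = scenario$sets_per_category,
    controls_per_case = scenario$controls_per_case,
    interaction_pairs = lapply(scenario$interaction_pairs, as.list),
    true_gamma = scenario$true_gamma,
    true_intercept = scenario$true_intercept,
    var_area = scenario$var_area, var_pair = scenario$var_pair,
    seed = scenario$seed), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
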