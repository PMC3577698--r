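# Small studies and manifests built in code for the unit tests.

toy_manifest <- function(G = 1L, coding = "additive") {
  snp_manifest(snp_id = sprintf("snp%d", seq_len(G)),
               ref = rep("A", G), alt = rep("B", G),
               coding = rep(coding, length.out = G))
}

# genotype string from a coded alt-allele count (biallelic A/B)
gt <- function(n_alt) c("A/A", "A/B", "B/B")[n_alt + 1L]

# Build a 1:1 matched study from explicit per-set genotype codes.
# codes: list of lists; codes[[p]] is a list(case = c(...), control = c(...))
# with one alt-allele count per SNP; categories: category label per set.
toy_study <- function(codes, categories, manifest) {
  rows <- list()
  for (p in seq_along(codes)) {
    members <- codes[[p]]
    statuses <- c(1L, rep(0L, length(members) - 1L))
    for (j in seq_along(members)) {
      row <- list(subject_id = sprintf("s%d_%d", p, j),
                  set_id = sprintf("set%d", p),
                  category = categories[p], status = statuses[j])
      for (g in seq_len(nrow(manifest)))
        row[[manifest$snp_id[g]]] <- gt(members[[j]][g])
      rows[[length(rows) + 1L]] <- row
    }
  }
  subjects <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  study_data(subjects, manifest)
}

# deterministic 3-category, 6-subject toy used by likelihood oracles
six_subject_study <- function() {
  m <- toy_manifest(2L)
  toy_study(codes = list(list(c(1L, 0L), c(0L, 1L)),
                         list(c(2L, 2L), c(0L, 0L)),
                         list(c(1L, 1L), c(1L, 1L))),
            categories = c("I", "II", "II"), manifest = m)
}

# a small simulated two-SNP study for sampler-level tests
small_sim_study <- function(seed = 11L, sets = 20L, cats = 2L) {
  m <- toy_manifest(2L)
  sc <- sim_scenario(m, alt_freq = c(0.3, 0.4), n_categories = cats,
                     sets_per_category = sets, true_mu = c(0.4, 0),
                     true_tau2 = c(0.5, 0), seed = seed)
  simulate_matched_study(sc)
}

# an arbitrary but fixed non-trivial parameter state for a study/spec
nontrivial_state <- function(data, spec, seed = 42L) {
  set.seed(seed)
  st <- init_state(data, spec)
  st$alpha <- rnorm(1L)
  st$beta[] <- rnorm(length(st$beta))
  st$mu[] <- rnorm(length(st$mu))
  st$tau2[] <- rexp(length(st$tau2)) + 0.1
  if (length(st$gamma)) st$gamma <- rnorm(length(st$gamma))
  if (length(st$delta)) st$delta[] <- rnorm(length(st$delta))
  st$a <- rnorm(length(st$a))
  st$b <- rnorm(length(st$b))
  st$var_area <- rexp(1L) + 0.1
  st$var_pair <- rexp(1L) + 0.1
  st
}
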