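# harmonized set taken straight from a simulated dataset: the instrument
# variants share one allele frame by construction, so no harmonization step
# is needed inside simulation loops
sim_hset <- function(sim, mediator = FALSE) {
  J <- sim$config$J
  idx <- seq_len(J)
  h <- tibble::tibble(
    rsid = sim$exposure$rsid[idx],
    effect_allele = sim$exposure$effect_allele[idx],
    other_allele = sim$exposure$other_allele[idx],
    beta_exp = sim$exposure$beta[idx],
    se_exp = sim$exposure$se[idx],
    eaf_exp = sim$exposure$eaf[idx],
    beta_out = sim$outcome$beta[idx],
    se_out = sim$outcome$se[idx],
    flipped = FALSE
  )
  if (mediator) {
    h$beta_med <- sim$mediator$beta[idx]
    h$se_med <- sim$mediator$se[idx]
  }
  h
}

# generator configuration without the candidate-trait machinery, for
# estimator-level simulation loops where only the instrument variants matter
lean_config <- function(...) {
  sim_config(
    n_decoy_traits = 0, n_weak_traits = 0, n_null_candidate_traits = 0,
    n_duplicate_traits = 0, trait_instruments = 2, ...
  )
}

# small random harmonized set for oracle-equivalence tests
rand_hset <- function(J, seed, theta = 0.3) {
  withr::with_seed(seed, {
    g <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
    sG <- runif(J, 0.05, 0.2)
    tibble::tibble(
      rsid = sprintf("s%03d", seq_len(J)),
      beta_exp = g,
      se_exp = runif(J, 0.01, 0.05),
      beta_out = theta * g + rnorm(J) * sG,
      se_out = sG
    )
  })
}
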