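# crafted trait table whose trait-level IVW p-values are exact by
# construction: 4 instruments with effect 1, outcome beta z_k, outcome SE 2
# -> IVW slope z_k, SE 1, zero residuals
crafted_traits <- function(z_by_trait, outlier = "o1") {
  tt <- list()
  oc <- list()
  for (k in seq_along(z_by_trait)) {
    id <- names(z_by_trait)[k]
    snps <- sprintf("%s_i%d", id, 1:4)
    tt[[length(tt) + 1]] <- tibble::tibble(
      trait_id = id, trait_label = id, rsid = snps,
      beta = 1, se = 0.01, pval = 1e-20
    )
    tt[[length(tt) + 1]] <- tibble::tibble(
      trait_id = id, trait_label = id, rsid = outlier,
      beta = 1, se = 0.05, pval = 1e-20
    )
    oc[[length(oc) + 1]] <- tibble::tibble(
      rsid = snps, beta = z_by_trait[[k]], se = 2
    )
  }
  list(
    table = purrr::list_rbind(tt),
    outcome = purrr::list_rbind(oc)
  )
}

test_that("candidate scan keeps only outlier-linked genome-wide hits", {
  tt <- tibble::tibble(
    trait_id = c("a", "b", "c"),
    trait_label = c("a", "b", "c"),
    rsid = c("o1", "o1", "x9"),
    beta = 1, se = 0.1,
    pval = c(1e-9, 1e-7, 1e-12)
  )
  cand <- scan_candidates(tt, outliers = "o1")
  expect_identical(cand$trait_id, "a") # b sub-threshold, c not on an outlier
  expect_identical(cand$outlier_rsids[[1]], "o1")

  expect_warning(
    empty <- scan_candidates(tt[0, ], outliers = "o1"),
    "empty trait table"
  )
  expect_equal(nrow(empty), 0)
  expect_error(scan_candidates(tt, character(0)),
    class = "mrdissect_config_error"
  )
})

test_that("FDR filtering reproduces step-up Benjamini-Hochberg", {
  p_target <- c(t1 = 0.01, t2 = 0.02, t3 = 0.03, t4 = 0.5)
  z <- qnorm(1 - p_target / 2)
  cr <- crafted_traits(as.list(z))
  cand <- scan_candidates(cr$table, "o1")
  kept <- filter_traits(cand, cr$table, cr$outcome, "o1", fdr_alpha = 0.05)
  expect_equal(kept$pval[order(kept$trait_id)],
    unname(p_target[sort(kept$trait_id)]),
    tolerance = 1e-10
  )
  oracle_keep <- bh_keep_oracle(unname(p_target), 0.05)
  expect_setequal(kept$trait_id, names(p_target)[oracle_keep])
  expect_setequal(kept$trait_id, c("t1", "t2", "t3"))
  expect_true(all(kept$fdr_q >= kept$pval))
})

test_that("blocklisted traits are removed regardless of q", {
  cr <- crafted_traits(list(metformin_use = 8, keepme = 8))
  cand <- scan_candidates(cr$table, "o1")
  kept <- filter_traits(cand, cr$table, cr$outcome, "o1",
    blocklist = "metformin"
  )
  expect_identical(kept$trait_id, "keepme")
  ex <- attr(kept, "excluded")
  expect_identical(ex$reason[ex$trait_id == "metformin_use"], "blocklist match")
})

test_that("duplicate traits collapse to the better-instrumented one", {
  snps <- sprintf("s%02d", 1:10)
  v <- seq(0.1, 1, by = 0.1)
  tt <- dplyr::bind_rows(
    tibble::tibble(
      trait_id = "big", trait_label = "big", rsid = snps,
      beta = v, se = 0.01, pval = 1e-20
    ),
    tibble::tibble(
      trait_id = "small", trait_label = "small", rsid = snps[1:8],
      beta = v[1:8], se = 0.01, pval = 1e-20
    ),
    tibble::tibble(
      trait_id = c("big", "small"), trait_label = c("big", "small"),
      rsid = "o1", beta = 1, se = 0.05, pval = 1e-20
    )
  )
  outcome <- tibble::tibble(rsid = snps, beta = 0.5 * v, se = 0.01)
  cand <- scan_candidates(tt, "o1")
  kept <- filter_traits(cand, tt, outcome, "o1")
  expect_identical(kept$trait_id, "big")
  ex <- attr(kept, "excluded")
  expect_match(ex$reason[ex$trait_id == "small"], "duplicate of big")
})

test_that("traits with too few usable instruments are excluded with reason", {
  tt <- tibble::tibble(
    trait_id = "lone", trait_label = "lone",
    rsid = c("s1", "o1"), beta = 1, se = 0.01, pval = 1e-20
  )
  outcome <- tibble::tibble(rsid = "s1", beta = 0.5, se = 0.01)
  cand <- scan_candidates(tt, "o1")
  kept <- filter_traits(cand, tt, outcome, "o1")
  expect_equal(nrow(kept), 0)
  expect_match(attr(kept, "excluded")$reason, "fewer than 2")
})

test_that("unpenalized single-trait LASSO equals the weighted slope", {
  withr::with_seed(12, {
    snps <- sprintf("s%02d", 1:20)
    x <- runif(20, 0.05, 0.3)
    tt <- tibble::tibble(
      trait_id = "t1", trait_label = "t1", rsid = snps,
      beta = x, se = 0.01, pval = 1e-20
    )
    outcome <- tibble::tibble(
      rsid = snps, beta = 0.4 * x + rnorm(20) * 0.02, se = 0.02
    )
    traits <- tibble::tibble(trait_id = "t1", trait_label = "t1")
    sel <- lasso_prune(traits, tt, outcome, lambda = 0)
    oracle <- stats::lm(outcome$beta ~ 0 + x, weights = 1 / outcome$se^2)
    expect_equal(sel$b, unname(coef(oracle)[1]), tolerance = 1e-10)
  })
})

test_that("an infinite penalty shrinks every coefficient to zero", {
  cr <- crafted_traits(list(t1 = 8, t2 = 6))
  traits <- tibble::tibble(
    trait_id = c("t1", "t2"), trait_label = c("t1", "t2")
  )
  expect_warning(
    sel <- lasso_prune(traits, cr$table, cr$outcome, lambda = Inf),
    "infinite penalty"
  )
  expect_equal(nrow(sel), 0)
})

test_that("the LASSO recovers the active/null pattern on orthogonal traits", {
  one_sim <- function(seed) {
    withr::with_seed(seed, {
      snps1 <- sprintf("a%03d", 1:50)
      snps2 <- sprintf("b%03d", 1:50)
      x1 <- runif(50, 0.05, 0.15) * sample(c(-1, 1), 50, replace = TRUE)
      x2 <- runif(50, 0.05, 0.15) * sample(c(-1, 1), 50, replace = TRUE)
      tt <- dplyr::bind_rows(
        tibble::tibble(
          trait_id = "active", trait_label = "active", rsid = snps1,
          beta = x1, se = 0.005, pval = 1e-20
        ),
        tibble::tibble(
          trait_id = "null", trait_label = "null", rsid = snps2,
          beta = x2, se = 0.005, pval = 1e-20
        )
      )
      outcome <- tibble::tibble(
        rsid = c(snps1, snps2),
        beta = c(0.3 * x1, 0 * x2) + rnorm(100) * 0.02, se = 0.02
      )
      traits <- tibble::tibble(
        trait_id = c("active", "null"), trait_label = c("active", "null"),
        fdr_q = c(0.01, 0.04)
      )
      # the one-standard-error rule is the standard parsimony choice for
      # support recovery; lambda_min targets prediction, not selection
      sel <- suppressWarnings(
        lasso_prune(traits, tt, outcome, lambda = "cv_1se", seed = seed)
      )
      identical(sel$trait_id, "active")
    })
  }
  hits <- vapply(1:100, one_sim, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("outcome adjustment subtracts the trait terms additively", {
  h <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    beta_exp = 0.1, se_exp = 0.01,
    beta_out = c(0.02, 0.30, 0.05), se_out = 0.02
  )
  tt <- tibble::tibble(
    trait_id = c("t1", "t2"), trait_label = c("t1", "t2"),
    rsid = "rs2", beta = c(0.5, 0.8), se = 0.01, pval = 1e-20
  )
  sel <- tibble::tibble(trait_id = "t1", b = 0.2, se = 0.01)
  adj <- adjust_outcome(h, "rs2", sel, tt)
  expect_equal(adj$beta_out, c(0.02, 0.30 - 0.1, 0.05))
  expect_equal(adj$se_out, h$se_out) # default sigma policy: unchanged

  # two traits: the subtracted sum is order-independent
  sel2 <- tibble::tibble(trait_id = c("t1", "t2"), b = c(0.2, 0.1), se = 0.01)
  a1 <- adjust_outcome(h, "rs2", sel2, tt)
  a2 <- adjust_outcome(h, "rs2", sel2[2:1, ], tt)
  expect_equal(a1$beta_out, a2$beta_out)
  expect_equal(a1$beta_out[2], 0.30 - 0.2 * 0.5 - 0.1 * 0.8)

  # propagate policy inflates the SE in quadrature
  a3 <- adjust_outcome(h, "rs2", sel, tt, sigma_policy = "propagate")
  expect_equal(a3$se_out[2], sqrt(0.02^2 + 0.5^2 * 0.01^2))

  # no selected traits: identity
  a4 <- adjust_outcome(h, "rs2", sel[0, ], tt)
  expect_equal(a4$beta_out, h$beta_out)

  # a triggering variant with no usable association is skipped with warning
  sel5 <- tibble::tibble(
    trait_id = "t1", b = 0.2, se = 0.01,
    outlier_rsids = list(c("rs2", "rs9"))
  )
  expect_warning(adjust_outcome(h, c("rs2", "rs9"), sel5, tt), "rs9")
})

test_that("re-estimation is the identity when nothing was adjusted", {
  h <- rand_hset(20, 61)
  re <- reestimate(h, h, outliers = character(0))
  expect_identical(re$adjusted$b, re$original$b)
  expect_identical(re$adjusted$se, re$original$se)
  expect_equal(re$het_reduction_ivw, 0)
})

test_that("the leave-out variant hits the insufficient-instruments wall when
           almost all variants are outliers", {
  h <- rand_hset(3, 62)
  expect_error(
    reestimate(h, h, outliers = h$rsid[1:2]),
    class = "mrdissect_insufficient_instruments"
  )
})

test_that("the full dissection stage prunes decoys and adjusts outliers", {
  sim <- simulate_gwas(sim_config(seed = 314))
  h <- sim_hset(sim)
  out <- detect_outliers(radial_fit(h))
  expect_true(all(sim$truth$outliers %in% out))
  tx <- suppressWarnings(suppressMessages(
    run_tryx(h, sim$trait_table, sim$outcome, out, seed = 314)
  ))
  f <- tx$funnel
  expect_true(all(diff(f[c(
    "traits_scanned", "candidates", "post_fdr_curation", "lasso_prioritized"
  )]) <= 0))
  real <- sim$truth$trait_roster$trait_id[sim$truth$trait_roster$type == "real"]
  expect_true(all(tx$selected$trait_id %in% real))
  expect_gt(tx$reestimate$het_reduction_ivw, 0)
  # only outlier variants were touched
  changed <- h$beta_out != tx$hset_adjusted$beta_out
  expect_true(all(h$rsid[changed] %in% out))
})
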