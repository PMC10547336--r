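test_that("Wald ratio arithmetic and both SE orders are exact", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(w$b, 0.5)
  expect_equal(w$se, 0.2)

  w2 <- wald_ratio(0.1, 0.01, 0.05, 0.02, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.04 + 0.0025)) # 0.2061553...

  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$b, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02),
    class = "mrdissect_validation_error"
  )
})

test_that("IVW handles degenerate and symmetric two-point cases", {
  h <- tibble::tibble(
    beta_exp = c(0.1, 0.2), se_exp = 0.01,
    beta_out = c(0.05, 0.10), se_out = c(0.02, 0.03)
  )
  f <- mr_ivw(h)
  expect_equal(f$b, 0.5)
  expect_equal(f$Q, 0)
  expect_equal(f$phi, 1)

  h2 <- tibble::tibble(
    beta_exp = c(1, 1), se_exp = 0.01, beta_out = c(0, 1), se_out = 1
  )
  f2 <- mr_ivw(h2)
  expect_equal(f2$b, 0.5)
  expect_equal(f2$Q, 0.5)

  expect_error(mr_ivw(h2[1, ]), class = "mrdissect_insufficient_instruments")
})

test_that("IVW matches the weighted-least-squares oracle", {
  for (seed in 1:5) {
    h <- rand_hset(20, seed)
    f <- mr_ivw(h, floor_phi = FALSE)
    o <- ivw_oracle(h)
    expect_equal(f$b, o$b, tolerance = 1e-10)
    # lm's residual variance is exactly the unfloored overdispersion
    expect_equal(f$se, o$se, tolerance = 1e-10)
  }
})

test_that("fixed and multiplicative-random IVW share the point estimate", {
  for (seed in 6:10) {
    h <- rand_hset(15, seed)
    fe <- mr_ivw(h, mode = "fixed")
    re <- mr_ivw(h)
    expect_identical(fe$b, re$b)
    expect_gte(re$se, fe$se) # floored phi never shrinks the SE
  }
})

test_that("Egger recovers exact affine data and matches its oracle", {
  g <- seq(0.05, 0.5, length.out = 10)
  h <- tibble::tibble(
    beta_exp = g, se_exp = 0.01, beta_out = 0.1 + 0.3 * g, se_out = 0.02
  )
  f <- mr_egger(h)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  expect_equal(f$b, 0.3, tolerance = 1e-12)
  expect_equal(f$Q, 0, tolerance = 1e-18)

  for (seed in 1:5) {
    h <- rand_hset(20, seed + 100)
    f <- mr_egger(h, floor_phi = FALSE)
    o <- egger_oracle(h)
    expect_equal(f$b, o$b, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$se, o$se, tolerance = 1e-10)
    expect_equal(f$intercept_se, o$intercept_se, tolerance = 1e-10)
  }
})

test_that("Egger is invariant to joint variant-level sign flips", {
  h <- rand_hset(20, 42)
  flip <- withr::with_seed(43, sample(c(-1, 1), 20, replace = TRUE))
  h2 <- h
  h2$beta_exp <- h$beta_exp * flip
  h2$beta_out <- h$beta_out * flip
  f1 <- mr_egger(h)
  f2 <- mr_egger(h2)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight correctly", {
  # equal weights, symmetric ratios
  h <- tibble::tibble(
    beta_exp = c(1, 1, 1), se_exp = 0.01,
    beta_out = c(0.1, 0.2, 0.3), se_out = 1
  )
  expect_equal(mr_weighted_median(h, n_boot = 10)$b, 0.2)

  # unequal weights: independent hand evaluation of the interpolation.
  # raw weights (0.1, 0.2, 0.3, 0.4) and ratios (0.1, 0.2, 0.4, 0.8):
  # centred cumulative weights s = (0.05, 0.20, 0.45, 0.80); 0.5 falls
  # between s3 and s4: 0.4 + (0.5-0.45)/(0.80-0.45) * (0.8-0.4)
  w_raw <- c(0.1, 0.2, 0.3, 0.4)
  r <- c(0.1, 0.2, 0.4, 0.8)
  h2 <- tibble::tibble(
    beta_exp = sqrt(w_raw), se_exp = 1e-6,
    beta_out = r * sqrt(w_raw), se_out = 1
  )
  expect_equal(
    mr_weighted_median(h2, n_boot = 10)$b,
    0.4 + (0.5 - 0.45) / (0.80 - 0.45) * (0.8 - 0.4)
  )
})

test_that("the weighted median resists a wild outlier ratio", {
  h <- tibble::tibble(
    beta_exp = rep(0.1, 10), se_exp = 0.001,
    beta_out = c(rep(0.1, 9) * seq(0.95, 1.05, length.out = 9), 5) * 0.1,
    se_out = 0.02
  )
  f <- mr_weighted_median(h, n_boot = 50)
  expect_gte(f$b, 0.09)
  expect_lte(f$b, 0.11)
})

test_that("weighted-median bootstrap is reproducible under a fixed seed", {
  h <- rand_hset(15, 7)
  f1 <- mr_weighted_median(h, n_boot = 200, seed = 1)
  f2 <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_identical(f1$se, f2$se)
})

test_that("estimators are equivariant under exposure rescaling", {
  h <- rand_hset(20, 55)
  c_scale <- 3.7
  h2 <- h
  h2$beta_exp <- h$beta_exp * c_scale
  h2$se_exp <- h$se_exp * c_scale
  expect_equal(mr_ivw(h2)$b, mr_ivw(h)$b / c_scale, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$b, mr_egger(h)$b / c_scale, tolerance = 1e-12)
  expect_equal(
    mr_weighted_median(h2, n_boot = 10)$b,
    mr_weighted_median(h, n_boot = 10)$b / c_scale,
    tolerance = 1e-12
  )
})

test_that("Cochran's Q is zero for proportional data and exact otherwise", {
  h <- tibble::tibble(
    beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
    beta_out = c(0.05, 0.10, 0.15), se_out = 0.02
  )
  q <- cochran_q(h, 0.5)
  expect_equal(q$Q, 0)
  expect_equal(q$pval, 1)

  h2 <- tibble::tibble(
    beta_exp = c(1, 1), se_exp = 0.01, beta_out = c(0, 1), se_out = 1
  )
  expect_equal(cochran_q(h2, mr_ivw(h2)$b)$Q, 0.5)
})

test_that("Q follows its chi-square law under the null model", {
  J <- 10
  qdf <- withr::with_seed(99, {
    vapply(seq_len(1000), function(i) {
      g <- runif(J, 0.05, 0.3)
      sG <- runif(J, 0.05, 0.15)
      h <- tibble::tibble(
        beta_exp = g, se_exp = 1e-8,
        beta_out = 0.2 * g + rnorm(J) * sG, se_out = sG
      )
      cochran_q(h, mr_ivw(h)$b)$Q / (J - 1)
    }, numeric(1))
  })
  mc_se <- sd(qdf) / sqrt(length(qdf))
  expect_lt(abs(mean(qdf) - 1), 3 * mc_se)
})

test_that("tidy and glance return the documented one-row summaries", {
  h <- rand_hset(20, 3)
  f <- mr_egger(h)
  t <- tidy(f)
  expect_equal(nrow(t), 1)
  expect_equal(t$or, exp(t$b))
  g <- glance(f)
  expect_equal(g$Q_df, 18)
  panel <- mr_all(h, n_boot = 20)
  expect_identical(panel$method, c("ivw_mre", "egger", "weighted_median"))
  expect_true(all(panel$ci_low <= panel$b & panel$b <= panel$ci_high))
})
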