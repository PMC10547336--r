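new_mr_result <- function(method, nsnp, b, se, Q = NA_real_, Q_df = NA_real_,
                          phi = NA_real_, intercept = NA_real_,
                          intercept_se = NA_real_, mode = NA_character_,
                          exposure = "exp") {
  structure(
    list(
      method = method, nsnp = nsnp, b = b, se = se,
      ci_low = b - Z95 * se, ci_high = b + Z95 * se,
      pval = p_from_z(b, se),
      Q = Q, Q_df = Q_df,
      Q_pval = if (is.na(Q)) NA_real_ else pchisq(Q, Q_df, lower.tail = FALSE),
      phi = phi,
      intercept = intercept, intercept_se = intercept_se,
      intercept_pval = if (is.na(intercept)) NA_real_ else {
        p_from_z(intercept, intercept_se)
      },
      mode = mode, exposure = exposure
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "MR estimate (%s), %d SNP(s)\n  b = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$nsnp, x$b, x$se, exp(x$b), exp(x$ci_low), exp(x$ci_high),
    x$pval
  ))
  if (!is.na(x$Q)) {
    cat(sprintf(
      "  Q = %.2f on %d df (p = %.3g), phi = %.3f\n",
      x$Q, x$Q_df, x$Q_pval, x$phi
    ))
  }
  if (!is.na(x$intercept)) {
    cat(sprintf(
      "  intercept = %.4f (SE %.4f), p = %.3g\n",
      x$intercept, x$intercept_se, x$intercept_pval
    ))
  }
  invisible(x)
}

#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, nsnp = x$nsnp, b = x$b, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    or = exp(x$b), or_ci_low = exp(x$ci_low), or_ci_high = exp(x$ci_high)
  )
}

#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, nsnp = x$nsnp, Q = x$Q, Q_df = x$Q_df,
    Q_pval = x$Q_pval, phi = x$phi, intercept = x$intercept,
    intercept_se = x$intercept_se, intercept_pval = x$intercept_pval
  )
}

check_hset <- function(hset, min_snps, caller, zero_se_exp_ok = FALSE) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(hset))) {
    abort(paste0(caller, ": input must carry columns ",
      paste(need, collapse = ", ")), class = "mrdissect_config_error")
  }
  if (nrow(hset) < min_snps) {
    abort(paste0(
      caller, ": at least ", min_snps, " instruments required, got ",
      nrow(hset)
    ), class = "mrdissect_insufficient_instruments")
  }
  se_exp_bad <- if (zero_se_exp_ok) {
    any(hset$se_exp < 0)
  } else {
    any(hset$se_exp <= 0)
  }
  if (any(hset$se_out <= 0) || se_exp_bad) {
    abort(paste0(caller, ": standard errors must be positive"),
      class = "mrdissect_validation_error"
    )
  }
  invisible(hset)
}

#' Wald ratio estimate for a single variant
#'
#' The per-variant causal estimate `Gamma / gamma` with, by default, the
#' first-order delta-method standard error `se_Gamma / |gamma|`. The
#' second-order option adds the contribution of sampling noise in the
#' variant-exposure association:
#' `se^2 = se_Gamma^2 / gamma^2 + Gamma^2 se_gamma^2 / gamma^4`.
#'
#' @param gamma,se_gamma variant-exposure effect and its standard error.
#' @param Gamma,se_Gamma variant-outcome effect and its standard error.
#' @param second_order use the second-order standard error (default FALSE).
#' @return an `mr_result` object.
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.02)
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       second_order = FALSE) {
  stopifnot(length(gamma) == 1, se_gamma > 0, se_Gamma > 0)
  if (gamma == 0) {
    abort("wald_ratio: undefined for gamma = 0",
      class = "mrdissect_validation_error"
    )
  }
  b <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  new_mr_result("wald", 1L, b, se)
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of the variant-outcome effects on the
#' variant-exposure effects through the origin, with weights `1/se_out^2` —
#' the meta-analysis of Wald ratios. Under
#' `mode = "multiplicative_random"` (the default, and the primary analysis
#' model) the fixed-effect standard error is inflated by
#' `sqrt(phi)` with `phi = max(1, Q/(J-1))`, so balanced heterogeneity
#' widens the interval but can never shrink it below the fixed-effect one.
#'
#' @param hset harmonized set ([harmonize()]) or any tibble with columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param mode `"multiplicative_random"` (alias `"random"`) or `"fixed"`.
#' @param floor_phi floor the overdispersion at 1 (default TRUE). The
#'   unfloored variant lets `phi < 1` deflate the standard error.
#' @return an `mr_result` with Cochran's Q on `J - 1` degrees of freedom.
#' @examples
#' h <- tibble::tibble(
#'   beta_exp = c(1, 1), se_exp = c(0.1, 0.1),
#'   beta_out = c(0, 1), se_out = c(1, 1)
#' )
#' mr_ivw(h) # b = 0.5, Q = 0.5
#' @export
mr_ivw <- function(hset, mode = c("multiplicative_random", "random", "fixed"),
                   floor_phi = TRUE) {
  mode <- match.arg(mode)
  if (mode == "random") mode <- "multiplicative_random"
  check_hset(hset, 2L, "mr_ivw")
  g <- hset$beta_exp
  G <- hset$beta_out
  w <- 1 / hset$se_out^2
  b <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- 1 / sqrt(sum(w * g^2))
  J <- length(g)
  Q <- sum(w * (G - b * g)^2)
  phi <- Q / (J - 1)
  if (floor_phi) phi <- max(1, phi)
  se <- if (mode == "multiplicative_random") se_fixed * sqrt(phi) else se_fixed
  new_mr_result("ivw_mre", J, b, se,
    Q = Q, Q_df = J - 1,
    phi = if (mode == "multiplicative_random") phi else 1, mode = mode
  )
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome effects on variant-exposure
#' effects *with* an intercept, after orienting every variant so its
#' exposure effect is positive (variant-level joint sign flips leave the fit
#' invariant). The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Standard errors carry the multiplicative overdispersion
#' `phi = max(1, Q_egger/(J-2))`.
#'
#' @inheritParams mr_ivw
#' @return an `mr_result` with `intercept`, `intercept_se`,
#'   `intercept_pval`, and Q on `J - 2` degrees of freedom.
#' @export
mr_egger <- function(hset, floor_phi = TRUE) {
  check_hset(hset, 3L, "mr_egger")
  flip <- sign(hset$beta_exp)
  flip[flip == 0] <- 1
  g <- hset$beta_exp * flip
  G <- hset$beta_out * flip
  w <- 1 / hset$se_out^2
  J <- length(g)
  # weighted normal equations for (intercept, slope)
  sw <- sum(w)
  swx <- sum(w * g)
  swx2 <- sum(w * g^2)
  swy <- sum(w * G)
  swxy <- sum(w * g * G)
  det <- sw * swx2 - swx^2
  a <- (swx2 * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  Q <- sum(w * (G - a - b * g)^2)
  phi <- Q / (J - 2)
  if (floor_phi) phi <- max(1, phi)
  se_b <- sqrt(phi * sw / det)
  se_a <- sqrt(phi * swx2 / det)
  out <- new_mr_result("egger", J, b, se_b,
    Q = Q, Q_df = J - 2, phi = phi,
    intercept = a, intercept_se = se_a, mode = "multiplicative_random"
  )
  out
}

weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) {
    return(r[1])
  }
  if (0.5 >= s[length(s)]) {
    return(r[length(r)])
  }
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when at least half the weight comes from valid instruments.
#' Ratios are sorted, weights `gamma^2/se_out^2` normalized to sum one, and
#' the estimate is the linear interpolation of the ratio across the centred
#' cumulative weight at 0.5. The standard error comes from a parametric
#' bootstrap resampling each `(gamma, Gamma)` pair from its normal sampling
#' distribution.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap resamples for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap (default 1, for reproducibility).
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1) {
  check_hset(hset, 3L, "mr_weighted_median")
  g <- hset$beta_exp
  G <- hset$beta_out
  ratios <- G / g
  weights <- g^2 / hset$se_out^2
  b <- weighted_median_point(ratios, weights)
  J <- length(g)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      gb <- rnorm(J, g, hset$se_exp)
      Gb <- rnorm(J, G, hset$se_out)
      weighted_median_point(Gb / gb, gb^2 / hset$se_out^2)
    }, numeric(1))
  })
  new_mr_result("weighted_median", J, b, sd(boot))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((beta_out - b * beta_exp)^2 / se_out^2)` against a fixed slope
#' `b`, referred to the chi-square distribution on `J - 1` degrees of
#' freedom.
#'
#' @inheritParams mr_ivw
#' @param beta_hat the slope at which residuals are evaluated (typically the
#'   IVW estimate).
#' @return a list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(hset, beta_hat) {
  check_hset(hset, 2L, "cochran_q")
  Q <- sum((hset$beta_out - beta_hat * hset$beta_exp)^2 / hset$se_out^2)
  df <- nrow(hset) - 1
  list(Q = Q, df = df, pval = pchisq(Q, df, lower.tail = FALSE))
}

#' Run the full univariable estimator panel
#'
#' IVW with multiplicative random effects (the primary model), MR-Egger and
#' the weighted median on the same harmonized set, returned as one tidy
#' table mirroring a forest-plot layout.
#'
#' @inheritParams mr_weighted_median
#' @return a tibble with one row per method: `method`, `nsnp`, `b`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or`, `or_ci_low`, `or_ci_high`, `Q`,
#'   `Q_df`, `Q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`.
#' @export
mr_all <- function(hset, n_boot = 1000, seed = 1) {
  fits <- list(
    mr_ivw(hset),
    mr_egger(hset),
    mr_weighted_median(hset, n_boot = n_boot, seed = seed)
  )
  purrr::map_dfr(fits, function(f) {
    dplyr::bind_cols(
      tidy(f),
      tibble::tibble(
        Q = f$Q, Q_df = f$Q_df, Q_pval = f$Q_pval,
        egger_intercept = f$intercept,
        egger_intercept_se = f$intercept_se,
        egger_intercept_pval = f$intercept_pval
      )
    )
  })
}
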