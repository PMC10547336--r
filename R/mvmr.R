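#' Attach a co-exposure to a harmonized set
#'
#' Looks up a second exposure's (e.g. a putative mediator's) associations
#' for the variants already in the harmonized set and aligns them to the
#' set's effect-allele frame: swapped codings negate the beta, strand flips
#' are resolved, palindromic variants are oriented by EAF when possible and
#' set to missing otherwise. The instrument frame stays the primary
#' exposure's — no new variants are added.
#'
#' @param hset harmonized set from [harmonize()].
#' @param assocs canonical sumstats tibble for the co-exposure.
#' @param name short name for the co-exposure; creates columns
#'   `beta_<name>`, `se_<name>`.
#' @return the harmonized set with the two new columns (`NA` where the
#'   co-exposure lacks an alignable association).
#' @export
add_exposure <- function(hset, assocs, name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  assocs <- tibble::as_tibble(assocs)
  idx <- match(hset$rsid, assocs$rsid)
  beta <- se <- rep(NA_real_, nrow(hset))
  for (i in seq_len(nrow(hset))) {
    j <- idx[i]
    if (is.na(j)) next
    ea_x <- hset$effect_allele[i]
    oa_x <- hset$other_allele[i]
    ea_y <- assocs$effect_allele[j]
    oa_y <- assocs$other_allele[j]
    b <- assocs$beta[j]
    s <- assocs$se[j]
    if (is_palindromic(ea_x, oa_x)) {
      same <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
      if (!same) next
      ef_x <- hset$eaf_exp[i]
      ef_y <- if ("eaf" %in% names(assocs)) assocs$eaf[j] else NA_real_
      if (is.na(ef_x) || is.na(ef_y)) next
      if ((ef_x - 0.5) * (ef_y - 0.5) < 0) b <- -b
    } else if (ea_y == ea_x && oa_y == oa_x) {
      # aligned
    } else if (ea_y == oa_x && oa_y == ea_x) {
      b <- -b
    } else if (is_acgt(ea_y) && is_acgt(oa_y) &&
      complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x) {
      # strand flip, aligned
    } else if (is_acgt(ea_y) && is_acgt(oa_y) &&
      complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x) {
      b <- -b
    } else {
      next
    }
    beta[i] <- b
    se[i] <- s
  }
  hset[[paste0("beta_", name)]] <- beta
  hset[[paste0("se_", name)]] <- se
  hset
}

#' Multivariable MR fit
#'
#' Weighted multivariable regression of the variant-outcome effects on the
#' variant-exposure effect matrix, without intercept, with weights
#' `1/se_out^2`. Each coefficient is the direct effect of its exposure,
#' conditional on the others. Standard errors carry the multiplicative
#' overdispersion `phi = max(1, Q_mv/(J-K))`. With a single exposure the
#' fit reduces exactly to univariable IVW.
#'
#' @param hset harmonized set carrying `beta_out`, `se_out`, `beta_exp`
#'   and, for each co-exposure `x`, `beta_x` (see [add_exposure()]). Rows
#'   with a missing co-exposure effect are dropped.
#' @param exposures character vector of exposure names, `"exp"` being the
#'   primary one; defaults to every `beta_*` column present.
#' @param floor_phi floor the overdispersion at 1 (default TRUE).
#' @return an object of class `mvmr_result`; [tidy()] gives one row per
#'   exposure (`exposure`, `b`, `se`, `ci_low`, `ci_high`, `pval`, `or`,
#'   `or_ci_low`, `or_ci_high`), [glance()] the model-level `J`, `K`, `Q`,
#'   `phi`.
#' @export
mvmr_fit <- function(hset, exposures = NULL, floor_phi = TRUE) {
  if (is.null(exposures)) {
    cand <- grep("^beta_", names(hset), value = TRUE)
    exposures <- setdiff(sub("^beta_", "", cand), "out")
    exposures <- c(intersect("exp", exposures), setdiff(exposures, "exp"))
  }
  cols <- paste0("beta_", exposures)
  missing_cols <- setdiff(cols, names(hset))
  if (length(missing_cols)) {
    abort(paste0(
      "mvmr_fit: missing exposure column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "mrdissect_config_error")
  }
  X <- as.matrix(hset[, cols, drop = FALSE])
  colnames(X) <- exposures
  keep <- complete.cases(X) & !is.na(hset$beta_out)
  X <- X[keep, , drop = FALSE]
  y <- hset$beta_out[keep]
  w <- 1 / hset$se_out[keep]^2
  J <- nrow(X)
  K <- ncol(X)
  if (J < K + 1) {
    abort(paste0(
      "mvmr_fit: need at least K + 1 = ", K + 1, " variants, got ", J
    ), class = "mrdissect_insufficient_instruments")
  }
  Xw <- X * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < K) {
    cc <- suppressWarnings(cor(X))
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc), na.rm = TRUE), arr.ind = TRUE)[1, ]
    abort(paste0(
      "mvmr_fit: exposure-effect matrix is rank deficient; near-collinear ",
      "pair: ", exposures[worst[1]], ", ", exposures[worst[2]]
    ), class = "mrdissect_collinearity_error")
  }
  if (K == 1) {
    # same arithmetic as univariable IVW so the K = 1 reduction is exact
    x <- drop(X)
    b <- sum(w * x * y) / sum(w * x^2)
    se_fixed <- 1 / sqrt(sum(w * x^2))
    Q <- sum(w * (y - b * x)^2)
    phi <- Q / (J - 1)
    if (floor_phi) phi <- max(1, phi)
    se <- se_fixed * sqrt(phi)
  } else {
    XtX <- crossprod(Xw)
    b <- unname(drop(solve(XtX, crossprod(Xw, y * sqrt(w)))))
    Q <- sum(w * (y - drop(X %*% b))^2)
    phi <- Q / (J - K)
    if (floor_phi) phi <- max(1, phi)
    se <- unname(sqrt(diag(solve(XtX)) * phi))
  }
  tab <- tibble::tibble(
    exposure = exposures, b = b, se = se,
    ci_low = b - Z95 * se, ci_high = b + Z95 * se,
    pval = p_from_z(b, se),
    or = exp(b), or_ci_low = exp(b - Z95 * se), or_ci_high = exp(b + Z95 * se)
  )
  structure(
    list(estimates = tab, J = J, K = K, Q = Q, Q_df = J - K, phi = phi),
    class = "mvmr_result"
  )
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf(
    "Multivariable MR: %d variants, %d exposures (phi = %.3f)\n",
    x$J, x$K, x$phi
  ))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.mvmr_result <- function(x, ...) x$estimates

#' @export
glance.mvmr_result <- function(x, ...) {
  tibble::tibble(J = x$J, K = x$K, Q = x$Q, Q_df = x$Q_df, phi = x$phi)
}

#' Qualitative mediation comparison of total and direct effects
#'
#' Compares the univariable (total) effect of the primary exposure with its
#' multivariable (direct, mediator-conditioned) effect. Because odds ratios
#' are noncollapsible, no indirect effect or proportion mediated is
#' computed; the comparison is qualitative:
#' \describe{
#'   \item{`"full"`}{total significant (`p < alpha`), direct not.}
#'   \item{`"partial"`}{both significant and `|direct| < |total|`.}
#'   \item{`"none"`}{otherwise.}
#' }
#'
#' @param total an `mr_result` for the total effect.
#' @param direct an `mvmr_result` containing the primary exposure.
#' @param exposure name of the primary exposure in `direct`
#'   (default `"exp"`).
#' @param alpha two-sided significance threshold (default 0.05).
#' @return an object of class `mediation_report`; [tidy()] gives a one-row
#'   summary.
#' @export
mediation_compare <- function(total, direct, exposure = "exp", alpha = 0.05) {
  stopifnot(inherits(total, "mr_result"), inherits(direct, "mvmr_result"))
  if (!identical(total$exposure, exposure)) {
    abort(paste0(
      "mediation_compare: total effect is for exposure '", total$exposure,
      "', not '", exposure, "'"
    ), class = "mrdissect_contract_error")
  }
  row <- direct$estimates[direct$estimates$exposure == exposure, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(paste0(
      "mediation_compare: exposure '", exposure,
      "' not found in the multivariable fit"
    ), class = "mrdissect_contract_error")
  }
  tot_sig <- total$pval < alpha
  dir_sig <- row$pval < alpha
  verdict <- if (tot_sig && !dir_sig) {
    "full"
  } else if (tot_sig && dir_sig && abs(row$b) < abs(total$b)) {
    "partial"
  } else {
    "none"
  }
  mediators <- setdiff(direct$estimates$exposure, exposure)
  structure(
    list(
      verdict = verdict, alpha = alpha, exposure = exposure,
      mediators = mediators,
      total = tidy(total), direct = row
    ),
    class = "mediation_report"
  )
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf(
    "Mediation comparison (%s | conditioning on %s): %s attenuation\n",
    x$exposure, paste(x$mediators, collapse = " + "), x$verdict
  ))
  cat(sprintf(
    "  total  OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$total$or, x$total$or_ci_low, x$total$or_ci_high, x$total$pval
  ))
  cat(sprintf(
    "  direct OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$direct$or, x$direct$or_ci_low, x$direct$or_ci_high, x$direct$pval
  ))
  invisible(x)
}

#' @export
tidy.mediation_report <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure,
    mediators = paste(x$mediators, collapse = "+"),
    verdict = x$verdict,
    b_total = x$total$b, pval_total = x$total$pval,
    b_direct = x$direct$b, pval_direct = x$direct$pval,
    or_total = x$total$or, or_direct = x$direct$or
  )
}
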