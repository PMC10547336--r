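check_trait_table <- function(table) {
  need <- c("trait_id", "trait_label", "rsid", "beta", "se", "pval")
  if (!all(need %in% names(table))) {
    abort(paste0(
      "trait table must have columns ", paste(need, collapse = ", ")
    ), class = "mrdissect_config_error")
  }
  if (any(table$se <= 0)) {
    abort("trait table standard errors must be positive",
      class = "mrdissect_validation_error"
    )
  }
  if (anyDuplicated(table[, c("trait_id", "rsid")])) {
    abort("trait table (trait_id, rsid) pairs must be unique",
      class = "mrdissect_validation_error"
    )
  }
  invisible(table)
}

#' Read a trait-association table
#'
#' A local stand-in for a phenome-wide association database: one row per
#' (trait, variant) association with columns `trait_id`, `trait_label`,
#' `rsid`, `beta`, `se`, `pval`. Genome-wide-significant rows double as the
#' trait's own instrument list for trait-level MR.
#'
#' @param path path to the TSV file.
#' @return a validated tibble.
#' @export
read_trait_table <- function(path) {
  tt <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_trait_table(tt)
  tibble::as_tibble(tt)
}

#' Scan a trait table for candidate pleiotropic traits
#'
#' A trait is a candidate when at least one outlier variant associates with
#' it at `p < p_threshold` (genome-wide significance by default). Each
#' candidate is annotated with the outlier variants that triggered it.
#'
#' @param table trait-association table, see [read_trait_table()].
#' @param outliers character vector of outlier rsids
#'   (from [detect_outliers()]); must be non-empty.
#' @param p_threshold association threshold (default 5e-8).
#' @return a tibble with one row per candidate: `trait_id`, `trait_label`,
#'   `outlier_rsids` (list column), `n_outlier_hits`, `min_pval`.
#' @export
scan_candidates <- function(table, outliers, p_threshold = 5e-8) {
  if (length(outliers) == 0) {
    abort("scan_candidates: outliers must be non-empty",
      class = "mrdissect_config_error"
    )
  }
  if (nrow(table) == 0) {
    warn("scan_candidates: empty trait table, no candidates")
    return(tibble::tibble(
      trait_id = character(), trait_label = character(),
      outlier_rsids = list(), n_outlier_hits = integer(), min_pval = double()
    ))
  }
  check_trait_table(table)
  hits <- dplyr::filter(
    table, .data$rsid %in% outliers, .data$pval < p_threshold
  )
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      trait_id = character(), trait_label = character(),
      outlier_rsids = list(), n_outlier_hits = integer(), min_pval = double()
    ))
  }
  hits |>
    dplyr::group_by(.data$trait_id, .data$trait_label) |>
    dplyr::summarise(
      outlier_rsids = list(sort(unique(.data$rsid))),
      n_outlier_hits = dplyr::n_distinct(.data$rsid),
      min_pval = min(.data$pval),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$min_pval, .data$trait_id)
}

trait_instruments <- function(table, trait, outliers, instrument_p) {
  dplyr::filter(
    table, .data$trait_id == trait, .data$pval < instrument_p,
    !(.data$rsid %in% outliers)
  )
}

# IVW-MRE of the outcome on one trait's instruments (outliers excluded)
trait_outcome_ivw <- function(table, trait, outcome, outliers, instrument_p,
                              min_instruments = 2) {
  ins <- trait_instruments(table, trait, outliers, instrument_p)
  m <- dplyr::inner_join(
    ins, outcome[, c("rsid", "beta", "se")],
    by = "rsid", suffix = c("", "_out")
  )
  if (nrow(m) < min_instruments) {
    return(list(ok = FALSE, n = nrow(m)))
  }
  h <- tibble::tibble(
    rsid = m$rsid, beta_exp = m$beta, se_exp = m$se,
    beta_out = m$beta_out, se_out = m$se_out
  )
  list(ok = TRUE, n = nrow(m), fit = mr_ivw(h), rsids = m$rsid)
}

#' Filter candidate traits: trait-level MR, FDR, curation rules
#'
#' For every candidate trait: (i) an IVW multiplicative-random-effects MR of
#' the outcome on the trait's own instruments, with the original outlier
#' variants excluded from the instrument set; (ii) Benjamini-Hochberg FDR
#' across all candidates at `fdr_alpha`, keeping traits with `q <=
#' fdr_alpha`; (iii) a declarative blocklist of regular expressions applied
#' to trait labels and ids (the reproducible counterpart of removing
#' exposure- or outcome-related traits by hand); (iv) duplicate collapse:
#' among traits whose instrument-effect vectors over shared variants
#' correlate above `dup_threshold`, only the trait with the most instruments
#' is kept (ties broken lexicographically by `trait_id`).
#'
#' If `exposure` is supplied, a bidirectional diagnostic (trait-on-exposure
#' IVW over the trait's instruments) is attached as columns `b_rev`,
#' `pval_rev`; it excludes traits only when `bidirectional_filter = TRUE`
#' (excluding traits with `pval_rev < 0.05`), since exclusion on this step
#' is a curation choice rather than a fixed rule.
#'
#' @param candidates output of [scan_candidates()].
#' @param table trait-association table.
#' @param outcome canonical sumstats tibble for the outcome, covering the
#'   traits' instrument variants.
#' @param outliers outlier rsids excluded from every trait's instruments.
#' @param fdr_alpha Benjamini-Hochberg level (default 0.05).
#' @param blocklist character vector of regex patterns; matching traits are
#'   removed regardless of q.
#' @param dup_threshold correlation above which two traits are duplicates
#'   (default 0.9).
#' @param instrument_p significance threshold defining a trait's instruments
#'   (default 5e-8).
#' @param min_instruments minimum usable instruments per trait (default 2).
#' @param exposure optional canonical sumstats tibble for the exposure
#'   (bidirectional diagnostic).
#' @param bidirectional_filter exclude traits significantly associated with
#'   the exposure (default FALSE).
#' @return a tibble of surviving traits (`trait_id`, `trait_label`, `b`,
#'   `se`, `pval`, `fdr_q`, `n_instruments`, `excluded_rsids`,
#'   `outlier_rsids`, and the diagnostic columns when requested); excluded
#'   candidates with reasons are in `attr(, "excluded")`.
#' @export
filter_traits <- function(candidates, table, outcome, outliers,
                          fdr_alpha = 0.05, blocklist = character(),
                          dup_threshold = 0.9, instrument_p = 5e-8,
                          min_instruments = 2, exposure = NULL,
                          bidirectional_filter = FALSE) {
  check_trait_table(table)
  if (nrow(candidates) == 0) {
    return(structure(
      tibble::tibble(),
      excluded = tibble::tibble(trait_id = character(), reason = character())
    ))
  }
  excluded <- list()

  rows <- purrr::pmap(
    list(candidates$trait_id, candidates$trait_label, candidates$outlier_rsids),
    function(id, label, trig) {
      est <- trait_outcome_ivw(
        table, id, outcome, outliers, instrument_p, min_instruments
      )
      if (!est$ok) {
        return(tibble::tibble(
          trait_id = id, trait_label = label, ok = FALSE,
          n_instruments = est$n
        ))
      }
      tibble::tibble(
        trait_id = id, trait_label = label, ok = TRUE,
        b = est$fit$b, se = est$fit$se, pval = est$fit$pval,
        n_instruments = est$n,
        excluded_rsids = list(intersect(
          table$rsid[table$trait_id == id & table$pval < instrument_p],
          outliers
        )),
        outlier_rsids = list(trig)
      )
    }
  ) |> purrr::list_rbind()

  weak <- rows[!rows$ok, , drop = FALSE]
  if (nrow(weak)) {
    excluded$weak <- tibble::tibble(
      trait_id = weak$trait_id,
      reason = paste0("fewer than ", min_instruments, " usable instruments")
    )
  }
  rows <- rows[rows$ok, , drop = FALSE]
  if (nrow(rows) == 0) {
    out <- tibble::tibble()
    attr(out, "excluded") <- purrr::list_rbind(excluded)
    return(out)
  }

  # (ii) BH FDR across all candidates jointly
  rows$fdr_q <- p.adjust(rows$pval, method = "BH")
  fail_fdr <- rows$fdr_q > fdr_alpha
  if (any(fail_fdr)) {
    excluded$fdr <- tibble::tibble(
      trait_id = rows$trait_id[fail_fdr],
      reason = paste0("FDR q > ", fdr_alpha)
    )
  }
  rows <- rows[!fail_fdr, , drop = FALSE]

  # (iii) blocklist on label or id
  if (length(blocklist) && nrow(rows)) {
    hit <- Reduce(`|`, lapply(blocklist, function(p) {
      grepl(p, rows$trait_label, ignore.case = TRUE) |
        grepl(p, rows$trait_id, ignore.case = TRUE)
    }))
    if (any(hit)) {
      excluded$block <- tibble::tibble(
        trait_id = rows$trait_id[hit], reason = "blocklist match"
      )
      rows <- rows[!hit, , drop = FALSE]
    }
  }

  # bidirectional diagnostic (and optional filter)
  if (!is.null(exposure) && nrow(rows)) {
    rev <- purrr::map(rows$trait_id, function(id) {
      est <- trait_outcome_ivw(
        table, id, exposure, outliers, instrument_p, min_instruments
      )
      if (!est$ok) {
        return(tibble::tibble(b_rev = NA_real_, pval_rev = NA_real_))
      }
      tibble::tibble(b_rev = est$fit$b, pval_rev = est$fit$pval)
    }) |> purrr::list_rbind()
    rows <- dplyr::bind_cols(rows, rev)
    if (bidirectional_filter) {
      hit <- !is.na(rows$pval_rev) & rows$pval_rev < 0.05
      if (any(hit)) {
        excluded$bidir <- tibble::tibble(
          trait_id = rows$trait_id[hit],
          reason = "associated with exposure (bidirectional filter)"
        )
        rows <- rows[!hit, , drop = FALSE]
      }
    }
  }

  # (iv) duplicate collapse by instrument-effect correlation over shared SNPs
  if (nrow(rows) > 1) {
    ids <- rows$trait_id
    ins <- lapply(ids, function(id) {
      x <- trait_instruments(table, id, outliers, instrument_p)
      setNames(x$beta, x$rsid)
    })
    n <- length(ids)
    dup <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(ins[[i]]), names(ins[[j]]))
        if (length(shared) >= 3) {
          r <- suppressWarnings(cor(ins[[i]][shared], ins[[j]][shared]))
          if (!is.na(r) && r > dup_threshold) dup[i, j] <- dup[j, i] <- TRUE
        }
      }
    }
    # connected components of the duplicate graph
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (dup[i, j] && comp[j] != comp[i]) {
            comp[c(i, j)] <- min(comp[i], comp[j])
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    keep <- logical(n)
    for (g in unique(comp)) {
      members <- which(comp == g)
      o <- members[order(-rows$n_instruments[members], rows$trait_id[members])]
      keep[o[1]] <- TRUE
    }
    if (any(!keep)) {
      excluded$dup <- tibble::tibble(
        trait_id = rows$trait_id[!keep],
        reason = paste0(
          "duplicate of ",
          vapply(which(!keep), function(i) {
            members <- which(comp == comp[i] & keep)
            rows$trait_id[members[1]]
          }, character(1))
        )
      )
      rows <- rows[keep, , drop = FALSE]
    }
  }

  rows$ok <- NULL
  attr(rows, "excluded") <- if (length(excluded)) {
    purrr::list_rbind(excluded)
  } else {
    tibble::tibble(trait_id = character(), reason = character())
  }
  rows
}

# design matrix for the trait multivariable model: rows are variants with
# outcome data and at least one trait instrument association (outliers
# excluded), columns are traits, entries are trait betas (0 when absent)
trait_design <- function(traits, table, outcome, outliers, instrument_p) {
  ids <- traits$trait_id
  tt <- dplyr::filter(
    table, .data$trait_id %in% ids, .data$pval < instrument_p,
    !(.data$rsid %in% outliers)
  )
  snps <- sort(intersect(unique(tt$rsid), outcome$rsid))
  X <- matrix(0, nrow = length(snps), ncol = length(ids),
    dimnames = list(snps, ids)
  )
  for (k in seq_along(ids)) {
    rows_k <- tt[tt$trait_id == ids[k] & tt$rsid %in% snps, ]
    X[match(rows_k$rsid, snps), k] <- rows_k$beta
  }
  oc <- outcome[match(snps, outcome$rsid), ]
  list(X = X, y = oc$beta, w = 1 / oc$se^2, snps = snps)
}

# unpenalized weighted least squares through the origin; returns per-column
# estimates, SEs (with multiplicative overdispersion) and p-values
wls_refit <- function(X, y, w, floor_phi = TRUE) {
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  XtX <- crossprod(Xw)
  b <- drop(solve(XtX, crossprod(Xw, yw)))
  J <- length(y)
  K <- ncol(X)
  Q <- sum(w * (y - drop(X %*% b))^2)
  phi <- if (J > K) Q / (J - K) else 1
  if (floor_phi) phi <- max(1, phi)
  se <- sqrt(diag(solve(XtX)) * phi)
  list(b = b, se = se, pval = p_from_z(b, se), Q = Q, phi = phi)
}

#' Prune redundant candidate traits with a weighted LASSO
#'
#' Minimizes the weighted multivariable-MR objective
#' `sum_j w_j (Gamma_j - sum_k beta_k gamma_jk)^2 + lambda sum_k |beta_k|`
#' with `w_j = 1/se_out_j^2` over the variants instrumenting the candidate
#' traits (outlier variants excluded); predictors are standardized
#' internally and effects back-transformed. `lambda` is chosen by 10-fold
#' cross-validation minimizing weighted prediction error (`"cv_min"`, the
#' default) or by the one-standard-error rule (`"cv_1se"`); `0` and `Inf`
#' are accepted as exact no-penalty / full-shrinkage limits. Traits with a
#' zero coefficient are pruned and the survivors are refit unpenalized; if
#' every coefficient is zero at the cross-validated lambda, the single trait
#' with the smallest FDR q is kept with a warning.
#'
#' @param traits surviving traits from [filter_traits()].
#' @param table trait-association table (supplies per-variant trait effects).
#' @param outcome canonical sumstats tibble for the outcome.
#' @param outliers outlier rsids excluded from the design.
#' @param lambda `"cv_min"`, `"cv_1se"`, or a non-negative number
#'   (0 = no penalty, Inf = total shrinkage).
#' @param seed RNG seed for the cross-validation folds (default 1).
#' @param nfolds cross-validation folds (default 10).
#' @param instrument_p threshold defining trait instruments (default 5e-8).
#' @return the selected subset of `traits`, with columns `b`, `se`, `pval`
#'   replaced by unpenalized multivariable refit values and `b_lasso` added;
#'   `attr(, "lambda")` records the penalty used and `attr(, "n_snps")` the
#'   design size.
#' @export
lasso_prune <- function(traits, table, outcome, outliers = character(),
                        lambda = "cv_min", seed = 1, nfolds = 10,
                        instrument_p = 5e-8) {
  if (nrow(traits) == 0) {
    abort("lasso_prune: at least one trait required",
      class = "mrdissect_config_error"
    )
  }
  check_trait_table(table)
  des <- trait_design(traits, table, outcome, outliers, instrument_p)
  X <- des$X
  K <- ncol(X)
  if (nrow(X) < K + 1) {
    abort("lasso_prune: fewer design variants than traits + 1",
      class = "mrdissect_insufficient_instruments"
    )
  }

  finalize <- function(kept_ids, b_lasso, lambda_used) {
    kept <- traits[traits$trait_id %in% kept_ids, , drop = FALSE]
    refit <- wls_refit(
      X[, kept$trait_id, drop = FALSE], des$y, des$w
    )
    kept$b_lasso <- unname(b_lasso[kept$trait_id])
    kept$b <- unname(refit$b[kept$trait_id])
    kept$se <- unname(refit$se[kept$trait_id])
    kept$pval <- unname(refit$pval[kept$trait_id])
    attr(kept, "lambda") <- lambda_used
    attr(kept, "n_snps") <- nrow(X)
    kept
  }

  if (is.numeric(lambda) && lambda == 0) {
    refit <- wls_refit(X, des$y, des$w)
    return(finalize(colnames(X), setNames(refit$b, colnames(X)), 0))
  }
  if (is.numeric(lambda) && is.infinite(lambda)) {
    warn("lasso_prune: infinite penalty shrinks every coefficient to zero")
    out <- traits[0, , drop = FALSE]
    attr(out, "lambda") <- Inf
    attr(out, "n_snps") <- nrow(X)
    attr(out, "b_lasso") <- setNames(rep(0, K), colnames(X))
    return(out)
  }
  if (K == 1) {
    # single candidate: nothing to prune, report the weighted slope
    refit <- wls_refit(X, des$y, des$w)
    return(finalize(colnames(X), setNames(refit$b, colnames(X)), 0))
  }

  fit_coefs <- if (is.numeric(lambda)) {
    fit <- glmnet::glmnet(X, des$y,
      weights = des$w, alpha = 1,
      intercept = FALSE, standardize = TRUE
    )
    cf <- coef(fit, s = lambda, exact = TRUE, x = X, y = des$y,
      weights = des$w, alpha = 1, intercept = FALSE, standardize = TRUE
    )
    list(b = drop(cf)[-1], lambda = lambda)
  } else {
    lambda <- match.arg(lambda, c("cv_min", "cv_1se"))
    foldid <- withr::with_seed(
      seed, sample(rep_len(seq_len(nfolds), nrow(X)))
    )
    cvfit <- glmnet::cv.glmnet(X, des$y,
      weights = des$w, alpha = 1,
      intercept = FALSE, standardize = TRUE, foldid = foldid
    )
    s <- if (lambda == "cv_min") cvfit$lambda.min else cvfit$lambda.1se
    list(b = drop(coef(cvfit, s = s))[-1], lambda = s)
  }
  b_lasso <- setNames(fit_coefs$b, colnames(X))
  kept_ids <- names(b_lasso)[b_lasso != 0]
  if (length(kept_ids) == 0) {
    warn(paste0(
      "lasso_prune: all coefficients zero at the cross-validated lambda; ",
      "falling back to the single best-q trait"
    ))
    best <- if ("fdr_q" %in% names(traits)) {
      traits$trait_id[order(traits$fdr_q, traits$trait_id)][1]
    } else {
      traits$trait_id[order(traits$pval, traits$trait_id)][1]
    }
    kept_ids <- best
  }
  finalize(kept_ids, b_lasso, fit_coefs$lambda)
}

#' Adjust outcome associations for candidate-trait pleiotropy
#'
#' For every outlier variant `j`, subtracts the pleiotropic contribution of
#' each selected trait `p` from the variant-outcome effect:
#' `Gamma_j_adj = Gamma_j - sum_p beta_p * delta_jp`, where `beta_p` is the
#' trait's effect on the outcome (from [lasso_prune()]) and `delta_jp` the
#' variant's association with the trait (from the trait table, at
#' `p < p_threshold`). Non-outlier variants are untouched. Under the default
#' sigma policy the outcome standard errors are left unchanged; the
#' `"propagate"` variant adds `sum_p delta_jp^2 se(beta_p)^2` in quadrature.
#'
#' @param hset harmonized set.
#' @param outliers outlier rsids to adjust.
#' @param selected selected traits with trait-on-outcome effects (columns
#'   `trait_id`, `b`, `se`; optionally `outlier_rsids` for the
#'   missing-association warning).
#' @param table trait-association table carrying the `delta_jp` values.
#' @param sigma_policy `"unchanged"` (default) or `"propagate"`.
#' @param p_threshold significance threshold a (trait, outlier) association
#'   must meet to contribute (default 5e-8).
#' @return the harmonized set with adjusted `beta_out` (and `se_out` under
#'   `"propagate"`); per-term details in `attr(, "adjustments")`.
#' @export
adjust_outcome <- function(hset, outliers, selected, table,
                           sigma_policy = c("unchanged", "propagate"),
                           p_threshold = 5e-8) {
  sigma_policy <- match.arg(sigma_policy)
  out <- hset
  adjustments <- tibble::tibble(
    rsid = character(), trait_id = character(),
    delta = double(), beta_trait = double(), term = double()
  )
  if (nrow(selected) == 0 || length(outliers) == 0) {
    attr(out, "adjustments") <- adjustments
    attr(out, "sigma_policy") <- sigma_policy
    return(out)
  }
  check_trait_table(table)
  # warn when a selected trait has no usable association for a variant that
  # triggered it
  if ("outlier_rsids" %in% names(selected)) {
    for (i in seq_len(nrow(selected))) {
      trig <- intersect(selected$outlier_rsids[[i]], outliers)
      have <- table$rsid[
        table$trait_id == selected$trait_id[i] & table$pval < p_threshold
      ]
      missing <- setdiff(trig, have)
      if (length(missing)) {
        warn(paste0(
          "adjust_outcome: trait ", selected$trait_id[i],
          " has no usable association for triggering variant(s) ",
          paste(missing, collapse = ", "), "; term(s) skipped"
        ))
      }
    }
  }
  for (j in which(out$rsid %in% outliers)) {
    rows <- table[
      table$rsid == out$rsid[j] &
        table$trait_id %in% selected$trait_id &
        table$pval < p_threshold, ,
      drop = FALSE
    ]
    if (nrow(rows) == 0) next
    bp <- selected$b[match(rows$trait_id, selected$trait_id)]
    terms <- bp * rows$beta
    out$beta_out[j] <- out$beta_out[j] - sum(terms)
    if (sigma_policy == "propagate") {
      sp <- selected$se[match(rows$trait_id, selected$trait_id)]
      out$se_out[j] <- sqrt(out$se_out[j]^2 + sum(rows$beta^2 * sp^2))
    }
    adjustments <- dplyr::bind_rows(adjustments, tibble::tibble(
      rsid = out$rsid[j], trait_id = rows$trait_id,
      delta = rows$beta, beta_trait = bp, term = terms
    ))
  }
  attr(out, "adjustments") <- adjustments
  attr(out, "sigma_policy") <- sigma_policy
  out
}

#' Re-estimate the causal effect after pleiotropy adjustment
#'
#' IVW with multiplicative random effects on (i) the adjusted associations
#' and (ii) the original associations with the outlier variants removed
#' entirely (the leave-out variant), alongside the original fit and the
#' percentage heterogeneity reductions. Because the appropriate baseline
#' for the reduction is a modelling choice, it is reported against both the
#' IVW Cochran's Q and the radial `Q_R` (modified second-order weights).
#'
#' @param hset_adjusted adjusted harmonized set from [adjust_outcome()].
#' @param hset_original the unadjusted harmonized set.
#' @param outliers outlier rsids (for the leave-out variant).
#' @return an object of class `tryx_reestimate` with elements `original`,
#'   `adjusted`, `leave_out` (each an `mr_result`), `het_reduction_ivw`,
#'   `het_reduction_radial`, `het_reduction_leave_out`.
#' @export
reestimate <- function(hset_adjusted, hset_original, outliers = character()) {
  original <- mr_ivw(hset_original)
  adjusted <- mr_ivw(hset_adjusted)
  keep <- !(hset_original$rsid %in% outliers)
  leave_out <- mr_ivw(hset_original[keep, , drop = FALSE])
  rad_orig <- radial_fit(hset_original)
  rad_adj <- radial_fit(hset_adjusted)
  structure(
    list(
      original = original, adjusted = adjusted, leave_out = leave_out,
      het_reduction_ivw = heterogeneity_reduction(original$Q, adjusted$Q),
      het_reduction_radial = heterogeneity_reduction(rad_orig$Q, rad_adj$Q),
      het_reduction_leave_out = heterogeneity_reduction(
        original$Q, leave_out$Q
      )
    ),
    class = "tryx_reestimate"
  )
}

#' @export
print.tryx_reestimate <- function(x, ...) {
  cat("TRYX re-estimation\n")
  for (nm in c("original", "adjusted", "leave_out")) {
    f <- x[[nm]]
    cat(sprintf(
      "  %-10s OR = %.3f [%.3f, %.3f], p = %.3g, Q = %.1f\n",
      nm, exp(f$b), exp(f$ci_low), exp(f$ci_high), f$pval, f$Q
    ))
  }
  cat(sprintf(
    "  heterogeneity reduction: %.1f%% (IVW Q), %.1f%% (radial Q_R)\n",
    x$het_reduction_ivw, x$het_reduction_radial
  ))
  invisible(x)
}

#' @export
tidy.tryx_reestimate <- function(x, ...) {
  purrr::map_dfr(
    c("original", "adjusted", "leave_out"),
    function(nm) dplyr::mutate(tidy(x[[nm]]), model = nm, .before = 1)
  )
}

#' Run the full TRYX pleiotropy-dissection stage
#'
#' Candidate scan, FDR/curation filtering, LASSO pruning, outcome
#' adjustment and re-estimation, wired together; see the individual stage
#' functions for the rules applied.
#'
#' @inheritParams filter_traits
#' @inheritParams adjust_outcome
#' @param hset harmonized set for the primary exposure-outcome model.
#' @param lambda,seed,nfolds passed to [lasso_prune()].
#' @param scan_p candidate-scan threshold (default 5e-8).
#' @return a list with `candidates`, `traits`, `selected`, `hset_adjusted`,
#'   `reestimate`, and `funnel` (named counts: traits scanned, candidates,
#'   surviving FDR/curation, LASSO-prioritized).
#' @export
run_tryx <- function(hset, table, outcome, outliers,
                     scan_p = 5e-8, fdr_alpha = 0.05,
                     blocklist = character(), dup_threshold = 0.9,
                     instrument_p = 5e-8, exposure = NULL,
                     bidirectional_filter = FALSE,
                     lambda = "cv_min", seed = 1, nfolds = 10,
                     sigma_policy = "unchanged") {
  candidates <- scan_candidates(table, outliers, scan_p)
  traits <- filter_traits(
    candidates, table, outcome, outliers,
    fdr_alpha = fdr_alpha, blocklist = blocklist,
    dup_threshold = dup_threshold, instrument_p = instrument_p,
    exposure = exposure, bidirectional_filter = bidirectional_filter
  )
  selected <- if (nrow(traits)) {
    lasso_prune(traits, table, outcome, outliers,
      lambda = lambda, seed = seed, nfolds = nfolds,
      instrument_p = instrument_p
    )
  } else {
    traits
  }
  hset_adjusted <- adjust_outcome(
    hset, outliers, selected, table,
    sigma_policy = sigma_policy, p_threshold = scan_p
  )
  list(
    candidates = candidates,
    traits = traits,
    selected = selected,
    hset_adjusted = hset_adjusted,
    reestimate = reestimate(hset_adjusted, hset, outliers),
    funnel = c(
      traits_scanned = dplyr::n_distinct(table$trait_id),
      candidates = nrow(candidates),
      post_fdr_curation = nrow(traits),
      lasso_prioritized = nrow(selected)
    )
  )
}
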