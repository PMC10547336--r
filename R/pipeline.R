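pipeline_policies <- list(
  palindrome_policy = c("drop_ambiguous", "drop_all"),
  alpha_policy = c("bonferroni", "fixed"),
  radial_weights = c("modified_second_order", "first_order"),
  sigma_policy = c("unchanged", "propagate")
)

#' Build and validate a pipeline configuration
#'
#' A single declarative configuration drives the whole analysis; every
#' module-level default is surfaced here. Data inputs may be in-memory data
#' frames or file paths (TSV/CSV read with [read_sumstats()],
#' [read_trait_table()], [read_ld_table()]). Unknown policy names fail here,
#' before any computation.
#'
#' @param exposure,outcome exposure and outcome summary statistics (data
#'   frame or path).
#' @param mediators named list of putative mediator summary statistics
#'   (data frames or paths); each is conditioned on individually.
#' @param trait_table optional trait-association table for the pleiotropy
#'   dissection stage (data frame or path).
#' @param ld optional LD table (data frame or path).
#' @param column_map column mapping for file inputs, see [sumstats_cols()].
#' @param p_threshold,r2_threshold instrument selection thresholds.
#' @param palindrome_policy,maf_window harmonization policy,
#'   see [harmonize()].
#' @param radial_weights radial weighting scheme, see [radial_fit()].
#' @param alpha_policy,outlier_alpha outlier flagging policy,
#'   see [detect_outliers()].
#' @param scan_p,fdr_alpha,blocklist,dup_threshold,bidirectional_filter,
#'   lambda,sigma_policy pleiotropy-dissection stage controls, see
#'   [run_tryx()].
#' @param n_boot weighted-median bootstrap resamples.
#' @param mediation_alpha significance level for the mediation verdict.
#' @param seed seed for every stochastic step (bootstrap, LASSO folds).
#' @return a validated list of class `mr_pipeline_config`.
#' @export
pipeline_config <- function(exposure, outcome, mediators = list(),
                            trait_table = NULL, ld = NULL,
                            column_map = sumstats_cols(),
                            p_threshold = 5e-8, r2_threshold = 0.001,
                            palindrome_policy = "drop_ambiguous",
                            maf_window = 0.08,
                            radial_weights = "modified_second_order",
                            alpha_policy = "bonferroni", outlier_alpha = 0.05,
                            scan_p = 5e-8, fdr_alpha = 0.05,
                            blocklist = character(), dup_threshold = 0.9,
                            bidirectional_filter = FALSE,
                            lambda = "cv_min", sigma_policy = "unchanged",
                            n_boot = 1000, mediation_alpha = 0.05, seed = 1) {
  cfg <- list(
    exposure = exposure, outcome = outcome, mediators = mediators,
    trait_table = trait_table, ld = ld, column_map = column_map,
    p_threshold = p_threshold, r2_threshold = r2_threshold,
    palindrome_policy = palindrome_policy, maf_window = maf_window,
    radial_weights = radial_weights, alpha_policy = alpha_policy,
    outlier_alpha = outlier_alpha, scan_p = scan_p, fdr_alpha = fdr_alpha,
    blocklist = blocklist, dup_threshold = dup_threshold,
    bidirectional_filter = bidirectional_filter, lambda = lambda,
    sigma_policy = sigma_policy, n_boot = n_boot,
    mediation_alpha = mediation_alpha, seed = seed
  )
  for (nm in names(pipeline_policies)) {
    if (!cfg[[nm]] %in% pipeline_policies[[nm]]) {
      abort(paste0(
        "pipeline_config: unknown ", nm, " '", cfg[[nm]], "'; valid: ",
        paste(pipeline_policies[[nm]], collapse = ", ")
      ), class = "mrdissect_config_error")
    }
  }
  if (!(is.character(cfg$lambda) &&
    cfg$lambda %in% c("cv_min", "cv_1se")) &&
    !(is.numeric(cfg$lambda) && cfg$lambda >= 0)) {
    abort("pipeline_config: lambda must be 'cv_min', 'cv_1se' or a non-negative number",
      class = "mrdissect_config_error"
    )
  }
  if (length(cfg$mediators) &&
    (is.null(names(cfg$mediators)) || any(names(cfg$mediators) == ""))) {
    abort("pipeline_config: mediators must be a named list",
      class = "mrdissect_config_error"
    )
  }
  structure(cfg, class = "mr_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File keys mirror the arguments of [pipeline_config()]; data inputs are
#' given as file paths relative to the configuration file's directory.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return a validated `mr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0(
      "unknown configuration key(s): ", paste(unknown, collapse = ", ")
    ), class = "mrdissect_config_error")
  }
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else {
      p
    }
  }
  for (nm in c("exposure", "outcome", "trait_table", "ld")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- rel(raw[[nm]])
  }
  if (!is.null(raw$mediators)) raw$mediators <- lapply(raw$mediators, rel)
  if (!is.null(raw$blocklist)) raw$blocklist <- as.character(raw$blocklist)
  do.call(pipeline_config, raw)
}

load_input <- function(x, reader, column_map = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (is.null(column_map)) reader(x) else reader(x, column_map)
  } else {
    tibble::as_tibble(x)
  }
}

#' Run the full causal-dissection pipeline
#'
#' Executes, in order: instrument selection, harmonization, the univariable
#' estimator panel, radial MR outlier detection, the TRYX pleiotropy
#' dissection (skipped with a notice when no outliers are found or no trait
#' table is supplied), multivariable MR conditioning on each mediator
#' individually, and the qualitative mediation comparison. Every stage
#' decision (dropped variants, excluded traits, funnel counts) is recorded
#' in the returned report, and input tables are content-hashed so each
#' estimate is traceable to its inputs. Re-running with an identical
#' configuration yields an identical report.
#'
#' @param config an `mr_pipeline_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return an object of class `mr_pipeline_report`; see
#'   [write_report()] for serialization.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_pipeline_config"))
  exposure <- load_input(config$exposure, read_sumstats, config$column_map)
  outcome <- load_input(config$outcome, read_sumstats, config$column_map)
  exposure <- as_sumstats(exposure)
  outcome <- as_sumstats(outcome)
  trait_table <- if (!is.null(config$trait_table)) {
    load_input(config$trait_table, read_trait_table)
  }
  ld <- if (!is.null(config$ld)) load_input(config$ld, read_ld_table)
  mediators <- lapply(config$mediators, function(m) {
    as_sumstats(load_input(m, read_sumstats, config$column_map))
  })

  input_hashes <- list(
    exposure = hash(exposure), outcome = hash(outcome),
    trait_table = if (!is.null(trait_table)) hash(trait_table),
    mediators = lapply(mediators, hash)
  )

  instruments <- select_instruments(
    exposure, config$p_threshold, ld, config$r2_threshold
  )
  hset <- harmonize(
    instruments, outcome, config$palindrome_policy, config$maf_window
  )
  univariable <- mr_all(hset, n_boot = config$n_boot, seed = config$seed)
  total <- mr_ivw(hset)
  rad <- radial_fit(hset, weights = config$radial_weights)
  outliers <- detect_outliers(rad, config$alpha_policy, config$outlier_alpha)

  tryx <- NULL
  tryx_skipped <- NULL
  if (length(outliers) == 0) {
    tryx_skipped <- "no outlier variants detected"
  } else if (is.null(trait_table)) {
    tryx_skipped <- "no trait table supplied"
  }
  if (is.null(tryx_skipped)) {
    tryx <- run_tryx(
      hset, trait_table, outcome, outliers,
      scan_p = config$scan_p, fdr_alpha = config$fdr_alpha,
      blocklist = config$blocklist, dup_threshold = config$dup_threshold,
      exposure = exposure,
      bidirectional_filter = config$bidirectional_filter,
      lambda = config$lambda, seed = config$seed,
      sigma_policy = config$sigma_policy
    )
  } else {
    inform(paste0("pleiotropy-dissection stage skipped: ", tryx_skipped))
  }

  mvmr <- list()
  mediation <- list()
  for (nm in names(mediators)) {
    h2 <- add_exposure(hset, mediators[[nm]], nm)
    fit <- mvmr_fit(h2, c("exp", nm))
    mvmr[[nm]] <- fit
    mediation[[nm]] <- mediation_compare(
      total, fit, "exp", config$mediation_alpha
    )
  }

  structure(
    list(
      config = config,
      input_hashes = input_hashes,
      n_instruments = nrow(hset),
      instruments = hset$rsid,
      harmonized = hset,
      univariable = univariable,
      total = total,
      radial = rad,
      outliers = outliers,
      tryx = tryx,
      tryx_skipped = tryx_skipped,
      funnel = if (!is.null(tryx)) tryx$funnel,
      mvmr = mvmr,
      mediation = mediation,
      seed = config$seed
    ),
    class = "mr_pipeline_report"
  )
}

#' @export
print.mr_pipeline_report <- function(x, ...) {
  cat("Two-sample MR causal-dissection report\n")
  cat(sprintf("  instruments harmonized: %d\n", x$n_instruments))
  cat("  univariable estimates:\n")
  u <- x$univariable
  for (i in seq_len(nrow(u))) {
    cat(sprintf(
      "    %-16s OR = %.3f [%.3f, %.3f], p = %.3g\n",
      u$method[i], u$or[i], u$or_ci_low[i], u$or_ci_high[i], u$pval[i]
    ))
  }
  cat(sprintf(
    "  heterogeneity: Q = %.1f on %d df (p = %.3g)\n",
    x$total$Q, x$total$Q_df, x$total$Q_pval
  ))
  cat(sprintf(
    "  radial outliers (%d): %s\n", length(x$outliers),
    if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none"
  ))
  if (!is.null(x$tryx)) {
    cat(sprintf(
      "  trait funnel: %d scanned -> %d candidates -> %d post-FDR/curation -> %d prioritized\n",
      x$funnel[["traits_scanned"]], x$funnel[["candidates"]],
      x$funnel[["post_fdr_curation"]], x$funnel[["lasso_prioritized"]]
    ))
    adj <- x$tryx$reestimate$adjusted
    cat(sprintf(
      "  outlier-adjusted IVW: OR = %.3f [%.3f, %.3f], p = %.3g (Q reduced %.1f%%)\n",
      exp(adj$b), exp(adj$ci_low), exp(adj$ci_high), adj$pval,
      x$tryx$reestimate$het_reduction_ivw
    ))
  } else if (!is.null(x$tryx_skipped)) {
    cat(sprintf("  pleiotropy dissection skipped: %s\n", x$tryx_skipped))
  }
  for (nm in names(x$mediation)) {
    m <- x$mediation[[nm]]
    cat(sprintf(
      "  conditioning on %s: direct OR = %.3f [%.3f, %.3f], p = %.3g (%s attenuation)\n",
      nm, m$direct$or, m$direct$or_ci_low, m$direct$or_ci_high,
      m$direct$pval, m$verdict
    ))
  }
  invisible(x)
}

report_as_list <- function(x) {
  list(
    seed = x$seed,
    input_hashes = x$input_hashes,
    n_instruments = x$n_instruments,
    instruments = x$instruments,
    univariable = x$univariable,
    heterogeneity = list(
      Q = x$total$Q, Q_df = x$total$Q_df, Q_pval = x$total$Q_pval
    ),
    radial = glance(x$radial),
    outliers = x$outliers,
    tryx_skipped = x$tryx_skipped,
    funnel = as.list(x$funnel),
    tryx = if (!is.null(x$tryx)) {
      list(
        candidates = dplyr::select(x$tryx$candidates, -"outlier_rsids"),
        selected = x$tryx$selected$trait_id,
        reestimate = tidy(x$tryx$reestimate),
        het_reduction_ivw = x$tryx$reestimate$het_reduction_ivw,
        het_reduction_radial = x$tryx$reestimate$het_reduction_radial,
        het_reduction_leave_out = x$tryx$reestimate$het_reduction_leave_out
      )
    },
    mvmr = lapply(x$mvmr, tidy),
    mediation = if (length(x$mediation)) {
      purrr::map_dfr(x$mediation, tidy)
    }
  )
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (the machine-readable stage-by-stage report) plus
#' per-stage TSV tables (`harmonized.tsv`, `univariable.tsv`,
#' `radial.tsv`, and when the dissection stage ran, `traits.tsv` and
#' `reestimate.tsv`; `mvmr.tsv` when mediators were analysed).
#'
#' @param report an `mr_pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report_as_list(report), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  write_harmonized(report$harmonized, file.path(dir, "harmonized.tsv"))
  readr::write_tsv(report$univariable, file.path(dir, "univariable.tsv"),
    progress = FALSE
  )
  readr::write_tsv(tidy(report$radial), file.path(dir, "radial.tsv"),
    progress = FALSE
  )
  if (!is.null(report$tryx)) {
    if (nrow(report$tryx$traits)) {
      readr::write_tsv(
        dplyr::select(
          report$tryx$traits,
          -dplyr::any_of(c("outlier_rsids", "excluded_rsids"))
        ),
        file.path(dir, "traits.tsv"),
        progress = FALSE
      )
    }
    readr::write_tsv(
      tidy(report$tryx$reestimate), file.path(dir, "reestimate.tsv"),
      progress = FALSE
    )
  }
  if (length(report$mvmr)) {
    readr::write_tsv(
      purrr::imap_dfr(report$mvmr, function(f, nm) {
        dplyr::mutate(tidy(f), adjustment = nm, .before = 1)
      }),
      file.path(dir, "mvmr.tsv"),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' Forest plot of MR estimates
#'
#' @param estimates a tibble with columns `method` (or another label
#'   column), `or`, `or_ci_low`, `or_ci_high`.
#' @param label column to label rows by (default `"method"`).
#' @return a ggplot object.
#' @export
plot_forest <- function(estimates, label = "method") {
  d <- tibble::as_tibble(estimates)
  d$label <- d[[label]]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$or, y = .data$label,
    xmin = .data$or_ci_low, xmax = .data$or_ci_high
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pipeline report
#'
#' Univariable panel, outlier-adjusted and leave-out estimates, and the
#' mediator-conditioned direct effects on one forest.
#'
#' @param object an `mr_pipeline_report`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.mr_pipeline_report <- function(object, ...) {
  rows <- object$univariable[, c("method", "or", "or_ci_low", "or_ci_high")]
  if (!is.null(object$tryx)) {
    re <- tidy(object$tryx$reestimate)
    re <- re[re$model != "original", c("model", "or", "or_ci_low", "or_ci_high")]
    names(re)[1] <- "method"
    rows <- dplyr::bind_rows(rows, re)
  }
  for (nm in names(object$mvmr)) {
    t <- tidy(object$mvmr[[nm]])
    t <- t[t$exposure == "exp", c("or", "or_ci_low", "or_ci_high")]
    t$method <- paste0("direct | ", nm)
    rows <- dplyr::bind_rows(rows, t)
  }
  rows$method <- factor(rows$method, levels = rev(unique(rows$method)))
  plot_forest(rows)
}
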