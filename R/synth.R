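#' Configuration of the synthetic GWAS summary-statistic generator
#'
#' Bundles and validates the generative parameters. The defaults emulate a
#' well-powered two-sample design for a binary liability exposure and a
#' binary outcome: 182 independent instruments, a total causal effect of
#' `log(1.08)` on the outcome log-odds scale, 4 planted outlier variants
#' whose horizontal pleiotropy acts entirely through a small set of
#' candidate traits, and mild balanced pleiotropy across the remaining
#' variants. Units: exposure effects are log-odds of exposure liability per
#' allele; mediator and trait effects are SD units; outcome effects are
#' log-odds.
#'
#' @param J number of instrument variants (default 182).
#' @param theta_direct direct causal effect of the exposure on the outcome
#'   (log-odds; default `log(1.08)`).
#' @param kappa exposure-on-mediator effect (SD units per liability unit;
#'   default 0).
#' @param mu mediator-on-outcome effect (log-odds per SD; default 0). The
#'   total effect recovered by univariable MR is
#'   `theta_direct + kappa * mu`.
#' @param mediator_het_sd SD of variant-level heterogeneity in the mediator
#'   pathway (default 0.03): each variant's true mediator effect is
#'   `kappa * gamma_j + eta_j`, `eta_j ~ N(0, mediator_het_sd^2)`. This
#'   variant-specific channel is what renders the mediator conditionally
#'   identifiable in multivariable MR.
#' @param n_outliers planted pleiotropic outlier variants (default 4).
#' @param outlier_trait_count distinct candidate traits carrying the
#'   outlier pleiotropy (default 3; outliers are assigned round-robin).
#' @param alpha_trait trait-on-outcome effect(s), recycled over traits
#'   (default 0.3 log-odds per SD).
#' @param outlier_delta_range magnitude range of outlier-variant-on-trait
#'   effects (default `c(1.0, 1.5)` SD), so each planted offset
#'   `alpha_trait * delta` is roughly ten times the outcome standard error.
#' @param pleiotropy_mode `"balanced"` (default), `"directional"`, or
#'   `"none"`: the diffuse pleiotropy channel added to every variant.
#' @param pleiotropy_sd SD of the balanced component (default 0.01).
#' @param directional_offset constant per-variant offset under
#'   `"directional"` (default 0.005).
#' @param gamma_range magnitude range of true variant-exposure effects
#'   (default `c(0.03, 0.15)`; signs random).
#' @param se_gamma_range,se_outcome_range,se_mediator_range,se_trait_range
#'   uniform ranges for the per-variant standard errors (defaults
#'   `c(0.004, 0.009)`, `c(0.02, 0.04)`, `c(0.002, 0.004)`,
#'   `c(0.003, 0.006)`).
#' @param trait_instruments own instruments per candidate trait
#'   (default 25).
#' @param trait_instrument_range magnitude range of trait-instrument
#'   effects (default `c(0.04, 0.12)` SD, all genome-wide significant at
#'   the trait SE scale).
#' @param n_decoy_traits traits associated only with non-outlier variants
#'   (default 2; removed at the candidate scan).
#' @param n_weak_traits traits whose outlier association is sub-threshold
#'   (default 1).
#' @param n_null_candidate_traits traits associated with an outlier but
#'   with no effect on the outcome (default 1; removed by the FDR step).
#' @param n_duplicate_traits near-copies of the first real trait(s) sharing
#'   instruments (default 1; removed by the duplicate collapse).
#' @param eaf_range effect-allele frequency range (default `c(0.05, 0.95)`).
#' @param n_exposure,n_outcome GWAS sample sizes recorded in the tables.
#' @param outlier_rsids optional explicit rsids for the planted outliers
#'   (length `n_outliers`).
#' @param seed RNG seed; the whole dataset is a pure function of the
#'   configuration.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_gwas()]
#' @export
sim_config <- function(J = 182,
                       theta_direct = log(1.08),
                       kappa = 0,
                       mu = 0,
                       mediator_het_sd = 0.03,
                       n_outliers = 4,
                       outlier_trait_count = 3,
                       alpha_trait = 0.3,
                       outlier_delta_range = c(1.0, 1.5),
                       pleiotropy_mode = c("balanced", "directional", "none"),
                       pleiotropy_sd = 0.01,
                       directional_offset = 0.005,
                       gamma_range = c(0.03, 0.15),
                       se_gamma_range = c(0.004, 0.009),
                       se_outcome_range = c(0.02, 0.04),
                       se_mediator_range = c(0.002, 0.004),
                       se_trait_range = c(0.003, 0.006),
                       trait_instruments = 25,
                       trait_instrument_range = c(0.04, 0.12),
                       n_decoy_traits = 2,
                       n_weak_traits = 1,
                       n_null_candidate_traits = 1,
                       n_duplicate_traits = 1,
                       eaf_range = c(0.05, 0.95),
                       n_exposure = 1339889,
                       n_outcome = 237690,
                       outlier_rsids = NULL,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(
    J = as.integer(J), theta_direct = theta_direct, kappa = kappa, mu = mu,
    mediator_het_sd = mediator_het_sd, n_outliers = as.integer(n_outliers),
    outlier_trait_count = as.integer(outlier_trait_count),
    alpha_trait = alpha_trait, outlier_delta_range = outlier_delta_range,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    directional_offset = directional_offset, gamma_range = gamma_range,
    se_gamma_range = se_gamma_range, se_outcome_range = se_outcome_range,
    se_mediator_range = se_mediator_range, se_trait_range = se_trait_range,
    trait_instruments = as.integer(trait_instruments),
    trait_instrument_range = trait_instrument_range,
    n_decoy_traits = as.integer(n_decoy_traits),
    n_weak_traits = as.integer(n_weak_traits),
    n_null_candidate_traits = as.integer(n_null_candidate_traits),
    n_duplicate_traits = as.integer(n_duplicate_traits),
    eaf_range = eaf_range, n_exposure = n_exposure, n_outcome = n_outcome,
    outlier_rsids = outlier_rsids, seed = as.integer(seed)
  )
  if (cfg$J < 2) abort("sim_config: J must be >= 2",
    class = "mrdissect_config_error")
  if (cfg$n_outliers < 0 || cfg$n_outliers > cfg$J) {
    abort("sim_config: need J >= n_outliers >= 0",
      class = "mrdissect_config_error")
  }
  if (cfg$n_outliers > 0 && cfg$outlier_trait_count < 1) {
    abort("sim_config: outlier_trait_count must be >= 1 when outliers are planted",
      class = "mrdissect_config_error")
  }
  for (nm in c(
    "outlier_delta_range", "gamma_range", "se_gamma_range",
    "se_outcome_range", "se_mediator_range", "se_trait_range",
    "trait_instrument_range", "eaf_range"
  )) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] >= r[2] || any(r < 0)) {
      abort(paste0("sim_config: ", nm, " must be an increasing ",
        "non-negative pair"), class = "mrdissect_config_error")
    }
  }
  for (nm in c("se_gamma_range", "se_outcome_range", "se_mediator_range",
               "se_trait_range")) {
    if (cfg[[nm]][1] <= 0) {
      abort(paste0("sim_config: ", nm, " must be strictly positive"),
        class = "mrdissect_config_error")
    }
  }
  if (!is.null(cfg$outlier_rsids) &&
      length(cfg$outlier_rsids) != cfg$n_outliers) {
    abort("sim_config: outlier_rsids must have length n_outliers",
      class = "mrdissect_config_error")
  }
  structure(cfg, class = "sim_config")
}

# non-palindromic allele pairs only, so harmonization keeps every variant
allele_pairs <- matrix(
  c(
    "A", "G", "A", "C", "T", "G", "T", "C",
    "G", "A", "C", "A", "G", "T", "C", "T"
  ),
  ncol = 2, byrow = TRUE
)

sumstats_row <- function(rsid, ea, oa, beta, se, eaf, n) {
  tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    beta = beta, se = se, eaf = eaf,
    pval = p_from_z(beta, se), n = n
  )
}

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Generates exposure, outcome and mediator GWAS summary-statistic tables
#' plus a candidate-trait association table, all reproducible from the
#' configuration seed, together with the realized generative truth.
#'
#' The generative model, per instrument variant `j`:
#' \itemize{
#'   \item true exposure effect `gamma_j = s_j * U(gamma_range)`, random
#'     sign; observed with `N(0, se_gamma_j^2)` noise;
#'   \item true mediator effect `m_j = kappa * gamma_j + eta_j` with
#'     variant-level pathway heterogeneity `eta_j`;
#'   \item true outcome effect `Gamma_j = theta_direct * gamma_j +
#'     mu * m_j + e_j + sum_p alpha_p * delta_jp`, where `e_j` is the
#'     diffuse pleiotropy channel and the last sum is nonzero only for the
#'     planted outlier variants;
#'   \item observed effects add independent normal noise at the drawn
#'     per-variant standard errors.
#' }
#' Candidate traits come in four kinds: real pleiotropic traits (carry the
#' outlier offsets, have their own instruments and a nonzero effect on the
#' outcome), decoys (associated only with non-outlier variants), weak
#' traits (sub-threshold outlier association), null candidates (outlier
#' association but no outcome effect), plus near-duplicate copies of real
#' traits.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `mr_sim`: a list with canonical sumstats
#'   tibbles `exposure`, `outcome`, `mediator`, the `trait_table`, the
#'   `truth` list (true effects, outlier identities, trait roster,
#'   `theta_total`), and the `config`.
#' @examples
#' sim <- simulate_gwas(sim_config(J = 20, n_outliers = 2, seed = 7))
#' names(sim)
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    J <- cfg$J
    rsid <- sprintf("rs1%06d", seq_len(J))
    out_idx <- if (cfg$n_outliers > 0) sort(sample(J, cfg$n_outliers)) else integer(0)
    if (!is.null(cfg$outlier_rsids)) rsid[out_idx] <- cfg$outlier_rsids
    ap <- allele_pairs[sample(nrow(allele_pairs), J, replace = TRUE), , drop = FALSE]
    eaf <- runif(J, cfg$eaf_range[1], cfg$eaf_range[2])

    gamma <- sample(c(-1, 1), J, replace = TRUE) *
      runif(J, cfg$gamma_range[1], cfg$gamma_range[2])
    se_g <- runif(J, cfg$se_gamma_range[1], cfg$se_gamma_range[2])
    gamma_hat <- gamma + rnorm(J) * se_g

    m <- cfg$kappa * gamma + rnorm(J) * cfg$mediator_het_sd
    se_m <- runif(J, cfg$se_mediator_range[1], cfg$se_mediator_range[2])
    m_hat <- m + rnorm(J) * se_m

    # directional pleiotropy is defined in the oriented frame (per copy of
    # the exposure-increasing allele), so the offset carries gamma's sign
    e <- switch(cfg$pleiotropy_mode,
      none = rep(0, J),
      balanced = rnorm(J) * cfg$pleiotropy_sd,
      directional = rnorm(J) * cfg$pleiotropy_sd +
        sign(gamma) * cfg$directional_offset
    )

    # trait roster ---------------------------------------------------------
    P <- if (cfg$n_outliers > 0) cfg$outlier_trait_count else 0L
    roster <- tibble::tibble(
      trait_id = character(), trait_label = character(),
      type = character(), alpha = double()
    )
    add_trait <- function(roster, id, label, type, alpha) {
      dplyr::bind_rows(roster, tibble::tibble(
        trait_id = id, trait_label = label, type = type, alpha = alpha
      ))
    }
    alpha_real <- rep_len(cfg$alpha_trait, max(P, 1))
    for (p in seq_len(P)) {
      roster <- add_trait(
        roster, sprintf("t%02d", p), sprintf("candidate trait %d", p),
        "real", alpha_real[p]
      )
    }
    for (d in seq_len(cfg$n_decoy_traits)) {
      roster <- add_trait(
        roster, sprintf("d%02d", d), sprintf("decoy trait %d", d), "decoy", 0
      )
    }
    for (d in seq_len(cfg$n_weak_traits)) {
      roster <- add_trait(
        roster, sprintf("w%02d", d), sprintf("weakly associated trait %d", d),
        "weak", 0
      )
    }
    for (d in seq_len(cfg$n_null_candidate_traits)) {
      roster <- add_trait(
        roster, sprintf("n%02d", d), sprintf("null candidate trait %d", d),
        "null_candidate", 0
      )
    }
    n_dup <- min(cfg$n_duplicate_traits, P)
    for (d in seq_len(n_dup)) {
      roster <- add_trait(
        roster, sprintf("t%02ddup", d),
        sprintf("candidate trait %d (duplicate phenotype)", d),
        "duplicate", alpha_real[d]
      )
    }

    # outlier -> trait assignment and planted offsets ----------------------
    delta <- tibble::tibble(
      trait_id = character(), rsid = character(), delta = double()
    )
    offset <- rep(0, J)
    if (cfg$n_outliers > 0) {
      assign_p <- ((seq_len(cfg$n_outliers) - 1) %% P) + 1
      dsign <- if (cfg$pleiotropy_mode == "directional") {
        rep(1, cfg$n_outliers)
      } else {
        sample(c(-1, 1), cfg$n_outliers, replace = TRUE)
      }
      dmag <- runif(
        cfg$n_outliers, cfg$outlier_delta_range[1], cfg$outlier_delta_range[2]
      )
      for (i in seq_len(cfg$n_outliers)) {
        p <- assign_p[i]
        delta <- dplyr::bind_rows(delta, tibble::tibble(
          trait_id = sprintf("t%02d", p), rsid = rsid[out_idx[i]],
          delta = dsign[i] * dmag[i]
        ))
        offset[out_idx[i]] <- offset[out_idx[i]] +
          alpha_real[p] * dsign[i] * dmag[i]
      }
    }

    Gamma <- cfg$theta_direct * gamma + cfg$mu * m + e + offset
    se_o <- runif(J, cfg$se_outcome_range[1], cfg$se_outcome_range[2])
    Gamma_hat <- Gamma + rnorm(J) * se_o

    exposure <- sumstats_row(
      rsid, ap[, 1], ap[, 2], gamma_hat, se_g, eaf, cfg$n_exposure
    )
    outcome <- sumstats_row(
      rsid, ap[, 1], ap[, 2], Gamma_hat, se_o, eaf, cfg$n_outcome
    )
    mediator <- sumstats_row(
      rsid, ap[, 1], ap[, 2], m_hat, se_m, eaf, cfg$n_outcome
    )

    # trait table and trait-instrument variants ----------------------------
    trait_rows <- list()
    n_ti <- cfg$trait_instruments
    underlying <- roster[roster$type != "duplicate", , drop = FALSE]
    ti_store <- list() # true instrument effects per underlying trait
    for (k in seq_len(nrow(underlying))) {
      tr <- underlying[k, ]
      ti_rsid <- sprintf("rs9%02d%04d", k, seq_len(n_ti))
      zeta <- sample(c(-1, 1), n_ti, replace = TRUE) *
        runif(n_ti, cfg$trait_instrument_range[1], cfg$trait_instrument_range[2])
      se_t <- runif(n_ti, cfg$se_trait_range[1], cfg$se_trait_range[2])
      zeta_hat <- zeta + rnorm(n_ti) * se_t
      ti_store[[tr$trait_id]] <- list(
        rsid = ti_rsid, zeta = zeta, se = se_t, k = k
      )
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = tr$trait_id, trait_label = tr$trait_label,
        rsid = ti_rsid, beta = zeta_hat, se = se_t,
        pval = p_from_z(zeta_hat, se_t)
      )
      # outcome and exposure rows for the trait's instrument variants
      ti_ap <- allele_pairs[
        sample(nrow(allele_pairs), n_ti, replace = TRUE), ,
        drop = FALSE
      ]
      ti_eaf <- runif(n_ti, cfg$eaf_range[1], cfg$eaf_range[2])
      se_o2 <- runif(n_ti, cfg$se_outcome_range[1], cfg$se_outcome_range[2])
      outcome <- dplyr::bind_rows(outcome, sumstats_row(
        ti_rsid, ti_ap[, 1], ti_ap[, 2],
        tr$alpha * zeta + rnorm(n_ti) * se_o2, se_o2, ti_eaf, cfg$n_outcome
      ))
      se_g2 <- runif(n_ti, cfg$se_gamma_range[1], cfg$se_gamma_range[2])
      exposure <- dplyr::bind_rows(exposure, sumstats_row(
        ti_rsid, ti_ap[, 1], ti_ap[, 2],
        rnorm(n_ti) * se_g2, se_g2, ti_eaf, cfg$n_exposure
      ))
    }
    # outlier / non-outlier associations of the traits
    se_assoc <- function(n) {
      runif(n, cfg$se_trait_range[1], cfg$se_trait_range[2])
    }
    if (nrow(delta)) {
      se_d <- se_assoc(nrow(delta))
      dhat <- delta$delta + rnorm(nrow(delta)) * se_d
      dl <- roster$trait_label[match(delta$trait_id, roster$trait_id)]
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = delta$trait_id, trait_label = dl, rsid = delta$rsid,
        beta = dhat, se = se_d, pval = p_from_z(dhat, se_d)
      )
    }
    decoys <- roster[roster$type == "decoy", , drop = FALSE]
    non_out <- setdiff(rsid, rsid[out_idx])
    for (k in seq_len(nrow(decoys))) {
      pick <- sample(non_out, min(2, length(non_out)))
      se_d <- se_assoc(length(pick))
      b <- 1.2 + rnorm(length(pick)) * se_d
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = decoys$trait_id[k], trait_label = decoys$trait_label[k],
        rsid = pick, beta = b, se = se_d, pval = p_from_z(b, se_d)
      )
    }
    weaks <- roster[roster$type == "weak", , drop = FALSE]
    for (k in seq_len(nrow(weaks))) {
      if (length(out_idx) == 0) break
      target <- rsid[out_idx[1 + (k - 1) %% length(out_idx)]]
      se_d <- se_assoc(1)
      b <- 3.5 * se_d + rnorm(1) * se_d # ~z of 3.5: real but sub-threshold
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = weaks$trait_id[k], trait_label = weaks$trait_label[k],
        rsid = target, beta = b, se = se_d, pval = p_from_z(b, se_d)
      )
    }
    nulls <- roster[roster$type == "null_candidate", , drop = FALSE]
    for (k in seq_len(nrow(nulls))) {
      if (length(out_idx) == 0) break
      target <- rsid[out_idx[1 + (k - 1) %% length(out_idx)]]
      se_d <- se_assoc(1)
      b <- 1.2 + rnorm(1) * se_d
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = nulls$trait_id[k], trait_label = nulls$trait_label[k],
        rsid = target, beta = b, se = se_d, pval = p_from_z(b, se_d)
      )
    }
    dups <- roster[roster$type == "duplicate", , drop = FALSE]
    for (k in seq_len(nrow(dups))) {
      src <- sub("dup$", "", dups$trait_id[k])
      ti <- ti_store[[src]]
      nk <- max(2L, floor(0.8 * length(ti$rsid)))
      se_t <- se_assoc(nk)
      b <- ti$zeta[seq_len(nk)] + rnorm(nk) * se_t
      trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
        trait_id = dups$trait_id[k], trait_label = dups$trait_label[k],
        rsid = ti$rsid[seq_len(nk)], beta = b, se = se_t,
        pval = p_from_z(b, se_t)
      )
      # the duplicate shares the source trait's outlier associations
      src_delta <- delta[delta$trait_id == src, , drop = FALSE]
      if (nrow(src_delta)) {
        se_d <- se_assoc(nrow(src_delta))
        bd <- src_delta$delta + rnorm(nrow(src_delta)) * se_d
        trait_rows[[length(trait_rows) + 1]] <- tibble::tibble(
          trait_id = dups$trait_id[k], trait_label = dups$trait_label[k],
          rsid = src_delta$rsid, beta = bd, se = se_d,
          pval = p_from_z(bd, se_d)
        )
      }
    }
    trait_table <- purrr::list_rbind(trait_rows)

    truth <- list(
      gamma = setNames(gamma, rsid),
      mediator = setNames(m, rsid),
      pleiotropy = setNames(e, rsid),
      delta = delta,
      outliers = rsid[out_idx],
      alpha = setNames(roster$alpha, roster$trait_id),
      trait_roster = roster,
      theta_direct = cfg$theta_direct,
      kappa = cfg$kappa, mu = cfg$mu,
      theta_total = cfg$theta_direct + cfg$kappa * cfg$mu
    )
    structure(
      list(
        exposure = exposure, outcome = outcome, mediator = mediator,
        trait_table = trait_table, truth = truth, config = cfg
      ),
      class = "mr_sim"
    )
  })
}

#' @export
print.mr_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic two-sample MR dataset: %d instruments (%d planted outliers), %d traits, theta_total = %.4f\n",
    x$config$J, x$config$n_outliers,
    dplyr::n_distinct(x$trait_table$trait_id), x$truth$theta_total
  ))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' TSV tables in the dialect [read_sumstats()] reads back, plus the truth
#' as JSON.
#'
#' @param sim an `mr_sim` object from [simulate_gwas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$exposure, file.path(dir, "exposure.tsv"),
    progress = FALSE)
  readr::write_tsv(sim$outcome, file.path(dir, "outcome.tsv"),
    progress = FALSE)
  readr::write_tsv(sim$mediator, file.path(dir, "mediator.tsv"),
    progress = FALSE)
  readr::write_tsv(sim$trait_table, file.path(dir, "trait_table.tsv"),
    progress = FALSE)
  truth <- sim$truth
  truth$delta <- as.list(truth$delta)
  truth$trait_roster <- as.list(truth$trait_roster)
  jsonlite::write_json(
    truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write the deterministic test fixtures
#'
#' Two small, fully deterministic file sets used by the test suite and the
#' documentation:
#' \itemize{
#'   \item `harmonization/` — a hand-built 10-variant exposure/outcome pair
#'     covering identical coding, swapped alleles, strand flips, orientable
#'     and ambiguous palindromes, and an irreconcilable pair, plus a small
#'     LD table;
#'   \item `outlier_scenario/` — a simulated 60-variant dataset with four
#'     planted pleiotropic outliers named rs2080385, rs55872725, rs635634
#'     and rs76895963, strong enough that radial MR flags exactly those
#'     four under the Bonferroni policy.
#' }
#' Re-running overwrites the files with identical content.
#'
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  hdir <- file.path(out_dir, "harmonization")
  dir.create(hdir, showWarnings = FALSE)
  exposure <- tibble::tibble(
    rsid = sprintf("rs%d", 1:10),
    effect_allele = c("A", "A", "C", "A", "A", "A", "A", "C", "A", "T"),
    other_allele = c("G", "C", "T", "C", "T", "T", "T", "G", "G", "G"),
    beta = c(0.10, 0.08, 0.12, 0.09, 0.11, 0.07, 0.13, 0.06, 0.10, 0.09),
    se = c(0.010, 0.009, 0.011, 0.010, 0.012, 0.008, 0.010, 0.009, 0.010, 0.011),
    eaf = c(0.30, 0.60, 0.25, 0.40, 0.20, 0.50, 0.70, 0.45, 0.35, 0.55),
    pval = rep(1e-12, 10),
    n = rep(100000, 10)
  )
  outcome <- tibble::tibble(
    rsid = sprintf("rs%d", 1:10),
    effect_allele = c(
      "A", # rs1 identical coding
      "C", # rs2 swapped coding (A/C in the exposure)
      "G", # rs3 strand flip (C/T -> G/A), aligned
      "G", # rs4 strand flip + swap (A/C -> T/G, coded G/T)
      "A", # rs5 palindromic A/T, orientable (EAFs concordant)
      "A", # rs6 palindromic A/T, ambiguous (EAF ~ 0.5)
      "T", # rs7 palindromic A/T, EAF-discordant -> flipped
      "C", # rs8 palindromic C/G, ambiguous (EAF near 0.5 both studies)
      "A", # rs9 identical coding
      "A"  # rs10 incompatible alleles (T/G vs A/G)
    ),
    other_allele = c("G", "A", "A", "T", "T", "T", "A", "G", "G", "G"),
    beta = c(0.020, 0.015, 0.025, 0.018, 0.022, 0.014, 0.026, 0.012, 0.020, 0.018),
    se = c(0.020, 0.018, 0.022, 0.020, 0.024, 0.016, 0.020, 0.018, 0.020, 0.022),
    eaf = c(0.31, 0.41, 0.26, 0.62, 0.22, 0.48, 0.28, 0.46, 0.36, 0.55),
    pval = rep(0.3, 10),
    n = rep(50000, 10)
  )
  ld <- tibble::tibble(
    rsid_a = c("rs1", "rs1", "rs2"),
    rsid_b = c("rs9", "rs3", "rs4"),
    r2 = c(0.85, 0.0005, 0.4)
  )
  readr::write_tsv(exposure, file.path(hdir, "exposure.tsv"), progress = FALSE)
  readr::write_tsv(outcome, file.path(hdir, "outcome.tsv"), progress = FALSE)
  readr::write_tsv(ld, file.path(hdir, "ld.tsv"), progress = FALSE)

  odir <- file.path(out_dir, "outlier_scenario")
  sim <- simulate_gwas(sim_config(
    J = 60, n_outliers = 4,
    outlier_rsids = c("rs2080385", "rs55872725", "rs635634", "rs76895963"),
    alpha_trait = 0.5, outlier_delta_range = c(1.2, 1.6),
    pleiotropy_mode = "none", trait_instruments = 15,
    seed = 20240602
  ))
  write_sim(sim, odir)

  files <- c(
    file.path("harmonization", c("exposure.tsv", "outcome.tsv", "ld.tsv")),
    file.path("outlier_scenario", c(
      "exposure.tsv", "outcome.tsv", "mediator.tsv", "trait_table.tsv",
      "truth.json"
    ))
  )
  manifest <- list(
    files = lapply(files, function(f) {
      list(
        path = f,
        rows = if (grepl("\\.tsv$", f)) {
          nrow(readr::read_tsv(file.path(out_dir, f),
            show_col_types = FALSE, progress = FALSE
          ))
        } else {
          NA
        }
      )
    })
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
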