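#' Column mappings for GWAS summary-statistic files
#'
#' Builds a named character vector mapping the roles `mrdissect` needs
#' (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pval`, `n`)
#' to the column names used in a particular file dialect. Two presets cover
#' the common cases: `"twosamplemr"` (SNP / effect_allele / ... / samplesize)
#' and `"gwas_catalog"` (variant_id / standard_error / p_value / ...).
#' Individual roles can be overridden on top of any preset.
#'
#' @param preset one of `"default"`, `"twosamplemr"`, `"gwas_catalog"`.
#' @param ... role = "column" overrides, e.g. `rsid = "MarkerName"`.
#' @return named character vector of length 8 (roles as names).
#' @examples
#' sumstats_cols("twosamplemr")
#' sumstats_cols(rsid = "MarkerName", pval = "P")
#' @export
sumstats_cols <- function(preset = c("default", "twosamplemr", "gwas_catalog"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = c(
      rsid = "rsid", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "se",
      eaf = "eaf", pval = "pval", n = "n"
    ),
    twosamplemr = c(
      rsid = "SNP", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "se",
      eaf = "eaf", pval = "pval", n = "samplesize"
    ),
    gwas_catalog = c(
      rsid = "variant_id", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "standard_error",
      eaf = "effect_allele_frequency", pval = "p_value", n = "n"
    )
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) {
      abort(paste0("unknown column roles: ", paste(bad, collapse = ", ")))
    }
    base[names(over)] <- over
  }
  base
}

sumstats_roles_required <- c(
  "rsid", "effect_allele", "other_allele", "beta", "se", "pval"
)

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated summary-statistics file with a header row
#' and returns a tibble in the package's canonical column layout. Alleles are
#' uppercased; rows whose numeric fields fail coercion (or with empty rsid or
#' alleles) are rejected with their row numbers reported in a warning.
#' Missing p-values are recomputed from `beta`/`se` as two-sided normal tail
#' probabilities.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param column_map role-to-column mapping, see [sumstats_cols()].
#' @return a tibble with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `eaf`, `pval`, `n` (the last two may be `NA`).
#' @seealso [harmonize()], [select_instruments()]
#' @export
read_sumstats <- function(path, column_map = sumstats_cols()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, col_types = readr::cols(.default = readr::col_character())
  )
  as_sumstats(raw, column_map = column_map)
}

#' Coerce a data frame of per-variant associations into canonical form
#'
#' The data-frame-first counterpart of [read_sumstats()]: validates and
#' normalizes an in-memory association table.
#'
#' @param x data frame holding one row per variant.
#' @inheritParams read_sumstats
#' @return a canonical sumstats tibble; see [read_sumstats()].
#' @export
as_sumstats <- function(x, column_map = sumstats_cols()) {
  x <- tibble::as_tibble(x)
  for (role in sumstats_roles_required) {
    if (!column_map[[role]] %in% names(x)) {
      abort(paste0(
        "required column for role '", role, "' (mapped to '",
        column_map[[role]], "') is missing"
      ), class = "mrdissect_config_error")
    }
  }
  pick <- function(role) {
    col <- column_map[[role]]
    if (col %in% names(x)) x[[col]] else rep(NA_character_, nrow(x))
  }
  out <- tibble::tibble(
    rsid = as.character(pick("rsid")),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    other_allele = toupper(as.character(pick("other_allele"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    eaf = suppressWarnings(as.numeric(pick("eaf"))),
    pval = suppressWarnings(as.numeric(pick("pval"))),
    n = suppressWarnings(as.numeric(pick("n")))
  )
  bad <- which(
    is.na(out$rsid) | out$rsid == "" |
      is.na(out$effect_allele) | out$effect_allele == "" |
      is.na(out$other_allele) | out$other_allele == "" |
      is.na(out$beta) | is.na(out$se)
  )
  if (length(bad)) {
    warn(paste0(
      "rejected ", length(bad), " row(s) failing type coercion: rows ",
      paste(bad, collapse = ", ")
    ))
    out <- out[-bad, , drop = FALSE]
  }
  if (any(out$se <= 0)) {
    abort(paste0(
      "non-positive standard error for rsid(s): ",
      paste(out$rsid[out$se <= 0], collapse = ", ")
    ), class = "mrdissect_validation_error")
  }
  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  if (any(bad_eaf)) {
    warn(paste0(
      "effect-allele frequency outside [0,1] set to NA for: ",
      paste(out$rsid[bad_eaf], collapse = ", ")
    ))
    out$eaf[bad_eaf] <- NA_real_
  }
  # recompute missing p from beta/se (two-sided normal); reported p is kept
  # where present and used for thresholding only
  miss_p <- is.na(out$pval)
  out$pval[miss_p] <- p_from_z(out$beta[miss_p], out$se[miss_p])
  bad_p <- out$pval <= 0 | out$pval > 1
  if (any(bad_p)) {
    abort(paste0(
      "p-value outside (0, 1] for rsid(s): ",
      paste(out$rsid[bad_p], collapse = ", ")
    ), class = "mrdissect_validation_error")
  }
  out
}

# strand complement of an allele string; returns NA if not pure A/C/G/T
complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_acgt <- function(a) grepl("^[ACGT]+$", a)

is_palindromic <- function(ea, oa) {
  is_acgt(ea) & is_acgt(oa) & complement_allele(ea) == oa
}

#' Harmonize exposure and outcome summary statistics to a common allele frame
#'
#' Joins exposure and outcome association tables by rsid and expresses every
#' outcome effect per copy of the exposure's effect allele. Swapped allele
#' codings are resolved by negating the outcome beta and complementing its
#' EAF; strand flips (A<->T, C<->G complements) are resolved before
#' comparison. Palindromic (A/T, C/G) variants are handled per
#' `palindrome_policy`:
#' \describe{
#'   \item{`"drop_all"`}{every palindromic variant is dropped.}
#'   \item{`"drop_ambiguous"`}{(default) palindromic variants whose EAF lies
#'     within `maf_window` of 0.5 in either study — or whose EAF is missing
#'     in either study — are dropped; the rest are oriented by EAF
#'     concordance (effects flipped when the two EAFs fall on opposite sides
#'     of 0.5).}
#' }
#' Variants whose allele pairs are irreconcilable after strand resolution are
#' excluded (not fatal) and recorded; an empty harmonized set is an error.
#'
#' @param exposure,outcome canonical sumstats tibbles ([read_sumstats()]).
#' @param palindrome_policy `"drop_ambiguous"` or `"drop_all"`.
#' @param maf_window half-width of the ambiguity window around EAF 0.5
#'   (default 0.08) used by `"drop_ambiguous"`.
#' @return a tibble of class `mr_harmonized` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`,
#'   `pval_exp`, `beta_out`, `se_out`, `eaf_out`, `flipped`; dropped variants
#'   and their reasons are available via [harmonization_log()].
#' @examples
#' exp <- tibble::tibble(
#'   rsid = c("rs1", "rs2"), effect_allele = c("A", "G"),
#'   other_allele = c("G", "C"), beta = c(0.1, 0.08), se = c(0.01, 0.01),
#'   eaf = c(0.3, 0.6), pval = c(1e-20, 1e-15), n = NA
#' )
#' out <- exp
#' out$beta <- c(0.02, 0.015)
#' out$se <- c(0.02, 0.02)
#' harmonize(exp, out)
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all"),
                      maf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(maf_window >= 0, maf_window < 0.5)
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)

  joined <- dplyr::inner_join(
    exposure, outcome,
    by = "rsid", suffix = c("_exp", "_out")
  )
  if (nrow(joined) == 0) {
    abort("no shared rsids between exposure and outcome",
      class = "mrdissect_validation_error"
    )
  }

  resolve_row <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y) {
    # returns list(action = keep|flip|drop, reason)
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      # outcome alleles must still name the same variant
      same <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
      if (!same) {
        return(list(action = "drop", reason = "incompatible_alleles"))
      }
      if (palindrome_policy == "drop_all") {
        return(list(action = "drop", reason = "palindromic"))
      }
      if (is.na(eaf_x) || is.na(eaf_y)) {
        return(list(action = "drop", reason = "palindromic_missing_eaf"))
      }
      if (abs(eaf_x - 0.5) < maf_window || abs(eaf_y - 0.5) < maf_window) {
        return(list(action = "drop", reason = "palindromic_ambiguous"))
      }
      # orient by EAF concordance: same side of 0.5 means same allele frame
      concordant <- (eaf_x - 0.5) * (eaf_y - 0.5) > 0
      return(list(
        action = if (concordant) "keep" else "flip",
        reason = NA_character_
      ))
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      return(list(action = "keep", reason = NA_character_))
    }
    if (ea_y == oa_x && oa_y == ea_x) {
      return(list(action = "flip", reason = NA_character_))
    }
    if (is_acgt(ea_y) && is_acgt(oa_y)) {
      cea <- complement_allele(ea_y)
      coa <- complement_allele(oa_y)
      if (cea == ea_x && coa == oa_x) {
        return(list(action = "keep", reason = NA_character_))
      }
      if (cea == oa_x && coa == ea_x) {
        return(list(action = "flip", reason = NA_character_))
      }
    }
    list(action = "drop", reason = "incompatible_alleles")
  }

  res <- purrr::pmap(
    list(
      joined$effect_allele_exp, joined$other_allele_exp,
      joined$effect_allele_out, joined$other_allele_out,
      joined$eaf_exp, joined$eaf_out
    ),
    resolve_row
  )
  action <- purrr::map_chr(res, "action")
  reason <- purrr::map_chr(res, "reason")

  kept <- joined[action != "drop", , drop = FALSE]
  flip <- action[action != "drop"] == "flip"
  hset <- tibble::tibble(
    rsid = kept$rsid,
    effect_allele = kept$effect_allele_exp,
    other_allele = kept$other_allele_exp,
    beta_exp = kept$beta_exp,
    se_exp = kept$se_exp,
    eaf_exp = kept$eaf_exp,
    pval_exp = kept$pval_exp,
    beta_out = ifelse(flip, -kept$beta_out, kept$beta_out),
    se_out = kept$se_out,
    eaf_out = ifelse(flip, 1 - kept$eaf_out, kept$eaf_out),
    flipped = flip
  )
  dropped <- tibble::tibble(
    rsid = joined$rsid[action == "drop"],
    reason = reason[action == "drop"]
  )
  if (nrow(dropped)) {
    inform(paste0(
      "harmonize: dropped ", nrow(dropped), " variant(s): ",
      paste(paste0(dropped$rsid, " (", dropped$reason, ")"), collapse = ", ")
    ))
  }
  if (nrow(hset) == 0) {
    abort("harmonization produced an empty set",
      class = "mrdissect_validation_error"
    )
  }
  structure(hset,
    class = c("mr_harmonized", class(hset)),
    dropped = dropped,
    palindrome_policy = palindrome_policy,
    maf_window = maf_window
  )
}

#' Alignment metadata of a harmonized set
#'
#' @param hset a harmonized set from [harmonize()].
#' @return a tibble of dropped variants with columns `rsid`, `reason`.
#' @export
harmonization_log <- function(hset) {
  attr(hset, "dropped") %||% tibble::tibble(
    rsid = character(), reason = character()
  )
}

#' Write a harmonized set as TSV
#'
#' Fixed column order `rsid, ea, oa, beta_exp, se_exp, beta_out, se_out,
#' flipped, dropped_reason`; variants dropped during harmonization are
#' appended with their reason and NA effects.
#'
#' @param hset a harmonized set from [harmonize()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hset, path) {
  kept <- tibble::tibble(
    rsid = hset$rsid, ea = hset$effect_allele, oa = hset$other_allele,
    beta_exp = hset$beta_exp, se_exp = hset$se_exp,
    beta_out = hset$beta_out, se_out = hset$se_out,
    flipped = hset$flipped, dropped_reason = NA_character_
  )
  drp <- harmonization_log(hset)
  if (nrow(drp)) {
    kept <- dplyr::bind_rows(kept, tibble::tibble(
      rsid = drp$rsid, ea = NA_character_, oa = NA_character_,
      beta_exp = NA_real_, se_exp = NA_real_, beta_out = NA_real_,
      se_out = NA_real_, flipped = NA, dropped_reason = drp$reason
    ))
  }
  readr::write_tsv(kept, path, progress = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three tab-separated columns `rsid_a`, `rsid_b`, `r2`. Pairs absent from
#' the table are treated as r-squared 0 by [select_instruments()].
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `rsid_a`, `rsid_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  ld <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(ld))) {
    abort("LD table must have columns rsid_a, rsid_b, r2",
      class = "mrdissect_config_error"
    )
  }
  if (any(ld$r2 < 0 | ld$r2 > 1)) {
    abort("r2 values must lie in [0, 1]", class = "mrdissect_validation_error")
  }
  ld[, need]
}

#' Select approximately independent genome-wide-significant instruments
#'
#' Greedy clumping on precomputed LD: variants with p below `p_threshold`
#' are visited in ascending p-value order (ties broken lexicographically by
#' rsid) and a variant is retained only if its r-squared with every
#' already-retained variant is below `r2_threshold`. The result is
#' independent of the input row order. LD pairs absent from `ld` are treated
#' as r-squared 0, so `ld = NULL` means the input is assumed pre-clumped and
#' only the p-value filter applies.
#'
#' @param assocs canonical sumstats tibble.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param ld optional LD tibble (`rsid_a`, `rsid_b`, `r2`), see
#'   [read_ld_table()].
#' @param r2_threshold LD independence threshold (default 0.001).
#' @return the retained subset of `assocs`, in selection order.
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  assocs <- tibble::as_tibble(assocs)
  p <- assocs$pval
  miss <- is.na(p)
  p[miss] <- p_from_z(assocs$beta[miss], assocs$se[miss])
  cand <- assocs[p < p_threshold, , drop = FALSE]
  pc <- p[p < p_threshold]
  if (nrow(cand) == 0) {
    abort(paste0(
      "no variants pass p < ", format(p_threshold),
      "; consider relaxing the threshold"
    ), class = "mrdissect_validation_error")
  }
  ord <- order(pc, cand$rsid)
  cand <- cand[ord, , drop = FALSE]

  if (is.null(ld) || nrow(ld) == 0) {
    return(cand)
  }
  # symmetric lookup of r2, absent pairs = 0
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  r2map <- setNames(ld$r2, key(ld$rsid_a, ld$rsid_b))
  kept <- character(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rs <- cand$rsid[i]
    if (length(kept) == 0) {
      take[i] <- TRUE
      kept <- rs
      next
    }
    r2s <- r2map[key(rep(rs, length(kept)), kept)]
    r2s[is.na(r2s)] <- 0
    if (all(r2s < r2_threshold)) {
      take[i] <- TRUE
      kept <- c(kept, rs)
    }
  }
  cand[take, , drop = FALSE]
}
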