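fixture_dir <- withr::local_tempdir(.local_envir = teardown_env())
make_fixtures(fixture_dir)
hdir <- file.path(fixture_dir, "harmonization")

test_that("reading a well-formed file round-trips every field", {
  x <- read_sumstats(file.path(hdir, "exposure.tsv"))
  expect_equal(nrow(x), 10)
  expect_identical(
    names(x),
    c("rsid", "effect_allele", "other_allele", "beta", "se", "eaf", "pval", "n")
  )
  raw <- readr::read_tsv(file.path(hdir, "exposure.tsv"),
    show_col_types = FALSE
  )
  expect_equal(x$beta, raw$beta)
  expect_equal(x$se, raw$se)
  expect_identical(x$rsid, raw$rsid)
})

test_that("column-map dialects and case normalization work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2"), effect_allele = c("a", "g"),
    other_allele = c("t", "c"), beta = c(0.1, -0.2), se = c(0.01, 0.02),
    eaf = c(0.3, 0.4), pval = c(1e-9, 1e-10), samplesize = c(1000, 1000)
  ), f)
  x <- read_sumstats(f, sumstats_cols("twosamplemr"))
  expect_identical(x$effect_allele, c("A", "G"))
  expect_identical(x$other_allele, c("T", "C"))
  expect_equal(x$n, c(1000, 1000))
})

test_that("missing required columns and bad values are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    rsid = "rs1", effect_allele = "A", other_allele = "G", beta = 0.1,
    pval = 0.01
  ), f)
  expect_error(read_sumstats(f), "se", class = "mrdissect_config_error")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    rsid = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = c(0.01, -1), pval = 0.01
  ), f2)
  expect_error(read_sumstats(f2), "rs2", class = "mrdissect_validation_error")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\teffect_allele\tother_allele\tbeta\tse\tpval",
    "rs1\tA\tG\t0.1\t0.01\t1e-9",
    "rs2\tA\tG\tnot_a_number\t0.01\t1e-9"
  ), f3)
  expect_warning(x <- read_sumstats(f3), "rejected 1 row")
  expect_equal(x$rsid, "rs1")
})

test_that("missing p-values are recomputed from beta and se", {
  x <- as_sumstats(tibble::tibble(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.2, se = 0.1, pval = NA
  ))
  expect_equal(x$pval, 2 * pnorm(-2))
})

test_that("harmonization resolves swaps, strand flips and palindromes", {
  exposure <- read_sumstats(file.path(hdir, "exposure.tsv"))
  outcome <- read_sumstats(file.path(hdir, "outcome.tsv"))
  h <- suppressMessages(harmonize(exposure, outcome))

  # identical coding: kept unchanged
  expect_true(all(c("rs1", "rs9") %in% h$rsid))
  expect_false(h$flipped[h$rsid == "rs1"])
  expect_equal(h$beta_out[h$rsid == "rs1"], 0.020)

  # swapped coding: beta negated, EAF complemented
  expect_true(h$flipped[h$rsid == "rs2"])
  expect_equal(h$beta_out[h$rsid == "rs2"], -0.015)
  expect_equal(h$eaf_out[h$rsid == "rs2"], 1 - 0.41)

  # strand flip aligned / strand flip + swap
  expect_false(h$flipped[h$rsid == "rs3"])
  expect_equal(h$beta_out[h$rsid == "rs3"], 0.025)
  expect_true(h$flipped[h$rsid == "rs4"])
  expect_equal(h$beta_out[h$rsid == "rs4"], -0.018)

  # palindromic: concordant kept, discordant flipped, ambiguous dropped
  expect_false(h$flipped[h$rsid == "rs5"])
  expect_true(h$flipped[h$rsid == "rs7"])
  dropped <- harmonization_log(h)
  expect_setequal(
    dropped$rsid[dropped$reason == "palindromic_ambiguous"], c("rs6", "rs8")
  )
  expect_equal(dropped$reason[dropped$rsid == "rs10"], "incompatible_alleles")
})

test_that("drop_all removes every palindromic variant", {
  exposure <- read_sumstats(file.path(hdir, "exposure.tsv"))
  outcome <- read_sumstats(file.path(hdir, "outcome.tsv"))
  h <- suppressMessages(harmonize(exposure, outcome, "drop_all"))
  expect_false(any(c("rs5", "rs6", "rs7", "rs8") %in% h$rsid))
  expect_setequal(
    harmonization_log(h)$rsid[harmonization_log(h)$reason == "palindromic"],
    c("rs5", "rs6", "rs7", "rs8")
  )
})

test_that("palindromic variants with missing EAF are dropped", {
  exposure <- tibble::tibble(
    rsid = "rs1", effect_allele = "A", other_allele = "T",
    beta = 0.1, se = 0.01, eaf = NA_real_, pval = 1e-10
  )
  h_err <- tryCatch(
    suppressMessages(harmonize(exposure, exposure)),
    error = function(e) e
  )
  expect_s3_class(h_err, "error") # the only variant drops -> empty set
})

test_that("harmonization against itself is the identity with zero flips", {
  exposure <- read_sumstats(file.path(hdir, "exposure.tsv"))
  h <- suppressMessages(harmonize(exposure, exposure))
  expect_false(any(h$flipped))
  expect_equal(h$beta_out, h$beta_exp)
  # only the ambiguous palindromes may drop
  expect_true(all(
    harmonization_log(h)$reason == "palindromic_ambiguous"
  ))
})

test_that("applying the allele flip twice restores the original signs", {
  exposure <- read_sumstats(file.path(hdir, "exposure.tsv"))
  outcome <- read_sumstats(file.path(hdir, "outcome.tsv"))
  swapped <- outcome
  swapped$effect_allele <- outcome$other_allele
  swapped$other_allele <- outcome$effect_allele
  swapped$beta <- -outcome$beta
  swapped$eaf <- 1 - outcome$eaf
  h1 <- suppressMessages(harmonize(exposure, outcome))
  h2 <- suppressMessages(harmonize(exposure, swapped))
  shared <- intersect(h1$rsid, h2$rsid)
  expect_equal(
    h1$beta_out[match(shared, h1$rsid)],
    h2$beta_out[match(shared, h2$rsid)]
  )
})

test_that("instrument selection applies thresholds and greedy clumping", {
  mk <- function(rsid, pval) {
    tibble::tibble(
      rsid = rsid, effect_allele = "A", other_allele = "G",
      beta = 0.1, se = 0.01, eaf = 0.3, pval = pval
    )
  }
  # independent variants all retained
  a <- mk(c("rs1", "rs2", "rs3"), rep(1e-9, 3))
  expect_equal(nrow(select_instruments(a)), 3)

  # correlated pair: only the smaller p survives
  b <- mk(c("rs1", "rs2"), c(1e-10, 1e-9))
  ld <- tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.5)
  kept <- select_instruments(b, ld = ld)
  expect_identical(kept$rsid, "rs1")

  # threshold is strict
  c3 <- mk(c("rs1", "rs2"), c(1e-9, 6e-8))
  expect_identical(select_instruments(c3)$rsid, "rs1")

  # empty result is fatal
  expect_error(
    select_instruments(mk("rs1", 1e-4)),
    class = "mrdissect_validation_error"
  )
})

test_that("instrument selection is invariant to input row order", {
  withr::with_seed(11, {
    J <- 30
    tab <- tibble::tibble(
      rsid = sprintf("rs%02d", seq_len(J)), effect_allele = "A",
      other_allele = "G", beta = 0.1, se = 0.01, eaf = 0.3,
      pval = 10^runif(J, -12, -8)
    )
    pairs <- t(utils::combn(tab$rsid, 2))
    ld <- tibble::tibble(
      rsid_a = pairs[, 1], rsid_b = pairs[, 2],
      r2 = sample(c(0, 0.5), nrow(pairs), replace = TRUE, prob = c(0.8, 0.2))
    )
    ref <- select_instruments(tab, ld = ld)
    for (i in 1:5) {
      shuffled <- tab[sample(J), , drop = FALSE]
      expect_identical(sort(select_instruments(shuffled, ld = ld)$rsid),
        sort(ref$rsid))
    }
  })
})

test_that("harmonized sets serialize with dropped variants and reasons", {
  exposure <- read_sumstats(file.path(hdir, "exposure.tsv"))
  outcome <- read_sumstats(file.path(hdir, "outcome.tsv"))
  h <- suppressMessages(harmonize(exposure, outcome))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_identical(
    names(back),
    c("rsid", "ea", "oa", "beta_exp", "se_exp", "beta_out", "se_out",
      "flipped", "dropped_reason")
  )
  expect_equal(sum(!is.na(back$dropped_reason)), nrow(harmonization_log(h)))
})
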