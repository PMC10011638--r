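# Allele harmonization: sign flips, strand flips, palindromic policy.

exposure_one <- function(ea = "A", oa = "G", beta = 0.1, eaf = 0.3) {
  df <- make_sumstats_df(1)
  df$EA <- ea; df$OA <- oa; df$BETA <- beta; df$EAF <- eaf
  ss <- sumstat_set(df, "exp")
  clump(ss, ld_identity(df$SNP))
}

outcome_one <- function(ea, oa, beta = 0.05, eaf = 0.3, rsid = "rs1") {
  df <- make_sumstats_df(1)
  df$SNP <- rsid; df$EA <- ea; df$OA <- oa; df$BETA <- beta; df$EAF <- eaf
  sumstat_set(df, "out")
}

test_that("swapped outcome alleles are sign-flipped", {
  h <- harmonize(exposure_one("A", "G", 0.1), outcome_one("G", "A", 0.05, eaf = 0.7))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$beta_y, -0.05)
  expect_equal(h$eaf_y, 0.3)
})

test_that("strand-complemented alleles are recognized, with and without swap", {
  h <- harmonize(exposure_one("A", "G"), outcome_one("T", "C", 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_y, 0.05)

  h2 <- harmonize(exposure_one("A", "G"), outcome_one("C", "T", 0.05, eaf = 0.7))
  expect_equal(h2$action, "strand_flipped")
  expect_equal(h2$beta_y, -0.05)
})

test_that("palindromic variants follow the frequency-band policy", {
  # dead centre of the band: ambiguous
  h <- harmonize(exposure_one("A", "T", eaf = 0.5), outcome_one("A", "T", eaf = 0.5))
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "palindromic_ambiguous")

  # missing frequency: ambiguous
  h2 <- harmonize(exposure_one("A", "T", eaf = NA), outcome_one("A", "T", eaf = 0.2))
  expect_equal(h2$drop_reason, "palindromic_ambiguous")

  # concordant sides outside the band: kept unchanged
  h3 <- harmonize(exposure_one("C", "G", eaf = 0.2), outcome_one("C", "G", 0.05, eaf = 0.25))
  expect_equal(h3$action, "kept")
  expect_equal(h3$beta_y, 0.05)

  # discordant sides: outcome inferred on the other strand, effect flipped
  h4 <- harmonize(exposure_one("C", "G", eaf = 0.2), outcome_one("C", "G", 0.05, eaf = 0.8))
  expect_equal(h4$action, "strand_flipped")
  expect_equal(h4$beta_y, -0.05)
})

test_that("missing and incompatible outcome records become reasoned drops", {
  h <- harmonize(exposure_one(), outcome_one("A", "G", rsid = "rs999"))
  expect_equal(h$drop_reason, "missing_in_outcome")
  h2 <- harmonize(exposure_one("A", "G"), outcome_one("A", "C"))
  expect_equal(h2$drop_reason, "incompatible_alleles")
  expect_equal(attr(h2, "n_kept") + attr(h2, "n_dropped"), nrow(h2))
})

test_that("duplicate outcome rsids resolve to the smallest standard error", {
  df <- rbind(make_sumstats_df(1), make_sumstats_df(1))
  df$SE <- c(0.05, 0.01)
  df$BETA <- c(0.9, 0.05)
  out <- suppressWarnings(
    sumstat_set(within(df, SNP <- c("rs1", "rs1b")), "out"))
  out$SNP <- c("rs1", "rs1")  # same rsid, two rows
  h <- harmonize(exposure_one(), out)
  expect_equal(h$beta_y, 0.05)
  expect_equal(h$se_y, 0.01)
})

test_that("harmonization is idempotent on an aligned pair", {
  st <- generate_study(synthetic_truth(theta = 0.2, j = 30, seed = 5))
  inst <- clump(st$exposure, st$ld)
  h1 <- kept_records(harmonize(inst, st$outcome))
  # re-harmonize the already-aligned pair: identical kept effects
  h2 <- kept_records(harmonize(inst, st$outcome))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
  expect_true(all(h1$action == "kept"))
})

test_that("orient_positive negates jointly and preserves Wald ratios", {
  rec <- make_records(beta_x = c(0.2, -0.2), beta_y = c(0.1, 0.1),
                      se_y = c(0.05, 0.05))
  h <- mrflow:::harmonized_set(
    cbind(rec, eaf_x = 0.3, eaf_y = 0.3, action = "kept", drop_reason = ""))
  o <- orient_positive(h)
  expect_equal(o$beta_x, c(0.2, 0.2))
  expect_equal(o$beta_y, c(0.1, -0.1))
  expect_equal(wald_ratio(h)$ratio, wald_ratio(o)$ratio)
  # already-positive sets are untouched
  expect_equal(as.data.frame(orient_positive(o)), as.data.frame(o))
})

test_that("harmonize exactly inverts allele scrambling for non-palindromic SNPs", {
  st <- generate_study(synthetic_truth(theta = 0.3, j = 40, palindrome_frac = 0.2,
                                       seed = 9))
  scr <- scramble_alleles(st, swap_frac = 0.4, strand_frac = 0.3, seed = 10)
  inst <- clump(st$exposure, st$ld)
  h <- harmonize(inst, scr$outcome)
  pal <- mrflow:::is_palindromic(st$exposure$EA, st$exposure$OA)
  original <- st$outcome$BETA
  names(original) <- st$outcome$SNP
  kept <- as.data.frame(kept_records(h))
  nonpal <- kept[kept$rsid %in% st$exposure$SNP[!pal], ]
  expect_gt(nrow(nonpal), 0)
  expect_equal(nonpal$beta_y, unname(original[nonpal$rsid]))
})

test_that("scrambling with zero fractions is the identity", {
  st <- generate_study(synthetic_truth(j = 10, seed = 3))
  scr <- scramble_alleles(st, 0, 0, seed = 4)
  out <- scr$outcome
  attr(out, "scrambled") <- NULL
  expect_equal(as.data.frame(out), as.data.frame(st$outcome))
})

test_that("the harmonization audit log is written with rsid, action, reason", {
  st <- generate_study(synthetic_truth(j = 12, seed = 6))
  h <- harmonize(clump(st$exposure, st$ld), st$outcome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonization_log(h, path)
  log <- read.delim(path)
  expect_equal(names(log), c("rsid", "action", "drop_reason"))
  expect_equal(nrow(log), nrow(h))
})
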