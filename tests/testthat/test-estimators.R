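# Causal-effect estimators against arithmetic examples and independently
# coded weighted-least-squares / interpolation oracles.

test_that("Wald ratios follow the first-order delta method", {
  r <- wald_ratio(make_records(0.5, 0.25, 0.1))
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(r$weight, 1 / 0.2^2)

  r0 <- wald_ratio(make_records(0.5, 0, 0.1))
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se, 0.2)

  # orientation invariance under joint negation
  a <- wald_ratio(make_records(0.4, -0.1, 0.05))
  b <- wald_ratio(make_records(-0.4, 0.1, 0.05))
  expect_equal(a[c("ratio", "se", "weight")], b[c("ratio", "se", "weight")])

  expect_error(wald_ratio(make_records(0, 0.1, 0.05)), "beta_x = 0")
})

test_that("IVW combines ratios by inverse variance; equal weights give the mean", {
  rec <- make_ratio_records(c(1, 3), c(1, 1))
  fe <- mr_ivw(rec, "fixed")
  expect_equal(fe$estimate, 2.0)
  expect_equal(fe$se, 1 / sqrt(2), tolerance = 1e-10)

  # homogeneous limit: Q = 0, random se equals fixed se
  hom <- make_ratio_records(rep(1.5, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(mr_ivw(hom, "fixed")$estimate, 1.5)
  expect_equal(mr_ivw(hom, "random")$se, mr_ivw(hom, "fixed")$se)
})

test_that("IVW-FE equals WLS through the origin on random instances", {
  for (seed in 1:20) {
    rec <- random_records(20, seed)
    fit <- mr_ivw(rec, "fixed")
    oracle <- oracle_wls_origin(rec$beta_x, rec$beta_y, 1 / rec$se_y^2)
    expect_equal(fit$estimate, oracle$slope, tolerance = 1e-8)
    expect_equal(fit$se, oracle$se_fe, tolerance = 1e-8)
  }
})

test_that("IVW-RE shares the FE point estimate and never shrinks the se", {
  for (seed in 21:35) {
    rec <- random_records(15, seed)
    fe <- mr_ivw(rec, "fixed"); re <- mr_ivw(rec, "random")
    expect_equal(re$estimate, fe$estimate)
    expect_gte(re$se, fe$se)
    q <- cochran_q(rec)
    if (q$q <= q$df) expect_equal(re$se, fe$se)
    else expect_equal(re$se, fe$se * sqrt(q$q / q$df), tolerance = 1e-10)
  }
})

test_that("estimators are permutation- and joint-sign-flip-invariant", {
  rec <- random_records(12, 99)
  perm <- rec[sample(nrow(rec)), ]
  flip <- rec
  flip[c(2, 5), c("beta_x", "beta_y")] <- -flip[c(2, 5), c("beta_x", "beta_y")]
  for (variant in list(perm, flip)) {
    expect_equal(mr_ivw(variant, "fixed")$estimate, mr_ivw(rec, "fixed")$estimate)
    expect_equal(mr_egger(variant)$result$estimate, mr_egger(rec)$result$estimate,
                 tolerance = 1e-12)
    expect_equal(
      mr_weighted_median(variant, n_boot = 50, seed = 1)$estimate,
      mr_weighted_median(rec, n_boot = 50, seed = 1)$estimate)
  }
})

test_that("a single instrument collapses IVW to the Wald ratio with a warning", {
  rec <- make_records(0.5, 0.25, 0.1)
  expect_warning(fit <- mr_ivw(rec, "fixed"), "single instrument")
  expect_equal(fit$estimate, mr_wald(rec)$estimate)
  expect_equal(fit$se, mr_wald(rec)$se)
})

test_that("MR-Egger recovers an exact affine relationship and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  exact <- make_records(bx, 0.1 + 0.5 * bx, se_y = rep(0.05, 5))
  fit <- mr_egger(exact)
  expect_equal(fit$result$estimate, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-10)

  for (seed in 41:60) {
    rec <- random_records(20, seed)
    rec$beta_x <- abs(rec$beta_x)
    fit <- mr_egger(rec)
    oracle <- oracle_wls_intercept(rec$beta_x, rec$beta_y, 1 / rec$se_y^2)
    expect_equal(fit$result$estimate, oracle$slope, tolerance = 1e-8)
    expect_equal(fit$intercept$intercept, oracle$intercept, tolerance = 1e-8)
    expect_equal(fit$result$se, oracle$se_slope, tolerance = 1e-8)
    expect_equal(fit$intercept$se, oracle$se_intercept, tolerance = 1e-8)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  }
})

test_that("Egger with the intercept constrained to zero is IVW-FE", {
  rec <- random_records(15, 70)
  rec$beta_x <- abs(rec$beta_x)
  fit0 <- mrflow:::wls_fit(rec$beta_x, rec$beta_y, 1 / rec$se_y^2,
                           intercept = FALSE)
  expect_equal(unname(fit0$coef[1]), mr_ivw(rec, "fixed")$estimate,
               tolerance = 1e-10)
})

test_that("Egger requires at least three instruments", {
  expect_error(mr_egger(random_records(2, 1)), "at least 3")
})

test_that("weighted median interpolates cumulative weights and matches the oracle", {
  eq <- make_ratio_records(c(1, 2, 3), rep(1, 3))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$estimate, 2)

  conc <- make_ratio_records(c(0.5, 5, 6), c(0.001, 10, 10))
  expect_equal(mr_weighted_median(conc, n_boot = 50, seed = 1)$estimate, 0.5,
               tolerance = 1e-6)

  for (seed in 61:75) {
    rec <- random_records(15, seed)
    r <- wald_ratio(rec)
    expect_equal(mr_weighted_median(rec, n_boot = 2, seed = 1)$estimate,
                 oracle_weighted_median(r$ratio, r$weight), tolerance = 1e-10)
  }
})

test_that("weighted median bootstrap is seed-reproducible and seed-sensitive", {
  rec <- random_records(10, 80)
  a <- mr_weighted_median(rec, n_boot = 200, seed = 5)
  b <- mr_weighted_median(rec, n_boot = 200, seed = 5)
  c <- mr_weighted_median(rec, n_boot = 200, seed = 6)
  expect_equal(a$se, b$se)
  expect_false(isTRUE(all.equal(a$se, c$se)))
  expect_error(mr_weighted_median(rec, n_boot = 10), "seed")
})

test_that("penalized IVW reduces to IVW when homogeneous and tames outliers", {
  hom <- make_ratio_records(rep(0.8, 5), rep(0.1, 5))
  expect_equal(mr_ivw_penalized(hom)$estimate, mr_ivw(hom, "fixed")$estimate)

  ratios <- c(rep(0.2, 10), 5)
  rec <- make_ratio_records(ratios, rep(0.05, 11))
  plain <- mr_ivw(rec, "fixed")$estimate
  pen <- mr_ivw_penalized(rec)$estimate
  expect_lt(abs(pen - 0.2), abs(plain - 0.2))

  # penalized weights never exceed the originals
  r <- wald_ratio(rec)
  est0 <- sum(r$weight * r$ratio) / sum(r$weight)
  pj <- pchisq(r$weight * (r$ratio - est0)^2, 1, lower.tail = FALSE)
  expect_true(all(r$weight * pmin(1, 20 * pj) <= r$weight))
})

test_that("binary outcomes add the exponentiated odds-ratio scale exactly", {
  rec <- random_records(10, 90)
  fit <- mr_ivw(rec, "random", outcome_type = "binary")
  expect_equal(fit$or, exp(fit$estimate))
  expect_equal(fit$or_ci_low, exp(fit$ci_low))
  expect_equal(fit$or_ci_high, exp(fit$ci_high))
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
})
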