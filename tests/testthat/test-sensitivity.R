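# Heterogeneity and pleiotropy diagnostics.

test_that("Cochran's Q matches its algebraic identity and decomposes exactly", {
  ident <- make_ratio_records(rep(1.2, 5), rep(0.2, 5))
  q0 <- cochran_q(ident)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)

  two <- make_ratio_records(c(0, 2), c(1, 1))
  expect_equal(cochran_q(two)$q, 2)

  for (seed in 1:10) {
    rec <- random_records(20, seed)
    r <- wald_ratio(rec)
    w <- r$weight
    q_identity <- sum(w * r$ratio^2) - sum(w * r$ratio)^2 / sum(w)
    out <- cochran_q(rec)
    expect_equal(out$q, q_identity, tolerance = 1e-9)
    expect_equal(sum(attr(out, "contributions")$q), out$q, tolerance = 1e-12)
    expect_equal(out$df, 19)
  }
  expect_error(cochran_q(make_ratio_records(1, 1)), "at least 2")
})

test_that("Ruecker's Q is the Egger weighted RSS and never exceeds Cochran's Q", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  exact <- make_records(bx, 0.05 + 0.4 * bx, se_y = rep(0.03, 4))
  expect_equal(rucker_q(exact)$q, 0, tolerance = 1e-10)

  for (seed in 11:30) {
    rec <- random_records(20, seed)
    rec$beta_x <- abs(rec$beta_x)
    rq <- rucker_q(rec)
    cq <- cochran_q(rec)
    expect_equal(rq$q, oracle_wls_intercept(rec$beta_x, rec$beta_y,
                                            1 / rec$se_y^2)$rss,
                 tolerance = 1e-8)
    expect_lte(rq$q, cq$q + 1e-12)
    expect_equal(rq$df, 18)
  }
})

test_that("the Egger intercept detects a forced directional offset", {
  bx <- seq(0.1, 0.5, length.out = 6)
  noise <- mrflow:::with_seed(4, rnorm(6, 0, 1e-6))
  rec <- make_records(bx, 0.1 + 0.5 * bx + noise, se_y = rep(1e-4, 6))
  out <- egger_intercept_test(rec)
  expect_lt(out$pval, 1e-6)
  expect_equal(out$intercept, 0.1, tolerance = 1e-3)
})

test_that("MR-PRESSO is seed-reproducible and its empirical p has the smoothing floor", {
  rec <- random_records(10, 31)
  a <- mr_presso(rec, n_sim = 200, seed = 5)
  b <- mr_presso(rec, n_sim = 200, seed = 5)
  expect_equal(a[names(a) != "seed"], b[names(b) != "seed"])
  expect_gte(a$global_pval, 1 / 201)
  expect_true(all(a$outlier_pvals >= 1 / 201))
  expect_error(mr_presso(random_records(3, 1), seed = 1), "at least 4")
})

test_that("MR-PRESSO passes clean instruments and flags an injected outlier", {
  st <- generate_study(synthetic_truth(theta = 0.2, j = 20, seed = 77))
  h <- kept_records(harmonize(clump(st$exposure, st$ld), st$outcome))
  clean <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_gt(clean$global_pval, 0.05)
  expect_length(clean$outlier_indices, 0)
  expect_true(is.na(clean$distortion_pval))

  # add one instrument whose pleiotropic offset is 10x the ratio spread
  r <- wald_ratio(h)
  offset <- 10 * diff(range(r$ratio))
  df <- as.data.frame(h)[c("rsid", "beta_x", "se_x", "beta_y", "se_y")]
  out_row <- df[1, ]
  out_row$rsid <- "rs_outlier"
  out_row$beta_y <- out_row$beta_y + offset * out_row$beta_x
  dirty <- rbind(df, out_row)
  flagged <- mr_presso(dirty, n_sim = 1000, seed = 11)
  expect_true("rs_outlier" %in% flagged$outlier_rsids)
  expect_lt(flagged$global_pval, 0.05)
  # removal moves the estimate back toward the clean consensus
  expect_lt(abs(flagged$estimate_after - clean$estimate_before),
            abs(flagged$estimate_before - clean$estimate_before))
  expect_false(is.na(flagged$distortion_pval))
})

test_that("leave-one-out produces J entries of J-1 instruments and finds influence", {
  ident <- make_ratio_records(rep(0.7, 5), rep(0.1, 5))
  loo <- leave_one_out(ident)
  expect_equal(nrow(loo), 5)
  expect_true(all(loo$n_snp == 4))
  expect_true(all(abs(loo$estimate - 0.7) < 1e-12))

  three <- random_records(3, 50)
  expect_equal(nrow(leave_one_out(three)), 3)

  # two-cluster instance: dropping the heavy outlier moves the estimate
  # toward the consensus cluster
  rec <- make_ratio_records(c(rep(0.1, 6), 3), c(rep(0.2, 6), 0.05))
  loo2 <- leave_one_out(rec)
  full <- mr_ivw(rec, "random")$estimate
  drop_out <- loo2$estimate[loo2$rsid_left_out == "s007"]
  expect_lt(abs(drop_out - 0.1), abs(full - 0.1))
})

test_that("funnel tables carry ratio, precision and the combined reference", {
  rec <- random_records(5, 60)
  combined <- mr_ivw(rec, "random")
  fd <- funnel_data(rec, combined)
  expect_equal(nrow(fd), 5)
  expect_true(all(fd$precision > 0))
  expect_equal(unique(fd$combined_estimate), combined$estimate)

  one <- make_records(0.3, 0.1, 0.05)
  fd1 <- funnel_data(one, mr_wald(one))
  expect_equal(nrow(fd1), 1)

  # constructed symmetric set: signed deviations about the combined
  # estimate cancel
  sym <- make_ratio_records(0.5 + c(-0.2, -0.1, 0, 0.1, 0.2), rep(0.1, 5))
  fds <- funnel_data(sym, mr_ivw(sym, "fixed"))
  expect_equal(mean(fds$ratio - fds$combined_estimate), 0, tolerance = 1e-12)
})

test_that("diagnostics are permutation-invariant in the instruments", {
  rec <- random_records(12, 70)
  perm <- rec[c(5, 1, 9, 12, 2, 7, 3, 11, 4, 10, 6, 8), ]
  expect_equal(cochran_q(perm)$q, cochran_q(rec)$q, tolerance = 1e-12)
  expect_equal(rucker_q(perm)$q, rucker_q(rec)$q, tolerance = 1e-10)
  expect_equal(egger_intercept_test(perm)$pval, egger_intercept_test(rec)$pval,
               tolerance = 1e-10)
})
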