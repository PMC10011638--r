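# Heterogeneity and pleiotropy diagnostics: Cochran's and Ruecker's Q,
# the Egger intercept test, MR-PRESSO outlier detection, leave-one-out
# influence analysis, and funnel-plot tables.

#' Cochran's Q heterogeneity statistic (IVW model)
#'
#' \code{Q = sum w_j (ratio_j - theta_IVW)^2} with \code{J - 1} degrees of
#' freedom and an upper-tail chi-square p-value. P below 0.05 is the
#' conventional signal that per-SNP causal effects are heterogeneous, in
#' which case the multiplicative random-effects IVW (and penalized IVW)
#' are the appropriate summaries.
#'
#' @inheritParams wald_ratio
#' @return data frame: \code{statistic} (\code{"cochran_ivw"}), \code{q},
#'   \code{df}, \code{pval}, plus attribute \code{contributions} (per-SNP
#'   q_j, summing exactly to Q).
#' @export
cochran_q <- function(records) {
  r <- wald_ratio(records)
  if (nrow(r) < 2) stop("Cochran's Q needs at least 2 instruments")
  w <- r$weight
  est <- sum(w * r$ratio) / sum(w)
  qj <- w * (r$ratio - est)^2
  q <- sum(qj)
  df <- nrow(r) - 1
  out <- data.frame(statistic = "cochran_ivw", q = q, df = df,
                    pval = stats::pchisq(q, df, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "contributions") <- data.frame(rsid = r$rsid, q = qj,
                                           stringsAsFactors = FALSE)
  out
}

#' Ruecker's Q heterogeneity statistic (MR-Egger model)
#'
#' The weighted residual sum of squares about the Egger fit,
#' \code{Q' = sum w_j (beta_y_j - a - theta b_x_j)^2}, with \code{J - 2}
#' degrees of freedom. Because the intercept can only reduce weighted
#' residuals, \code{Q' <= Q} on every dataset.
#'
#' @inheritParams mr_egger
#' @return data frame: \code{statistic} (\code{"rucker_egger"}), \code{q},
#'   \code{df}, \code{pval}.
#' @export
rucker_q <- function(records) {
  fit <- mr_egger(records)
  j <- fit$result$n_snp
  data.frame(statistic = "rucker_egger", q = fit$rss, df = j - 2,
             pval = stats::pchisq(fit$rss, j - 2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; a deviation
#' from zero indicates directional pleiotropy. Two-sided t test with
#' \code{J - 2} degrees of freedom. Note the known limitation: directional
#' pleiotropy that is correlated with instrument strength (an InSIDE
#' violation) is absorbed into the slope and escapes this test.
#'
#' @inheritParams mr_egger
#' @return data frame: \code{intercept}, \code{se}, \code{pval}.
#' @export
egger_intercept_test <- function(records) {
  mr_egger(records)$intercept
}

# IVW slope of beta_y on beta_x through the origin (weights 1/se_y^2),
# identical to the IVW ratio combination under first-order Wald SEs.
ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontally pleiotropic instruments by comparing each SNP's
#' observed outcome effect with the effect expected from the IVW slope
#' fitted on the other SNPs (leave-one-out expectation). The observed
#' weighted residual sum of squares is referred to a simulated null in
#' which, \code{n_sim} times, exposure and outcome effects are redrawn
#' from normals centred on the observed (respectively fitted) values with
#' the observed standard errors and the RSS recomputed.
#'
#' Empirical p-values use (count + 1)/(n_sim + 1) smoothing, so the floor
#' is 1/(n_sim + 1) and zero is never reported. Per-SNP outlier p-values
#' come from each SNP's own simulated residual distribution and are
#' flagged at the Bonferroni-adjusted level \code{outlier_alpha / J}. When
#' outliers are flagged, the distortion test reports the two-sided
#' empirical probability, under random removal of as many SNPs, of an IVW
#' estimate shift at least as large as the observed one; with no flagged
#' outliers it is \code{NA}.
#'
#' @inheritParams mr_wald
#' @param n_sim simulated null datasets (>= 100; default 1000).
#' @param outlier_alpha significance level for the outlier test (default
#'   0.05, Bonferroni-adjusted across instruments).
#' @param seed integer seed (required; the test is simulation-based).
#' @return an object of class \code{presso_result}: list with
#'   \code{rss_obs}, \code{global_pval}, \code{outlier_pvals},
#'   \code{outlier_indices}, \code{outlier_rsids}, \code{distortion_pval},
#'   \code{estimate_before}, \code{estimate_after}, \code{n_sim},
#'   \code{seed}.
#' @export
mr_presso <- function(records, n_sim = 1000, outlier_alpha = 0.05, seed) {
  df <- ratio_input(records)
  j <- nrow(df)
  if (j < 4) stop("MR-PRESSO needs at least 4 instruments; got ", j)
  stopifnot(is_scalar_number(n_sim), n_sim >= 100,
            is_scalar_number(outlier_alpha), outlier_alpha > 0, outlier_alpha < 1)
  if (missing(seed)) stop("mr_presso requires an explicit seed")
  if (any(df$se_x <= 0) || any(is.na(df$se_x)))
    stop("MR-PRESSO needs positive exposure standard errors")

  bx <- df$beta_x; by <- df$beta_y; sx <- df$se_x; sy <- df$se_y
  w <- 1 / sy^2

  # leave-one-out slopes via sufficient statistics
  swxy <- sum(w * bx * by); swxx <- sum(w * bx^2)
  loo_slope <- (swxy - w * bx * by) / (swxx - w * bx^2)
  resid_obs <- by - bx * loo_slope
  rss_terms_obs <- w * resid_obs^2
  rss_obs <- sum(rss_terms_obs)

  sims <- with_seed(seed, {
    BX <- matrix(stats::rnorm(n_sim * j, mean = rep(bx, each = n_sim),
                              sd = rep(sx, each = n_sim)), nrow = n_sim)
    # no-pleiotropy null: expected outcome effect from the LOO slope
    BY <- matrix(stats::rnorm(n_sim * j, mean = rep(bx * loo_slope, each = n_sim),
                              sd = rep(sy, each = n_sim)), nrow = n_sim)
    W <- matrix(w, nrow = n_sim, ncol = j, byrow = TRUE)
    SWXY <- rowSums(W * BX * BY); SWXX <- rowSums(W * BX^2)
    LOOS <- (SWXY - W * BX * BY) / (SWXX - W * BX^2)
    RES <- BY - BX * LOOS
    TERMS <- W * RES^2
    list(rss = rowSums(TERMS), terms = TERMS)
  })

  global_pval <- (sum(sims$rss >= rss_obs) + 1) / (n_sim + 1)
  outlier_pvals <- vapply(seq_len(j), function(k) {
    (sum(sims$terms[, k] >= rss_terms_obs[k]) + 1) / (n_sim + 1)
  }, numeric(1))
  outlier_indices <- which(outlier_pvals < outlier_alpha / j)

  estimate_before <- ivw_slope(bx, by, w)
  estimate_after <- NA_real_
  distortion_pval <- NA_real_
  if (length(outlier_indices) > 0 && length(outlier_indices) < j) {
    keep <- setdiff(seq_len(j), outlier_indices)
    estimate_after <- ivw_slope(bx[keep], by[keep], w[keep])
    d_obs <- estimate_before - estimate_after
    d_sim <- with_seed(child_seed(seed, 1), {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(j, length(outlier_indices))
        kk <- setdiff(seq_len(j), drop_idx)
        estimate_before - ivw_slope(bx[kk], by[kk], w[kk])
      }, numeric(1))
    })
    distortion_pval <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
  }

  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 outlier_pvals = outlier_pvals,
                 outlier_indices = outlier_indices,
                 outlier_rsids = df$rsid[outlier_indices],
                 distortion_pval = distortion_pval,
                 estimate_before = estimate_before,
                 estimate_after = estimate_after,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS = %.4g, global p = %.4g (n_sim = %d)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_indices))
    cat("outliers:", paste(x$outlier_rsids, collapse = ", "),
        sprintf("(distortion p = %.4g)\n", x$distortion_pval))
  else cat("no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out analysis (IVW random effects)
#'
#' Refits the multiplicative random-effects IVW estimator J times, each
#' omitting one instrument, to expose single-SNP influence. An entry is
#' flagged when dropping that SNP overturns the full-set conclusion: the
#' leave-one-out confidence interval lies entirely on the other side of
#' zero, or loses/gains significance relative to the full-set interval's
#' sign conclusion.
#'
#' @inheritParams mr_wald
#' @return data frame with one row per left-out rsid: \code{rsid_left_out},
#'   \code{n_snp}, \code{estimate}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{pval}, \code{flagged}.
#' @export
leave_one_out <- function(records, outcome_type = outcome_type_of(records)) {
  df <- ratio_input(records)
  if (nrow(df) < 3) stop("leave-one-out needs at least 3 instruments")
  full <- mr_ivw(df, mode = "random", outcome_type = outcome_type)
  full_sig <- full$ci_low > 0 || full$ci_high < 0
  full_sign <- sign(full$estimate)
  rows <- lapply(seq_len(nrow(df)), function(k) {
    fit <- mr_ivw(df[-k, , drop = FALSE], mode = "random",
                  outcome_type = outcome_type)
    loo_sig <- fit$ci_low > 0 || fit$ci_high < 0
    flagged <- if (full_sig) !(loo_sig && sign(fit$estimate) == full_sign)
               else loo_sig
    data.frame(rsid_left_out = df$rsid[k], n_snp = fit$n_snp,
               estimate = fit$estimate, se = fit$se, ci_low = fit$ci_low,
               ci_high = fit$ci_high, pval = fit$pval, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Funnel-plot table
#'
#' Emits the plottable columns for the standard MR funnel diagnostic: each
#' instrument's ratio estimate against its precision (1/se), with the
#' combined estimate as the reference line. Symmetry is assessed visually;
#' no statistic is computed.
#'
#' @inheritParams wald_ratio
#' @param combined an \code{mr_result} row giving the combined estimate.
#' @return data frame: \code{rsid}, \code{ratio}, \code{precision},
#'   \code{combined_estimate}.
#' @export
funnel_data <- function(records, combined) {
  r <- wald_ratio(records)
  if (nrow(r) == 0) stop("funnel_data needs at least one instrument")
  stopifnot(inherits(combined, "mr_result"))
  data.frame(rsid = r$rsid, ratio = r$ratio, precision = 1 / r$se,
             combined_estimate = combined$estimate, stringsAsFactors = FALSE)
}
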