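# Causal-effect estimators for two-sample MR: per-SNP Wald ratios and the
# combined IVW (fixed and multiplicative random effects), MR-Egger,
# weighted-median and penalized-IVW estimators.
#
# Throughout, ratio standard errors use the first-order delta method
# (se_y / |beta_x|), ignoring exposure-side uncertainty. Under this
# convention IVW-FE is exactly weighted least squares of beta_y on beta_x
# through the origin with weights 1/se_y^2, which the test suite exploits
# as an independent oracle.

#' Per-SNP Wald ratio estimates
#'
#' The ratio of the outcome to the exposure association, with first-order
#' delta-method standard error and inverse-variance weight.
#'
#' @param records a \code{harmonized_set} (dropped records are ignored) or
#'   a data frame with \code{rsid}, \code{beta_x}, \code{beta_y},
#'   \code{se_y}.
#' @return data frame with columns \code{rsid}, \code{ratio}, \code{se},
#'   \code{weight} (\code{weight = 1/se^2}).
#' @export
wald_ratio <- function(records) {
  df <- ratio_input(records)
  if (any(df$beta_x == 0))
    stop("Wald ratio undefined for instrument(s) with beta_x = 0: ",
         paste(df$rsid[df$beta_x == 0], collapse = ", "))
  se <- df$se_y / abs(df$beta_x)
  data.frame(rsid = df$rsid, ratio = df$beta_y / df$beta_x,
             se = se, weight = 1 / se^2, stringsAsFactors = FALSE)
}

# Accept a harmonized_set (kept records only) or a prepared data frame.
ratio_input <- function(records) {
  if (inherits(records, "harmonized_set")) records <- kept_records(records)
  df <- as.data.frame(records)
  needed <- c("rsid", "beta_x", "beta_y", "se_y")
  stopifnot(all(needed %in% names(df)))
  stopifnot(all(df$se_y > 0))
  df
}

# Shared constructor for one method's result row.
mr_result <- function(method, n_snp, estimate, se, pval = NULL, df = NULL,
                      outcome_type = "continuous") {
  ci <- estimate + c(-1, 1) * stats::qnorm(0.975) * se
  if (is.null(pval)) {
    pval <- if (is.null(df)) z_pvalue(estimate, se)
            else 2 * stats::pt(-abs(estimate / se), df = df)
  }
  out <- data.frame(method = method, n_snp = n_snp, estimate = estimate,
                    se = se, ci_low = ci[1], ci_high = ci[2], pval = pval,
                    or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  if (identical(outcome_type, "binary")) {
    out$or <- exp(estimate); out$or_ci_low <- exp(ci[1]); out$or_ci_high <- exp(ci[2])
  }
  class(out) <- c("mr_result", "data.frame")
  out
}

outcome_type_of <- function(records, default = "continuous") {
  ot <- attr(records, "outcome_type", exact = TRUE)
  if (is.null(ot) || is.na(ot)) default else ot
}

#' Wald estimator for a single instrument
#'
#' Used when exactly one instrument survives selection (the single-SNP
#' regime); the p-value is from the standard normal.
#'
#' @inheritParams wald_ratio
#' @param outcome_type \code{"continuous"} or \code{"binary"}; binary
#'   outcomes add the exponentiated (odds-ratio) scale.
#' @return an \code{mr_result} row.
#' @export
mr_wald <- function(records, outcome_type = outcome_type_of(records)) {
  r <- wald_ratio(records)
  if (nrow(r) != 1)
    stop("mr_wald expects exactly one instrument; got ", nrow(r))
  mr_result("wald", 1L, r$ratio, r$se, outcome_type = outcome_type)
}

#' Inverse-variance weighted estimator
#'
#' Meta-analytic combination of the Wald ratios with weights
#' \code{1/se^2}. The fixed-effects standard error is
#' \code{(sum w)^(-1/2)}; the multiplicative random-effects variant
#' inflates it by \code{max(1, sqrt(Q/(J-1)))} with Q the Cochran
#' heterogeneity statistic, leaving the point estimate unchanged.
#' P-values use the standard normal.
#'
#' With a single instrument the estimator collapses to the Wald ratio with
#' a warning.
#'
#' @inheritParams mr_wald
#' @param mode \code{"fixed"} or \code{"random"}.
#' @return an \code{mr_result} row (method \code{ivw_fe} or \code{ivw_re}).
#' @export
mr_ivw <- function(records, mode = c("fixed", "random"),
                   outcome_type = outcome_type_of(records)) {
  mode <- match.arg(mode)
  r <- wald_ratio(records)
  if (nrow(r) == 0) stop("no instruments supplied to mr_ivw")
  if (nrow(r) == 1) {
    warning("single instrument: IVW collapses to the Wald ratio")
    out <- mr_result(if (mode == "fixed") "ivw_fe" else "ivw_re",
                     1L, r$ratio, r$se, outcome_type = outcome_type)
    return(out)
  }
  w <- r$weight
  est <- sum(w * r$ratio) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  if (mode == "fixed") {
    return(mr_result("ivw_fe", nrow(r), est, se_fe, outcome_type = outcome_type))
  }
  q <- sum(w * (r$ratio - est)^2)
  infl <- max(1, sqrt(q / (nrow(r) - 1)))
  mr_result("ivw_re", nrow(r), est, se_fe * infl, outcome_type = outcome_type)
}

# Closed-form weighted least squares of y on (1, x) with weights w.
# Returns coefficients, their standard errors scaled by the dispersion
# floor, the weighted RSS, and residual df.
wls_fit <- function(x, y, w, intercept = TRUE, min_dispersion = 1) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  coef <- drop(solve(XtWX, XtWy))
  resid <- y - drop(X %*% coef)
  rss <- sum(w * resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) max(min_dispersion, rss / df) else NA_real_
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  list(coef = coef, se = se, rss = rss, df = df, sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with a free intercept, weights \code{1/se_y^2}, after orienting
#' all exposure effects positive. The slope is the pleiotropy-robust
#' causal estimate (consistent under the InSIDE assumption); the intercept
#' estimates average directional pleiotropy. Standard errors use a
#' residual dispersion parameter floored at 1 (no super-efficiency);
#' p-values use the t distribution with J - 2 degrees of freedom.
#'
#' @inheritParams mr_wald
#' @return list with components \code{result} (slope \code{mr_result}),
#'   \code{intercept} (data frame: intercept, se, pval), and \code{rss}
#'   (the weighted residual sum of squares, i.e. Ruecker's Q).
#' @export
mr_egger <- function(records, outcome_type = outcome_type_of(records)) {
  if (inherits(records, "harmonized_set")) records <- orient_positive(records)
  df <- ratio_input(records)
  if (nrow(df) < 3) stop("MR-Egger needs at least 3 instruments; got ", nrow(df))
  if (any(df$beta_x < 0))
    df[df$beta_x < 0, c("beta_x", "beta_y")] <- -df[df$beta_x < 0, c("beta_x", "beta_y")]
  w <- 1 / df$se_y^2
  fit <- wls_fit(df$beta_x, df$beta_y, w, intercept = TRUE)
  j <- nrow(df)
  slope <- mr_result("egger", j, fit$coef[2], fit$se[2], df = j - 2,
                     outcome_type = outcome_type)
  intercept <- data.frame(
    intercept = fit$coef[1], se = fit$se[1],
    pval = 2 * stats::pt(-abs(fit$coef[1] / fit$se[1]), df = j - 2))
  list(result = slope, intercept = intercept, rss = fit$rss)
}

# Weighted-median point estimate by cumulative-weight interpolation.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median estimator
#'
#' Consistent when instruments carrying at least half the total
#' inverse-variance weight are valid. The point estimate interpolates the
#' weighted empirical quantile function of the ratio estimates at 0.5; the
#' standard error comes from a seeded parametric bootstrap (each ratio
#' resampled from a normal with its own mean and SE).
#'
#' @inheritParams mr_wald
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed, required for reproducibility.
#' @return an \code{mr_result} row (method \code{weighted_median}).
#' @export
mr_weighted_median <- function(records, n_boot = 1000, seed,
                               outcome_type = outcome_type_of(records)) {
  r <- wald_ratio(records)
  if (nrow(r) < 3) stop("weighted median needs at least 3 instruments; got ", nrow(r))
  stopifnot(is_scalar_number(n_boot), n_boot >= 1)
  if (missing(seed)) stop("mr_weighted_median requires an explicit seed")
  est <- weighted_median_point(r$ratio, r$weight)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rb <- stats::rnorm(nrow(r), mean = r$ratio, sd = r$se)
      weighted_median_point(rb, r$weight)
    }, numeric(1))
  })
  mr_result("weighted_median", nrow(r), est, stats::sd(boot),
            outcome_type = outcome_type)
}

#' Penalized-weight IVW estimator
#'
#' Downweights heterogeneous instruments: each SNP's contribution to
#' Cochran's Q, \code{q_j = w_j (ratio_j - theta_IVW)^2}, is referred to a
#' chi-square(1) upper tail to give \code{p_j}, and the weight is
#' multiplied by \code{min(1, 20 p_j)}. Instruments consistent with the
#' pooled estimate keep their weight (penalty 1); outlying instruments are
#' heavily downweighted. Used as the headline-adjacent estimator when the
#' heterogeneity test triggers.
#'
#' @inheritParams mr_wald
#' @return an \code{mr_result} row (method \code{ivw_penalized}).
#' @export
mr_ivw_penalized <- function(records, outcome_type = outcome_type_of(records)) {
  r <- wald_ratio(records)
  if (nrow(r) == 0) stop("no instruments supplied to mr_ivw_penalized")
  w <- r$weight
  est0 <- sum(w * r$ratio) / sum(w)
  qj <- w * (r$ratio - est0)^2
  pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
  wstar <- w * pmin(1, 20 * pj)
  est <- sum(wstar * r$ratio) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  mr_result("ivw_penalized", nrow(r), est, se, outcome_type = outcome_type)
}
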