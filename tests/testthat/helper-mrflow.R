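# Builders shared across the test files.

# A plain data frame of harmonized-style records; every estimator accepts
# this shape directly (rsid, beta_x, se_x, beta_y, se_y).
make_records <- function(beta_x, beta_y, se_y, se_x = rep(0.05, length(beta_x)),
                         rsid = sprintf("s%03d", seq_along(beta_x))) {
  data.frame(rsid = rsid, beta_x = beta_x, se_x = se_x,
             beta_y = beta_y, se_y = se_y, stringsAsFactors = FALSE)
}

# Records whose Wald ratios and SEs are exactly the given values
# (beta_x = 1 makes ratio = beta_y and ratio se = se_y).
make_ratio_records <- function(ratio, se) {
  make_records(beta_x = rep(1, length(ratio)), beta_y = ratio, se_y = se)
}

# Random record set for oracle comparisons.
random_records <- function(j, seed) {
  mrflow:::with_seed(seed, {
    make_records(beta_x = runif(j, 0.05, 0.3) * sample(c(-1, 1), j, TRUE),
                 beta_y = rnorm(j, 0, 0.05),
                 se_y = runif(j, 0.01, 0.1),
                 se_x = runif(j, 0.005, 0.03))
  })
}

# A minimal valid summary-statistics data frame.
make_sumstats_df <- function(n = 3, ea = "A", oa = "G") {
  data.frame(SNP = sprintf("rs%d", seq_len(n)), CHR = "1",
             POS = seq_len(n) * 1e6, EA = ea, OA = oa, EAF = 0.3,
             BETA = seq_len(n) / 10, SE = 0.01, P = 1e-10, N = 1000,
             stringsAsFactors = FALSE)
}

# Independently coded WLS oracles (kept deliberately separate from the
# package's own linear-algebra path).
oracle_wls_origin <- function(bx, by, w) {
  fit <- lm(by ~ 0 + bx, weights = w)
  s <- summary(fit)
  list(slope = unname(coef(fit)[1]),
       se_fe = unname(s$coefficients[1, 2] / s$sigma))
}

oracle_wls_intercept <- function(bx, by, w) {
  fit <- lm(by ~ bx, weights = w)
  s <- summary(fit)
  disp <- max(1, s$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(s$coefficients[1, 2] / s$sigma * disp),
       se_slope = unname(s$coefficients[2, 2] / s$sigma * disp),
       rss = sum(w * residuals(fit)^2))
}

# Brute-force weighted-median interpolation, coded from the definition.
oracle_weighted_median <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5)); above <- below + 1
  r[below] + (0.5 - s[below]) / (s[above] - s[below]) * (r[above] - r[below])
}

# Exhaustive reference implementation of greedy p-value clumping.
oracle_clump <- function(df, r2mat, r2_threshold, window_kb) {
  remaining <- df[order(df$P, df$POS, df$SNP), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$SNP)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- remaining$CHR == idx$CHR &
      abs(remaining$POS - idx$POS) <= window_kb * 1000 &
      r2mat[remaining$SNP, idx$SNP] >= r2_threshold
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}
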