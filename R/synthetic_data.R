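# Seeded generation of paired exposure/outcome GWAS summary statistics
# with known causal structure, so instrument selection, harmonization,
# estimation and sensitivity analysis are all testable without external
# downloads.
#
# Generating model, per SNP j:
#   maf_j        ~ uniform(maf_low, maf_high)
#   se_x_j       = 1 / sqrt(2 maf_j (1 - maf_j) n_x)        (standardized trait)
#   gamma_j      : true SNP-exposure effect, |gamma_j| = sqrt(F_target) se_x_j
#                  with F_target uniform over f_range, sign random
#   beta_x_j     ~ N(gamma_j, se_x_j)
#   alpha_j      ~ N(pleio_mean, pleio_sd)   (direct, pleiotropic effect;
#                  n_outliers SNPs get alpha_j = outlier_offset instead)
#   se_y_j       = 1 / sqrt(2 maf_j (1 - maf_j) n_y)
#   beta_y_j     ~ N(theta gamma_j + alpha_j, se_y_j)
# P-values come from the standard normal. Binary outcomes reuse the same
# SE formula with n_y read as an effective sample size on the log-odds
# scale.

NON_PALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                              c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Parameters of a synthetic two-sample MR study
#'
#' Encodes the generating truth against which recovery is tested: the
#' causal effect, the per-SNP direct-effect (pleiotropy) distribution,
#' injected outliers, and the sample sizes that drive the standard errors.
#' \code{pleio_mean = 0, pleio_sd > 0} gives balanced pleiotropy (InSIDE
#' holds); \code{pleio_mean != 0} gives directional pleiotropy.
#'
#' Defaults mirror a well-powered thyroid-trait-to-disease analysis: an
#' exposure GWAS of ~72k individuals, an outcome GWAS with an effective
#' sample size of ~287k, instrument strength spanning F of 30 to 400, and
#' common variants (MAF 0.05 to 0.5) of which roughly one in six is
#' palindromic.
#'
#' @param theta true causal effect of the exposure on the outcome.
#' @param j number of instruments (>= 1).
#' @param pleio_mean,pleio_sd mean and SD of the per-SNP direct effects.
#' @param n_outliers number of SNPs given the fixed pleiotropic offset
#'   \code{outlier_offset} instead of a draw.
#' @param outlier_offset pleiotropic offset for outlier SNPs.
#' @param n_x,n_y effective sample sizes of the exposure and outcome GWAS.
#' @param maf_low,maf_high uniform range of minor-allele frequencies,
#'   within (0, 0.5].
#' @param palindrome_frac fraction of SNPs given A/T or C/G allele pairs.
#' @param f_range range of target instrument F statistics.
#' @param gamma_sign \code{"random"} (alleles as reported by a GWAS, half
#'   the true effects negative) or \code{"positive"} (instruments already
#'   coded by exposure-increasing allele). Directional pleiotropy is only
#'   identifiable as an Egger intercept under consistent coding, so
#'   simulations of that regime should use \code{"positive"}.
#' @param outcome_type \code{"continuous"} or \code{"binary"} (reporting
#'   scale only).
#' @param seed integer seed; all randomness in \code{generate_study} flows
#'   from it.
#' @return an object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(theta = 0, j = 50, pleio_mean = 0, pleio_sd = 0,
                            n_outliers = 0, outlier_offset = 0,
                            n_x = 72167, n_y = 287132,
                            maf_low = 0.05, maf_high = 0.5,
                            palindrome_frac = 0.15, f_range = c(30, 400),
                            gamma_sign = c("random", "positive"),
                            outcome_type = c("continuous", "binary"),
                            seed = 1) {
  outcome_type <- match.arg(outcome_type)
  gamma_sign <- match.arg(gamma_sign)
  stopifnot(is_scalar_number(theta), is_scalar_number(j), j >= 1,
            is_scalar_number(pleio_sd), pleio_sd >= 0,
            is_scalar_number(n_outliers), n_outliers >= 0, n_outliers <= j,
            is_scalar_number(n_x), n_x > 0, is_scalar_number(n_y), n_y > 0,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
            palindrome_frac >= 0, palindrome_frac <= 1,
            length(f_range) == 2, all(f_range > 0), f_range[1] <= f_range[2],
            is_scalar_number(seed))
  structure(list(theta = theta, j = as.integer(j), pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, n_outliers = as.integer(n_outliers),
                 outlier_offset = outlier_offset, n_x = n_x, n_y = n_y,
                 maf_low = maf_low, maf_high = maf_high,
                 palindrome_frac = palindrome_frac, f_range = f_range,
                 gamma_sign = gamma_sign,
                 outcome_type = outcome_type, seed = as.integer(seed)),
            class = "synthetic_truth")
}

se_from_n <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# normal p-value kept strictly positive (extreme z scores underflow)
safe_pvalue <- function(beta, se) pmax(z_pvalue(beta, se), .Machine$double.xmin)

#' Generate a synthetic two-sample MR study
#'
#' Draws paired exposure and outcome summary-statistics sets from the
#' generating model described in \code{\link{synthetic_truth}}. The two
#' sets share rsids, positions, allele encodings and allele frequencies
#' before any deliberate scrambling (see \code{\link{scramble_alleles}});
#' the LD matrix is the identity (independent instruments). SNPs are
#' placed 20 Mb apart along chromosomes 1-22 so default clumping windows
#' never collide.
#'
#' @param truth a \code{synthetic_truth}.
#' @return an object of class \code{synthetic_study}: list with
#'   \code{truth}, \code{exposure} and \code{outcome}
#'   (\code{sumstat_set}s), \code{ld} (identity \code{ld_matrix}),
#'   \code{outlier_rsids}, and \code{gamma} (the true SNP-exposure
#'   effects).
#' @export
generate_study <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  j <- truth$j
  with_seed(truth$seed, {
    rsid <- sprintf("rs%06d", seq_len(j))
    chr <- as.character(((seq_len(j) - 1) %% 22) + 1)
    pos <- 1e6 + ((seq_len(j) - 1) %/% 22) * 2e7

    n_pal <- round(truth$palindrome_frac * j)
    pal <- rep(FALSE, j)
    if (n_pal > 0) pal[sample.int(j, n_pal)] <- TRUE
    alleles <- t(vapply(pal, function(p) {
      pool <- if (p) PALINDROMIC_PAIRS else NON_PALINDROMIC_PAIRS
      unlist(pool[[sample.int(length(pool), 1)]])
    }, character(2)))

    maf <- stats::runif(j, truth$maf_low, truth$maf_high)
    eaf <- ifelse(stats::runif(j) < 0.5, maf, 1 - maf)

    se_x <- se_from_n(maf, truth$n_x)
    f_target <- stats::runif(j, truth$f_range[1], truth$f_range[2])
    sign_draw <- if (truth$gamma_sign == "positive") rep(1, j)
                 else sample(c(-1, 1), j, replace = TRUE)
    gamma <- sqrt(f_target) * se_x * sign_draw
    beta_x <- stats::rnorm(j, gamma, se_x)

    alpha <- stats::rnorm(j, truth$pleio_mean, truth$pleio_sd)
    outlier_idx <- integer(0)
    if (truth$n_outliers > 0) {
      outlier_idx <- sample.int(j, truth$n_outliers)
      alpha[outlier_idx] <- truth$outlier_offset
    }
    se_y <- se_from_n(maf, truth$n_y)
    beta_y <- stats::rnorm(j, truth$theta * gamma + alpha, se_y)

    exposure <- sumstat_set(data.frame(
      SNP = rsid, CHR = chr, POS = pos, EA = alleles[, 1], OA = alleles[, 2],
      EAF = eaf, BETA = beta_x, SE = se_x, P = safe_pvalue(beta_x, se_x),
      N = truth$n_x, stringsAsFactors = FALSE),
      trait_name = "synthetic_exposure", trait_type = "continuous")
    outcome <- sumstat_set(data.frame(
      SNP = rsid, CHR = chr, POS = pos, EA = alleles[, 1], OA = alleles[, 2],
      EAF = eaf, BETA = beta_y, SE = se_y, P = safe_pvalue(beta_y, se_y),
      N = truth$n_y, stringsAsFactors = FALSE),
      trait_name = "synthetic_outcome", trait_type = truth$outcome_type)

    structure(list(truth = truth, exposure = exposure, outcome = outcome,
                   ld = ld_identity(rsid),
                   outlier_rsids = rsid[sort(outlier_idx)],
                   gamma = stats::setNames(gamma, rsid)),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> J = %d, theta = %g, pleiotropy N(%g, %g), %d outlier(s), seed %d\n",
    x$truth$j, x$truth$theta, x$truth$pleio_mean, x$truth$pleio_sd,
    length(x$outlier_rsids), x$truth$seed))
  invisible(x)
}

#' Scramble outcome allele encodings
#'
#' Information-preserving re-encoding of the outcome set, used as a
#' harmonization test fixture: a seeded random fraction of SNPs get their
#' alleles swapped (beta negated, eaf complemented) and another fraction
#' get strand-complemented allele labels. \code{\link{harmonize}} must
#' exactly invert both for non-palindromic SNPs.
#'
#' @param study a \code{synthetic_study}.
#' @param swap_frac fraction of SNPs with allele labels swapped.
#' @param strand_frac fraction of SNPs with strand-complemented labels.
#' @param seed integer seed.
#' @return the study with a scrambled outcome set; attribute
#'   \code{scrambled} on the outcome records which SNPs were altered.
#' @export
scramble_alleles <- function(study, swap_frac = 0, strand_frac = 0, seed = 1) {
  stopifnot(inherits(study, "synthetic_study"),
            swap_frac >= 0, swap_frac <= 1, strand_frac >= 0, strand_frac <= 1)
  odf <- as.data.frame(study$outcome)
  j <- nrow(odf)
  with_seed(seed, {
    swap_idx <- if (swap_frac > 0) sample.int(j, round(swap_frac * j)) else integer(0)
    strand_idx <- if (strand_frac > 0) sample.int(j, round(strand_frac * j)) else integer(0)
    if (length(swap_idx) > 0) {
      tmp <- odf$EA[swap_idx]
      odf$EA[swap_idx] <- odf$OA[swap_idx]
      odf$OA[swap_idx] <- tmp
      odf$BETA[swap_idx] <- -odf$BETA[swap_idx]
      odf$EAF[swap_idx] <- 1 - odf$EAF[swap_idx]
    }
    if (length(strand_idx) > 0) {
      odf$EA[strand_idx] <- unname(COMPLEMENT[odf$EA[strand_idx]])
      odf$OA[strand_idx] <- unname(COMPLEMENT[odf$OA[strand_idx]])
    }
    out <- sumstat_set(odf, trait_name = attr(study$outcome, "trait_name"),
                       trait_type = attr(study$outcome, "trait_type"))
    attr(out, "scrambled") <- list(swapped = odf$SNP[sort(swap_idx)],
                                   strand_flipped = odf$SNP[sort(strand_idx)])
    study$outcome <- out
    study
  })
}

# Build a sumstat pair directly from fully specified per-SNP vectors
# (deterministic fixture plumbing).
build_pair <- function(rsid, chr, pos, ea, oa, eaf, beta_x, se_x, beta_y, se_y,
                       n_x, n_y, exposure_name, outcome_name, outcome_type) {
  exposure <- sumstat_set(data.frame(
    SNP = rsid, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
    BETA = beta_x, SE = se_x, P = safe_pvalue(beta_x, se_x), N = n_x,
    stringsAsFactors = FALSE), exposure_name, "continuous")
  outcome <- sumstat_set(data.frame(
    SNP = rsid, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
    BETA = beta_y, SE = se_y, P = safe_pvalue(beta_y, se_y), N = n_y,
    stringsAsFactors = FALSE), outcome_name, outcome_type)
  list(exposure = exposure, outcome = outcome)
}

#' Regime fixtures mirroring the study designs of a thyroid-function MR
#'
#' Deterministically constructed exposure/outcome pairs reproducing the
#' qualitative instrument regimes of a thyroid-trait analysis of diabetic
#' microvascular outcomes, so routing behaviour can be asserted per
#' regime:
#' \describe{
#'   \item{\code{tsh_dkd}}{many-instrument homogeneous regime: 61
#'     genome-wide candidates of which 39 survive significance filtering
#'     and clumping (binary outcome, true log-OR log(1.44)).}
#'   \item{\code{ft4_acr}}{moderate-instrument regime: 31 candidates, 16
#'     surviving (continuous outcome, true effect -0.078).}
#'   \item{\code{ft3ft4_single_snp}}{single-instrument regime: one strong
#'     variant (rs2235544), routing to the Wald-only path.}
#'   \item{\code{tpoab_heterogeneous}}{few-instrument heterogeneous
#'     regime: 5 candidates, 4 surviving, with per-SNP pleiotropy large
#'     enough to trigger the heterogeneity test and the penalized-IVW
#'     row.}
#' }
#' Candidate attrition is built in by construction: sub-threshold
#' candidates have a true effect of zero, and clumped candidates sit
#' within 10 kb of an index SNP at r^2 = 0.9 with a deterministically
#' larger p-value.
#'
#' @param analysis regime name.
#' @param seed integer seed for the stochastic draws.
#' @return a \code{synthetic_study} (with a non-identity \code{ld} where
#'   the regime includes clumped candidates).
#' @export
fixture_study <- function(analysis = c("tsh_dkd", "ft4_acr", "ft3ft4_single_snp",
                                       "tpoab_heterogeneous"), seed = 1) {
  analysis <- match.arg(analysis)
  spec <- switch(analysis,
    tsh_dkd = list(n_index = 39, n_weak = 15, n_clumped = 7,
                   theta = log(1.44), pleio_sd = 0, outcome_type = "binary",
                   outcome_name = "DKD", exposure_name = "TSH"),
    ft4_acr = list(n_index = 16, n_weak = 10, n_clumped = 5,
                   theta = -0.078, pleio_sd = 0, outcome_type = "continuous",
                   outcome_name = "ACR", exposure_name = "FT4"),
    ft3ft4_single_snp = list(n_index = 1, n_weak = 0, n_clumped = 0,
                             theta = log(0.73), pleio_sd = 0,
                             outcome_type = "binary", outcome_name = "DKD",
                             exposure_name = "FT3:FT4"),
    tpoab_heterogeneous = list(n_index = 4, n_weak = 0, n_clumped = 1,
                               theta = log(1.17), pleio_sd = 0,
                               outcome_type = "binary", outcome_name = "DKD",
                               exposure_name = "TPOAB"))
  n_x <- 72167; n_y <- 287132
  with_seed(child_seed(seed, match(analysis, c("tsh_dkd", "ft4_acr",
                                               "ft3ft4_single_snp",
                                               "tpoab_heterogeneous"))), {
    n_all <- spec$n_index + spec$n_weak + spec$n_clumped
    role <- c(rep("index", spec$n_index), rep("weak", spec$n_weak),
              rep("clumped", spec$n_clumped))
    rsid <- if (analysis == "ft3ft4_single_snp") "rs2235544"
            else sprintf("rs%06d", seq_len(n_all))
    chr <- as.character(((seq_along(role) - 1) %% 22) + 1)
    pos <- 1e6 + ((seq_along(role) - 1) %/% 22) * 2e7
    # clumped candidates sit 5 kb from their index partner
    partner <- rep(NA_integer_, n_all)
    if (spec$n_clumped > 0) {
      idx_rows <- which(role == "index")[seq_len(spec$n_clumped)]
      cl_rows <- which(role == "clumped")
      partner[cl_rows] <- idx_rows
      chr[cl_rows] <- chr[idx_rows]
      pos[cl_rows] <- pos[idx_rows] + 5000
    }
    maf <- stats::runif(n_all, 0.1, 0.5)
    se_x <- se_from_n(maf, n_x)
    f_target <- stats::runif(n_all, 40, 400)
    gamma <- sqrt(f_target) * se_x
    gamma[role == "weak"] <- 0
    beta_x <- stats::rnorm(n_all, gamma, se_x)
    # a clumped partner echoes its index with a deterministically larger p
    cl <- which(role == "clumped")
    if (length(cl) > 0) beta_x[cl] <- beta_x[partner[cl]] * 0.95
    # guarantee index significance with margin (so clumped echoes at 0.95x
    # still clear 5e-8 and drop by clumping, not by p): redraw any index
    # SNP above p = 5e-9 (rejection sampling, seeded)
    repeat {
      p_x <- z_pvalue(beta_x, se_x)
      bad <- which(role == "index" & p_x >= 5e-9)
      if (length(bad) == 0) break
      beta_x[bad] <- stats::rnorm(length(bad), gamma[bad], se_x[bad])
    }
    if (length(cl) > 0) beta_x[cl] <- beta_x[partner[cl]] * 0.95

    alpha <- if (analysis == "tpoab_heterogeneous") {
      # deterministic alternating direct effects sized to trigger the
      # heterogeneity test without tripping per-SNP outlier flags
      rep_len(c(1, -1), n_all) * 2.2 * se_from_n(maf, n_y)
    } else {
      stats::rnorm(n_all, 0, spec$pleio_sd)
    }
    se_y <- se_from_n(maf, n_y)
    beta_y <- stats::rnorm(n_all, spec$theta * gamma + alpha, se_y)

    ea <- rep(c("A", "G", "T", "C"), length.out = n_all)
    oa <- rep(c("G", "A", "C", "T"), length.out = n_all)
    pair <- build_pair(rsid, chr, pos, ea, oa, eaf = maf, beta_x, se_x,
                       beta_y, se_y, n_x, n_y,
                       spec$exposure_name, spec$outcome_name, spec$outcome_type)
    r2 <- diag(n_all)
    if (length(cl) > 0) {
      r2[cbind(cl, partner[cl])] <- 0.9
      r2[cbind(partner[cl], cl)] <- 0.9
    }
    dimnames(r2) <- list(rsid, rsid)
    truth <- synthetic_truth(theta = spec$theta, j = n_all,
                             pleio_sd = spec$pleio_sd, n_x = n_x, n_y = n_y,
                             outcome_type = spec$outcome_type, seed = seed)
    structure(list(truth = truth, exposure = pair$exposure,
                   outcome = pair$outcome, ld = ld_matrix(r2),
                   outlier_rsids = character(0),
                   gamma = stats::setNames(gamma, rsid)),
              class = "synthetic_study")
  })
}
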