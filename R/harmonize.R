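# Reconciling exposure and outcome summary statistics to a common effect
# allele per SNP: sign flips for swapped allele labels, strand flips for
# complementary encodings, and frequency-based resolution of palindromic
# (A/T, C/G) variants.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' For each exposure instrument found in the outcome set, aligns the
#' outcome association to the exposure's effect allele:
#' \itemize{
#'   \item alleles match directly: record kept as-is;
#'   \item outcome alleles swapped: outcome beta negated and eaf
#'     complemented (\code{sign_flipped});
#'   \item alleles match only after strand complement (A<->T, C<->G):
#'     complemented and re-evaluated (\code{strand_flipped}; a swap after
#'     complement also negates the outcome beta);
#'   \item palindromic variants (A/T or C/G pairs), for which allele labels
#'     cannot distinguish strands, are resolved by allele frequency: kept
#'     only when both eafs are available and both lie outside
#'     [0.5 - band, 0.5 + band]; discordant sides imply opposite strands
#'     and the outcome effect is flipped (\code{strand_flipped}); otherwise
#'     dropped as \code{palindromic_ambiguous};
#'   \item any other allele configuration is dropped as
#'     \code{incompatible_alleles}; instruments absent from the outcome are
#'     dropped as \code{missing_in_outcome}.
#' }
#' Failures never abort the analysis: they become dropped records with
#' reasons. Duplicate outcome rows for one rsid are resolved to the one
#' with the smallest standard error.
#'
#' @param exposure an \code{instrument_set} (or \code{sumstat_set}) for the
#'   exposure.
#' @param outcome a \code{sumstat_set} for the outcome.
#' @param palindrome_eaf_band half-width of the ambiguity band around 0.5
#'   (default 0.08: drop when either eaf falls in [0.42, 0.58] or is
#'   missing).
#' @return a \code{harmonized_set}: data frame with columns \code{rsid},
#'   \code{beta_x}, \code{se_x}, \code{beta_y}, \code{se_y}, \code{eaf_x},
#'   \code{eaf_y}, \code{action}, \code{drop_reason}, plus attributes
#'   \code{n_kept}, \code{n_dropped}, trait metadata.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_band = 0.08) {
  if (inherits(exposure, "instrument_set")) {
    exp_name <- exposure$trait_name; exp_type <- exposure$trait_type
    edf <- exposure$data
  } else if (inherits(exposure, "sumstat_set")) {
    exp_name <- attr(exposure, "trait_name"); exp_type <- attr(exposure, "trait_type")
    edf <- as.data.frame(exposure)
  } else stop("exposure must be an instrument_set or sumstat_set")
  stopifnot(inherits(outcome, "sumstat_set"),
            is_scalar_number(palindrome_eaf_band),
            palindrome_eaf_band >= 0, palindrome_eaf_band < 0.5)
  odf <- as.data.frame(outcome)

  rows <- lapply(seq_len(nrow(edf)), function(i) {
    e <- edf[i, ]
    rec <- list(rsid = e$SNP, beta_x = e$BETA, se_x = e$SE,
                beta_y = NA_real_, se_y = NA_real_,
                eaf_x = e$EAF, eaf_y = NA_real_,
                action = "dropped", drop_reason = "")
    hits <- odf[odf$SNP == e$SNP, , drop = FALSE]
    if (nrow(hits) == 0) {
      rec$drop_reason <- "missing_in_outcome"
      return(rec)
    }
    o <- hits[which.min(hits$SE), ]
    ea <- o$EA; oa <- o$OA; by <- o$BETA; fy <- o$EAF
    action <- "kept"

    if (is_palindromic(e$EA, e$OA)) {
      # allele labels carry no strand information; resolve by frequency
      if (!(identical(ea, e$EA) && identical(oa, e$OA)) &&
          !(identical(ea, e$OA) && identical(oa, e$EA))) {
        rec$drop_reason <- "incompatible_alleles"
        return(rec)
      }
      if (identical(ea, e$OA)) {  # label swap first
        by <- -by; fy <- if (is.na(fy)) NA_real_ else 1 - fy
        action <- "sign_flipped"
      }
      fx <- e$EAF
      band_lo <- 0.5 - palindrome_eaf_band; band_hi <- 0.5 + palindrome_eaf_band
      if (is.na(fx) || is.na(fy) ||
          (fx >= band_lo && fx <= band_hi) || (fy >= band_lo && fy <= band_hi)) {
        rec$drop_reason <- "palindromic_ambiguous"
        return(rec)
      }
      if ((fx < 0.5) != (fy < 0.5)) {  # opposite sides: outcome on other strand
        by <- -by; fy <- 1 - fy
        action <- "strand_flipped"
      }
    } else {
      if (identical(ea, e$EA) && identical(oa, e$OA)) {
        # direct match
      } else if (identical(ea, e$OA) && identical(oa, e$EA)) {
        by <- -by; fy <- if (is.na(fy)) NA_real_ else 1 - fy
        action <- "sign_flipped"
      } else {
        cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
        if (identical(cea, e$EA) && identical(coa, e$OA)) {
          action <- "strand_flipped"
        } else if (identical(cea, e$OA) && identical(coa, e$EA)) {
          by <- -by; fy <- if (is.na(fy)) NA_real_ else 1 - fy
          action <- "strand_flipped"
        } else {
          rec$drop_reason <- "incompatible_alleles"
          return(rec)
        }
      }
    }
    rec$beta_y <- by; rec$se_y <- o$SE; rec$eaf_y <- fy; rec$action <- action
    rec
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(rsid = character(0), beta_x = numeric(0),
                                    se_x = numeric(0), beta_y = numeric(0),
                                    se_y = numeric(0), eaf_x = numeric(0),
                                    eaf_y = numeric(0), action = character(0),
                                    drop_reason = character(0))
  rownames(df) <- NULL
  harmonized_set(df, exposure_name = exp_name, exposure_type = exp_type,
                 outcome_name = attr(outcome, "trait_name"),
                 outcome_type = attr(outcome, "trait_type"))
}

harmonized_set <- function(df, exposure_name = NA, exposure_type = NA,
                           outcome_name = NA, outcome_type = "continuous") {
  n_kept <- sum(df$action != "dropped")
  structure(df,
            n_kept = n_kept, n_dropped = nrow(df) - n_kept,
            exposure_name = exposure_name, exposure_type = exposure_type,
            outcome_name = outcome_name, outcome_type = outcome_type,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d kept, %d dropped\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"),
              attr(x, "n_kept"), attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Kept (non-dropped) harmonized records
#' @param records a \code{harmonized_set}.
#' @return the subset with \code{action != "dropped"}, same class.
#' @export
kept_records <- function(records) {
  stopifnot(inherits(records, "harmonized_set"))
  df <- as.data.frame(records)[records$action != "dropped", , drop = FALSE]
  rownames(df) <- NULL
  harmonized_set(df, attr(records, "exposure_name"), attr(records, "exposure_type"),
                 attr(records, "outcome_name"), attr(records, "outcome_type"))
}

#' Orient all exposure effects positive
#'
#' Jointly negates \code{(beta_x, beta_y)} (and complements the allele
#' frequencies) for records with negative exposure effect. Wald ratios are
#' invariant under this joint negation; orientation is the standard
#' precondition for MR-Egger regression, whose intercept is not invariant
#' to instrument coding.
#'
#' @param records a \code{harmonized_set}.
#' @return the oriented \code{harmonized_set}.
#' @export
orient_positive <- function(records) {
  stopifnot(inherits(records, "harmonized_set"))
  df <- as.data.frame(records)
  flip <- !is.na(df$beta_x) & df$beta_x < 0 & df$action != "dropped"
  df$beta_x[flip] <- -df$beta_x[flip]
  df$beta_y[flip] <- -df$beta_y[flip]
  df$eaf_x[flip] <- 1 - df$eaf_x[flip]
  df$eaf_y[flip] <- 1 - df$eaf_y[flip]
  harmonized_set(df, attr(records, "exposure_name"), attr(records, "exposure_type"),
                 attr(records, "outcome_name"), attr(records, "outcome_type"))
}

#' Write the harmonization audit log
#'
#' One row per exposure instrument: rsid, action taken, drop reason.
#'
#' @param records a \code{harmonized_set}.
#' @param path output path (TSV).
#' @return \code{path}, invisibly.
#' @export
write_harmonization_log <- function(records, path) {
  stopifnot(inherits(records, "harmonized_set"))
  utils::write.table(as.data.frame(records)[c("rsid", "action", "drop_reason")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
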