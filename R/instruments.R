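# Instrument selection: genome-wide significance filtering, greedy LD
# clumping against an explicit r-squared matrix, and instrument-strength
# (F-statistic) screening.

#' Construct an LD matrix
#'
#' A symmetric matrix of squared correlations (r^2) between variants, unit
#' diagonal, used by \code{\link{clump}}. The LD reference is an explicit
#' input: the package never computes LD from genotypes.
#'
#' @param r2 square numeric matrix of squared correlations in [0, 1].
#' @param rsids variant identifiers for the rows/columns (defaults to the
#'   matrix dimnames).
#' @return an object of class \code{ld_matrix}.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop("ld_matrix needs rsids (or matrix dimnames)")
  rsids <- as.character(rsids)
  stopifnot(nrow(r2) == ncol(r2), length(rsids) == nrow(r2))
  if (anyDuplicated(rsids)) stop("duplicate rsids in LD matrix")
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 entries must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must equal 1")
  if (any(abs(r2 - t(r2)) > 1e-8, na.rm = TRUE)) stop("LD matrix must be symmetric")
  dimnames(r2) <- list(rsids, rsids)
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Identity LD matrix (all variants independent)
#' @param rsids variant identifiers.
#' @return an \code{ld_matrix} with zero off-diagonal entries.
#' @export
ld_identity <- function(rsids) {
  m <- diag(length(rsids))
  dimnames(m) <- list(rsids, rsids)
  ld_matrix(m)
}

#' Read / write an LD matrix
#'
#' Delimited text: first column \code{SNP}, remaining columns the symmetric
#' r^2 values under a header row of rsids.
#'
#' @param path file path.
#' @return an \code{ld_matrix} (for \code{read_ld_matrix}).
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  rsids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rsids
  ld_matrix(m, rsids)
}

#' @rdname read_ld_matrix
#' @param ld an \code{ld_matrix}.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld), as.data.frame(unclass(ld), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter to genome-wide significant variants
#'
#' Keeps exactly the records with \code{P < p_threshold}, preserving input
#' order. Idempotent at a fixed threshold.
#'
#' @param exposure a \code{sumstat_set}.
#' @param p_threshold significance threshold in (0, 1); the conventional
#'   genome-wide level is 5e-8.
#' @return the filtered \code{sumstat_set}.
#' @export
filter_significant <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "sumstat_set"),
            is_scalar_number(p_threshold), p_threshold > 0, p_threshold <= 1)
  keep <- exposure$P < p_threshold
  out <- exposure[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out),
                       attributes(exposure)[c("trait_name", "trait_type", "n_dropped")])
  class(out) <- class(exposure)
  out
}

#' Per-variant instrument strength
#'
#' The F statistic of a single genetic instrument, beta squared over its
#' squared standard error. Values below roughly 10 conventionally flag weak
#' instruments.
#'
#' @param beta,se effect and standard error (vectorized); \code{se > 0}.
#' @return numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  beta^2 / se^2
}

#' Greedy LD clumping
#'
#' Selects approximately independent instruments: repeatedly take the
#' remaining candidate with the smallest p-value as an index variant and
#' drop every remaining candidate on the same chromosome within
#' \code{window_kb} kilobases whose r^2 with the index is at least
#' \code{r2_threshold}. Ties on p-value break by smaller genomic position,
#' then lexicographic rsid, so the result is order-independent.
#'
#' Candidates with unknown chromosome or position are never within any
#' window and are retained as their own clumps. A candidate absent from
#' \code{ld} is a hard error unless \code{allow_missing_ld} is set, in
#' which case absent pairs are treated as r^2 = 0 with a warning.
#'
#' @param candidates a \code{sumstat_set} of significance-filtered exposure
#'   variants.
#' @param ld an \code{ld_matrix}, or \code{NULL} (requires
#'   \code{allow_missing_ld = TRUE}; all pairs treated as independent).
#' @param r2_threshold squared-correlation threshold (default 0.001).
#' @param window_kb clumping window half-width in kilobases (default
#'   10000, i.e. +/- 10 Mb).
#' @param allow_missing_ld treat pairs absent from \code{ld} as r^2 = 0.
#' @return an \code{instrument_set}: list with \code{data} (the kept
#'   records with an \code{F} column) and \code{provenance} (per-candidate
#'   decision log).
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000, allow_missing_ld = is.null(ld)) {
  stopifnot(inherits(candidates, "sumstat_set"),
            is_scalar_number(r2_threshold), is_scalar_number(window_kb),
            window_kb > 0)
  if (!is.null(ld)) stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(candidates)
  if (!is.null(ld)) {
    absent <- setdiff(df$SNP, rownames(ld))
    if (length(absent) > 0 && !allow_missing_ld)
      stop("candidate(s) missing from LD matrix: ",
           paste(utils::head(absent, 5), collapse = ", "))
    if (length(absent) > 0)
      warning(length(absent), " candidate(s) absent from LD matrix treated as r2 = 0")
  } else if (!allow_missing_ld) {
    stop("no LD matrix supplied; pass allow_missing_ld = TRUE to treat all pairs as independent")
  }

  r2_of <- function(a, b) {
    if (is.null(ld) || !(a %in% rownames(ld)) || !(b %in% rownames(ld))) 0
    else unclass(ld)[a, b]
  }

  decision <- setNames(rep(NA_character_, nrow(df)), df$SNP)
  # deterministic processing order: p, then position, then rsid
  ord <- order(df$P, df$POS, df$SNP, method = "radix", na.last = TRUE)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    kept <- c(kept, i)
    decision[df$SNP[i]] <- "kept"
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- !is.na(df$CHR[remaining]) & !is.na(df$CHR[i]) &
      df$CHR[remaining] == df$CHR[i]
    within <- same_chr & !is.na(df$POS[remaining]) & !is.na(df$POS[i]) &
      abs(df$POS[remaining] - df$POS[i]) <= window_kb * 1000
    if (any(within)) {
      r2v <- vapply(df$SNP[remaining[within]], r2_of, numeric(1), b = df$SNP[i])
      drop_idx <- remaining[within][r2v >= r2_threshold]
      for (j in drop_idx)
        decision[df$SNP[j]] <- paste0("dropped:clumped-with:", df$SNP[i])
      remaining <- setdiff(remaining, drop_idx)
    }
  }
  kept <- sort(kept)  # preserve original row order among kept records
  data <- df[kept, , drop = FALSE]
  rownames(data) <- NULL
  data$F <- if (nrow(data)) f_statistic(data$BETA, data$SE) else numeric(0)
  instrument_set(
    data,
    provenance = data.frame(rsid = df$SNP, decision = unname(decision[df$SNP]),
                            stringsAsFactors = FALSE),
    trait_name = attr(candidates, "trait_name"),
    trait_type = attr(candidates, "trait_type")
  )
}

instrument_set <- function(data, provenance, trait_name, trait_type) {
  structure(list(data = data, provenance = provenance,
                 trait_name = trait_name, trait_type = trait_type),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instrument(s) for '%s'", nrow(x$data), x$trait_name))
  if (nrow(x$data))
    cat(sprintf("; F range %.1f-%.1f", min(x$data$F), max(x$data$F)))
  cat("\n")
  invisible(x)
}

#' Screen weak instruments by F statistic
#'
#' Keeps instruments with \code{F >= f_min}. The default \code{f_min = 0}
#' makes this report-only (min/max F are always available in the
#' instrument set), matching the common practice of inspecting rather than
#' excluding; \code{f_min = 10} applies the conventional weak-instrument
#' cutoff.
#'
#' @param instruments an \code{instrument_set}.
#' @param f_min minimum F statistic (>= 0).
#' @return the screened \code{instrument_set}, provenance updated.
#' @export
screen_weak <- function(instruments, f_min = 0) {
  stopifnot(inherits(instruments, "instrument_set"),
            is_scalar_number(f_min), f_min >= 0)
  keep <- instruments$data$F >= f_min
  dropped <- instruments$data$SNP[!keep]
  prov <- instruments$provenance
  prov$decision[prov$rsid %in% dropped] <- "dropped:weak-instrument"
  data <- instruments$data[keep, , drop = FALSE]
  rownames(data) <- NULL
  if (nrow(data) == 0 && length(dropped) > 0)
    warning("all instruments fall below f_min = ", f_min)
  instrument_set(data, prov, instruments$trait_name, instruments$trait_type)
}

#' Select instruments end to end
#'
#' Convenience wrapper chaining \code{\link{filter_significant}},
#' \code{\link{clump}} and \code{\link{screen_weak}}, with a provenance log
#' covering every candidate (kept / dropped:p-threshold /
#' dropped:clumped-with:<rsid> / dropped:weak-instrument).
#'
#' @inheritParams filter_significant
#' @inheritParams clump
#' @inheritParams screen_weak
#' @return an \code{instrument_set}.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 0, allow_missing_ld = is.null(ld)) {
  sig <- filter_significant(exposure, p_threshold)
  inst <- clump(sig, ld, r2_threshold, window_kb, allow_missing_ld)
  inst <- screen_weak(inst, f_min)
  nonsig <- setdiff(exposure$SNP, sig$SNP)
  if (length(nonsig) > 0) {
    inst$provenance <- rbind(
      data.frame(rsid = nonsig, decision = "dropped:p-threshold",
                 stringsAsFactors = FALSE),
      inst$provenance)
    # restore input candidate order in the log
    inst$provenance <- inst$provenance[match(exposure$SNP, inst$provenance$rsid), ]
    rownames(inst$provenance) <- NULL
  }
  inst
}
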