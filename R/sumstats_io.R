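# Reading, validating and writing GWAS summary-statistics tables.
#
# The canonical column dialect is
#   SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N
# one variant per row, header mandatory, TSV by default (CSV accepted).
# Source files in other dialects are adapted through `column_map`.

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
MANDATORY_COLS <- c("SNP", "EA", "OA", "BETA", "SE", "P")

#' Construct a summary-statistics set
#'
#' Validates a data frame of per-variant GWAS associations and attaches the
#' trait metadata used downstream (reporting on the beta scale for
#' continuous traits, the odds-ratio scale for binary ones). Rows failing
#' validation are dropped and counted; the drop count is kept as an
#' attribute and reported by \code{print}.
#'
#' Validation rules: alleles are uppercased and must be single A/C/G/T
#' letters with effect allele distinct from the other allele; \code{SE}
#' must be strictly positive; \code{P} must lie in (0, 1] (exact zeros are
#' clamped to the smallest positive double with a warning, since log-scale
#' diagnostics need positivity); \code{BETA} must be finite; \code{EAF}, if
#' present, must be in [0, 1] or missing; rsids must be unique.
#'
#' @param df data frame with canonical columns (missing optional columns
#'   are filled with \code{NA}).
#' @param trait_name name of the trait.
#' @param trait_type \code{"continuous"} or \code{"binary"}.
#' @return an object of class \code{sumstat_set} (a data frame with
#'   attributes \code{trait_name}, \code{trait_type}, \code{n_dropped}).
#' @export
sumstat_set <- function(df, trait_name, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(CANONICAL_COLS, names(df))) df[[col]] <- NA
  df <- df[CANONICAL_COLS]

  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  df$EA <- toupper(as.character(df$EA))
  df$OA <- toupper(as.character(df$OA))
  for (col in c("POS", "EAF", "BETA", "SE", "P", "N")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  if (any(!is.na(df$P) & df$P == 0)) {
    warning("p-values of exactly 0 clamped to the smallest positive double")
    df$P[!is.na(df$P) & df$P == 0] <- .Machine$double.xmin
  }

  ok <- !is.na(df$SNP) & nzchar(df$SNP) &
    df$EA %in% c("A", "C", "G", "T") &
    df$OA %in% c("A", "C", "G", "T") &
    df$EA != df$OA &
    !is.na(df$BETA) & is.finite(df$BETA) &
    !is.na(df$SE) & df$SE > 0 &
    !is.na(df$P) & df$P > 0 & df$P <= 1 &
    (is.na(df$EAF) | (df$EAF >= 0 & df$EAF <= 1)) &
    (is.na(df$N) | df$N > 0)
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  if (anyDuplicated(df$SNP)) {
    dup <- unique(df$SNP[duplicated(df$SNP)])
    stop("duplicate rsids in summary statistics for '", trait_name, "': ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("sumstat_set", "data.frame"))
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat(sprintf("<sumstat_set> trait '%s' (%s): %d variants, %d rows dropped at validation\n",
              attr(x, "trait_name"), attr(x, "trait_type"),
              nrow(x), attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Detect tab vs comma from the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty summary-statistics file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab or comma, auto-detected from the header
#' line), renames source headers to the canonical dialect via
#' \code{column_map}, and validates the result. Rows failing validation are
#' dropped, counted and reported via a message; a missing mandatory column
#' (SNP, EA, OA, BETA, SE, P) is a hard error naming the column.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to the
#'   file's headers, e.g. \code{c(SNP = "rsid", BETA = "b")}. Headers
#'   already in canonical form need no entry. \code{NULL} means the file is
#'   already canonical.
#' @param trait_name,trait_type trait metadata (see \code{\link{sumstat_set}}).
#' @return a \code{sumstat_set}.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = basename(path),
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE, quote = "")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df))
        stop("column '", src, "' (mapped to ", canon, ") not found in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  absent <- setdiff(MANDATORY_COLS, names(df))
  if (length(absent) > 0)
    stop("mandatory column(s) missing from ", path, ": ",
         paste(absent, collapse = ", "))
  out <- sumstat_set(df, trait_name = trait_name, trait_type = trait_type)
  if (attr(out, "n_dropped") > 0)
    message(attr(out, "n_dropped"), " row(s) dropped at validation for '",
            trait_name, "'")
  out
}

#' Write a summary-statistics set to delimited text
#'
#' Serializes in the canonical dialect (tab-separated, \code{NA} sentinel
#' for missing values) so that \code{read_sumstats(write_sumstats(x))}
#' reproduces \code{x} field for field.
#'
#' @param dataset a \code{sumstat_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  stopifnot(inherits(dataset, "sumstat_set"))
  utils::write.table(as.data.frame(dataset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
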