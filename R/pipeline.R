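# Orchestration: one exposure-outcome analysis end to end, batches of
# analyses, and report emission (delimited tables plus a machine-readable
# JSON object per analysis).

#' Analysis configuration
#'
#' Bundles the inputs and tuning parameters of one exposure-outcome
#' analysis. Exposure, outcome and LD inputs may be given either as file
#' paths (read with \code{\link{read_sumstats}} /
#' \code{\link{read_ld_matrix}}) or as in-memory objects.
#'
#' @param exposure,outcome path to a summary-statistics file or a
#'   \code{sumstat_set}.
#' @param exposure_name,outcome_name trait labels (default: taken from the
#'   objects or file names).
#' @param outcome_type \code{"continuous"} or \code{"binary"} (odds-ratio
#'   reporting scale).
#' @param exposure_map,outcome_map optional \code{column_map}s for file
#'   inputs.
#' @param ld path to an LD-matrix file, an \code{ld_matrix}, or
#'   \code{NULL} (all candidate pairs treated as independent, with a
#'   warning at clump time).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param clump_r2 clumping r^2 threshold (default 0.001).
#' @param clump_kb clumping window half-width in kb (default 10000).
#' @param f_min weak-instrument cutoff (default 0: report-only).
#' @param palindrome_eaf_band palindromic ambiguity band (default 0.08).
#' @param n_boot weighted-median bootstrap replicates (default 1000).
#' @param presso_n_sim MR-PRESSO simulations (default 1000).
#' @param presso_alpha MR-PRESSO outlier level (default 0.05).
#' @param seed integer seed, required (weighted median and MR-PRESSO are
#'   stochastic).
#' @return an object of class \code{analysis_config}.
#' @export
analysis_config <- function(exposure, outcome,
                            exposure_name = NULL, outcome_name = NULL,
                            outcome_type = c("continuous", "binary"),
                            exposure_map = NULL, outcome_map = NULL,
                            ld = NULL, p_threshold = 5e-8, clump_r2 = 0.001,
                            clump_kb = 10000, f_min = 0,
                            palindrome_eaf_band = 0.08, n_boot = 1000,
                            presso_n_sim = 1000, presso_alpha = 0.05, seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop("analysis_config requires an explicit seed")
  # YAML 1.1 parses bare y/n/yes/no as logicals; trait labels are strings
  if (!is.null(exposure_name)) exposure_name <- as.character(exposure_name)
  if (!is.null(outcome_name)) outcome_name <- as.character(outcome_name)
  stopifnot(is_scalar_number(seed),
            is_scalar_number(p_threshold), p_threshold > 0, p_threshold <= 1,
            is_scalar_number(clump_r2), clump_r2 >= 0, clump_r2 <= 1,
            is_scalar_number(clump_kb), clump_kb > 0,
            is_scalar_number(f_min), f_min >= 0,
            is_scalar_number(n_boot), n_boot >= 1,
            is_scalar_number(presso_n_sim), presso_n_sim >= 100,
            is_scalar_number(presso_alpha), presso_alpha > 0, presso_alpha < 1)
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 outcome_type = outcome_type,
                 exposure_map = exposure_map, outcome_map = outcome_map,
                 ld = ld, p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 palindrome_eaf_band = palindrome_eaf_band, n_boot = n_boot,
                 presso_n_sim = presso_n_sim, presso_alpha = presso_alpha,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read analysis configurations from a YAML file
#'
#' One analysis per document (or a top-level list of analyses); fields
#' mirror the arguments of \code{\link{analysis_config}} with file paths
#' for \code{exposure}, \code{outcome} and \code{ld}.
#'
#' @param path YAML file path.
#' @return a list of \code{analysis_config} objects.
#' @export
read_config <- function(path) {
  docs <- yaml::read_yaml(path)
  if (!is.null(docs$exposure)) docs <- list(docs)
  lapply(docs, function(d) do.call(analysis_config, d))
}

resolve_sumstats <- function(x, map, name, type) {
  if (inherits(x, "sumstat_set")) {
    if (!is.null(name)) attr(x, "trait_name") <- name
    attr(x, "trait_type") <- type
    return(x)
  }
  read_sumstats(x, column_map = map, trait_name = name %||% basename(x),
                trait_type = type)
}

pipeline_fail <- function(stage, msg) {
  stop_mrflow(paste0("analysis failed at stage '", stage, "': ", msg),
              "mrflow_pipeline_error", stage = stage)
}

#' Run one exposure-outcome MR analysis
#'
#' Executes the full pipeline: read and validate inputs, filter to
#' genome-wide significance, clump, screen instrument strength, harmonize
#' to the outcome, run MR-PRESSO once (flagged outliers are removed from
#' all subsequent estimators and logged), then the estimator and
#' sensitivity suites.
#'
#' Routing rules: a single surviving instrument reports only the Wald
#' estimator (no heterogeneity statistics); two instruments report the
#' IVW pair and Cochran's Q; three or more add MR-Egger, the weighted
#' median, Ruecker's Q, the Egger intercept test and leave-one-out.
#' MR-PRESSO runs with four or more. When Cochran's Q has p < 0.05 the
#' penalized-IVW row is added and flagged as the recommended summary
#' alongside the headline IVW-RE row. Estimators whose preconditions are
#' unmet are marked not-estimable and the run continues; exhausting all
#' instruments at any stage raises a structured error naming that stage.
#'
#' @param config an \code{analysis_config}.
#' @return an object of class \code{mr_report}: list with \code{header},
#'   \code{results} (method rows), \code{heterogeneity},
#'   \code{egger_intercept}, \code{presso}, \code{loo}, \code{funnel},
#'   \code{provenance}, \code{harmonization}, \code{not_estimable}.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- resolve_sumstats(config$exposure, config$exposure_map,
                               config$exposure_name, "continuous")
  outcome <- resolve_sumstats(config$outcome, config$outcome_map,
                              config$outcome_name, config$outcome_type)
  ld <- config$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)

  if (nrow(exposure) == 0) pipeline_fail("read", "exposure set is empty")

  inst <- select_instruments(exposure, p_threshold = config$p_threshold,
                             ld = ld, r2_threshold = config$clump_r2,
                             window_kb = config$clump_kb, f_min = config$f_min,
                             allow_missing_ld = is.null(ld))
  if (nrow(inst$data) == 0)
    pipeline_fail("instrument_selection", "no instruments survive the p-value/clumping/F screen")

  harm <- harmonize(inst, outcome,
                    palindrome_eaf_band = config$palindrome_eaf_band)
  hk <- kept_records(harm)
  if (nrow(hk) == 0)
    pipeline_fail("harmonization", "no instruments survive harmonization")
  hk <- orient_positive(hk)
  ot <- config$outcome_type

  presso <- NULL
  removed <- character(0)
  if (nrow(hk) >= 4) {
    presso <- mr_presso(hk, n_sim = config$presso_n_sim,
                        outlier_alpha = config$presso_alpha,
                        seed = child_seed(config$seed, 11))
    if (length(presso$outlier_indices) > 0 &&
        length(presso$outlier_indices) < nrow(hk)) {
      removed <- presso$outlier_rsids
      hk <- harmonized_set(
        as.data.frame(hk)[!hk$rsid %in% removed, , drop = FALSE],
        attr(hk, "exposure_name"), attr(hk, "exposure_type"),
        attr(hk, "outcome_name"), attr(hk, "outcome_type"))
    }
  }
  j <- nrow(hk)

  results <- list()
  not_estimable <- character(0)
  het <- NULL; intercept <- NULL; loo <- NULL

  if (j == 1) {
    results$wald <- mr_wald(hk, outcome_type = ot)
  } else {
    results$ivw_fe <- mr_ivw(hk, "fixed", outcome_type = ot)
    results$ivw_re <- mr_ivw(hk, "random", outcome_type = ot)
    het <- cochran_q(hk)
    if (j >= 3) {
      eg <- mr_egger(hk, outcome_type = ot)
      results$egger <- eg$result
      intercept <- eg$intercept
      results$weighted_median <- mr_weighted_median(
        hk, n_boot = config$n_boot, seed = child_seed(config$seed, 7),
        outcome_type = ot)
      het <- rbind(het, rucker_q(hk))
      loo <- leave_one_out(hk, outcome_type = ot)
    } else {
      not_estimable <- c(not_estimable, "egger", "weighted_median")
    }
    if (het$pval[het$statistic == "cochran_ivw"] < 0.05) {
      results$ivw_penalized <- mr_ivw_penalized(hk, outcome_type = ot)
    }
  }
  results_df <- do.call(rbind, results)
  rownames(results_df) <- NULL
  results_df <- cbind(exposure = attr(hk, "exposure_name"),
                      outcome = attr(hk, "outcome_name"), results_df,
                      stringsAsFactors = FALSE)

  headline <- if (j == 1) "wald" else "ivw_re"
  combined <- results_df[results_df$method == headline, , drop = FALSE]
  class(combined) <- c("mr_result", "data.frame")
  funnel <- if (j >= 2) funnel_data(hk, combined) else NULL

  prov <- inst$provenance
  miss <- as.data.frame(harm)[harm$action == "dropped", c("rsid", "drop_reason")]
  if (nrow(miss) > 0)
    prov$decision[match(miss$rsid, prov$rsid)] <-
      paste0("dropped:harmonization:", miss$drop_reason)
  if (length(removed) > 0)
    prov$decision[match(removed, prov$rsid)] <- "dropped:presso-outlier"

  header <- list(
    exposure = attr(hk, "exposure_name"), outcome = attr(hk, "outcome_name"),
    outcome_type = ot, p_threshold = config$p_threshold,
    clump_r2 = config$clump_r2, clump_kb = config$clump_kb,
    f_min = config$f_min, palindrome_eaf_band = config$palindrome_eaf_band,
    n_boot = config$n_boot, presso_n_sim = config$presso_n_sim,
    presso_alpha = config$presso_alpha, seed = config$seed,
    n_candidates = nrow(exposure), n_instruments = j,
    f_min_observed = if (j > 0) min(f_statistic(hk$beta_x, hk$se_x)) else NA,
    f_max_observed = if (j > 0) max(f_statistic(hk$beta_x, hk$se_x)) else NA,
    headline_method = if (!is.null(het) &&
                          het$pval[het$statistic == "cochran_ivw"] < 0.05)
                        "ivw_re (heterogeneity detected; see ivw_penalized)"
                      else headline,
    version = as.character(utils::packageVersion("mrflow")))

  structure(list(header = header, results = results_df, heterogeneity = het,
                 egger_intercept = intercept, presso = presso, loo = loo,
                 funnel = funnel, provenance = prov,
                 harmonization = as.data.frame(harm)[c("rsid", "action", "drop_reason")],
                 not_estimable = not_estimable),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  h <- x$header
  cat(sprintf("<mr_report> %s -> %s (%s outcome), %d instrument(s)\n",
              h$exposure, h$outcome, h$outcome_type, h$n_instruments))
  cat(sprintf("  F range %.1f-%.1f; headline: %s\n",
              h$f_min_observed, h$f_max_observed, h$headline_method))
  print(x$results, digits = 4)
  if (!is.null(x$heterogeneity)) {
    cat("heterogeneity:\n"); print(x$heterogeneity, digits = 4)
  }
  if (!is.null(x$egger_intercept)) {
    cat("Egger intercept:\n"); print(x$egger_intercept, digits = 4)
  }
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}

#' Serialize a report to JSON text
#'
#' Deterministic (fixed digit formatting), so byte-identical reports
#' certify byte-identical analyses.
#'
#' @param report an \code{mr_report}.
#' @return a JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  x <- report
  x$presso <- if (!is.null(x$presso)) unclass(x$presso)
  as.character(jsonlite::toJSON(unclass(x), dataframe = "rows",
                                auto_unbox = TRUE, digits = 10, na = "null"))
}

#' Write a report's tables to a directory
#'
#' Emits \code{results.tsv}, \code{diagnostics.tsv}, \code{loo.tsv},
#' \code{funnel.tsv}, \code{provenance.tsv}, \code{harmonization.tsv} and
#' \code{report.json}.
#'
#' @param report an \code{mr_report}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
  }
  wt(report$results, "results.tsv")
  diag <- report$heterogeneity
  if (!is.null(report$egger_intercept)) {
    ei <- report$egger_intercept
    diag <- rbind(diag, data.frame(statistic = "egger_intercept",
                                   q = ei$intercept, df = NA, pval = ei$pval))
  }
  if (!is.null(report$presso)) {
    diag <- rbind(diag,
                  data.frame(statistic = "presso_global", q = report$presso$rss_obs,
                             df = NA, pval = report$presso$global_pval),
                  data.frame(statistic = "presso_distortion", q = NA, df = NA,
                             pval = report$presso$distortion_pval))
  }
  wt(diag, "diagnostics.tsv")
  wt(report$loo, "loo.tsv")
  wt(report$funnel, "funnel.tsv")
  wt(report$provenance, "provenance.tsv")
  wt(report$harmonization, "harmonization.tsv")
  writeLines(report_json(report), file.path(dir, "report.json"))
  invisible(dir)
}

#' Run a batch of analyses
#'
#' Runs each configuration independently; one failing pair does not abort
#' the batch. Returns the reports plus a combined summary table keyed by
#' (exposure, outcome, method).
#'
#' @param configs list of \code{analysis_config} objects.
#' @return list with \code{reports} (one \code{mr_report} or failure
#'   record per config) and \code{summary} (combined method-row table;
#'   empty data frame for an empty batch).
#' @export
run_batch <- function(configs) {
  stopifnot(is.list(configs))
  reports <- lapply(configs, function(cfg) {
    tryCatch(run_analysis(cfg), mrflow_error = function(e) {
      list(failed = TRUE, stage = e$stage %||% NA_character_,
           message = conditionMessage(e))
    })
  })
  ok <- vapply(reports, function(r) inherits(r, "mr_report"), logical(1))
  summary <- if (any(ok)) {
    out <- do.call(rbind, lapply(reports[ok], `[[`, "results"))
    rownames(out) <- NULL
    out
  } else {
    data.frame(exposure = character(0), outcome = character(0),
               method = character(0), n_snp = integer(0),
               estimate = numeric(0), se = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), pval = numeric(0), or = numeric(0),
               or_ci_low = numeric(0), or_ci_high = numeric(0))
  }
  failures <- lapply(reports[!ok], function(r) r[c("stage", "message")])
  list(reports = reports, summary = summary, failures = failures)
}
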