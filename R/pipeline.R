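# End-to-end orchestration: many exposures, one binary outcome. Exposures
# are analyzed marginally and independently (no multivariable MR); one
# failing exposure never aborts the run. Structured per-stage counts make
# the "how many instruments survived" audit reproducible on any dataset.

#' Build a validated run configuration
#'
#' @param exposure_paths character vector of exposure summary-statistics TSV
#'   paths (quantitative, per-SD scale).
#' @param outcome_path outcome summary-statistics TSV (binary, log-odds
#'   scale).
#' @param ld_dir LD reference directory (see [read_ld()]).
#' @param p_threshold instrument significance threshold (default `1e-8`;
#'   note this is stricter than the conventional `5e-8`).
#' @param clump_r2,clump_window_bp clumping parameters (defaults 0.001 and
#'   10 Mb).
#' @param min_f weak-instrument threshold; instruments with F below this are
#'   dropped (default 10).
#' @param maf_threshold minor-allele-frequency exclusion boundary,
#'   inclusive (default 0.01).
#' @param ci_level confidence level for reported intervals (default 0.95).
#' @param alpha nominal significance threshold for [significant_results()]
#'   (default 0.05).
#' @param wald_se_order,steiger_effective_n estimation options, see
#'   [estimate_exposure()].
#' @param sources optional character vector labelling the association source
#'   of each exposure (recycled); carried into the results table so
#'   multi-source replication can be tabulated.
#' @param seed optional integer seed set at the start of [mr_run()] (the
#'   pipeline itself is deterministic; this pins any stochastic subroutine a
#'   caller adds downstream).
#' @param output_dir if non-NULL, [mr_run()] writes `results.tsv`,
#'   `significant.tsv`, `forest.tsv`, `selection_log.tsv`,
#'   `exclusion_log.tsv` and `run_report.json` there.
#' @return An `mr_config` list.
#' @export
mr_config <- function(exposure_paths, outcome_path, ld_dir,
                      p_threshold = 1e-8, clump_r2 = 0.001,
                      clump_window_bp = 1e7, min_f = 10,
                      maf_threshold = 0.01, ci_level = 0.95, alpha = 0.05,
                      wald_se_order = 1, steiger_effective_n = FALSE,
                      sources = NA_character_, seed = NULL,
                      output_dir = NULL) {
  check_fraction(p_threshold, "p_threshold")
  check_fraction(clump_r2, "clump_r2", lo_open = FALSE, hi_open = FALSE)
  check_fraction(maf_threshold, "maf_threshold", lo_open = FALSE)
  check_fraction(ci_level, "ci_level")
  check_fraction(alpha, "alpha")
  if (min_f < 0) abort("`min_f` must be >= 0")
  if (clump_window_bp < 0) abort("`clump_window_bp` must be >= 0")
  structure(list(exposure_paths = exposure_paths,
                 outcome_path = outcome_path, ld_dir = ld_dir,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, min_f = min_f,
                 maf_threshold = maf_threshold, ci_level = ci_level,
                 alpha = alpha, wald_se_order = wald_se_order,
                 steiger_effective_n = steiger_effective_n,
                 sources = rep_len(sources, length(exposure_paths)),
                 seed = seed, output_dir = output_dir),
            class = "mr_config")
}

no_instrument_row <- function(exposure_id, source, status) {
  data.frame(exposure_id = exposure_id, source = source, status = status,
             method = NA_character_, n_iv = 0L, theta = NA_real_,
             se = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pvalue = NA_real_, q_stat = NA_real_,
             steiger_direction = NA_character_, steiger_pvalue = NA_real_,
             iv_ids = "", stringsAsFactors = FALSE)
}

#' Run the full two-sample MR pipeline
#'
#' For each exposure: [select_instruments()] (significance filter, LD
#' clumping, F screen) -> [harmonize_set()] -> [estimate_exposure()].
#' Exposures with zero surviving instruments appear in the results with
#' status `"no_instruments"`; an exposure whose estimation errors gets
#' status `"error"` with the message — neither aborts the others. An
#' unreadable outcome or LD reference fails fast, naming the file.
#'
#' @param config an [mr_config()]. Exposure entries may be file paths or
#'   in-memory [sumstats()] objects.
#' @return An `mr_run` list: `results` (one data.frame row per exposure,
#'   with `status` and `source` columns and an informational
#'   Benjamini-Hochberg `pvalue_fdr` that never gates the significance
#'   calls), `mr_results` (list of `mr_result`
#'   objects for successful exposures), `selection_log`, `exclusion_log`,
#'   and `report` (per-stage counts per exposure plus the total instrument
#'   counts before and after harmonization).
#' @export
mr_run <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  outcome <- if (inherits(config$outcome_path, "sumstats")) config$outcome_path
             else read_sumstats(config$outcome_path, trait_type = "binary")
  ld <- if (inherits(config$ld_dir, "ld_reference")) config$ld_dir
        else read_ld(config$ld_dir)

  rows <- list(); mr_results <- list()
  sel_logs <- list(); excl_logs <- list(); stage_counts <- list()

  for (i in seq_along(config$exposure_paths)) {
    exp_in <- if (is.list(config$exposure_paths)) config$exposure_paths[[i]]
              else config$exposure_paths[i]
    src <- config$sources[i]
    eid <- if (inherits(exp_in, "sumstats")) exp_in$trait_id
           else sub("\\.[^.]*$", "", basename(exp_in))

    row <- tryCatch({
      ss <- if (inherits(exp_in, "sumstats")) exp_in
            else read_sumstats(exp_in, trait_type = "quantitative")
      eid <- ss$trait_id
      iset <- select_instruments(ss, ld,
                                 p_threshold = config$p_threshold,
                                 f_min = config$min_f,
                                 r2_threshold = config$clump_r2,
                                 window_bp = config$clump_window_bp)
      sel <- iset$selection_log
      sel$exposure_id <- eid
      sel_logs[[length(sel_logs) + 1L]] <- sel

      counts <- list(exposure_id = eid,
                     n_candidates = nrow(ss$records),
                     n_significant = sum(sel$disposition != "dropped-p"),
                     n_post_clump = sum(sel$disposition %in% c("kept", "dropped-F")),
                     n_post_f = nrow(iset$members))

      if (nrow(iset$members) == 0L) {
        counts$n_harmonized <- 0L
        stage_counts[[length(stage_counts) + 1L]] <- counts
        no_instrument_row(eid, src, "no_instruments")
      } else {
        hset <- harmonize_set(iset, outcome,
                              maf_threshold = config$maf_threshold)
        if (nrow(hset$exclusions) > 0L) {
          ex <- hset$exclusions
          ex$exposure_id <- eid
          excl_logs[[length(excl_logs) + 1L]] <- ex
        }
        counts$n_harmonized <- nrow(hset$instruments)
        stage_counts[[length(stage_counts) + 1L]] <- counts

        if (nrow(hset$instruments) == 0L) {
          no_instrument_row(eid, src, "no_instruments")
        } else {
          res <- estimate_exposure(hset, ci_level = config$ci_level,
                                   wald_se_order = config$wald_se_order,
                                   steiger_effective_n = config$steiger_effective_n)
          mr_results[[eid]] <- res
          df <- as.data.frame(res)
          df$source <- src
          df$status <- "ok"
          df[, c("exposure_id", "source", "status",
                 setdiff(names(df), c("exposure_id", "source", "status")))]
        }
      }
    }, error = function(e) {
      r <- no_instrument_row(eid, src, "error")
      r$iv_ids <- conditionMessage(e)
      r
    })
    rows[[length(rows) + 1L]] <- row
  }

  results <- data.table::rbindlist(rows, fill = TRUE)
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  # informational Benjamini-Hochberg column; never gates significance calls
  results$pvalue_fdr <- NA_real_
  ok_idx <- results$status == "ok"
  results$pvalue_fdr[ok_idx] <- stats::p.adjust(results$pvalue[ok_idx],
                                                method = "BH")
  selection_log <- if (length(sel_logs)) do.call(rbind, sel_logs) else
    data.frame(variant_id = character(0), disposition = character(0),
               exposure_id = character(0), stringsAsFactors = FALSE)
  exclusion_log <- if (length(excl_logs)) do.call(rbind, excl_logs) else
    data.frame(variant_id = character(0), reason = character(0),
               exposure_id = character(0), stringsAsFactors = FALSE)

  report <- list(
    n_exposures = length(config$exposure_paths),
    n_estimated = sum(results$status == "ok"),
    n_no_instruments = sum(results$status == "no_instruments"),
    n_errors = sum(results$status == "error"),
    total_ivs_selected = sum(vapply(stage_counts, `[[`, integer(1), "n_post_f")),
    total_ivs_harmonized = sum(vapply(stage_counts, `[[`, integer(1), "n_harmonized")),
    per_exposure = stage_counts
  )

  run <- structure(list(results = results, mr_results = mr_results,
                        selection_log = selection_log,
                        exclusion_log = exclusion_log,
                        report = report, config = config),
                   class = "mr_run")

  if (!is.null(config$output_dir)) write_run_outputs(run, config$output_dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- run$results[run$results$status == "ok", , drop = FALSE]
  if (nrow(ok) > 0L) {
    write_results(ok, file.path(dir, "results.tsv"))
  } else {
    suppressWarnings(write_results(ok, file.path(dir, "results.tsv")))
  }
  sig <- significant_results(run$results, run$config$alpha)
  data.table::fwrite(sig, file.path(dir, "significant.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  data.table::fwrite(forest_data(run$results, run$config$alpha),
                     file.path(dir, "forest.tsv"), sep = "\t", quote = FALSE,
                     na = "NA")
  data.table::fwrite(run$selection_log, file.path(dir, "selection_log.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(run$exclusion_log, file.path(dir, "exclusion_log.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(run$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.mr_run <- function(x, ...) {
  cat(sprintf("<mr_run> %d exposure(s): %d estimated, %d without instruments, %d error(s); %d instrument(s) after harmonization\n",
              x$report$n_exposures, x$report$n_estimated,
              x$report$n_no_instruments, x$report$n_errors,
              x$report$total_ivs_harmonized))
  invisible(x)
}

#' Filter results to nominal significance and annotate effect direction
#'
#' Keeps successfully estimated rows with `pvalue < alpha`, annotates each
#' as `"protective"` (OR < 1) or `"risk"` (OR > 1), and sorts by OR.
#'
#' @param results results data.frame from [mr_run()] (`$results`) or an
#'   `mr_run` object.
#' @param alpha nominal threshold; default 0.05.
#' @return data.frame with a `class` column, sorted by `or`.
#' @export
significant_results <- function(results, alpha = 0.05) {
  if (inherits(results, "mr_run")) results <- results$results
  check_fraction(alpha, "alpha")
  if (!"status" %in% names(results)) results$status <- "ok"
  keep <- results$status == "ok" & !is.na(results$pvalue) &
    results$pvalue < alpha
  out <- results[keep, , drop = FALSE]
  out$class <- ifelse(out$or < 1, "protective",
                      ifelse(out$or > 1, "risk", "null"))
  out <- out[order(out$or, out$exposure_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forest-plot table of significant associations
#'
#' Plot-ready rows (label, OR, CI bounds, protective/risk class), ordered by
#' decreasing OR so risk-enhancing exposures sit at the top. No graphics are
#' computed; render with any plotting layer.
#'
#' @inheritParams significant_results
#' @return data.frame with columns `label`, `or`, `ci_low`, `ci_high`,
#'   `pvalue`, `class`.
#' @export
forest_data <- function(results, alpha = 0.05) {
  sig <- significant_results(results, alpha)
  out <- data.frame(label = sig$exposure_id, or = sig$or,
                    ci_low = sig$ci_low, ci_high = sig$ci_high,
                    pvalue = sig$pvalue, class = sig$class,
                    stringsAsFactors = FALSE)
  out[order(-out$or, out$label), , drop = FALSE]
}
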