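# File I/O for GWAS summary statistics, LD references, and results tables.
# This module is the pipeline's only contact with files. The tabular dialect
# is fixed (no auto-detection of alternative GWAS header conventions):
# tab-separated, UTF-8, header required.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")
SUMSTATS_BINARY_COLS <- c("n_case", "n_control")

RESULTS_COLS <- c("exposure_id", "method", "n_iv", "theta", "se", "or",
                  "ci_low", "ci_high", "pvalue", "steiger_direction",
                  "steiger_pvalue", "iv_ids")

#' Construct a summary-statistics object from a data frame
#'
#' The in-memory container for one GWAS: one row per variant with alleles,
#' effect-allele frequency, effect size, standard error, p-value and sample
#' size. Exposure effects are per SD of the trait; binary-outcome effects are
#' log odds per effect-allele copy. Rows violating the per-variant invariants
#' (ACGT alleles, distinct alleles, `se > 0`, `eaf` in \[0,1\], `pvalue` in
#' (0,1\], `pos >= 1`, `n >= 2`) are dropped and counted in the `rejections`
#' attribute; a duplicated `variant_id` is an error.
#'
#' @param records data.frame with columns
#'   `variant_id chrom pos effect_allele other_allele eaf beta se pvalue n`
#'   (plus `n_case`, `n_control` for a binary trait). Lowercase alleles are
#'   normalized to uppercase; a missing `eaf` is permitted (palindromic
#'   variants are dropped in harmonization, so frequency-based strand
#'   inference is never needed) and flagged in `n_missing_eaf`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`; binary requires
#'   `n_case`/`n_control` columns.
#' @return A `sumstats` object: list with `trait_id`, `trait_type`, `records`
#'   (validated data.frame keyed by `variant_id`), and attributes
#'   `rejections` (data.frame of dropped rows with reasons) and
#'   `n_missing_eaf`.
#' @seealso [read_sumstats()], [write_sumstats()]
#' @export
#' @examples
#' df <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = 0.1, se = 0.02, pvalue = 1e-9, n = 1800)
#' ss <- sumstats(df, trait_id = "taxon1", trait_type = "quantitative")
sumstats <- function(records, trait_id, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  missing_cols <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing_cols) > 0L)
    abort("summary statistics for '%s' lack required column(s): %s",
          trait_id, paste(missing_cols, collapse = ", "))
  if (trait_type == "binary") {
    missing_bin <- setdiff(SUMSTATS_BINARY_COLS, names(records))
    if (length(missing_bin) > 0L)
      abort("binary trait '%s' lacks required column(s): %s",
            trait_id, paste(missing_bin, collapse = ", "))
  } else {
    for (col in SUMSTATS_BINARY_COLS)
      if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  records <- records[, c(SUMSTATS_COLS, SUMSTATS_BINARY_COLS)]

  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n", "n_case", "n_control"))
    records[[col]] <- as.numeric(records[[col]])

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(!records$effect_allele %in% ACGT | !records$other_allele %in% ACGT,
       "non_acgt_allele")
  flag(records$effect_allele == records$other_allele, "identical_alleles")
  flag(!is.finite(records$se) | records$se <= 0, "nonpositive_se")
  flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1), "eaf_range")
  flag(!is.finite(records$beta), "nonfinite_beta")
  flag(!is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
       "pvalue_range")
  flag(is.na(records$pos) | records$pos < 1L, "bad_position")
  flag(!is.finite(records$n) | records$n < 2, "bad_n")
  if (trait_type == "binary")
    flag(!is.finite(records$n_case) | !is.finite(records$n_control) |
           records$n_case < 1 | records$n_control < 1, "bad_case_counts")

  rejections <- data.frame(variant_id = records$variant_id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  kept <- records[is.na(reason), , drop = FALSE]

  dup <- unique(kept$variant_id[duplicated(kept$variant_id)])
  if (length(dup) > 0L)
    abort("duplicate variant_id in '%s': %s", trait_id,
          paste(head(dup, 5L), collapse = ", "))
  rownames(kept) <- NULL

  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = kept),
    rejections = rejections,
    n_missing_eaf = sum(is.na(kept$eaf)),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s): %d variants", x$trait_id, x$trait_type,
              nrow(x$records)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0L)
    cat(sprintf(", %d rejected on read", nrow(rej)))
  cat("\n")
  invisible(x)
}

#' Read GWAS summary statistics from a TSV file
#'
#' Expects the fixed tab-separated dialect with header columns
#' `variant_id chrom pos effect_allele other_allele eaf beta se pvalue n`
#' (plus `n_case n_control` for a binary trait). Invalid rows are dropped and
#' counted (see [sumstats()]); a missing required column or a duplicate
#' `variant_id` is an error.
#'
#' @param path path to the TSV file.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id trait name; defaults to the file name without extension.
#' @return A [sumstats()] object.
#' @export
read_sumstats <- function(path, trait_type = c("quantitative", "binary"),
                          trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort("summary-statistics file not found: %s", path)
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("variant_id", "chrom")),
                          data.table = FALSE, showProgress = FALSE)
  sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write summary statistics to the canonical TSV dialect
#'
#' Values round-trip through [read_sumstats()] to at least 12 significant
#' digits.
#'
#' @param ss a [sumstats()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  df <- ss$records
  if (ss$trait_type != "binary")
    df <- df[, SUMSTATS_COLS]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "pos"
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# LD reference ---------------------------------------------------------------

ld_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Construct an LD reference from positions and signed correlations
#'
#' A file-backed stand-in for a genotype reference panel: variant positions
#' plus a sparse symmetric map of signed correlations `r`. Absent pairs mean
#' `r = 0`; the diagonal is exactly 1.
#'
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`.
#' @param pairs data.frame with columns `id_a`, `id_b`, `r` (long format;
#'   either orientation, symmetric closure is applied). May be empty.
#' @param strict if `TRUE` (default) a self-pair with `r != 1` or a duplicated
#'   pair with conflicting values is an error; with `strict = FALSE`
#'   self-pairs are coerced to 1 (conflicts remain errors).
#' @return An `ld_reference` object with elements `positions` and `r` (an
#'   internal keyed map); query it with [ld_r()].
#' @export
ld_reference <- function(positions, pairs = NULL, strict = TRUE) {
  positions <- as.data.frame(positions, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos")
  if (!all(need %in% names(positions)))
    abort("LD positions table needs columns: %s", paste(need, collapse = ", "))
  positions$variant_id <- as.character(positions$variant_id)
  positions$chrom <- as.character(positions$chrom)
  positions$pos <- as.integer(positions$pos)
  if (anyDuplicated(positions$variant_id))
    abort("duplicate variant_id in LD positions table")
  if (any(is.na(positions$pos) | positions$pos < 1L))
    abort("LD positions must be 1-based integers")
  rownames(positions) <- NULL

  rmap <- numeric(0)
  n_rejected <- 0L
  if (!is.null(pairs) && nrow(as.data.frame(pairs)) > 0L) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b", "r") %in% names(pairs)))
      abort("LD pair table needs columns: id_a, id_b, r")
    pairs$id_a <- as.character(pairs$id_a)
    pairs$id_b <- as.character(pairs$id_b)
    pairs$r <- as.numeric(pairs$r)

    unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), positions$variant_id)
    if (length(unknown) > 0L)
      abort("LD pairs reference variant(s) absent from the positions table: %s",
            paste(head(unknown, 5L), collapse = ", "))

    bad <- !is.finite(pairs$r) | abs(pairs$r) > 1
    n_rejected <- sum(bad)
    pairs <- pairs[!bad, , drop = FALSE]

    self <- pairs$id_a == pairs$id_b
    if (any(self & pairs$r != 1)) {
      if (strict)
        abort("LD self-pair with r != 1 for variant(s): %s (set strict = FALSE to coerce to 1)",
              paste(head(unique(pairs$id_a[self & pairs$r != 1]), 5L),
                    collapse = ", "))
      pairs$r[self] <- 1
    }
    pairs <- pairs[!self, , drop = FALSE]

    if (nrow(pairs) > 0L) {
      key <- ld_pair_key(pairs$id_a, pairs$id_b)
      split_r <- split(pairs$r, key)
      conflict <- vapply(split_r, function(v) diff(range(v)) > 1e-9, logical(1))
      if (any(conflict))
        abort("conflicting LD values for pair(s): %s",
              paste(head(gsub("\t", "/", names(split_r)[conflict]), 5L),
                    collapse = ", "))
      rmap <- vapply(split_r, `[[`, numeric(1), 1L)
    }
  }

  structure(
    list(positions = positions, r = rmap),
    n_rejected = n_rejected,
    class = "ld_reference"
  )
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants, %d stored off-diagonal pairs\n",
              nrow(x$positions), length(x$r)))
  invisible(x)
}

#' Look up signed LD correlations
#'
#' Vectorized over `a`/`b`. Pairs absent from the reference return 0;
#' self-pairs return 1.
#'
#' @param ld an [ld_reference()].
#' @param a,b character vectors of variant ids (recycled to common length).
#' @return numeric vector of signed correlations in \[-1, 1\].
#' @export
ld_r <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  r <- unname(ld$r[ld_pair_key(a, b)])
  r[is.na(r)] <- 0
  r[a == b] <- 1
  r
}

#' Read an LD reference directory
#'
#' Expects `positions.tsv` (`variant_id chrom pos`) and `ld.tsv`
#' (`id_a id_b r`, long format, sparse: absent pairs mean r = 0) inside
#' `dir`. Symmetric closure is applied; pairs with `|r| > 1` are dropped and
#' counted; conflicting duplicates are an error.
#'
#' @param dir directory containing the two files.
#' @param strict passed to [ld_reference()]: error on self-pairs with
#'   `r != 1` (default) or coerce them to 1.
#' @return An [ld_reference()].
#' @export
read_ld <- function(dir, strict = TRUE) {
  pos_path <- file.path(dir, "positions.tsv")
  ld_path <- file.path(dir, "ld.tsv")
  if (!file.exists(pos_path)) abort("LD positions file not found: %s", pos_path)
  if (!file.exists(ld_path)) abort("LD pair file not found: %s", ld_path)
  positions <- data.table::fread(pos_path, sep = "\t", header = TRUE,
                                 colClasses = list(character = c("variant_id", "chrom")),
                                 data.table = FALSE, showProgress = FALSE)
  pairs <- data.table::fread(ld_path, sep = "\t", header = TRUE,
                             colClasses = list(character = c("id_a", "id_b")),
                             data.table = FALSE, showProgress = FALSE)
  ld_reference(positions, pairs, strict = strict)
}

#' Write an LD reference directory
#'
#' Inverse of [read_ld()]: writes `positions.tsv` and `ld.tsv` under `dir`
#' (created if needed).
#'
#' @param ld an [ld_reference()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ld <- function(ld, dir) {
  stopifnot(inherits(ld, "ld_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(ld$positions, file.path(dir, "positions.tsv"),
                     sep = "\t", quote = FALSE)
  if (length(ld$r) > 0L) {
    ids <- strsplit(names(ld$r), "\t", fixed = TRUE)
    pairs <- data.frame(id_a = vapply(ids, `[[`, "", 1L),
                        id_b = vapply(ids, `[[`, "", 2L),
                        r = formatC(unname(ld$r), digits = 12, format = "g"),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id_a = character(0), id_b = character(0),
                        r = character(0))
  }
  data.table::fwrite(pairs, file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

# Results table --------------------------------------------------------------

#' Write an MR results table
#'
#' One row per (exposure, method); columns
#' `exposure_id method n_iv theta se or ci_low ci_high pvalue
#' steiger_direction steiger_pvalue iv_ids`. Numeric values round-trip
#' through [read_results()] to at least 12 significant digits. An empty
#' collection writes a header-only file with a warning.
#'
#' @param results a data.frame of results (e.g. `$results` from [mr_run()],
#'   or `as.data.frame()` of one or more `mr_result` objects).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "mr_result")) results <- as.data.frame(results)
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  if (nrow(results) == 0L) {
    warning("writing header-only results file: empty result collection")
    empty <- setNames(rep(list(character(0)), length(RESULTS_COLS)), RESULTS_COLS)
    data.table::fwrite(as.data.frame(empty), path, sep = "\t", quote = FALSE)
    return(invisible(path))
  }
  missing_cols <- setdiff(RESULTS_COLS, names(results))
  if (length(missing_cols) > 0L)
    abort("results table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  out <- results[, RESULTS_COLS]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_iv"
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12, format = "g"))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an MR results table written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame with the canonical results columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort("results file not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("exposure_id", "method",
                                                          "steiger_direction", "iv_ids")),
                          showProgress = FALSE)
  missing_cols <- setdiff(RESULTS_COLS, names(df))
  if (length(missing_cols) > 0L)
    abort("results file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  df
}
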