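# Instrument selection: genome-wide significance filter, greedy LD clumping,
# and the weak-instrument F screen. Filter order is fixed and documented:
# significance -> clump -> F. Boundary behavior is strict and deterministic:
# keep p < p_threshold; drop F < f_min (so F == f_min is retained).

#' Single-variant instrument-strength F statistic
#'
#' The single-SNP approximation `F = (beta/se)^2`, i.e. the squared z score.
#' The alternative `F = r2 * (n - 2) / (1 - r2)` with
#' `r2 = z^2 / (z^2 + n - 2)` (see [r2_from_association()]) is available via
#' `method = "r2"`; for a single variant the two forms are algebraically
#' identical, so the option exists for transparency rather than numerics.
#' Instruments with F below 10 are conventionally considered too weak.
#'
#' @param beta,se effect estimate and its standard error (vectorized).
#' @param method `"z2"` (default) or `"r2"`.
#' @param n sample size, required for `method = "r2"`.
#' @return numeric vector of F statistics (>= 0).
#' @export
#' @examples
#' f_statistic(0.1, 0.01) # 100
f_statistic <- function(beta, se, method = c("z2", "r2"), n = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be > 0 and finite")
  z2 <- (beta / se)^2
  if (method == "z2") return(z2)
  if (is.null(n)) abort("`n` is required for method = \"r2\"")
  if (any(n <= 2)) abort("`n` must exceed 2 for method = \"r2\"")
  r2 <- z2 / (z2 + n - 2)
  r2 * (n - 2) / (1 - r2)
}

#' Filter variants by genome-wide significance
#'
#' Keeps rows with `pvalue` strictly below the threshold; a variant at
#' exactly the threshold is excluded.
#'
#' @param ss a [sumstats()] object.
#' @param p_threshold significance threshold in (0, 1); default `1e-8`.
#' @return data.frame of retained variant rows (possibly empty).
#' @export
significance_filter <- function(ss, p_threshold = 1e-8) {
  stopifnot(inherits(ss, "sumstats"))
  check_fraction(p_threshold, "p_threshold")
  ss$records[ss$records$pvalue < p_threshold, , drop = FALSE]
}

canonical_candidate_order <- function(df) {
  order(df$pvalue, df$chrom, df$pos, df$variant_id, method = "radix")
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining candidate with the smallest p-value as an
#' index variant and removes every remaining candidate on the same chromosome
#' within `window_bp` of it (inclusive) whose squared correlation with it
#' exceeds `r2_threshold`. Ties on p-value are broken by
#' (chrom, pos, variant_id) order, so the output is independent of input row
#' order. Clumping uses `r^2` from the signed reference; the sign is ignored.
#' Variants on different chromosomes are never clumped together, whatever the
#' reference records for the pair.
#'
#' @param candidates data.frame of variant rows (as from
#'   [significance_filter()]); every `variant_id` must be present in
#'   `ld$positions` — an absent one is an error, not a silent `r = 0`.
#' @param ld an [ld_reference()].
#' @param r2_threshold squared-correlation threshold; default 0.001.
#' @param window_bp clumping window in base pairs, inclusive at both ends;
#'   default 10 Mb.
#' @param exposure_id label carried into the result.
#' @return An `instrument_set`: list with `exposure_id`, `members` (index
#'   variants in selection order, with an `f_stat` column) and
#'   `selection_log` (one row per input candidate: `kept` or
#'   `clumped-away-by:<index id>`).
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, window_bp = 1e7,
                  exposure_id = NA_character_) {
  stopifnot(inherits(ld, "ld_reference"))
  check_fraction(r2_threshold, "r2_threshold", lo_open = FALSE, hi_open = FALSE)
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)

  if (nrow(candidates) == 0L) {
    return(new_instrument_set(exposure_id, candidates,
                              data.frame(variant_id = character(0),
                                         disposition = character(0))))
  }
  missing_ids <- setdiff(candidates$variant_id, ld$positions$variant_id)
  if (length(missing_ids) > 0L)
    abort("clump(): candidate variant(s) absent from the LD reference positions: %s",
          paste(head(missing_ids, 5L), collapse = ", "))

  # Positions/chromosomes come from the LD reference, the clumping authority.
  idx <- match(candidates$variant_id, ld$positions$variant_id)
  cand <- data.frame(variant_id = candidates$variant_id,
                     chrom = ld$positions$chrom[idx],
                     pos = ld$positions$pos[idx],
                     pvalue = candidates$pvalue,
                     stringsAsFactors = FALSE)
  ord <- canonical_candidate_order(cand)
  cand <- cand[ord, , drop = FALSE]

  disposition <- setNames(rep(NA_character_, nrow(cand)), cand$variant_id)
  keep_ids <- character(0)
  remaining <- seq_len(nrow(cand))
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    id_i <- cand$variant_id[i]
    keep_ids <- c(keep_ids, id_i)
    disposition[id_i] <- "kept"
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    same_chrom <- cand$chrom[remaining] == cand$chrom[i]
    in_window <- abs(cand$pos[remaining] - cand$pos[i]) <= window_bp
    r <- ld_r(ld, cand$variant_id[remaining], id_i)
    hit <- same_chrom & in_window & (r * r > r2_threshold)
    if (any(hit)) {
      disposition[cand$variant_id[remaining[hit]]] <-
        paste0("clumped-away-by:", id_i)
      remaining <- remaining[!hit]
    }
  }

  members <- candidates[match(keep_ids, candidates$variant_id), , drop = FALSE]
  rownames(members) <- NULL
  log_df <- data.frame(variant_id = cand$variant_id,
                       disposition = unname(disposition[cand$variant_id]),
                       stringsAsFactors = FALSE)
  new_instrument_set(exposure_id, members, log_df)
}

new_instrument_set <- function(exposure_id, members, selection_log) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (!"f_stat" %in% names(members)) {
    members$f_stat <- if (nrow(members) > 0L &&
                          all(c("beta", "se") %in% names(members)))
      f_statistic(members$beta, members$se) else rep(NA_real_, nrow(members))
  }
  rownames(members) <- NULL
  structure(list(exposure_id = exposure_id, members = members,
                 selection_log = selection_log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instrument(s) of %d candidate(s)\n",
              x$exposure_id, nrow(x$members), nrow(x$selection_log)))
  invisible(x)
}

#' Select independent, strong instruments for one exposure
#'
#' Composition of [significance_filter()] (keep `pvalue < p_threshold`),
#' [clump()], and the weak-instrument screen (drop `f_stat < f_min`, so a
#' variant with F exactly at `f_min` is retained). The selection log accounts
#' for every variant in the input with one of `kept`, `dropped-p`,
#' `dropped-F`, or `clumped-away-by:<id>`. An index variant dropped by the F
#' screen is not replaced by the candidates it clumped away.
#'
#' @param ss exposure [sumstats()].
#' @param ld an [ld_reference()] covering at least the significant candidates.
#' @param p_threshold significance threshold; default `1e-8`.
#' @param f_min minimum F statistic; default 10.
#' @param r2_threshold,window_bp clumping parameters (defaults 0.001, 10 Mb).
#' @return An `instrument_set` (see [clump()]); `members` may be empty.
#' @export
select_instruments <- function(ss, ld, p_threshold = 1e-8, f_min = 10,
                               r2_threshold = 0.001, window_bp = 1e7) {
  stopifnot(inherits(ss, "sumstats"))
  sig <- significance_filter(ss, p_threshold)
  iset <- clump(sig, ld, r2_threshold = r2_threshold, window_bp = window_bp,
                exposure_id = ss$trait_id)

  weak <- iset$members$f_stat < f_min
  log_df <- iset$selection_log
  if (any(weak)) {
    log_df$disposition[log_df$variant_id %in% iset$members$variant_id[weak]] <-
      "dropped-F"
    iset$members <- iset$members[!weak, , drop = FALSE]
    rownames(iset$members) <- NULL
  }

  dropped_p <- setdiff(ss$records$variant_id, log_df$variant_id)
  if (length(dropped_p) > 0L)
    log_df <- rbind(log_df,
                    data.frame(variant_id = dropped_p,
                               disposition = "dropped-p",
                               stringsAsFactors = FALSE))
  iset$selection_log <- log_df
  iset
}
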