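# Allele harmonization: re-express the outcome association on the exposure's
# effect allele, excluding palindromic, rare, and unresolvable variants.
# The exposure orientation is never altered; only the outcome record is
# re-expressed. Palindromic variants are dropped outright (never
# frequency-inferred), so the pipeline does not depend on eaf for strand
# resolution.

#' Is an allele pair palindromic?
#'
#' A biallelic SNV is palindromic (strand-ambiguous) when its two alleles are
#' reverse complements of each other: \{A,T\} or \{C,G\}. For such variants
#' the reporting strand cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-base alleles (A/C/G/T,
#'   vectorized; case-insensitive).
#' @return logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T") # TRUE
#' is_palindromic("A", "G") # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!ea %in% ACGT) || any(!oa %in% ACGT))
    abort("alleles must be single bases A/C/G/T")
  unname(BASE_COMPLEMENT[ea] == oa)
}

complement_alleles <- function(a) unname(BASE_COMPLEMENT[toupper(a)])

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome association onto the exposure's effect allele. Cases,
#' tested in order:
#' \enumerate{
#'   \item palindromic allele pair: excluded (`"palindrome"`);
#'   \item outcome alleles identical to the exposure's: effects copied;
#'   \item outcome alleles swapped: `beta_y` negated, outcome `eaf`
#'     replaced by `1 - eaf`;
#'   \item outcome alleles match after strand complementation (including
#'     complement + swap): complemented, then as (2)/(3);
#'   \item anything else: excluded (`"allele_mismatch"`) — the unresolvable
#'     "ambiguity" class for biallelic SNVs.
#' }
#' After alignment the minor-allele-frequency rule applies: variants with
#' `min(eaf, 1 - eaf) <= maf_threshold` are excluded (`"maf"`), using the
#' exposure-study frequency (the exposure defines the instrument), falling
#' back to the aligned outcome frequency when the exposure's is missing.
#'
#' @param exposure_rec,outcome_rec single variant rows (1-row data.frame or
#'   named list) with the [sumstats()] record fields; must share `variant_id`.
#' @param maf_threshold exclusion boundary, inclusive; default 0.01.
#' @return On success, a list `(status = "ok", instrument = <1-row
#'   data.frame>)` where the instrument carries `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `eaf`, `n_x`, `n_y`, `n_case`, `n_control`, `pvalue_x`. On exclusion,
#'   `(status = "excluded", reason = <string>)`.
#' @export
harmonize_pair <- function(exposure_rec, outcome_rec, maf_threshold = 0.01) {
  ex <- as.list(exposure_rec)
  oc <- as.list(outcome_rec)
  if (!identical(as.character(ex$variant_id), as.character(oc$variant_id)))
    abort("harmonize_pair(): records refer to different variants (%s vs %s)",
          ex$variant_id, oc$variant_id)

  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(oc$effect_allele); oa_y <- toupper(oc$other_allele)

  if (is_palindromic(ea_x, oa_x) || is_palindromic(ea_y, oa_y))
    return(list(status = "excluded", reason = "palindrome"))

  beta_y <- oc$beta
  eaf_y <- oc$eaf
  if (ea_y == ea_x && oa_y == oa_x) {
    # identical orientation: copy
  } else if (ea_y == oa_x && oa_y == ea_x) {
    beta_y <- -beta_y
    eaf_y <- 1 - eaf_y
  } else {
    cea <- complement_alleles(ea_y)
    coa <- complement_alleles(oa_y)
    if (cea == ea_x && coa == oa_x) {
      # strand flip only
    } else if (cea == oa_x && coa == ea_x) {
      beta_y <- -beta_y
      eaf_y <- 1 - eaf_y
    } else {
      return(list(status = "excluded", reason = "allele_mismatch"))
    }
  }

  eaf <- if (!is.null(ex$eaf) && !is.na(ex$eaf)) ex$eaf else eaf_y
  # two-sided comparison avoids 1 - eaf rounding at the exclusion boundary
  if (!is.null(eaf) && !is.na(eaf) &&
      (eaf <= maf_threshold || eaf >= 1 - maf_threshold))
    return(list(status = "excluded", reason = "maf"))

  inst <- data.frame(
    variant_id = as.character(ex$variant_id),
    effect_allele = ea_x, other_allele = oa_x,
    beta_x = ex$beta, se_x = ex$se,
    beta_y = beta_y, se_y = oc$se,
    eaf = if (is.null(eaf)) NA_real_ else as.numeric(eaf),
    n_x = ex$n, n_y = oc$n,
    n_case = as.numeric(oc$n_case %||% NA_real_),
    n_control = as.numeric(oc$n_control %||% NA_real_),
    pvalue_x = ex$pvalue,
    stringsAsFactors = FALSE
  )
  list(status = "ok", instrument = inst)
}

#' Harmonize an instrument set against the outcome GWAS
#'
#' Dispatches every selected instrument through [harmonize_pair()].
#' Instruments absent from the outcome summary statistics are excluded with
#' reason `"missing_in_outcome"`; the exclusion log accounts for every input
#' instrument, so harmonized + excluded counts always equal the input count.
#'
#' @param iset an `instrument_set` from [select_instruments()] or [clump()].
#' @param outcome outcome [sumstats()] (typically binary).
#' @param maf_threshold passed to [harmonize_pair()]; default 0.01.
#' @return A `harmonized_set`: list with `exposure_id`, `instruments` (one
#'   row per harmonized instrument, including the exposure `f_stat`), and
#'   `exclusions` (`variant_id`, `reason`).
#' @export
harmonize_set <- function(iset, outcome, maf_threshold = 0.01) {
  stopifnot(inherits(iset, "instrument_set"), inherits(outcome, "sumstats"))
  members <- iset$members
  out_rec <- outcome$records

  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(members))) {
    vid <- members$variant_id[i]
    j <- match(vid, out_rec$variant_id)
    if (is.na(j)) {
      excl[[length(excl) + 1L]] <- data.frame(variant_id = vid,
                                              reason = "missing_in_outcome",
                                              stringsAsFactors = FALSE)
      next
    }
    res <- harmonize_pair(members[i, , drop = FALSE],
                          out_rec[j, , drop = FALSE],
                          maf_threshold = maf_threshold)
    if (res$status == "ok") {
      res$instrument$f_stat <- members$f_stat[i]
      rows[[length(rows) + 1L]] <- res$instrument
    } else {
      excl[[length(excl) + 1L]] <- data.frame(variant_id = vid,
                                              reason = res$reason,
                                              stringsAsFactors = FALSE)
    }
  }

  instruments <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(variant_id = character(0), effect_allele = character(0),
               other_allele = character(0), beta_x = numeric(0),
               se_x = numeric(0), beta_y = numeric(0), se_y = numeric(0),
               eaf = numeric(0), n_x = numeric(0), n_y = numeric(0),
               n_case = numeric(0), n_control = numeric(0),
               pvalue_x = numeric(0), f_stat = numeric(0),
               stringsAsFactors = FALSE)
  exclusions <- if (length(excl) > 0L) do.call(rbind, excl) else
    data.frame(variant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(instruments) <- NULL
  structure(list(exposure_id = iset$exposure_id, instruments = instruments,
                 exclusions = exclusions),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s: %d instrument(s), %d excluded\n",
              x$exposure_id, nrow(x$instruments), nrow(x$exclusions)))
  invisible(x)
}
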