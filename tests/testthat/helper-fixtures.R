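# In-code fixtures: tiny summary-statistics tables, LD references, and an
# independent brute-force clumping oracle. No data files.

make_assoc <- function(variant_id = "rs1", chrom = "1", pos = 1000L,
                       effect_allele = "A", other_allele = "G", eaf = 0.3,
                       beta = 0.1, se = 0.01, pvalue = NULL, n = 1800,
                       n_case = NA_real_, n_control = NA_real_) {
  pvalue <- pvalue %||% (2 * pnorm(abs(beta / se), lower.tail = FALSE))
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             pvalue = pmax(pvalue, .Machine$double.xmin), n = n,
             n_case = n_case, n_control = n_control,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# k variants on one chromosome, independent unless `pairs` given
toy_ld <- function(ids, chrom = "1", pos = NULL, pairs = NULL) {
  pos <- pos %||% (seq_along(ids) * 1000L)
  ld_reference(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE),
               pairs)
}

# Literal brute-force restatement of the greedy clumping definition:
# repeatedly take the remaining minimum-p candidate (ties by chrom, pos, id)
# as index; discard remaining candidates on its chromosome within the window
# whose r^2 exceeds the threshold. Independent of clump()'s implementation.
oracle_clump <- function(candidates, ld, r2_threshold, window_bp) {
  pos <- ld$positions
  rem <- merge(candidates[, c("variant_id", "pvalue")], pos, by = "variant_id")
  kept <- character(0)
  while (nrow(rem) > 0L) {
    o <- order(rem$pvalue, rem$chrom, rem$pos, rem$variant_id, method = "radix")
    index <- rem[o[1L], ]
    kept <- c(kept, index$variant_id)
    rem <- rem[rem$variant_id != index$variant_id, , drop = FALSE]
    if (nrow(rem) == 0L) break
    drop <- logical(nrow(rem))
    for (k in seq_len(nrow(rem))) {
      r <- ld_r(ld, rem$variant_id[k], index$variant_id)
      drop[k] <- rem$chrom[k] == index$chrom &&
        abs(rem$pos[k] - index$pos) <= window_bp &&
        r * r > r2_threshold
    }
    rem <- rem[!drop, , drop = FALSE]
  }
  kept
}

# A random clumping instance on one or two chromosomes
random_clump_instance <- function(n_snp = 10L) {
  ids <- sprintf("s%02d", seq_len(n_snp))
  chrom <- sample(c("1", "2"), n_snp, replace = TRUE)
  pos <- sample.int(3e7, n_snp)
  positions <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE)
  comb <- t(combn(n_snp, 2L))
  keep <- runif(nrow(comb)) < 0.4
  pairs <- if (any(keep)) {
    data.frame(id_a = ids[comb[keep, 1L]], id_b = ids[comb[keep, 2L]],
               r = runif(sum(keep), -1, 1), stringsAsFactors = FALSE)
  } else NULL
  ld <- ld_reference(positions, pairs)
  # duplicated p-values exercise the tie-break
  pvals <- sample(10^-runif(n_snp, 4, 16))
  pvals[sample.int(n_snp, 2L)] <- pvals[1L]
  cand <- make_assoc(variant_id = ids, chrom = chrom, pos = pos,
                     pvalue = pvals, beta = 0.1, se = 0.01)
  list(cand = cand, ld = ld)
}

# Harmonizable three-variant world used across harmonize/estimate tests
toy_harmonized <- function(beta_x = c(0.2, 0.25, 0.3),
                           se_x = c(0.02, 0.02, 0.02),
                           beta_y = c(0.1, 0.12, 0.15),
                           se_y = c(0.03, 0.03, 0.03),
                           n_x = 1800, n_y = 11600) {
  k <- length(beta_x)
  data.frame(variant_id = sprintf("rs%d", seq_len(k)),
             effect_allele = "A", other_allele = "G",
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             eaf = 0.3, n_x = n_x, n_y = n_y,
             n_case = round(0.41 * n_y), n_control = round(0.59 * n_y),
             f_stat = (beta_x / se_x)^2,
             stringsAsFactors = FALSE)
}
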