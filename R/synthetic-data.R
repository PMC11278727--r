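# Ground-truth synthetic GWAS summary statistics for two-sample MR.
#
# The generator emulates the statistical shape of a microbiome-exposure /
# binary-disease-outcome design: weakly heritable quantitative exposures
# with a few genome-wide-significant loci, a large imbalanced case-control
# outcome, block-diagonal AR(1) LD, and optional pleiotropy, confounding,
# and reverse causation. The default "fast" mode draws summary statistics
# directly from their sampling distribution; a "individual" mode generates
# individual-level data and regresses per variant, and exists solely as the
# distributional oracle for the fast mode.

NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2L, byrow = TRUE)

ar1_matrix <- function(k, rho) {
  if (k == 1L) return(matrix(1, 1L, 1L))
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Specify the ground truth of a simulated two-sample MR dataset
#'
#' Defaults describe the stated world of the package's calibration tests:
#' sample sizes one tenth of the real consortia the design mirrors
#' (`n_x = 1800` exposure subjects, `n_y = 11600` outcome subjects at case
#' fraction 0.41), three independent loci of five variants in AR(1) LD
#' (`rho = 0.5`), and one causal variant per locus with a per-SD effect
#' `sqrt(100 / n_x)`, i.e. expected instrument strength F of about 100.
#'
#' @param theta_true causal effect of exposure on outcome, log odds per SD
#'   of exposure; default 0.
#' @param n_blocks,block_size,rho,bp_spacing LD structure: number of
#'   independent blocks (each on its own synthetic chromosome), variants per
#'   block, within-block AR(1) correlation (|rho| < 1), base-pair spacing.
#' @param gamma per-variant true exposure effects (per SD of exposure,
#'   standardized-genotype scale), length `n_blocks * block_size`; default
#'   places `sqrt(100 / n_x)` on the first variant of each block.
#' @param phi per-variant horizontal-pleiotropy effects on the outcome
#'   (log odds, standardized-genotype scale); default all zero.
#' @param confounder_effect_x,confounder_effect_y loadings of a shared
#'   standard-normal confounder on exposure and outcome liability. The
#'   instruments are independent of the confounder by construction, so these
#'   bias the observational X-Y association but not the genetic effects.
#' @param reverse if `TRUE` the causal roles are swapped before generation:
#'   the instruments drive the outcome trait, and the exposure inherits
#'   `theta_true` times its liability.
#' @param n_x,n_y,n_case_frac sample sizes and outcome case fraction.
#' @param eaf_noise_sd between-study effect-allele-frequency jitter
#'   (default 0.002).
#' @param seed integer seed applied at the start of [simulate_sumstats()];
#'   `NULL` (default) leaves the RNG state alone.
#' @param id_prefix,chrom_prefix prefixes for variant ids and chromosome
#'   labels, used to keep multi-exposure panels disjoint.
#' @return A validated `sim_truth` list.
#' @export
sim_truth <- function(theta_true = 0, n_blocks = 3L, block_size = 5L,
                      rho = 0.5, bp_spacing = 50000L,
                      gamma = NULL, phi = NULL,
                      confounder_effect_x = 0, confounder_effect_y = 0,
                      reverse = FALSE,
                      n_x = 1800L, n_y = 11600L, n_case_frac = 0.41,
                      eaf_noise_sd = 0.002, seed = NULL,
                      id_prefix = "", chrom_prefix = "chr") {
  if (n_x < 100 || n_y < 100) abort("sim_truth(): sample sizes must be >= 100")
  if (abs(rho) >= 1) abort("sim_truth(): |rho| must be < 1")
  check_fraction(n_case_frac, "n_case_frac")
  if (n_blocks < 1L || block_size < 1L)
    abort("sim_truth(): need at least one block of one variant")
  m <- n_blocks * block_size
  if (is.null(gamma)) {
    gamma <- numeric(m)
    gamma[(seq_len(n_blocks) - 1L) * block_size + 1L] <- sqrt(100 / n_x)
  }
  if (is.null(phi)) phi <- numeric(m)
  if (length(gamma) != m || length(phi) != m)
    abort("sim_truth(): `gamma` and `phi` must have length n_blocks * block_size = %d", m)

  structure(list(theta_true = theta_true, n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size), rho = rho,
                 bp_spacing = as.integer(bp_spacing),
                 gamma = gamma, phi = phi,
                 confounder_effect_x = confounder_effect_x,
                 confounder_effect_y = confounder_effect_y,
                 reverse = isTRUE(reverse),
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 n_case_frac = n_case_frac,
                 eaf_noise_sd = eaf_noise_sd, seed = seed,
                 id_prefix = id_prefix, chrom_prefix = chrom_prefix),
            class = "sim_truth")
}

#' Build a block-diagonal AR(1) LD reference
#'
#' Within a block, `r(i, j) = rho^|i - j|`; across blocks `r = 0` (each
#' block sits on its own synthetic chromosome). Positions are spaced
#' `bp_spacing` apart.
#'
#' @inheritParams sim_truth
#' @param id_prefix,chrom_prefix label prefixes.
#' @return An [ld_reference()].
#' @export
#' @examples
#' ld <- make_ld(2, 3, rho = 0.5)
#' ld_r(ld, "b01_s01", "b01_s03") # 0.25
make_ld <- function(n_blocks, block_size, rho, bp_spacing = 50000L,
                    id_prefix = "", chrom_prefix = "chr") {
  if (abs(rho) >= 1) abort("make_ld(): |rho| must be < 1")
  ids <- sprintf("%sb%02d_s%02d", id_prefix,
                 rep(seq_len(n_blocks), each = block_size),
                 rep(seq_len(block_size), n_blocks))
  positions <- data.frame(
    variant_id = ids,
    chrom = sprintf("%s%d", chrom_prefix, rep(seq_len(n_blocks), each = block_size)),
    pos = rep(seq_len(block_size), n_blocks) * as.integer(bp_spacing),
    stringsAsFactors = FALSE
  )
  pairs <- NULL
  if (rho != 0 && block_size > 1L) {
    ij <- which(upper.tri(diag(block_size)), arr.ind = TRUE)
    pairs <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      off <- (b - 1L) * block_size
      data.frame(id_a = ids[off + ij[, 1L]], id_b = ids[off + ij[, 2L]],
                 r = rho^abs(ij[, 2L] - ij[, 1L]), stringsAsFactors = FALSE)
    }))
  }
  ld_reference(positions, pairs)
}

# Draw one block-correlated noise vector: cov = scale^2 * R (R = chol_R'chol_R)
block_noise <- function(chol_R, scale) {
  as.numeric(crossprod(chol_R, rnorm(nrow(chol_R)))) * scale
}

sim_alleles <- function(m) {
  pick <- sample.int(nrow(NONPALINDROMIC_PAIRS), m, replace = TRUE)
  list(ea = NONPALINDROMIC_PAIRS[pick, 1L], oa = NONPALINDROMIC_PAIRS[pick, 2L])
}

assemble_records <- function(ids, ld, ea, oa, eaf, beta, se, n) {
  data.frame(variant_id = ids,
             chrom = ld$positions$chrom[match(ids, ld$positions$variant_id)],
             pos = ld$positions$pos[match(ids, ld$positions$variant_id)],
             effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pvalue = wald_pvalue(beta, se), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Fast mode (default) draws the summary statistics directly: marginal
#' standardized exposure effects `b_x = R gamma` with estimates
#' `N(b_x, R / n_x)`; marginal outcome log-odds effects
#' `b_y = R (theta_true * gamma + phi)` with per-variant standard deviation
#' `1 / sqrt(n_y * c (1 - c))` (the logistic score approximation at case
#' fraction `c`) and `R`-correlated noise. Standardized quantities are then
#' re-expressed per effect-allele copy by dividing by `sqrt(2 f (1 - f))`
#' using each study's own allele frequency (drawn Uniform(0.05, 0.95) in the
#' exposure study and shared with the outcome up to jitter `eaf_noise_sd`).
#' Alleles are drawn from the eight non-palindromic ordered pairs, so
#' default data loses nothing to the palindrome exclusion. With
#' `reverse = TRUE` the instruments drive the outcome (`b_y = R (gamma +
#' phi)`) and the exposure inherits `b_x = theta_true * R gamma`.
#'
#' Individual mode generates Gaussian-dosage genotypes with exact LD `R` for
#' two non-overlapping studies, a shared standard-normal confounder, the
#' exposure as a unit-variance linear trait, and the outcome by a Bernoulli
#' draw from a logistic liability, then regresses trait on allele count per
#' variant (linear for the exposure, logistic for the outcome). It is the
#' oracle for fast mode's distributional claims, not a realistic genotype
#' model.
#'
#' @param truth a [sim_truth()].
#' @param mode `"fast"` or `"individual"`.
#' @return A `sim_output` list: `exposure` ([sumstats()], quantitative),
#'   `outcome` ([sumstats()], binary), `ld` ([ld_reference()]), `truth`.
#' @export
simulate_sumstats <- function(truth, mode = c("fast", "individual")) {
  stopifnot(inherits(truth, "sim_truth"))
  mode <- match.arg(mode)
  if (!is.null(truth$seed)) set.seed(truth$seed)

  ld <- make_ld(truth$n_blocks, truth$block_size, truth$rho,
                truth$bp_spacing, truth$id_prefix, truth$chrom_prefix)
  ids <- ld$positions$variant_id
  m <- length(ids)
  cfrac <- truth$n_case_frac

  al <- sim_alleles(m)
  f_x <- runif(m, 0.05, 0.95)
  f_y <- pmin(pmax(f_x + rnorm(m, 0, truth$eaf_noise_sd), 0.02), 0.98)

  if (truth$reverse) {
    eff_x_std <- truth$theta_true * truth$gamma
    eff_y_std <- truth$gamma + truth$phi
  } else {
    eff_x_std <- truth$gamma
    eff_y_std <- truth$theta_true * truth$gamma + truth$phi
  }

  blocks <- split(seq_len(m), rep(seq_len(truth$n_blocks),
                                  each = truth$block_size))
  R_block <- ar1_matrix(truth$block_size, truth$rho)
  chol_R <- chol(R_block)
  se_y_std <- 1 / sqrt(truth$n_y * cfrac * (1 - cfrac))

  if (mode == "fast") {
    bhat_x_std <- numeric(m)
    bhat_y_std <- numeric(m)
    for (bi in blocks) {
      bhat_x_std[bi] <- as.numeric(R_block %*% eff_x_std[bi]) +
        block_noise(chol_R, 1 / sqrt(truth$n_x))
      bhat_y_std[bi] <- as.numeric(R_block %*% eff_y_std[bi]) +
        block_noise(chol_R, se_y_std)
    }
    sd_gx <- sqrt(2 * f_x * (1 - f_x))
    sd_gy <- sqrt(2 * f_y * (1 - f_y))
    beta_x <- bhat_x_std / sd_gx
    se_x <- rep(1 / sqrt(truth$n_x), m) / sd_gx
    beta_y <- bhat_y_std / sd_gy
    se_y <- rep(se_y_std, m) / sd_gy
  } else {
    fit_x <- individual_study(truth, blocks, R_block, chol_R, f_x,
                              study = "exposure", eff_std = eff_x_std)
    fit_y <- individual_study(truth, blocks, R_block, chol_R, f_y,
                              study = "outcome", eff_std = eff_y_std)
    beta_x <- fit_x$beta; se_x <- fit_x$se
    beta_y <- fit_y$beta; se_y <- fit_y$se
  }

  n_case <- round(truth$n_y * cfrac)
  exposure <- sumstats(
    assemble_records(ids, ld, al$ea, al$oa, f_x, beta_x, se_x, truth$n_x),
    trait_id = paste0(truth$id_prefix, "exposure"),
    trait_type = "quantitative"
  )
  out_rec <- assemble_records(ids, ld, al$ea, al$oa, f_y, beta_y, se_y,
                              truth$n_y)
  out_rec$n_case <- n_case
  out_rec$n_control <- truth$n_y - n_case
  outcome <- sumstats(out_rec, trait_id = paste0(truth$id_prefix, "outcome"),
                      trait_type = "binary")

  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 truth = truth),
            class = "sim_output")
}

# Individual-level half of simulate_sumstats: one study, per-variant
# regressions on allele-count genotypes. Gaussian dosages keep the realized
# LD exactly R (binomial thresholding would attenuate it and break the
# fast-mode comparison).
individual_study <- function(truth, blocks, R_block, chol_R, f,
                             study = c("exposure", "outcome"), eff_std) {
  study <- match.arg(study)
  n <- if (study == "exposure") truth$n_x else truth$n_y
  m <- length(f)

  Z <- matrix(0, n, m)
  for (bi in blocks)
    Z[, bi] <- matrix(rnorm(n * length(bi)), n) %*% chol_R

  var_gen <- sum(vapply(blocks, function(bi)
    as.numeric(t(eff_std[bi]) %*% R_block %*% eff_std[bi]), numeric(1)))

  U <- rnorm(n)
  if (study == "exposure") {
    a <- truth$confounder_effect_x
    resid_var <- 1 - var_gen - a^2
    if (resid_var <= 0)
      abort("simulate_sumstats(): genetic + confounder variance exceeds 1; shrink gamma or the confounder loading")
    y <- as.numeric(Z %*% eff_std) + a * U + rnorm(n, 0, sqrt(resid_var))
  } else {
    a <- truth$confounder_effect_y
    if (truth$reverse) {
      eta <- qlogis(truth$n_case_frac) + as.numeric(Z %*% eff_std) + a * U
    } else {
      # Liability: outcome depends on the exposure trait (rebuilt in this
      # sample) plus pleiotropy and the confounder.
      ax <- truth$confounder_effect_x
      gamma_var <- sum(vapply(blocks, function(bi)
        as.numeric(t(truth$gamma[bi]) %*% R_block %*% truth$gamma[bi]),
        numeric(1)))
      rx <- 1 - gamma_var - ax^2
      if (rx <= 0)
        abort("simulate_sumstats(): genetic + confounder variance exceeds 1; shrink gamma or the confounder loading")
      x_here <- as.numeric(Z %*% truth$gamma) + ax * U + rnorm(n, 0, sqrt(rx))
      eta <- qlogis(truth$n_case_frac) + truth$theta_true * x_here +
        as.numeric(Z %*% truth$phi) + a * U
    }
    y <- rbinom(n, 1L, plogis(eta))
  }

  # Allele-count genotype: linear transform of the standardized dosage.
  beta <- numeric(m); se <- numeric(m)
  for (j in seq_len(m)) {
    g <- 2 * f[j] + sqrt(2 * f[j] * (1 - f[j])) * Z[, j]
    if (study == "exposure") {
      fit <- summary(stats::lm(y ~ g))$coefficients
    } else {
      fit <- summary(stats::glm(y ~ g, family = stats::binomial()))$coefficients
    }
    beta[j] <- fit["g", 1L]
    se[j] <- fit["g", 2L]
  }
  list(beta = beta, se = se)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> theta_true = %g%s: %d variants, n_x = %d, n_y = %d\n",
              x$truth$theta_true, if (x$truth$reverse) " (reverse)" else "",
              nrow(x$exposure$records), x$truth$n_x, x$truth$n_y))
  invisible(x)
}

#' Write a multi-exposure synthetic panel to disk
#'
#' Generates `k_taxa` exposures (disjoint loci, one causal effect each on a
#' shared binary outcome) and writes everything in the canonical dialects:
#' one exposure TSV per taxon, one pooled outcome TSV, the LD reference
#' directory, and a `truth.json` with the generative parameters. The output
#' is ready for [mr_run()]. Byte-identical under a fixed `seed`.
#'
#' @param k_taxa number of exposures (>= 1).
#' @param thetas per-taxon true causal effects, recycled to length `k_taxa`.
#' @param dir output directory (created if needed).
#' @param seed integer master seed; taxon `i` uses `seed + i`.
#' @param base a [sim_truth()] supplying everything but `theta_true`, the
#'   seed, and the label prefixes.
#' @return Invisibly, a list with `exposure_paths`, `outcome_path`,
#'   `ld_dir`, `truth_path`.
#' @export
make_panel <- function(k_taxa, thetas = 0, dir, seed = 1L,
                       base = sim_truth()) {
  if (k_taxa < 1L) abort("make_panel(): k_taxa must be >= 1")
  thetas <- rep_len(thetas, k_taxa)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  out_records <- list()
  positions <- list()
  rmaps <- list()
  exposure_paths <- character(k_taxa)
  truth_list <- list()
  for (i in seq_len(k_taxa)) {
    tr <- base
    tr$theta_true <- thetas[i]
    tr$seed <- seed + i
    tr$id_prefix <- sprintf("t%02d_", i)
    tr$chrom_prefix <- sprintf("t%02d_chr", i)
    sim <- simulate_sumstats(tr, mode = "fast")
    tid <- sprintf("taxon%02d", i)
    sim$exposure$trait_id <- tid
    exposure_paths[i] <- file.path(dir, sprintf("exposure_%s.tsv", tid))
    write_sumstats(sim$exposure, exposure_paths[i])
    out_records[[i]] <- sim$outcome$records
    positions[[i]] <- sim$ld$positions
    rmaps[[i]] <- sim$ld$r
    truth_list[[tid]] <- list(theta_true = tr$theta_true, seed = tr$seed,
                              gamma = tr$gamma, phi = tr$phi,
                              reverse = tr$reverse,
                              causal_ids = sim$ld$positions$variant_id[tr$gamma != 0])
  }

  outcome <- sumstats(do.call(rbind, out_records), trait_id = "outcome",
                      trait_type = "binary")
  outcome_path <- file.path(dir, "outcome.tsv")
  write_sumstats(outcome, outcome_path)

  ld <- structure(list(positions = do.call(rbind, positions),
                       r = do.call(c, rmaps) %||% numeric(0)),
                  class = "ld_reference")
  ld_dir <- file.path(dir, "ld")
  write_ld(ld, ld_dir)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(k_taxa = k_taxa, seed = seed,
                            n_x = base$n_x, n_y = base$n_y,
                            n_case_frac = base$n_case_frac,
                            taxa = truth_list),
                       truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(exposure_paths = exposure_paths, outcome_path = outcome_path,
                 ld_dir = ld_dir, truth_path = truth_path))
}
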