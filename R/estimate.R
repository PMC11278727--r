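# Causal estimation from harmonized instruments: per-instrument Wald ratios,
# fixed-effect IVW pooling, odds-ratio reporting, and the Steiger
# directionality test. Fixed-effect IVW is deliberate: microbiome exposures
# typically carry 1-2 instruments, where random-effects heterogeneity models
# are undefined; Cochran's Q is still reported when n_iv >= 2.

#' Wald ratio causal estimate for a single instrument
#'
#' `theta = beta_y / beta_x`, the outcome effect per unit (SD) of exposure.
#' The default standard error is the first-order delta-method form
#' `se_y / |beta_x|`; `se_order = 2` adds the exposure-uncertainty term
#' `beta_y^2 * se_x^2 / beta_x^4` under the square root.
#'
#' @param beta_x,se_x exposure effect and SE (per SD); `beta_x` must be
#'   nonzero.
#' @param beta_y,se_y outcome effect and SE (log odds).
#' @param se_order 1 (default) or 2.
#' @return list with `theta` and `se` (vectorized).
#' @export
#' @examples
#' wald_ratio(0.1, 0.02, 0.2, 0.05)
wald_ratio <- function(beta_x, se_x, beta_y, se_y, se_order = 1) {
  if (any(!is.finite(beta_x) | beta_x == 0))
    abort("wald_ratio(): `beta_x` must be nonzero (ratio undefined)")
  if (any(se_x <= 0) || any(se_y <= 0))
    abort("wald_ratio(): standard errors must be > 0")
  if (!se_order %in% c(1, 2)) abort("`se_order` must be 1 or 2")
  theta <- beta_y / beta_x
  se <- if (se_order == 1) {
    se_y / abs(beta_x)
  } else {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  }
  list(theta = theta, se = se)
}

#' Fixed-effect inverse-variance-weighted pooling
#'
#' Pools per-instrument estimates with weights `w_j = se_j^-2`:
#' `theta = sum(w * theta_j) / sum(w)`, `se = sum(w)^-1/2`, and Cochran's
#' heterogeneity statistic `Q = sum(w * (theta_j - theta)^2)`. A single
#' element returns `(theta_1, se_1, 0)` identically, so IVW with one
#' instrument reduces exactly to the Wald ratio.
#'
#' @param thetas per-instrument estimates (length >= 1).
#' @param ses per-instrument standard errors (> 0).
#' @return list with `theta`, `se`, `q_stat`.
#' @export
ivw_pool <- function(thetas, ses) {
  if (length(thetas) == 0L) abort("ivw_pool(): empty input")
  if (length(thetas) != length(ses))
    abort("ivw_pool(): `thetas` and `ses` differ in length")
  if (any(!is.finite(ses) | ses <= 0))
    abort("ivw_pool(): standard errors must be > 0 and finite")
  w <- ses^-2
  theta <- sum(w * thetas) / sum(w)
  list(theta = theta,
       se = 1 / sqrt(sum(w)),
       q_stat = sum(w * (thetas - theta)^2))
}

#' Express a log-odds effect as an odds ratio with confidence interval
#'
#' `or = exp(theta)` with bounds `exp(theta -+ z * se)` where `z` is the
#' two-sided normal quantile for `level`.
#'
#' @param theta log-odds causal estimate.
#' @param se its standard error (> 0).
#' @param level confidence level; default 0.95.
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(theta, se, level = 0.95) {
  check_fraction(level, "level")
  if (any(se <= 0)) abort("to_odds_ratio(): `se` must be > 0")
  z <- qnorm((1 + level) / 2)
  list(or = exp(theta), ci_low = exp(theta - z * se),
       ci_high = exp(theta + z * se))
}

#' Two-sided Wald p-value
#'
#' `p = 2 * P(Z > |theta/se|)` under the standard normal, computed with the
#' upper-tail form of `pnorm()` so deep tails (|z| > 8) do not lose
#' precision to cancellation. The result is clamped away from exact zero so
#' it stays in (0, 1].
#'
#' @param theta estimate (vectorized).
#' @param se standard error (> 0).
#' @return two-sided p-value in (0, 1].
#' @export
wald_pvalue <- function(theta, se) {
  if (any(se <= 0)) abort("wald_pvalue(): `se` must be > 0")
  p <- 2 * pnorm(abs(theta / se), lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Reconstruct a Wald p-value from a printed OR and confidence interval
#'
#' Consistency checker for published odds-ratio triplets: recovers
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)` and returns
#' `wald_pvalue(log(or), se)`.
#'
#' @param or odds ratio.
#' @param ci_low,ci_high confidence bounds; must satisfy
#'   `0 < ci_low < or < ci_high`.
#' @param level the interval's confidence level; default 0.95.
#' @return two-sided p-value.
#' @export
#' @examples
#' pvalue_from_or_ci(2.89, 1.67, 5) # ~1.5e-4
pvalue_from_or_ci <- function(or, ci_low, ci_high, level = 0.95) {
  check_fraction(level, "level")
  if (any(!(ci_low > 0 & ci_low < or & or < ci_high)))
    abort("pvalue_from_or_ci(): need 0 < ci_low < or < ci_high")
  z <- qnorm((1 + level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  wald_pvalue(log(or), se)
}

#' Variance explained by a single variant from its summary statistics
#'
#' `r2 = z^2 / (z^2 + n - 2)` with `z = beta/se` — the squared sample
#' correlation implied by the t statistic of a simple regression. For a
#' binary trait this is a pseudo-r2 on the test-statistic scale.
#'
#' @param beta,se association estimate and SE (vectorized).
#' @param n sample size (> 2).
#' @return r2 in \[0, 1).
#' @export
r2_from_association <- function(beta, se, n) {
  if (any(se <= 0)) abort("r2_from_association(): `se` must be > 0")
  if (any(n <= 2)) abort("r2_from_association(): `n` must exceed 2")
  z2 <- (beta / se)^2
  z2 / (z2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome. Direction is called correct (exposure -> outcome) when
#' `r2_x > r2_y` strictly; a tie is conservatively called not-correct. The
#' p-value comes from the two-sample comparison of Fisher-z-transformed
#' correlations: `z_k = atanh(sqrt(r2_k))`, statistic
#' `(z_x - z_y) / sqrt(1/(n_x - 3) + 1/(n_y - 3))`, two-sided normal.
#'
#' @param r2_x,r2_y variance explained in exposure / outcome, each in
#'   \[0, 1).
#' @param n_x,n_y the corresponding sample sizes (>= 4).
#' @return list with `correct_direction` (logical), `pvalue`, `statistic`.
#' @export
steiger_test <- function(r2_x, r2_y, n_x, n_y) {
  if (any(r2_x < 0 | r2_x >= 1 | r2_y < 0 | r2_y >= 1))
    abort("steiger_test(): r2 values must lie in [0, 1)")
  if (any(n_x < 4 | n_y < 4))
    abort("steiger_test(): sample sizes must be >= 4")
  zx <- atanh(sqrt(r2_x))
  zy <- atanh(sqrt(r2_y))
  stat <- (zx - zy) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  list(correct_direction = r2_x > r2_y,
       pvalue = wald_pvalue(stat, 1),
       statistic = stat)
}

#' Estimate the causal effect of one exposure from harmonized instruments
#'
#' Computes per-instrument Wald ratios, pools them by fixed-effect IVW
#' (method `"wald_ratio"` when a single instrument survives, `"ivw"`
#' otherwise), expresses the estimate as an odds ratio with confidence
#' interval and two-sided p-value, and runs the Steiger directionality test
#' on the summed per-instrument r2 of each side (exposure side with `n_x`;
#' outcome side with total `n_y`, or the effective case-control size
#' `4 / (1/n_case + 1/n_control)` when `steiger_effective_n = TRUE`).
#'
#' @param hset a `harmonized_set` from [harmonize_set()], or a data.frame
#'   with its `instruments` columns.
#' @param exposure_id label; defaults to the set's `exposure_id`.
#' @param ci_level confidence level; default 0.95.
#' @param wald_se_order 1 or 2, see [wald_ratio()].
#' @param steiger_effective_n use the effective outcome sample size for the
#'   Steiger outcome r2; default `FALSE`.
#' @return An `mr_result`: list with `exposure_id`, `method`, `n_iv`,
#'   `theta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`, `q_stat` (NA for a
#'   single instrument), `steiger_correct`, `steiger_direction`
#'   (`"forward"`/`"reverse"`), `steiger_pvalue`, `iv_ids`. Convert with
#'   `as.data.frame()`.
#' @export
estimate_exposure <- function(hset, exposure_id = NULL, ci_level = 0.95,
                              wald_se_order = 1, steiger_effective_n = FALSE) {
  if (inherits(hset, "harmonized_set")) {
    exposure_id <- exposure_id %||% hset$exposure_id
    inst <- hset$instruments
  } else {
    inst <- as.data.frame(hset, stringsAsFactors = FALSE)
  }
  exposure_id <- exposure_id %||% NA_character_
  if (nrow(inst) == 0L)
    abort("estimate_exposure(): no harmonized instruments for exposure '%s'",
          exposure_id)

  wr <- wald_ratio(inst$beta_x, inst$se_x, inst$beta_y, inst$se_y,
                   se_order = wald_se_order)
  pooled <- ivw_pool(wr$theta, wr$se)
  n_iv <- nrow(inst)
  orci <- to_odds_ratio(pooled$theta, pooled$se, level = ci_level)

  r2_x <- sum(r2_from_association(inst$beta_x, inst$se_x, inst$n_x))
  n_y_eff <- if (steiger_effective_n && all(is.finite(inst$n_case)) &&
                 all(is.finite(inst$n_control))) {
    4 / (1 / inst$n_case + 1 / inst$n_control)
  } else {
    inst$n_y
  }
  r2_y <- sum(r2_from_association(inst$beta_y, inst$se_y, n_y_eff))
  r2_x <- min(r2_x, 1 - 1e-12)
  r2_y <- min(r2_y, 1 - 1e-12)
  st <- steiger_test(r2_x, r2_y, round(mean(inst$n_x)), round(mean(n_y_eff)))

  structure(list(
    exposure_id = exposure_id,
    method = if (n_iv == 1L) "wald_ratio" else "ivw",
    n_iv = n_iv,
    theta = pooled$theta,
    se = pooled$se,
    or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
    pvalue = wald_pvalue(pooled$theta, pooled$se),
    q_stat = if (n_iv >= 2L) pooled$q_stat else NA_real_,
    steiger_correct = st$correct_direction,
    steiger_direction = if (st$correct_direction) "forward" else "reverse",
    steiger_pvalue = st$pvalue,
    steiger_r2_x = r2_x, steiger_r2_y = r2_y,
    iv_ids = inst$variant_id
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s [%s, %d IV%s]\n  OR %.3g (95%% CI %.3g-%.3g), p = %.3g; Steiger: %s (p = %.3g)\n",
              x$exposure_id, x$method, x$n_iv, if (x$n_iv == 1L) "" else "s",
              x$or, x$ci_low, x$ci_high, x$pvalue,
              x$steiger_direction, x$steiger_pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(
    exposure_id = x$exposure_id, method = x$method, n_iv = x$n_iv,
    theta = x$theta, se = x$se, or = x$or,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    q_stat = x$q_stat,
    steiger_direction = x$steiger_direction,
    steiger_pvalue = x$steiger_pvalue,
    iv_ids = paste(x$iv_ids, collapse = ","),
    stringsAsFactors = FALSE
  )
}
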