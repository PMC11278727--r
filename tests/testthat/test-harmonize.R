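test_that("is_palindromic identifies complement pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("a", "g", "T"), c("t", "c", "C")),
               c(TRUE, TRUE, FALSE))
  expect_error(is_palindromic("A", "N"), "A/C/G/T")
})

exp_rec <- function(ea = "A", oa = "G", beta = 0.1, eaf = 0.3, id = "rs1")
  make_assoc(id, effect_allele = ea, other_allele = oa, beta = beta,
             eaf = eaf)
out_rec <- function(ea = "A", oa = "G", beta = 0.2, eaf = 0.3, id = "rs1")
  make_assoc(id, effect_allele = ea, other_allele = oa, beta = beta,
             eaf = eaf, n = 11600, n_case = 4756, n_control = 6844)

test_that("harmonize_pair handles identity, swap, strand flip, and exclusions", {
  # identity
  h <- harmonize_pair(exp_rec(), out_rec())
  expect_identical(h$status, "ok")
  expect_equal(h$instrument$beta_y, 0.2)
  # swap: negate and flip the outcome frequency
  h <- harmonize_pair(exp_rec(), out_rec(ea = "G", oa = "A", eaf = 0.3))
  expect_equal(h$instrument$beta_y, -0.2)
  # strand complement, same orientation
  h <- harmonize_pair(exp_rec(), out_rec(ea = "T", oa = "C"))
  expect_equal(h$instrument$beta_y, 0.2)
  # complement + swap
  h <- harmonize_pair(exp_rec(), out_rec(ea = "C", oa = "T"))
  expect_equal(h$instrument$beta_y, -0.2)
  # palindromic exposure: dropped whatever the outcome says
  h <- harmonize_pair(exp_rec(ea = "A", oa = "T"), out_rec(ea = "A", oa = "T"))
  expect_identical(h$reason, "palindrome")
  # unresolvable allele sets
  h <- harmonize_pair(exp_rec(), out_rec(ea = "A", oa = "C"))
  expect_identical(h$reason, "allele_mismatch")
  # exposure orientation is never altered
  h <- harmonize_pair(exp_rec(beta = -0.4), out_rec(ea = "G", oa = "A"))
  expect_equal(h$instrument$beta_x, -0.4)
  expect_identical(h$instrument$effect_allele, "A")
  expect_error(harmonize_pair(exp_rec(id = "rs1"), out_rec(id = "rs2")),
               "different variants")
})

test_that("harmonization truth table over all outcome allele configurations", {
  # Exposure fixed at (A, G). Expected action for each ordered outcome pair,
  # hand-derived from the strand/orientation rules: copy (same orientation,
  # possibly after complementing), flip (swapped orientation), palindrome
  # (strand-unresolvable outcome pair), mismatch (unresolvable allele sets).
  expected <- c(
    "A/C" = "mismatch",  "A/G" = "copy",      "A/T" = "palindrome",
    "C/A" = "mismatch",  "C/G" = "palindrome", "C/T" = "flip",
    "G/A" = "flip",      "G/C" = "palindrome", "G/T" = "mismatch",
    "T/A" = "palindrome", "T/C" = "copy",      "T/G" = "mismatch")
  for (cfg in names(expected)) {
    al <- strsplit(cfg, "/")[[1]]
    h <- harmonize_pair(exp_rec(), out_rec(ea = al[1], oa = al[2]))
    got <- if (h$status == "ok") {
      if (h$instrument$beta_y == 0.2) "copy" else "flip"
    } else {
      switch(h$reason, palindrome = "palindrome",
             allele_mismatch = "mismatch", h$reason)
    }
    expect_identical(got, unname(expected[cfg]), label = cfg)
  }
})

test_that("MAF rule is inclusive at the boundary and uses the exposure eaf", {
  expect_identical(harmonize_pair(exp_rec(eaf = 0.01), out_rec())$reason, "maf")
  expect_identical(harmonize_pair(exp_rec(eaf = 0.99), out_rec())$reason, "maf")
  expect_identical(harmonize_pair(exp_rec(eaf = 0.011), out_rec())$status, "ok")
  # exposure frequency wins over a rare outcome frequency
  expect_identical(harmonize_pair(exp_rec(eaf = 0.3),
                                  out_rec(eaf = 0.005))$status, "ok")
  # missing exposure eaf falls back to the aligned outcome eaf
  expect_identical(harmonize_pair(exp_rec(eaf = NA),
                                  out_rec(eaf = 0.005))$reason, "maf")
})

test_that("harmonize_set accounts for every instrument (conservation)", {
  ids <- c("rs1", "rs2", "rs3", "rs4", "rs5")
  ex <- make_assoc(ids, pos = 1:5 * 1000L,
                   effect_allele = c("A", "A", "A", "A", "A"),
                   other_allele = c("G", "G", "T", "G", "G"),
                   eaf = c(0.3, 0.3, 0.3, 0.005, 0.3),
                   beta = 0.1, se = 0.01)
  iset <- clump(sumstats(ex, "x", "quantitative")$records,
                toy_ld(ids, pos = 1:5 * 1000L), r2_threshold = 1,
                exposure_id = "x")
  out <- sumstats(out_rec(id = c("rs1", "rs2", "rs3", "rs4"),
                          ea = "A", oa = c("G", "G", "T", "G")),
                  "ms", "binary")
  hs <- harmonize_set(iset, out)
  expect_equal(nrow(hs$instruments) + nrow(hs$exclusions), 5L)
  expect_setequal(hs$instruments$variant_id, c("rs1", "rs2"))
  reasons <- setNames(hs$exclusions$reason, hs$exclusions$variant_id)
  expect_identical(unname(reasons[c("rs3", "rs4", "rs5")]),
                   c("palindrome", "maf", "missing_in_outcome"))
  # no harmonized instrument is palindromic or rare
  expect_false(any(is_palindromic(hs$instruments$effect_allele,
                                  hs$instruments$other_allele)))
  expect_true(all(pmin(hs$instruments$eaf, 1 - hs$instruments$eaf) > 0.01))
})

test_that("harmonization is idempotent and involutive", {
  set.seed(55)
  pairs <- list(c("A", "G"), c("G", "A"), c("T", "C"), c("C", "T"))
  for (i in 1:25) {
    ex <- exp_rec(beta = rnorm(1))
    al <- pairs[[sample.int(4, 1)]]
    oc <- out_rec(ea = al[1], oa = al[2], beta = rnorm(1), eaf = runif(1, 0.1, 0.9))
    h1 <- harmonize_pair(ex, oc)
    expect_identical(h1$status, "ok")
    # re-harmonizing the already-aligned record changes nothing (idempotence)
    oc2 <- oc
    oc2$effect_allele <- h1$instrument$effect_allele
    oc2$other_allele <- h1$instrument$other_allele
    oc2$beta <- h1$instrument$beta_y
    h2 <- harmonize_pair(ex, oc2)
    expect_equal(h2$instrument$beta_y, h1$instrument$beta_y)
    # involution: swapping the outcome orientation and negating beta_y
    # leaves the harmonized pair unchanged
    oc3 <- oc
    oc3$effect_allele <- oc$other_allele
    oc3$other_allele <- oc$effect_allele
    oc3$beta <- -oc$beta
    oc3$eaf <- 1 - oc$eaf
    h3 <- harmonize_pair(ex, oc3)
    expect_equal(h3$instrument$beta_y, h1$instrument$beta_y)
    expect_equal(h3$instrument$beta_x, h1$instrument$beta_x)
  }
})

test_that("causal estimates are invariant to the outcome's reported strand", {
  set.seed(77)
  tr <- sim_truth(theta_true = 0.4, seed = 909)
  sim <- simulate_sumstats(tr)
  iset <- select_instruments(sim$exposure, sim$ld)
  base <- estimate_exposure(harmonize_set(iset, sim$outcome))

  flipped <- sim$outcome
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  k <- seq(1, nrow(flipped$records), by = 2)  # flip every other record
  flipped$records$effect_allele[k] <- comp[flipped$records$effect_allele[k]]
  flipped$records$other_allele[k] <- comp[flipped$records$other_allele[k]]
  alt <- estimate_exposure(harmonize_set(iset, flipped))
  expect_equal(alt$theta, base$theta, tolerance = 1e-12)
  expect_equal(alt$pvalue, base$pvalue, tolerance = 1e-12)
})
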