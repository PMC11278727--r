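test_that("f_statistic matches the squared z score and its boundary arithmetic", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.05), 0)
  # boundary-adjacent value, frozen from direct arithmetic (0.05/0.0158)^2
  expect_equal(f_statistic(0.05, 0.0158), 10.0144207659, tolerance = 1e-10)
  # r2-based form is algebraically identical for a single variant
  expect_equal(f_statistic(0.05, 0.0158, method = "r2", n = 1800),
               f_statistic(0.05, 0.0158), tolerance = 1e-12)
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("f_statistic is monotone in |beta| and in se", {
  b <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(b, 0.05)) > 0))
  s <- seq(0.01, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(0.1, s)) < 0))
})

test_that("significance_filter keeps strictly below the threshold", {
  ss <- sumstats(make_assoc(c("a", "b", "c"), pos = c(1L, 2L, 3L),
                            pvalue = c(1e-9, 1e-8, 1e-7)),
                 "x", "quantitative")
  kept <- significance_filter(ss, 1e-8)
  expect_identical(kept$variant_id, "a")  # 1e-8 exactly is excluded
  expect_equal(nrow(significance_filter(ss, 1 - 1e-12)), 3L)
  empty <- sumstats(make_assoc("a")[0, ], "x", "quantitative")
  expect_equal(nrow(significance_filter(empty)), 0L)
})

test_that("clump keeps the smaller-p SNP of a correlated nearby pair", {
  ld <- toy_ld(c("s1", "s2"), pos = c(1000L, 2000L),
               pairs = data.frame(id_a = "s1", id_b = "s2", r = sqrt(0.5)))
  cand <- make_assoc(c("s1", "s2"), pos = c(1000L, 2000L),
                     pvalue = c(1e-12, 1e-9))
  iset <- clump(cand, ld)
  expect_identical(iset$members$variant_id, "s1")
  expect_identical(
    iset$selection_log$disposition[iset$selection_log$variant_id == "s2"],
    "clumped-away-by:s1")
})

test_that("cross-chromosome pairs are never clumped, whatever r says", {
  pos <- data.frame(variant_id = c("s1", "s2"), chrom = c("1", "2"),
                    pos = c(1000L, 1500L))
  ld <- ld_reference(pos, data.frame(id_a = "s1", id_b = "s2", r = 0.95))
  cand <- make_assoc(c("s1", "s2"), chrom = c("1", "2"),
                     pos = c(1000L, 1500L), pvalue = c(1e-12, 1e-9))
  expect_setequal(clump(cand, ld)$members$variant_id, c("s1", "s2"))
})

test_that("clump errors when a candidate is missing from the LD positions", {
  ld <- toy_ld(c("s1"))
  cand <- make_assoc(c("s1", "sX"), pos = c(1000L, 2000L))
  expect_error(clump(cand, ld), "sX")
})

test_that("clump equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_clump_instance(10L)
    got <- clump(inst$cand, inst$ld, r2_threshold = 0.1, window_bp = 5e6)
    expect_identical(got$members$variant_id,
                     oracle_clump(inst$cand, inst$ld, 0.1, 5e6))
  }
})

test_that("clump output is order-invariant and pairwise-independent", {
  set.seed(202)
  for (i in 1:30) {
    inst <- random_clump_instance(10L)
    got <- clump(inst$cand, inst$ld, r2_threshold = 0.05, window_bp = 8e6)
    shuf <- clump(inst$cand[sample.int(nrow(inst$cand)), ], inst$ld,
                  r2_threshold = 0.05, window_bp = 8e6)
    expect_identical(got$members$variant_id, shuf$members$variant_id)

    # every kept pair satisfies: different chrom OR outside window OR r^2 <= t
    m <- merge(got$members[, "variant_id", drop = FALSE], inst$ld$positions)
    if (nrow(m) >= 2L) {
      for (a in seq_len(nrow(m) - 1L)) for (b in (a + 1L):nrow(m)) {
        r2 <- ld_r(inst$ld, m$variant_id[a], m$variant_id[b])^2
        ok <- m$chrom[a] != m$chrom[b] ||
          abs(m$pos[a] - m$pos[b]) > 8e6 || r2 <= 0.05
        expect_true(ok)
      }
    }
    # selection log covers every candidate exactly once
    expect_setequal(got$selection_log$variant_id, inst$cand$variant_id)
    expect_false(anyDuplicated(got$selection_log$variant_id) > 0)
  }
})

test_that("select_instruments composes the filters with strict boundaries", {
  n <- 1800
  # F exactly 10 is retained; 9.999 is dropped
  se <- 0.01
  b_keep <- sqrt(10) * se
  b_drop <- sqrt(9.999) * se
  ss <- sumstats(make_assoc(c("s1", "s2"), pos = c(1000L, 5e6L),
                            beta = c(b_keep, b_drop), se = se,
                            pvalue = c(1e-10, 1e-10), n = n),
                 "x", "quantitative")
  ld <- toy_ld(c("s1", "s2"), pos = c(1000L, 5e6L))
  iset <- select_instruments(ss, ld, f_min = 10)
  expect_identical(iset$members$variant_id, "s1")
  log <- iset$selection_log
  expect_identical(log$disposition[log$variant_id == "s2"], "dropped-F")

  # all weak -> empty set, all dropped-F
  ss2 <- sumstats(make_assoc(c("s1", "s2"), pos = c(1000L, 5e6L),
                             beta = b_drop, se = se, pvalue = 1e-10),
                  "x", "quantitative")
  iset2 <- select_instruments(ss2, ld)
  expect_equal(nrow(iset2$members), 0L)
  expect_true(all(iset2$selection_log$disposition == "dropped-F"))

  # threshold below the file minimum: empty, never an error
  iset3 <- select_instruments(ss, ld, p_threshold = 1e-300)
  expect_equal(nrow(iset3$members), 0L)
  expect_true(all(iset3$selection_log$disposition == "dropped-p"))

  # singleton strong candidate
  ss4 <- sumstats(make_assoc("s1", pvalue = 1e-10, beta = 0.1, se = 0.01),
                  "x", "quantitative")
  iset4 <- select_instruments(ss4, toy_ld("s1"))
  expect_identical(iset4$members$variant_id, "s1")
  expect_equal(iset4$members$f_stat, 100)
})

test_that("select_instruments keeps one index SNP per simulated locus", {
  # 3 loci of 2 correlated SNPs: expect the per-locus minimum-p member
  ids <- sprintf("b%02d_s%02d", rep(1:3, each = 2), rep(1:2, 3))
  pos <- data.frame(variant_id = ids, chrom = rep(c("1", "2", "3"), each = 2),
                    pos = rep(c(1000L, 2000L), 3))
  pairs <- data.frame(id_a = ids[c(1, 3, 5)], id_b = ids[c(2, 4, 6)], r = 0.8)
  ld <- ld_reference(pos, pairs)
  set.seed(33)
  betas <- runif(6, 0.08, 0.2)
  ss <- sumstats(make_assoc(ids, chrom = pos$chrom, pos = pos$pos,
                            beta = betas, se = 0.01),
                 "x", "quantitative")
  iset <- select_instruments(ss, ld)
  expect_equal(nrow(iset$members), 3L)
  per_locus <- split(ss$records, pos$chrom[match(ss$records$variant_id, ids)])
  best <- vapply(per_locus, function(d) d$variant_id[which.min(d$pvalue)], "")
  expect_setequal(iset$members$variant_id, unname(best))
})
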