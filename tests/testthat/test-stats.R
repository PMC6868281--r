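test_that("chi-squared skewing reproduces printed cohort p-values", {
  expect_equal(round(chi_squared_skew(134, 2660, 117, 2843)$p_value, 4),
               0.1013)
  expect_equal(round(chi_squared_skew(6, 751, 26, 740)$p_value, 4),
               0.0003)
  # equal proportions: statistic 0, p 1
  eq <- chi_squared_skew(5, 100, 5, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # invariances: group order and positive/negative label swap
  a <- chi_squared_skew(52, 384, 20, 384)
  b <- chi_squared_skew(20, 384, 52, 384)
  c_ <- chi_squared_skew(384 - 52, 384, 384 - 20, 384)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$p_value, c_$p_value)
  expect_error(chi_squared_skew(1, 0, 2, 10),
               class = "tcrclonal_data_error")
})

test_that("two-stage FDR has the published threshold and step-up logic", {
  fdr <- bky_two_stage(c(1, 1, 1), Q = 0.05)
  expect_equal(fdr$stage1_threshold, 0.05 / 1.05)
  expect_equal(round(fdr$stage1_threshold, 6), 0.047619)
  expect_false(any(fdr$discoveries))

  # all tiny p-values: everything discovered
  all_small <- bky_two_stage(rep(1e-6, 4))
  expect_true(all(all_small$discoveries))
  expect_identical(all_small$m0, 0L)

  # empty input
  expect_identical(length(bky_two_stage(numeric(0))$discoveries), 0L)

  # never less powerful than plain BH at level Q
  set.seed(41)
  for (i in 1:50) {
    p <- c(runif(15), rbeta(5, 0.2, 4))
    fdr <- bky_two_stage(p)
    bh <- stats::p.adjust(p, "BH") <= 0.05
    expect_true(all(bh <= fdr$discoveries))
  }
})

test_that("two-stage FDR controls the error rate under the global null", {
  set.seed(61)
  fdp <- replicate(1000, {
    disc <- bky_two_stage(runif(20))$discoveries
    as.numeric(any(disc))   # all nulls: any rejection is a false discovery
  })
  mc_err <- sqrt(mean(fdp) * (1 - mean(fdp)) / 1000)
  expect_lte(mean(fdp), 0.05 + 2 * max(mc_err, sqrt(0.05 * 0.95 / 1000)))
})

test_that("location tests behave on degenerate and planted-shift samples", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  pt <- paired_t(x, x)
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
  expect_error(paired_t(1:3, 1:4), class = "tcrclonal_data_error")

  # exact Mann-Whitney by enumeration: 1/binom(6,3) tail both sides
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  # Welch power at effect size 1 SD, n = 50
  set.seed(71)
  hits <- replicate(100, {
    welch_t(rnorm(50), rnorm(50, 1))$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tetramer ranks are normalized and scale-invariant", {
  expect_equal(tetramer_rank(300, 5e4, 300, 5e4), 1)
  expect_equal(tetramer_rank(600, 5e4, 300, 5e4), 2)
  # joint rescaling of all FI (or all FSC) leaves the rank unchanged
  expect_equal(tetramer_rank(600 * 7, 5e4, 300 * 7, 5e4),
               tetramer_rank(600, 5e4, 300, 5e4))
  expect_equal(tetramer_rank(600, 5e4 * 3, 300, 5e4 * 3),
               tetramer_rank(600, 5e4, 300, 5e4))
  expect_error(tetramer_rank(1, 0, 1, 1), class = "tcrclonal_data_error")

  # category mean/SEM match the direct formula
  fx <- zero_noise_fixture()
  rs <- tetramer_rank_summary(fx$pipeline$analyzed,
                              fx$cohort$index_negative)
  one <- rs[1, ]
  cells <- fx$pipeline$analyzed |>
    dplyr::filter(donor == one$donor, tetramer == one$tetramer) |>
    dplyr::left_join(fx$cohort$index_negative, by = "plate_id")
  r <- (cells$fi_tetramer / cells$fsc) / (cells$neg_mfi / cells$neg_mean_fsc)
  expect_equal(one$mean_rank, mean(r))
  expect_equal(one$sem_rank, sd(r) / sqrt(length(r)))
})

test_that("phenotype skewing reproduces printed cluster statistics", {
  rep_tab <- phenotype_skew_from_counts(example_counts("phenotype_clusters"))
  expect_equal(round(rep_tab$p_value[rep_tab$marker == "PRF1"], 4), 0.0073)
  expect_equal(round(rep_tab$p_value[rep_tab$marker == "TGFB1"], 4), 0.0004)

  folds <- phenotype_skew_from_counts(example_counts("phenotype_expansion"))
  expect_equal(folds$fold_label[folds$marker == "PRF1"], 11)
  expect_equal(folds$fold_label[folds$marker == "IFNG"], 16)
  expect_true(all(folds$p_value < 1e-4))

  # identical clusters: all p = 1, all folds 1
  bits <- tibble::tibble(TBX21 = c(1, 0, 1), PRF1 = c(0, 0, 1))
  same <- phenotype_skew_report(bits, bits, c("TBX21", "PRF1"))
  expect_true(all(same$p_value == 1))
  expect_true(all(same$fold == 1))
})

test_that("competition percentages classify strong/weak/non-binders", {
  out <- percent_competition(c(2.6, 100, 47, 25))
  expect_equal(out$percent_competition, c(97.4, 0, 53, 75))
  expect_identical(out$class, c("strong", "non-binder", "weak", "weak"))
  expect_error(percent_competition(101), class = "tcrclonal_data_error")
})

test_that("tidy and glance methods expose the FDR audit trail", {
  fdr <- bky_two_stage(c(0.001, 0.2, 0.04))
  td <- tidy(fdr)
  expect_identical(nrow(td), 3L)
  expect_named(td, c("p_value", "q_value", "discovery"))
  gl <- glance(fdr)
  expect_identical(gl$n_tests, 3L)
  expect_equal(gl$stage1_threshold, 0.05 / 1.05)
})
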