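make_map <- function() {
  tibble::tibble(
    well_id = c("PL001-A01", "PL001-B07"),
    plate_id = "PL001",
    plate_bc = strrep("A", 8),
    row_bc = c(strrep("C", 8), strrep("G", 8)),
    col_bc = c(strrep("T", 8), strrep("T", 8))
  )
}

test_that("demultiplexing is exact-match and conserves reads", {
  map <- make_map()
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(
      paste0(strrep("A", 8), strrep("G", 8), strrep("T", 8), "ACGTACGT"),
      paste0(strrep("A", 8), strrep("C", 8), strrep("T", 8), "TTTTAAAA"),
      paste0(strrep("A", 8), strrep("G", 7), "A", strrep("T", 8), "CCCC")
    )
  )
  out <- demultiplex(reads, map)
  expect_identical(nrow(out), 3L)
  expect_identical(out$well_id, c("PL001-B07", "PL001-A01", NA))
  expect_identical(out$sequence[[1]], "ACGTACGT")

  dup <- map; dup$well_id <- c("w1", "w2"); dup$row_bc <- strrep("C", 8)
  expect_error(demultiplex(reads, dup), class = "tcrclonal_config_error")
})

test_that("simulated reads demultiplex to their true wells with no losses", {
  fx <- zero_noise_fixture()
  dm <- demultiplex(fx$cohort$reads, fx$cohort$barcode_map)
  expect_identical(nrow(dm), nrow(fx$cohort$reads))
  expect_false(any(is.na(dm$well_id)))
  expect_identical(dm$well_id, fx$cohort$reads$well_id)
})

test_that("clustering groups identical reads and splits dissimilar ones", {
  cl <- cluster_well_reads(rep("ACGTACGTACGTACGTACGT", 10))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$size, 10L)
  expect_identical(cl$consensus, "ACGTACGTACGTACGTACGT")

  # two groups at 80% mutual identity stay apart at the 95% threshold
  a <- strrep("ACGTT", 8)
  b <- paste0(strrep("ACGTT", 6), strrep("TTTTA", 2))
  cl2 <- cluster_well_reads(c(rep(a, 6), rep(b, 4)))
  expect_identical(nrow(cl2), 2L)
  expect_identical(cl2$size, c(6L, 4L))
})

test_that("consensus is column-majority with ties to the centroid", {
  base <- strrep("ACGTACGTAC", 4)
  mut1 <- base
  substr(mut1, 4, 4) <- "A"   # single substitution, identity 39/40
  reads <- c(rep(base, 3), rep(mut1, 2))
  cl <- cluster_well_reads(reads)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$consensus, base)
  # majority flips when the variant dominates
  cl2 <- cluster_well_reads(c(rep(base, 2), rep(mut1, 3)))
  expect_identical(cl2$consensus, mut1)
})

test_that("clustering equals the brute-force oracle on random small bins", {
  base <- with_seed_for_test(99, paste(
    sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""))
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:20, 1)
    # a few templates at varying divergence, some with indels
    templates <- c(base,
                   tcrclonal:::mutate_sequences(base, 0.02),
                   tcrclonal:::mutate_sequences(base, 0.15),
                   paste0(substr(base, 1, 50),
                          paste(sample(c("A", "C", "G", "T"), 14,
                                       replace = TRUE), collapse = "")))
    reads <- tcrclonal:::mutate_sequences(
      sample(templates, n, replace = TRUE), 0.01)
    got <- cluster_well_reads(reads)
    want <- oracle_cluster(reads)
    # same partition: membership of every unique sequence agrees
    got_map <- got |>
      dplyr::mutate(k = dplyr::row_number()) |>
      tidyr::unnest(members) |>
      dplyr::arrange(members)
    expect_identical(nrow(got_map), length(reads))
    want_assign <- want$cluster[match(reads, want$sequence)]
    # partitions equal up to label permutation
    expect_identical(
      as.integer(factor(got_map$k[order(got_map$members)],
                        levels = unique(got_map$k[order(got_map$members)]))),
      as.integer(factor(want_assign, levels = unique(want_assign))))
  }
})

test_that("well calling enforces the strict confidence thresholds", {
  fx <- zero_noise_fixture()
  ref <- fx$cohort$reference
  phen <- fx$cohort$phenotype_ref
  beta1 <- build_amplicon(ref, "TRBV29-1", "TRBJ2-5",
                          recombine_cdr3(ref, "TRBV29-1", "TRBJ2-5",
                                         "GCAAGC", j_trim = 0))
  beta2 <- build_amplicon(ref, "TRBV19", "TRBJ2-1",
                          recombine_cdr3(ref, "TRBV19", "TRBJ2-1",
                                         "TCTTCA", j_trim = 1))
  alpha1 <- build_amplicon(ref, "TRAV6", "TRAJ24",
                           recombine_cdr3(ref, "TRAV6", "TRAJ24",
                                          "GCTCTTTCTGAT", j_trim = 2,
                                          allele = "G"))
  alpha2 <- build_amplicon(ref, "TRAV10", "TRAJ18",
                           recombine_cdr3(ref, "TRAV10", "TRAJ18",
                                          "GGGAGC", j_trim = 1))
  alpha3 <- build_amplicon(ref, "TRAV1-2", "TRAJ33",
                           recombine_cdr3(ref, "TRAV1-2", "TRAJ33",
                                          "CCTAGC", j_trim = 1))

  # beta split 90/10: called with confidence 0.909...
  wc <- call_well(cluster_well_reads(c(rep(beta1, 90), rep(beta2, 10))),
                  ref, phen)
  expect_identical(wc$beta_consensus, beta1)
  expect_equal(wc$beta_confidence, 90 / 99, tolerance = 0.02)

  # beta split 60/40: 0.60 <= 0.80, no call
  wc2 <- call_well(cluster_well_reads(c(rep(beta1, 60), rep(beta2, 40))),
                   ref, phen)
  expect_true(is.na(wc2$beta_consensus))
  expect_equal(wc2$beta_confidence, 0.6)

  # alpha split 50/35/15: dominant and alternative both assigned
  wc3 <- call_well(cluster_well_reads(c(rep(alpha1, 50), rep(alpha2, 35),
                                        rep(alpha3, 15))), ref, phen)
  expect_identical(wc3$alpha_consensus, alpha1)
  expect_identical(wc3$alt_alpha_consensus, alpha2)
  expect_equal(wc3$alpha_confidence, 0.5)
  expect_equal(wc3$alt_alpha_confidence, 0.35)

  # exactly at 80% is not a call (strict inequality)
  wc4 <- call_well(cluster_well_reads(c(rep(beta1, 80), rep(beta2, 20))),
                   ref, phen)
  expect_true(is.na(wc4$beta_consensus))
})

test_that("phenotype binarization is presence/absence", {
  expect_identical(binarize_phenotypes(c(TBX21 = 37, IFNG = 0)),
                   c(TBX21 = 1L, IFNG = 0L))
  expect_error(binarize_phenotypes(c(TBX21 = -1)),
               class = "tcrclonal_data_error")
})

test_that("zero-noise phenotype bits equal the ground truth for all wells", {
  fx <- zero_noise_fixture()
  bits <- binarize_phenotypes(fx$pipeline$well_calls) |>
    tidyr::pivot_longer(-well_id, names_to = "marker", values_to = "bit")
  cmp <- bits |>
    dplyr::inner_join(fx$cohort$truth$phenotypes,
                      by = c("well_id", "marker"), suffix = c("", "_true"))
  expect_identical(nrow(cmp), nrow(fx$cohort$truth$phenotypes))
  expect_identical(cmp$bit, cmp$bit_true)
})

test_that("well coverage accounts over all sorted wells", {
  fx <- zero_noise_fixture()
  cov <- fx$pipeline$coverage
  expect_identical(cov$n_wells, nrow(fx$cohort$barcode_map))
  truth_covered <- fx$cohort$truth$wells |>
    dplyr::filter(depth > 0)
  expect_identical(cov$n_tcr_detected,
                   sum(fx$pipeline$well_calls$tcr_detected))
  # wells with only phenotype reads exist in principle; every well with a
  # TCR read must be detected
  expect_lte(cov$n_tcr_detected, nrow(truth_covered))
})
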