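test_that("mini reference is deterministic and anchor-consistent", {
  a <- build_mini_reference(2, 2, seed = 1)
  b <- build_mini_reference(2, 2, seed = 1)
  expect_identical(a, b)

  for (ref in list(a, build_mini_reference(6, 5, seed = 42))) {
    for (i in seq_len(nrow(ref))) {
      seg <- ref[i, ]
      expect_gte(nchar(seg$nt_sequence), 3 * (seg$anchor + 1))
      codon <- substr(seg$nt_sequence, 3 * seg$anchor + 1,
                      3 * seg$anchor + 3)
      aa <- translate_nt(codon)
      if (seg$segment_class == "V") expect_identical(aa, "C")
      else expect_true(aa %in% c("F", "W"))
    }
  }
  expect_error(build_mini_reference(0, 2), class = "tcrclonal_config_error")
})

test_that("TRAJ24 allele variants encode L (G allele) and F (C allele)", {
  ref <- mini_ref_fixture()
  for (case in list(c("G", "L", "G-allele/L"), c("C", "F", "C-allele/F"))) {
    cdr3 <- recombine_cdr3(ref, "TRAV6", "TRAJ24",
                           insert_nt = "GCTCTTTCTGAT", j_trim = 2,
                           allele = case[[1]])
    aa <- translate_nt(cdr3)
    # SNP residue sits two positions before the CDR3-terminal F
    expect_identical(substr(aa, nchar(aa) - 2, nchar(aa) - 2), case[[2]])
    expect_match(aa, "^CAL.*DSWGK[LF]QF$")
    expect_identical(traj24_allele(cdr3), case[[3]])
  }
})

test_that("cohort simulation is deterministic and conserves the plan", {
  fx <- zero_noise_fixture()
  again <- simulate_cohort(fx$config)
  expect_identical(fx$cohort$reads, again$reads)
  expect_identical(fx$cohort$truth, again$truth)
  expect_identical(fx$cohort$index, again$index)

  # truth tallies equal the clonal plan
  plan <- fx$config$clonal_plan |>
    dplyr::select(clone_id, donor, n_isolates) |>
    dplyr::arrange(clone_id)
  tallies <- fx$cohort$truth$clonotypes |>
    dplyr::select(clone_id, donor, n_isolates) |>
    dplyr::arrange(clone_id)
  expect_equal(as.data.frame(tallies), as.data.frame(plan))

  # read conservation: reads written equal the summed per-well depths
  expect_identical(nrow(fx$cohort$reads),
                   as.integer(sum(fx$cohort$truth$wells$depth)))
  # non-empty wells = wells with truth occupancy and positive depth
  wells_with_reads <- unique(fx$cohort$reads$well_id)
  truth_occ <- fx$cohort$truth$wells |>
    dplyr::filter(occupied, depth > 0)
  expect_setequal(wells_with_reads, truth_occ$well_id)
})

test_that("zero-noise reads are byte-identical to the planted amplicons", {
  fx <- zero_noise_fixture()
  plan <- fx$config$clonal_plan
  ref <- fx$cohort$reference
  clone <- plan[plan$clone_id == "eTRAJ24L-1", ]
  beta_amp <- build_amplicon(ref, clone$trbv, clone$trbj, clone$cdr3b_nt)
  wells <- fx$cohort$truth$wells |>
    dplyr::filter(clone_id == "eTRAJ24L-1") |>
    dplyr::pull(well_id)
  reads <- demultiplex(fx$cohort$reads, fx$cohort$barcode_map) |>
    dplyr::filter(well_id %in% wells)
  expect_gt(nrow(reads), 0)
  # every beta-derived read in those wells equals the planted amplicon
  expect_true(beta_amp %in% reads$sequence)
  expect_true(all(nchar(reads$sequence) > 0))
})

test_that("read depth model matches its mean at study-scale parameters", {
  depths <- with_seed_for_test(123, tcrclonal:::draw_depths(1000, 6091, 4556))
  se <- 4556 / sqrt(1000)
  expect_lt(abs(mean(depths) - 6091), 3 * se)
  expect_true(all(depths >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_donor_pairs = 0),
               class = "tcrclonal_config_error")
  expect_error(simulation_config(per_base_error_rate = 1.5),
               class = "tcrclonal_config_error")
  ref <- mini_ref_fixture()
  bad_plan <- tibble::tibble(
    clone_id = "x", donor = "P1", trbv = "NOPE", trbj = "TRBJ2-5",
    cdr3b_nt = "TGTTTT", trav = "TRAV6", traj = "TRAJ24",
    cdr3a_nt = "TGTTTT", allele = NA_character_,
    tetramers = list("HCRT1-13"), n_isolates = 2L
  )
  expect_error(
    simulation_config(n_donor_pairs = 1, clonal_plan = bad_plan,
                      reference = ref),
    class = "tcrclonal_config_error")
  over_plan <- default_clonal_plan(ref, c("C1", "P1"), "HCRT1-13") |>
    dplyr::mutate(n_isolates = 500L)
  expect_error(
    simulation_config(n_donor_pairs = 1, wells_per_plate = 10,
                      tetramer_categories = "HCRT1-13",
                      clonal_plan = over_plan, reference = ref),
    class = "tcrclonal_config_error")
})

test_that("written cohort round-trips through the plain-text formats", {
  fx <- zero_noise_fixture()
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, dir)
  reads <- read_fastq_reads(file.path(dir, "reads.fastq"))
  expect_identical(nrow(reads), nrow(fx$cohort$reads))
  expect_identical(reads$sequence, fx$cohort$reads$sequence)
  bm <- utils::read.delim(file.path(dir, "barcode_map.tsv"))
  expect_identical(nrow(bm), nrow(fx$cohort$barcode_map))
})
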