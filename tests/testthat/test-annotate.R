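test_that("segment assignment recovers planted segments exactly", {
  ref <- mini_ref_fixture()
  cdr3 <- recombine_cdr3(ref, "TRBV29-1", "TRBJ2-5", "GCAAGCAGT",
                         j_trim = 0)
  amp <- build_amplicon(ref, "TRBV29-1", "TRBJ2-5", cdr3)
  segs <- assign_segments(amp, ref, "beta")
  expect_identical(segs$v_gene, "TRBV29-1")
  expect_identical(segs$j_gene, "TRBJ2-5")

  # V-only sequence: J unassignable
  vonly <- substr(amp, 1, 150)
  segs2 <- assign_segments(vonly, ref, "beta")
  expect_true(is.na(segs2$j_gene))
  expect_identical(segs2$reason, "below score floor")
})

test_that("segment assignment agrees with a brute-force oracle", {
  ref <- mini_ref_fixture()
  score_one <- function(query, seg_nt) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      query, seg_nt, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 0, gapExtension = 5))
  }
  set.seed(21)
  for (i in 1:10) {
    v <- sample(ref$name[ref$segment_class == "V" & ref$chain == "alpha"], 1)
    j <- sample(ref$name[ref$segment_class == "J" & ref$chain == "alpha"], 1)
    jrow <- ref[ref$name == j, ]
    cdr3 <- recombine_cdr3(ref, v, j,
                           insert_nt = tcrclonal:::random_codons(3),
                           j_trim = min(2L, jrow$anchor))
    amp <- tcrclonal:::mutate_sequences(
      build_amplicon(ref, v, j, cdr3), 0.01)
    segs <- assign_segments(amp, ref, "alpha")
    vs <- ref[ref$segment_class == "V" & ref$chain == "alpha", ]
    js <- ref[ref$segment_class == "J" & ref$chain == "alpha", ]
    v_scores <- vapply(vs$nt_sequence, score_one, numeric(1), query = amp)
    j_scores <- vapply(js$nt_sequence, score_one, numeric(1), query = amp)
    expect_identical(segs$v_gene,
                     vs$name[order(-v_scores, vs$name)][1])
    expect_identical(segs$j_gene,
                     js$name[order(-j_scores, js$name)][1])
  }
})

test_that("CDR3 extraction spans the anchors and flags productivity", {
  ref <- mini_ref_fixture()
  cdr3_nt <- recombine_cdr3(ref, "TRAV6", "TRAJ24", "GCTCTTTCTGAT",
                            j_trim = 2, allele = "G")
  amp <- build_amplicon(ref, "TRAV6", "TRAJ24", cdr3_nt)
  segs <- assign_segments(amp, ref, "alpha")
  got <- extract_cdr3(amp, segs, ref)
  expect_identical(got$cdr3_nt, cdr3_nt)
  expect_identical(got$cdr3_aa, "CALSDTDSWGKLQF")
  expect_true(got$productive)

  # internal stop codon -> non-productive
  stop_nt <- recombine_cdr3(ref, "TRAV6", "TRAJ24", "GCTTAATCTGAT",
                            j_trim = 2, allele = "G")
  amp2 <- build_amplicon(ref, "TRAV6", "TRAJ24", stop_nt)
  got2 <- extract_cdr3(amp2, assign_segments(amp2, ref, "alpha"), ref)
  expect_false(got2$productive)
  expect_identical(got2$reason, "stop codon")

  # frameshifted junction -> non-productive
  fs_nt <- recombine_cdr3(ref, "TRAV6", "TRAJ24", "GCTCTTTCTGA",
                          j_trim = 2, allele = "G")
  amp3 <- build_amplicon(ref, "TRAV6", "TRAJ24", fs_nt)
  got3 <- extract_cdr3(amp3, assign_segments(amp3, ref, "alpha"), ref)
  expect_false(got3$productive)
  expect_identical(got3$reason, "out of frame")
})

test_that("TRAJ24 allele calling follows the TTG/TTC codon rule", {
  ref <- mini_ref_fixture()
  g <- recombine_cdr3(ref, "TRAV6", "TRAJ24", "GCTCTT", j_trim = 2,
                      allele = "G")
  c_ <- recombine_cdr3(ref, "TRAV6", "TRAJ24", "GCTCTT", j_trim = 2,
                       allele = "C")
  expect_identical(traj24_allele(g), "G-allele/L")
  expect_identical(traj24_allele(c_), "C-allele/F")

  # CTG also encodes leucine but is outside the stated codon pair
  n <- nchar(g)
  ctg <- g
  substr(ctg, n - 8, n - 6) <- "CTG"
  expect_warning(out <- traj24_allele(ctg), "CTG")
  expect_identical(out, "undetermined")

  expect_error(traj24_allele(g, j_gene = "TRAJ18"),
               class = "tcrclonal_contract_error")
})

test_that("all productive CDR3s match the anchored pattern", {
  fx <- zero_noise_fixture()
  cells <- fx$pipeline$analyzed
  expect_gt(nrow(cells), 0)
  expect_true(all(grepl("^C.*[FW]$", cells$cdr3b_aa)))
  expect_true(all(grepl("^C.*[FW]$", cells$cdr3a_aa)))
  expect_true(all(nchar(cells$cdr3b_nt) %% 3 == 0))
  expect_true(all(nchar(cells$cdr3a_nt) %% 3 == 0))
})

test_that("zero-noise annotation of planted cells is exact", {
  fx <- zero_noise_fixture()
  jt <- joined_truth(fx)
  expect_identical(nrow(jt$cells), nrow(jt$truth))
  expect_identical(jt$cells$trbv, jt$cells$t_trbv)
  expect_identical(jt$cells$trbj, jt$cells$t_trbj)
  expect_identical(jt$cells$cdr3b_aa, jt$cells$t_cdr3b)
  expect_identical(jt$cells$trav, jt$cells$t_trav)
  expect_identical(jt$cells$traj, jt$cells$t_traj)
  expect_identical(jt$cells$cdr3a_aa, jt$cells$t_cdr3a)
  traj24 <- jt$cells |> dplyr::filter(!is.na(t_allele))
  expect_identical(substr(traj24$allele_call, 1, 1), traj24$t_allele)
})
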