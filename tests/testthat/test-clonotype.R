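toy_cell <- function(donor, tetramer, well, cdr3b = "CASSAETQYF",
                     cdr3a = "CALSDTDSWGKLQF", trbv = "TRBV29-1",
                     trbj = "TRBJ2-5", trav = "TRAV6", traj = "TRAJ24") {
  tibble::tibble(
    well_id = well, donor = donor, status = ifelse(startsWith(donor, "P"),
                                                   "case", "control"),
    tetramer = tetramer, trbv = trbv, trbj = trbj,
    cdr3b_nt = NA_character_, cdr3b_aa = cdr3b, beta_productive = TRUE,
    trav = trav, traj = traj, cdr3a_nt = NA_character_, cdr3a_aa = cdr3a,
    alpha_productive = TRUE, allele_call = NA_character_
  )
}

test_that("clonotypes partition cells by donor, genes and both CDR3s", {
  cells <- dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"),
    toy_cell("P1", "HCRT87-100", "w2"),       # same clone, other tetramer
    toy_cell("P1", "HCRT1-13", "w3", cdr3b = "CASSLETQYF"),
    toy_cell("C1", "HCRT1-13", "w4")          # public partner, 1 isolate
  )
  ct <- build_clonotypes(cells)
  expect_identical(nrow(ct), 3L)
  expect_identical(sum(ct$n_isolates), nrow(cells))

  main <- ct |> dplyr::filter(donor == "P1", n_isolates == 2)
  expect_true(main$expanded)
  expect_false(main$highly_expanded)
  expect_true(main$cross_binding)
  expect_identical(main$public_partners[[1]], "C1")

  pub <- ct |> dplyr::filter(donor == "C1")
  expect_false(pub$expanded)
  expect_identical(pub$public_partners[[1]], "P1")
})

test_that("expansion is donor-scoped", {
  cells <- dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"),
    toy_cell("P2", "HCRT1-13", "w2"),
    toy_cell("P3", "HCRT1-13", "w3")
  )
  ct <- build_clonotypes(cells)
  expect_identical(nrow(ct), 3L)
  expect_false(any(ct$expanded))
  # same cells under one donor collapse to a single expanded clonotype
  ct2 <- build_clonotypes(cells |> dplyr::mutate(donor = "P1"))
  expect_identical(nrow(ct2), 1L)
  expect_true(ct2$expanded)
})

test_that("zero-noise clonotype table matches the planted plan exactly", {
  fx <- zero_noise_fixture()
  plan <- fx$config$clonal_plan
  ct <- fx$pipeline$clonotypes
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    hit <- ct |>
      dplyr::filter(donor == p$donor, trbv == p$trbv, trbj == p$trbj,
                    trav == p$trav, traj == p$traj,
                    cdr3b == translate_nt(p$cdr3b_nt),
                    cdr3a == translate_nt(p$cdr3a_nt))
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$n_isolates, p$n_isolates)
    expect_identical(hit$expanded, p$n_isolates >= 2L)
    expect_identical(hit$cross_binding,
                     length(unique(p$tetramers[[1]])) > 1L)
    if (!is.na(p$allele)) {
      expect_identical(substr(hit$allele_call, 1, 1), p$allele)
    }
  }
  # partition property
  expect_identical(sum(ct$n_isolates), nrow(fx$pipeline$analyzed))
})

test_that("contingency tables reproduce printed-precision percentages", {
  cells <- dplyr::bind_rows(
    purrr::map_dfr(1:751, ~ toy_cell("C1", "HCRT87-100", paste0("c", .x),
                                     cdr3b = paste0("CAS", .x, "F"))),
    purrr::map_dfr(1:740, ~ toy_cell("P1", "HCRT87-100", paste0("p", .x),
                                     cdr3b = paste0("CAT", .x, "F")))
  ) |>
    dplyr::mutate(expanded = c(rep(TRUE, 6), rep(FALSE, 745),
                               rep(TRUE, 26), rep(FALSE, 714)))
  tab <- expansion_contingency(cells, include_all = FALSE)
  expect_equal(tab$control_expanded, 6)
  expect_equal(tab$case_expanded, 26)
  expect_equal(tab$control_pct, 0.8)
  expect_equal(tab$case_pct, 3.51)
})

test_that("J-gene sharing groups span multiple subjects only", {
  cells <- dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"), toy_cell("P1", "HCRT1-13", "w2"),
    toy_cell("C1", "HCRT1-13", "w3", cdr3b = "CASSLETQYF"),
    toy_cell("C1", "HCRT1-13", "w4", cdr3b = "CASSLETQYF"),
    toy_cell("P2", "HCRT1-13", "w5", trbj = "TRBJ2-1", traj = "TRAJ18",
             cdr3b = "CASSXF", cdr3a = "CAXF"),
    toy_cell("P2", "HCRT1-13", "w6", trbj = "TRBJ2-1", traj = "TRAJ18",
             cdr3b = "CASSXF", cdr3a = "CAXF")
  )
  ct <- build_clonotypes(cells)
  grp <- jgene_sharing_groups(ct)
  expect_identical(nrow(grp), 1L)
  expect_identical(grp$trbj, "TRBJ2-5")
  expect_identical(grp$traj, "TRAJ24")
  expect_identical(grp$n_subjects, 2L)
  mat <- jgene_sharing_matrix(grp)
  expect_identical(sort(unique(mat$donor)), c("C1", "P1"))

  # all-distinct J pairs: no groups
  solo <- build_clonotypes(dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"),
    toy_cell("C1", "HCRT1-13", "w2", trbj = "TRBJ2-1", cdr3b = "CASSXF")
  ))
  expect_identical(nrow(jgene_sharing_groups(solo)), 0L)
})

test_that("gene-usage folds are exact frequency ratios", {
  uni <- purrr::map_dfr(1:100, ~ toy_cell("P1", "HCRT1-13",
                                          paste0("u", .x),
                                          trbv = ifelse(.x <= 20,
                                                        "TRBV29-1",
                                                        "TRBV19")))
  sub <- uni[1:10, ]
  tab <- gene_usage_enrichment(sub, uni)
  row <- tab |> dplyr::filter(segment_class == "TRBV", gene == "TRBV29-1")
  expect_equal(row$fold, (10 / 10) / (20 / 100))
  # identical frequencies give fold 1
  tab2 <- gene_usage_enrichment(uni, uni)
  expect_true(all(tab2$fold == 1))
  # exact arithmetic on study-scale counts
  expect_equal((15 / 302) / (74 / 2762), 41430 / 22348, tolerance = 1e-12)
  expect_error(gene_usage_enrichment(uni[0, ], uni),
               class = "tcrclonal_data_error")
})

test_that("cross-binding flags are monotone in tetramer categories", {
  base <- dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"),
    toy_cell("P1", "HCRT1-13", "w2")
  )
  ct1 <- build_clonotypes(base)
  expect_false(ct1$cross_binding)
  more <- dplyr::bind_rows(base, toy_cell("P1", "HCRT87-100", "w3"))
  ct2 <- build_clonotypes(more)
  expect_true(ct2$cross_binding)
})

test_that("near-identical clonotype pairs are reported, not merged", {
  cells <- dplyr::bind_rows(
    toy_cell("P1", "HCRT1-13", "w1"), toy_cell("P1", "HCRT1-13", "w2"),
    toy_cell("P1", "HCRT1-13", "w3", cdr3b = "CASSAETQYG",
             cdr3a = "CALSETDSWGKLQF")
  )
  ct <- build_clonotypes(cells)
  expect_identical(nrow(ct), 2L)
  pairs <- relaxed_clonotype_pairs(ct)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$dist_cdr3b, 1L)
  expect_identical(pairs$dist_cdr3a, 1L)
})
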