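# Shared simulated cohorts, built lazily once per test run.

with_seed_for_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

.cohort_cache <- new.env(parent = emptyenv())

# Zero-noise desk-scale cohort: 2 donor pairs, 24-well plates, two
# tetramer categories, depth ~40 reads/well.
zero_noise_fixture <- function() {
  if (is.null(.cohort_cache$zero)) {
    cfg <- simulation_config(
      n_donor_pairs = 2, wells_per_plate = 24,
      reads_per_well_mean = 40, reads_per_well_sd = 10,
      per_base_error_rate = 0, seed = 7
    )
    cohort <- simulate_cohort(cfg)
    .cohort_cache$zero <- list(config = cfg, cohort = cohort,
                               pipeline = run_pipeline(cohort))
  }
  .cohort_cache$zero
}

# 1% per-base error, 200 reads/well, every well occupied and dropout-free.
noisy_fixture <- function() {
  if (is.null(.cohort_cache$noisy)) {
    cfg <- simulation_config(
      n_donor_pairs = 1, wells_per_plate = 12,
      reads_per_well_mean = 200, reads_per_well_sd = 30,
      per_base_error_rate = 0.01, p_well_empty = 0,
      p_beta_dropout = 0, p_alpha_dropout = 0, seed = 11
    )
    cohort <- simulate_cohort(cfg)
    .cohort_cache$noisy <- list(config = cfg, cohort = cohort,
                                pipeline = run_pipeline(cohort))
  }
  .cohort_cache$noisy
}

mini_ref_fixture <- function() {
  if (is.null(.cohort_cache$ref)) {
    .cohort_cache$ref <- build_mini_reference(4, 4, seed = 1)
  }
  .cohort_cache$ref
}

alpha_reference_fixture <- function() {
  if (is.null(.cohort_cache$alpha_ref)) {
    .cohort_cache$alpha_ref <- naive_reference_repertoire(
      mini_ref_fixture(), "alpha", n = 10000, seed = 2)
  }
  .cohort_cache$alpha_ref
}

# Join analyzed cells to the planted-well truth of a cohort.
joined_truth <- function(fx) {
  truth <- fx$cohort$truth$wells |>
    dplyr::filter(occupied, !startsWith(clone_id, "bg-"))
  cells <- fx$pipeline$analyzed |>
    dplyr::inner_join(
      truth |>
        dplyr::select(well_id, t_trbv = trbv, t_trbj = trbj,
                      t_cdr3b = cdr3b_aa, t_trav = trav, t_traj = traj,
                      t_cdr3a = cdr3a_aa, t_allele = allele),
      by = "well_id")
  list(truth = truth, cells = cells)
}

# Independent global-alignment identity (no fast path), for oracles.
oracle_identity <- function(seqs, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), subject, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 0, gapExtension = 5
  )
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# Brute-force single-linkage-to-centroid clustering oracle: repeatedly
# take the most abundant remaining unique sequence (ties lexicographic)
# as centroid and sweep in everything within the identity radius.
oracle_cluster <- function(sequences, min_identity = 0.95) {
  tab <- table(sequences)
  uni <- names(tab); cnt <- as.integer(tab)
  ord <- order(-cnt, uni)
  uni <- uni[ord]; cnt <- cnt[ord]
  assign <- integer(length(uni))
  k <- 0L
  remaining <- seq_along(uni)
  while (length(remaining) > 0L) {
    k <- k + 1L
    cen <- remaining[[1L]]
    ident <- oracle_identity(uni[remaining], uni[[cen]])
    assign[remaining[ident >= min_identity]] <- k
    remaining <- remaining[ident < min_identity]
  }
  tibble::tibble(sequence = uni, count = cnt, cluster = assign)
}

random_cdr3_aa <- function(n, len_range = 10:16,
                           alphabet = strsplit("ACDEGHIKLMNPQRSTVY", "")[[1]]) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range, 1L)
    paste0("C", paste(sample(alphabet, len - 2L, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}
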