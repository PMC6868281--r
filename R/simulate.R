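#' Recombine a CDR3 junction from germline segments
#'
#' Composes a CDR3 nucleotide sequence the way V(D)J recombination does in
#' this simplified model: the V segment's conserved 2nd-CYS anchor codon,
#' an untemplated insert, then the J segment's CDR3 tail from codon
#' `j_trim` through its F/W anchor codon (inclusive). For segments carrying
#' an allele annotation (TRAJ24), `allele` selects the SNP base.
#'
#' @param reference Reference tibble from [build_mini_reference()].
#' @param v_gene,j_gene Segment names.
#' @param insert_nt Untemplated junction nucleotides (may be `""`).
#' @param j_trim 0-based codon index in the J germline where the CDR3 tail
#'   starts; must be `<=` the J anchor.
#' @param allele Optional allele label (e.g. `"G"`/`"C"` for TRAJ24).
#' @return The CDR3 nucleotide string (starts with the V cysteine codon,
#'   ends with the J anchor codon).
#' @export
recombine_cdr3 <- function(reference, v_gene, j_gene, insert_nt = "",
                           j_trim = 2L, allele = NULL) {
  v <- reference[reference$name == v_gene & reference$segment_class == "V", ]
  j <- reference[reference$name == j_gene & reference$segment_class == "J", ]
  if (nrow(v) != 1L || nrow(j) != 1L) {
    abort(paste0("unknown segment(s): ", v_gene, "/", j_gene),
          class = "tcrclonal_config_error")
  }
  if (j_trim > j$anchor) abort("j_trim beyond the J anchor")
  j_nt <- if (!is.null(allele)) apply_allele(reference, j_gene, allele) else j$nt_sequence
  paste0(
    substr(v$nt_sequence, 3L * v$anchor + 1L, 3L * v$anchor + 3L),
    insert_nt,
    substr(j_nt, 3L * j_trim + 1L, 3L * j$anchor + 3L)
  )
}

#' Compose the full amplicon read for a rearranged chain
#'
#' The simulated amplicon spans the V body up to (not including) the
#' 2nd-CYS codon, the CDR3 junction, then the J body downstream of its
#' anchor codon -- i.e. the V(D)J region including the CDR3, as a
#' plate-based multiplex TCR amplicon covers.
#'
#' @inheritParams recombine_cdr3
#' @param cdr3_nt CDR3 junction nucleotides (as from [recombine_cdr3()]).
#' @return Amplicon nucleotide string.
#' @export
build_amplicon <- function(reference, v_gene, j_gene, cdr3_nt) {
  v <- reference[reference$name == v_gene & reference$segment_class == "V", ]
  j <- reference[reference$name == j_gene & reference$segment_class == "J", ]
  if (nrow(v) != 1L || nrow(j) != 1L) {
    abort(paste0("unknown segment(s): ", v_gene, "/", j_gene),
          class = "tcrclonal_config_error")
  }
  paste0(
    substr(v$nt_sequence, 1L, 3L * v$anchor),
    cdr3_nt,
    substr(j$nt_sequence, 3L * j$anchor + 4L, nchar(j$nt_sequence))
  )
}

#' Default per-marker phenotype emission probabilities
#'
#' Probability that a cell's well yields at least one read of each
#' phenotyping transcript, conditional on the cell belonging to an expanded
#' clonotype. Values for the effector markers reflect the frequencies
#' observed in tetramer-sorted CD4+ repertoires (e.g. TBX21 0.89 vs 0.183,
#' IFNG 0.378 vs 0.024, PRF1 0.516 vs 0.047); remaining markers are given
#' low background rates.
#'
#' @return A tibble with columns `marker`, `p_expanded`, `p_unexpanded`.
#' @export
default_phenotype_emission <- function() {
  panel <- phenotype_panel()$marker
  em <- tibble(marker = panel, p_expanded = 0.10, p_unexpanded = 0.05)
  set_p <- function(em, m, pe, pu) {
    em$p_expanded[em$marker == m] <- pe
    em$p_unexpanded[em$marker == m] <- pu
    em
  }
  em <- set_p(em, "TBX21", 0.890, 0.183)
  em <- set_p(em, "IFNG",  0.378, 0.024)
  em <- set_p(em, "PRF1",  0.516, 0.047)
  em <- set_p(em, "TGFB1", 0.40,  0.15)
  em <- set_p(em, "GZMB",  0.30,  0.05)
  em <- set_p(em, "RORC",  0.01,  0.02)
  em <- set_p(em, "FOXP3", 0.01,  0.03)
  em <- set_p(em, "BCL6",  0.04,  0.05)
  em
}

#' Default planted clonal structure
#'
#' Builds a clonal plan emulating the hallmark repertoire findings: two
#' patients carrying expanded TRAJ24 G-allele (leucine) clonotypes with
#' TRBV29-1_TRBJ2-5 / TRAV6_TRAJ24 genes and conserved CDR3s
#' (`CALxxDSWGKLQF`-type alpha, `E.DRGRSET`-motif beta), isolated under two
#' tetramer specificities (cross-binding); one control with an expanded
#' TRAJ24 C-allele (phenylalanine) clonotype on the same gene combination;
#' one control sharing the patient clonotype as a single public isolate;
#' and a generic expanded clonotype on unrelated genes.
#'
#' @param reference Reference tibble from [build_mini_reference()].
#' @param donors Character vector of donor ids (e.g. `c("C1","P1",...)`).
#' @param tetramers Tetramer category labels in use.
#' @return A tibble, one row per planted clonotype: `clone_id`, `donor`,
#'   `trbv`, `trbj`, `cdr3b_nt`, `trav`, `traj`, `cdr3a_nt`, `allele`,
#'   `tetramers` (list-column), `n_isolates`.
#' @export
default_clonal_plan <- function(reference, donors, tetramers) {
  patients <- donors[startsWith(donors, "P")]
  controls <- donors[startsWith(donors, "C")]
  tet2 <- utils::head(tetramers, 2L)

  # CDR3b CASSEGDRGRSETQYF / CASSEADRGRSETQYF: carry the E.DRGRSET motif,
  # end in the TRBJ2-5 germline ETQYF. CDR3a CALSDTDSWGKLQF variants carry
  # the TDSWGK motif and the TRAJ24 SNP codon at position length-2.
  b_ins <- c(p1 = "GCCTCTTCAGAAGGGGACAGGGGGCGGAGC",   # ASSEGDRGRS
             p2 = "GCCTCTTCAGAAGCGGACAGGGGGCGGAGC",   # ASSEADRGRS
             c1 = "GCCTCTTCACTTAGGACCGGG")            # ASSLRTG
  a_ins <- c(p1 = "GCTCTTTCTGAT",                     # ALSD
             p2 = "GCTCTTTCTGAA",                     # ALSE
             c1 = "GCTCTTTCTGAT")                     # ALSD

  row_for <- function(id, donor, bk, ak, allele, tets, n) {
    tibble(
      clone_id = id, donor = donor,
      trbv = "TRBV29-1", trbj = "TRBJ2-5",
      cdr3b_nt = recombine_cdr3(reference, "TRBV29-1", "TRBJ2-5",
                                insert_nt = b_ins[[bk]], j_trim = 0L),
      trav = "TRAV6", traj = "TRAJ24",
      cdr3a_nt = recombine_cdr3(reference, "TRAV6", "TRAJ24",
                                insert_nt = a_ins[[ak]], j_trim = 2L,
                                allele = allele),
      allele = allele, tetramers = list(tets), n_isolates = n
    )
  }

  rows <- list()
  if (length(patients) >= 1L) {
    rows$p1 <- row_for("eTRAJ24L-1", patients[[1L]], "p1", "p1", "G", tet2, 7L)
  }
  if (length(patients) >= 2L) {
    rows$p2 <- row_for("eTRAJ24L-2", patients[[2L]], "p2", "p2", "G", tet2, 5L)
  }
  if (length(controls) >= 1L) {
    rows$c1 <- row_for("eTRAJ24F-1", controls[[1L]], "c1", "c1", "C",
                       tet2[[1L]], 6L)
  }
  if (length(controls) >= 2L && length(patients) >= 2L) {
    # public partner: identical clonotype to eTRAJ24L-2, single isolate.
    pub <- row_for("pubTRAJ24L", controls[[2L]], "p2", "p2", "G",
                   tetramers[[length(tetramers)]], 1L)
    rows$pub <- pub
  }
  if (length(patients) >= 1L) {
    segs <- function(cls, ch) {
      reference$name[reference$segment_class == cls & reference$chain == ch]
    }
    bv <- setdiff(segs("V", "beta"), "TRBV29-1")[1L]
    bj <- setdiff(segs("J", "beta"), "TRBJ2-5")[1L]
    av <- setdiff(segs("V", "alpha"), "TRAV6")[1L]
    aj <- setdiff(segs("J", "alpha"), "TRAJ24")[1L]
    if (!anyNA(c(bv, bj, av, aj))) {
      rows$gen <- tibble(
        clone_id = "expanded-generic", donor = patients[[1L]],
        trbv = bv, trbj = bj,
        cdr3b_nt = recombine_cdr3(reference, bv, bj,
                                  insert_nt = "GCTAGCAGGACT", j_trim = 1L),
        trav = av, traj = aj,
        cdr3a_nt = recombine_cdr3(reference, av, aj,
                                  insert_nt = "GTTAGCGGGACT", j_trim = 1L),
        allele = NA_character_, tetramers = list(tet2[[1L]]), n_isolates = 3L
      )
    }
  }
  bind_rows(rows)
}

#' Configure a synthetic single-cell TCR cohort
#'
#' Collects and validates all simulation parameters. Defaults encode the
#' study-scale conditions: 12 blinded case/control donor pairs, 96-well
#' plates (one plate per donor-tetramer category), read depth per well
#' drawn from a negative binomial with mean 6091 and standard deviation
#' 4556, and error-free 8-nt plate/row/column barcodes. Tests and examples
#' typically pass smaller `n_donor_pairs`, `wells_per_plate` and read
#' depths explicitly.
#'
#' @param n_donor_pairs Number of case/control pairs.
#' @param tetramer_categories Tetramer labels; each donor receives one
#'   plate per category.
#' @param wells_per_plate Wells sorted per plate (<= 96).
#' @param reads_per_well_mean,reads_per_well_sd Depth model (negative
#'   binomial when `sd^2 > mean`, else Poisson).
#' @param per_base_error_rate Per-base substitution probability.
#' @param p_well_empty Probability a sorted well yields no reads at all
#'   (no-cell wells; drives the well-coverage accounting).
#' @param p_beta_dropout,p_alpha_dropout Probability that a background
#'   (non-planted) cell's beta or alpha amplicon fails, yielding a well
#'   without a paired TCR call. Planted cells never drop out.
#' @param frac_beta,frac_alpha Expected fractions of a well's reads from
#'   the beta and (total) alpha amplicons; the remainder is split across
#'   the cell's positive phenotype markers.
#' @param p_alt_alpha Probability a background cell expresses a second
#'   productive alpha chain.
#' @param alt_alpha_frac Share of alpha reads taken by the alternative
#'   alpha when present.
#' @param min_reads_occupied Floor on the read count for wells that
#'   contain a cell (a sorted, lysed cell essentially always amplifies).
#' @param clonal_plan Planted clonotypes; see [default_clonal_plan()].
#' @param phenotype_emission See [default_phenotype_emission()].
#' @param index_model Named list: `background_mfi`, `background_mean_fsc`,
#'   `fi_meanlog`, `fi_sdlog`, `fsc_mean`, `fsc_sd`.
#' @param tiv_donors Donor ids flagged as recently influenza (TIV)
#'   vaccinated (used by exclusion filters in the statistics layer).
#' @param reference Germline reference; defaults to
#'   [build_mini_reference()].
#' @param phenotype_ref Marker amplicon panel; defaults to
#'   [phenotype_panel()].
#' @param seed Integer seed controlling every random draw.
#' @return A validated `tcr_sim_config` list.
#' @export
simulation_config <- function(n_donor_pairs = 12,
                              tetramer_categories = c("HCRT1-13", "HCRT87-100"),
                              wells_per_plate = 96,
                              reads_per_well_mean = 6091,
                              reads_per_well_sd = 4556,
                              per_base_error_rate = 0,
                              p_well_empty = 0.163,
                              p_beta_dropout = 0.20,
                              p_alpha_dropout = 0.25,
                              frac_beta = 0.45,
                              frac_alpha = 0.30,
                              p_alt_alpha = 0.10,
                              alt_alpha_frac = 0.35,
                              min_reads_occupied = 12,
                              clonal_plan = NULL,
                              phenotype_emission = default_phenotype_emission(),
                              index_model = list(background_mfi = 150,
                                                 background_mean_fsc = 5e4,
                                                 fi_meanlog = log(1500),
                                                 fi_sdlog = 0.6,
                                                 fsc_mean = 5e4,
                                                 fsc_sd = 8e3),
                              tiv_donors = c("C5", "C6", "C11", "P5"),
                              reference = NULL,
                              phenotype_ref = phenotype_panel(),
                              seed = 1) {
  if (is.null(reference)) reference <- build_mini_reference(4, 4, seed = seed)
  n_pairs <- as.integer(n_donor_pairs)
  if (n_pairs < 1L) abort("n_donor_pairs must be >= 1",
                          class = "tcrclonal_config_error")
  if (wells_per_plate < 1L || wells_per_plate > 96L) {
    abort("wells_per_plate must be in 1..96", class = "tcrclonal_config_error")
  }
  probs <- c(per_base_error_rate, p_well_empty, p_beta_dropout,
             p_alpha_dropout, frac_beta, frac_alpha, p_alt_alpha,
             alt_alpha_frac, phenotype_emission$p_expanded,
             phenotype_emission$p_unexpanded)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "tcrclonal_config_error")
  }
  if (frac_beta + frac_alpha >= 1) {
    abort("frac_beta + frac_alpha must be < 1",
          class = "tcrclonal_config_error")
  }
  donors <- as.vector(t(cbind(paste0("C", seq_len(n_pairs)),
                              paste0("P", seq_len(n_pairs)))))
  if (is.null(clonal_plan)) {
    clonal_plan <- default_clonal_plan(reference, donors, tetramer_categories)
  }
  validate_clonal_plan(clonal_plan, reference, donors, tetramer_categories,
                       wells_per_plate)
  structure(list(
    n_donor_pairs = n_pairs, donors = donors,
    tetramer_categories = tetramer_categories,
    wells_per_plate = as.integer(wells_per_plate),
    reads_per_well_mean = reads_per_well_mean,
    reads_per_well_sd = reads_per_well_sd,
    per_base_error_rate = per_base_error_rate,
    p_well_empty = p_well_empty,
    p_beta_dropout = p_beta_dropout, p_alpha_dropout = p_alpha_dropout,
    frac_beta = frac_beta, frac_alpha = frac_alpha,
    p_alt_alpha = p_alt_alpha, alt_alpha_frac = alt_alpha_frac,
    min_reads_occupied = as.integer(min_reads_occupied),
    clonal_plan = clonal_plan,
    phenotype_emission = phenotype_emission,
    index_model = index_model,
    tiv_donors = tiv_donors,
    reference = reference, phenotype_ref = phenotype_ref,
    seed = as.integer(seed)
  ), class = "tcr_sim_config")
}

validate_clonal_plan <- function(plan, reference, donors, tetramers,
                                 wells_per_plate) {
  if (is.null(plan) || nrow(plan) == 0L) return(invisible(plan))
  segs <- reference$name
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    if (!all(c(row$trbv, row$trbj, row$trav, row$traj) %in% segs)) {
      abort(paste0("clonal_plan row ", i, " references unknown segments"),
            class = "tcrclonal_config_error")
    }
    if (!row$donor %in% donors) {
      abort(paste0("clonal_plan row ", i, " references unknown donor ",
                   row$donor), class = "tcrclonal_config_error")
    }
    if (!all(row$tetramers[[1L]] %in% tetramers)) {
      abort(paste0("clonal_plan row ", i, " references unknown tetramer"),
            class = "tcrclonal_config_error")
    }
  }
  # capacity: isolates of one donor-tetramer plate must fit in the plate
  alloc <- allocate_plan(plan)
  over <- alloc |>
    count(donor, tetramer) |>
    filter(n > wells_per_plate)
  if (nrow(over) > 0L) {
    abort("clonal_plan exceeds plate capacity",
          class = "tcrclonal_config_error")
  }
  invisible(plan)
}

# Expand the plan into one row per planted isolate, distributing isolates
# round-robin across the clone's tetramer categories.
allocate_plan <- function(plan) {
  if (is.null(plan) || nrow(plan) == 0L) {
    return(tibble(clone_id = character(), donor = character(),
                  tetramer = character()))
  }
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    tets <- row$tetramers[[1L]]
    tibble(
      clone_id = row$clone_id, donor = row$donor,
      tetramer = rep_len(tets, row$n_isolates)
    )
  })
}

mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    pos <- sample.int(lens[[i]], n_err[[i]])
    for (p in pos) {
      chars[[p]] <- sample(setdiff(bases, chars[[p]]), 1L)
    }
    seqs[[i]] <- paste(chars, collapse = "")
  }
  seqs
}

draw_depths <- function(n, mean, sd, floor_at = 0L) {
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    d <- rnbinom(n, size = size, mu = mean)
  } else {
    d <- rpois(n, mean)
  }
  pmax(d, floor_at)
}

random_background_cell <- function(reference, p_alt_alpha) {
  pick <- function(cls, ch) {
    nm <- reference$name[reference$segment_class == cls & reference$chain == ch]
    nm[[sample.int(length(nm), 1L)]]
  }
  rand_cdr3 <- function(v, j) {
    jrow <- reference[reference$name == j, ]
    j_trim <- sample.int(min(3L, jrow$anchor), 1L)
    allele <- NULL
    if (!is.na(jrow$snp_position)) {
      allele <- sample(names(jrow$snp_alleles[[1L]]), 1L)
    }
    list(
      nt = recombine_cdr3(reference, v, j,
                          insert_nt = random_codons(sample(2:6, 1L)),
                          j_trim = j_trim, allele = allele),
      allele = allele %||% NA_character_
    )
  }
  bv <- pick("V", "beta"); bj <- pick("J", "beta")
  av <- pick("V", "alpha"); aj <- pick("J", "alpha")
  b <- rand_cdr3(bv, bj); a <- rand_cdr3(av, aj)
  alt <- NULL
  if (runif(1) < p_alt_alpha) {
    av2 <- pick("V", "alpha"); aj2 <- pick("J", "alpha")
    alt <- c(list(trav = av2, traj = aj2), rand_cdr3(av2, aj2))
  }
  list(trbv = bv, trbj = bj, cdr3b_nt = b$nt,
       trav = av, traj = aj, cdr3a_nt = a$nt, allele = a$allele,
       alt = alt)
}

#' Simulate a full synthetic cohort
#'
#' Generates plates, wells, barcoded amplicon reads, the index-sort table,
#' donor metadata and a complete ground truth for a configured cohort. Each
#' read is the concatenation of its well's 8-nt plate, row and column
#' barcodes and a V(D)J (or phenotype-marker) amplicon with per-base
#' substitution errors. Output is deterministic for a fixed config seed.
#'
#' @param config A `tcr_sim_config` from [simulation_config()].
#' @return A list of class `tcr_cohort`:
#'   \describe{
#'     \item{reads}{tibble `read_id`, `well_id` (truth; ignored by the
#'       pipeline), `sequence`.}
#'     \item{barcode_map}{tibble `well_id`, `plate_id`, `plate_bc`,
#'       `row_bc`, `col_bc`.}
#'     \item{metadata}{tibble `donor`, `status`, `tiv_vaccinated`,
#'       `tetramer`, `plate_id`.}
#'     \item{index}{tibble `well_id`, `fi_tetramer`, `fsc`; plus
#'       `index_negative`: per-plate tetramer-negative population summary
#'       (`neg_mfi`, `neg_mean_fsc`).}
#'     \item{truth}{list with `wells` (per-well clonotype identity and
#'       chain truth), `phenotypes` (long well x marker bits) and
#'       `clonotypes` (per planted clone isolate tallies).}
#'     \item{reference, phenotype_ref, config}{inputs carried through.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tcr_sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ref <- config$reference
  phen <- config$phenotype_ref
  im <- config$index_model

  plates <- tidyr::expand_grid(
    donor = config$donors, tetramer = config$tetramer_categories
  ) |>
    mutate(
      plate_id = sprintf("PL%03d", row_number()),
      status = if_else(startsWith(donor, "P"), "case", "control"),
      tiv_vaccinated = donor %in% config$tiv_donors
    )

  # barcodes: per-plate, per-row, per-column; unique within each family
  uniq_bc <- function(n, width = 8L) {
    out <- character(0)
    while (length(out) < n) {
      out <- unique(c(out, vapply(seq_len(n), function(i) random_dna(width),
                                  character(1))))
    }
    out[seq_len(n)]
  }
  plate_bcs <- uniq_bc(nrow(plates))
  row_bcs <- uniq_bc(8L)
  col_bcs <- uniq_bc(12L)

  wells_tpl <- tidyr::expand_grid(row = LETTERS[1:8], col = 1:12) |>
    mutate(pos = paste0(row, sprintf("%02d", col))) |>
    head(config$wells_per_plate)

  barcode_map <- plates |>
    select(plate_id) |>
    mutate(plate_bc = plate_bcs) |>
    tidyr::expand_grid(wells_tpl) |>
    mutate(
      well_id = paste0(plate_id, "-", pos),
      row_bc = row_bcs[match(row, LETTERS)],
      col_bc = col_bcs[col]
    ) |>
    select(well_id, plate_id, plate_bc, row_bc, col_bc)

  alloc <- allocate_plan(config$clonal_plan)
  plan <- config$clonal_plan
  emission <- config$phenotype_emission
  markers <- phen$marker

  truth_rows <- list()
  pheno_rows <- list()
  read_chunks <- list()
  index_rows <- list()

  for (pi in seq_len(nrow(plates))) {
    pl <- plates[pi, ]
    pw <- barcode_map |> filter(plate_id == pl$plate_id)
    n_wells <- nrow(pw)
    planted_here <- alloc |>
      filter(donor == pl$donor, tetramer == pl$tetramer)
    n_planted <- nrow(planted_here)

    # planted isolates occupy the first wells; remaining wells are empty
    # with p_well_empty, otherwise hold a background singleton cell
    slot <- rep("background", n_wells)
    if (n_planted > 0L) slot[seq_len(n_planted)] <- planted_here$clone_id
    rest <- which(slot == "background")
    empty <- rest[runif(length(rest)) < config$p_well_empty]
    slot[empty] <- NA_character_

    for (wi in seq_len(n_wells)) {
      wid <- pw$well_id[[wi]]
      occupied <- !is.na(slot[[wi]])
      expanded_truth <- FALSE
      cell <- NULL
      clone_id <- NA_character_
      b_drop <- FALSE; a_drop <- FALSE
      if (occupied) {
        if (slot[[wi]] != "background") {
          clone_id <- slot[[wi]]
          pr <- plan[plan$clone_id == clone_id, ]
          cell <- list(trbv = pr$trbv, trbj = pr$trbj, cdr3b_nt = pr$cdr3b_nt,
                       trav = pr$trav, traj = pr$traj, cdr3a_nt = pr$cdr3a_nt,
                       allele = pr$allele, alt = NULL)
          expanded_truth <- pr$n_isolates > 1L
        } else {
          clone_id <- paste0("bg-", wid)
          cell <- random_background_cell(ref, config$p_alt_alpha)
          b_drop <- runif(1) < config$p_beta_dropout
          a_drop <- runif(1) < config$p_alpha_dropout
        }
      }

      # phenotype bits
      if (occupied) {
        p <- if (expanded_truth) emission$p_expanded else emission$p_unexpanded
        bits <- as.integer(runif(length(markers)) < p)
      } else {
        bits <- integer(length(markers))
      }
      pheno_rows[[wid]] <- tibble(well_id = wid, marker = markers, bit = bits)

      # index values
      fsc <- max(rnorm(1, im$fsc_mean, im$fsc_sd), im$fsc_mean / 10)
      fi <- if (occupied) rlnorm(1, im$fi_meanlog, im$fi_sdlog) else
        abs(rnorm(1, im$background_mfi, im$background_mfi / 4))
      index_rows[[wid]] <- tibble(well_id = wid, fi_tetramer = fi, fsc = fsc)

      # reads
      depth <- 0L
      if (occupied) {
        depth <- draw_depths(1L, config$reads_per_well_mean,
                             config$reads_per_well_sd,
                             floor_at = config$min_reads_occupied)
        amplicons <- character(0)
        weights <- numeric(0)
        if (!b_drop) {
          amplicons <- c(amplicons, build_amplicon(ref, cell$trbv, cell$trbj,
                                                   cell$cdr3b_nt))
          weights <- c(weights, config$frac_beta)
        }
        if (!a_drop) {
          a_amp <- build_amplicon(ref, cell$trav, cell$traj, cell$cdr3a_nt)
          if (!is.null(cell$alt)) {
            amplicons <- c(amplicons, a_amp,
                           build_amplicon(ref, cell$alt$trav, cell$alt$traj,
                                          cell$alt$nt))
            weights <- c(weights,
                         config$frac_alpha * (1 - config$alt_alpha_frac),
                         config$frac_alpha * config$alt_alpha_frac)
          } else {
            amplicons <- c(amplicons, a_amp)
            weights <- c(weights, config$frac_alpha)
          }
        }
        pos_markers <- markers[bits == 1L]
        if (length(pos_markers) > 0L) {
          amplicons <- c(amplicons,
                         phen$nt_sequence[match(pos_markers, phen$marker)])
          weights <- c(weights,
                       rep((1 - config$frac_beta - config$frac_alpha) /
                             length(pos_markers), length(pos_markers)))
        }
        if (length(amplicons) == 0L) {
          # both chains dropped and no positive marker: the well yields
          # nothing (counts as uncovered)
          depth <- 0L
        } else {
        weights <- weights / sum(weights)
        # every amplicon present in the well gets at least one read so that
        # phenotype bits and planted chains survive small depths
        counts <- as.vector(stats::rmultinom(1L, size = depth, prob = weights))
        short <- which(counts == 0L)
        counts[short] <- 1L
        depth <- sum(counts)
        seqs <- rep(amplicons, counts)
        seqs <- mutate_sequences(seqs, config$per_base_error_rate)
        bc <- paste0(pw$plate_bc[[wi]], pw$row_bc[[wi]], pw$col_bc[[wi]])
        read_chunks[[wid]] <- tibble(
          well_id = wid, sequence = paste0(bc, seqs)
        )
        }
      }

      truth_rows[[wid]] <- tibble(
        well_id = wid, plate_id = pl$plate_id, donor = pl$donor,
        status = pl$status, tetramer = pl$tetramer,
        occupied = occupied, clone_id = clone_id,
        expanded = expanded_truth,
        trbv = cell$trbv %||% NA_character_,
        trbj = cell$trbj %||% NA_character_,
        cdr3b_nt = cell$cdr3b_nt %||% NA_character_,
        trav = cell$trav %||% NA_character_,
        traj = cell$traj %||% NA_character_,
        cdr3a_nt = cell$cdr3a_nt %||% NA_character_,
        allele = if (is.null(cell)) NA_character_ else cell$allele,
        alt_trav = if (is.null(cell$alt)) NA_character_ else cell$alt$trav,
        alt_traj = if (is.null(cell$alt)) NA_character_ else cell$alt$traj,
        alt_cdr3a_nt = if (is.null(cell$alt)) NA_character_ else cell$alt$nt,
        beta_dropout = b_drop, alpha_dropout = a_drop,
        depth = depth, fi_tetramer = fi, fsc = fsc
      )
    }
  }

  truth_wells <- bind_rows(truth_rows) |>
    mutate(
      cdr3b_aa = vapply(cdr3b_nt, function(x)
        if (is.na(x)) NA_character_ else translate_nt(x), character(1),
        USE.NAMES = FALSE),
      cdr3a_aa = vapply(cdr3a_nt, function(x)
        if (is.na(x)) NA_character_ else translate_nt(x), character(1),
        USE.NAMES = FALSE)
    )
  truth_clonotypes <- truth_wells |>
    filter(occupied, !startsWith(clone_id, "bg-")) |>
    count(clone_id, donor, name = "n_isolates")

  reads <- bind_rows(read_chunks)
  reads <- if (nrow(reads) > 0L) {
    reads |> mutate(read_id = sprintf("read%07d", row_number())) |>
      select(read_id, well_id, sequence)
  } else {
    tibble(read_id = character(), well_id = character(),
           sequence = character())
  }

  index_negative <- plates |>
    select(plate_id) |>
    mutate(
      neg_mfi = im$background_mfi * exp(rnorm(n(), 0, 0.05)),
      neg_mean_fsc = im$background_mean_fsc * exp(rnorm(n(), 0, 0.02))
    )

  structure(list(
    reads = reads,
    barcode_map = barcode_map,
    metadata = plates |> select(donor, status, tiv_vaccinated, tetramer,
                                plate_id),
    index = bind_rows(index_rows),
    index_negative = index_negative,
    truth = list(wells = truth_wells,
                 phenotypes = bind_rows(pheno_rows),
                 clonotypes = truth_clonotypes),
    reference = ref, phenotype_ref = phen, config = config
  ), class = "tcr_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `reads.fastq` (constant high base qualities), `barcode_map.tsv`,
#' `metadata.tsv`, `index.csv`, `index_negative.csv`, `truth_wells.tsv`,
#' `truth_phenotypes.tsv`, the germline reference (`reference.fasta` +
#' `reference.tsv`) and the phenotype panel (`phenotype_panel.fasta`).
#'
#' @param cohort A `tcr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "reads.fastq")
  rd <- cohort$reads
  lines <- character(4L * nrow(rd))
  lines[seq(1, length(lines), 4)] <- paste0("@", rd$read_id)
  lines[seq(2, length(lines), 4)] <- rd$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep("I", nchar(rd$sequence))
  writeLines(lines, fq)
  utils::write.table(cohort$barcode_map, file.path(dir, "barcode_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$index, file.path(dir, "index.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$index_negative, file.path(dir, "index_negative.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$truth$wells, file.path(dir, "truth_wells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth$phenotypes,
                     file.path(dir, "truth_phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ref <- cohort$reference
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ref$nt_sequence, ref$name)),
    file.path(dir, "reference.fasta"))
  utils::write.table(
    ref |> select(name, segment_class, chain, anchor, snp_position),
    file.path(dir, "reference.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(cohort$phenotype_ref$nt_sequence,
                                      cohort$phenotype_ref$marker)),
    file.path(dir, "phenotype_panel.fasta"))
  invisible(dir)
}

#' Read FASTQ reads into a tibble
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}
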