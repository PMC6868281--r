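#' Build donor-level clonotypes
#'
#' Partitions analyzed cells within each donor by identical V/J gene pairs
#' and identical alpha and beta CDR3s (amino-acid identity by default;
#' nucleotide identity via `by_nt = TRUE`). Isolates are counted across
#' all tetramer categories of the donor; a clonotype is `expanded` with
#' two or more isolates and `highly_expanded` with five or more, and
#' `cross_binding` when its isolates were sorted under more than one
#' tetramer. `public_partners` lists other donors carrying the identical
#' paired clonotype. A cell matches a clonotype on its dominant alpha
#' only; alternative alpha chains are carried on the cell but do not enter
#' clonotype identity.
#'
#' @param cells Analyzed cell tibble (see [analyzed_cells()]).
#' @param by_nt Use nucleotide CDR3 identity instead of amino acid.
#' @return A tibble, one row per clonotype: `clonotype_id`, `donor`,
#'   `trbv`, `trbj`, `cdr3b`, `trav`, `traj`, `cdr3a`, `n_isolates`,
#'   `expanded`, `highly_expanded`, `cross_binding`, `tetramers`
#'   (list-column), `allele_call`, `public_partners` (list-column),
#'   `wells` (list-column of member well ids).
#' @export
build_clonotypes <- function(cells, by_nt = FALSE) {
  stopifnot(nrow(cells) > 0L)
  cdr3b <- if (by_nt) cells$cdr3b_nt else cells$cdr3b_aa
  cdr3a <- if (by_nt) cells$cdr3a_nt else cells$cdr3a_aa
  keyed <- cells |>
    mutate(cdr3b = cdr3b, cdr3a = cdr3a,
           clone_key = paste(trbv, trbj, cdr3b, trav, traj, cdr3a,
                             sep = "|"))
  clones <- keyed |>
    group_by(donor, clone_key, trbv, trbj, cdr3b, trav, traj, cdr3a) |>
    summarise(
      n_isolates = n(),
      tetramers = list(sort(unique(tetramer))),
      allele_call = {
        al <- allele_call[!is.na(allele_call)]
        if (length(al)) names(sort(table(al), decreasing = TRUE))[1]
        else NA_character_
      },
      wells = list(well_id),
      .groups = "drop"
    ) |>
    mutate(
      expanded = n_isolates >= 2L,
      highly_expanded = n_isolates >= 5L,
      cross_binding = purrr::map_int(tetramers, length) > 1L
    )
  partners <- clones |>
    group_by(clone_key) |>
    summarise(all_donors = list(unique(donor)), .groups = "drop")
  clones <- clones |>
    left_join(partners, by = "clone_key") |>
    mutate(public_partners = purrr::map2(all_donors, donor, setdiff)) |>
    select(-all_donors) |>
    arrange(desc(n_isolates), donor, clone_key) |>
    mutate(clonotype_id = sprintf("CT%04d", row_number())) |>
    select(clonotype_id, donor, trbv, trbj, cdr3b, trav, traj, cdr3a,
           n_isolates, expanded, highly_expanded, cross_binding,
           tetramers, allele_call, public_partners, wells, clone_key)
  clones
}

#' Flag each cell with its clonotype's expansion status
#'
#' @param cells Analyzed cell tibble.
#' @param clonotypes Output of [build_clonotypes()] on the same cells.
#' @return `cells` with `clonotype_id` and logical `expanded` columns.
#' @export
label_expansion <- function(cells, clonotypes) {
  membership <- clonotypes |>
    select(clonotype_id, expanded, wells) |>
    tidyr::unnest(wells) |>
    rename(well_id = wells)
  cells |> left_join(membership, by = "well_id")
}

#' Expanded-cell contingency tables per tetramer category
#'
#' For each tetramer category (and the pooled "All" row) counts expanded
#' and total analyzed cells per group (case vs control by default), the
#' input for chi-squared skewing tests. Optional donor exclusion supports
#' e.g. dropping recently influenza-vaccinated subjects.
#'
#' @param cells Cell tibble labelled by [label_expansion()].
#' @param group Column name holding the two group labels (default
#'   `"status"`).
#' @param exclude_donors Donor ids to drop before tabulating.
#' @param include_all Add the pooled "All" row.
#' @return A tibble: `tetramer`, then per group `<g>_expanded`,
#'   `<g>_total`, `<g>_pct` (percent, half-away-from-zero at 2 decimals).
#' @export
expansion_contingency <- function(cells, group = "status",
                                  exclude_donors = NULL,
                                  include_all = TRUE) {
  dat <- cells
  if (!is.null(exclude_donors)) dat <- dat |> filter(!donor %in% exclude_donors)
  if (nrow(dat) == 0L) {
    abort("no cells left to tabulate", class = "tcrclonal_data_error")
  }
  groups <- sort(unique(dat[[group]]))
  if (length(groups) != 2L) {
    abort("expansion_contingency needs exactly two groups",
          class = "tcrclonal_data_error")
  }
  tab_one <- function(d, label) {
    row <- tibble(tetramer = label)
    for (g in groups) {
      sub <- d[d[[group]] == g, ]
      e <- sum(sub$expanded, na.rm = TRUE)
      t <- nrow(sub)
      row[[paste0(g, "_expanded")]] <- e
      row[[paste0(g, "_total")]] <- t
      row[[paste0(g, "_pct")]] <-
        if (t > 0) round_half_up(100 * e / t, 2) else NA_real_
    }
    row
  }
  out <- dat |>
    group_by(tetramer) |>
    group_map(~ tab_one(.x, .y$tetramer), .keep = TRUE) |>
    bind_rows()
  if (include_all) out <- bind_rows(tab_one(dat, "All"), out)
  out
}

#' Group clonotypes sharing identical paired TRBJ/TRAJ genes
#'
#' Restricted to clonotypes observed more than once in the dataset
#' (expanded within a donor or public across donors), groups them by the
#' paired (TRBJ, TRAJ) key and reports only groups spanning at least two
#' subjects, labelled I, II, ... in decreasing group size.
#'
#' @param clonotypes Output of [build_clonotypes()].
#' @return A tibble: `group`, `trbj`, `traj`, `n_subjects`,
#'   `n_clonotypes`, `clonotypes` (nested member rows).
#' @export
jgene_sharing_groups <- function(clonotypes) {
  multi <- clonotypes |>
    filter(expanded | purrr::map_int(public_partners, length) > 0L)
  if (nrow(multi) == 0L) {
    return(tibble(group = character(), trbj = character(),
                  traj = character(), n_subjects = integer(),
                  n_clonotypes = integer(), clonotypes = list()))
  }
  grouped <- multi |>
    group_by(trbj, traj) |>
    summarise(n_subjects = n_distinct(donor), n_clonotypes = n(),
              clonotypes = list(pick(dplyr::everything())),
              .groups = "drop") |>
    filter(n_subjects >= 2L) |>
    arrange(desc(n_clonotypes), trbj, traj)
  grouped |>
    mutate(group = vapply(row_number(), as_roman_label, character(1))) |>
    select(group, trbj, traj, n_subjects, n_clonotypes, clonotypes)
}

#' Clonotype-by-subject isolate matrix for a J-sharing group set
#'
#' @param groups Output of [jgene_sharing_groups()].
#' @return A tibble, one row per (group, clonotype, donor) with
#'   `n_isolates` and the clonotype's tetramer labels collapsed with ";".
#' @export
jgene_sharing_matrix <- function(groups) {
  if (nrow(groups) == 0L) {
    return(tibble(group = character(), clonotype_id = character(),
                  donor = character(), n_isolates = integer(),
                  tetramers = character()))
  }
  groups |>
    select(group, clonotypes) |>
    tidyr::unnest(clonotypes) |>
    mutate(tetramers = purrr::map_chr(tetramers, paste, collapse = ";")) |>
    select(group, clonotype_id, donor, n_isolates, tetramers)
}

#' Gene-usage frequencies and fold enrichment
#'
#' Per-gene usage frequencies in a subset of cells against a universe of
#' cells, for each of the four segment classes (TRBV/TRBJ/TRAV/TRAJ), with
#' fold enrichment = subset frequency / universe frequency. Genes absent
#' from the universe get an undefined (`NA`) fold.
#'
#' @param subset_cells,universe_cells Cell tibbles with `trbv`, `trbj`,
#'   `trav`, `traj` columns.
#' @return A tibble: `segment_class`, `gene`, `n_subset`, `freq_subset`,
#'   `n_universe`, `freq_universe`, `fold`.
#' @export
gene_usage_enrichment <- function(subset_cells, universe_cells) {
  if (nrow(subset_cells) == 0L) {
    abort("empty subset", class = "tcrclonal_data_error")
  }
  one_class <- function(col) {
    s <- table(subset_cells[[col]])
    u <- table(universe_cells[[col]])
    genes <- sort(union(names(s), names(u)))
    ns <- as.integer(s[genes]); ns[is.na(ns)] <- 0L
    nu <- as.integer(u[genes]); nu[is.na(nu)] <- 0L
    fs <- ns / nrow(subset_cells)
    fu <- nu / nrow(universe_cells)
    tibble(segment_class = toupper(col), gene = genes,
           n_subset = ns, freq_subset = fs,
           n_universe = nu, freq_universe = fu,
           fold = if_else(nu > 0L, fs / fu, NA_real_))
  }
  bind_rows(lapply(c("trbv", "trbj", "trav", "traj"), one_class))
}

#' Cross-binding summary over expanded clonotypes
#'
#' @param clonotypes Output of [build_clonotypes()].
#' @return One-row tibble: `n_expanded`, `n_cross_binding`,
#'   `cross_binding_pct` (one decimal, half away from zero).
#' @export
cross_binding_fraction <- function(clonotypes) {
  exp_ct <- clonotypes |> filter(expanded)
  n <- nrow(exp_ct)
  k <- sum(exp_ct$cross_binding)
  tibble(n_expanded = n, n_cross_binding = k,
         cross_binding_pct = if (n > 0) round_half_up(100 * k / n, 1)
                             else NA_real_)
}

#' Near-identical clonotype pairs for manual review
#'
#' Optional "relaxed" report: clonotype pairs from the same donor whose
#' alpha and beta CDR3s are each within Hamming distance 1 (equal
#' lengths). Mirrors the single documented near-merge exception in the
#' expanded-TRAJ24L phenotype cluster; no automatic merging is performed.
#'
#' @param clonotypes Output of [build_clonotypes()].
#' @return Tibble of candidate pairs with both clonotype ids and the two
#'   distances.
#' @export
relaxed_clonotype_pairs <- function(clonotypes) {
  hamming1 <- function(x, y) {
    if (nchar(x) != nchar(y)) return(NA_integer_)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  out <- list()
  by_donor <- split(clonotypes, clonotypes$donor)
  for (d in by_donor) {
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      for (k in seq((i + 1L), nrow(d))) {
        db <- hamming1(d$cdr3b[[i]], d$cdr3b[[k]])
        da <- hamming1(d$cdr3a[[i]], d$cdr3a[[k]])
        if (!is.na(db) && !is.na(da) && db <= 1L && da <= 1L &&
            (db + da) > 0L) {
          out[[length(out) + 1L]] <- tibble(
            donor = d$donor[[i]],
            clonotype_1 = d$clonotype_id[[i]],
            clonotype_2 = d$clonotype_id[[k]],
            dist_cdr3b = db, dist_cdr3a = da
          )
        }
      }
    }
  }
  bind_rows(out)
}
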