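#' Run the full analysis pipeline on a cohort
#'
#' Chains the stages on a simulated (or equivalently structured) cohort:
#' demultiplexing, per-well consensus calling, V(D)J annotation and CDR3
#' extraction, clonotype construction with expansion labelling, the
#' expanded-cell contingency tables with chi-squared skewing tests under
#' two-stage FDR adjustment, J-gene sharing groups, gene-usage enrichment
#' of multi-isolate clonotypes and tetramer-rank summaries; optionally the
#' GLIPH-style motif analysis for both chains. Every stage appends an
#' in/out row-count record to the log.
#'
#' @param cohort A `tcr_cohort` (see [simulate_cohort()]).
#' @param min_identity Consensus clustering identity threshold.
#' @param beta_min,alpha_min,alt_alpha_min Well-call confidence
#'   thresholds.
#' @param Q Desired FDR for the skewing-test stack.
#' @param motifs Run the motif analysis (slower; default `FALSE`).
#' @param exclude_tiv Also compute the contingency row excluding
#'   TIV-vaccinated donors for the last tetramer category.
#' @param seed Seed for motif reference generation/subsampling.
#' @return An object of class `tcr_pipeline`: list with `well_calls`,
#'   `coverage`, `cells`, `analyzed`, `clonotypes`, `contingency`,
#'   `skew_tests`, `fdr`, `jgroups`, `gene_usage`, `rank_summary`,
#'   `motifs` (or `NULL`), `cross_binding`, `log` and the input `cohort`.
#' @export
run_pipeline <- function(cohort, min_identity = 0.95, beta_min = 0.80,
                         alpha_min = 0.30, alt_alpha_min = 0.10,
                         Q = 0.05, motifs = FALSE, exclude_tiv = TRUE,
                         seed = 1) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in,
                                       n_out = n_out, detail = detail)
  }

  demuxed <- demultiplex(cohort$reads, cohort$barcode_map)
  note("demultiplex", nrow(cohort$reads), sum(!is.na(demuxed$well_id)),
       paste0("unassigned=", sum(is.na(demuxed$well_id))))

  well_calls <- call_wells(demuxed, cohort$barcode_map, cohort$reference,
                           cohort$phenotype_ref, min_identity, beta_min,
                           alpha_min, alt_alpha_min)
  cov <- well_coverage(well_calls)
  note("call_wells", n_distinct(demuxed$well_id, na.rm = TRUE),
       nrow(well_calls),
       paste0("coverage=", cov$coverage_pct, "%"))

  cells <- annotate_cells(well_calls, cohort$reference, cohort$metadata,
                          cohort$index)
  analyzed <- analyzed_cells(cells)
  note("annotate", nrow(well_calls), nrow(analyzed),
       "paired productive cells")

  clonotypes <- build_clonotypes(analyzed)
  labelled <- label_expansion(analyzed, clonotypes)
  note("clonotypes", nrow(analyzed), nrow(clonotypes),
       paste0("expanded=", sum(clonotypes$expanded)))

  contingency <- expansion_contingency(labelled)
  if (exclude_tiv && any(cohort$metadata$tiv_vaccinated)) {
    last_tet <- utils::tail(cohort$config$tetramer_categories, 1L)
    tiv <- unique(cohort$metadata$donor[cohort$metadata$tiv_vaccinated])
    excl <- labelled |> filter(tetramer == last_tet)
    if (nrow(excl) > 0L && length(setdiff(unique(excl$donor), tiv)) > 1L) {
      row <- expansion_contingency(excl, exclude_donors = tiv,
                                   include_all = FALSE)
      row$tetramer <- paste0(last_tet, " (excl. TIV)")
      contingency <- bind_rows(contingency, row)
    }
  }
  skew <- expansion_skew_tests(contingency, Q = Q)
  note("skew_tests", nrow(contingency), nrow(skew$tests),
       paste0("discoveries=", sum(skew$fdr$discoveries)))

  jgroups <- jgene_sharing_groups(clonotypes)
  multi_wells <- clonotypes |>
    filter(expanded | purrr::map_int(public_partners, length) > 0L) |>
    pull(wells) |> unlist()
  usage <- if (length(multi_wells) > 0L) {
    gene_usage_enrichment(analyzed |> filter(well_id %in% multi_wells),
                          analyzed)
  } else NULL
  ranks <- tetramer_rank_summary(analyzed, cohort$index_negative)

  motif_res <- NULL
  if (motifs) {
    motif_res <- bind_rows(
      gliph_analysis(labelled, "beta", germline = cohort$reference,
                     seed = seed),
      gliph_analysis(labelled, "alpha", germline = cohort$reference,
                     seed = seed + 1L)
    )
    note("motifs", nrow(labelled), nrow(motif_res),
         paste0("significant=", sum(motif_res$significant)))
  }

  structure(list(
    well_calls = well_calls, coverage = cov, cells = cells,
    analyzed = labelled, clonotypes = clonotypes,
    contingency = contingency, skew_tests = skew$tests, fdr = skew$fdr,
    jgroups = jgroups, gene_usage = usage, rank_summary = ranks,
    motifs = motif_res, cross_binding = cross_binding_fraction(clonotypes),
    log = bind_rows(log), cohort = cohort
  ), class = "tcr_pipeline")
}

#' Chi-squared skewing tests with FDR adjustment on a contingency table
#'
#' Runs [chi_squared_skew()] on every row of an [expansion_contingency()]
#' table and adjusts the p-value stack with [bky_two_stage()].
#'
#' @param contingency Output of [expansion_contingency()] (two groups).
#' @param Q Desired FDR.
#' @return List with `tests` (tibble: `tetramer`, counts, `statistic`,
#'   `p_value`, `q_value`, `discovery`) and `fdr` (the `tcr_bky` object).
#' @export
expansion_skew_tests <- function(contingency, Q = 0.05) {
  cols <- names(contingency)
  gexp <- grep("_expanded$", cols, value = TRUE)
  gtot <- grep("_total$", cols, value = TRUE)
  stopifnot(length(gexp) == 2L, length(gtot) == 2L)
  tests <- purrr::map_dfr(seq_len(nrow(contingency)), function(i) {
    r <- contingency[i, ]
    st <- chi_squared_skew(r[[gexp[1]]], r[[gtot[1]]],
                           r[[gexp[2]]], r[[gtot[2]]])
    bind_cols(r |> select(tetramer, dplyr::all_of(c(gexp, gtot))), st)
  })
  fdr <- bky_two_stage(tests$p_value, Q = Q)
  tests$q_value <- fdr$q_values
  tests$discovery <- fdr$discoveries
  list(tests = tests, fdr = fdr)
}

#' @export
print.tcr_pipeline <- function(x, ...) {
  cat("tcrclonal pipeline result\n")
  cat("  wells:", x$coverage$n_wells,
      sprintf("(TCR coverage %.1f%%)", x$coverage$coverage_pct), "\n")
  cat("  analyzed paired cells:", nrow(x$analyzed), "\n")
  cat("  clonotypes:", nrow(x$clonotypes),
      sprintf("(expanded %d, cross-binding %d)",
              sum(x$clonotypes$expanded),
              sum(x$clonotypes$cross_binding)), "\n")
  cat("  skewing discoveries:", sum(x$skew_tests$discovery), "of",
      nrow(x$skew_tests), "\n")
  invisible(x)
}

#' Summary tables for a pipeline result
#'
#' Emits the standard report tables: per donor-tetramer cell accounting,
#' the contingency/FDR table, the J-sharing clonotype-by-subject matrix,
#' gene-usage folds, the motif scatter table (when motifs were run), rank
#' summaries and per-marker expanded-vs-unexpanded phenotype frequencies.
#'
#' @param pipeline A `tcr_pipeline`.
#' @return Named list of tibbles.
#' @export
report_tables <- function(pipeline) {
  p <- pipeline
  cells_per_donor <- p$analyzed |>
    group_by(donor, status, tetramer) |>
    summarise(n_cells = n(), .groups = "drop") |>
    left_join(
      p$clonotypes |> filter(expanded) |>
        tidyr::unnest(tetramers) |>
        group_by(donor, tetramer = tetramers) |>
        summarise(n_expanded_clonotypes = n(), .groups = "drop"),
      by = c("donor", "tetramer")
    ) |>
    mutate(n_expanded_clonotypes =
             tidyr::replace_na(n_expanded_clonotypes, 0L))

  markers <- intersect(phenotype_panel()$marker, names(p$analyzed))
  pheno_freq <- NULL
  if (length(markers) > 0L && any(p$analyzed$expanded) &&
      any(!p$analyzed$expanded)) {
    pheno_freq <- phenotype_skew_report(
      p$analyzed |> filter(expanded),
      p$analyzed |> filter(!expanded),
      markers
    )
  }

  list(
    cells_per_donor = cells_per_donor,
    contingency = p$skew_tests,
    jgene_matrix = jgene_sharing_matrix(p$jgroups),
    gene_usage = p$gene_usage,
    motif_scatter = if (!is.null(p$motifs)) {
      p$motifs |> select(chain, motif, kind, size, dominant_v,
                         vgene_enrichment_p, expansion_enrichment_p,
                         final_score, significant)
    } else NULL,
    rank_summary = p$rank_summary,
    phenotype_frequencies = pheno_freq
  )
}

#' Write all report tables to CSV
#'
#' @param pipeline A `tcr_pipeline`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(pipeline)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    utils::write.csv(tabs[[nm]] |>
                       mutate(across(dplyr::where(is.list),
                                     ~ purrr::map_chr(.x, paste, collapse = ";"))),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(pipeline$log, file.path(dir, "pipeline_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Packaged example contingency counts
#'
#' Small plain-text count tables for a hypocretin (HCRT) tetramer-sorted
#' CD4+ T-cell case/control repertoire cohort, packaged so the statistics
#' layer can be exercised independently of simulation: the per-tetramer
#' expanded-cell contingency table, phenotype-marker counts for the
#' expanded TRAJ24-L vs TRAJ24-F cell clusters, phenotype counts for
#' expanded vs unexpanded cells, and the well/cross-binding accounting
#' totals.
#'
#' @param name One of `"expansion_contingency"`, `"phenotype_clusters"`,
#'   `"phenotype_expansion"`, `"accounting"`.
#' @return A tibble.
#' @export
example_counts <- function(name = c("expansion_contingency",
                                    "phenotype_clusters",
                                    "phenotype_expansion",
                                    "accounting")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "tcrclonal", mustWork = TRUE)
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
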