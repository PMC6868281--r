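#' Demultiplex barcoded reads to wells
#'
#' Splits the leading 24 nt of each read into its 8-nt plate, row and
#' column barcodes and assigns the read to the well whose barcode triplet
#' matches exactly. Reads whose triplet matches no well are kept with
#' `well_id = NA` (the "unassigned" bin); read counts are conserved.
#'
#' @param reads Tibble with columns `read_id` and `sequence` (barcodes
#'   prepended, as written by [simulate_cohort()]).
#' @param barcode_map Tibble with columns `well_id`, `plate_bc`, `row_bc`,
#'   `col_bc`; triplets must be unique per well.
#' @param barcode_width Width of each barcode (default 8).
#' @return The reads tibble with `well_id` (or `NA`) and `sequence`
#'   replaced by the barcode-stripped amplicon.
#' @export
demultiplex <- function(reads, barcode_map, barcode_width = 8L) {
  key <- paste0(barcode_map$plate_bc, barcode_map$row_bc, barcode_map$col_bc)
  if (anyDuplicated(key)) {
    abort("barcode_map contains duplicate plate/row/column triplets",
          class = "tcrclonal_config_error")
  }
  w <- 3L * barcode_width
  triplet <- substr(reads$sequence, 1L, w)
  tibble(
    read_id = reads$read_id,
    well_id = barcode_map$well_id[match(triplet, key)],
    sequence = substr(reads$sequence, w + 1L, nchar(reads$sequence))
  )
}

# Global pairwise identity = matches / alignment columns, computed for a
# set of sequences against one subject. Linear gap penalty. Equal-length
# pairs take the Hamming fast path: with this scoring (gap -5 > mismatch
# -3) the optimal global alignment of substitution-divergent equal-length
# sequences is the diagonal, so matches/columns equals 1 - hamming/length.
pairwise_identity <- function(seqs, subject) {
  out <- numeric(length(seqs))
  len_s <- nchar(subject)
  eq <- which(nchar(seqs) == len_s)
  if (length(eq) > 0L) {
    sub_raw <- charToRaw(subject)
    out[eq] <- vapply(seqs[eq], function(x)
      1 - sum(charToRaw(x) != sub_raw) / len_s, numeric(1))
  }
  ne <- setdiff(seq_along(seqs), eq)
  if (length(ne) > 0L) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[ne]), subject, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 0, gapExtension = 5
    )
    out[ne] <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  }
  out
}

#' Cluster a well's reads at a minimum identity
#'
#' Greedy abundance-sorted centroid clustering: the most abundant unique
#' sequence (ties broken lexicographically) founds a cluster and sweeps in
#' every remaining sequence within `min_identity` global alignment
#' identity (matches / alignment columns) of it; the procedure repeats on
#' the remainder until all reads are assigned.
#'
#' @param sequences Character vector of amplicon sequences (one well's
#'   reads, one chain of origin not assumed).
#' @param min_identity Identity threshold in (0, 1]; default 0.95.
#' @return A tibble with one row per cluster, ordered by decreasing size:
#'   `cluster_id`, `size`, `centroid`, `consensus` (per-column majority
#'   over members star-aligned to the centroid, ties to the centroid
#'   base), and `members` (list-column of member indices into
#'   `sequences`).
#' @export
cluster_well_reads <- function(sequences, min_identity = 0.95) {
  stopifnot(length(sequences) > 0L, min_identity > 0, min_identity <= 1)
  tab <- table(sequences)
  uni <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uni)
  uni <- uni[ord]; cnt <- cnt[ord]

  assign <- integer(length(uni))
  centroids <- character(0)
  remaining <- seq_along(uni)
  while (length(remaining) > 0L) {
    cen <- remaining[[1L]]
    ident <- if (length(remaining) == 1L) 1 else
      pairwise_identity(uni[remaining], uni[[cen]])
    hit <- remaining[ident >= min_identity]
    centroids <- c(centroids, uni[[cen]])
    assign[hit] <- length(centroids)
    remaining <- remaining[ident < min_identity]
  }

  member_idx <- match(sequences, uni)
  clusters <- purrr::map_dfr(seq_along(centroids), function(k) {
    mem_u <- which(assign == k)
    members <- which(assign[member_idx] == k)
    tibble(
      centroid = centroids[[k]],
      size = sum(cnt[mem_u]),
      consensus = consensus_sequence(uni[mem_u], centroids[[k]],
                                     weights = cnt[mem_u]),
      members = list(members)
    )
  }) |>
    arrange(desc(size), centroid) |>
    mutate(cluster_id = row_number()) |>
    select(cluster_id, size, centroid, consensus, members)
  clusters
}

# Column-majority consensus over a star alignment of members to the
# centroid; insertions relative to the centroid are dropped, deletions are
# skipped in the tally, ties resolve to the centroid base. `weights`
# allows unique member sequences with read counts.
consensus_sequence <- function(members, centroid, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, length(members))
  if (length(members) == 1L) return(members[[1L]])
  if (all(nchar(members) == nchar(centroid))) {
    mat <- matrix(unlist(strsplit(members, "", fixed = TRUE)),
                  nrow = length(members), byrow = TRUE)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(members), centroid, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 0, gapExtension = 5
    )
    mat <- as.matrix(Biostrings::aligned(pa))
  }
  cen <- strsplit(centroid, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  tall <- vapply(bases, function(b)
    colSums(weights * (mat == b)), numeric(ncol(mat)))
  tall <- matrix(tall, ncol = 4L)
  best <- max.col(tall, ties.method = "first")
  top <- tall[cbind(seq_len(nrow(tall)), best)]
  cen_score <- tall[cbind(seq_len(nrow(tall)), match(cen, bases))]
  out <- ifelse(top == 0L, cen,
                ifelse(cen_score == top, cen, bases[best]))
  paste(out, collapse = "")
}

# Local-alignment scores of many query sequences against a panel; one
# pairwiseAlignment call per panel entry (queries vectorized as patterns).
# Returns an n_query x n_panel score matrix.
panel_scores <- function(queries, panel_seqs) {
  sapply(panel_seqs, function(s) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(queries), s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 0, gapExtension = 5
    ))
  }) |> matrix(nrow = length(queries))
}

best_of <- function(scores, names) {
  # per-row best column, ties broken alphabetically by name
  ord <- order(names)
  scores <- scores[, ord, drop = FALSE]
  names <- names[ord]
  idx <- apply(scores, 1L, which.max)
  list(name = names[idx], score = scores[cbind(seq_len(nrow(scores)), idx)])
}

# Classify cluster consensus sequences as beta TCR, alpha TCR or phenotype
# marker by best local V-panel / marker-panel score; phenotype wins only
# when its best score beats the best TCR score. Vectorized over queries.
classify_clusters <- function(consensus, reference, phenotype_ref) {
  uniq <- unique(consensus)
  if (length(uniq) < length(consensus)) {
    u <- classify_clusters(uniq, reference, phenotype_ref)
    return(u[match(consensus, uniq), ])
  }
  vb <- reference |> filter(segment_class == "V", chain == "beta")
  va <- reference |> filter(segment_class == "V", chain == "alpha")
  hit_b <- best_of(panel_scores(consensus, vb$nt_sequence), vb$name)
  hit_a <- best_of(panel_scores(consensus, va$nt_sequence), va$name)
  hit_p <- best_of(panel_scores(consensus, phenotype_ref$nt_sequence),
                   phenotype_ref$marker)
  cls <- ifelse(hit_p$score > pmax(hit_b$score, hit_a$score), "phenotype",
                ifelse(hit_b$score >= hit_a$score, "beta", "alpha"))
  tibble(
    class = cls,
    label = ifelse(cls == "phenotype", hit_p$name,
                   ifelse(cls == "beta", hit_b$name, hit_a$name))
  )
}

#' Call one well from its read clusters
#'
#' Applies the per-well confidence rules to chain-classified clusters: the
#' top beta cluster is assigned as the consensus TCRbeta iff it holds
#' strictly more than `beta_min` (default 80%) of the well's beta-assigned
#' reads; the top alpha cluster iff strictly more than `alpha_min` (30%)
#' of alpha reads; a second alpha consensus iff it strictly exceeds
#' `alt_alpha_min` (10%). Confidences are the supporting read fractions
#' over chain-assigned reads. Phenotype read counts are totalled per
#' marker.
#'
#' @param clusters Output of [cluster_well_reads()].
#' @param reference Germline reference tibble.
#' @param phenotype_ref Phenotype marker panel.
#' @param beta_min,alpha_min,alt_alpha_min Strict lower thresholds on the
#'   supporting-read fractions.
#' @param well_id Optional well identifier carried into the result.
#' @return One-row tibble: `well_id`, `tcr_detected`, `beta_consensus`,
#'   `beta_confidence`, `alpha_consensus`, `alpha_confidence`,
#'   `alt_alpha_consensus`, `alt_alpha_confidence`, `phenotype_counts`
#'   (list-column: named integer vector per marker).
#' @export
call_well <- function(clusters, reference, phenotype_ref,
                      beta_min = 0.80, alpha_min = 0.30,
                      alt_alpha_min = 0.10, well_id = NA_character_) {
  if (!all(c("class", "label") %in% names(clusters))) {
    cls <- classify_clusters(clusters$consensus, reference, phenotype_ref)
    clusters$class <- cls$class
    clusters$label <- cls$label
  }

  pheno <- clusters |> filter(class == "phenotype")
  counts <- setNames(integer(nrow(phenotype_ref)), phenotype_ref$marker)
  if (nrow(pheno) > 0L) {
    agg <- pheno |> group_by(label) |> summarise(n = sum(size))
    counts[agg$label] <- as.integer(agg$n)
  }

  top_frac <- function(sub) {
    tot <- sum(sub$size)
    sub <- sub |> arrange(desc(size), centroid)
    list(tot = tot, sub = sub)
  }

  beta_consensus <- NA_character_; beta_conf <- NA_real_
  b <- clusters |> filter(class == "beta")
  if (nrow(b) > 0L) {
    tb <- top_frac(b)
    f <- tb$sub$size[[1L]] / tb$tot
    beta_conf <- f
    if (f > beta_min) beta_consensus <- tb$sub$consensus[[1L]]
  }

  alpha_consensus <- NA_character_; alpha_conf <- NA_real_
  alt_consensus <- NA_character_; alt_conf <- NA_real_
  a <- clusters |> filter(class == "alpha")
  if (nrow(a) > 0L) {
    ta <- top_frac(a)
    f1 <- ta$sub$size[[1L]] / ta$tot
    alpha_conf <- f1
    if (f1 > alpha_min) {
      alpha_consensus <- ta$sub$consensus[[1L]]
      if (nrow(ta$sub) >= 2L) {
        f2 <- ta$sub$size[[2L]] / ta$tot
        if (f2 > alt_alpha_min) {
          alt_consensus <- ta$sub$consensus[[2L]]
          alt_conf <- f2
        }
      }
    }
  }

  tibble(
    well_id = well_id,
    tcr_detected = nrow(b) + nrow(a) > 0L,
    beta_consensus = beta_consensus, beta_confidence = beta_conf,
    alpha_consensus = alpha_consensus, alpha_confidence = alpha_conf,
    alt_alpha_consensus = alt_consensus, alt_alpha_confidence = alt_conf,
    phenotype_counts = list(counts)
  )
}

#' Call all wells of a demultiplexed read set
#'
#' Clusters and calls every well; wells present in `barcode_map` but
#' receiving no reads are emitted with `tcr_detected = FALSE` so that
#' well-coverage accounting runs over all sorted wells.
#'
#' @param demuxed Output of [demultiplex()] (unassigned reads are ignored).
#' @param barcode_map The barcode map (defines the well universe).
#' @inheritParams call_well
#' @param min_identity Clustering identity threshold.
#' @return Tibble of well calls, one row per well in `barcode_map`.
#' @export
call_wells <- function(demuxed, barcode_map, reference, phenotype_ref,
                       min_identity = 0.95, beta_min = 0.80,
                       alpha_min = 0.30, alt_alpha_min = 0.10) {
  assigned <- demuxed |> filter(!is.na(well_id))
  clustered <- assigned |>
    group_by(well_id) |>
    group_map(function(df, key) {
      cluster_well_reads(df$sequence, min_identity) |>
        mutate(well_id = key$well_id)
    }) |>
    bind_rows()
  # classify all cluster consensus sequences in one batched pass
  cls <- classify_clusters(clustered$consensus, reference, phenotype_ref)
  clustered$class <- cls$class
  clustered$label <- cls$label
  called <- clustered |>
    group_by(well_id) |>
    group_map(function(df, key) {
      call_well(df, reference, phenotype_ref, beta_min, alpha_min,
                alt_alpha_min, well_id = key$well_id)
    }) |>
    bind_rows()
  missing <- setdiff(barcode_map$well_id, called$well_id)
  if (length(missing) > 0L) {
    counts0 <- setNames(integer(nrow(phenotype_ref)), phenotype_ref$marker)
    called <- bind_rows(called, tibble(
      well_id = missing, tcr_detected = FALSE,
      beta_consensus = NA_character_, beta_confidence = NA_real_,
      alpha_consensus = NA_character_, alpha_confidence = NA_real_,
      alt_alpha_consensus = NA_character_, alt_alpha_confidence = NA_real_,
      phenotype_counts = purrr::map(missing, function(...) counts0)
    ))
  }
  called |> arrange(well_id)
}

#' Binarize phenotype read counts
#'
#' A marker is scored present (1) iff its well has at least one read of
#' the marker amplicon, without weighing the actual read count (read
#' counts after nested PCR do not track per-cell transcript levels).
#'
#' @param counts Named numeric vector, or a well-call tibble holding a
#'   `phenotype_counts` list-column.
#' @return For a vector, a named 0/1 integer vector; for well calls, a
#'   tibble `well_id` x marker bit columns.
#' @export
binarize_phenotypes <- function(counts) {
  if (is.data.frame(counts)) {
    bits <- purrr::map(counts$phenotype_counts, binarize_phenotypes)
    mat <- do.call(rbind, bits)
    return(bind_cols(tibble(well_id = counts$well_id), as_tibble(mat)))
  }
  if (any(counts < 0)) {
    abort("negative phenotype read counts", class = "tcrclonal_data_error")
  }
  setNames(as.integer(counts > 0), names(counts))
}

#' Well-coverage accounting
#'
#' @param well_calls Output of [call_wells()].
#' @return One-row tibble: `n_wells`, `n_tcr_detected`, `coverage_pct`
#'   (percent, rounded half away from zero to one decimal).
#' @export
well_coverage <- function(well_calls) {
  n <- nrow(well_calls)
  k <- sum(well_calls$tcr_detected)
  tibble(n_wells = n, n_tcr_detected = k,
         coverage_pct = round_half_up(100 * k / n, 1))
}

#' Export well calls as TSV
#'
#' Writes one row per well with the confidence columns named `BetaConfi`,
#' `AlphaConfi` and `altAlphaConfi` (the field vocabulary for these
#' quantities) and one count column per phenotype marker.
#'
#' @param well_calls Output of [call_wells()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_well_calls <- function(well_calls, path) {
  counts <- do.call(rbind, well_calls$phenotype_counts)
  out <- well_calls |>
    select(well_id, tcr_detected, beta_consensus,
           BetaConfi = beta_confidence,
           alpha_consensus, AlphaConfi = alpha_confidence,
           alt_alpha_consensus, altAlphaConfi = alt_alpha_confidence) |>
    bind_cols(as_tibble(counts))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
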