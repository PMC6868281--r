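# Local alignment of many queries (patterns) against one germline segment
# (subject); keeps the gapped alignment strings so germline coordinates
# can be mapped onto each read exactly, through indels.
segment_align <- function(queries, segment_nt) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), segment_nt, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 0, gapExtension = 5
  )
  list(
    score = Biostrings::score(pa),
    read_start = Biostrings::start(Biostrings::pattern(pa)),
    read_end = Biostrings::end(Biostrings::pattern(pa)),
    seg_start = Biostrings::start(Biostrings::subject(pa)),
    seg_end = Biostrings::end(Biostrings::subject(pa)),
    gapped_read = as.character(Biostrings::pattern(pa)),
    gapped_seg = as.character(Biostrings::subject(pa))
  )
}

# Map a germline-segment coordinate onto the read through one query's
# alignment; positions outside the aligned block are extrapolated
# gaplessly from the nearest aligned end. Returns NA when the target
# lands on a read gap.
map_seg_pos_to_read <- function(al, i, target) {
  if (target < al$seg_start[[i]]) {
    return(al$read_start[[i]] - (al$seg_start[[i]] - target))
  }
  if (target > al$seg_end[[i]]) {
    return(al$read_end[[i]] + (target - al$seg_end[[i]]))
  }
  rc <- strsplit(al$gapped_read[[i]], "", fixed = TRUE)[[1L]]
  sc <- strsplit(al$gapped_seg[[i]], "", fixed = TRUE)[[1L]]
  rp <- al$read_start[[i]] - 1L
  sp <- al$seg_start[[i]] - 1L
  for (k in seq_along(rc)) {
    if (rc[[k]] != "-") rp <- rp + 1L
    if (sc[[k]] != "-") sp <- sp + 1L
    if (sp == target && sc[[k]] != "-") {
      return(if (rc[[k]] != "-") rp else NA_integer_)
    }
  }
  NA_integer_
}

# Vectorized segment assignment: one alignment pass per panel segment,
# best V and J per query with alphabetical tie-break and the score floor,
# plus the read coordinates of the CDR3 anchors (V 2nd-CYS codon start,
# J F/W codon end) mapped through the winning alignments.
assign_segments_batch <- function(queries, reference, chain,
                                  score_floor_frac = 0.6) {
  n <- length(queries)
  pick_class <- function(cls, anchor_end) {
    panel <- reference[reference$segment_class == cls &
                         reference$chain == chain, ]
    if (nrow(panel) == 0L) {
      abort(paste0("reference holds no ", cls, " segments for ", chain),
            class = "tcrclonal_config_error")
    }
    ord <- order(panel$name)
    panel <- panel[ord, ]
    als <- lapply(panel$nt_sequence, segment_align, queries = queries)
    scores <- vapply(als, `[[`, numeric(n), "score") |> matrix(nrow = n)
    best <- apply(scores, 1L, which.max)
    gene <- panel$name[best]
    sc <- scores[cbind(seq_len(n), best)]
    floor_score <- score_floor_frac * 2 *
      pmin(nchar(queries), nchar(panel$nt_sequence[best]))
    ok <- sc >= floor_score
    anchor_pos <- vapply(seq_len(n), function(i) {
      if (!ok[[i]]) return(NA_integer_)
      b <- best[[i]]
      target <- if (anchor_end) 3L * panel$anchor[[b]] + 3L
                else 3L * panel$anchor[[b]] + 1L
      map_seg_pos_to_read(als[[b]], i, target)
    }, integer(1))
    list(gene = ifelse(ok, gene, NA_character_), score = sc,
         anchor_pos = anchor_pos, ok = ok)
  }
  v <- pick_class("V", anchor_end = FALSE)
  j <- pick_class("J", anchor_end = TRUE)
  tibble(
    v_gene = v$gene, j_gene = j$gene,
    v_score = v$score, j_score = j$score,
    cdr3_start = v$anchor_pos, cdr3_end = j$anchor_pos,
    reason = ifelse(v$ok & j$ok, NA_character_, "below score floor")
  )
}

#' Assign germline V and J segments to a consensus sequence
#'
#' Scores the consensus against every V and every J germline of the chain
#' by local alignment (match +2, mismatch -3, linear gap -5) and returns
#' the highest-scoring segment of each class; ties break alphabetically by
#' segment name. A segment whose best score falls below the floor (60% of
#' the maximum attainable score for the shorter of read and segment) is
#' unassignable. The conserved anchor codon positions of the winning
#' segments are mapped onto the read through the alignments (gap-aware),
#' giving the CDR3 boundary coordinates.
#'
#' @param consensus_nt Consensus nucleotide sequence.
#' @param reference Germline reference tibble.
#' @param chain `"alpha"` or `"beta"`.
#' @param score_floor_frac Floor fraction of the maximum attainable score.
#' @return A list: `v_gene`, `j_gene` (either `NA` with a `reason`),
#'   `v_score`, `j_score`, and the read coordinates `cdr3_start` (first nt
#'   of the V 2nd-CYS codon) and `cdr3_end` (last nt of the J F/W codon).
#' @export
assign_segments <- function(consensus_nt, reference, chain,
                            score_floor_frac = 0.6) {
  stopifnot(chain %in% c("alpha", "beta"), length(consensus_nt) == 1L)
  as.list(assign_segments_batch(consensus_nt, reference, chain,
                                score_floor_frac))
}

#' Extract the CDR3 junction from an annotated consensus
#'
#' The CDR3 spans the V segment's 2nd-CYS codon through the J segment's
#' F/W anchor codon, both inclusive, at the read coordinates mapped by
#' [assign_segments()]. Productivity requires an in-frame (length
#' divisible by 3), stop-free junction that starts with C and ends with F
#' or W.
#'
#' @param consensus_nt Consensus nucleotide sequence.
#' @param segs Result of [assign_segments()].
#' @param reference Germline reference tibble (unused in the extraction
#'   itself; kept for interface symmetry).
#' @return A list: `cdr3_nt`, `cdr3_aa`, `productive`, `reason`.
#' @export
extract_cdr3 <- function(consensus_nt, segs, reference = NULL) {
  fail <- function(reason) list(cdr3_nt = NA_character_,
                                cdr3_aa = NA_character_,
                                productive = FALSE, reason = reason)
  if (is.na(segs$v_gene) || is.na(segs$j_gene)) {
    return(fail("segment unassigned"))
  }
  start <- segs$cdr3_start
  end <- segs$cdr3_end
  if (is.na(start) || is.na(end) || start < 1L ||
      end > nchar(consensus_nt) || end <= start) {
    return(fail("anchor not found"))
  }
  cdr3_nt <- substr(consensus_nt, start, end)
  cdr3_aa <- translate_nt(cdr3_nt)
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  stop_free <- !grepl("*", cdr3_aa, fixed = TRUE)
  anchored <- grepl("^C.*[FW]$", cdr3_aa)
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
       productive = in_frame && stop_free && anchored,
       reason = if (in_frame && stop_free && anchored) NA_character_
                else if (!in_frame) "out of frame"
                else if (!stop_free) "stop codon"
                else "anchor residues missing")
}

#' Call the TRAJ24 G/C (rs1483979) allele from a CDR3
#'
#' For TRAJ24-bearing alpha chains the SNP codon sits two codons upstream
#' of the CDR3-terminal J anchor. The G allele leaves `TTG` (leucine), the
#' C allele `TTC` (phenylalanine); any other codon at that position --
#' including synonymous leucine codons outside the TTG/TTC pair -- is
#' reported `undetermined`.
#'
#' @param cdr3_nt CDR3 nucleotide string of a TRAJ24+ alpha chain.
#' @param j_gene The assigned J gene; must be `"TRAJ24"`.
#' @return One of `"G-allele/L"`, `"C-allele/F"`, `"undetermined"`.
#' @export
traj24_allele <- function(cdr3_nt, j_gene = "TRAJ24") {
  if (!identical(j_gene, "TRAJ24")) {
    abort("traj24_allele is defined only for TRAJ24-bearing chains",
          class = "tcrclonal_contract_error")
  }
  n <- nchar(cdr3_nt)
  if (is.na(cdr3_nt) || n < 9L || n %% 3L != 0L) return("undetermined")
  codon <- substr(cdr3_nt, n - 8L, n - 6L)
  if (codon == "TTG") return("G-allele/L")
  if (codon == "TTC") return("C-allele/F")
  warn(paste0("TRAJ24 SNP codon ", codon,
              " outside the TTG/TTC pair; allele undetermined"))
  "undetermined"
}

# Batched chain annotation: assign segments for all consensus sequences of
# one chain in one panel pass, then extract CDR3s and allele calls.
annotate_chain_batch <- function(consensus_nt, reference, chain,
                                 confidence) {
  n <- length(consensus_nt)
  out <- tibble(v_gene = NA_character_, j_gene = NA_character_,
                cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                productive = logical(n), allele_call = NA_character_,
                confidence = confidence, reason = NA_character_)
  present <- which(!is.na(consensus_nt))
  if (length(present) == 0L) return(out)
  uniq <- unique(consensus_nt[present])
  segs_u <- assign_segments_batch(uniq, reference, chain)
  ukey <- match(consensus_nt[present], uniq)
  for (k in seq_along(present)) {
    i <- present[[k]]
    s <- as.list(segs_u[ukey[[k]], ])
    cdr3 <- extract_cdr3(consensus_nt[[i]], s)
    out$v_gene[[i]] <- s$v_gene
    out$j_gene[[i]] <- s$j_gene
    out$cdr3_nt[[i]] <- cdr3$cdr3_nt
    out$cdr3_aa[[i]] <- cdr3$cdr3_aa
    out$productive[[i]] <- cdr3$productive
    out$reason[[i]] <- if (!is.na(cdr3$reason)) cdr3$reason else s$reason
    if (chain == "alpha" && !is.na(s$j_gene) && s$j_gene == "TRAJ24" &&
        cdr3$productive) {
      out$allele_call[[i]] <-
        suppressWarnings(traj24_allele(cdr3$cdr3_nt, s$j_gene))
    }
  }
  out
}

#' Annotate called wells into a cell table
#'
#' Runs segment assignment, CDR3 extraction and TRAJ24 allele calling on
#' every well call, joins donor/plate metadata, index-sort values and
#' binarized phenotype bits, and returns one row per well that produced at
#' least one consensus chain.
#'
#' @param well_calls Output of [call_wells()].
#' @param reference Germline reference tibble.
#' @param metadata Plate metadata (`donor`, `status`, `tiv_vaccinated`,
#'   `tetramer`, `plate_id`).
#' @param index Optional index-sort tibble (`well_id`, `fi_tetramer`,
#'   `fsc`).
#' @return A cell tibble with beta (`trbv`, `trbj`, `cdr3b_nt`, `cdr3b_aa`,
#'   `beta_productive`, `beta_confidence`), alpha (`trav`, `traj`,
#'   `cdr3a_nt`, `cdr3a_aa`, `alpha_productive`, `allele_call`,
#'   `alpha_confidence`), alternative-alpha columns (`alt_` prefix),
#'   metadata, index values and one 0/1 column per phenotype marker.
#' @export
annotate_cells <- function(well_calls, reference, metadata, index = NULL) {
  wc <- well_calls |>
    filter(!is.na(beta_consensus) | !is.na(alpha_consensus))
  if (nrow(wc) == 0L) {
    abort("no wells with called consensus chains",
          class = "tcrclonal_data_error")
  }
  b <- annotate_chain_batch(wc$beta_consensus, reference, "beta",
                            wc$beta_confidence)
  a <- annotate_chain_batch(wc$alpha_consensus, reference, "alpha",
                            wc$alpha_confidence)
  alt <- annotate_chain_batch(wc$alt_alpha_consensus, reference, "alpha",
                              wc$alt_alpha_confidence)
  rows <- tibble(
    well_id = wc$well_id,
    trbv = b$v_gene, trbj = b$j_gene, cdr3b_nt = b$cdr3_nt,
    cdr3b_aa = b$cdr3_aa, beta_productive = b$productive,
    beta_confidence = b$confidence,
    trav = a$v_gene, traj = a$j_gene, cdr3a_nt = a$cdr3_nt,
    cdr3a_aa = a$cdr3_aa, alpha_productive = a$productive,
    allele_call = a$allele_call, alpha_confidence = a$confidence,
    alt_trav = alt$v_gene, alt_traj = alt$j_gene,
    alt_cdr3a_nt = alt$cdr3_nt, alt_cdr3a_aa = alt$cdr3_aa,
    alt_alpha_productive = alt$productive
  )
  rows <- rows |>
    mutate(plate_id = sub("-[A-H][0-9]{2}$", "", well_id)) |>
    left_join(metadata, by = "plate_id")
  if (!is.null(index)) {
    rows <- rows |> left_join(index, by = "well_id")
  }
  bits <- binarize_phenotypes(well_calls |>
                                filter(well_id %in% rows$well_id))
  rows |> left_join(bits, by = "well_id")
}

#' Restrict a cell table to analyzed cells
#'
#' Keeps cells with paired TCRalphabeta: both a beta and a dominant alpha
#' consensus called, and both CDR3s productive.
#'
#' @param cells Output of [annotate_cells()].
#' @return The filtered tibble.
#' @export
analyzed_cells <- function(cells) {
  cells |> filter(beta_productive, alpha_productive)
}
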