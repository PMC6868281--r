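#' Build a miniature germline TCR segment reference
#'
#' Generates a small panel of TCR alpha/beta V and J germline segments
#' suitable for simulating and annotating plate-based TCR amplicons. The
#' panel always contains the four segments central to hypocretin-tetramer
#' repertoire work -- `TRBV29-1`, `TRBJ2-5`, `TRAV6` and `TRAJ24` -- so that
#' J-sharing groups, gene-usage enrichment and the TRAJ24 allele read-out
#' are exercisable. Additional filler segments carry real gene names drawn
#' from common human TRB/TRA segments, with synthetic (but
#' anchor-consistent) sequence bodies.
#'
#' Each V segment ends at its conserved 2nd-CYS anchor codon (`TGT`/`TGC`);
#' each J segment carries the J-phenylalanine/tryptophan of the F/W-G-x-G
#' motif at its recorded anchor codon. `TRAJ24` carries the rs1483979 G/C
#' single-nucleotide polymorphism two codons upstream of its anchor: the G
#' allele leaves the codon `TTG` (leucine), the C allele makes it `TTC`
#' (phenylalanine).
#'
#' @param n_v_per_chain Number of V segments per chain (>= 1).
#' @param n_j_per_chain Number of J segments per chain (>= 1).
#' @param seed Integer seed; output is byte-identical for equal seeds. The
#'   four named core segments are seed-invariant.
#' @return A tibble with columns `name`, `segment_class` ("V"/"J"),
#'   `chain` ("alpha"/"beta"), `nt_sequence`, `anchor` (0-based codon index
#'   of the conserved anchor), `snp_position` (1-based nt offset of the
#'   rs1483979 site, `NA` elsewhere) and `snp_alleles` (named character,
#'   e.g. `c(G = "G", C = "C")` giving the base at `snp_position`).
#' @examples
#' ref <- build_mini_reference(3, 3, seed = 1)
#' ref[ref$name == "TRAJ24", ]
#' @export
build_mini_reference <- function(n_v_per_chain = 4, n_j_per_chain = 4,
                                 seed = 1) {
  if (!is.numeric(n_v_per_chain) || n_v_per_chain < 1 ||
      !is.numeric(n_j_per_chain) || n_j_per_chain < 1) {
    abort("n_v_per_chain and n_j_per_chain must both be >= 1",
          class = "tcrclonal_config_error")
  }
  n_v <- as.integer(n_v_per_chain)
  n_j <- as.integer(n_j_per_chain)

  core <- core_segments()
  v_names <- list(
    beta  = c("TRBV29-1", "TRBV25-1", "TRBV19", "TRBV5-1", "TRBV7-9",
              "TRBV6-5", "TRBV28", "TRBV2"),
    alpha = c("TRAV6", "TRAV10", "TRAV1-2", "TRAV8-2", "TRAV12-1",
              "TRAV21", "TRAV26-1", "TRAV38-1")
  )
  j_names <- list(
    beta  = c("TRBJ2-5", "TRBJ2-1", "TRBJ1-1", "TRBJ2-7", "TRBJ1-2",
              "TRBJ2-3"),
    alpha = c("TRAJ24", "TRAJ18", "TRAJ33", "TRAJ42", "TRAJ49", "TRAJ20")
  )
  pad_names <- function(pool, n, stem) {
    if (n <= length(pool)) pool[seq_len(n)]
    else c(pool, paste0(stem, seq_len(n - length(pool))))
  }

  with_seed(seed, {
    rows <- list()
    for (chain in c("beta", "alpha")) {
      vn <- pad_names(v_names[[chain]], n_v, paste0("TR", toupper(substr(chain, 1, 1)), "VS"))
      for (nm in vn) {
        rows[[length(rows) + 1L]] <-
          if (nm %in% names(core)) core[[nm]] else synth_v_segment(nm, chain)
      }
      jn <- pad_names(j_names[[chain]], n_j, paste0("TR", toupper(substr(chain, 1, 1)), "JS"))
      for (nm in jn) {
        rows[[length(rows) + 1L]] <-
          if (nm %in% names(core)) core[[nm]] else synth_j_segment(nm, chain)
      }
    }
    out <- bind_rows(rows)
    validate_reference(out)
    out
  })
}

# The four named segments are deterministic constants: their CDR3-proximal
# ends mimic the true human germline (anchor context, TRAJ24 SNP codon),
# while V bodies are synthetic filler kept stop-free and fixed by a local
# seed so they never vary with the caller's seed.
core_segments <- function() {
  body <- function(nm, n) {
    with_seed(10007L + name_seed(nm), random_codons(n))
  }
  list(
    # V bodies: 62 filler codons + anchor TGT; anchor codon index 62.
    `TRBV29-1` = tibble(
      name = "TRBV29-1", segment_class = "V", chain = "beta",
      nt_sequence = paste0(body("TRBV29-1", 60), "TATCTCTGT"),
      anchor = 62L, snp_position = NA_integer_, snp_alleles = list(NULL)
    ),
    `TRAV6` = tibble(
      name = "TRAV6", segment_class = "V", chain = "alpha",
      nt_sequence = paste0(body("TRAV6", 60), "TACTTCTGT"),
      anchor = 62L, snp_position = NA_integer_, snp_alleles = list(NULL)
    ),
    # TRBJ2-5: E T Q Y F G P G T R L L V L ; anchor F at codon 4.
    `TRBJ2-5` = tibble(
      name = "TRBJ2-5", segment_class = "J", chain = "beta",
      nt_sequence = "GAGACCCAGTACTTCGGGCCAGGCACGCGGCTCCTGGTGCTC",
      anchor = 4L, snp_position = NA_integer_, snp_alleles = list(NULL)
    ),
    # TRAJ24: L T T D S W G K L Q F G A G T Q V V V T P ; anchor F at
    # codon 10; rs1483979 at the third base of codon 8 (TTG/TTC -> L/F).
    `TRAJ24` = tibble(
      name = "TRAJ24", segment_class = "J", chain = "alpha",
      nt_sequence = "TTGACAACTGACTCCTGGGGCAAATTGCAGTTTGGAGCAGGGACCCAGGTAGTGGTCACACCA",
      anchor = 10L, snp_position = 27L, snp_alleles = list(c(G = "G", C = "C"))
    )
  )
}

synth_v_segment <- function(name, chain) {
  anchor <- 62L
  tibble(
    name = name, segment_class = "V", chain = chain,
    nt_sequence = paste0(random_codons(anchor),
                         sample(c("TGT", "TGC"), 1L)),
    anchor = anchor, snp_position = NA_integer_, snp_alleles = list(NULL)
  )
}

synth_j_segment <- function(name, chain) {
  anchor <- 3L
  anchor_codon <- sample(c("TTT", "TTC", "TGG"), 1L)
  gxg <- paste0(sample(c("GGA", "GGC", "GGG", "GGT"), 1L),
                sample(stopfree_codons(), 1L),
                sample(c("GGA", "GGC", "GGG", "GGT"), 1L))
  tibble(
    name = name, segment_class = "J", chain = chain,
    nt_sequence = paste0(random_codons(anchor), anchor_codon, gxg,
                         random_codons(7L)),
    anchor = anchor, snp_position = NA_integer_, snp_alleles = list(NULL)
  )
}

validate_reference <- function(ref) {
  for (i in seq_len(nrow(ref))) {
    seg <- ref[i, ]
    if (nchar(seg$nt_sequence) < 3 * (seg$anchor + 1)) {
      abort(paste0("segment ", seg$name, " shorter than its anchor"),
            class = "tcrclonal_config_error")
    }
    codon <- substr(seg$nt_sequence, 3L * seg$anchor + 1L, 3L * seg$anchor + 3L)
    aa <- translate_nt(codon)
    ok <- if (seg$segment_class == "V") aa == "C" else aa %in% c("F", "W")
    if (!ok) {
      abort(paste0("segment ", seg$name, " anchor codon ", codon,
                   " violates the anchor invariant"),
            class = "tcrclonal_config_error")
    }
  }
  invisible(ref)
}

#' Apply an allele variant to a germline segment sequence
#'
#' Substitutes the base recorded for `allele` at the segment's SNP position.
#' For `TRAJ24` the G allele yields the `TTG` (leucine) codon and the C
#' allele the `TTC` (phenylalanine) codon.
#'
#' @param reference A reference tibble from [build_mini_reference()].
#' @param name Segment name.
#' @param allele Allele label, one of the names of that segment's
#'   `snp_alleles` entry (e.g. `"G"` or `"C"`).
#' @return The segment's nucleotide sequence with the allele applied.
#' @export
apply_allele <- function(reference, name, allele) {
  seg <- reference[reference$name == name, ]
  if (nrow(seg) != 1L) abort(paste0("unknown segment ", name))
  alleles <- seg$snp_alleles[[1L]]
  if (is.null(alleles) || !allele %in% names(alleles)) {
    abort(paste0("segment ", name, " has no allele ", allele),
          class = "tcrclonal_config_error")
  }
  nt <- seg$nt_sequence
  substr(nt, seg$snp_position, seg$snp_position) <- alleles[[allele]]
  nt
}

#' Reference amplicons for the phenotyping marker panel
#'
#' Returns the 25-marker transcription-factor/cytokine amplicon panel used
#' for per-well phenotype read classification. Sequences are synthetic,
#' deterministic and mutually dissimilar; they stand in for the real
#' marker-specific amplicons, which are not redistributable.
#'
#' @param markers Optional character vector to subset the default panel.
#' @return A tibble with columns `marker` and `nt_sequence`.
#' @export
phenotype_panel <- function(markers = NULL) {
  all_markers <- c("TBX21", "GATA3", "RORC", "FOXP3", "BCL6", "RUNX1",
                   "IFNG", "TNF", "IL2", "IL4", "IL5", "IL10", "IL13",
                   "IL17A", "IL21", "IL22", "TGFB1", "PRF1", "GZMB",
                   "GZMK", "CCR7", "SELL", "CXCR5", "PDCD1", "CTLA4")
  if (!is.null(markers)) {
    bad <- setdiff(markers, all_markers)
    if (length(bad)) abort(paste0("unknown markers: ", paste(bad, collapse = ", ")))
    all_markers <- markers
  }
  tibble(
    marker = all_markers,
    nt_sequence = vapply(all_markers, function(m) {
      with_seed(20011L + name_seed(m), random_dna(220L))
    }, character(1))
  )
}
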