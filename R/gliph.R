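#' Generate a naive reference CDR3 repertoire
#'
#' Draws CDR3s from a naive recombination model over the germline panel:
#' uniform V and J segment choice, a random untemplated insert of 2-6
#' stop-free codons, and a random J trim; alleles at annotated SNP sites
#' are drawn uniformly. Used as the background repertoire for motif
#' enrichment when no user reference is supplied.
#'
#' @param reference Germline reference tibble.
#' @param chain `"alpha"` or `"beta"`.
#' @param n Number of CDR3s (default 10000; a floor of 10000 is enforced
#'   unless `allow_small = TRUE`, for toy examples).
#' @param seed Integer seed.
#' @param allow_small Permit `n < 10000`.
#' @return A tibble with columns `cdr3_aa` and `v_gene`; all sequences
#'   match `^C.*[FW]$`.
#' @export
naive_reference_repertoire <- function(reference, chain, n = 10000,
                                       seed = 1, allow_small = FALSE) {
  if (n < 10000 && !allow_small) {
    abort("reference repertoire smaller than 10000; pass allow_small = TRUE",
          class = "tcrclonal_config_error")
  }
  vs <- reference |> filter(segment_class == "V", chain == !!chain)
  js <- reference |> filter(segment_class == "J", chain == !!chain)
  with_seed(seed, {
    vi <- sample.int(nrow(vs), n, replace = TRUE)
    ji <- sample.int(nrow(js), n, replace = TRUE)
    cdr3 <- vapply(seq_len(n), function(i) {
      j <- js[ji[[i]], ]
      allele <- if (!is.na(j$snp_position)) {
        sample(names(j$snp_alleles[[1L]]), 1L)
      } else NULL
      translate_nt(recombine_cdr3(
        reference, vs$name[[vi[[i]]]], j$name,
        insert_nt = random_codons(sample(2:6, 1L)),
        j_trim = sample.int(min(3L, j$anchor), 1L),
        allele = allele
      ))
    }, character(1))
    tibble(cdr3_aa = cdr3, v_gene = vs$name[vi])
  })
}

# CDR3 interior: strip the first 3 and last 2 residues before k-mer
# extraction / global distance, leaving the antigen-facing loop center.
cdr3_interior <- function(cdr3_aa) {
  n <- nchar(cdr3_aa)
  ifelse(n > 5L, substr(cdr3_aa, 4L, n - 2L), "")
}

#' Find enriched local CDR3 motifs
#'
#' Extracts interior k-mers (k in `k_range`) from the sample CDR3s and
#' keeps those whose sample frequency exceeds `fold_min` times their
#' frequency in the reference repertoire, whose sample support is at least
#' `min_count` CDR3s, and whose subsample probability -- the fraction of
#' `n_subsamples` sample-sized draws from the reference containing the
#' motif at least as often as the sample does -- is below `prob_max`.
#'
#' @param sample_cdr3s Character vector of sample CDR3 amino-acid
#'   sequences.
#' @param reference Reference repertoire tibble (from
#'   [naive_reference_repertoire()]) or character vector of CDR3s.
#' @param k_range Motif lengths (default 2:4).
#' @param fold_min Minimum enrichment fold (default 10).
#' @param prob_max Maximum subsample probability (default 0.001).
#' @param n_subsamples Number of reference subsamples (default 1000).
#' @param min_count Minimum sample CDR3s containing the motif (default 3).
#' @param seed Seed for the subsampling.
#' @return A tibble of local motif groups: `motif`, `kind` ("local"),
#'   `members` (list of sample indices), `size`, `fold_vs_reference`,
#'   `subsample_probability`.
#' @export
find_local_motifs <- function(sample_cdr3s, reference, k_range = 2:4,
                              fold_min = 10, prob_max = 0.001,
                              n_subsamples = 1000, min_count = 3,
                              seed = 1) {
  ref_cdr3 <- if (is.data.frame(reference)) reference$cdr3_aa else reference
  n_s <- length(sample_cdr3s)
  n_r <- length(ref_cdr3)
  if (n_s == 0L) abort("empty sample", class = "tcrclonal_data_error")
  if (n_r < n_s) {
    abort("reference repertoire smaller than the sample",
          class = "tcrclonal_config_error")
  }
  si <- cdr3_interior(sample_cdr3s)
  ri <- cdr3_interior(ref_cdr3)

  kmers_of <- function(x, k) {
    n <- nchar(x)
    if (n < k) return(character(0))
    unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  cand <- unique(unlist(lapply(k_range, function(k)
    unlist(lapply(si, kmers_of, k = k)))))
  if (length(cand) == 0L) return(empty_motif_tbl())

  s_count <- vapply(cand, function(m)
    sum(stringr::str_detect(si, stringr::fixed(m))), integer(1),
    USE.NAMES = FALSE)
  cand <- cand[s_count >= min_count]
  s_count <- s_count[s_count >= min_count]
  if (length(cand) == 0L) return(empty_motif_tbl())

  r_presence <- vapply(cand, function(m)
    stringr::str_detect(ri, stringr::fixed(m)), logical(n_r))
  r_presence <- matrix(r_presence, nrow = n_r)
  r_count <- colSums(r_presence)
  fold <- (s_count / n_s) / pmax(r_count, 0.5) * n_r  # 0.5 pseudo-count for
  # reference-absent motifs so the fold is finite but large
  keep <- fold >= fold_min
  cand <- cand[keep]; s_count <- s_count[keep]
  fold <- fold[keep]; r_presence <- r_presence[, keep, drop = FALSE]
  if (length(cand) == 0L) return(empty_motif_tbl())

  probs <- with_seed(seed, {
    hits <- integer(length(cand))
    for (b in seq_len(n_subsamples)) {
      idx <- sample.int(n_r, n_s)
      cnt <- colSums(r_presence[idx, , drop = FALSE])
      hits <- hits + as.integer(cnt >= s_count)
    }
    hits / n_subsamples
  })
  keep <- probs < prob_max
  if (!any(keep)) return(empty_motif_tbl())
  tibble(
    motif = cand[keep], kind = "local",
    members = purrr::map(cand[keep], function(m)
      which(stringr::str_detect(si, stringr::fixed(m)))),
    size = s_count[keep],
    fold_vs_reference = fold[keep],
    subsample_probability = probs[keep]
  )
}

empty_motif_tbl <- function() {
  tibble(motif = character(), kind = character(), members = list(),
         size = integer(), fold_vs_reference = numeric(),
         subsample_probability = numeric())
}

#' Group CDR3s by global similarity
#'
#' Global motif groups are connected components of same-length CDR3s whose
#' non-interior residues agree and whose interiors differ at no more than
#' `max_interior_hamming` positions. The group motif string shows the
#' shared residues with `%` at varying positions, prefixed `global-`.
#'
#' @param sample_cdr3s Character vector of CDR3 amino-acid sequences.
#' @param max_interior_hamming Maximum interior Hamming distance linking
#'   two CDR3s (default 1).
#' @return A tibble of global groups: `motif`, `kind` ("global"),
#'   `members` (list of sample indices), `size`.
#' @export
find_global_groups <- function(sample_cdr3s, max_interior_hamming = 1L) {
  n <- length(sample_cdr3s)
  if (n == 0L) return(empty_motif_tbl()[, c("motif", "kind", "members", "size")])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  unite <- function(i, k) {
    ri <- find(i); rk <- find(k)
    if (ri != rk) parent[[rk]] <<- ri
  }
  lens <- nchar(sample_cdr3s)
  for (len in unique(lens)) {
    idx <- which(lens == len)
    if (length(idx) < 2L || len <= 5L) next
    chars <- strsplit(sample_cdr3s[idx], "", fixed = TRUE)
    interior <- 4:(len - 2L)
    for (a in seq_len(length(idx) - 1L)) {
      for (b in seq((a + 1L), length(idx))) {
        di <- sum(chars[[a]][interior] != chars[[b]][interior])
        if (di <= max_interior_hamming) unite(idx[[a]], idx[[b]])
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  comp <- comp[lengths(comp) >= 2L]
  if (length(comp) == 0L) {
    return(empty_motif_tbl()[, c("motif", "kind", "members", "size")])
  }
  purrr::map_dfr(comp, function(mem) {
    seqs <- sample_cdr3s[mem]
    chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    pattern <- vapply(seq_len(ncol(chars)), function(j) {
      u <- unique(chars[, j])
      if (length(u) == 1L) u else "%"
    }, character(1))
    tibble(motif = paste0("global-", paste(pattern, collapse = "")),
           kind = "global", members = list(mem),
           size = length(mem))
  }) |>
    arrange(desc(size), motif)
}

#' Assemble global, local and single motif groups for a sample
#'
#' Runs [find_global_groups()] and [find_local_motifs()] and adds a
#' `single` group for every CDR3 that belongs to no global group and
#' contains no enriched local motif, so that every sample CDR3 appears in
#' at least one group (kinds are not mutually exclusive).
#'
#' @inheritParams find_local_motifs
#' @param max_interior_hamming Passed to [find_global_groups()].
#' @return A motif-group tibble (`motif`, `kind`, `members`, `size`,
#'   `fold_vs_reference`, `subsample_probability`; the latter two `NA` for
#'   global/single groups).
#' @export
gliph_motifs <- function(sample_cdr3s, reference, k_range = 2:4,
                         fold_min = 10, prob_max = 0.001,
                         n_subsamples = 1000, min_count = 3,
                         max_interior_hamming = 1L, seed = 1) {
  glob <- find_global_groups(sample_cdr3s, max_interior_hamming)
  loc <- find_local_motifs(sample_cdr3s, reference, k_range, fold_min,
                           prob_max, n_subsamples, min_count, seed)
  covered <- sort(unique(c(unlist(glob$members), unlist(loc$members))))
  singles_idx <- setdiff(seq_along(sample_cdr3s), covered)
  singles <- tibble(
    motif = paste0("single-", singles_idx), kind = "single",
    members = purrr::map(singles_idx, identity),
    size = 1L, fold_vs_reference = NA_real_,
    subsample_probability = NA_real_
  )
  bind_rows(
    glob |> mutate(fold_vs_reference = NA_real_,
                   subsample_probability = NA_real_),
    loc, singles
  )
}

# Exact multinomial tail P(max_v count_v >= k) for n draws from the
# category distribution p: 1 - P(all counts <= k - 1), via truncated
# exponential-generating-function convolution.
multinomial_max_tail <- function(n, p, k) {
  if (k > n) return(0)
  if (k <= 0) return(1)
  p <- p[p > 0]
  coef <- c(1, rep(0, n))          # polynomial in x, coef[j+1] ~ x^j
  lim <- k - 1L
  for (pv in p) {
    term <- pv^(0:min(lim, n)) / factorial(0:min(lim, n))
    newc <- rep(0, n + 1L)
    for (j in seq_along(term)) {
      idx <- j:(n + 1L)
      newc[idx] <- newc[idx] + coef[seq_len(n + 2L - j)] * term[[j]]
    }
    coef <- newc
  }
  p_all_below <- coef[[n + 1L]] * exp(lgamma(n + 1))
  max(0, min(1, 1 - p_all_below))
}

#' Score a motif group for V-gene and expansion enrichment
#'
#' `vgene_enrichment_p` is the exact tail probability, under draws of the
#' group's size from the sample's V-gene distribution, that some V gene
#' reaches at least the observed dominant-V count. `expansion_enrichment_p`
#' is the exact binomial tail for the group's expanded-cell count at the
#' sample's expanded fraction. The final score is
#' `-log10(vgene_p * expansion_p)` (the plotted dot radius); a group is
#' `significant` iff both p-values are below `alpha` and the group has at
#' least two members -- singletons are scored but never significant.
#'
#' @param groups Motif-group tibble ([gliph_motifs()] output).
#' @param v_genes Character vector: V gene of each sample CDR3.
#' @param expanded Logical vector: expanded status of each sample CDR3.
#' @param alpha Significance level (default 0.05).
#' @return `groups` with `dominant_v`, `vgene_enrichment_p`,
#'   `expansion_enrichment_p`, `final_score`, `significant`.
#' @export
score_motif_groups <- function(groups, v_genes, expanded, alpha = 0.05) {
  stopifnot(length(v_genes) == length(expanded))
  pv_bg <- table(v_genes) / length(v_genes)
  pe_bg <- mean(expanded)
  scored <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    mem <- groups$members[[i]]
    n <- length(mem)
    vt <- sort(table(v_genes[mem]), decreasing = TRUE)
    k_v <- as.integer(vt[[1L]])
    p_v <- multinomial_max_tail(n, as.numeric(pv_bg), k_v)
    k_e <- sum(expanded[mem])
    p_e <- if (pe_bg %in% c(0, 1)) 1 else
      pbinom(k_e - 1L, n, pe_bg, lower.tail = FALSE)
    tibble(dominant_v = names(vt)[[1L]],
           vgene_enrichment_p = p_v,
           expansion_enrichment_p = p_e,
           final_score = -log10(max(p_v * p_e, .Machine$double.xmin)),
           significant = n >= 2L && p_v < alpha && p_e < alpha)
  })
  bind_cols(groups, scored)
}

#' Full GLIPH-style motif analysis for one chain
#'
#' @param cells Cell tibble labelled by [label_expansion()].
#' @param chain `"alpha"` or `"beta"` (selects `cdr3a_aa`/`trav` or
#'   `cdr3b_aa`/`trbv`).
#' @param reference Reference repertoire; defaults to
#'   [naive_reference_repertoire()] on `germline`.
#' @param germline Germline reference tibble (needed when `reference` is
#'   `NULL`).
#' @param ... Passed to [gliph_motifs()].
#' @param seed Seed for reference generation and subsampling.
#' @return Scored motif-group tibble with a `chain` column.
#' @export
gliph_analysis <- function(cells, chain, reference = NULL, germline = NULL,
                           seed = 1, ...) {
  cdr3 <- if (chain == "alpha") cells$cdr3a_aa else cells$cdr3b_aa
  vg <- if (chain == "alpha") cells$trav else cells$trbv
  if (is.null(reference)) {
    if (is.null(germline)) {
      abort("supply either a reference repertoire or a germline panel",
            class = "tcrclonal_config_error")
    }
    reference <- naive_reference_repertoire(
      germline, chain, n = max(10000, 10 * length(cdr3)), seed = seed)
  }
  groups <- gliph_motifs(cdr3, reference, seed = seed, ...)
  score_motif_groups(groups, vg, cells$expanded) |>
    mutate(chain = chain)
}
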