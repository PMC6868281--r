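#' Pearson chi-squared skewing test on a 2x2 table
#'
#' Pearson chi-squared with one degree of freedom and no continuity
#' correction (the variant that reproduces printed repertoire-skewing
#' p-values from their count tables), on positive/total counts for two
#' groups.
#'
#' @param pos1,tot1 Positive count and total for group 1.
#' @param pos2,tot2 Positive count and total for group 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared_skew <- function(pos1, tot1, pos2, tot2) {
  if (tot1 <= 0 || tot2 <= 0) {
    abort("zero-total group in contingency table",
          class = "tcrclonal_data_error")
  }
  if (pos1 > tot1 || pos2 > tot2 || min(pos1, pos2) < 0) {
    abort("invalid contingency counts", class = "tcrclonal_data_error")
  }
  m <- matrix(c(pos1, tot1 - pos1, pos2, tot2 - pos2), nrow = 2,
              byrow = TRUE)
  if (sum(m[, 1]) == 0 || sum(m[, 2]) == 0) {
    # all-positive or all-negative margin: no skewing information
    return(tibble(statistic = 0, df = 1L, p_value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value))
}

#' Benjamini-Krieger-Yekutieli two-stage step-up FDR procedure
#'
#' Stage one runs Benjamini-Hochberg step-up at level `Q/(1+Q)` to obtain
#' `r1` rejections and the null-count estimate `m0 = m - r1`; if `r1 = 0`
#' nothing is discovered, if `m0 = 0` everything is; otherwise stage two
#' re-runs BH at the inflated level `Q*m/((1+Q)*m0)`. For `Q = 0.05` the
#' stage-one threshold is `0.047619`. The optional `q_values` are adaptive
#' BH adjusted p-values (`BH * m0/m`), reported for reference; the
#' discovery decisions are the procedure's contract.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param Q Desired false discovery rate (default 0.05).
#' @return An object of class `tcr_bky`: list with `pvalues`, `Q`,
#'   `stage1_threshold`, `r1`, `m0`, `stage2_level`, `discoveries`
#'   (logical, input order) and `q_values`. Has [tidy()] and [glance()]
#'   methods.
#' @export
bky_two_stage <- function(pvalues, Q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]", class = "tcrclonal_data_error")
  }
  m <- length(pvalues)
  q1 <- Q / (1 + Q)
  if (m == 0L) {
    return(structure(list(pvalues = pvalues, Q = Q, stage1_threshold = q1,
                          r1 = 0L, m0 = 0L, stage2_level = NA_real_,
                          discoveries = logical(0), q_values = numeric(0)),
                     class = "tcr_bky"))
  }
  bh_reject <- function(p, level) stats::p.adjust(p, "BH") <= level
  stage1 <- bh_reject(pvalues, q1)
  r1 <- sum(stage1)
  m0 <- m - r1
  if (r1 == 0L) {
    disc <- rep(FALSE, m)
    stage2_level <- q1
  } else if (m0 == 0L) {
    disc <- rep(TRUE, m)
    stage2_level <- 1
  } else {
    stage2_level <- Q * m / ((1 + Q) * m0)
    disc <- bh_reject(pvalues, stage2_level)
  }
  qv <- pmin(stats::p.adjust(pvalues, "BH") * (if (m0 > 0) m0 else m) / m, 1)
  structure(list(pvalues = pvalues, Q = Q, stage1_threshold = q1,
                 r1 = r1, m0 = m0, stage2_level = stage2_level,
                 discoveries = disc, q_values = qv),
            class = "tcr_bky")
}

#' @export
print.tcr_bky <- function(x, ...) {
  cat("Two-stage step-up FDR (Q =", x$Q, ")\n")
  cat("  stage-1 threshold:", format(x$stage1_threshold, digits = 6), "\n")
  cat("  r1 =", x$r1, "; m0 =", x$m0, "; stage-2 level =",
      format(x$stage2_level, digits = 6), "\n")
  cat("  discoveries:", sum(x$discoveries), "of", length(x$pvalues), "\n")
  invisible(x)
}

#' Welch (unequal-variance) t-test
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble(test = "welch_t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value)
}

#' Paired-samples t-test
#'
#' Degenerate pairs (all differences zero) are reported with statistic 0
#' and p-value 1 rather than as an error.
#'
#' @param x,y Numeric samples of equal length (correlated pairs).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort("paired test needs equal-length samples",
          class = "tcrclonal_data_error")
  }
  stopifnot(length(x) >= 2L)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(test = "paired_t", statistic = 0,
                    df = length(x) - 1L, p_value = 1))
    }
    return(tibble(test = "paired_t",
                  statistic = sign(mean(d)) * Inf,
                  df = length(x) - 1L, p_value = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble(test = "paired_t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Exact null distribution for combined sample sizes up to 20 without
#' ties; normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `test`, `statistic` (the U / W statistic),
#'   `p_value`, `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y) <= 20L) && no_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  tibble(test = "mann_whitney_u", statistic = unname(ht$statistic),
         p_value = ht$p.value, exact = use_exact)
}

#' Tetramer-binding rank from index-sort values
#'
#' Rank = (cell tetramer-channel FI / cell FSC) divided by (tetramer-
#' negative population MFI / its mean FSC). Scale-invariant to joint
#' rescaling of all FI or all FSC values.
#'
#' @param fi,fsc Per-cell tetramer-channel fluorescence and forward
#'   scatter (vectors).
#' @param neg_mfi,neg_mean_fsc Tetramer-negative population summary.
#' @return Numeric vector of ranks.
#' @export
tetramer_rank <- function(fi, fsc, neg_mfi, neg_mean_fsc) {
  if (any(fsc <= 0) || any(neg_mfi <= 0) || any(neg_mean_fsc <= 0)) {
    abort("FSC and negative-population denominators must be positive",
          class = "tcrclonal_data_error")
  }
  (fi / fsc) / (neg_mfi / neg_mean_fsc)
}

#' Per-category tetramer-rank summaries
#'
#' Mean and standard error of the tetramer-binding rank per
#' subject-tetramer category.
#'
#' @param cells Cell tibble with `donor`, `tetramer`, `fi_tetramer`,
#'   `fsc` and `plate_id` columns.
#' @param index_negative Per-plate negative-population summary
#'   (`plate_id`, `neg_mfi`, `neg_mean_fsc`).
#' @return Tibble: `donor`, `tetramer`, `n`, `mean_rank`, `sem_rank`.
#' @export
tetramer_rank_summary <- function(cells, index_negative) {
  cells |>
    left_join(index_negative, by = "plate_id") |>
    mutate(rank = tetramer_rank(fi_tetramer, fsc, neg_mfi, neg_mean_fsc)) |>
    group_by(donor, tetramer) |>
    summarise(n = n(), mean_rank = mean(rank),
              sem_rank = sd(rank) / sqrt(n()), .groups = "drop")
}

#' Phenotype skewing report between two cell clusters
#'
#' Per marker, a 2x2 Pearson chi-squared test (no continuity correction)
#' between two disjoint cell clusters on the binarized phenotype bits; the
#' p-value stack is adjusted with [bky_two_stage()]; the fold change of
#' positive fractions is reported, with `fold_label` rounded to the
#' nearest integer when the magnitude is at least 2 (matching "by N fold"
#' phrasing) and to one decimal otherwise.
#'
#' @param cluster_a,cluster_b Cell tibbles (disjoint clusters) holding 0/1
#'   phenotype marker columns.
#' @param markers Marker column names to compare.
#' @param Q Desired FDR for the adjustment.
#' @return A tibble with per-marker counts, fractions, `statistic`,
#'   `p_value`, `q_value`, `discovery`, `fold`, `fold_label`; the
#'   `tcr_bky` object is attached as attribute `"fdr"`.
#' @export
phenotype_skew_report <- function(cluster_a, cluster_b, markers,
                                  Q = 0.05) {
  if (nrow(cluster_a) == 0L || nrow(cluster_b) == 0L) {
    abort("empty cluster", class = "tcrclonal_data_error")
  }
  rows <- purrr::map_dfr(markers, function(m) {
    pa <- sum(cluster_a[[m]]); na <- nrow(cluster_a)
    pb <- sum(cluster_b[[m]]); nb <- nrow(cluster_b)
    st <- chi_squared_skew(pa, na, pb, nb)
    tibble(marker = m, pos_a = pa, n_a = na, frac_a = pa / na,
           pos_b = pb, n_b = nb, frac_b = pb / nb,
           statistic = st$statistic, p_value = st$p_value)
  })
  fdr <- bky_two_stage(rows$p_value, Q = Q)
  rows <- rows |>
    mutate(
      q_value = fdr$q_values,
      discovery = fdr$discoveries,
      fold = frac_a / frac_b,
      fold_label = dplyr::case_when(
        !is.finite(fold) ~ NA_real_,
        abs(fold) >= 2 ~ round_half_up(fold, 0),
        TRUE ~ round_half_up(fold, 1)
      )
    )
  attr(rows, "fdr") <- fdr
  rows
}

#' Phenotype skewing from printed count tables
#'
#' Variant of [phenotype_skew_report()] taking explicit per-marker counts
#' (e.g. counts reconstructed from printed percentages and cluster sizes,
#' as `round(percent * n)`).
#'
#' @param counts Tibble with columns `marker`, `pos_a`, `n_a`, `pos_b`,
#'   `n_b`.
#' @param Q Desired FDR.
#' @return As [phenotype_skew_report()].
#' @export
phenotype_skew_from_counts <- function(counts, Q = 0.05) {
  rows <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    st <- chi_squared_skew(r$pos_a, r$n_a, r$pos_b, r$n_b)
    tibble(marker = r$marker, pos_a = r$pos_a, n_a = r$n_a,
           frac_a = r$pos_a / r$n_a, pos_b = r$pos_b, n_b = r$n_b,
           frac_b = r$pos_b / r$n_b,
           statistic = st$statistic, p_value = st$p_value)
  })
  fdr <- bky_two_stage(rows$p_value, Q = Q)
  rows <- rows |>
    mutate(
      q_value = fdr$q_values,
      discovery = fdr$discoveries,
      fold = frac_a / frac_b,
      fold_label = dplyr::case_when(
        !is.finite(fold) ~ NA_real_,
        abs(fold) >= 2 ~ round_half_up(fold, 0),
        TRUE ~ round_half_up(fold, 1)
      )
    )
  attr(rows, "fdr") <- fdr
  rows
}

#' Competition-binding classification
#'
#' Converts the indicator-peptide binding percentage of a competition
#' assay into percent competition (`100 - percent_binding`) and classifies
#' the competitor: strong (> 75% competition), weak (50-75%), otherwise
#' non-binder.
#'
#' @param percent_binding Numeric vector in `[0, 100]`.
#' @return Tibble: `percent_binding`, `percent_competition`, `class`.
#' @export
percent_competition <- function(percent_binding) {
  if (any(percent_binding < 0 | percent_binding > 100)) {
    abort("percent_binding must lie in [0, 100]",
          class = "tcrclonal_data_error")
  }
  comp <- 100 - percent_binding
  tibble(
    percent_binding = percent_binding,
    percent_competition = comp,
    class = dplyr::case_when(
      comp > 75 ~ "strong",
      comp >= 50 ~ "weak",
      TRUE ~ "non-binder"
    )
  )
}
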