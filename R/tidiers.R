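#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-stage FDR result
#'
#' @param x A `tcr_bky` object.
#' @param ... Unused.
#' @return Tibble, one row per input p-value in input order: `p_value`,
#'   `q_value`, `discovery`.
#' @export
tidy.tcr_bky <- function(x, ...) {
  tibble(p_value = x$pvalues, q_value = x$q_values,
         discovery = x$discoveries)
}

#' One-row summary of a two-stage FDR result
#'
#' @param x A `tcr_bky` object.
#' @param ... Unused.
#' @return One-row tibble: `Q`, `stage1_threshold`, `r1`, `m0`,
#'   `stage2_level`, `n_tests`, `n_discoveries`.
#' @export
glance.tcr_bky <- function(x, ...) {
  tibble(Q = x$Q, stage1_threshold = x$stage1_threshold, r1 = x$r1,
         m0 = x$m0, stage2_level = x$stage2_level,
         n_tests = length(x$pvalues),
         n_discoveries = sum(x$discoveries))
}

#' Tidy a pipeline result
#'
#' @param x A `tcr_pipeline` object.
#' @param ... Unused.
#' @return The clonotype table.
#' @export
tidy.tcr_pipeline <- function(x, ...) x$clonotypes

#' One-row summary of a pipeline result
#'
#' @param x A `tcr_pipeline` object.
#' @param ... Unused.
#' @return One-row tibble with the headline accounting: wells, coverage,
#'   analyzed cells, clonotypes, expanded / highly expanded /
#'   cross-binding clonotypes, skewing discoveries.
#' @export
glance.tcr_pipeline <- function(x, ...) {
  tibble(
    n_wells = x$coverage$n_wells,
    coverage_pct = x$coverage$coverage_pct,
    n_analyzed_cells = nrow(x$analyzed),
    n_clonotypes = nrow(x$clonotypes),
    n_expanded = sum(x$clonotypes$expanded),
    n_highly_expanded = sum(x$clonotypes$highly_expanded),
    n_cross_binding = sum(x$clonotypes$cross_binding),
    n_discoveries = sum(x$skew_tests$discovery)
  )
}
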