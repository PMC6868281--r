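#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols n n_distinct row_number distinct
#'   rename count pull if_else first slice desc group_map pick
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rnorm rlnorm rnbinom rpois runif pbinom pchisq
#'   setNames sd
#' @importFrom utils head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Translate a nucleotide string to amino acids
#'
#' Standard-code translation via codon lookup against
#' [Biostrings::GENETIC_CODE]. Tolerates sequences whose length is not a
#' multiple of three (trailing bases are dropped, as for an out-of-frame
#' junction); unresolvable codons become `X`.
#'
#' @param nt A nucleotide string.
#' @return An amino-acid string; `""` for input shorter than one codon.
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  if (n < 3L) return("")
  n <- n - (n %% 3L)
  starts <- seq.int(1L, n, 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Stop-free codon alphabet used when composing synthetic germline bodies.
stopfree_codons <- function() {
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

random_codons <- function(n) {
  paste(sample(stopfree_codons(), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Position-weighted name hash for per-name deterministic seeds; a plain
# character sum collides for anagram-like names (e.g. GZMB vs SELL).
name_seed <- function(nm) {
  x <- utf8ToInt(nm)
  as.integer(sum(x * seq_along(x) * 131L) %% 1000003L)
}

# Lowercase roman numerals are never used in the exports; groups are keyed
# I, II, ... like sharing-group labels on repertoire heatmaps.
as_roman_label <- function(i) as.character(utils::as.roman(i))

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
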