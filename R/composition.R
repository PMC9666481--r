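#' Strand-asymmetry skew
#'
#' The skew statistic `(x - y) / (x + y)` used for mitochondrial strand
#' asymmetry: AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C).
#' Accepts raw counts or percentages (the statistic is scale-free).
#'
#' @param x,y nonnegative counts or percentages of the two bases
#'   (A and T, or G and C). Vectorized.
#' @return dimensionless value in `[-1, 1]`; `NA` when `x + y == 0`
#'   (skew undefined).
#' @export
#' @examples
#' skew(38.46, 39.29)  # AT-skew of a 77.75% A+T genome
skew <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop("skew inputs must be nonnegative")
  out <- (x - y) / (x + y)
  out[(x + y) == 0] <- NA_real_
  out
}

#' Base composition and skew statistics of a sequence
#'
#' Counts `A,C,G,T` (characters outside the alphabet are tallied as
#' `n_other` and excluded from skew numerators and denominators),
#' percentages of total length, A+T% and G+C%, and AT/GC skews.
#'
#' @param seq DNA string.
#' @param region_name label carried into the output.
#' @return one-row `data.frame` with columns `region`, `n_A`..`n_other`,
#'   `pct_A`..`pct_T`, `pct_other`, `pct_AT`, `pct_GC`, `at_skew`, `gc_skew`.
#' @export
base_composition <- function(seq, region_name = "region") {
  if (is.null(seq) || !nzchar(seq)) stop("empty sequence")
  ch <- seq_chars(seq)
  n <- length(ch)
  cnt <- c(A = sum(ch == "A"), C = sum(ch == "C"),
           G = sum(ch == "G"), T = sum(ch == "T"))
  other <- n - sum(cnt)
  pct <- 100 * cnt / n
  data.frame(region = region_name,
             n_A = cnt[["A"]], n_C = cnt[["C"]], n_G = cnt[["G"]],
             n_T = cnt[["T"]], n_other = other,
             pct_A = pct[["A"]], pct_C = pct[["C"]], pct_G = pct[["G"]],
             pct_T = pct[["T"]], pct_other = 100 * other / n,
             pct_AT = pct[["A"]] + pct[["T"]],
             pct_GC = pct[["G"]] + pct[["C"]],
             at_skew = skew(cnt[["A"]], cnt[["T"]]),
             gc_skew = skew(cnt[["G"]], cnt[["C"]]),
             stringsAsFactors = FALSE)
}

#' Per-region composition table
#'
#' Computes a composition/skew row for each requested region of an annotated
#' mitogenome, in the layout of published mitogenome composition tables:
#' by default the whole genome (deposited strand), each PCG and rRNA on its
#' reading orientation, a pooled `tRNA` row concatenating all tRNAs in their
#' reading orientations, and the control region when present. Computing
#' gene rows on the reading orientation (J-strand genes on the complement)
#' is what produces the characteristic sign flip of GC skew between
#' N-encoded and J-encoded genes.
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param regions optional character vector of region selectors: feature
#'   names, `"whole_genome"`, and/or `"tRNA"` (pooled). Default layout when
#'   `NULL`.
#' @return `data.frame`, one row per region.
#' @export
per_region_composition <- function(record, regions = NULL) {
  stop_if_no_sequence(record)
  f <- record$features
  if (is.null(regions)) {
    regions <- c("whole_genome",
                 f$name[f$feature_class %in% c("PCG", "rRNA")],
                 if (any(f$feature_class == "tRNA")) "tRNA",
                 f$name[f$feature_class == "control_region"])
  }
  known <- c("whole_genome", "tRNA", f$name)
  bad <- setdiff(regions, known)
  if (length(bad))
    stop("unknown region name(s): ", paste(bad, collapse = ", "),
         "; known: whole_genome, tRNA, ", paste(f$name, collapse = ", "))
  rows <- lapply(regions, function(r) {
    s <- if (r == "whole_genome") record$sequence
    else if (r == "tRNA")
      paste(vapply(which(f$feature_class == "tRNA"),
                   function(i) extract_region(record, i), character(1)),
            collapse = "")
    else extract_region(record, r)
    base_composition(s, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a composition table to reporting precision
#'
#' Percentages to 2 decimals and skews to 3 decimals, the precision at which
#' mitogenome composition tables are conventionally printed. Internal
#' computation elsewhere stays at full precision.
#'
#' @param comp output of [per_region_composition()] or [base_composition()].
#' @return `data.frame` with rounded reporting columns.
#' @export
format_composition <- function(comp) {
  pctc <- grep("^pct_", names(comp), value = TRUE)
  comp[pctc] <- lapply(comp[pctc], round, 2)
  comp[c("at_skew", "gc_skew")] <- lapply(comp[c("at_skew", "gc_skew")],
                                          round, 3)
  comp
}
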