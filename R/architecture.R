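#' Junction spacing analysis
#'
#' One row per consecutive feature pair in genomic order: signed spacing
#' `downstream$start - upstream$end - 1` (positive = intergenic gap,
#' negative = overlap, 0 = abutting). On circular records a closure
#' junction from the last feature back to the first is appended, with
#' spacing `L + first$start - last$end - 1`.
#'
#' @param record a `mitogenome_record` (sequence not required).
#' @param closure include the circular closure junction (default `TRUE`
#'   when the record is circular).
#' @return `data.frame` with columns `upstream`, `downstream`, `spacing`,
#'   `is_circular_closure`.
#' @export
junction_analysis <- function(record, closure = record$circular) {
  f <- record$features
  if (nrow(f) < 2) stop("need at least 2 features for junction analysis")
  if (is.unsorted(f$start)) {
    warning("features not sorted by start; sorting")
    f <- f[order(f$start), , drop = FALSE]
  }
  if (anyDuplicated(f[c("start", "end")]))
    stop("duplicated feature coordinates")
  n <- nrow(f)
  sp <- f$start[-1L] - f$end[-n] - 1L
  out <- data.frame(upstream = f$name[-n], downstream = f$name[-1L],
                    spacing = as.integer(sp),
                    is_circular_closure = FALSE, stringsAsFactors = FALSE)
  if (isTRUE(closure)) {
    if (is.null(record$length)) stop("circular closure needs genome length")
    out <- rbind(out, data.frame(
      upstream = f$name[n], downstream = f$name[1L],
      spacing = as.integer(record$length + f$start[1L] - f$end[n] - 1L),
      is_circular_closure = TRUE, stringsAsFactors = FALSE))
  }
  out
}

#' Junctions from a printed intergenic-nucleotide column
#'
#' Organization tables print the junction spacing on the row of the
#' upstream feature; the last row's value is the circular closure. This
#' reconstructs the junction table from those printed values (carried by
#' [make_paper_fixture()] records as the `intergenic_printed` attribute
#' column), treating blanks as 0 (abutting). Printed columns are the
#' authoritative path when reproducing a published table's own totals,
#' which can differ by small annotation artifacts from the
#' coordinate-derived path of [junction_analysis()].
#'
#' @param record a `mitogenome_record` whose `extra_columns`/fixture
#'   attribute carries `intergenic_printed`, or a data.frame with columns
#'   `name` and `intergenic_printed`.
#' @return `data.frame` in the layout of [junction_analysis()].
#' @export
junctions_from_printed <- function(record) {
  if (inherits(record, "mitogenome_record")) {
    tab <- attr(record, "printed")
    if (is.null(tab)) stop("record carries no printed intergenic column")
  } else tab <- record
  n <- nrow(tab)
  sp <- clean_int(tab$intergenic_printed)
  sp[is.na(sp)] <- 0L
  data.frame(upstream = tab$name,
             downstream = c(tab$name[-1L], tab$name[1L]),
             spacing = sp,
             is_circular_closure = c(rep(FALSE, n - 1L), TRUE),
             stringsAsFactors = FALSE)
}

#' Strand census
#'
#' @param features feature `data.frame`.
#' @return named integer vector `c(J = ..., N = ...)`.
#' @export
strand_census <- function(features) {
  if (nrow(features) == 0) stop("empty feature list")
  bad <- setdiff(unique(features$strand), c("J", "N"))
  if (length(bad)) stop("unknown strand label(s): ", paste(bad, collapse = ", "))
  c(J = sum(features$strand == "J"), N = sum(features$strand == "N"))
}

#' Summed length per feature class
#'
#' @param features feature `data.frame`.
#' @param genome_length genome length (for origin-spanning features).
#' @return named numeric vector over the classes present (absent class = 0
#'   when queried).
#' @export
class_totals <- function(features, genome_length = NULL) {
  len <- feature_lengths(features, genome_length)
  out <- tapply(len, factor(features$feature_class,
                            c("PCG", "tRNA", "rRNA", "control_region")), sum)
  out[is.na(out)] <- 0
  out
}

#' Architecture summary of a mitogenome
#'
#' Aggregates a junction table and feature list into the bookkeeping
#' reported for new mitogenomes: number/total/range of overlaps and of
#' intergenic spacers, strand census, per-class length totals, and the
#' tRNA length range.
#'
#' @param junctions output of [junction_analysis()] or
#'   [junctions_from_printed()].
#' @param features feature `data.frame`.
#' @param include_closure count the circular closure junction (default
#'   `TRUE`).
#' @param genome_length genome length (for origin-spanning features).
#' @return object of class `architecture_summary` (a list).
#' @export
summarize_architecture <- function(junctions, features,
                                   include_closure = TRUE,
                                   genome_length = NULL) {
  if (is.null(junctions) || nrow(junctions) == 0) {
    warning("empty junction list; all-zero summary")
    junctions <- data.frame(upstream = character(), downstream = character(),
                            spacing = integer(),
                            is_circular_closure = logical())
  }
  if (!include_closure)
    junctions <- junctions[!junctions$is_circular_closure, , drop = FALSE]
  ov <- -junctions$spacing[junctions$spacing < 0]
  gp <- junctions$spacing[junctions$spacing > 0]
  rng <- function(x) if (length(x)) range(x) else c(NA_integer_, NA_integer_)
  len <- if (nrow(features)) feature_lengths(features, genome_length) else integer()
  trna <- len[features$feature_class == "tRNA"]
  structure(list(
    n_overlaps = length(ov), overlap_total_bp = sum(ov),
    overlap_range = rng(ov),
    n_gaps = length(gp), gap_total_bp = sum(gp), gap_range = rng(gp),
    strand_counts = if (nrow(features)) strand_census(features)
                    else c(J = 0L, N = 0L),
    class_totals = class_totals(features, genome_length),
    trna_length_range = rng(trna),
    n_junctions = nrow(junctions)), class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("<architecture_summary>\n")
  cat(sprintf("  overlaps: %d totaling %d bp (range %s-%s)\n",
              x$n_overlaps, x$overlap_total_bp,
              x$overlap_range[1], x$overlap_range[2]))
  cat(sprintf("  spacers:  %d totaling %d bp (range %s-%s)\n",
              x$n_gaps, x$gap_total_bp, x$gap_range[1], x$gap_range[2]))
  cat(sprintf("  strands:  J=%d N=%d\n",
              x$strand_counts[["J"]], x$strand_counts[["N"]]))
  ct <- x$class_totals
  cat("  class bp: ", paste(names(ct), ct, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  tRNA length range: %s-%s\n",
              x$trna_length_range[1], x$trna_length_range[2]))
  invisible(x)
}

#' Check an annotated tRNA anticodon against the sequence
#'
#' Scans the central third of the tRNA's reading-orientation sequence (a
#' heuristic window for the anticodon loop) for the annotated triplet.
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param feature a tRNA feature (name, index or one-row data.frame) with
#'   an `anticodon` annotation.
#' @return list with `found` (logical) and `position` (1-based offset of
#'   the first in-window match in the reading-orientation sequence, or
#'   `NA`).
#' @export
anticodon_check <- function(record, feature) {
  f <- resolve_feature(record, feature)
  if (f$feature_class != "tRNA")
    stop("anticodon_check requires a tRNA feature ('", f$name, "')")
  if (is.na(f$anticodon)) stop("feature '", f$name, "' has no anticodon annotation")
  s <- extract_region(record, f)
  n <- nchar(s)
  lo <- max(1L, floor(n / 3))
  hi <- min(n, ceiling(2 * n / 3))
  window <- substr(s, lo, hi)
  hit <- regexpr(toupper(f$anticodon), window, fixed = TRUE)
  if (hit > 0) list(found = TRUE, position = lo + as.integer(hit) - 1L)
  else list(found = FALSE, position = NA_integer_)
}
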