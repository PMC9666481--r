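#' Construct a gene feature table row
#'
#' A gene feature is one annotated region of a mitogenome: a protein-coding
#' gene (PCG), tRNA, rRNA or control region. Coordinates are 1-based and
#' inclusive on both ends, as in published mitogenome organization tables.
#' Strands use the tick-mitogenomics J/N labels (majority/minority); the
#' deposited sequence orientation is taken as the N reading orientation, so
#' J features are read as the reverse complement (see
#' [extract_region()]).
#'
#' @param name gene label, e.g. `"cox1"`, `"trnK"`, `"rrnL"`, `"OH"`.
#' @param feature_class one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`.
#' @param strand `"J"` or `"N"`.
#' @param start,end 1-based inclusive coordinates; `end >= start` unless
#'   `origin_spanning`.
#' @param origin_spanning logical; `TRUE` for a feature crossing the circular
#'   origin (then `end < start` is allowed).
#' @param anticodon optional 3-letter triplet (tRNA only).
#' @param start_codon,stop_codon optional codon annotations (PCG only);
#'   stop may be an incomplete `"T"`/`"TA"` or the `"T(AA)"`/`"TA(A)"`
#'   polyadenylation notation.
#' @return a one-row `data.frame` suitable for `rbind`-ing into a feature table.
#' @export
gene_feature <- function(name, feature_class, strand, start, end,
                         origin_spanning = FALSE, anticodon = NA_character_,
                         start_codon = NA_character_, stop_codon = NA_character_) {
  feature_class <- match.arg(feature_class,
                             c("PCG", "tRNA", "rRNA", "control_region"))
  strand <- match.arg(strand, c("J", "N"))
  start <- clean_int(start); end <- clean_int(end)
  if (is.na(start) || is.na(end) || start < 1)
    stop("invalid coordinates for feature '", name, "'")
  if (end < start && !origin_spanning)
    stop("end < start for feature '", name, "' without origin_spanning flag")
  if (!is.na(anticodon) && feature_class != "tRNA")
    stop("anticodon only allowed on tRNA features ('", name, "')")
  if ((!is.na(start_codon) || !is.na(stop_codon)) && feature_class != "PCG")
    stop("codon fields only allowed on PCG features ('", name, "')")
  data.frame(name = name, feature_class = feature_class, strand = strand,
             start = start, end = end, origin_spanning = origin_spanning,
             anticodon = anticodon, start_codon = start_codon,
             stop_codon = stop_codon, stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome record
#'
#' The central container of the package: a (usually circular) mitochondrial
#' genome sequence plus its ordered feature annotation. The sequence may be
#' absent ("table-only" mode, e.g. a record built from a printed organization
#' table); sequence-dependent operations then refuse with an informative error.
#'
#' @param record_id identifier.
#' @param features feature `data.frame` as built by [gene_feature()].
#' @param sequence optional DNA string over `A,C,G,T,N`.
#' @param length genome length; mandatory when `sequence` is absent and any
#'   feature is origin-spanning, otherwise inferred.
#' @param circular logical, default `TRUE`.
#' @return an object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(record_id, features, sequence = NULL,
                              length = NULL, circular = TRUE) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
      stop("sequence contains characters outside {A,C,G,T,N}")
    if (!is.null(length) && length != nchar(sequence))
      stop("declared length disagrees with sequence length")
    length <- nchar(sequence)
  }
  if (nrow(features) > 0) {
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    if (is.null(length)) length <- max(features$end)
    bad <- !features$origin_spanning & features$end > length
    if (any(bad))
      stop("feature(s) beyond genome length: ",
           paste(features$name[bad], collapse = ", "))
  }
  structure(list(record_id = record_id, sequence = sequence,
                 length = length, circular = circular, features = features),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat("<mitogenome_record> ", x$record_id, "\n", sep = "")
  cat("  length:   ", x$length,
      if (is.null(x$sequence)) " bp (table-only, no sequence)" else " bp",
      if (x$circular) ", circular" else ", linear", "\n", sep = "")
  cls <- table(x$features$feature_class)
  cat("  features: ", nrow(x$features), " (",
      paste(names(cls), as.integer(cls), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Feature lengths in nucleotides
#'
#' Length of each feature from its coordinates; origin-spanning features
#' contribute `(L - start + 1) + end` on a genome of length `L`.
#'
#' @param features feature `data.frame`.
#' @param genome_length genome length `L` (needed only for origin-spanning
#'   features).
#' @return integer vector.
#' @export
feature_lengths <- function(features, genome_length = NULL) {
  len <- features$end - features$start + 1L
  sp <- which(features$origin_spanning)
  if (length(sp)) {
    if (is.null(genome_length))
      stop("genome_length required for origin-spanning features")
    len[sp] <- (genome_length - features$start[sp] + 1L) + features$end[sp]
  }
  as.integer(len)
}

#' Validate a mitogenome record
#'
#' Structural checks plus the optional 37-gene completeness check typical of
#' complete metazoan mitogenomes (13 PCGs + 22 tRNAs + 2 rRNAs).
#'
#' @param record a `mitogenome_record`.
#' @param require_37 logical; error when the 13/22/2 census fails.
#' @return `TRUE` invisibly on success.
#' @export
validate_mitogenome <- function(record, require_37 = FALSE) {
  stopifnot(inherits(record, "mitogenome_record"))
  f <- record$features
  if (anyDuplicated(f[c("start", "end")]))
    stop("duplicated feature coordinates")
  cnt <- c(PCG = sum(f$feature_class == "PCG"),
           tRNA = sum(f$feature_class == "tRNA"),
           rRNA = sum(f$feature_class == "rRNA"))
  ok <- identical(unname(cnt), c(13L, 22L, 2L))
  if (require_37 && !ok)
    stop("not a complete 37-gene mitogenome: ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "))
  invisible(TRUE)
}

stop_if_no_sequence <- function(record) {
  if (is.null(record$sequence))
    stop("sequence required: record '", record$record_id, "' is table-only")
}

#' Extract a feature's sequence in reading orientation
#'
#' Returns the subsequence of the deposited genome covered by a feature, in
#' the feature's reading orientation: N-strand features are returned as
#' deposited, J-strand features reverse-complemented. Origin-spanning
#' features on circular genomes concatenate the tail and head of the
#' deposited sequence.
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param feature a feature name, row index, or one-row feature `data.frame`.
#' @return DNA string.
#' @export
extract_region <- function(record, feature) {
  stop_if_no_sequence(record)
  f <- resolve_feature(record, feature)
  s <- record$sequence
  if (f$origin_spanning) {
    if (!record$circular) stop("origin-spanning feature on a linear record")
    sub <- paste0(substr(s, f$start, record$length), substr(s, 1L, f$end))
  } else {
    sub <- substr(s, f$start, f$end)
  }
  if (f$strand == "J") revcomp(sub) else sub
}

resolve_feature <- function(record, feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    return(feature)
  }
  f <- record$features
  if (is.character(feature)) {
    i <- which(f$name == feature)
    if (length(i) == 0)
      stop("unknown region name '", feature, "'; known: ",
           paste(f$name, collapse = ", "))
    if (length(i) > 1) stop("ambiguous feature name '", feature, "'")
  } else {
    i <- as.integer(feature)
    stopifnot(i >= 1, i <= nrow(f))
  }
  f[i, , drop = FALSE]
}
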