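#' Genetic code table
#'
#' Codon-to-amino-acid map for an NCBI translation table. Defaults to
#' table 5 (invertebrate mitochondrial), the standard code for tick
#' (Ixodida) mitogenomes: ATA=Met, TGA=Trp, AGA/AGG=Ser; stops TAA, TAG.
#'
#' @param table_id NCBI translation table number (default 5).
#' @return list with `table_id`, `codon_map` (named character vector of 64
#'   codons, `*` marking stops) and `stops` (stop codons).
#' @export
genetic_code <- function(table_id = 5) {
  cm <- Biostrings::getGeneticCode(as.character(table_id))
  cm <- stats::setNames(as.character(cm), chartr("U", "T", names(cm)))
  stopifnot(length(cm) == 64)
  list(table_id = table_id, codon_map = cm, stops = names(cm)[cm == "*"])
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length ", n, " not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Extract a CDS with incomplete-stop completion
#'
#' Extracts a protein-coding gene's reading-orientation sequence and, when
#' the annotated length is not a codon multiple, completes the truncated
#' terminal stop by the polyadenylation convention: a trailing `T` becomes
#' `TAA` (length mod 3 = 1), a trailing `TA` becomes `TAA` (mod 3 = 2).
#' Such incomplete stops arise where a gene is truncated at the junction
#' with its downstream neighbour and the mRNA stop is restored by
#' polyadenylation; organization tables print them as `T(AA)`/`TA(A)`.
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param feature a PCG feature (name, index or one-row data.frame).
#' @return list with `cds` (completed, length divisible by 3) and
#'   `completion` (`"none"`, `"T(AA)"` or `"TA(A)"`).
#' @export
extract_cds <- function(record, feature) {
  f <- resolve_feature(record, feature)
  if (f$feature_class != "PCG")
    stop("extract_cds requires a PCG feature ('", f$name, "')")
  s <- extract_region(record, f)
  r <- nchar(s) %% 3
  if (r == 0) return(list(cds = s, completion = "none"))
  tail <- substr(s, nchar(s) - (if (r == 1) 0 else 1), nchar(s))
  if (r == 1 && tail == "T")
    list(cds = paste0(s, "AA"), completion = "T(AA)")
  else if (r == 2 && tail == "TA")
    list(cds = paste0(s, "A"), completion = "TA(A)")
  else
    stop("not an incomplete stop: '", f$name, "' ends in '", tail,
         "' with length mod 3 = ", r)
}

#' Translate a CDS
#'
#' Frame-0 per-codon translation under a [genetic_code()]; a terminal stop
#' codon is dropped, an internal stop is an error naming the codon
#' position.
#'
#' @param cds DNA string, length divisible by 3.
#' @param code a [genetic_code()] (default table 5).
#' @return amino-acid string (one-letter).
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  codons <- split_codons(toupper(cds))
  aa <- unname(code$codon_map[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  n <- length(aa)
  if (n && aa[n] == "*") aa <- aa[-n]
  internal <- which(aa == "*")
  if (length(internal))
    stop("internal stop codon at codon ", internal[1])
  paste(aa, collapse = "")
}

#' Start/stop codon census over the protein-coding genes
#'
#' Per-gene initiation and termination codons read from the sequence, with
#' incomplete stops reported in `T(AA)`/`TA(A)` notation. A start codon
#' outside the mitochondrial `ATN` set is kept verbatim with a warning.
#'
#' @param record a `mitogenome_record` with sequence and PCG features.
#' @return `data.frame` with columns `gene`, `start_codon`, `stop_codon`;
#'   aggregate counts in attributes `start_counts` and `stop_counts`.
#' @export
start_stop_census <- function(record) {
  stop_if_no_sequence(record)
  pcg <- which(record$features$feature_class == "PCG")
  if (!length(pcg)) stop("record has no PCG features")
  rows <- lapply(pcg, function(i) {
    ec <- extract_cds(record, i)
    stop_c <- if (ec$completion == "none")
      substr(ec$cds, nchar(ec$cds) - 2, nchar(ec$cds)) else ec$completion
    data.frame(gene = record$features$name[i],
               start_codon = substr(ec$cds, 1, 3),
               stop_codon = stop_c, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  notATN <- !grepl("^AT[ACGT]$", out$start_codon)
  if (any(notATN))
    warning("non-ATN start codon(s): ",
            paste0(out$gene[notATN], "=", out$start_codon[notATN],
                   collapse = ", "))
  attr(out, "start_counts") <- table(out$start_codon)
  attr(out, "stop_counts") <- table(out$stop_codon)
  out
}

#' Relative synonymous codon usage
#'
#' Codon counts over a set of CDSs (frame 0 of each), RSCU values and
#' amino-acid frequencies. RSCU of a codon is its observed count times the
#' size of its synonymous family, divided by the family's total count
#' (1 = uniform use within the family; 0 when the amino acid is absent).
#' Stop codons - complete or completed - are excluded from both RSCU and
#' the amino-acid totals by default; start codons are counted as the amino
#' acid they encode (not forced to Met).
#'
#' @param cds_set character vector or list of CDS strings (each length
#'   divisible by 3; run [extract_cds()] first for incomplete stops).
#' @param code a [genetic_code()].
#' @param exclude_stops drop stop codons from counts (default `TRUE`).
#' @return object of class `codon_usage_table`: list with `codons`
#'   (data.frame codon/aa/count/rscu), `aa_counts`, `aa_freq` (percent),
#'   `total_aa`, `table_id`.
#' @export
rscu <- function(cds_set, code = genetic_code(), exclude_stops = TRUE) {
  cds_set <- unlist(cds_set, use.names = FALSE)
  if (!length(cds_set)) stop("need at least one CDS")
  codons <- unlist(lapply(toupper(cds_set), split_codons))
  codons <- codons[codons %in% names(code$codon_map)]  # drop ambiguous
  if (exclude_stops) codons <- codons[!codons %in% code$stops]
  cnt <- table(factor(codons, levels = names(code$codon_map)))
  df <- data.frame(codon = names(code$codon_map),
                   aa = unname(code$codon_map),
                   count = as.integer(cnt), stringsAsFactors = FALSE)
  if (exclude_stops) df <- df[df$aa != "*", , drop = FALSE]
  fam_size <- ave(rep(1L, nrow(df)), df$aa, FUN = sum)
  fam_total <- ave(df$count, df$aa, FUN = sum)
  df$rscu <- ifelse(fam_total > 0, df$count * fam_size / fam_total, 0)
  aa_counts <- tapply(df$count, df$aa, sum)
  total <- sum(df$count)
  structure(list(codons = df,
                 aa_counts = aa_counts,
                 aa_freq = 100 * aa_counts / total,
                 total_aa = total,
                 table_id = code$table_id),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table> ", x$total_aa, " amino acids, NCBI table ",
      x$table_id, "\n", sep = "")
  top <- utils::head(sort(x$aa_freq, decreasing = TRUE), 5)
  cat("  top residues: ",
      paste(sprintf("%s %.2f%%", names(top), top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Amino-acid frequency ranking
#'
#' @param table a `codon_usage_table` from [rscu()].
#' @return `data.frame` with `aa`, `count`, `pct`, sorted by decreasing
#'   usage.
#' @export
aa_frequencies <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (table$total_aa == 0) stop("empty codon usage table")
  out <- data.frame(aa = names(table$aa_counts),
                    count = as.integer(table$aa_counts),
                    pct = as.numeric(table$aa_freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct, out$aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
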