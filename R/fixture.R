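#' Packaged organization tables for two Haemaphysalis mitogenomes
#'
#' Returns table-only [mitogenome_record()]s for the published
#' *H. nepalensis* and *H. yeni* mitogenome organization tables (gene
#' names, strands, 1-based coordinates, codon and anticodon annotations,
#' and the printed intergenic-nucleotide column). These are annotation
#' tables as printed - including their known oddities, flagged in the
#' `note` column of the underlying CSV (wildly differing printed rRNA
#' lengths, a closure spacing that is off by one from the coordinates).
#' The printed whole-genome sizes (14,720 and 14,895 bp) are carried as
#' metadata; they, like amino-acid totals, are properties of the deposited
#' sequences and are not recomputable from the table alone.
#'
#' Each record carries two attributes: `printed` (the verbatim table,
#' including `length_printed` and `intergenic_printed` for
#' [junctions_from_printed()]) and `printed_genome_length`.
#'
#' @return named list of two `mitogenome_record`s: `nepalensis` (38
#'   features, incl. the OH control region) and `yeni` (37 features, no
#'   control region).
#' @export
make_paper_fixture <- function() {
  path <- system.file("extdata", "table1_haemaphysalis.csv",
                      package = "mitocomp", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  sizes <- c(nepalensis = 14720L, yeni = 14895L)
  out <- lapply(c(nepalensis = "nepalensis", yeni = "yeni"), function(sp) {
    df <- tab[tab$species == sp, , drop = FALSE]
    feats <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      gene_feature(df$name[i], df$feature_class[i], df$strand[i],
                   df$start[i], df$end[i],
                   anticodon = na_if_blank(df$anticodon[i],
                                           df$feature_class[i] == "tRNA"),
                   start_codon = na_if_blank(df$start_codon[i],
                                             df$feature_class[i] == "PCG"),
                   stop_codon = na_if_blank(df$stop_codon[i],
                                            df$feature_class[i] == "PCG"))
    }))
    rec <- mitogenome_record(paste0("Haemaphysalis_", sp), feats,
                             length = sizes[[sp]], circular = TRUE)
    attr(rec, "printed") <- df
    attr(rec, "printed_genome_length") <- sizes[[sp]]
    rec
  })
  out
}

#' Printed whole-genome composition rows for the fixture species
#'
#' The published whole-genome and cox1 composition percentages for the two
#' fixture mitogenomes, as printed (2-decimal percentages). These are
#' inputs for skew recomputation, not outputs of this package; the second
#' species' whole-genome A+T is printed inconsistently in its source
#' (78.41 in the abstract vs a row summing to 78.39), flagged here
#' verbatim via both columns.
#'
#' @return `data.frame` with columns `species`, `region`, `pct_A`, `pct_C`,
#'   `pct_G`, `pct_T`, `pct_AT_printed`, `pct_GC_printed`.
#' @export
printed_composition <- function() {
  data.frame(
    species = c("nepalensis", "yeni", "nepalensis", "yeni"),
    region = c("whole_genome", "whole_genome", "cox1", "cox1"),
    pct_A = c(38.46, 38.65, 31.04, 31.50),
    pct_C = c(12.74, 12.28, 16.08, 15.07),
    pct_G = c(9.51, 9.31, 14.63, 14.10),
    pct_T = c(39.29, 39.74, 38.25, 39.31),
    pct_AT_printed = c(77.75, 78.39, 69.29, 70.81),
    pct_GC_printed = c(22.25, 21.59, 30.71, 29.17),
    stringsAsFactors = FALSE)
}
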