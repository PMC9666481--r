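#' Characterize one or more mitogenomes and write a report bundle
#'
#' Runs the composition, architecture and codon-usage stages end-to-end
#' for each input genome and writes per-genome TSV/JSON reports shaped
#' like the tables of a mitogenome announcement: an organization table
#' (gene, strand, coordinates, length, codons, junction spacing), a
#' composition/skew table, a start/stop codon census, a per-codon RSCU
#' table and a JSON architecture summary. Table-only inputs (no sequence)
#' produce the organization report only; sequence-dependent reports are
#' skipped with a notice.
#'
#' @param genomes list of `mitogenome_record`s and/or file paths (GenBank
#'   flat file, `.tbl`, or CSV/TSV feature table).
#' @param out_dir output directory (created if needed).
#' @param code_id NCBI translation table (default 5, invertebrate
#'   mitochondrial).
#' @return invisible named list of per-genome result lists (`composition`,
#'   `architecture`, `census`, `rscu`, paths of files written).
#' @export
run_characterize <- function(genomes, out_dir, code_id = 5) {
  if (inherits(genomes, "mitogenome_record")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- genetic_code(code_id)
  out <- lapply(genomes, function(g) {
    if (is.character(g)) {
      g <- if (grepl("\\.(gb|gbk|genbank)$", g, ignore.case = TRUE))
        read_genbank(g) else read_feature_table(g)
    }
    stopifnot(inherits(g, "mitogenome_record"))
    id <- gsub("[^A-Za-z0-9_.-]", "_", g$record_id)
    res <- list(record = g)
    jn <- junction_analysis(g)
    org <- g$features
    org$length <- feature_lengths(org, g$length)
    org$spacing_after <- c(jn$spacing[match(org$name, jn$upstream)])
    utils::write.table(org, file.path(out_dir, paste0(id, "_organization.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_architecture(jn, g$features, genome_length = g$length)
    res$architecture <- summ
    jsonlite::write_json(
      list(record_id = g$record_id, genome_length = g$length,
           n_features = nrow(g$features), summary = unclass(summ)),
      file.path(out_dir, paste0(id, "_architecture.json")),
      auto_unbox = TRUE, digits = NA)
    if (is.null(g$sequence)) {
      message("record '", g$record_id,
              "' is table-only; composition/codon reports skipped")
      return(res)
    }
    comp <- format_composition(per_region_composition(g))
    utils::write.table(comp, file.path(out_dir, paste0(id, "_composition.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$composition <- comp
    census <- start_stop_census(g)
    utils::write.table(census, file.path(out_dir, paste0(id, "_codon_census.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$census <- census
    pcg <- which(g$features$feature_class == "PCG")
    cds <- vapply(pcg, function(i) extract_cds(g, i)$cds, character(1))
    usage <- rscu(cds, code)
    utils::write.table(usage$codons, file.path(out_dir, paste0(id, "_rscu.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$rscu <- usage
    res
  })
  names(out) <- vapply(out, function(x) x$record$record_id, character(1))
  invisible(out)
}

#' Concatenation-to-bootstrap phylogeny run
#'
#' Orchestrates the phylogeny stage: per-gene alignments are concatenated,
#' filtered by complete deletion, converted to distances, and a Minimum
#' Evolution tree (NJ start, OLS branch lengths, NNI search) with
#' bootstrap support is written as newick, together with the distance
#' matrix (PHYLIP square) and a support table.
#'
#' @param alignments named list of alignments/file paths (see
#'   [concatenate_alignments()]), or a directory containing aligned FASTA
#'   files (`.fa`, `.fasta`).
#' @param out_dir output directory.
#' @param model distance model (`"p"`, `"jc69"`, `"k2p"`).
#' @param n_boot bootstrap replicates (0 = point estimate only).
#' @param seed seed for the bootstrap resampler.
#' @return invisible list with `tree`, `distances`, `alignment` and file
#'   paths.
#' @export
run_phylo <- function(alignments, out_dir, model = "k2p", n_boot = 100L,
                      seed = 1L) {
  if (is.character(alignments) && length(alignments) == 1 &&
      dir.exists(alignments)) {
    paths <- list.files(alignments, "\\.(fa|fasta)$", full.names = TRUE)
    if (!length(paths)) stop("no FASTA files in ", alignments)
    alignments <- stats::setNames(as.list(paths),
                                  sub("\\.(fa|fasta)$", "", basename(paths)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- complete_deletion(concatenate_alignments(alignments))
  d <- dist_matrix(aln, model)
  tree <- if (n_boot >= 1) bootstrap_support(aln, model, n_boot, seed)
          else me_tree(aln, model)
  write_phylip_dist(d, file.path(out_dir, "distances.phy"))
  write_newick(tree, file.path(out_dir, "me_tree.nwk"))
  st <- attr(tree, "support_table")
  if (!is.null(st))
    utils::write.table(st, file.path(out_dir, "support.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(tree = tree, distances = d, alignment = aln,
                 files = file.path(out_dir,
                                   c("distances.phy", "me_tree.nwk",
                                     if (!is.null(st)) "support.tsv"))))
}
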