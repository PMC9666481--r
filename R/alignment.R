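as_alignment <- function(m, gene_bounds = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate taxon labels")
  if (is.null(gene_bounds))
    gene_bounds <- data.frame(gene = "all", start = 1L,
                              end = ncol(m), stringsAsFactors = FALSE)
  structure(m, gene_bounds = gene_bounds, class = c("mito_alignment", "matrix"))
}

#' @export
print.mito_alignment <- function(x, ...) {
  gb <- attr(x, "gene_bounds")
  cat("<mito_alignment> ", nrow(x), " taxa x ", ncol(x), " sites, ",
      nrow(gb), " gene block(s)\n", sep = "")
  invisible(x)
}

#' Concatenate per-gene alignments
#'
#' Column-wise concatenation of per-gene multiple sequence alignments into
#' one supermatrix, recording each gene's column bounds. Every gene must
#' contain exactly the same taxon set; rows are matched by taxon label, so
#' input row order is irrelevant.
#'
#' @param per_gene named list of alignments: `mito_alignment` matrices,
#'   plain character matrices with rownames, or aligned-FASTA file paths.
#' @return a `mito_alignment` with a `gene_bounds` attribute.
#' @export
concatenate_alignments <- function(per_gene) {
  stopifnot(length(per_gene) >= 1)
  if (is.null(names(per_gene)) || any(!nzchar(names(per_gene))))
    names(per_gene) <- paste0("gene", seq_along(per_gene))
  mats <- lapply(per_gene, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      x <- read_alignment(x)
    stopifnot(is.matrix(x))
    x
  })
  taxa <- sort(rownames(mats[[1]]))
  for (g in seq_along(mats)) {
    tg <- rownames(mats[[g]])
    missing <- setdiff(taxa, tg); extra <- setdiff(tg, taxa)
    if (length(missing) || length(extra))
      stop("taxon sets differ in gene '", names(mats)[g], "': missing {",
           paste(missing, collapse = ", "), "}, extra {",
           paste(extra, collapse = ", "), "}")
    mats[[g]] <- mats[[g]][taxa, , drop = FALSE]
  }
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  gb <- data.frame(gene = names(mats),
                   start = c(1L, utils::head(ends, -1) + 1L),
                   end = ends, stringsAsFactors = FALSE)
  as_alignment(do.call(cbind, mats), gb)
}

#' Complete-deletion filtering
#'
#' Removes every column that contains a gap (`-`) or ambiguity (anything
#' outside `A,C,G,T`) in any taxon - the "complete deletion" treatment of
#' missing data in distance phylogenetics. Gene bounds are re-indexed to
#' the surviving columns.
#'
#' @param aln a `mito_alignment`.
#' @return filtered `mito_alignment`.
#' @export
complete_deletion <- function(aln) {
  stopifnot(ncol(aln) >= 1)
  clean <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(clean)) stop("no sites remain after complete deletion")
  gb <- attr(aln, "gene_bounds")
  surv <- cumsum(clean)
  new_gb <- do.call(rbind, lapply(seq_len(nrow(gb)), function(i) {
    n_in <- sum(clean[gb$start[i]:gb$end[i]])
    if (n_in == 0) return(NULL)
    s <- if (gb$start[i] == 1) 1L else surv[gb$start[i] - 1L] + 1L
    data.frame(gene = gb$gene[i], start = s, end = s + n_in - 1L,
               stringsAsFactors = FALSE)
  }))
  m <- unclass(aln)[, clean, drop = FALSE]
  attr(m, "gene_bounds") <- NULL
  as_alignment(m, new_gb)
}
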