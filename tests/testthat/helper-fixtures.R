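# small builders shared across tests

toy_record <- function(seq = "ACGTACGTACGTACGTACGT",
                       feats = NULL, circular = TRUE) {
  if (is.null(feats))
    feats <- rbind(
      gene_feature("g1", "PCG", "N", 1, 9,
                   start_codon = "ATG", stop_codon = "TAA"),
      gene_feature("t1", "tRNA", "N", 11, 16, anticodon = "GCA"))
  mitogenome_record("toy", feats, sequence = seq, circular = circular)
}

# an alignment matrix from named equal-length strings
aln_from_strings <- function(...) {
  x <- c(...)
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  mitocomp:::as_alignment(m)
}

# balanced 8-taxon tree with every branch `b` substitutions/site
balanced8 <- function(b = 0.05) {
  txt <- gsub("B", format(b, scientific = FALSE),
              "(((t1:B,t2:B):B,(t3:B,t4:B):B):B,((t5:B,t6:B):B,(t7:B,t8:B):B):B);")
  ape::read.tree(text = txt)
}

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}
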