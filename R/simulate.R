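#' Simulation specification for a synthetic mitogenome
#'
#' Bundles the knobs of [simulate_mitogenome()]. The defaults describe a
#' typical tick mitogenome: the 37-gene Haemaphysalis gene order with one
#' control region (the `"haemaphysalis37"` template carries the published
#' order, strands, feature lengths, codon assignments and junction
#' spacings), ~78% A+T, ATN start codons, and incomplete stop codons
#' (single `T` or `TA`) wherever the template gene length is not a codon
#' multiple.
#'
#' @param seed integer seed; the whole genome is reproducible from it.
#' @param genome_length target length in bp (approximate: the feature
#'   layout is laid down first and the circular closure spacer absorbs the
#'   remainder).
#' @param at_fraction target A+T fraction in `[0, 1]`.
#' @param gene_order_template currently `"haemaphysalis37"`.
#' @param codons `"template"` uses the template's published start/stop
#'   assignments; `"draw"` samples starts from `start_codon_pool` and full
#'   stops from `TAA`/`TAG`.
#' @param start_codon_pool candidate start codons for `codons = "draw"`.
#' @param incomplete_stop_fraction retained for drawn-length simulations;
#'   with template lengths the stop type is dictated by length mod 3 and
#'   this knob is unused.
#' @param overlap_model `"template"` realizes the template junction
#'   spacings (overlaps 1-41 bp, spacers 2-334 bp); `"none"` lays all
#'   features with 2-bp spacers.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, genome_length = 14750L,
                            at_fraction = 0.78,
                            gene_order_template = "haemaphysalis37",
                            codons = c("template", "draw"),
                            start_codon_pool = c("ATA", "ATT", "ATG", "ATC"),
                            incomplete_stop_fraction = 0.3,
                            overlap_model = c("template", "none")) {
  stopifnot(at_fraction >= 0, at_fraction <= 1,
            incomplete_stop_fraction >= 0, incomplete_stop_fraction <= 1)
  gene_order_template <- match.arg(gene_order_template, "haemaphysalis37")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 at_fraction = at_fraction,
                 gene_order_template = gene_order_template,
                 codons = match.arg(codons),
                 start_codon_pool = start_codon_pool,
                 incomplete_stop_fraction = incomplete_stop_fraction,
                 overlap_model = match.arg(overlap_model)),
            class = "simulation_spec")
}

#' The 37-gene Haemaphysalis gene-order template
#'
#' Gene order, strands, classes, lengths, codon/anticodon assignments and
#' junction spacings of the published *H. nepalensis* organization (37
#' genes plus the OH control region). Spacings whose published value is an
#' overlap between two protein-coding genes are resolved to abutting (0):
#' two PCGs cannot share bases while both keeping their own drawn start
#' and stop codons, so the generator realizes overlaps only where the
#' shared bases have a single codon-constrained owner.
#'
#' @return `data.frame` with columns `name`, `feature_class`, `strand`,
#'   `length`, `start_codon`, `stop_codon`, `anticodon`, `spacing_after`
#'   (signed spacing to the next feature; last row's value is ignored in
#'   favour of the closure spacer).
#' @export
haemaphysalis37_template <- function() {
  fx <- make_paper_fixture()$nepalensis
  tab <- attr(fx, "printed")
  n <- nrow(tab)
  sp <- clean_int(tab$intergenic_printed)
  sp[is.na(sp)] <- 0L
  cls <- tab$feature_class
  pcg_pcg <- sp < 0 & cls == "PCG" & c(cls[-1], cls[1]) == "PCG"
  sp[pcg_pcg] <- 0L
  data.frame(name = tab$name, feature_class = cls, strand = tab$strand,
             length = clean_int(tab$length_printed),
             start_codon = tab$start_codon, stop_codon = tab$stop_codon,
             anticodon = tab$anticodon, spacing_after = sp,
             stringsAsFactors = FALSE)
}

# Rejecting the AT-rich stop codons TAA/TAG shifts accepted-codon
# composition below the nominal A+T target; invert that bias by solving
# for the pre-rejection draw fraction whose post-rejection expectation
# equals the target.
adjust_at_for_rejection <- function(at, stops = c("TAA", "TAG")) {
  if (at <= 0 || at >= 1) return(at)
  bases <- c("A", "C", "G", "T")
  codons <- as.matrix(expand.grid(bases, bases, bases,
                                  stringsAsFactors = FALSE))
  atc <- rowSums(codons == "A" | codons == "T")
  keep <- !(paste0(codons[, 1], codons[, 2], codons[, 3]) %in% stops)
  realized <- function(a) {
    p <- ifelse(codons == "A" | codons == "T", a / 2, (1 - a) / 2)
    w <- p[, 1] * p[, 2] * p[, 3]
    sum(w[keep] * atc[keep]) / (3 * sum(w[keep])) - at
  }
  stats::uniroot(realized, c(at, min(1 - 1e-6, at + 0.1)),
                 tol = 1e-9)$root
}

# one random codon with AT-biased bases, excluding the genetic code's stops
draw_codon <- function(n, at, stops = c("TAA", "TAG")) {
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- vapply(todo, function(i) random_dna(3L, at), character(1))
    ok <- !cand %in% stops
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# reading-orientation sequence for one template feature
feature_sequence <- function(row, spec) {
  len <- row$length
  if (row$feature_class == "PCG") {
    start <- if (spec$codons == "template" && !is_blank(row$start_codon))
      row$start_codon else sample(spec$start_codon_pool, 1L)
    pad <- len %% 3
    stop_c <- if (pad == 1) "T" else if (pad == 2) "TA"
    else if (spec$codons == "template" && !is_blank(row$stop_codon) &&
             row$stop_codon %in% c("TAA", "TAG")) row$stop_codon
    else sample(c("TAA", "TAG"), 1L)
    n_mid <- (len - nchar(stop_c)) %/% 3L - 1L
    stopifnot(n_mid >= 0)
    seq <- paste0(start,
                  paste(draw_codon(n_mid,
                                   adjust_at_for_rejection(spec$at_fraction)),
                        collapse = ""), stop_c)
    stopifnot(nchar(seq) == len)
    list(seq = seq, start_codon = start, stop_codon = stop_c)
  } else if (row$feature_class == "tRNA") {
    s <- random_dna(len, spec$at_fraction)
    anti <- if (!is_blank(row$anticodon)) row$anticodon else "CAT"
    pos <- floor((len - 3) / 2) + 1L
    substr(s, pos, pos + 2L) <- toupper(anti)
    list(seq = s, anticodon = toupper(anti))
  } else {
    list(seq = random_dna(len, spec$at_fraction))
  }
}

#' Simulate an annotated circular mitogenome
#'
#' Generates a fully annotated synthetic mitogenome under a
#' [simulation_spec()]: features are laid down in template order with the
#' template's junction spacings; protein-coding genes are internal-stop-free
#' open reading frames (codon rejection sampling) with their assigned start
#' codons and complete or truncated (`T`/`TA`) stops; tRNAs carry their
#' anticodon triplet planted at the centre of the gene; J-strand features
#' are written reverse-complemented into the deposited sequence. At an
#' overlap junction the shared bases belong to the codon-constrained side:
#' a downstream PCG overwrites its upstream neighbour's tail, while a
#' downstream RNA gene simply reads the bases already written. Base
#' composition is drawn to hit `at_fraction` in expectation. Everything is
#' reproducible from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return a [mitogenome_record()] with sequence, 37 genes (+ control
#'   region) and realized codon metadata.
#' @export
simulate_mitogenome <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tmpl <- haemaphysalis37_template()
  if (spec$overlap_model == "none") tmpl$spacing_after <- 2L
  n <- nrow(tmpl)
  genome <- character(spec$genome_length + 1000L)  # per-base buffer
  feats <- vector("list", n)
  cursor <- 1L   # start of the next feature
  prev_end <- 0L
  for (i in seq_len(n)) {
    row <- tmpl[i, ]
    drawn <- feature_sequence(row, spec)
    start <- cursor
    end <- start + row$length - 1L
    o <- if (i > 1L) max(0L, prev_end - start + 1L) else 0L
    if (o >= row$length)
      stop("infeasible spacing: overlap ", o, " >= length of ", row$name)
    deposited <- if (row$strand == "J") revcomp(drawn$seq) else drawn$seq
    bases <- strsplit(deposited, "", fixed = TRUE)[[1]]
    if (o > 0L && row$feature_class != "PCG") {
      # RNA gene: keep the already-written shared bases
      genome[(start + o):end] <- bases[(o + 1L):row$length]
    } else {
      genome[start:end] <- bases
    }
    feats[[i]] <- gene_feature(
      row$name, row$feature_class, row$strand, start, end,
      anticodon = if (row$feature_class == "tRNA") drawn$anticodon
                  else NA_character_,
      start_codon = if (row$feature_class == "PCG") drawn$start_codon
                    else NA_character_,
      stop_codon = if (row$feature_class == "PCG") drawn$stop_codon
                   else NA_character_)
    prev_end <- max(prev_end, end)
    if (i < n) {
      gap <- tmpl$spacing_after[i]
      if (gap > 0L)
        genome[(end + 1L):(end + gap)] <-
          strsplit(random_dna(gap, spec$at_fraction), "", fixed = TRUE)[[1]]
      cursor <- end + gap + 1L
    }
  }
  closure <- spec$genome_length - prev_end
  if (closure < 1L) closure <- 7L
  genome[(prev_end + 1L):(prev_end + closure)] <-
    strsplit(random_dna(closure, spec$at_fraction), "", fixed = TRUE)[[1]]
  L <- prev_end + closure
  mitogenome_record(sprintf("sim_mitogenome_seed%d", spec$seed),
                    do.call(rbind, feats),
                    sequence = paste(genome[1:L], collapse = ""),
                    circular = TRUE)
}

# substitution probabilities after branch length d (expected subs/site)
# under K2P with ts/tv rate ratio kappa (kappa = 1 gives JC)
k2p_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)  # per transversion target (two of them)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

evolve_branch <- function(seq_chars_vec, d, kappa) {
  if (d <= 0) return(seq_chars_vec)
  p <- k2p_probs(d, kappa)
  n <- length(seq_chars_vec)
  u <- stats::runif(n)
  out <- seq_chars_vec
  ts <- u < p[["ts"]]
  tv1 <- !ts & u < p[["ts"]] + p[["tv"]]
  tv2 <- !ts & !tv1 & u < p[["ts"]] + 2 * p[["tv"]]
  out[ts] <- TS_PARTNER[seq_chars_vec[ts]]
  for (b in c("A", "C", "G", "T")) {
    i1 <- tv1 & seq_chars_vec == b
    i2 <- tv2 & seq_chars_vec == b
    out[i1] <- TV_PARTNERS[[b]][1]
    out[i2] <- TV_PARTNERS[[b]][2]
  }
  out
}

#' Evolve gene sequences along a tree
#'
#' Simulates per-site independent substitution of each root gene sequence
#' along a tree with branch lengths in expected substitutions per site,
#' under JC (all substitutions equiprobable) or K2P (transition/transversion
#' rate ratio `kappa`). No indels are introduced, so the resulting per-gene
#' matrices are alignments as-is.
#'
#' @param root_genes named list/vector of root DNA strings (one per gene).
#' @param tree `phylo` with branch lengths.
#' @param model `"jc"` or `"k2p"`.
#' @param kappa transition/transversion rate ratio for `"k2p"`.
#' @param seed integer seed.
#' @return named list of `mito_alignment` matrices (taxa x sites), one per
#'   gene.
#' @export
evolve_alignment <- function(root_genes, tree, model = c("jc", "k2p"),
                             kappa = 2, seed = 1L) {
  model <- match.arg(model)
  if (model == "jc") kappa <- 1
  root_genes <- as.list(root_genes)
  if (is.null(names(root_genes)))
    names(root_genes) <- paste0("gene", seq_along(root_genes))
  if (any(!nchar(unlist(root_genes))))
    stop("zero-length root sequence(s)")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]  # preorder
  root <- edges[1, 1]
  lens <- tree$edge.length[rev(ape::postorder(tree))]
  lapply(root_genes, function(g) {
    states <- vector("list", max(tree$edge))
    states[[root]] <- seq_chars(g)
    for (k in seq_len(nrow(edges))) {
      par <- edges[k, 1]; child <- edges[k, 2]
      states[[child]] <- evolve_branch(states[[par]], lens[k], kappa)
    }
    m <- do.call(rbind, states[seq_len(ntip)])
    rownames(m) <- tree$tip.label
    as_alignment(m)
  })
}
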