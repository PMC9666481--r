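#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in the Q
#' matrix are broken deterministically by the lexicographic order of the
#' joined clusters' smallest original taxon labels, so the result does not
#' depend on input row order.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return unrooted `phylo` tree (negative NJ branch lengths are kept;
#'   [me_refine()] clamps after OLS refitting).
#' @export
nj_build <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  nwk <- rownames(d)         # newick fragment per active node
  ord <- rownames(d)         # smallest original label in each cluster
  D <- d
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(c(ord[ij[1]], ord[ij[2]])), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    merged <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], vi, nwk[j], vj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    rownames(D) <- colnames(D) <- NULL
    nwk <- c(nwk[keep], merged)
    ord <- c(ord[keep], min(ord[c(i, j)]))
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1], a, nwk[2], b, nwk[3], c3)
  ape::read.tree(text = txt)
}

#' Ordinary least-squares branch lengths on a fixed topology
#'
#' Fits branch lengths by least squares on the path-length equations
#' (pairwise distance = sum of branch lengths on the connecting path),
#' then clamps negative estimates to zero. The clamped total tree length
#' is the Minimum Evolution score used by [me_refine()].
#'
#' @param tree `phylo` topology (branch lengths, if any, are ignored).
#' @param d distance matrix over the tree's tips.
#' @return list with `tree` (lengths = clamped OLS estimates),
#'   `raw_lengths`, `sse` (residual sum of squares) and `tree_length`
#'   (clamped total).
#' @export
ols_fit <- function(tree, d) {
  d <- as_dist_matrix(d)
  tree <- ape::unroot(tree)
  tl <- tree$tip.label
  n <- length(tl)
  if (!all(tl %in% rownames(d)))
    stop("distance matrix missing taxa: ",
         paste(setdiff(tl, rownames(d)), collapse = ", "))
  dd <- d[tl, tl]
  edges <- tree$edge
  ne <- nrow(edges)
  desc <- phangorn::Descendants(tree, edges[, 2], "tips")
  inset <- matrix(FALSE, ne, n)
  for (e in seq_len(ne)) inset[e, desc[[e]]] <- TRUE
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne))
    A[, e] <- as.numeric(xor(inset[e, pairs[, 1]], inset[e, pairs[, 2]]))
  y <- dd[pairs]
  beta <- qr.coef(qr(A), y)
  beta[is.na(beta)] <- 0
  resid <- y - as.numeric(A %*% beta)
  clamped <- pmax(beta, 0)
  tree$edge.length <- clamped
  list(tree = tree, raw_lengths = beta, sse = sum(resid^2),
       tree_length = sum(clamped))
}

#' Minimum Evolution refinement by NNI search
#'
#' Hill-climbs from a start topology (typically [nj_build()]) over
#' nearest-neighbor interchanges, re-fitting branch lengths by OLS for
#' every candidate and accepting the neighbour with the smallest clamped
#' total tree length; stops when no interchange shortens the tree. On an
#' exactly additive matrix the start tree is an immediate fixed point
#' (OLS residual 0).
#'
#' @param tree start `phylo` topology.
#' @param d distance matrix.
#' @param max_iter safety cap on accepted interchanges.
#' @return `phylo` tree with OLS branch lengths; attributes `tree_length`
#'   and `sse`.
#' @export
me_refine <- function(tree, d, max_iter = 100L) {
  d <- as_dist_matrix(d)
  cur <- ols_fit(tree, d)
  if (length(cur$tree$tip.label) > 3) {
    for (it in seq_len(max_iter)) {
      nbrs <- phangorn::nni(cur$tree)
      fits <- lapply(nbrs, ols_fit, d = d)
      tls <- vapply(fits, `[[`, numeric(1), "tree_length")
      best <- which.min(tls)
      if (!length(tls) || tls[best] >= cur$tree_length - 1e-10) break
      cur <- fits[[best]]
    }
  }
  out <- cur$tree
  attr(out, "tree_length") <- cur$tree_length
  attr(out, "sse") <- cur$sse
  out
}

#' Distance + NJ + ME point estimate from an alignment
#'
#' @param aln gap-free `mito_alignment`.
#' @param model distance model, see [dist_matrix()].
#' @return `phylo` tree.
#' @export
me_tree <- function(aln, model = "jc69") {
  d <- dist_matrix(aln, model)
  me_refine(nj_build(d), d)
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge -> sorted labels of the side NOT containing the
# alphabetically first taxon, joined by "|"
bipartition_keys <- function(tree) {
  tree <- ape::unroot(tree)
  tl <- tree$tip.label
  n <- length(tl)
  anchor <- sort(tl)[1]
  edges <- tree$edge
  internal <- edges[, 2] > n
  if (!any(internal)) return(character(0))
  desc <- phangorn::Descendants(tree, edges[internal, 2], "tips")
  keys <- vapply(desc, function(tips) {
    side <- tl[tips]
    if (anchor %in% side) side <- setdiff(tl, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Nonparametric bootstrap support for the ME tree
#'
#' Resamples alignment columns with replacement, reruns the full
#' distance + NJ + ME pipeline on each replicate, and scores each internal
#' bipartition of the point-estimate tree by the percentage of replicates
#' containing it. All replicate column draws come from one seeded
#' generator, drawn up front in replicate-sized blocks, so replicate `r`
#' always sees the same columns regardless of evaluation order. A
#' replicate whose distance matrix saturates is skipped with a warning and
#' removed from the denominator.
#'
#' @param aln gap-free `mito_alignment`.
#' @param model distance model.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the point-estimate `phylo` tree with `node.label` holding
#'   support percentages; attributes `support_table` (data.frame
#'   `bipartition`/`support`) and `n_valid` (replicates used).
#' @export
bootstrap_support <- function(aln, model = "jc69", n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  point <- me_tree(aln, model)
  L <- ncol(aln)
  set.seed(seed)
  idx <- matrix(sample.int(L, L * n_reps, replace = TRUE), nrow = n_reps)
  keys <- bipartition_keys(point)
  counts <- stats::setNames(numeric(length(keys)), keys)
  valid <- 0L
  for (r in seq_len(n_reps)) {
    sub <- as_alignment(unclass(aln)[, idx[r, ], drop = FALSE])
    tr <- tryCatch(me_tree(sub, model), error = function(e) {
      warning("bootstrap replicate ", r, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(tr)) next
    valid <- valid + 1L
    hit <- keys %in% bipartition_keys(tr)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / max(valid, 1L)
  point <- annotate_support(point, support)
  attr(point, "support_table") <- data.frame(bipartition = keys,
                                             support = as.numeric(support),
                                             stringsAsFactors = FALSE)
  attr(point, "n_valid") <- valid
  point
}

# write per-internal-node support values as node labels
annotate_support <- function(tree, support) {
  n <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  edges <- tree$edge
  anchor <- sort(tree$tip.label)[1]
  internal <- which(edges[, 2] > n)
  desc <- phangorn::Descendants(tree, edges[internal, 2], "tips")
  for (k in seq_along(internal)) {
    side <- tree$tip.label[desc[[k]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labs[edges[internal[k], 2] - n] <- sprintf("%g", support[[key]])
  }
  tree$node.label <- labs
  tree
}

#' Test whether a taxon set is monophyletic in an unrooted tree
#'
#' True when the set forms one side of some edge (a clade on the unrooted
#' tree).
#'
#' @param tree `phylo`.
#' @param taxa character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  tl <- tree$tip.label
  stopifnot(all(taxa %in% tl))
  k <- length(taxa)
  if (k <= 1 || k >= length(tl) - 1) return(TRUE)
  anchor <- sort(tl)[1]
  side <- sort(taxa)
  if (anchor %in% side) side <- sort(setdiff(tl, taxa))
  paste(side, collapse = "|") %in% bipartition_keys(tree)
}

#' Write a tree in newick format
#'
#' Branch lengths and any node labels (bootstrap support) are written;
#' the file round-trips through [ape::read.tree()].
#'
#' @param tree `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
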