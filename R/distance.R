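#' Pairwise distance matrix from a gap-free alignment
#'
#' Distance models:
#' \describe{
#'   \item{`p`}{mismatch proportion.}
#'   \item{`jc69`}{Jukes-Cantor, `-(3/4) log(1 - (4/3) p)`.}
#'   \item{`k2p`}{Kimura two-parameter,
#'     `(1/2) log(1/(1 - 2P - Q)) + (1/4) log(1/(1 - 2Q))` with `P` the
#'     transition and `Q` the transversion proportion.}
#' }
#' A non-positive logarithm argument (substitution saturation) is an error
#' naming the offending pair, never an infinite entry.
#'
#' @param aln a gap-free `mito_alignment` (run [complete_deletion()] first).
#' @param model `"p"`, `"jc69"` or `"k2p"`.
#' @return symmetric numeric matrix with zero diagonal and taxon dimnames.
#' @export
dist_matrix <- function(aln, model = c("p", "jc69", "k2p")) {
  model <- match.arg(model)
  if (any(!aln %in% c("A", "C", "G", "T")))
    stop("alignment contains gaps/ambiguities; run complete_deletion() first")
  taxa <- rownames(aln)
  n <- length(taxa); L <- ncol(aln)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  purine <- matrix(aln %in% c("A", "G"), n, ncol(aln))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff <- aln[i, ] != aln[j, ]
    p <- sum(diff) / L
    val <- switch(model,
      p = p,
      jc69 = {
        arg <- 1 - 4 * p / 3
        if (arg <= 0) stop("saturated distance (jc69) between '",
                           taxa[i], "' and '", taxa[j], "'")
        -0.75 * log(arg)
      },
      k2p = {
        ts <- sum(diff & (purine[i, ] == purine[j, ])) / L
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0)
          stop("saturated distance (k2p) between '", taxa[i], "' and '",
               taxa[j], "'")
        0.5 * log(1 / a1) + 0.25 * log(1 / a2)
      })
    d[i, j] <- d[j, i] <- val
  }
  d
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  d
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric matrix with taxon dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as_dist_matrix(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(sprintf("%-10s", rownames(d)[i]),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
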