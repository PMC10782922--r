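#' Remove peaks accessible in too few cells
#'
#' Standard scCAS quality filter: a peak is kept when the fraction of cells
#' with at least one read count reaches \code{min_cell_fraction} (inclusive).
#' The conventional threshold is 1% of cells.
#'
#' @param cm a CountMatrix
#' @param min_cell_fraction minimum fraction of cells with count >= 1,
#'   in [0, 1]; default 0.01
#' @return list with the filtered \code{CountMatrix} and \code{kept_indices}
#'   mapping new rows to original rows (original order preserved)
#' @export
filter_by_prevalence <- function(cm, min_cell_fraction = 0.01) {
  stopifnot(min_cell_fraction >= 0, min_cell_fraction <= 1)
  n <- ncol(cm$values)
  frac <- peak_prevalence(cm) / n
  keep <- which(frac >= min_cell_fraction)
  if (length(keep) < 2L)
    stop(sprintf(paste("prevalence filter at %.3g keeps %d peak(s);",
                       "need at least 2 - lower the threshold"),
                 min_cell_fraction, length(keep)))
  out <- count_matrix(cm$values[keep, , drop = FALSE],
                      cm$peaks[keep, , drop = FALSE],
                      cm$barcodes, cm$labels)
  list(counts = out, kept_indices = keep)
}

#' TF-IDF transformation of a peak-by-cell matrix
#'
#' Reweights raw counts by per-cell sequencing depth (term frequency) and
#' per-peak prevalence (inverse document frequency). Three variants are
#' provided:
#' \describe{
#'   \item{signac}{the default: x'_ij = log(1 + (x_ij / depth_j) *
#'     (n / total_i) * scale_factor), natural log, where depth_j is the
#'     column (cell) sum and total_i the row (peak) sum.}
#'   \item{origin}{classic LSI: TF = x_ij / depth_j multiplied by
#'     IDF = log(1 + n / ncells_i) with ncells_i the number of cells in
#'     which peak i is open.}
#'   \item{scopen}{TF as in \code{origin}, IDF computed on binarised counts
#'     as in \code{origin}, then log1p of the product scaled by
#'     \code{scale_factor}.}
#' }
#'
#' @param cm a CountMatrix
#' @param variant one of "signac", "origin", "scopen"
#' @param scale_factor multiplier inside the log, default 1e4
#' @return list of class \code{TransformedMatrix} with \code{values}
#'   (sparse p x n) and \code{variant}
#' @export
tfidf_transform <- function(cm, variant = c("signac", "origin", "scopen"),
                            scale_factor = 1e4) {
  variant <- match.arg(variant)
  x <- cm$values
  depth <- Matrix::colSums(x)
  if (any(depth == 0))
    stop(sprintf("cell (column) %d has zero counts; run filter/QC first",
                 which(depth == 0)[1]))
  total <- Matrix::rowSums(x)
  ncells <- Matrix::rowSums(x > 0)
  if (variant == "signac" && any(total == 0))
    stop(sprintf(paste("peak (row) %d has zero counts; apply",
                       "filter_by_prevalence first"), which(total == 0)[1]))
  if (variant != "signac" && any(ncells == 0))
    stop(sprintf(paste("peak (row) %d is open in no cell; apply",
                       "filter_by_prevalence first"), which(ncells == 0)[1]))

  t_ <- methods::as(x, "TsparseMatrix")
  n <- ncol(x)
  tf <- t_@x / depth[t_@j + 1L]
  v <- switch(variant,
    signac = log1p(tf * (n / total[t_@i + 1L]) * scale_factor),
    origin = tf * log1p(n / ncells[t_@i + 1L]),
    scopen = log1p(tf * log1p(n / ncells[t_@i + 1L]) * scale_factor))
  out <- Matrix::sparseMatrix(i = t_@i + 1L, j = t_@j + 1L, x = v,
                              dims = dim(x))
  structure(list(values = out, variant = variant),
            class = "TransformedMatrix")
}

#' Cell-wise PCA giving a peak-by-PC embedding
#'
#' Treats each peak as an observation and each cell as a variable: columns
#' (cells) are mean-centred and the peaks are projected on the top principal
#' axes, yielding the p x q peak embedding on which inter-peak correlations
#' are computed. Note this is the transpose of the usual single-cell PCA
#' orientation.
#'
#' @param tm a TransformedMatrix (or any matrix-like with peaks as rows)
#' @param n_components number of components q, default 100; clamped to
#'   min(p, n) - 1 with a warning if larger
#' @param seed seed for the randomised solver used on very large inputs
#' @return list of class \code{PeakEmbedding}: \code{values} (p x q dense),
#'   \code{n_components}, \code{explained_variance} (non-increasing)
#' @export
pca_peak_embedding <- function(tm, n_components = 100, seed = 0) {
  x <- if (inherits(tm, "TransformedMatrix")) tm$values else tm
  stopifnot(n_components >= 2)
  p <- nrow(x); n <- ncol(x)
  qmax <- min(p, n) - 1L
  if (n_components > qmax) {
    warning(sprintf("n_components clamped from %d to %d (= min(p, n) - 1)",
                    n_components, qmax))
    n_components <- qmax
  }
  emb <- pca_scores(x, n_components, seed)
  if (sum(emb$eigenvalues) <= .Machine$double.eps * p)
    stop("input matrix is constant across peaks: PCA is undefined")
  structure(list(values = emb$scores, n_components = ncol(emb$scores),
                 explained_variance = emb$eigenvalues / (p - 1)),
            class = "PeakEmbedding")
}

# internal PCA on rows-as-observations. Centers columns, takes the top q
# principal coordinates. Exact eigendecomposition of the smaller Gram matrix
# for moderate inputs, irlba (seeded) beyond 1e7 entries.
pca_scores <- function(x, q, seed = 0) {
  p <- nrow(x); n <- ncol(x)
  mu <- Matrix::colMeans(x)
  if (as.numeric(p) * n <= 1e7) {
    xc <- as.matrix(x)
    xc <- sweep(xc, 2, mu, "-")
    if (n <= p) {
      g <- crossprod(xc)             # n x n
      eg <- eigen(g, symmetric = TRUE)
      ev <- pmax(eg$values[seq_len(q)], 0)
      rot <- eg$vectors[, seq_len(q), drop = FALSE]
      scores <- xc %*% rot
    } else {
      g <- tcrossprod(xc)            # p x p
      eg <- eigen(g, symmetric = TRUE)
      ev <- pmax(eg$values[seq_len(q)], 0)
      u <- eg$vectors[, seq_len(q), drop = FALSE]
      scores <- u %*% diag(sqrt(ev), q)
      rot <- crossprod(xc, u)
      rot <- sweep(rot, 2, pmax(sqrt(ev), .Machine$double.eps), "/")
    }
  } else {
    set.seed(seed)
    sv <- irlba::irlba(x, nv = q, center = mu)
    ev <- sv$d^2
    rot <- sv$v
    scores <- sv$u %*% diag(sv$d, q)
  }
  # sign convention: each loading vector's largest-magnitude entry positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  list(scores = scores, eigenvalues = ev)
}
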