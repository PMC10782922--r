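#' Per-peak mean and mean-square of inter-peak correlations
#'
#' For every peak j, summarises its p - 1 correlation coefficients with all
#' other peaks by their mean m_j and mean square s_j. The p x p correlation
#' matrix is never materialised: peak rows are standardised once, then
#' correlations are computed block-by-block as a chunk_size x p slab, reduced
#' to the two per-peak sums, and discarded. The self-correlation (1 for a
#' well-defined row) is removed analytically before averaging.
#'
#' Peaks whose embedding row has zero variance (pcc/spcc) or zero norm (csc)
#' are assigned coefficient 0 against every other peak and flagged in
#' \code{degenerate}.
#'
#' @param pe a PeakEmbedding (or p x q numeric matrix)
#' @param method "pcc" (Pearson, default), "spcc" (Spearman) or "csc"
#'   (cosine similarity)
#' @param chunk_size peaks per block, default 1000
#' @param n_workers parallel workers mapped over blocks; the reduction order
#'   is fixed so results do not depend on n_workers
#' @return list of class \code{CorrelationSummary}: \code{mean},
#'   \code{mean_square} (length-p numeric), \code{method}, \code{n_peaks},
#'   \code{degenerate} (logical flags)
#' @export
correlation_summary <- function(pe, method = c("pcc", "spcc", "csc"),
                                chunk_size = 1000, n_workers = 1) {
  method <- match.arg(method)
  x <- if (inherits(pe, "PeakEmbedding")) pe$values else as.matrix(pe)
  p <- nrow(x); q <- ncol(x)
  stopifnot(p >= 2, chunk_size >= 1, n_workers >= 1)
  if (q < 2 && method %in% c("pcc", "spcc"))
    stop("correlation over a single component is degenerate; need q >= 2")

  z <- standardize_rows(x, method)   # degenerate rows become all-zero
  degenerate <- attr(z, "degenerate")

  starts <- seq(1L, p, by = as.integer(chunk_size))
  blocks <- lapply(starts, function(s) s:min(s + chunk_size - 1L, p))
  slab_sums <- function(idx) {
    slab <- z[idx, , drop = FALSE] %*% t(z)   # |block| x p coefficients
    cbind(rowSums(slab), rowSums(slab^2))
  }
  res <- if (n_workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, slab_sums, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(blocks, slab_sums)
  }
  sums <- do.call(rbind, res)        # block-index order: deterministic

  self <- ifelse(degenerate, 0, 1)   # c_jj = 1 unless the row is degenerate
  m <- (sums[, 1] - self) / (p - 1)
  s <- (sums[, 2] - self^2) / (p - 1)
  structure(list(mean = as.numeric(m), mean_square = as.numeric(s),
                 method = method, n_peaks = p,
                 degenerate = degenerate),
            class = "CorrelationSummary")
}

#' Correlation coefficient between two embedding rows
#'
#' @param row_a,row_b numeric vectors of equal length q >= 2
#' @param method "pcc", "spcc" or "csc"
#' @return a single coefficient in [-1, 1]; 0 when either input is
#'   zero-variance (pcc/spcc) or zero-norm (csc)
#' @export
pairwise_correlation <- function(row_a, row_b,
                                 method = c("pcc", "spcc", "csc")) {
  method <- match.arg(method)
  if (length(row_a) != length(row_b))
    stop(sprintf("length mismatch: %d vs %d", length(row_a), length(row_b)))
  z <- standardize_rows(rbind(row_a, row_b), method)
  if (any(attr(z, "degenerate"))) return(0)
  as.numeric(z[1, ] %*% z[2, ])
}

# internal: rows scaled so that the plain dot product of two rows is the
# requested coefficient. pcc: center + unit norm; spcc: average-rank
# transform then pcc; csc: unit norm only. Degenerate rows -> all zeros.
standardize_rows <- function(x, method) {
  if (method == "spcc")
    x <- t(apply(x, 1, rank, ties.method = "average"))
  if (method %in% c("pcc", "spcc"))
    x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  degenerate <- nrm <= .Machine$double.eps * ncol(x) * 16
  nrm[degenerate] <- 1
  z <- x / nrm
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- degenerate
  z
}
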