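#' Construct a peak-by-cell count matrix
#'
#' The central container of the package: a sparse non-negative integer matrix
#' with peaks (genomic intervals) as rows and cell barcodes as columns,
#' optionally carrying per-cell type labels. Mirrors the peak-by-cell matrix
#' X (p features x n cells) that scATAC-seq pipelines produce after peak
#' calling and cell filtering.
#'
#' @param values matrix-like (dense or \code{Matrix} sparse), p x n,
#'   non-negative integers.
#' @param peaks data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (BED convention: 0-based half-open), one row per peak.
#' @param barcodes character vector of unique cell identifiers, length n.
#' @param labels optional named character vector mapping barcode -> cell type.
#' @return an object of class \code{CountMatrix} with fields \code{values}
#'   (a \code{dgCMatrix}), \code{peaks}, \code{barcodes}, \code{labels}.
#' @export
count_matrix <- function(values, peaks, barcodes, labels = NULL) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  values <- methods::as(values, "dMatrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("CountMatrix must have at least one peak and one cell")
  v <- values@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("CountMatrix values must be non-negative integers")
  peaks <- as.data.frame(peaks)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks must have columns chrom, start, end")
  if (nrow(peaks) != nrow(values))
    stop(sprintf("peak table has %d rows but matrix has %d rows",
                 nrow(peaks), nrow(values)))
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end))
    stop("peak intervals must satisfy 0 <= start < end")
  barcodes <- as.character(barcodes)
  if (length(barcodes) != ncol(values))
    stop(sprintf("%d barcodes but matrix has %d columns",
                 length(barcodes), ncol(values)))
  if (anyDuplicated(barcodes))
    stop("cell barcodes must be unique")
  if (!is.null(labels)) {
    labels <- labels[barcodes]
    if (anyNA(labels))
      stop("labels must cover every barcode")
    names(labels) <- barcodes
  }
  structure(list(values = values,
                 peaks = peaks[, c("chrom", "start", "end")],
                 barcodes = barcodes, labels = labels),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  d <- dim(x$values)
  dens <- Matrix::nnzero(x$values) / prod(d)
  cat(sprintf("CountMatrix: %d peaks x %d cells (density %.3f)%s\n",
              d[1], d[2], dens,
              if (is.null(x$labels)) "" else
                sprintf(", %d cell types", length(unique(x$labels)))))
  invisible(x)
}

#' Peak identifiers in "chrom:start-end" form
#' @param cm a CountMatrix
#' @return character vector of length p
#' @export
peak_ids <- function(cm) {
  with(cm$peaks, sprintf("%s:%d-%d", chrom, start, end))
}

# internal: number of cells with count >= 1 per peak
peak_prevalence <- function(cm) {
  x <- cm$values
  Matrix::rowSums(x > 0)
}

#' Construct a feature score table
#'
#' @param peak_index 1-based original peak indices.
#' @param peak_id "chrom:start-end" strings.
#' @param score non-negative significance scores.
#' @param rank 1 = most significant; a permutation of 1..p.
#' @param selected logical flags.
#' @return a \code{data.frame} of class \code{ScoreTable}, rows ordered by rank.
#' @export
score_table <- function(peak_index, peak_id, score, rank, selected) {
  st <- data.frame(peak_index = as.integer(peak_index),
                   peak_id = as.character(peak_id),
                   score = as.numeric(score),
                   rank = as.integer(rank),
                   selected = as.logical(selected),
                   stringsAsFactors = FALSE)
  p <- nrow(st)
  if (p > 0) {
    if (!setequal(st$rank, seq_len(p)))
      stop("ranks must be a permutation of 1..p")
    st <- st[order(st$rank), , drop = FALSE]
    if (is.unsorted(-st$score))
      stop("score must be non-increasing along rank")
    if (any(st$score < 0))
      stop("scores must be non-negative")
  }
  rownames(st) <- NULL
  class(st) <- c("ScoreTable", "data.frame")
  st
}

#' Indices of selected peaks in a ScoreTable
#' @param st a ScoreTable
#' @return integer vector of original peak indices with \code{selected == TRUE}
#' @export
selected_peaks <- function(st) st$peak_index[st$selected]
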