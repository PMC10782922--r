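#' Read a peak-by-cell matrix from MTX + BED + barcode files
#'
#' Reads the conventional sparse triplet on-disk layout of single-cell
#' accessibility matrices: a Matrix Market coordinate file, a BED3 peak file
#' (0-based half-open) giving row order, and a one-barcode-per-line TSV giving
#' column order.
#'
#' @param mtx_path Matrix Market coordinate file (integer or real entries).
#' @param bed_path BED3 file, one row per peak.
#' @param barcodes_path one barcode per line.
#' @param labels_path optional two-column TSV barcode -> cell type.
#' @return a validated \code{\link{count_matrix}}
#' @export
read_count_matrix <- function(mtx_path, bed_path, barcodes_path,
                              labels_path = NULL) {
  for (f in c(mtx_path, bed_path, barcodes_path))
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
  m <- Matrix::readMM(mtx_path)
  peaks <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(peaks) < 3)
    stop(sprintf("%s: BED file needs at least 3 columns", bed_path))
  names(peaks)[1:3] <- c("chrom", "start", "end")
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(peaks))
    stop(sprintf("%s declares %d rows but %s has %d peaks",
                 mtx_path, nrow(m), bed_path, nrow(peaks)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("%s declares %d columns but %s has %d barcodes",
                 mtx_path, ncol(m), barcodes_path, length(barcodes)))
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("matrix must have at least 2 peaks and 2 cells")
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  }
  count_matrix(m, peaks, barcodes, labels)
}

#' Write a CountMatrix as MTX + BED + barcode files
#'
#' MTX is written in the "coordinate integer general" dialect with 1-based
#' indices; BED is 3-column 0-based half-open.
#'
#' @param cm a CountMatrix
#' @param out_dir output directory (created if absent)
#' @param prefix file name stem, default "matrix"/"peaks"/"barcodes"
#' @return named list of the three paths (plus \code{labels} if present)
#' @export
write_count_matrix <- function(cm, out_dir, prefix = "") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- function(name) file.path(out_dir, paste0(prefix, name))
  mtx_path <- stem("matrix.mtx")
  bed_path <- stem("peaks.bed")
  barcodes_path <- stem("barcodes.tsv")

  x <- methods::as(cm$values, "TsparseMatrix")
  con <- file(mtx_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(x), ncol(x), length(x@x))), con)
  if (length(x@x))
    writeLines(sprintf("%d %d %d", x@i + 1L, x@j + 1L, as.integer(x@x)), con)

  utils::write.table(cm$peaks, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cm$barcodes, barcodes_path)
  out <- list(mtx = mtx_path, bed = bed_path, barcodes = barcodes_path)
  if (!is.null(cm$labels)) {
    labels_path <- stem("labels.tsv")
    utils::write.table(data.frame(cm$barcodes, cm$labels[cm$barcodes]),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out$labels <- labels_path
  }
  out
}

#' Read a dense delimited peak-by-cell table
#'
#' Convenience reader for toy examples: rows named "chrom:start-end", columns
#' named by barcode.
#'
#' @param path CSV/TSV file with row names in the first column
#' @param sep field separator, default tab
#' @return a \code{\link{count_matrix}}
#' @export
read_dense_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  ids <- rownames(df)
  parts <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  if (any(lengths(parts) != 4))
    stop(sprintf("%s: row names must be chrom:start-end peak ids", path))
  peaks <- data.frame(chrom = vapply(parts, `[`, "", 2),
                      start = as.integer(vapply(parts, `[`, "", 3)),
                      end = as.integer(vapply(parts, `[`, "", 4)))
  count_matrix(as.matrix(df), peaks, colnames(df))
}

#' Write a ScoreTable as TSV
#'
#' @param st a ScoreTable
#' @param path output TSV; rows in rank order
#' @return \code{path}, invisibly
#' @export
write_scores <- function(st, path) {
  utils::write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a ScoreTable written by \code{\link{write_scores}}
#' @param path TSV file
#' @return a ScoreTable
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "numeric",
                                         "integer", "logical"))
  if (nrow(df) == 0)
    return(score_table(integer(), character(), numeric(), integer(), logical()))
  score_table(df$peak_index, df$peak_id, df$score, df$rank, df$selected)
}
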