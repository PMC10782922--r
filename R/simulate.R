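#' Specification of a synthetic scCAS dataset
#'
#' Describes one of five simulation archetypes with planted ground truth:
#' \describe{
#'   \item{S1_uniform}{discrete cell types; each type's specific peaks open
#'     at one fixed probability (consistent accessibility).}
#'   \item{S2_dynamic}{as S1, but each specific peak's open probability is
#'     drawn from a range (dynamic accessibility).}
#'   \item{S3_dynamic_hard}{as S2 with a wider, harder range.}
#'   \item{S4_rare}{as S1 with three common types and one rare type
#'     (<= 5% of cells).}
#'   \item{S5_trajectory}{cells on a three-branch tree (a root splitting in
#'     two at pseudotime 0.5); branch-specific peaks open with probability
#'     ramping from the off-type to the specific level along the branch.}
#' }
#' Open sites receive count 1 + Poisson(depth_lambda), keeping the matrix
#' sparse and close to binary as in real scCAS data.
#'
#' @param archetype one of "S1_uniform", "S2_dynamic", "S3_dynamic_hard",
#'   "S4_rare", "S5_trajectory" (prefixes "S1".."S5" accepted)
#' @param n_cells_per_type cells per type (S1-S4) or per branch (S5)
#' @param n_specific_peaks_per_type planted specific peaks per type/branch
#' @param n_background_peaks shared background peaks
#' @param p_open_specific open probability of a specific peak in its own
#'   type: scalar (S1/S4/S5) or c(low, high) range (S2/S3)
#' @param p_open_offtype open probability of a specific peak in other types
#' @param p_open_background open probability of background peaks (scalar or
#'   range)
#' @param depth_lambda mean extra counts at open sites, default 0.15
#' @param seed RNG seed
#' @return a validated list of class \code{SimulationSpec}
#' @export
simulation_spec <- function(archetype = "S1_uniform",
                            n_cells_per_type = NULL,
                            n_specific_peaks_per_type = 200,
                            n_background_peaks = 1000,
                            p_open_specific = NULL,
                            p_open_offtype = 0.05,
                            p_open_background = 0.2,
                            depth_lambda = 0.15,
                            seed = 0) {
  full <- c(S1 = "S1_uniform", S2 = "S2_dynamic", S3 = "S3_dynamic_hard",
            S4 = "S4_rare", S5 = "S5_trajectory")
  key <- toupper(substr(archetype, 1, 2))
  if (!key %in% names(full) ||
      !(archetype %in% full || archetype %in% names(full)))
    stop(sprintf("unknown archetype '%s'", archetype))
  archetype <- full[[key]]
  if (is.null(n_cells_per_type))
    n_cells_per_type <- switch(archetype,
      S4_rare = c(320L, 320L, 320L, 40L),
      S5_trajectory = c(334L, 333L, 333L),
      c(250L, 250L, 250L, 250L))
  if (is.null(p_open_specific))
    p_open_specific <- switch(archetype,
      S2_dynamic = c(0.4, 0.8),
      S3_dynamic_hard = c(0.2, 0.9),
      0.6)
  probs <- c(p_open_specific, p_open_offtype, p_open_background)
  if (any(probs < 0) || any(probs > 1))
    stop("all open probabilities must lie in [0, 1]")
  if (length(p_open_specific) == 2 &&
      p_open_specific[1] > p_open_specific[2])
    stop("p_open_specific range is inverted")
  if (length(p_open_background) == 2 &&
      p_open_background[1] > p_open_background[2])
    stop("p_open_background range is inverted")
  if (min(p_open_specific) <= p_open_offtype)
    stop("p_open_specific must exceed p_open_offtype")
  if (archetype == "S4_rare" &&
      min(n_cells_per_type) / sum(n_cells_per_type) > 0.05)
    stop("S4_rare requires a rare type (<= 5% of cells)")
  structure(list(archetype = archetype,
                 n_cells_per_type = as.integer(n_cells_per_type),
                 n_specific_peaks_per_type =
                   as.integer(n_specific_peaks_per_type),
                 n_background_peaks = as.integer(n_background_peaks),
                 p_open_specific = p_open_specific,
                 p_open_offtype = p_open_offtype,
                 p_open_background = p_open_background,
                 depth_lambda = depth_lambda,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Generate a synthetic scCAS dataset with planted ground truth
#'
#' @param spec a \code{\link{simulation_spec}} (or an archetype string,
#'   passed through with \code{...})
#' @param ... forwarded to \code{simulation_spec} when \code{spec} is a string
#' @return list of class \code{SimulatedDataset}: \code{counts}
#'   (a labelled CountMatrix), \code{truth_specific} (named integer vector
#'   peak index -> owning type/branch), \code{truth_background} (integer
#'   vector), \code{spec}
#' @export
simulate_sccas <- function(spec, ...) {
  if (is.character(spec)) spec <- simulation_spec(spec, ...)
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n_types <- length(spec$n_cells_per_type)
  type_names <- LETTERS[seq_len(n_types)]
  n <- sum(spec$n_cells_per_type)
  n_spec <- spec$n_specific_peaks_per_type
  p <- n_types * n_spec + spec$n_background_peaks

  cell_type <- rep(type_names, spec$n_cells_per_type)
  if (spec$archetype == "S5_trajectory") {
    # local position along each branch; root = branch A, children B and C
    pseudotime <- stats::runif(n)
  } else {
    pseudotime <- NULL
  }

  draw <- function(prob_spec, n_peaks) {
    if (length(prob_spec) == 2)
      stats::runif(n_peaks, prob_spec[1], prob_spec[2])
    else rep(prob_spec, n_peaks)
  }

  # open-probability matrix built block by block, then one Bernoulli draw
  prob <- matrix(0, p, n)
  owner <- rep(NA_character_, p)
  for (t in seq_len(n_types)) {
    rows <- ((t - 1) * n_spec + 1):(t * n_spec)
    owner[rows] <- type_names[t]
    in_type <- cell_type == type_names[t]
    p_on <- draw(spec$p_open_specific, n_spec)
    if (spec$archetype == "S5_trajectory") {
      ramp <- spec$p_open_offtype +
        outer(p_on - spec$p_open_offtype, pseudotime[in_type])
      prob[rows, in_type] <- ramp
    } else {
      prob[rows, in_type] <- p_on
    }
    prob[rows, !in_type] <- spec$p_open_offtype
  }
  bg_rows <- (n_types * n_spec + 1):p
  prob[bg_rows, ] <- draw(spec$p_open_background, length(bg_rows))

  open <- matrix(stats::rbinom(p * n, 1L, prob), p, n)
  extra <- stats::rpois(p * n, spec$depth_lambda)
  counts <- open * (1L + extra)

  peaks <- data.frame(chrom = "chrS",
                      start = (seq_len(p) - 1L) * 1000L,
                      end = (seq_len(p) - 1L) * 1000L + 500L)
  barcodes <- sprintf("cell_%04d", seq_len(n))
  labels <- stats::setNames(cell_type, barcodes)
  cm <- count_matrix(counts, peaks, barcodes, labels)

  spec_idx <- seq_len(n_types * n_spec)
  structure(list(counts = cm,
                 truth_specific = stats::setNames(spec_idx, owner[spec_idx]),
                 truth_background = bg_rows,
                 spec = spec),
            class = "SimulatedDataset")
}

#' Randomly zero nonzero entries (dropout injection)
#'
#' Emulates additional technical dropout: every nonzero entry of the count
#' matrix is independently set to zero with probability \code{rate};
#' structural zeros, dimensions, peaks and barcodes are untouched.
#'
#' @param cm a CountMatrix
#' @param rate dropout probability in [0, 1]
#' @param seed RNG seed
#' @return a CountMatrix with the same shape
#' @export
inject_dropout <- function(cm, rate, seed = 0) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(cm)
  set.seed(seed)
  x <- methods::as(cm$values, "TsparseMatrix")
  keep <- stats::runif(length(x@x)) >= rate
  out <- Matrix::sparseMatrix(i = x@i[keep] + 1L, j = x@j[keep] + 1L,
                              x = x@x[keep], dims = dim(x))
  count_matrix(out, cm$peaks, cm$barcodes, cm$labels)
}
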