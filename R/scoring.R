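#' Iteratively trimmed LOWESS scoring of peaks
#'
#' Fits a LOWESS curve to the (mean, mean square) cloud of inter-peak
#' correlation summaries, which captures the trend followed by the mass of
#' background peaks. The fit is repeated \code{n_fits} times; after each fit
#' a normal distribution is fitted to the residuals of the points in that
#' fit, and points whose normal-CDF quantile falls outside
#' \code{trim_quantiles} are excluded from the next fit, so outliers cannot
#' drag the curve. After the last fit the curve is evaluated at every peak
#' (linear interpolation inside the fitted range, constant extrapolation
#' outside) and each peak is scored by the absolute residual |ds_j|.
#'
#' @param cs a CorrelationSummary
#' @param n_fits number of fits, default 3
#' @param trim_quantiles lower/upper normal-CDF quantiles for trimming,
#'   default c(0.05, 0.95)
#' @param frac LOWESS smoother span, default 0.3
#' @return list with \code{scores} (class \code{ResidualScores}: signed
#'   \code{residual}, \code{score} = |residual|, \code{quantile} under the
#'   last fit's normal model) and \code{fit} (class \code{LowessFit}:
#'   \code{fitted_x}, \code{fitted_y}, \code{frac}, \code{n_iterations_run})
#' @export
iterative_lowess_scores <- function(cs, n_fits = 3,
                                    trim_quantiles = c(0.05, 0.95),
                                    frac = 0.3) {
  m <- cs$mean; s <- cs$mean_square
  p <- length(m)
  stopifnot(p >= 20, length(s) == p,
            length(trim_quantiles) == 2,
            trim_quantiles[1] > 0, trim_quantiles[2] < 1,
            trim_quantiles[1] < trim_quantiles[2],
            n_fits >= 1, frac > 0, frac <= 1)

  idx <- seq_len(p)
  fit <- NULL
  res_mu <- 0; res_sd <- 0
  for (it in seq_len(n_fits)) {
    if (length(idx) < 10L)
      stop(sprintf(paste("only %d points survive trimming before fit %d;",
                         "widen trim_quantiles"), length(idx), it))
    fit <- stats::lowess(m[idx], s[idx], f = frac, iter = 3)
    pred <- stats::approx(fit$x, fit$y, xout = m[idx], rule = 2,
                          ties = "ordered")$y
    res <- s[idx] - pred
    res_mu <- mean(res)
    res_sd <- stats::sd(res)
    if (it < n_fits) {
      if (res_sd <= .Machine$double.eps * 100) next  # flat residuals: no trim
      qv <- stats::pnorm(res, res_mu, res_sd)
      idx <- idx[qv >= trim_quantiles[1] & qv <= trim_quantiles[2]]
    }
  }

  pred_all <- stats::approx(fit$x, fit$y, xout = m, rule = 2,
                            ties = "ordered")$y
  residual <- s - pred_all
  # snap numerically-exact fits to true zero so ties break by index, not by
  # accumulated floating-point noise
  residual[abs(residual) < 1e-12 * max(1, max(abs(s)))] <- 0
  qv_all <- if (res_sd > .Machine$double.eps * 100)
    stats::pnorm(residual, res_mu, res_sd) else rep(0.5, p)
  scores <- structure(list(residual = residual, score = abs(residual),
                           quantile = qv_all),
                      class = "ResidualScores")
  lfit <- structure(list(fitted_x = fit$x, fitted_y = fit$y,
                         frac = frac, n_iterations_run = n_fits),
                    class = "LowessFit")
  list(scores = scores, fit = lfit)
}

#' Select the top-k scoring peaks
#'
#' Ranks peaks by score descending, ties broken by ascending original index
#' (stable), and flags the k smallest ranks as selected.
#'
#' @param rs a ResidualScores (or plain numeric vector of scores)
#' @param k number of features to select, 1 <= k <= p
#' @param peak_id optional peak id strings (default "peak_<i>")
#' @param peak_index optional original indices (default 1..p)
#' @return a \code{\link{score_table}}
#' @export
select_features <- function(rs, k, peak_id = NULL, peak_index = NULL) {
  score <- if (inherits(rs, "ResidualScores")) rs$score else as.numeric(rs)
  p <- length(score)
  if (k < 1 || k > p)
    stop(sprintf("k = %d out of range [1, %d]", k, p))
  if (is.null(peak_index)) peak_index <- seq_len(p)
  if (is.null(peak_id)) peak_id <- sprintf("peak_%d", peak_index)
  ord <- order(-score, seq_len(p))
  rank <- integer(p); rank[ord] <- seq_len(p)
  score_table(peak_index, peak_id, score, rank, rank <= k)
}

#' Run the full feature-selection pipeline
#'
#' Orchestrates prevalence filtering, TF-IDF, cell-wise PCA, blockwise
#' inter-peak correlation summaries, iterative LOWESS scoring and top-k
#' selection. The returned ScoreTable covers all original peaks:
#' filtered-out peaks get score 0 and ranks after every scored peak.
#'
#' @param cm a CountMatrix
#' @param k number of informative features to select
#' @param min_cell_fraction prevalence filter threshold, default 0.01
#' @param tfidf_variant "signac" (default), "origin" or "scopen"
#' @param scale_factor TF-IDF scale factor, default 1e4
#' @param n_pcs number of principal components, default 100
#' @param corr_method "pcc" (default), "spcc" or "csc"
#' @param chunk_size correlation block size, default 1000
#' @param n_workers parallel workers for the correlation stage
#' @param n_fits LOWESS fits, default 3
#' @param trim_quantiles trimming quantiles, default c(0.05, 0.95)
#' @param frac LOWESS span, default 0.3
#' @param seed seed for the (rarely used) randomised PCA solver
#' @return a \code{\link{score_table}} over all original peaks
#' @export
run_cofea <- function(cm, k,
                      min_cell_fraction = 0.01,
                      tfidf_variant = "signac",
                      scale_factor = 1e4,
                      n_pcs = 100,
                      corr_method = "pcc",
                      chunk_size = 1000,
                      n_workers = 1,
                      n_fits = 3,
                      trim_quantiles = c(0.05, 0.95),
                      frac = 0.3,
                      seed = 0) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  flt <- stage("filter", filter_by_prevalence(cm, min_cell_fraction))
  kept <- flt$kept_indices
  if (k > length(kept))
    stop(sprintf("[select] k = %d exceeds the %d peaks left after filtering",
                 k, length(kept)))
  tm <- stage("tfidf", tfidf_transform(flt$counts, tfidf_variant, scale_factor))
  pe <- stage("pca", pca_peak_embedding(tm, n_pcs, seed))
  cs <- stage("correlation",
              correlation_summary(pe, corr_method, chunk_size, n_workers))
  sc <- stage("lowess",
              iterative_lowess_scores(cs, n_fits, trim_quantiles, frac))

  p_all <- nrow(cm$values)
  ids <- peak_ids(cm)
  st_kept <- select_features(sc$scores, k, peak_id = ids[kept],
                             peak_index = kept)
  dropped <- setdiff(seq_len(p_all), kept)
  peak_index <- c(st_kept$peak_index, dropped)
  score <- c(st_kept$score, rep(0, length(dropped)))
  rank <- seq_len(p_all)
  score_table(peak_index, ids[peak_index], score, rank,
              rank <= k)
}
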