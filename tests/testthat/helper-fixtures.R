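# fixtures built in code; no binary files

# random sparse non-negative integer CountMatrix
random_count_matrix <- function(p, n, density = 0.3, max_count = 3,
                                seed = 0) {
  set.seed(seed)
  vals <- matrix(0L, p, n)
  nz <- which(matrix(stats::runif(p * n) < density, p, n))
  vals[nz] <- sample.int(max_count, length(nz), replace = TRUE)
  # guarantee no all-zero row/column so TF-IDF preconditions hold
  for (i in which(rowSums(vals) == 0)) vals[i, sample.int(n, 1)] <- 1L
  for (j in which(colSums(vals) == 0)) vals[sample.int(p, 1), j] <- 1L
  peaks <- data.frame(chrom = "chr1",
                      start = (seq_len(p) - 1L) * 500L,
                      end = (seq_len(p) - 1L) * 500L + 200L)
  count_matrix(vals, peaks, sprintf("bc%04d", seq_len(n)))
}

# small S1-style simulation for fast pipeline tests
small_sim <- function(seed = 0, n_cells = 50, n_spec = 30, n_bg = 140) {
  simulate_sccas(simulation_spec(
    "S1", n_cells_per_type = rep(n_cells, 4),
    n_specific_peaks_per_type = n_spec, n_background_peaks = n_bg,
    seed = seed))
}

# dense brute-force correlation matrix for oracle comparisons
dense_corr <- function(x, method) {
  p <- nrow(x)
  out <- matrix(0, p, p)
  for (i in seq_len(p))
    for (j in seq_len(p))
      out[i, j] <- pairwise_correlation(x[i, ], x[j, ], method)
  out
}

# naive loop-based clustering metrics, independent of the package's
# vectorised implementation
naive_metrics <- function(pred, truth) {
  n <- length(pred)
  up <- unique(pred); ut <- unique(truth)
  nij <- outer(up, ut, Vectorize(function(u, v) sum(pred == u & truth == v)))
  a <- rowSums(nij); b <- colSums(nij)
  h <- function(cnt) {
    pr <- cnt[cnt > 0] / n
    -sum(pr * log(pr))
  }
  mi <- 0
  for (i in seq_along(up)) for (j in seq_along(ut))
    if (nij[i, j] > 0)
      mi <- mi + nij[i, j] / n * log(n * nij[i, j] / (a[i] * b[j]))
  hu <- h(a); hv <- h(b)
  nmi <- if (hu == 0 && hv == 0) 1 else mi / ((hu + hv) / 2)
  # expected MI by direct hypergeometric summation
  emi <- 0
  for (ai in a) for (bj in b) {
    for (k in max(1, ai + bj - n):min(ai, bj)) {
      pk <- exp(lchoose(bj, k) + lchoose(n - bj, ai - k) - lchoose(n, ai))
      emi <- emi + pk * k / n * log(n * k / (ai * bj))
    }
  }
  ami <- (mi - emi) / ((hu + hv) / 2 - emi)
  sij <- sum(choose(nij, 2)); sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  e <- sa * sb / choose(n, 2)
  ari <- (sij - e) / ((sa + sb) / 2 - e)
  hck <- 0
  for (i in seq_along(up)) for (j in seq_along(ut))
    if (nij[i, j] > 0)
      hck <- hck - nij[i, j] / n * log(nij[i, j] / a[i])
  homo <- if (hv == 0) 1 else 1 - hck / hv
  list(nmi = nmi, ami = ami, ari = ari, homo = homo)
}
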