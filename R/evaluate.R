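#' Overlap proportion between selected and ground-truth peaks
#'
#' Defined as |selected intersect truth| / min(|selected|, |truth|), so a
#' perfect selector attains 1 whether it selects fewer or more peaks than
#' the planted truth.
#'
#' @param selected integer set of selected peak indices
#' @param truth non-empty integer set of ground-truth peak indices
#' @return a proportion in [0, 1]
#' @export
overlap_proportion <- function(selected, truth) {
  truth <- unique(as.integer(truth))
  if (length(truth) == 0) stop("truth set must be non-empty")
  selected <- unique(as.integer(selected))
  if (length(selected) == 0) {
    warning("empty selection; overlap proportion is 0")
    return(0)
  }
  length(intersect(selected, truth)) / min(length(selected), length(truth))
}

#' Highest-degree-of-accessibility baseline
#'
#' Scores each peak by the number of cells in which it has at least one read
#' count (prevalence) and selects the top k, ties broken by index.
#'
#' @param cm a CountMatrix
#' @param k number of peaks to select
#' @return a \code{\link{score_table}}
#' @export
baseline_hda <- function(cm, k) {
  select_features(as.numeric(peak_prevalence(cm)), k, peak_id = peak_ids(cm))
}

#' Signac-style feature-selection baseline
#'
#' TF-IDF transformation (signac variant), then each peak is scored by the
#' empirical quantile of its row sum in the transformed matrix; top k
#' selected.
#'
#' @param cm a CountMatrix
#' @param k number of peaks to select
#' @return a \code{\link{score_table}}
#' @export
baseline_signac <- function(cm, k) {
  tm <- tfidf_transform(cm, "signac")
  rs <- Matrix::rowSums(tm$values)
  q <- stats::ecdf(rs)(rs)
  select_features(q, k, peak_id = peak_ids(cm))
}

#' epiScanpy-style variability baseline
#'
#' Scores each peak by how close its open fraction f (prevalence / n) is to
#' one half: score = 1 - |2f - 1|, maximal for peaks open in half of the
#' cells, zero for peaks open in none or all. This tent function implements
#' the behavioural description of the baseline, not its exact source
#' formula.
#'
#' @param cm a CountMatrix
#' @param k number of peaks to select
#' @return a \code{\link{score_table}}
#' @export
baseline_episcanpy <- function(cm, k) {
  f <- peak_prevalence(cm) / ncol(cm$values)
  select_features(1 - abs(2 * f - 1), k, peak_id = peak_ids(cm))
}

#' External clustering agreement metrics
#'
#' Computes normalised mutual information (arithmetic normalisation),
#' adjusted mutual information (exact expected-MI correction), adjusted Rand
#' index and homogeneity between a predicted and a reference partition.
#'
#' @param pred,truth vectors of cluster/type assignments, equal length
#' @return named list with \code{nmi}, \code{ami}, \code{ari}, \code{homo}
#' @export
clustering_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  ct <- table(pred, truth)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)

  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  hu <- -sum(plogp(a / n)); hv <- -sum(plogp(b / n))
  nz <- ct > 0
  mi <- sum((ct[nz] / n) * log(n * ct[nz] / outer(a, b)[nz]))

  nmi <- if (hu == 0 && hv == 0) 1 else if (mi == 0) 0 else mi / mean(c(hu, hv))

  emi <- expected_mutual_information(a, b, n)
  denom <- mean(c(hu, hv)) - emi
  ami <- if (hu == 0 && hv == 0) 1 else if (abs(denom) < 1e-15) 0 else
    (mi - emi) / denom

  sij <- sum(choose(ct, 2)); sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  exp_ij <- sa * sb / choose(n, 2)
  max_ij <- (sa + sb) / 2
  ari <- if (abs(max_ij - exp_ij) < 1e-15) 1 else
    (sij - exp_ij) / (max_ij - exp_ij)

  # homogeneity: 1 - H(classes | clusters) / H(classes), with
  # H(C|K) = -sum_ij (nij/n) log(nij / ai) over predicted clusters i
  hck <- -sum((ct[nz] / n) * log(ct[nz] / a[row(ct)[nz]]))
  homo <- if (hv == 0) 1 else 1 - hck / hv

  list(nmi = nmi, ami = ami, ari = ari, homo = homo)
}

# exact expected mutual information under the hypergeometric permutation
# model, for the AMI correction
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n); hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      logp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + sum(exp(logp) * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  emi
}

#' Downstream clustering pipeline and quality report
#'
#' Standard scCAS evaluation of a feature set: subset to the selected peaks,
#' TF-IDF (signac), PCA of cells to 50 components, k-nearest-neighbour graph
#' (k = 15, cosine distance), Leiden clustering with the resolution
#' binary-searched so the cluster count matches the number of true types
#' (at most 20 iterations, then the nearest count), then clustering and
#' embedding quality metrics against the true labels.
#'
#' ASW is the mean silhouette width of the true labels on the 50-dimensional
#' embedding rescaled to [0, 1]; cLISI is the rescaled inverse-Simpson index
#' of true labels over each cell's 30 nearest neighbours (median over cells;
#' 1 = perfect separation, 0 = full mixing).
#'
#' @param cm a labelled CountMatrix
#' @param selected integer set of peak indices to use (>= 10)
#' @param labels optional named vector barcode -> type (defaults to
#'   \code{cm$labels})
#' @param seed RNG seed for the clustering
#' @param n_pcs embedding dimension, default 50
#' @param knn_k graph neighbourhood size, default 15
#' @param lisi_k cLISI neighbourhood size, default 30
#' @return list of class \code{ClusteringReport}: \code{nmi}, \code{ami},
#'   \code{ari}, \code{homo}, \code{asw}, \code{clisi},
#'   \code{n_clusters_found}, \code{n_features_used}
#' @export
cluster_and_score <- function(cm, selected, labels = NULL, seed = 0,
                              n_pcs = 50, knn_k = 15, lisi_k = 30) {
  if (is.null(labels)) labels <- cm$labels
  if (is.null(labels)) stop("cell-type labels are required for evaluation")
  labels <- labels[cm$barcodes]
  if (anyNA(labels)) stop("labels must cover every barcode")
  selected <- unique(as.integer(selected))
  if (length(selected) < 10) stop("need at least 10 selected peaks")
  small <- table(labels) < 3
  if (any(small))
    warning(sprintf("true type(s) %s have fewer than 3 cells",
                    paste(names(small)[small], collapse = ", ")))

  sub <- cm$values[selected, , drop = FALSE]
  nonzero <- Matrix::rowSums(sub) > 0
  sub_cm <- count_matrix(sub[nonzero, , drop = FALSE],
                         cm$peaks[selected[nonzero], , drop = FALSE],
                         cm$barcodes)
  tm <- tfidf_transform(sub_cm, "signac")
  q <- min(n_pcs, min(dim(tm$values)) - 1L)
  emb <- pca_scores(Matrix::t(tm$values), q, seed)$scores  # cells x q

  nn <- knn_cosine(emb, max(knn_k, lisi_k))
  g <- knn_graph(nn[, seq_len(knn_k), drop = FALSE])
  n_types <- length(unique(labels))
  cl <- leiden_match_k(g, n_types, seed)

  ext <- clustering_metrics(cl$membership, labels)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(emb))
  asw <- (mean(sil[, "sil_width"]) + 1) / 2
  clisi <- clisi_score(nn[, seq_len(min(lisi_k, ncol(nn))), drop = FALSE],
                       labels)

  structure(c(ext, list(asw = asw, clisi = clisi,
                        n_clusters_found = cl$n_clusters,
                        n_features_used = nrow(sub_cm$values))),
            class = "ClusteringReport")
}

# k nearest neighbours (excluding self) under cosine distance
knn_cosine <- function(emb, k) {
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  z <- emb / nrm
  sim <- tcrossprod(z)
  diag(sim) <- -Inf
  t(apply(sim, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
}

knn_graph <- function(nn) {
  n <- nrow(nn)
  edges <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

# Leiden clustering with resolution binary-searched to hit a target cluster
# count; falls back to the closest count seen within max_iter halvings
leiden_match_k <- function(g, k_target, seed, max_iter = 20) {
  run <- function(res) {
    set.seed(seed)
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = res, n_iterations = 3)
  }
  lo <- 1e-3; hi <- 10
  best <- NULL; best_gap <- Inf
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    cl <- run(mid)
    nk <- length(unique(igraph::membership(cl)))
    gap <- abs(nk - k_target)
    if (gap < best_gap) { best <- cl; best_gap <- gap }
    if (nk == k_target) break
    if (nk < k_target) lo <- mid else hi <- mid
  }
  m <- igraph::membership(best)
  list(membership = as.integer(m), n_clusters = length(unique(m)))
}

# rescaled inverse-Simpson of labels over each cell's neighbourhood:
# 1 = every neighbourhood pure, 0 = labels fully mixed
clisi_score <- function(nn, labels) {
  lab <- as.integer(factor(labels))
  L <- length(unique(lab))
  if (L == 1) return(1)
  isi <- apply(nn, 1, function(idx) {
    pr <- tabulate(lab[idx], nbins = L) / length(idx)
    1 / sum(pr^2)
  })
  stats::median((L - isi) / (L - 1))
}
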