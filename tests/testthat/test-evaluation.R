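test_that("overlap proportion: trivial and brute-force cases", {
  expect_equal(overlap_proportion(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  expect_equal(overlap_proportion(1:10, 1:10), 1)
  expect_warning(v <- overlap_proportion(integer(), 1:5), "empty")
  expect_equal(v, 0)
  expect_error(overlap_proportion(1:3, integer()), "non-empty")

  set.seed(0)
  sel <- sample(1000, 100); tr <- sample(1000, 200)
  brute <- sum(!is.na(match(sel, tr))) / 100
  expect_equal(overlap_proportion(sel, tr), brute)
  # 1-attainable in both regimes
  expect_equal(overlap_proportion(tr[1:50], tr), 1)
  expect_equal(overlap_proportion(c(tr, 999:1200), tr), 1)
})

test_that("HDA baseline equals brute-force prevalence ranking", {
  cm <- random_count_matrix(500, 40, density = 0.2, seed = 12)
  prev <- rowSums(as.matrix(cm$values) > 0)
  st <- baseline_hda(cm, 50)
  ord <- order(-prev, seq_along(prev))
  expect_equal(selected_peaks(st), ord[1:50])

  # simple dominance and tie-break cases
  vals <- matrix(0L, 2, 4); vals[1, 1:3] <- 1L; vals[2, 1] <- 1L
  cm2 <- count_matrix(vals, data.frame(chrom = "c", start = c(0, 10),
                                       end = c(5, 15)), letters[1:4])
  expect_equal(selected_peaks(baseline_hda(cm2, 1)), 1L)
  vals3 <- matrix(1L, 3, 3)
  cm3 <- count_matrix(vals3, data.frame(chrom = "c", start = (0:2) * 10L,
                                        end = (0:2) * 10L + 5L), letters[1:3])
  expect_equal(selected_peaks(baseline_hda(cm3, 2)), 1:2)
})

test_that("Signac baseline equals brute-force transformed row-sum ranking", {
  cm <- random_count_matrix(300, 50, seed = 13)
  rs <- Matrix::rowSums(tfidf_transform(cm, "signac")$values)
  ord <- order(-rs, seq_along(rs))
  st <- baseline_signac(cm, 30)
  expect_setequal(selected_peaks(st), ord[1:30])

  # identical peaks score identically
  vals <- rbind(c(1L, 2L, 0L), c(1L, 2L, 0L), c(0L, 1L, 3L))
  cm2 <- count_matrix(vals, data.frame(chrom = "c", start = (0:2) * 10L,
                                       end = (0:2) * 10L + 5L), letters[1:3])
  st2 <- baseline_signac(cm2, 3)
  expect_equal(st2$score[st2$peak_index == 1], st2$score[st2$peak_index == 2])
  expect_true(all(baseline_signac(cm2, 3)$selected))
})

test_that("epiScanpy baseline is the tent function of open fraction", {
  n <- 10
  vals <- rbind(rep(1L, 5) |> c(rep(0L, 5)),   # f = 0.5
                rep(0L, n),                    # f = 0 -> filtered-free score 0
                rep(1L, n),                    # f = 1
                c(rep(1L, 3), rep(0L, 7)))     # f = 0.3
  cm <- count_matrix(vals, data.frame(chrom = "c", start = (0:3) * 10L,
                                      end = (0:3) * 10L + 5L),
                     sprintf("b%d", 1:n))
  st <- baseline_episcanpy(cm, 1)
  sc <- st$score[order(st$peak_index)]
  expect_equal(sc, c(1, 0, 0, 1 - abs(2 * 0.3 - 1)))
  expect_equal(selected_peaks(st), 1L)

  # symmetry: f and 1-f tie
  f <- seq(0, 1, by = 0.1)
  expect_equal(1 - abs(2 * f - 1), rev(1 - abs(2 * rev(f) - 1)))
  prev <- round(f * n)
  vals2 <- t(vapply(prev, function(k) c(rep(1L, k), rep(0L, n - k)),
                    integer(n)))
  cm2 <- count_matrix(vals2, data.frame(chrom = "c",
                                        start = (seq_along(f) - 1) * 10L,
                                        end = (seq_along(f) - 1) * 10L + 5L),
                      sprintf("c%d", 1:n))
  st2 <- baseline_episcanpy(cm2, 3)
  sc2 <- st2$score[order(st2$peak_index)]
  expect_equal(sc2, rev(sc2), tolerance = 1e-12)
})

test_that("clustering metrics match frozen scikit-learn oracle values", {
  # values computed once with sklearn.metrics (v1.9.0) and frozen
  m1 <- clustering_metrics(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3),
                           c(1, 1, 2, 2, 2, 3, 3, 3, 1, 1))
  expect_equal(m1$nmi, 0.394648371636, tolerance = 1e-10)
  expect_equal(m1$ami, 0.171524235401, tolerance = 1e-10)
  expect_equal(m1$ari, 0.090909090909, tolerance = 1e-10)
  expect_equal(m1$homo, 0.394648371636, tolerance = 1e-10)

  m2 <- clustering_metrics(c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                           c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  expect_equal(m2$nmi, 0)
  expect_equal(m2$ami, -0.441156329369, tolerance = 1e-10)
  expect_equal(m2$ari, -0.333333333333, tolerance = 1e-10)
  expect_equal(m2$homo, 0, tolerance = 1e-12)

  # relabeling invariance; degenerate single-cluster case
  m3 <- clustering_metrics(c(2, 2, 1, 1), c(1, 1, 2, 2))
  expect_equal(m3$nmi, 1)
  expect_equal(m3$ari, 1)
  m4 <- clustering_metrics(rep(1, 6), rep(1, 6))
  expect_equal(m4$nmi, 1)
  expect_equal(m4$homo, 1)
})

test_that("metric implementations match naive loops on random partitions", {
  set.seed(17)
  for (rep_ in 1:8) {
    n <- sample(15:50, 1)
    pred <- sample.int(4, n, replace = TRUE)
    truth <- sample.int(3, n, replace = TRUE)
    got <- clustering_metrics(pred, truth)
    ref <- naive_metrics(pred, truth)
    for (k in c("nmi", "ami", "ari", "homo"))
      expect_equal(got[[k]], ref[[k]], tolerance = 1e-10,
                   label = sprintf("%s at n=%d", k, n))
  }
})

test_that("perfect block simulation gives perfect downstream metrics", {
  # types larger than the 30-cell cLISI neighbourhood, so purity can reach 1
  spec <- simulation_spec("S1", n_cells_per_type = rep(60L, 3),
                          n_specific_peaks_per_type = 30L,
                          n_background_peaks = 30L,
                          p_open_specific = 1, p_open_offtype = 0,
                          p_open_background = 0.5, depth_lambda = 0)
  sim <- simulate_sccas(spec)
  rep_ <- cluster_and_score(sim$counts, seq_len(90), seed = 0)
  expect_equal(rep_$nmi, 1)
  expect_equal(rep_$ami, 1)
  expect_equal(rep_$ari, 1)
  expect_equal(rep_$homo, 1)
  expect_equal(rep_$clisi, 1)
  expect_equal(rep_$n_clusters_found, 3L)
  expect_gt(rep_$asw, 0.5)
  expect_true(rep_$asw <= 1)
})

test_that("cluster_and_score guards inputs", {
  sim <- small_sim(seed = 3)
  expect_error(cluster_and_score(sim$counts, 1:5), "at least 10")
  unlabelled <- count_matrix(sim$counts$values, sim$counts$peaks,
                             sim$counts$barcodes)
  expect_error(cluster_and_score(unlabelled, 1:50), "labels")
})

test_that("informative features beat baselines on a small S1 (1-seed smoke)", {
  # full 5-seed versions of this property run in test-acceptance.R
  sim <- small_sim(seed = 0, n_cells = 60, n_spec = 40, n_bg = 340)
  truth <- seq_along(sim$truth_specific)
  k <- length(truth)
  ov <- function(st) overlap_proportion(selected_peaks(st), truth)
  ov_cofea <- ov(run_cofea(sim$counts, k, n_pcs = 50))
  expect_gt(ov_cofea, ov(baseline_hda(sim$counts, k)))
  expect_gt(ov_cofea, ov(baseline_signac(sim$counts, k)))
  expect_gt(ov_cofea, ov(baseline_episcanpy(sim$counts, k)))
})
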