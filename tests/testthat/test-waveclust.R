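two_blobs <- function(n = 200, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), n / 2, 2),
             matrix(rnorm(n, sep), n / 2, 2))
  list(x = x, truth = rep(0:1, each = n / 2))
}

test_that("PCA explained-variance fractions are non-increasing", {
  set.seed(22)
  w <- matrix(rnorm(50 * 20), 50, 20)
  p <- pca_embed(w, 10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
  expect_error(pca_embed(w[1:3, ], 5), "fewer events")
})

test_that("planar waveforms are captured by two components", {
  set.seed(23)
  basis <- matrix(rnorm(2 * 30), 2, 30)
  scores <- matrix(rnorm(80 * 2), 80, 2)
  w <- scores %*% basis
  p <- pca_embed(w, 3)
  expect_gte(sum(p$explained[1:2]), 0.999)
})

test_that("PCA reconstruction error decreases with more components", {
  set.seed(24)
  w <- matrix(rnorm(60 * 25), 60, 25)
  pr <- stats::prcomp(w, center = TRUE)
  recon_err <- vapply(1:6, function(k) {
    rec <- pr$x[, 1:k, drop = FALSE] %*% t(pr$rotation[, 1:k, drop = FALSE])
    sum((scale(w, scale = FALSE) - rec)^2)
  }, numeric(1))
  expect_true(all(diff(recon_err) <= 1e-9))
})

test_that("mean-shift separates well-spaced blobs and merges single ones", {
  b <- two_blobs(200, 10, seed = 1)
  ms <- mean_shift_cluster(b$x)
  expect_identical(ms$n_clusters, 2L)
  # perfect label agreement up to permutation
  tab <- table(ms$labels, b$truth)
  expect_identical(sum(apply(tab, 1, max)), 200L)

  set.seed(2)
  one <- matrix(rnorm(160), 80, 2)
  expect_identical(mean_shift_cluster(one)$n_clusters, 1L)

  same <- matrix(1, 20, 2)
  ms_same <- mean_shift_cluster(same)
  expect_identical(ms_same$n_clusters, 1L)
  expect_true(all(ms_same$labels == 0L))
})

test_that("mean-shift is deterministic given its inputs", {
  b <- two_blobs(120, 6, seed = 3)
  expect_identical(mean_shift_cluster(b$x)$labels,
                   mean_shift_cluster(b$x)$labels)
})

test_that("silhouette matches the reference implementation and its range", {
  b <- two_blobs(100, 10, seed = 4)
  ms <- mean_shift_cluster(b$x)
  s <- silhouette_score(b$x, ms$labels)
  expect_true(all(s$values >= -1 & s$values <= 1))
  expect_gt(s$mean, 0.8)
  # independent oracle: cluster::silhouette
  ref <- cluster::silhouette(ms$labels + 1L, stats::dist(b$x))
  expect_equal(s$values, unname(ref[, "sil_width"]), tolerance = 1e-9)
  expect_equal(s$mean, mean(ref[, "sil_width"]), tolerance = 1e-9)
})

test_that("silhouette is invariant to global scaling of the embedding", {
  b <- two_blobs(80, 5, seed = 5)
  lab <- b$truth
  expect_equal(silhouette_score(b$x * 37, lab)$mean,
               silhouette_score(b$x, lab)$mean, tolerance = 1e-9)
  expect_error(silhouette_score(b$x, rep(0L, nrow(b$x))), "single cluster")
})

test_that("random splits of one blob score near zero silhouette", {
  set.seed(26)
  means <- vapply(1:100, function(i) {
    x <- matrix(rnorm(80), 40, 2)
    silhouette_score(x, sample(0:1, 40, TRUE))$mean
  }, numeric(1))
  expect_lte(stats::median(means), 0.1)
  expect_lte(mean(means > 0.25), 0.01)
})

test_that("waveform preprocessing aligns peaks and normalizes amplitude", {
  sr <- 1000
  tt <- seq_len(300) / sr
  w1 <- -200 * exp(-(tt - 0.10)^2 / (2 * 0.02^2))
  w2 <- -50 * exp(-(tt - 0.22)^2 / (2 * 0.02^2))
  ev <- mea_events(1:2, c(0L, 1L), c("LFP", "LFP"),
                   t_on = c(0, 1), t_peak = c(0.1, 1.22),
                   t_off = c(0.3, 1.3), amplitude_uv = c(200, 50),
                   waveform = list(w1, w2), snippet_rate = sr)
  wm <- waveform_matrix(ev, window_s = 0.2)
  expect_identical(ncol(wm), 201L)
  expect_equal(max(abs(wm[1, ])), 1)
  # same shape after alignment/normalization despite 4x amplitude and
  # shift (edge zero-padding differs only in the far Gaussian tails)
  expect_lt(max(abs(wm[1, ] - wm[2, ])), 1e-3)
})
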