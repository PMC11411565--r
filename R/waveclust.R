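#' Build a peak-aligned, amplitude-normalized waveform matrix
#'
#' Shape clustering must be amplitude-invariant (amplitude is tested
#' separately by the template), so snippets are aligned at their
#' largest-magnitude extremum, padded/truncated to a fixed window and
#' scaled to unit peak amplitude.
#'
#' @param events an `mea_events` with waveform snippets.
#' @param window_s total window length in seconds (1 s for LFP, 4 ms for
#'   spikes by convention; default picks by modality of the first event).
#' @return matrix (events x samples) with attribute `event_id`.
#' @export
waveform_matrix <- function(events, window_s = NULL) {
  if (nrow(events) == 0L) stop("no events")
  if (is.null(window_s))
    window_s <- if (events$modality[1L] == "LFP") 1 else 0.004
  sr <- events$snippet_rate[1L]
  half <- max(2L, round(window_s * sr / 2))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    w <- events$waveform[[i]]
    if (is.null(w)) stop(sprintf("event %d has no waveform",
                                 events$event_id[i]))
    pk <- which.max(abs(w))
    out <- numeric(2L * half + 1L)
    src <- (pk - half):(pk + half)
    ok <- src >= 1L & src <= length(w)
    out[ok] <- w[src[ok]]
    mx <- max(abs(out))
    if (mx > 0) out <- out / mx
    out
  })
  m <- do.call(rbind, rows)
  attr(m, "event_id") <- events$event_id
  m
}

#' PCA embedding of waveforms
#'
#' @param waveforms numeric matrix, rows = events.
#' @param n_components number of components (<= number of rows).
#' @return list with `embedding` (rows x n_components scores) and
#'   `explained` (non-increasing variance fractions).
#' @export
pca_embed <- function(waveforms, n_components = 2L) {
  if (nrow(waveforms) < n_components)
    stop("fewer events than requested components")
  p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  list(embedding = p$x[, seq_len(k), drop = FALSE],
       explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}

#' Choose a PCA dimensionality retaining a variance target
#'
#' @param waveforms waveform matrix.
#' @param target retained-variance fraction (default 0.9).
#' @param cap maximum components (default 10).
#' @return a [pca_embed()] result at the chosen dimensionality.
#' @export
pca_embed_auto <- function(waveforms, target = 0.9, cap = 10L) {
  p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- min(which(cumsum(expl) >= target), cap, nrow(waveforms))
  pca_embed(waveforms, max(1L, k))
}

#' Flat-kernel mean-shift clustering
#'
#' Mode seeking on the empirical density: every point is shifted
#' iteratively to the mean of its neighbours within the bandwidth until it
#' converges; converged modes closer than half a bandwidth are merged into
#' one cluster. The cluster count emerges from the data density and never
#' has to be specified. Deterministic given its inputs.
#'
#' @param embedding numeric matrix, rows = points (>= 2).
#' @param bandwidth flat-kernel radius; when NULL it is estimated as the
#'   0.3 quantile of the pairwise distances of a deterministic 25%
#'   subsample (every 4th point).
#' @return list with `labels` (0-based cluster ids, ordered by decreasing
#'   cluster size), `n_clusters`, `modes` (cluster centers), `bandwidth`.
#' @export
mean_shift_cluster <- function(embedding, bandwidth = NULL) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  if (n < 2L) stop("mean-shift needs at least 2 points")
  if (is.null(bandwidth)) {
    sub <- x[seq(1L, n, by = 4L), , drop = FALSE]
    dd <- stats::dist(sub)
    bandwidth <- as.numeric(stats::quantile(dd, 0.3))
    if (bandwidth == 0) bandwidth <- max(stats::dist(x)) * 0.1
  }
  if (bandwidth <= 0) {
    # all points identical: one cluster
    return(list(labels = rep(0L, n), n_clusters = 1L,
                modes = x[1L, , drop = FALSE], bandwidth = 0))
  }
  bw2 <- bandwidth^2
  modes <- x
  for (i in seq_len(n)) {
    m <- x[i, ]
    for (it in seq_len(200L)) {
      d2 <- colSums((t(x) - m)^2)
      nb <- d2 <= bw2
      m_new <- colMeans(x[nb, , drop = FALSE])
      if (sum((m_new - m)^2) < (1e-4 * bandwidth)^2) { m <- m_new; break }
      m <- m_new
    }
    modes[i, ] <- m
  }
  # merge modes within bandwidth/2 (greedy, in point order: deterministic)
  centers <- matrix(numeric(), 0, ncol(x))
  lab <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(centers)) {
      d <- sqrt(colSums((t(centers) - modes[i, ])^2))
      j <- which(d < bandwidth / 2)
    } else j <- integer()
    if (length(j)) lab[i] <- j[1L]
    else { centers <- rbind(centers, modes[i, ]); lab[i] <- nrow(centers) }
  }
  # relabel by decreasing cluster size (ties: first-seen order)
  sizes <- tabulate(lab, nbins = nrow(centers))
  new_id <- integer(nrow(centers))
  new_id[order(-sizes, seq_along(sizes))] <- seq_len(nrow(centers))
  lab <- new_id[lab]
  list(labels = lab - 1L, n_clusters = nrow(centers),
       modes = centers[order(new_id), , drop = FALSE],
       bandwidth = bandwidth)
}

#' Silhouette coefficients of a clustering
#'
#' Per point, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' intra-cluster distance and `b_i` the smallest mean distance to another
#' cluster; always in [-1, 1]. Points in singleton clusters score 0.
#'
#' @param embedding numeric matrix, rows = points.
#' @param labels integer cluster ids (>= 2 distinct values).
#' @return list with `values` (per point) and `mean`.
#' @export
silhouette_score <- function(embedding, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined for a single cluster")
  x <- as.matrix(embedding)
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1L)))
    (b - a) / max(a, b)
  }, numeric(1L))
  list(values = s, mean = mean(s))
}

#' End-to-end waveform clustering of an event table
#'
#' [waveform_matrix()] then [pca_embed_auto()] then
#' [mean_shift_cluster()], with silhouette assessment when more than one
#' cluster emerges.
#'
#' @param events an `mea_events` with waveforms.
#' @param window_s snippet window (see [waveform_matrix()]).
#' @param bandwidth optional mean-shift bandwidth.
#' @return list with `embedding`, `explained`, `labels`, `n_clusters`,
#'   `mean_silhouette` (NA when a single cluster) and `cluster_means`
#'   (per-cluster mean normalized waveform).
#' @export
cluster_waveforms <- function(events, window_s = NULL, bandwidth = NULL) {
  wm <- waveform_matrix(events, window_s)
  emb <- pca_embed_auto(wm)
  ms <- mean_shift_cluster(emb$embedding, bandwidth)
  sil <- if (ms$n_clusters >= 2L)
    silhouette_score(emb$embedding, ms$labels)$mean else NA_real_
  cm <- do.call(rbind, lapply(sort(unique(ms$labels)), function(l)
    colMeans(wm[ms$labels == l, , drop = FALSE])))
  list(embedding = emb$embedding, explained = emb$explained,
       labels = ms$labels, n_clusters = ms$n_clusters,
       mean_silhouette = sil, cluster_means = cm)
}
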