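#' k-nearest-neighbor gland graph
#'
#' Connects each gland to its k nearest centroids (Euclidean), then
#' symmetrizes by union. The graph defines which gland pairs are "neighbors"
#' for the orientation co-occurrence features.
#'
#' @param centroids `n x 2` matrix of (x, y) gland centroids.
#' @param k neighbors per gland (capped at n - 1).
#' @return list of class `gland_graph`: `n`, `edges` (m x 2 matrix, i < j),
#'   `adj` (adjacency list), `k`.
#' @export
build_graph <- function(centroids, k = 5L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n == 0) stop_domain("cannot build a graph on zero glands")
  if (k < 1) stop_domain("k must be >= 1")
  k <- min(k, n - 1L)
  edges <- matrix(integer(0), ncol = 2)
  if (k >= 1L && n >= 2L) {
    d <- as.matrix(stats::dist(centroids))
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[-1][seq_len(k)]
      cbind(pmin(i, nb), pmax(i, nb))
    }))
    edges <- unique(pairs)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  structure(list(n = n, edges = edges, adj = adj, k = k), class = "gland_graph")
}

#' Quantize an axial orientation into B bins
#'
#' Bin width is 180/B degrees; bin index is `floor(theta / (180/B))`, with
#' 180 wrapping to bin 0. Vectorized.
#'
#' @param theta_deg orientation(s) in `[0, 180)`.
#' @param B number of bins (>= 2).
#' @return integer bin indices in `[0, B)`.
#' @export
quantize_orientation <- function(theta_deg, B = 18L) {
  if (B < 2) stop_domain("B must be >= 2")
  if (any(theta_deg < 0 | theta_deg >= 180 + 1e-12))
    stop_domain("orientation outside [0, 180)")
  as.integer(floor((theta_deg %% 180) / (180 / B)))
}

#' Local orientation co-occurrence matrix of one gland
#'
#' Accumulates, for every edge of the subgraph induced by the glands within
#' `radius_hops` of the index gland, a symmetric count at the two glands'
#' orientation bins, then normalizes to a joint distribution. An isolated
#' gland yields the uniform matrix with `empty_edges = TRUE`, which keeps
#' downstream measures finite in sparse cores.
#'
#' @param bins integer vector of per-gland orientation bins in `[0, B)`.
#' @param graph a [build_graph()] result.
#' @param gland_id index of the focal gland (1-based).
#' @param radius_hops neighborhood radius in graph hops.
#' @param B bin count.
#' @return list of class `cooccurrence_matrix`: `B`, `p` (B x B),
#'   `empty_edges`.
#' @export
local_cooccurrence <- function(bins, graph, gland_id, radius_hops = 1L, B = 18L) {
  stopifnot(inherits(graph, "gland_graph"))
  if (gland_id < 1 || gland_id > graph$n) stop_domain("gland not in graph")
  # BFS out to radius_hops
  nodes <- gland_id
  frontier <- gland_id
  hops <- 0L
  while (hops < radius_hops && length(frontier)) {
    frontier <- setdiff(unique(unlist(graph$adj[frontier])), nodes)
    nodes <- c(nodes, frontier)
    hops <- hops + 1L
  }
  inset <- logical(graph$n); inset[nodes] <- TRUE
  e <- graph$edges
  keep <- inset[e[, 1]] & inset[e[, 2]]
  p <- matrix(0, B, B)
  if (!any(keep)) {
    return(structure(list(B = B, p = matrix(1 / B^2, B, B), empty_edges = TRUE),
                     class = "cooccurrence_matrix"))
  }
  for (r in which(keep)) {
    bi <- bins[e[r, 1]] + 1L; bj <- bins[e[r, 2]] + 1L
    p[bi, bj] <- p[bi, bj] + 1
    p[bj, bi] <- p[bj, bi] + 1
  }
  p <- p / sum(p)
  structure(list(B = B, p = p, empty_edges = FALSE),
            class = "cooccurrence_matrix")
}

#' Haralick-type disorder measures of an orientation co-occurrence matrix
#'
#' Second-order statistics of the joint distribution of quantized neighbor
#' orientations. Contrast terms use the circular bin distance
#' `d(i,j) = min(|i-j|, B-|i-j|)` because orientation is periodic:
#' contrast_average = sum d q(d), contrast_energy = sum d^2 q(d),
#' contrast_variance = sum (d - contrast_average)^2 q(d), where q(d) is the
#' total mass at circular distance d. Entropy terms are in bits.
#' info_measure1 = (HXY - HXY1) / max(HX, HY) is 0 at independence and
#' negative (down to -1) for strongly dependent matrices;
#' info_measure2 = sqrt(1 - exp(-2 (HXY2 - HXY))). Remaining measures follow
#' the standard grey-level co-occurrence definitions on the bin marginals.
#'
#' @param M a [local_cooccurrence()] matrix.
#' @return named list of 13 finite measures.
#' @export
tensor_measures <- function(M) {
  stopifnot(inherits(M, "cooccurrence_matrix"))
  B <- M$B; p <- M$p
  idx <- 0:(B - 1)
  D <- outer(idx, idx, function(i, j) pmin(abs(i - j), B - abs(i - j)))
  q <- vapply(0:floor(B / 2), function(d) sum(p[D == d]), numeric(1))
  dvals <- 0:floor(B / 2)
  ca <- sum(dvals * q)
  ce <- sum(dvals^2 * q)
  cv <- sum((dvals - ca)^2 * q)
  px <- rowSums(p); py <- colSums(p)
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  HXY <- h(p)
  HX <- h(px); HY <- h(py)
  pp <- outer(px, py)
  nz <- p > 0 & pp > 0
  HXY1 <- -sum(p[nz] * log2(pp[nz]))
  HXY2 <- h(pp)
  im1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  im2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  mux <- sum(idx * px); muy <- sum(idx * py)
  sx <- sqrt(sum((idx - mux)^2 * px)); sy <- sqrt(sum((idx - muy)^2 * py))
  corr <- if (sx > 0 && sy > 0)
    sum(outer(idx - mux, idx - muy) * p) / (sx * sy) else 0
  list(
    contrast_energy = ce,
    contrast_average = ca,
    contrast_variance = cv,
    entropy = HXY,
    energy = sum(p^2),
    correlation = corr,
    intensity_average = mux,
    intensity_variance = sum((idx - mux)^2 * px),
    intensity_entropy = HX,
    info_measure1 = im1,
    info_measure2 = im2,
    max_probability = max(p),
    diag_dominance = sum(diag(p))
  )
}

tensor_measure_names <- function() {
  c("contrast_energy", "contrast_average", "contrast_variance", "entropy",
    "energy", "correlation", "intensity_average", "intensity_variance",
    "intensity_entropy", "info_measure1", "info_measure2",
    "max_probability", "diag_dominance")
}

#' Image-level tensor features: mean and SD of per-gland measures
#'
#' Computes each gland's local co-occurrence matrix and its
#' [tensor_measures()], then aggregates across glands by mean and standard
#' deviation, yielding features named `mean_tensor_<measure>` and
#' `sd_tensor_<measure>`.
#'
#' @param glands a [gland_set()].
#' @param k neighbors for the gland graph.
#' @param B orientation bins.
#' @param radius_hops neighborhood radius.
#' @return named numeric vector (26 features); an empty set returns zeros
#'   with attribute `empty = TRUE`.
#' @export
image_tensor_features <- function(glands, k = 5L, B = 18L, radius_hops = 1L) {
  stopifnot(inherits(glands, "gland_set"))
  nm <- tensor_measure_names()
  out_names <- c(paste0("mean_tensor_", nm), paste0("sd_tensor_", nm))
  n <- length(glands$glands)
  if (n == 0) {
    out <- setNames(numeric(length(out_names)), out_names)
    attr(out, "empty") <- TRUE
    return(out)
  }
  cent <- t(vapply(glands$glands, function(g) g$centroid, numeric(2)))
  theta <- vapply(glands$glands, function(g) g$orientation_deg, numeric(1))
  graph <- build_graph(cent, k = k)
  bins <- quantize_orientation(theta, B = B)
  mm <- t(vapply(seq_len(n), function(i) {
    unlist(tensor_measures(local_cooccurrence(bins, graph, i, radius_hops, B)))
  }, numeric(length(nm))))
  mu <- colMeans(mm)
  sdv <- if (n > 1) apply(mm, 2, sd) else setNames(numeric(length(nm)), nm)
  setNames(c(mu, sdv), out_names)
}
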