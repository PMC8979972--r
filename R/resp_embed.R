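## Laplacian-Eigenmaps 1D embedding of the diaphragm ROI sequence.
##
## The ROI sub-images x_1..x_N are nodes of a temporal k-nearest-neighbour
## graph; edge weights are Gaussian in the squared Euclidean intensity
## distance, W(i,j) = exp(-||x_i - x_j||^2 / (2 sigma^2)). The respiratory
## curve y minimizes phi(y) = sum_ij (y_i - y_j)^2 W(i,j) subject to
## y' D y = 1 and y' D 1 = 0, i.e. y is the generalized eigenvector of
## L y = lambda D y (L = D - W) for the smallest nonzero lambda: the
## Fiedler vector of the weighted graph under the degree normalization.

#' Temporal k-nearest-neighbour edge set
#'
#' Node `i` connects to its `floor(k/2)` preceding and `ceiling(k/2)`
#' following frames (truncated at the sequence boundaries); the edge set
#' is symmetrized by union. Time does not wrap, and self-edges are
#' excluded.
#'
#' @param n number of frames (>= 4).
#' @param k neighbour count, `2 <= k <= n - 1`.
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   undirected edge.
#' @export
build_temporal_knn_graph <- function(n, k) {
  if (n < 4) stop("need at least 4 frames")
  if (k < 2) stop("k too small")
  if (k >= n) stop("k too large")
  before <- floor(k / 2); after <- ceiling(k / 2)
  i <- rep(seq_len(n), each = before + after)
  j <- i + rep(c(seq_len(before) * -1L, seq_len(after)), n)
  keep <- j >= 1 & j <= n
  e <- cbind(i = pmin(i[keep], j[keep]), j = pmax(i[keep], j[keep]))
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

edge_sq_distances <- function(x, edges) {
  rowSums((x[edges[, 1], , drop = FALSE] - x[edges[, 2], , drop = FALSE])^2)
}

sigma2_from_d2 <- function(d2) {
  ## distances below a relative floor are numerically "identical frames"
  pos <- d2[d2 > max(d2) * 1e-12]
  if (!length(pos)) stop("degenerate sequence: all connected frames identical")
  s2 <- stats::median(d2) / 2
  ## when over half the edges join (near-)identical frames (flat plateaus),
  ## fall back to the positive distances so the kernel keeps resolution
  if (s2 <= max(d2) * 1e-12 / 2) s2 <- stats::median(pos) / 2
  s2
}

#' Self-tuned Gaussian kernel bandwidth
#'
#' `sigma^2` is half the median squared Euclidean distance over the graph
#' edges, so that the median edge weight is `exp(-1/2)`; scale-equivariant
#' in the image intensities. If more than half the edges join identical
#' frames, the median of the positive distances is used instead.
#'
#' @param x `N x P` sub-image matrix (one flattened frame per row).
#' @param edges edge matrix from [build_temporal_knn_graph()].
#' @return Positive scalar `sigma^2`.
#' @export
estimate_sigma2 <- function(x, edges) {
  sigma2_from_d2(edge_sq_distances(x, edges))
}

#' Gaussian edge weight
#'
#' `exp(-d2 / (2 sigma^2))` for connected node pairs, exactly 0 otherwise.
#'
#' @param squared_distance squared Euclidean distance(s).
#' @param sigma2 positive kernel bandwidth.
#' @param connected logical; whether the pair is an edge of the graph.
#' @return Weight(s) in `(0, 1]`, or 0 when not connected.
#' @export
gaussian_weight <- function(squared_distance, sigma2, connected = TRUE) {
  if (sigma2 <= 0) stop("invalid bandwidth: sigma2 must be > 0")
  w <- exp(-squared_distance / (2 * sigma2))
  w * rep_len(as.numeric(connected), length(w))
}

## k_sim nearest neighbours of each frame in intensity (squared Euclidean)
## distance, symmetrized by union
similarity_knn_edges <- function(x, k_sim) {
  n <- nrow(x)
  d2m <- as.matrix(stats::dist(x))^2
  nn <- apply(d2m, 1, function(r) order(r)[2:(k_sim + 1)])
  e <- cbind(rep(seq_len(n), each = k_sim), as.vector(nn))
  e <- cbind(i = pmin(e[, 1], e[, 2]), j = pmax(e[, 1], e[, 2]))
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

#' Build the weighted neighbourhood graph of a sub-image sequence
#'
#' Edges are the union of each frame's `k` temporally nearest neighbours
#' (`floor(k/2)` before, `ceiling(k/2)` after) and, when `k_sim > 0`, its
#' `k_sim` nearest neighbours in intensity distance. The temporal edges
#' keep the graph a connected chain; the similarity edges link frames in
#' the same respiratory state across breathing cycles, which is what lets
#' the one-dimensional embedding order frames by respiratory position
#' rather than by acquisition time (a purely temporal chain's Fiedler
#' vector is a monotone function of time and carries no respiratory
#' signal).
#'
#' @param x `N x P` sub-image matrix (e.g. from [crop_roi()]).
#' @param k temporal neighbour count (default 10; about 0.35 s at typical
#'   real-time frame intervals).
#' @param k_sim intensity-similar neighbour count (default 10; 0 disables
#'   similarity edges and gives the purely temporal graph).
#' @param sigma2 kernel bandwidth override; default self-tuned by
#'   [estimate_sigma2()] over the union edge set.
#' @return An object of class `temporal_graph`: edges, weights, degrees.
#' @export
temporal_graph <- function(x, k = 10, k_sim = 10, sigma2 = NULL) {
  n <- nrow(x)
  edges <- build_temporal_knn_graph(n, k)
  if (k_sim > 0) {
    if (k_sim >= n) stop("k too large")
    edges <- unique(rbind(edges, similarity_knn_edges(x, k_sim)))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  d2 <- edge_sq_distances(x, edges)
  if (is.null(sigma2)) sigma2 <- sigma2_from_d2(d2)
  w <- gaussian_weight(d2, sigma2)
  structure(list(n = n, k = k, k_sim = k_sim, edges = edges, weights = w,
                 sigma2 = sigma2),
            class = "temporal_graph")
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat(sprintf("temporal_graph: %d nodes, %d edges, k = %d, k_sim = %d, sigma2 = %.4g\n",
              x$n, nrow(x$edges), x$k, if (is.null(x$k_sim)) 0L else x$k_sim,
              x$sigma2))
  invisible(x)
}

graph_is_connected <- function(n, edges) {
  ## union of temporal neighbourhoods always contains the chain i ~ i+1
  ## for k >= 2, but verify for externally supplied edge sets
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

sparse_W <- function(graph) {
  Matrix::sparseMatrix(i = graph$edges[, 1], j = graph$edges[, 2],
                       x = graph$weights, dims = c(graph$n, graph$n),
                       symmetric = TRUE)
}

#' One-dimensional Laplacian-Eigenmaps embedding
#'
#' Solves the generalized eigenproblem `L y = lambda D y` (`L = D - W`)
#' for the smallest nonzero eigenvalue by shifted inverse iteration on the
#' symmetrically normalized Laplacian with exact deflation of the constant
#' null vector (sparse Cholesky; the graph is banded in time). The
#' returned curve satisfies `y' D y = 1` and `y' D 1 = 0` and minimizes
#' the locality functional `phi` under those constraints.
#'
#' @param graph a [temporal_graph()].
#' @param tol relative eigen-residual tolerance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return An (unoriented) object of class `resp_curve`: `values`,
#'   `lambda`, `residual`, `orientation = "undetermined"`, and provenance
#'   (`k`, `sigma2`).
#' @export
laplacian_embedding_1d <- function(graph, tol = 1e-10, max_iter = 2000) {
  stopifnot(inherits(graph, "temporal_graph"))
  n <- graph$n
  if (n < 4) stop("need at least 4 frames")
  if (!graph_is_connected(n, graph$edges)) stop("graph not connected")
  W <- sparse_W(graph)
  d <- Matrix::rowSums(W)
  if (any(d <= 0)) stop("graph not connected")
  ds <- sqrt(d)
  ## A = I - D^-1/2 W D^-1/2, PSD with null vector v0 = D^1/2 1 / |.|
  A <- Matrix::Diagonal(n) -
    Matrix::Diagonal(n, 1 / ds) %*% W %*% Matrix::Diagonal(n, 1 / ds)
  A <- Matrix::forceSymmetric(A)
  v0 <- ds / sqrt(sum(d))
  ch <- Matrix::Cholesky(A + Matrix::Diagonal(n, 1e-10), LDL = FALSE)
  ## deterministic start with broad spectral overlap
  z <- seq_len(n) - (n + 1) / 2
  z <- z - sum(v0 * z) * v0
  z <- z / sqrt(sum(z^2))
  lambda <- NA_real_; res <- Inf
  for (it in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(ch, z))
    z <- z - sum(v0 * z) * v0
    z <- z / sqrt(sum(z^2))
    Az <- as.numeric(A %*% z)
    lambda <- sum(z * Az)
    res <- sqrt(sum((Az - lambda * z)^2))
    if (res <= tol * max(1, abs(lambda))) break
  }
  if (res > tol * max(1, abs(lambda)))
    stop(sprintf("embedding failed: eigen residual %.3g after %d iterations",
                 res, max_iter))
  y <- z / ds
  ## deterministic sign: largest-magnitude entry positive
  if (y[which.max(abs(y))] < 0) y <- -y
  structure(list(values = y, n = n, lambda = lambda, residual = res,
                 orientation = "undetermined", flipped = FALSE,
                 k = graph$k, sigma2 = graph$sigma2),
            class = "resp_curve")
}

#' @export
print.resp_curve <- function(x, ...) {
  cat(sprintf("resp_curve: %d frames, lambda = %.4g, residual = %.2g\n",
              x$n, x$lambda, x$residual))
  cat(sprintf("  orientation: %s (k = %d, sigma2 = %.4g)\n",
              x$orientation, x$k, x$sigma2))
  invisible(x)
}

#' @export
plot.resp_curve <- function(x, extrema = NULL, ...) {
  graphics::plot(seq_len(x$n), x$values, type = "l",
                 xlab = "frame", ylab = "respiratory curve", ...)
  if (!is.null(extrema)) {
    graphics::points(extrema$expiration_frames,
                     x$values[extrema$expiration_frames], pch = 17)
    graphics::points(extrema$inspiration_frames,
                     x$values[extrema$inspiration_frames], pch = 19)
  }
  invisible(x)
}

#' Locality functional of a candidate embedding
#'
#' `phi(y) = sum_ij (y_i - y_j)^2 W(i,j)` over the graph edges (each
#' undirected edge counted once).
#'
#' @param y candidate curve values.
#' @param graph a [temporal_graph()].
#' @return Scalar `phi`.
#' @export
embedding_objective <- function(y, graph) {
  sum((y[graph$edges[, 1]] - y[graph$edges[, 2]])^2 * graph$weights)
}

## intensity-weighted vertical centroid of each ROI frame (row units);
## the diaphragm is most cranial (smallest centroid row) at end expiration
roi_row_centroid <- function(x) {
  nr <- attr(x, "roi_nrow")
  if (is.null(nr)) stop("sub-image matrix lacks ROI shape attributes")
  nc <- attr(x, "roi_ncol")
  rows <- rep(seq_len(nr), nc)  # column-major flatten order
  w <- pmax(x, 0)
  as.numeric(w %*% rows) / rowSums(w)
}

#' Fix the sign of a respiratory curve
#'
#' The eigenvector is defined up to sign; orientation makes local maxima
#' correspond to end expiration. Primary heuristic: the intensity-weighted
#' vertical centroid of the ROI is most cranial (smallest row) at end
#' expiration, so the curve is flipped if it correlates positively with
#' the centroid row. When that correlation is weak (|r| < 0.3) a
#' plateau-duration heuristic decides (the extreme with more frames nearby
#' is expiration); if both are inconclusive the orientation is
#' `"undetermined"` and downstream use requires a manual assignment.
#'
#' @param curve a `resp_curve`.
#' @param x the sub-image matrix the curve was computed from
#'   (from [crop_roi()], carrying ROI shape attributes).
#' @param centroid_cor_min minimum |correlation| for the centroid rule.
#' @param plateau_ratio_min minimum high/low occupancy ratio for the
#'   plateau fallback.
#' @return The curve with `orientation` set (`"expiration-up"` or
#'   `"undetermined"`) and values flipped as needed.
#' @export
orient_curve <- function(curve, x, centroid_cor_min = 0.3,
                         plateau_ratio_min = 1.2) {
  stopifnot(inherits(curve, "resp_curve"))
  y <- curve$values
  cent <- roi_row_centroid(x)
  r <- suppressWarnings(stats::cor(y, cent))
  if (is.finite(r) && abs(r) >= centroid_cor_min) {
    if (r > 0) { y <- -y; curve$flipped <- TRUE }
    curve$orientation <- "expiration-up"
    curve$orientation_rule <- "centroid"
  } else {
    rng <- diff(range(y))
    n_hi <- sum(y >= max(y) - 0.1 * rng)
    n_lo <- sum(y <= min(y) + 0.1 * rng)
    if (n_hi >= plateau_ratio_min * n_lo) {
      curve$orientation <- "expiration-up"
      curve$orientation_rule <- "plateau"
    } else if (n_lo >= plateau_ratio_min * n_hi) {
      y <- -y; curve$flipped <- TRUE
      curve$orientation <- "expiration-up"
      curve$orientation_rule <- "plateau"
    } else {
      curve$orientation <- "undetermined"
      curve$orientation_rule <- "none"
    }
  }
  curve$values <- y
  curve$centroid_cor <- r
  curve
}

#' Respiratory curve from a cine series in one call
#'
#' Crops the diaphragm ROI, builds the temporal graph, solves the 1D
#' embedding and orients it.
#'
#' @param series a [cine_series()].
#' @param roi a [resp_roi()] covering the diaphragm.
#' @param k,k_sim,sigma2 graph parameters (see [temporal_graph()]).
#' @param ... passed to [laplacian_embedding_1d()].
#' @return An oriented `resp_curve`.
#' @export
resp_embed <- function(series, roi, k = 10, k_sim = 10, sigma2 = NULL, ...) {
  x <- crop_roi(series, roi)
  g <- temporal_graph(x, k = k, k_sim = k_sim, sigma2 = sigma2)
  orient_curve(laplacian_embedding_1d(g, ...), x)
}
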