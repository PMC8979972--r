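neighbours_of <- function(edges, i) {
  unname(sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])))
}

test_that("temporal kNN connects floor(k/2) before and ceiling(k/2) after", {
  e2 <- build_temporal_knn_graph(5, 2)
  expect_equal(neighbours_of(e2, 3), c(2, 4))
  ## full enumeration for N = 5, k = 2: the chain
  expect_equal(unname(e2), cbind(1:4, 2:5), ignore_attr = TRUE)
  ## k = 3: one before, two after; node 3 also receives the union-
  ## symmetrized edge from node 1's two successors
  e3 <- build_temporal_knn_graph(5, 3)
  expect_true(all(c(2, 4, 5) %in% neighbours_of(e3, 3)))
  ## full union edge set for N = 5, k = 3, enumerated by hand
  expect_equal(unname(e3),
               cbind(c(1, 1, 2, 2, 3, 3, 4),
                     c(2, 3, 3, 4, 4, 5, 5)), ignore_attr = TRUE)
  ## boundary truncation: first frame keeps only its successors
  expect_equal(neighbours_of(e2, 1), 2)
  expect_equal(neighbours_of(e3, 5), c(3, 4))
})

test_that("neighbour-count bounds are enforced", {
  expect_error(build_temporal_knn_graph(5, 1), "k too small")
  expect_error(build_temporal_knn_graph(5, 5), "k too large")
  expect_error(build_temporal_knn_graph(3, 2), "at least 4")
})

test_that("sigma2 is half the median squared edge distance", {
  x <- matrix(c(0, 1, 4), ncol = 1)  # edge distances^2: 1 and 9
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  expect_equal(estimate_sigma2(x, edges), 2.5)
  ## homogeneity: scaling intensities by c scales sigma2 by c^2
  expect_equal(estimate_sigma2(3 * x, edges), 9 * 2.5)
  expect_error(estimate_sigma2(matrix(1, 3, 2), edges),
               "degenerate sequence")
})

test_that("Gaussian weights follow the kernel and vanish off-graph", {
  expect_equal(gaussian_weight(0, 1), 1)
  expect_equal(gaussian_weight(2 * 3.7, 3.7), exp(-1))
  expect_equal(gaussian_weight(5, 1, connected = FALSE), 0)
  expect_equal(gaussian_weight(c(0, 2), 1, connected = c(TRUE, FALSE)),
               c(1, 0))
  expect_error(gaussian_weight(1, 0), "invalid bandwidth")
})

test_that("two-level toy sequence sign-separates and matches the dense oracle", {
  x <- matrix(rep(c(0, 1), each = 5), ncol = 1)
  g <- temporal_graph(x, k = 2, k_sim = 0, sigma2 = 0.5)
  y <- laplacian_embedding_1d(g)$values
  expect_true(all(sign(y[1:5]) == sign(y[1])))
  expect_true(all(sign(y[6:10]) == -sign(y[1])))
  o <- dense_fiedler(g)
  expect_lt(max(abs(sign_align(y, o$values) - o$values)), 1e-8)
})

test_that("sparse eigensolution matches dense oracle on random graphs and
           minimizes the locality functional", {
  for (case in 1:20) {
    n <- 10 + (case %% 5) * 10
    g <- random_graph_instance(n, seed = 100 + case)
    cur <- laplacian_embedding_1d(g)
    o <- dense_fiedler(g)
    expect_lt(max(abs(sign_align(cur$values, o$values) - o$values)), 1e-8)
    ## phi at the solution beats random feasible vectors
    W <- matrix(0, n, n); W[g$edges] <- g$weights; W <- W + t(W)
    d <- rowSums(W)
    phi_y <- embedding_objective(cur$values, g)
    set.seed(case)
    for (r in 1:50) {
      z <- rnorm(n)
      z <- z - sum(d * z) / sum(d)      # z' D 1 = 0
      z <- z / sqrt(sum(d * z^2))       # z' D z = 1
      expect_lte(phi_y, embedding_objective(z, g) + 1e-12)
    }
  }
})

test_that("the embedding objective is beaten by none of 1000 random
           feasible vectors on a fixed instance", {
  g <- random_graph_instance(40, seed = 77)
  cur <- laplacian_embedding_1d(g)
  W <- matrix(0, 40, 40); W[g$edges] <- g$weights; W <- W + t(W)
  d <- rowSums(W)
  phi_y <- embedding_objective(cur$values, g)
  set.seed(7)
  for (r in 1:1000) {
    z <- rnorm(40)
    z <- z - sum(d * z) / sum(d)
    z <- z / sqrt(sum(d * z^2))
    expect_lte(phi_y, embedding_objective(z, g) + 1e-12)
  }
})

test_that("constant intensity offsets leave weights and curve unchanged", {
  set.seed(42)
  x <- matrix(rnorm(30 * 8), 30, 8)
  g1 <- temporal_graph(x, k = 4)
  g2 <- temporal_graph(x + 123.4, k = 4)
  expect_equal(g1$sigma2, g2$sigma2)
  expect_equal(g1$weights, g2$weights)
  expect_equal(laplacian_embedding_1d(g1)$values,
               laplacian_embedding_1d(g2)$values)
})

test_that("identical frames are rejected as degenerate", {
  x <- matrix(1, 20, 16)
  expect_error(temporal_graph(x, k = 4), "degenerate sequence")
})

test_that("embedding recovers the respiratory coordinate on a phantom slice", {
  p <- small_slice(seed = 21, n_frames = 200, noise_sd = 0)
  curve <- resp_embed(p$series,
                      phantom_resp_roi(small_geometry(), small_resp()))
  rho <- cor(curve$values, p$truth$per_frame$displacement_px,
             method = "spearman")
  expect_gte(abs(rho), 0.95)
  ## oriented: maxima are end expiration, so correlation is positive
  expect_equal(curve$orientation, "expiration-up")
  expect_gt(rho, 0)
})

test_that("orientation is sign-symmetric and records its rule", {
  p <- small_slice(seed = 22, n_frames = 200, noise_sd = 0.02)
  roi <- phantom_resp_roi(small_geometry(), small_resp())
  x <- crop_roi(p$series, roi)
  g <- temporal_graph(x)
  raw <- laplacian_embedding_1d(g)
  a <- orient_curve(raw, x)
  flipped <- raw; flipped$values <- -raw$values
  b <- orient_curve(flipped, x)
  expect_equal(a$values, b$values)
  expect_equal(a$orientation, "expiration-up")
})

test_that("a symmetric oscillation with no centroid signal is undetermined", {
  ## horizontally translating pattern: row centroid constant by symmetry
  n <- 64
  x <- t(vapply(seq_len(n), function(t)
    rep(sin(2 * pi * (seq_len(16) / 16 + t / 32)), each = 8) + 2,
    numeric(128)))
  attr(x, "roi_nrow") <- 8; attr(x, "roi_ncol") <- 16
  fake <- structure(list(values = cos(2 * pi * seq_len(n) / 32), n = n,
                         lambda = 0, residual = 0,
                         orientation = "undetermined", flipped = FALSE,
                         k = 2, sigma2 = 1), class = "resp_curve")
  out <- orient_curve(fake, x)
  expect_equal(out$orientation, "undetermined")
})

test_that("disconnected graphs are rejected", {
  g <- structure(list(n = 6, k = 2, k_sim = 0,
                      edges = cbind(c(1L, 2L, 4L, 5L), c(2L, 3L, 5L, 6L)),
                      weights = rep(1, 4), sigma2 = 1),
                 class = "temporal_graph")
  expect_error(laplacian_embedding_1d(g), "not connected")
})
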