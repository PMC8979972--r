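# Independent dense oracle for the 1D embedding: full generalized
# eigendecomposition of L y = lambda D y via base eigen() on the
# symmetrically normalized Laplacian. Shares no code with the package's
# sparse inverse-iteration path.
dense_fiedler <- function(graph) {
  n <- graph$n
  W <- matrix(0, n, n)
  W[graph$edges] <- graph$weights
  W <- W + t(W)
  d <- rowSums(W)
  A <- diag(1 / sqrt(d)) %*% (diag(d) - W) %*% diag(1 / sqrt(d))
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  z <- e$vectors[, n - 1]
  y <- z / sqrt(d)
  y <- y / sqrt(sum(d * y^2))
  list(values = y, lambda = e$values[n - 1])
}

# align the sign of y to a reference vector
sign_align <- function(y, ref) if (sum(y * ref) < 0) -y else y

# random connected weighted graph instance on a small synthetic sequence
random_graph_instance <- function(n, seed) {
  set.seed(seed)
  k <- sample(2:min(8, n - 1), 1)
  p <- sample(3:6, 1)
  x <- matrix(rnorm(n * p), n, p)
  temporal_graph(x, k = k, k_sim = sample(0:4, 1))
}
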