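# Small in-code fixtures and independent oracles used across the suite.

# dataset with an annotation mosaic: `per_label` cells per label on a line
mosaic_dataset <- function(per_label = c(typeA = 100, typeB = 50),
                           n_genes = 5, seed = 7) {
  set.seed(seed)
  labels <- rep(names(per_label), per_label)
  n <- length(labels)
  X <- matrix(abs(rnorm(n * n_genes, mean = 2)), n, n_genes)
  colnames(X) <- paste0("g", seq_len(n_genes))
  coords <- cbind(x = seq_len(n) + runif(n, -0.3, 0.3),
                  y = runif(n, 0, 5))
  SpatialDataset(X, coords, annotations = list(type = labels))
}

# naive O(N^2) double-sum evaluation of the Moran's I equation
moran_oracle <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  }
  (n / sum(w)) * num / sum((x - xb)^2)
}

# reachability oracle for flood-fill: linear-algebra route, not a BFS.
# visited after s steps = support of (I + A)^s applied to the seed vector.
reach_oracle <- function(adj, seed, steps) {
  n <- nrow(adj)
  v <- numeric(n)
  v[seed] <- 1
  M <- diag(n) + adj
  for (s in seq_len(steps)) v <- as.numeric(crossprod(M, v))
  sort(which(v > 0))
}

# exhaustive hypergeometric upper tail P(X >= kobs):
# population N, K successes, n draws
hyper_tail_oracle <- function(kobs, K, N, n) {
  ks <- max(kobs, 0):min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# manual spatial weight object (bypasses build_weights) for hand-built w
manual_weights <- function(w) {
  w <- Matrix::Matrix(w, sparse = TRUE)
  structure(list(w = w, W = sum(w), scheme = "manual", n = nrow(w),
                 params = list()),
            class = c("SpatialWeightMatrix", "list"))
}

expect_same_file <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
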