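# Independent oracles used to check the package's implementations.
# Everything here is deliberately brute-force and shares no code with R/.

# all-pairs shortest paths by Floyd-Warshall on a boolean adjacency matrix
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_diameter <- function(A) {
  D <- oracle_floyd_warshall(A)
  max(D)
}

oracle_global_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  n <- nrow(A)
  sum(1 / D[row(D) != col(D)]) / (n * (n - 1))
}

# transitivity by exhaustive enumeration of ordered triples
oracle_transitivity <- function(A) {
  n <- nrow(A)
  triangles <- 0; triples <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i == j || j == k || i == k) next
    if (A[i, j] && A[j, k]) {          # ordered triple centred on j
      triples <- triples + 1
      if (A[i, k]) triangles <- triangles + 1
    }
  }
  if (triples == 0) return(0)
  # each triangle appears 6x among ordered closed triples, each connected
  # triple 2x among ordered ones, so the ratio equals 3T / triples
  triangles / triples
}

# connectivity by boolean matrix powers (no igraph)
oracle_connected <- function(A) {
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  for (k in seq_len(n)) R <- (R %*% R) > 0
  all(R)
}

# exhaustive MCC threshold: largest unique weight keeping the graph connected
oracle_mcc_threshold <- function(W) {
  ths <- sort(unique(W[upper.tri(W)]), decreasing = TRUE)
  for (t in ths) {
    if (t <= 0) next
    if (oracle_connected(W >= t & row(W) != col(W))) return(t)
  }
  NA_real_
}

# random connected undirected graph on n nodes (rejection sampling)
random_connected_graph <- function(n, p_edge = 0.35) {
  repeat {
    A <- matrix(runif(n * n) < p_edge, n, n)
    A <- A | t(A)
    diag(A) <- FALSE
    if (oracle_connected(A)) return(A)
  }
}

# stationary covariance of a VAR(1): solve the discrete Lyapunov equation
# S = A S A' + Q  via the Kronecker-vectorized linear system
oracle_var1_stationary_cov <- function(A, Q) {
  n <- nrow(A)
  S <- solve(diag(n * n) - kronecker(A, A), as.vector(Q))
  matrix(S, n, n)
}

# two-sided exact Wilcoxon rank-sum p by enumeration over rank assignments
oracle_wilcoxon_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[combs], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# complex frequency response of an FIR filter at frequency f (Hz)
oracle_fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  sum(h * exp(-2i * pi * f * k / fs))
}

# direct inversion of the VAR spectral polynomial (independent of
# transfer_matrix): A(f) assembled and inverted with a hand-rolled
# Gauss-Jordan elimination on the complex matrix
oracle_transfer <- function(coeffs, f, fs) {
  M <- nrow(coeffs[[1]])
  A <- diag(M) + 0i
  for (k in seq_along(coeffs))
    A <- A - coeffs[[k]] * exp(-2i * pi * f * k / fs)
  B <- cbind(A, diag(M) + 0i)
  for (c in 1:M) {
    piv <- which.max(Mod(B[c:M, c])) + c - 1
    if (piv != c) B[c(c, piv), ] <- B[c(piv, c), ]
    B[c, ] <- B[c, ] / B[c, c]
    for (r in setdiff(1:M, c)) B[r, ] <- B[r, ] - B[r, c] * B[c, ]
  }
  B[, (M + 1):(2 * M)]
}
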