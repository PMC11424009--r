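# Independent oracles used by more than one test file.

# Exhaustive active-set QP oracle for the static redundancy problem:
# enumerate every bound configuration (free / at 0 / at 1), solve the
# equality-constrained KKT system on the free block, keep the feasible
# candidate with the smallest objective.
qp_enumeration_oracle <- function(G, M, tol = 1e-8) {
  d <- nrow(G); m <- ncol(G)
  best <- NULL; best_obj <- Inf
  for (code in 0:(3^m - 1)) {
    state <- (code %/% 3^(seq_len(m) - 1)) %% 3
    a <- rep(0, m)
    a[state == 2] <- 1
    free <- state == 0
    rhs <- M - if (any(state == 2)) rowSums(G[, state == 2, drop = FALSE]) else rep(0, d)
    if (any(free)) {
      Gf <- G[, free, drop = FALSE]
      K <- Gf %*% t(Gf)
      if (rcond(K) < 1e-10) next
      a[free] <- as.numeric(t(Gf) %*% solve(K, rhs))
    }
    if (any(a < -tol) || any(a > 1 + tol)) next
    if (max(abs(G %*% a - M)) > tol * max(1, max(abs(M)))) next
    obj <- sum(a^2)
    if (obj < best_obj) { best_obj <- obj; best <- a }
  }
  best
}

random_static_instance <- function() {
  d <- sample(1:3, 1)
  m <- d + sample(1:4, 1)
  G <- matrix(stats::runif(d * m, 5, 50) * sample(c(-1, 1), d * m, TRUE), d, m)
  a_feas <- stats::runif(m, 0.05, 0.6)
  list(G = G, M = as.numeric(G %*% a_feas))
}
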