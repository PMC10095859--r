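# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Constrained least-squares fit of the Method I model on a cell-mean matrix,
# solved from the normal equations with the identifiability constraints
# (sum g = 0; s symmetric with zero row sums; r antisymmetric) enforced via
# KKT multipliers. Returns mu, g, s, r on the same layout as the package fit.
griffing_ls_oracle <- function(X) {
  n <- nrow(X)
  s_idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * n - (a - 1) * a / 2 + b
  }
  r_idx <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    (a - 1) * n - a * (a - 1) / 2 + (b - a)
  }
  n_s <- n * (n + 1) / 2
  n_r <- n * (n - 1) / 2
  p <- 1 + n + n_s + n_r
  cells <- expand.grid(i = seq_len(n), j = seq_len(n))
  A <- matrix(0, nrow(cells), p)
  y <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    i <- cells$i[k]; j <- cells$j[k]
    A[k, 1] <- 1
    A[k, 1 + i] <- A[k, 1 + i] + 1
    A[k, 1 + j] <- A[k, 1 + j] + 1
    A[k, 1 + n + s_idx(i, j)] <- 1
    if (i != j) A[k, 1 + n + n_s + r_idx(i, j)] <- if (i < j) 1 else -1
    y[k] <- X[i, j]
  }
  C <- matrix(0, 1 + n, p)
  C[1, 1 + seq_len(n)] <- 1
  for (i in seq_len(n))
    for (j in seq_len(n))
      C[1 + i, 1 + n + s_idx(i, j)] <- C[1 + i, 1 + n + s_idx(i, j)] + 1
  K <- rbind(cbind(crossprod(A), t(C)),
             cbind(C, matrix(0, nrow(C), nrow(C))))
  rhs <- c(crossprod(A, y), rep(0, nrow(C)))
  beta <- solve(K, rhs)[seq_len(p)]
  g <- beta[1 + seq_len(n)]
  s <- matrix(0, n, n)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq(i, n)) {
    s[i, j] <- s[j, i] <- beta[1 + n + s_idx(i, j)]
    if (i != j) {
      r[i, j] <- beta[1 + n + n_s + r_idx(i, j)]
      r[j, i] <- -r[i, j]
    }
  }
  list(mu = beta[1], g = g, s = s, r = r)
}

# Literal step-up definition of the BH adjustment:
# adj(i) = min over j with rank >= rank(i) of (m / rank(j)) * p(j).
bh_bruteforce <- function(p, m = length(p)) {
  o <- order(p)
  rk <- integer(length(p)); rk[o] <- seq_along(p)
  vapply(seq_along(p), function(i) {
    min(1, min(m * p[o][rk[i]:length(p)] / seq(rk[i], length(p))))
  }, numeric(1))
}

# Small noisy diallel plasticity table built directly (no simulator):
# cell mean FC matrix plus iid Gaussian FC replicates.
toy_ptab <- function(fc_matrix, parents, reps = 4, sd = 0.01) {
  n <- nrow(fc_matrix)
  rows <- expand.grid(j = seq_len(n), i = seq_len(n))
  out <- data.frame(mother = parents[rows$i], father = parents[rows$j],
                    stringsAsFactors = FALSE)
  out$is_self <- out$mother == out$father
  out$fc_reps <- I(lapply(seq_len(nrow(rows)), function(k)
    fc_matrix[rows$i[k], rows$j[k]] + stats::rnorm(reps, 0, sd)))
  out$mean_fc <- vapply(out$fc_reps, mean, numeric(1))
  out$sd_fc <- vapply(out$fc_reps, stats::sd, numeric(1))
  out$n_fc <- rep(as.integer(reps), nrow(out))
  out$mean_fd_low <- 3.6
  out$mean_fd_high <- 3.6 * out$mean_fc
  class(out) <- c("plasticity_table", class(out))
  out
}
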