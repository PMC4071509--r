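# independent oracles and shared fixtures, kept deliberately naive so they
# cannot share a bug with the implementation they check

default_game <- function() build_symbiosis_game(metabolic_yields())

# brute-force pure Nash enumeration by explicit deviation comparison
nash_oracle <- function(game) {
  A <- game$A; B <- game$B
  out <- list()
  for (i in 1:2) for (j in 1:2) {
    dev_i <- if (i == 1) 2 else 1
    dev_j <- if (j == 1) 2 else 1
    if (A[i, j] >= A[dev_i, j] && B[j, i] >= B[dev_j, i])
      out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

# classical two-population replicator field, coded independently of the
# package (explicit double loops, no shared helpers)
replicator_oracle <- function(x, y, A, B) {
  n <- length(x)
  rx <- numeric(n); ry <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    rx[i] <- rx[i] + A[i, j] * y[j]
    ry[i] <- ry[i] + B[i, j] * x[j]
  }
  mx <- sum(x * rx); my <- sum(y * ry)
  list(dx = x * (rx - mx), dy = y * (ry - my))
}

random_interior_state <- function() {
  u <- stats::runif(1, 0.02, 0.98); v <- stats::runif(1, 0.02, 0.98)
  population_state(c(u, 1 - u), c(v, 1 - v))
}

# connected-component check on a logical matrix (4-neighbourhood)
is_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
          mask[q[1], q[2]] && !seen[q[1], q[2]]) {
        seen[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  all(seen[mask])
}
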