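# shared numeric oracles and generators

# second-order central-difference curl of a velocity field f(x) -> 3-vector
num_curl <- function(f, x, d = 1e-5) {
  pd <- function(i, j) {
    xp <- x; xp[j] <- xp[j] + d
    xm <- x; xm[j] <- xm[j] - d
    (f(xp)[i] - f(xm)[i]) / (2 * d)
  }
  c(pd(3, 2) - pd(2, 3),
    pd(1, 3) - pd(3, 1),
    pd(2, 1) - pd(1, 2))
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# fast protocols for tests
quick_protocol <- function(t_max = 300, n_replicates = 2, seed = 11, ...) {
  simulation_protocol(t_max = t_max, n_replicates = n_replicates, seed = seed,
                      ...)
}
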