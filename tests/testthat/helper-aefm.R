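# Shared helpers: random fixtures and independent oracles.

rand_structure <- function(n = 8, elements = c("H", "C", "N", "O"),
                           spread = 1.5) {
  aefm_structure(sample(elements, n, replace = TRUE),
                 matrix(rnorm(3 * n, sd = spread), n, 3))
}

rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent superposition oracle: Horn's closed-form quaternion method.
# The optimal proper rotation corresponds to the largest eigenvalue of the
# 4x4 key matrix; rmsd^2 = (|P|^2 + |Q|^2 - 2 lambda_max) / N.
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile$coords, 2, colMeans(mobile$coords))
  Q <- sweep(reference$coords, 2, colMeans(reference$coords))
  S <- crossprod(P, Q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Independent exact Wasserstein-1 oracle: integral of |F_a - F_b| over the
# merged support (CDF-difference route, distinct from the package's
# quantile-merge implementation).
w1_cdf_oracle <- function(a, b) {
  z <- sort(unique(c(a, b)))
  if (length(z) < 2) return(0)
  Fa <- ecdf(a)(z)
  Fb <- ecdf(b)(z)
  k <- seq_len(length(z) - 1)
  sum(diff(z) * abs(Fa[k] - Fb[k]))
}

# Brute-force all-pairs neighbour scan (double loop).
brute_bond_pairs <- function(s, r_cut) {
  n <- n_atoms(s)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((s$coords[i, ] - s$coords[j, ])^2)) < r_cut)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Tiny deterministic structure set for model tests.
toy_structures <- function(k = 5, n = 6, seed = 42) {
  aefm:::.with_seed(seed, lapply(seq_len(k), function(i) rand_structure(n)))
}
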