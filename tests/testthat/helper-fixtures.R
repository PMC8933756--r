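# shared fixtures and independent brute-force oracles

lower_to_mat <- function(l) {
  matrix(c(l[1], l[2], l[4],
           l[2], l[3], l[5],
           l[4], l[5], l[6]), 3, 3)
}

mat_to_lower <- function(D) c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_spd_mat <- function() {
  Q <- random_rotation()
  lam <- sort(runif(3, 0.2, 2.0), decreasing = TRUE)
  Q %*% diag(lam) %*% t(Q)
}

# tensor_field holding a list of 3x3 tensors along the x axis
field_from_tensors <- function(tensors) {
  n <- length(tensors)
  lw <- array(0, dim = c(n, 1, 1, 6))
  for (i in seq_len(n)) lw[i, 1, 1, ] <- mat_to_lower(tensors[[i]])
  tensor_field(lw, volume_geometry(c(n, 1, 1), 2))
}

# brute-force all-pairs shortest paths (Floyd-Warshall) on lengths 1/w
fw_dist <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# brute-force Onnela clustering and weighted transitivity by triangle
# enumeration
onnela_brute <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  k <- rowSums(W > 0)
  Cn <- numeric(n)
  tot <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h &&
          W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0) {
        s <- s + ((W[i, j] / mx) * (W[i, h] / mx) * (W[j, h] / mx))^(1 / 3)
      }
    }
    Cn[i] <- if (k[i] > 1) s / (k[i] * (k[i] - 1)) else 0
    tot <- tot + s
  }
  denom <- sum(k * (k - 1))
  list(node = Cn, mean = mean(Cn),
       transitivity = if (denom > 0) tot / denom else 0)
}

# direct covariance-formula assortativity over doubled edge endpoints
assortativity_brute <- function(W) {
  s <- rowSums(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# minimal tractogram from a list of polylines (matrices of mm points)
toy_tract <- function(polylines, geometry, step = 1) {
  structure(list(
    streamlines = polylines,
    lengths = vapply(polylines, function(s) (nrow(s) - 1) * step, numeric(1)),
    step_mm = step, n_seeds = length(polylines),
    n_retained = length(polylines), params = list(), geometry = geometry
  ), class = "tractogram")
}

# cohort spec with no group effect: both groups share the control
# marginals for every shared variable (patient-only clinical variables
# keep their defaults and do not enter the group-comparison families)
null_cohort_spec <- function(n_patients = 109, n_controls = 88) {
  marg <- alpsdti:::default_marginals()
  shared <- names(marg$control)
  marg$patient[shared] <- marg$control[shared]
  cohort_spec(n_patients, n_controls, marginals = marg)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / abs(expected), rel_tol)
}
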