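# Independent oracles used across tests. These deliberately re-derive
# results through different algorithms than the package implementation.

# Quaternion-based optimal superposition (Horn's method): independent of
# the SVD-based Kabsch fit in the package.
quaternion_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# Dense pseudoinverse via MASS::ginv, as an independent route to GNM
# mean-square fluctuations.
ginv_msf <- function(K) {
  diag(MASS::ginv(K))
}

# Random rigid transformation (rotation + translation) of a coordinate
# matrix; used for invariance tests.
random_rigid <- function(X, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  tr <- runif(3, -20, 20)
  sweep(X %*% t(R), 2, tr, `+`)
}

# Apply a rigid transformation to a structure tibble.
transform_structure <- function(s, seed = 1) {
  X <- random_rigid(cbind(s$x, s$y, s$z), seed = seed)
  s$x <- X[, 1]; s$y <- X[, 2]; s$z <- X[, 3]
  s
}

# A minimal synthetic structure: one CA atom per residue at given coords,
# enough for network-model and site-logic tests.
ca_only_structure <- function(xyz, chain = "A", resname = "ALA", id = "toy") {
  n <- nrow(xyz)
  flapr:::new_structure(tibble::tibble(
    chain = chain, resno = seq_len(n), ins = "", resname = resname,
    atom = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = 1.70), id = id)
}

# Fabricated per-residue secondary-structure annotation for site-logic
# tests, paired with a matching CA-only structure spread out in x so that
# C-alpha distances are well defined.
ss_case <- function(ss_string, id = "toy") {
  ss <- strsplit(ss_string, "")[[1]]
  n <- length(ss)
  xyz <- cbind(seq_len(n) * 3.8, 0, 0)
  s <- ca_only_structure(xyz, id = id)
  list(s = s,
       ss = tibble::tibble(chain = "A", resno = seq_len(n), ins = "",
                           resname = "ALA", aa = "A", ss = ss))
}
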