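# Internal 3-D geometry helpers shared across modules. Coordinates are plain
# numeric matrices (rows = atoms, columns = x/y/z) in Angstrom.

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_norm <- function(a) sqrt(sum(a * a))

unit <- function(a) a / vec_norm(a)

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural-extension-reference-frame placement: given positions a-b-c, place d
# with |c-d| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) = torsion
# (degrees). Convention verified against reference dihedral calculators.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- unit(n)
  m <- vec_cross(bc, n)
  d <- c(-bond * cos(ang), -bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * n + d[3] * m
}

# Ideal peptide geometry used by the backbone builder (Engh-Huber-like values).
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# Build an idealized backbone (N, CA, C, O per residue) from phi/psi/omega
# torsions in degrees. Returns a (4n x 3) matrix ordered N,CA,C,O per residue.
build_backbone <- function(phi, psi, omega = rep(180, length(phi))) {
  stopifnot(length(phi) == length(psi))
  g <- .bb_geom
  n <- length(phi)
  X <- matrix(NA_real_, n * 4L, 3L)
  idx <- function(i, a) (i - 1L) * 4L + a # 1=N 2=CA 3=C 4=O
  X[idx(1L, 1L), ] <- c(0, 0, 0)
  X[idx(1L, 2L), ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  X[idx(1L, 3L), ] <- X[idx(1L, 2L), ] + c(-g$b_ca_c * cos(ang), g$b_ca_c * sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      X[idx(i, 1L), ] <- place_atom(X[idx(i - 1L, 1L), ], X[idx(i - 1L, 2L), ],
                                    X[idx(i - 1L, 3L), ], g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      X[idx(i, 2L), ] <- place_atom(X[idx(i - 1L, 2L), ], X[idx(i - 1L, 3L), ],
                                    X[idx(i, 1L), ], g$b_n_ca, g$a_c_n_ca, omega[i - 1L])
      X[idx(i, 3L), ] <- place_atom(X[idx(i - 1L, 3L), ], X[idx(i, 1L), ],
                                    X[idx(i, 2L), ], g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    # carbonyl O anti to the next amide N, i.e. torsion psi + 180 about N-CA-C
    X[idx(i, 4L), ] <- place_atom(X[idx(i, 1L), ], X[idx(i, 2L), ],
                                  X[idx(i, 3L), ], g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  X
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotation/translation minimising the RMSD of `mobile` onto `fixed`.
#'
#' @param mobile,fixed Matrices (n x 3) of paired coordinates.
#' @return List with `R` (3x3 rotation), `t` (translation applied after
#'   rotation), and `rmsd` of the fit points.
#' @keywords internal
#' @noRd
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cf - as.vector(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, tr, `+`)
  list(R = R, t = tr, rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

# Apply a kabsch_fit (or any R/t pair) to a coordinate matrix.
apply_fit <- function(X, fit) {
  sweep(X %*% t(fit$R), 2, fit$t, `+`)
}

# RMSD of two paired coordinate sets after optimal superposition.
superposed_rmsd <- function(X, Y) {
  kabsch_fit(X, Y)$rmsd
}
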