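# Synthetic structures, ensembles and complexes with known ground truth.
# Everything is generated from idealized geometry and frozen constants, so a
# given seed always produces byte-identical PDB output and every pipeline
# stage can be tested without downloading real structures.

# Frozen loop dihedrals for the beta-hairpin fixtures. Solved once by
# numerical chain closure against an ideal antiparallel strand placement:
# "open" keeps the 6-residue loop clash-free with few cross contacts,
# "clamped" pulls it against the strands, and "bulge10" is a 10-residue
# loop that arcs away from the scaffold body.
.hairpin_loops <- list(
  open = list(
    phi = c(112.402052, -25.448358, -152.138034, -178.166924, 111.591828,
            175.746166),
    psi = c(158.435865, -100.030080, 8.204083, 97.844446, 91.428490,
            -99.259899)),
  clamped = list(
    phi = c(57.215722, 126.890552, -20.452673, -111.034888, -65.711484,
            -30.483839),
    psi = c(21.010353, 131.320338, -78.402868, 6.201719, -123.684495,
            -63.425635))
)

.hairpin_strand <- c(phi = -139, psi = 135)
.hairpin_nstrand <- 9L

# Assemble a structure tibble from a backbone matrix (4 atoms/residue) plus
# template side chains for the given sequence.
backbone_to_structure <- function(X, seq1, id, chain = "A", start_resno = 1L) {
  n <- length(seq1)
  res3 <- aa_1to3(seq1)
  rows <- list()
  bb_names <- c("N", "CA", "C", "O")
  bb_elem <- c("N", "C", "C", "O")
  for (i in seq_len(n)) {
    base <- (i - 1L) * 4L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chain = chain, resno = start_resno + i - 1L, ins = "",
      resname = res3[i], atom = bb_names, element = bb_elem,
      x = X[base + 1:4, 1], y = X[base + 1:4, 2], z = X[base + 1:4, 3],
      radius = vdw_radius(bb_elem))
    if (res3[i] != "GLY") {
      sc <- build_sidechain(res3[i], X[base + 1L, ], X[base + 2L, ],
                            X[base + 3L, ],
                            chis = rep(-60, max(0, .n_chi[[res3[i]]])))
      if (nrow(sc))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chain = chain, resno = start_resno + i - 1L, ins = "",
          resname = res3[i], atom = sc$atom, element = sc$element,
          x = sc$x, y = sc$y, z = sc$z, radius = vdw_radius(sc$element))
    }
  }
  new_structure(dplyr::bind_rows(rows), id = id)
}

split_seq <- function(seq, n, default = "A") {
  if (is.null(seq)) return(rep(default, n))
  v <- strsplit(toupper(seq), "")[[1]]
  if (length(v) != n) stop("sequence length ", length(v),
                           " does not match residue count ", n)
  v
}

hairpin_dihedrals <- function(loop) {
  ns <- .hairpin_nstrand
  key <- if (identical(loop, "clamped")) "clamped" else "open"
  lp <- .hairpin_loops[[key]]
  list(phi = c(rep(.hairpin_strand[["phi"]], ns), lp$phi,
               rep(.hairpin_strand[["phi"]], ns)),
       psi = c(rep(.hairpin_strand[["psi"]], ns), lp$psi,
               rep(.hairpin_strand[["psi"]], ns)),
       nloop = length(lp$phi))
}

# Replace the 6-residue loop of the open hairpin by a wide 10-residue
# bulge. The first and last loop residues keep the compact-loop backbone
# (so the strand hydrogen-bond network, and hence the E labels of the
# flanks, is untouched); the interior eight residues follow a "keyhole"
# excursion - two straight legs more than a contact cutoff apart joined by
# a wide semicircular cap - so the interior stays out of contact range of
# both the strands and the opposite leg, leaving the loop mobile in the
# network model.
build_bulge_hairpin <- function(seq, id) {
  ns <- .hairpin_nstrand
  nl <- 10L
  dh <- hairpin_dihedrals("open")
  X6 <- build_backbone(dh$phi, dh$psi)
  n6 <- 2L * ns + dh$nloop
  row6 <- function(i) (i - 1L) * 4L + 1:4
  get6 <- function(i, a) X6[(i - 1L) * 4L + a, ]
  strand_rows <- c(seq_len(ns), (ns + dh$nloop + 1L):n6)
  strand_ca <- t(vapply(strand_rows, function(i) get6(i, 2L), numeric(3)))
  # anchors: the compact loop's first and last residues, kept verbatim
  first_keep <- X6[row6(ns + 1L), , drop = FALSE]
  last_keep <- X6[row6(ns + dh$nloop), , drop = FALSE]
  a <- first_keep[2L, ]; b <- last_keep[2L, ]
  chord <- b - a
  mid <- (a + b) / 2
  u0 <- mid - colMeans(strand_ca)
  u <- unit(u0 - sum(u0 * unit(chord)) * unit(chord)) # away from the body
  v <- unit(chord)
  n_int <- nl - 2L
  path_len <- (n_int + 1L) * 3.8
  r_cap <- 3.9                          # cap diameter 7.8 > contact cutoff
  cap_len <- pi * r_cap
  leg_len <- (path_len - cap_len) / 2
  dlat <- r_cap - vec_norm(chord) / 2   # outward splay of each leg
  H <- sqrt(max(leg_len^2 - dlat^2, 1))
  C0 <- mid + H * u                     # cap centre
  t1 <- C0 - r_cap * v                  # tangent points
  path_point <- function(s) {
    if (s <= leg_len) {                 # leg 1: a -> t1
      a + (s / leg_len) * (t1 - a)
    } else if (s <= leg_len + cap_len) { # cap: t1 over the top to t2
      th <- (s - leg_len) / r_cap
      C0 - r_cap * cos(th) * v + r_cap * sin(th) * u
    } else {                            # leg 2: t2 -> b
      t2 <- C0 + r_cap * v
      f <- (s - leg_len - cap_len) / leg_len
      t2 + f * (b - t2)
    }
  }
  s_k <- path_len * seq_len(n_int) / (n_int + 1L)
  int_ca <- t(vapply(s_k, path_point, numeric(3)))
  ca_ext <- rbind(a, int_ca, b)
  int_bb <- matrix(NA_real_, n_int * 4L, 3L)
  for (k in seq_len(n_int)) {
    ca <- ca_ext[k + 1L, ]
    tg <- unit(ca_ext[k + 2L, ] - ca_ext[k, ])
    rad0 <- ca - mid
    rad0 <- rad0 - sum(rad0 * tg) * tg
    rad <- if (vec_norm(rad0) > 1e-6) unit(rad0) else u
    nrm <- unit(vec_cross(tg, rad))
    int_bb[(k - 1L) * 4L + 1L, ] <- ca - 1.35 * tg + 0.55 * rad # N
    int_bb[(k - 1L) * 4L + 2L, ] <- ca                          # CA
    int_bb[(k - 1L) * 4L + 3L, ] <- ca + 1.35 * tg + 0.55 * rad # C
    int_bb[(k - 1L) * 4L + 4L, ] <- ca + 1.35 * tg + 0.55 * rad +
      1.23 * nrm                                                # O
  }
  X <- rbind(X6[seq_len(ns * 4L), , drop = FALSE],
             first_keep, int_bb, last_keep,
             X6[(ns + dh$nloop) * 4L + seq_len(ns * 4L), , drop = FALSE])
  backbone_to_structure(X, split_seq(seq, 2L * ns + nl), id = id)
}

# Orient a cysteine SG pair across the hairpin loop: scan chi1 on both
# flanking cysteines (deterministic 5-degree grid) for the closest SG-SG
# approach.
add_disulfide_clamp <- function(s, res_a, res_b, chain = "A") {
  frames <- lapply(c(res_a, res_b), function(r)
    list(N = atom_coord(s, chain, r, "N"), CA = atom_coord(s, chain, r, "CA"),
         C = atom_coord(s, chain, r, "C")))
  grid <- seq(-180, 175, by = 5)
  sg_pos <- lapply(frames, function(f) {
    cb <- place_atom(f$C, f$N, f$CA, 1.530, 110.5, -122.5)
    t(vapply(grid, function(chi)
      place_atom(f$N, f$CA, cb, 1.808, 113.8, chi), numeric(3)))
  })
  # all chi1 x chi1 SG-SG distances; pick the pair closest to an S-S bond
  D <- as.matrix(stats::dist(rbind(sg_pos[[1]], sg_pos[[2]])))
  ng <- length(grid)
  sub <- abs(D[seq_len(ng), ng + seq_len(ng)] - 2.04)
  ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
  best <- list(
    build_sidechain("CYS", frames[[1]]$N, frames[[1]]$CA, frames[[1]]$C,
                    chis = grid[ij[1]]),
    build_sidechain("CYS", frames[[2]]$N, frames[[2]]$CA, frames[[2]]$C,
                    chis = grid[ij[2]]))
  for (k in 1:2) {
    r <- c(res_a, res_b)[k]
    ri <- s$chain == chain & s$resno == r
    keep <- !(ri & !(s$atom %in% c("N", "CA", "C", "O")))
    first <- which(ri)[1]
    sc <- best[[k]]
    s <- s[keep, , drop = FALSE]
    ri2 <- s$chain == chain & s$resno == r
    s$resname[ri2] <- "CYS"
    add <- tibble::tibble(chain = chain, resno = as.integer(r), ins = "",
                          resname = "CYS", atom = sc$atom,
                          element = sc$element, x = sc$x, y = sc$y, z = sc$z,
                          radius = vdw_radius(sc$element))
    pos <- max(which(ri2))
    s <- dplyr::bind_rows(s[seq_len(pos), ], add,
                          s[seq_len(nrow(s)) > pos, ])
  }
  new_structure(s, id = structure_id(s))
}

# Two short helices whose bodies are far out of contact range, joined by a
# long, gently bowed crossover loop. The loop is anchored only at its ends,
# so it is genuinely mobile in the network model: the free-loop counterpart
# of the clamped hairpin site.
build_helix_loop_helix <- function(seq, id) {
  nh <- 7L; nl <- 8L; chord_len <- 30
  Xh <- build_backbone(rep(-57, nh), rep(-47, nh))
  ca <- function(X, i) X[(i - 1L) * 4L + 2L, ]
  axis <- unit(ca(Xh, nh) - ca(Xh, 1L))
  w0 <- c(1, 0, 0)
  if (abs(sum(w0 * axis)) > 0.9) w0 <- c(0, 1, 0)
  w <- unit(w0 - sum(w0 * axis) * axis)      # perpendicular to the helix axis
  a <- ca(Xh, nh)
  b <- a + chord_len * w
  Xh2 <- sweep(Xh, 2, b - ca(Xh, 1L), `+`)   # translated copy, same axis
  u <- unit(vec_cross(axis, w))              # bow direction, clear of both
  path_len <- (nl + 1L) * 3.8
  g <- function(R) 2 * R * asin(min(chord_len / (2 * R), 1)) - path_len
  R <- stats::uniroot(g, c(chord_len / 2 + 1e-9, 2000))$root
  th_tot <- 2 * asin(chord_len / (2 * R))
  mid <- (a + b) / 2
  O <- mid - sqrt(R^2 - (chord_len / 2)^2) * u
  e1 <- unit(a - O)
  e2 <- unit((b - O) - sum((b - O) * e1) * e1)
  th <- th_tot * seq_len(nl) / (nl + 1L)
  loop_ca <- t(vapply(th, function(t)
    O + R * (cos(t) * e1 + sin(t) * e2), numeric(3)))
  ca_ext <- rbind(a, loop_ca, b)
  loop_bb <- matrix(NA_real_, nl * 4L, 3L)
  for (k in seq_len(nl)) {
    cak <- ca_ext[k + 1L, ]
    tg <- unit(ca_ext[k + 2L, ] - ca_ext[k, ])
    rad <- unit(cak - O)
    rad <- unit(rad - sum(rad * tg) * tg)
    nrm <- unit(vec_cross(tg, rad))
    loop_bb[(k - 1L) * 4L + 1L, ] <- cak - 1.35 * tg + 0.55 * rad
    loop_bb[(k - 1L) * 4L + 2L, ] <- cak
    loop_bb[(k - 1L) * 4L + 3L, ] <- cak + 1.35 * tg + 0.55 * rad
    loop_bb[(k - 1L) * 4L + 4L, ] <- cak + 1.35 * tg + 0.55 * rad + 1.23 * nrm
  }
  X <- rbind(Xh, loop_bb, Xh2)
  backbone_to_structure(X, split_seq(seq, 2L * nh + nl), id = id)
}

rotation_between <- function(a, b) {
  # rotation matrix mapping unit vector a onto unit vector b (Rodrigues)
  a <- unit(a); b <- unit(b)
  v <- vec_cross(a, b)
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) { # opposite: rotate 180 about any perpendicular
    p <- if (abs(a[1]) < 0.9) vec_cross(a, c(1, 0, 0)) else vec_cross(a, c(0, 1, 0))
    p <- unit(p)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

build_toy_complex <- function(contacts, n_lig, id) {
  # ligand: extended chain, ARG at designed contact positions
  seq1 <- rep("A", n_lig)
  seq1[contacts] <- "R"
  phi <- rep(-139, n_lig); psi <- rep(135, n_lig)
  X <- build_backbone(phi, psi)
  lig <- backbone_to_structure(X, seq1, id = id, chain = "L")
  # ARG side chains fully extended toward their pleat side
  for (r in contacts) {
    ri <- lig$chain == "L" & lig$resno == r
    frames <- list(N = atom_coord(lig, "L", r, "N"),
                   CA = atom_coord(lig, "L", r, "CA"),
                   C = atom_coord(lig, "L", r, "C"))
    sc <- build_sidechain("ARG", frames$N, frames$CA, frames$C,
                          chis = c(180, 180, 180, 180))
    keep <- !(ri & !(lig$atom %in% c("N", "CA", "C", "O")))
    lig <- lig[keep, , drop = FALSE]
    ri2 <- lig$chain == "L" & lig$resno == r
    pos <- max(which(ri2))
    add <- tibble::tibble(chain = "L", resno = as.integer(r), ins = "",
                          resname = "ARG", atom = sc$atom,
                          element = sc$element, x = sc$x, y = sc$y, z = sc$z,
                          radius = vdw_radius(sc$element))
    lig <- dplyr::bind_rows(lig[seq_len(pos), ], add,
                            lig[seq_len(nrow(lig)) > pos, ])
  }
  lig <- new_structure(lig, id = id)
  # receptor: one glutamate placed opposite each designed arginine tip,
  # carboxylate midpoint 2.9 A out along the side-chain direction
  glu_bb <- build_backbone(-139, 135)
  glu_sc <- build_sidechain("GLU", glu_bb[1, ], glu_bb[2, ], glu_bb[3, ],
                            chis = c(180, 180, 0))
  glu <- rbind(glu_bb, as.matrix(glu_sc[, c("x", "y", "z")]))
  glu_names <- c("N", "CA", "C", "O", glu_sc$atom)
  glu_elem <- c("N", "C", "C", "O", glu_sc$element)
  oe_mid <- (unlist(glu_sc[glu_sc$atom == "OE1", c("x", "y", "z")]) +
             unlist(glu_sc[glu_sc$atom == "OE2", c("x", "y", "z")])) / 2
  glu_dir <- unit(oe_mid - glu_bb[2, ]) # CA -> carboxylate
  rec_rows <- list()
  for (k in seq_along(contacts)) {
    r <- contacts[k]
    ca <- atom_coord(lig, "L", r, "CA")
    nh1 <- atom_coord(lig, "L", r, "NH1")
    nh2 <- atom_coord(lig, "L", r, "NH2")
    tip <- (nh1 + nh2) / 2
    dir_out <- unit(tip - ca)
    targ <- tip + 3.5 * dir_out
    R <- rotation_between(glu_dir, -dir_out)
    moved <- sweep((sweep(glu, 2, oe_mid) %*% t(R)), 2, targ, `+`)
    rec_rows[[k]] <- tibble::tibble(
      chain = "R", resno = k, ins = "", resname = "GLU", atom = glu_names,
      element = glu_elem, x = moved[, 1], y = moved[, 2], z = moved[, 3],
      radius = vdw_radius(glu_elem))
  }
  new_structure(dplyr::bind_rows(list(lig), rec_rows), id = id)
}

.fixture_cache <- new.env(parent = emptyenv())

#' Build a synthetic fixture structure
#'
#' Deterministic idealized structures with designed ground truth:
#' \describe{
#'   \item{helix}{`n` residues at phi/psi -57/-47.}
#'   \item{strand}{`n` residues at phi/psi -120/+120.}
#'   \item{linear_peptide}{`n` residues in an extended conformation with
#'     free termini.}
#'   \item{hairpin}{two 9-residue antiparallel strands joined by a loop;
#'     `loop = 6` (default) is a compact clash-free loop, `loop = 10` a
#'     wide bulge that arcs away from the scaffold.}
#'   \item{clamped_hairpin}{the loop-6 hairpin with the loop pulled against
#'     the strands and the two loop-flanking residues replaced by a
#'     disulfide-bonded cysteine pair.}
#'   \item{helix_loop_helix}{two 7-residue helices, far out of mutual
#'     contact range, joined by an 8-residue crossover loop anchored only
#'     at its ends: a free-loop site that no graft can immobilise.}
#'   \item{toy_complex}{ligand chain `L` (extended, arginines at the
#'     designed `contacts` positions) plus receptor chain `R` (one
#'     glutamate facing each designed arginine at salt-bridge distance).}
#' }
#'
#' @param kind One of `"helix"`, `"strand"`, `"linear_peptide"`,
#'   `"hairpin"`, `"clamped_hairpin"`, `"helix_loop_helix"`,
#'   `"toy_complex"`.
#' @param n Residue count for helix/strand/linear_peptide (defaults 12, 8,
#'   6), or ligand length for toy_complex (default 28).
#' @param loop Hairpin loop length, 6 or 10.
#' @param seq Optional sequence (one-letter); defaults to poly-alanine with
#'   kind-specific substitutions.
#' @param contacts Designed ligand contact positions for toy_complex
#'   (default 10:15).
#' @param id Structure id; defaults to the kind.
#' @return A structure tibble.
#' @export
fixture_structure <- function(kind = c("helix", "strand", "linear_peptide",
                                       "hairpin", "clamped_hairpin",
                                       "helix_loop_helix", "toy_complex"),
                              n = NULL, loop = 6, seq = NULL,
                              contacts = 10:15, id = NULL) {
  kind <- match.arg(kind)
  id <- id %||% kind
  # fixtures are fully deterministic, so memoise by argument signature
  key <- paste(kind, n %||% "", loop, seq %||% "",
               paste(contacts, collapse = ","), id, sep = "~")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  on.exit(if (exists("out_cache", inherits = FALSE))
    assign(key, out_cache, envir = .fixture_cache))
  cache_and_return <- function(x) { out_cache <<- x; x }
  if (kind %in% c("helix", "strand", "linear_peptide")) {
    n <- n %||% switch(kind, helix = 12L, strand = 8L, linear_peptide = 6L)
    ang <- switch(kind, helix = c(-57, -47), c(-120, 120))
    X <- build_backbone(rep(ang[1], n), rep(ang[2], n))
    return(cache_and_return(backbone_to_structure(X, split_seq(seq, n),
                                                  id = id)))
  }
  if (kind %in% c("hairpin", "clamped_hairpin")) {
    if (!loop %in% c(6L, 10L))
      stop("supported hairpin loop lengths are 6 and 10")
    if (kind == "clamped_hairpin" && loop != 6L)
      stop("the clamped hairpin uses the 6-residue loop")
    if (loop == 10L)
      return(cache_and_return(build_bulge_hairpin(
        split_seq(seq, 2L * .hairpin_nstrand + 10L) |> paste(collapse = ""),
        id = id)))
    key <- if (kind == "clamped_hairpin") "clamped" else "open"
    dh <- hairpin_dihedrals(key)
    ntot <- 2L * .hairpin_nstrand + dh$nloop
    X <- build_backbone(dh$phi, dh$psi)
    s <- backbone_to_structure(X, split_seq(seq, ntot), id = id)
    if (kind == "clamped_hairpin") {
      ns <- .hairpin_nstrand
      s <- add_disulfide_clamp(s, ns, ns + dh$nloop + 1L)
    }
    return(cache_and_return(s))
  }
  if (kind == "helix_loop_helix")
    return(cache_and_return(build_helix_loop_helix(
      paste(split_seq(seq, 22L), collapse = ""), id = id)))
  # toy_complex
  n <- n %||% 28L
  stopifnot(all(contacts >= 1), all(contacts <= n))
  cache_and_return(build_toy_complex(sort(unique(contacts)), n, id = id))
}

#' Build a synthetic conformational ensemble
#'
#' Frames are the reference structure plus independent per-residue Gaussian
#' jitter (one displacement vector per residue per frame, applied to all its
#' atoms), optionally followed by a random rigid-body motion of the whole
#' frame to exercise superposition.
#'
#' @param s Reference structure tibble.
#' @param frames Number of frames (>= 2).
#' @param sigma Per-axis jitter standard deviation in Angstrom: a scalar or
#'   a per-residue vector (structure residue order).
#' @param seed Random seed; recorded in the result.
#' @param rigid_noise Add per-frame random rigid rotation (up to ~10 deg)
#'   and translation (up to 2 A)?
#' @return A `flap_ensemble` with attribute `seed` and `sigma`.
#' @export
fixture_ensemble <- function(s, frames = 500, sigma = 0.3, seed = 1,
                             rigid_noise = FALSE) {
  stopifnot(frames >= 2, all(sigma >= 0))
  rt <- residue_table(s)
  nres <- nrow(rt)
  if (length(sigma) == 1L) sigma <- rep(sigma, nres)
  stopifnot(length(sigma) == nres)
  key_all <- res_key(s$chain, s$resno, s$ins)
  key_res <- res_key(rt$chain, rt$resno, rt$ins)
  res_idx <- match(key_all, key_res)
  X0 <- coords_matrix(s)
  n <- nrow(X0)
  xyz <- array(NA_real_, c(frames, n, 3))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (f in seq_len(frames)) {
    disp <- matrix(stats::rnorm(nres * 3), nres, 3) * sigma
    Xf <- X0 + disp[res_idx, , drop = FALSE]
    if (rigid_noise) {
      ax <- unit(stats::rnorm(3))
      th <- stats::runif(1, -10, 10) * pi / 180
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      tr <- stats::runif(3, -2, 2)
      Xf <- sweep(Xf %*% t(R), 2, tr, `+`)
    }
    xyz[f, , ] <- Xf
  }
  e <- new_ensemble(s, xyz)
  attr(e, "seed") <- seed
  attr(e, "sigma") <- sigma
  e
}

#' Write a fixture manifest
#'
#' Records the fixture kind, seed and designed ground truth as structured
#' text (YAML) next to the generated structures.
#'
#' @param path Output file.
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @export
write_fixture_manifest <- function(path, ...) {
  yaml::write_yaml(list(...), path)
  invisible(path)
}
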