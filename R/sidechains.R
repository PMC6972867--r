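# Idealized side-chain templates built from internal coordinates, with a
# discrete rotamer search. Geometry: bond lengths/angles from standard
# amino-acid dictionaries; the CB chirality constant (dihedral C-N-CA-CB =
# -122.5 deg) reproduces L-amino acids.

# Each atom: ref atoms a/b/c (torsion dihedral(a,b,c,new), angle(b,c,new)),
# bond length, bond angle, and a torsion spec: number = fixed degrees,
# "cK" = rotatable chi K, "cK+off"/"cK-off" = chi K plus offset.
.sc_topo <- list(
  ALA = list(),
  GLY = NULL, # no side chain, not even CB
  SER = list(list("OG", "O", c("N", "CA", "CB"), 1.417, 110.8, "c1")),
  CYS = list(list("SG", "S", c("N", "CA", "CB"), 1.808, 113.8, "c1")),
  THR = list(list("OG1", "O", c("N", "CA", "CB"), 1.433, 109.5, "c1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.521, 110.5, "c1-120")),
  VAL = list(list("CG1", "C", c("N", "CA", "CB"), 1.527, 110.5, "c1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.527, 110.5, "c1+122")),
  LEU = list(list("CG", "C", c("N", "CA", "CB"), 1.530, 116.3, "c1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.524, 110.7, "c2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.524, 110.7, "c2+122")),
  ILE = list(list("CG1", "C", c("N", "CA", "CB"), 1.530, 110.4, "c1"),
             list("CG2", "C", c("N", "CA", "CB"), 1.530, 110.5, "c1-122"),
             list("CD1", "C", c("CA", "CB", "CG1"), 1.513, 113.8, "c2")),
  MET = list(list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, "c1"),
             list("SD", "S", c("CA", "CB", "CG"), 1.803, 112.7, "c2"),
             list("CE", "C", c("CB", "CG", "SD"), 1.791, 100.9, "c3")),
  PRO = list(list("CG", "C", c("N", "CA", "CB"), 1.492, 104.5, 30),
             list("CD", "C", c("CA", "CB", "CG"), 1.503, 106.1, -35)),
  PHE = list(list("CG", "C", c("N", "CA", "CB"), 1.502, 113.8, "c1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.390, 120.8, "c2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.390, 120.8, "c2+180"),
             list("CE1", "C", c("CB", "CG", "CD1"), 1.390, 121.0, 180),
             list("CE2", "C", c("CB", "CG", "CD2"), 1.390, 121.0, 180),
             list("CZ", "C", c("CG", "CD1", "CE1"), 1.390, 120.0, 0)),
  TYR = list(list("CG", "C", c("N", "CA", "CB"), 1.502, 113.8, "c1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.390, 120.8, "c2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.390, 120.8, "c2+180"),
             list("CE1", "C", c("CB", "CG", "CD1"), 1.390, 121.0, 180),
             list("CE2", "C", c("CB", "CG", "CD2"), 1.390, 121.0, 180),
             list("CZ", "C", c("CG", "CD1", "CE1"), 1.390, 120.0, 0),
             list("OH", "O", c("CD1", "CE1", "CZ"), 1.380, 119.9, 180)),
  TRP = list(list("CG", "C", c("N", "CA", "CB"), 1.500, 113.6, "c1"),
             list("CD1", "C", c("CA", "CB", "CG"), 1.365, 126.9, "c2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.433, 126.7, "c2+180"),
             list("NE1", "N", c("CB", "CG", "CD1"), 1.374, 110.2, 180),
             list("CE2", "C", c("CB", "CG", "CD2"), 1.409, 107.2, 180),
             list("CE3", "C", c("CB", "CG", "CD2"), 1.398, 133.9, 0),
             list("CZ2", "C", c("CG", "CD2", "CE2"), 1.394, 122.4, 180),
             list("CZ3", "C", c("CG", "CD2", "CE3"), 1.382, 118.6, 180),
             list("CH2", "C", c("CD2", "CE3", "CZ3"), 1.400, 121.1, 0)),
  ASP = list(list("CG", "C", c("N", "CA", "CB"), 1.516, 112.6, "c1"),
             list("OD1", "O", c("CA", "CB", "CG"), 1.249, 118.4, "c2"),
             list("OD2", "O", c("CA", "CB", "CG"), 1.249, 118.4, "c2+180")),
  ASN = list(list("CG", "C", c("N", "CA", "CB"), 1.516, 112.6, "c1"),
             list("OD1", "O", c("CA", "CB", "CG"), 1.231, 120.8, "c2"),
             list("ND2", "N", c("CA", "CB", "CG"), 1.328, 116.4, "c2+180")),
  GLU = list(list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, "c1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.516, 112.6, "c2"),
             list("OE1", "O", c("CB", "CG", "CD"), 1.249, 118.4, "c3"),
             list("OE2", "O", c("CB", "CG", "CD"), 1.249, 118.4, "c3+180")),
  GLN = list(list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, "c1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.516, 112.6, "c2"),
             list("OE1", "O", c("CB", "CG", "CD"), 1.231, 120.8, "c3"),
             list("NE2", "N", c("CB", "CG", "CD"), 1.328, 116.4, "c3+180")),
  LYS = list(list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, "c1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, "c2"),
             list("CE", "C", c("CB", "CG", "CD"), 1.520, 111.3, "c3"),
             list("NZ", "N", c("CG", "CD", "CE"), 1.489, 111.9, "c4")),
  ARG = list(list("CG", "C", c("N", "CA", "CB"), 1.520, 114.1, "c1"),
             list("CD", "C", c("CA", "CB", "CG"), 1.520, 111.3, "c2"),
             list("NE", "N", c("CB", "CG", "CD"), 1.461, 112.0, "c3"),
             list("CZ", "C", c("CG", "CD", "NE"), 1.329, 124.2, "c4"),
             list("NH1", "N", c("CD", "NE", "CZ"), 1.326, 120.0, 0),
             list("NH2", "N", c("CD", "NE", "CZ"), 1.326, 120.0, 180)),
  HIS = list(list("CG", "C", c("N", "CA", "CB"), 1.500, 113.8, "c1"),
             list("ND1", "N", c("CA", "CB", "CG"), 1.378, 122.7, "c2"),
             list("CD2", "C", c("CA", "CB", "CG"), 1.354, 131.0, "c2+180"),
             list("CE1", "C", c("CB", "CG", "ND1"), 1.320, 109.0, 180),
             list("NE2", "N", c("CB", "CG", "CD2"), 1.374, 107.0, 180))
)

.n_chi <- c(ALA = 0, GLY = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, PRO = 0,
            LEU = 2, ILE = 2, ASP = 2, ASN = 2, HIS = 2, PHE = 2, TYR = 2,
            TRP = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4)

.aromatic <- c("PHE", "TYR", "TRP", "HIS")

# Discrete chi angle options used in the rotamer search (degrees).
chi_options <- function(resname, k) {
  if (resname %in% .aromatic && k == 2L) c(90, -90) else c(-60, 180, 60)
}

# All rotamer combinations for a residue type, most-common-first so ties in
# clash count resolve deterministically to the canonical rotamer.
rotamer_set <- function(resname) {
  nc <- .n_chi[[resname]]
  if (is.na(nc) || nc == 0L) return(matrix(numeric(0), nrow = 1))
  opts <- lapply(seq_len(nc), function(k) chi_options(resname, k))
  as.matrix(rev(expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)))
}

parse_torsion <- function(spec, chis) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^c([0-9]+)([+-][0-9.]+)?$", spec))[[1]]
  k <- as.integer(m[2])
  off <- if (m[3] == "") 0 else as.numeric(m[3])
  chis[k] + off
}

# Fast internal variant: returns list(atom, element, xyz matrix).
build_sidechain_mat <- function(resname, N, CA, C, chis = numeric(0)) {
  if (resname == "GLY")
    return(list(atom = character(0), element = character(0),
                xyz = matrix(numeric(0), 0, 3)))
  topo <- .sc_topo[[resname]]
  if (is.null(topo)) topo <- list()
  n_at <- 1L + length(topo)
  atoms <- character(n_at); elems <- character(n_at)
  xyz <- matrix(NA_real_, n_at, 3)
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_atom(C, N, CA, 1.530, 110.5, -122.5)
  atoms[1] <- "CB"; elems[1] <- "C"; xyz[1, ] <- pos$CB
  k <- 1L
  for (at in topo) {
    refs <- at[[3]]
    tor <- parse_torsion(at[[6]], chis)
    p <- place_atom(pos[[refs[1]]], pos[[refs[2]]], pos[[refs[3]]],
                    at[[4]], at[[5]], tor)
    pos[[at[[1]]]] <- p
    k <- k + 1L
    atoms[k] <- at[[1]]; elems[k] <- at[[2]]; xyz[k, ] <- p
  }
  list(atom = atoms, element = elems, xyz = xyz)
}

# Build side-chain heavy atoms (including CB, except GLY) for one residue
# from its backbone N/CA/C positions and chi angles. Returns a tibble
# (atom, element, x, y, z).
build_sidechain <- function(resname, N, CA, C, chis = numeric(0)) {
  m <- build_sidechain_mat(resname, N, CA, C, chis)
  tibble::tibble(atom = m$atom, element = m$element,
                 x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3])
}

# Count steric clashes between a candidate atom set and an environment:
# heavy-atom pairs closer than 0.8 * (sum of vdW radii).
clash_count <- function(cand_xyz, cand_rad, env_xyz, env_rad) {
  if (nrow(cand_xyz) == 0L || nrow(env_xyz) == 0L) return(0L)
  n <- 0L
  for (i in seq_len(nrow(cand_xyz))) {
    d <- sqrt((env_xyz[, 1] - cand_xyz[i, 1])^2 +
              (env_xyz[, 2] - cand_xyz[i, 2])^2 +
              (env_xyz[, 3] - cand_xyz[i, 3])^2)
    n <- n + sum(d < 0.8 * (cand_rad[i] + env_rad))
  }
  n
}

# Replace the side chain of one residue in a structure, searching the
# discrete rotamer set for the minimal clash count against the rest of the
# structure. Returns the modified structure.
mutate_residue <- function(s, chain, resno, new_resname, ins = "") {
  ri <- s$chain == chain & s$resno == resno & s$ins == ins
  if (!any(ri)) stop("residue ", chain, ":", resno, " not found")
  bbN <- atom_coord(s, chain, resno, "N", ins)
  bbCA <- atom_coord(s, chain, resno, "CA", ins)
  bbC <- atom_coord(s, chain, resno, "C", ins)
  if (is.null(bbN) || is.null(bbCA) || is.null(bbC))
    stop("residue ", chain, ":", resno, " has an unresolvable backbone (missing N/CA/C)")
  keep_bb <- ri & s$atom %in% c("N", "CA", "C", "O")
  env <- s[!ri, , drop = FALSE]
  env_xyz <- coords_matrix(env)
  env_rad <- env$radius
  rots <- rotamer_set(new_resname)
  best <- NULL; best_clash <- Inf
  for (r in seq_len(nrow(rots))) {
    sc <- build_sidechain_mat(new_resname, bbN, bbCA, bbC, chis = rots[r, ])
    cl <- clash_count(sc$xyz, vdw_radius(sc$element), env_xyz, env_rad)
    if (cl < best_clash) { best <- sc; best_clash <- cl }
    if (best_clash == 0L) break
  }
  best <- tibble::tibble(atom = best$atom, element = best$element,
                         x = best$xyz[, 1], y = best$xyz[, 2],
                         z = best$xyz[, 3])
  first <- which(ri)[1]
  bb <- s[keep_bb, , drop = FALSE]
  bb$resname <- new_resname
  sc_rows <- tibble::tibble(
    chain = chain, resno = as.integer(resno), ins = ins,
    resname = new_resname, atom = best$atom, element = best$element,
    x = best$x, y = best$y, z = best$z, radius = vdw_radius(best$element))
  before <- s[seq_len(nrow(s)) < first & !ri, , drop = FALSE]
  after <- s[seq_len(nrow(s)) > first & !ri, , drop = FALSE]
  out <- dplyr::bind_rows(before, bb, sc_rows, after)
  new_structure(out, id = structure_id(s))
}
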