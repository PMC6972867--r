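# Fluctuation (RMSF) backends: conformational ensembles and the Gaussian
# network model (GNM). Profiles are per-heavy-atom tibbles so site means are
# averages over "all hydrogen-free atoms" of a window.

new_ensemble <- function(structure, xyz, frame_spacing = NA_real_) {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == nrow(structure),
            dim(xyz)[3] == 3L)
  out <- list(structure = structure, xyz = xyz, frame_spacing = frame_spacing)
  class(out) <- "flap_ensemble"
  out
}

#' @export
print.flap_ensemble <- function(x, ...) {
  cat("# A conformational ensemble: ", dim(x$xyz)[1], " frames x ",
      dim(x$xyz)[2], " heavy atoms (", structure_id(x$structure), ")\n", sep = "")
  invisible(x)
}

#' Read a multi-model PDB as a conformational ensemble
#'
#' Each MODEL becomes one frame; the atom list of the first model defines the
#' reference. Hydrogens and waters are dropped as in [read_structure()].
#'
#' @param path Path to a multi-model PDB file.
#' @param id Ensemble identifier.
#' @return A `flap_ensemble`: list with `structure` (reference tibble) and
#'   `xyz` (frames x atoms x 3 array).
#' @export
read_ensemble <- function(path, id = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(trimws(at$elety[bad]), 1L, 1L)
  keep <- !(elem %in% c("H", "D")) & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("no standard residues in '", path, "'")
  ref <- new_structure(tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), ins = at$insert,
    resname = at$resid, atom = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z, radius = vdw_radius(elem)
  ), id = id %||% sub("\\.(pdb|ent)$", "", basename(path)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  xyz <- xyz[, cols, drop = FALSE]
  f <- nrow(xyz)
  arr <- array(NA_real_, c(f, nrow(ref), 3))
  for (k in seq_len(f)) arr[k, , ] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  new_ensemble(ref, arr)
}

profile_tibble <- function(s, rmsf, backend, calibration = NA_real_) {
  out <- tibble::tibble(chain = s$chain, resno = s$resno, ins = s$ins,
                        resname = s$resname, atom = s$atom, rmsf = rmsf)
  attr(out, "backend") <- backend
  attr(out, "calibration") <- calibration
  class(out) <- unique(c("flap_rmsf", class(out)))
  out
}

#' Per-atom RMSF from a conformational ensemble
#'
#' Frames are least-squares superposed (Kabsch) onto the reference using the
#' fit selection, then the RMSF of every heavy atom about its mean position
#' is computed over the analysis window.
#'
#' @param e A `flap_ensemble`.
#' @param fit_selection Logical or integer index of atoms used for the
#'   superposition. Default: all atoms. The recommended scaffold practice is
#'   all backbone atoms outside the window under study, via
#'   [backbone_fit_selection()].
#' @param window Integer vector of frame indices to analyse. Default: the
#'   final half of the frames.
#' @return A per-atom RMSF tibble (columns `chain`, `resno`, `ins`,
#'   `resname`, `atom`, `rmsf`), backend `"ensemble"`.
#' @export
rmsf_from_ensemble <- function(e, fit_selection = NULL, window = NULL) {
  stopifnot(inherits(e, "flap_ensemble"))
  f <- dim(e$xyz)[1]
  if (f < 2L) stop("RMSF undefined for a single frame")
  if (is.null(window)) window <- seq.int(max(1L, floor(f / 2) + 1L), f)
  stopifnot(all(window >= 1L), all(window <= f), length(window) >= 2L)
  n <- dim(e$xyz)[2]
  if (is.null(fit_selection)) fit_selection <- seq_len(n)
  if (is.logical(fit_selection)) fit_selection <- which(fit_selection)
  if (length(fit_selection) == 0L) stop("empty fit selection")
  ref <- coords_matrix(e$structure)
  fitted <- array(NA_real_, c(length(window), n, 3))
  for (k in seq_along(window)) {
    fr <- e$xyz[window[k], , ]
    fit <- kabsch_fit(fr[fit_selection, , drop = FALSE],
                      ref[fit_selection, , drop = FALSE])
    fitted[k, , ] <- apply_fit(fr, fit)
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- sweep(fitted, c(2, 3), mean_pos)^2
  # dev2 is frames x atoms x 3: sum squared deviation over xyz, mean over frames
  rmsf <- sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))
  profile_tibble(e$structure, rmsf, backend = "ensemble")
}

#' Backbone fit selection excluding a residue window
#'
#' @param s A structure tibble.
#' @param chain,start,end Window to exclude (author numbering, inclusive).
#' @return Logical atom index suitable for `fit_selection`.
#' @export
backbone_fit_selection <- function(s, chain = NULL, start = NULL, end = NULL) {
  sel <- s$atom %in% c("N", "CA", "C", "O")
  if (!is.null(chain)) sel <- sel & !window_atom_idx(s, chain, start, end)
  sel
}

# Kirchhoff (connectivity) matrix on C-alpha nodes.
kirchhoff_matrix <- function(ca_xyz, cutoff) {
  D <- as.matrix(stats::dist(ca_xyz))
  K <- -(D <= cutoff) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  K
}

# Connected components of the contact graph (BFS).
graph_components <- function(K) {
  n <- nrow(K)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(K[v, ] != 0 & seq_len(n) != v & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Mean-square fluctuations from the pseudoinverse diagonal of the Kirchhoff
# matrix, via eigendecomposition with the zero mode removed.
gnm_msf <- function(K, tol = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  n <- nrow(K)
  keep <- e$values > tol * max(e$values)
  v <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  rowSums(sweep(v^2, 2, lam, `/`))
}

#' Per-atom RMSF from a Gaussian network model
#'
#' Builds the Kirchhoff matrix on C-alpha nodes with a distance cutoff; the
#' diagonal of its pseudoinverse gives per-residue mean-square fluctuations,
#' scaled into Angstrom by an explicit calibration constant and broadcast to
#' each residue's heavy atoms.
#'
#' @param s A structure tibble (>= 3 C-alpha atoms).
#' @param cutoff Contact cutoff in Angstrom (default 7.5).
#' @param temperature Temperature in K; fluctuations scale with sqrt(T/300).
#' @param calibration Scale constant (Angstrom per mode unit). Obtain one
#'   with [enm_calibration()]; default 1 leaves the profile in model units.
#' @return A per-atom RMSF tibble, backend `"enm"`.
#' @export
rmsf_from_enm <- function(s, cutoff = 7.5, temperature = 300, calibration = 1) {
  stopifnot(cutoff > 0, temperature > 0, calibration > 0)
  ca <- s[s$atom == "CA", , drop = FALSE]
  if (nrow(ca) < 3L) stop("need at least 3 C-alpha atoms for the network model")
  K <- kirchhoff_matrix(coords_matrix(ca), cutoff)
  comp <- graph_components(K)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("contact graph is disconnected at cutoff ", cutoff, " A: ",
         length(sizes), " components of sizes ",
         paste(sizes, collapse = ", "))
  }
  msf <- gnm_msf(K)
  res_rmsf <- calibration * sqrt(msf * temperature / 300)
  key_ca <- res_key(ca$chain, ca$resno, ca$ins)
  key_all <- res_key(s$chain, s$resno, s$ins)
  idx <- match(key_all, key_ca)
  if (anyNA(idx)) {
    # residues without CA (non-standard): give them the chain-median value
    fill <- stats::median(res_rmsf)
    atom_rmsf <- ifelse(is.na(idx), fill, res_rmsf[idx])
  } else atom_rmsf <- res_rmsf[idx]
  profile_tibble(s, atom_rmsf, backend = "enm", calibration = calibration)
}

#' Calibration constant for the network-model backend
#'
#' Returns the constant that maps raw network-model fluctuations to Angstrom
#' such that the median C-alpha RMSF of the reference structure equals
#' `target`. Grafting thresholds (1.0 and 1.5 Angstrom) are meaningful only
#' relative to such a calibration.
#'
#' @param s Reference structure tibble (typically the fixture hairpin).
#' @param target Target median C-alpha RMSF in Angstrom (default 0.8).
#' @param cutoff,temperature As in [rmsf_from_enm()].
#' @return A positive scalar.
#' @export
enm_calibration <- function(s, target = 0.8, cutoff = 7.5, temperature = 300) {
  stopifnot(target > 0)
  raw <- rmsf_from_enm(s, cutoff = cutoff, temperature = temperature,
                       calibration = 1)
  med <- stats::median(raw$rmsf[raw$atom == "CA"])
  target / med
}

#' Mean RMSF of a hexapeptide site
#'
#' Arithmetic mean of the per-atom RMSF over all heavy atoms of the six
#' residues of a site.
#'
#' @param profile A per-atom RMSF tibble.
#' @param site A one-row site tibble with columns `chain` and `start` (see
#'   [enumerate_loop_hexapeptides()]).
#' @return Mean RMSF in Angstrom.
#' @export
site_mean_rmsf <- function(profile, site) {
  stopifnot(nrow(site) == 1L)
  idx <- profile$chain == site$chain &
    profile$resno >= site$start & profile$resno <= site$start + 5L
  resnos <- unique(profile$resno[idx])
  if (length(resnos) != 6L)
    stop("site ", site$chain, ":", site$start, "-", site$start + 5L,
         " not fully covered by the fluctuation profile")
  mean(profile$rmsf[idx])
}

#' Import an externally computed per-atom RMSF table
#'
#' Reads a whitespace/tab-delimited table with columns `atom_index` and
#' `rmsf_A` (e.g. exported from an MD analysis) and attaches it to the atoms
#' of `s` by 1-based atom index.
#'
#' @param s A structure tibble the table refers to.
#' @param path Path to the table.
#' @return A per-atom RMSF tibble, backend `"ensemble"`.
#' @export
read_rmsf_table <- function(s, path) {
  tab <- utils::read.table(path, header = TRUE)
  if (!all(c("atom_index", "rmsf_A") %in% names(tab)))
    stop("RMSF table needs columns atom_index and rmsf_A")
  if (nrow(tab) != nrow(s))
    stop("RMSF table has ", nrow(tab), " rows but the structure has ",
         nrow(s), " heavy atoms")
  rmsf <- tab$rmsf_A[order(tab$atom_index)]
  if (any(rmsf < 0)) stop("negative RMSF values in table")
  profile_tibble(s, rmsf, backend = "ensemble")
}
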