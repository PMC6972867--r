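# Antigen-contact CDR hexapeptide identification and alanine-hexapeptide
# binding-energy-loss scanning.
#
# The interface score is a simplified physics energy (Lennard-Jones +
# Coulomb with a distance-dependent dielectric eps(r) = 4r + optional burial
# term). It is deliberately coarse: absolute values are in model units, not
# force-field kcal/mol, and selection is rank-based by default.

# Per-element Lennard-Jones parameters (sigma in Angstrom, epsilon kcal/mol).
.lj_params <- list(
  C = c(sigma = 3.40, eps = 0.10),
  N = c(sigma = 3.25, eps = 0.17),
  O = c(sigma = 2.96, eps = 0.21),
  S = c(sigma = 3.55, eps = 0.25),
  P = c(sigma = 3.74, eps = 0.20)
)

lj_sigma <- function(el) {
  v <- vapply(.lj_params, `[[`, numeric(1), "sigma")
  out <- v[el]; out[is.na(out)] <- 3.40; unname(out)
}
lj_eps <- function(el) {
  v <- vapply(.lj_params, `[[`, numeric(1), "eps")
  out <- v[el]; out[is.na(out)] <- 0.10; unname(out)
}

# Coarse per-atom partial charges (versioned data file shipped with the
# package): ionizable side-chain termini carry split formal charges and the
# backbone amide/carbonyl dipoles are represented; all other atoms are
# neutral.
charge_table <- function() {
  path <- system.file("extdata", "partial_charges.tsv", package = "flapr")
  if (path == "") path <- file.path("inst", "extdata", "partial_charges.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

atom_charges <- function(s) {
  tab <- charge_table()
  q <- numeric(nrow(s))
  generic <- tab[tab$resname == "*", ]
  idx <- match(s$atom, generic$atom)
  q[!is.na(idx)] <- generic$charge[idx[!is.na(idx)]]
  specific <- tab[tab$resname != "*", ]
  key_s <- paste(s$resname, s$atom)
  idx2 <- match(key_s, paste(specific$resname, specific$atom))
  q[!is.na(idx2)] <- specific$charge[idx2[!is.na(idx2)]]
  q
}

#' Energy-model configuration
#'
#' @param cutoff Pairwise interaction cutoff in Angstrom (default 12).
#' @param dielectric_factor The distance-dependent dielectric is
#'   `eps(r) = dielectric_factor * r` (default 4).
#' @param burial Include the per-residue burial solvation term (default
#'   FALSE; adds `-burial_coef *` buried interface area to binding energies).
#' @param burial_coef Burial coefficient in energy units per Angstrom^2.
#' @param clash_dist Interface atom pairs closer than this (Angstrom) raise
#'   a steric-clash error (default 0.5).
#' @param relax `"none"` (single-point, the default) or `"sd"`
#'   (fixed-step steepest descent before scoring).
#' @param sd_steps,sd_step Iteration cap and step size (Angstrom) for
#'   steepest-descent relaxation.
#' @return A validated configuration list.
#' @export
energy_config <- function(cutoff = 12, dielectric_factor = 4, burial = FALSE,
                          burial_coef = 0.005, clash_dist = 0.5,
                          relax = c("none", "sd"), sd_steps = 200,
                          sd_step = 0.01) {
  relax <- match.arg(relax)
  stopifnot(cutoff > 0, dielectric_factor > 0, burial_coef >= 0,
            clash_dist >= 0, sd_steps >= 1, sd_step > 0)
  list(cutoff = cutoff, dielectric_factor = dielectric_factor,
       burial = burial, burial_coef = burial_coef, clash_dist = clash_dist,
       relax = relax, sd_steps = sd_steps, sd_step = sd_step)
}

#' Describe an antibody-antigen complex
#'
#' @param s A structure tibble containing all chains.
#' @param receptor_chains Chain ids of the antigen (receptor).
#' @param ligand_chains Chain ids of the antibody variable domain (ligand).
#' @param cdr CDR boundary annotation: tibble with columns `chain`, `name`,
#'   `start`, `end` (author numbering, inclusive).
#' @param chain_prefix Named character vector mapping ligand chain id to the
#'   window-name prefix (e.g. `c(H = "TH", L = "TL")`).
#' @return A `flap_complex` list.
#' @export
complex_spec <- function(s, receptor_chains, ligand_chains,
                         cdr = NULL, chain_prefix = NULL) {
  if (length(intersect(receptor_chains, ligand_chains)))
    stop("receptor and ligand chain sets must be disjoint")
  present <- unique(s$chain)
  missing <- setdiff(c(receptor_chains, ligand_chains), present)
  if (length(missing)) stop("chain(s) not in structure: ",
                            paste(missing, collapse = ", "))
  if (!is.null(cdr)) {
    stopifnot(all(c("chain", "name", "start", "end") %in% names(cdr)))
    for (i in seq_len(nrow(cdr))) {
      rr <- range(s$resno[s$chain == cdr$chain[i]])
      if (cdr$start[i] < rr[1] || cdr$end[i] > rr[2])
        stop("CDR range ", cdr$name[i], " outside chain ", cdr$chain[i])
    }
  }
  if (is.null(chain_prefix)) {
    chain_prefix <- stats::setNames(ligand_chains, ligand_chains)
  }
  out <- list(structure = s, receptor_chains = receptor_chains,
              ligand_chains = ligand_chains, cdr = cdr,
              chain_prefix = chain_prefix)
  class(out) <- "flap_complex"
  out
}

#' Antigen-contact residues of the ligand
#'
#' Ligand residues with any heavy atom within `cutoff` of any receptor
#' heavy atom.
#'
#' @param cx A `flap_complex`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return A tibble of contact residues (`chain`, `resno`, `ins`,
#'   `resname`), one row per residue; empty (with a warning) when the
#'   chains do not touch.
#' @export
find_contact_residues <- function(cx, cutoff = 4.5) {
  stopifnot(inherits(cx, "flap_complex"), cutoff > 0)
  s <- cx$structure
  rec <- coords_matrix(s[s$chain %in% cx$receptor_chains, ])
  lig <- s[s$chain %in% cx$ligand_chains, ]
  lx <- coords_matrix(lig)
  keep <- logical(nrow(lig))
  for (i in seq_len(nrow(lig))) {
    d2 <- (rec[, 1] - lx[i, 1])^2 + (rec[, 2] - lx[i, 2])^2 +
      (rec[, 3] - lx[i, 3])^2
    if (any(d2 <= cutoff^2)) keep[i] <- TRUE
  }
  out <- dplyr::distinct(lig[keep, c("chain", "resno", "ins", "resname")])
  if (nrow(out) == 0L) warning("no interface contacts within ", cutoff, " A")
  out
}

#' Longest contiguous run of contact residues on a chain
#'
#' @param contacts Contact tibble from [find_contact_residues()].
#' @param chain Chain id.
#' @return Length of the longest run of consecutive residue numbers in the
#'   contact set (0 for an empty set).
#' @export
longest_contact_run <- function(contacts, chain) {
  v <- sort(unique(contacts$resno[contacts$chain == chain]))
  if (length(v) == 0L) return(0L)
  r <- rle(c(TRUE, diff(v) == 1L))
  best <- 1L
  run <- 1L
  for (k in seq_along(v)[-1]) {
    run <- if (v[k] - v[k - 1L] == 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Enumerate CDR hexapeptide windows
#'
#' All 6-mer windows of the ligand chains that overlap a CDR range. Windows
#' spanning a gap in residue numbering are skipped with a warning. With
#' `require_contact`, only windows containing at least one antigen-contact
#' residue are kept. Windows are named `<prefix><ordinal>` N to C per chain.
#'
#' @param cx A `flap_complex` with CDR annotation.
#' @param contacts Contact tibble from [find_contact_residues()].
#' @param require_contact Keep only windows with >= 1 contact residue
#'   (default TRUE).
#' @return A window tibble: `name`, `chain`, `start`, `seq`, `n_contacts`.
#' @export
enumerate_cdr_windows <- function(cx, contacts = NULL, require_contact = TRUE) {
  stopifnot(inherits(cx, "flap_complex"))
  if (is.null(cx$cdr)) stop("complex has no CDR annotation")
  if (is.null(contacts) && require_contact) contacts <- find_contact_residues(cx)
  s <- cx$structure
  rows <- list()
  for (ch in cx$ligand_chains) {
    rt <- residue_table(s[s$chain == ch, ])
    cdr_ch <- cx$cdr[cx$cdr$chain == ch, , drop = FALSE]
    if (nrow(cdr_ch) == 0L) next
    ckeys <- if (!is.null(contacts))
      contacts$resno[contacts$chain == ch] else integer(0)
    n <- nrow(rt)
    kept <- 0L
    for (w in seq_len(max(0L, n - 5L))) {
      resnos <- rt$resno[w:(w + 5L)]
      if (any(diff(resnos) != 1L)) {
        warning("window at ", ch, ":", resnos[1],
                " crosses a numbering gap; skipped")
        next
      }
      overlaps <- any(vapply(seq_len(nrow(cdr_ch)), function(k)
        resnos[6] >= cdr_ch$start[k] && resnos[1] <= cdr_ch$end[k],
        logical(1)))
      if (!overlaps) next
      ncont <- sum(resnos %in% ckeys)
      if (require_contact && ncont == 0L) next
      kept <- kept + 1L
      prefix <- cx$chain_prefix[[ch]] %||% ch
      rows[[length(rows) + 1L]] <- tibble::tibble(
        name = paste0(prefix, kept), chain = ch, start = resnos[1],
        seq = paste(rt$aa[w:(w + 5L)], collapse = ""), n_contacts = ncont)
    }
  }
  if (!length(rows))
    return(tibble::tibble(name = character(), chain = character(),
                          start = integer(), seq = character(),
                          n_contacts = integer()))
  dplyr::bind_rows(rows)
}

# Pairwise nonbonded energy between two atom sets (or within one set when
# ys is NULL): truncated LJ + screened Coulomb. Bonded/geminal pairs are not
# excluded, which cancels exactly in bound-minus-unbound differences.
pair_energy <- function(xs, qx, ex, ys = NULL, qy = NULL, ey = NULL,
                        cfg = energy_config()) {
  within <- is.null(ys)
  if (within) { ys <- xs; qy <- qx; ey <- ex }
  e_total <- 0
  sig_x <- lj_sigma(ex); eps_x <- lj_eps(ex)
  sig_y <- lj_sigma(ey); eps_y <- lj_eps(ey)
  for (i in seq_len(nrow(xs))) {
    jmax <- if (within) i - 1L else nrow(ys)
    if (jmax < 1L) next
    j <- seq_len(jmax)
    dx <- ys[j, 1] - xs[i, 1]; dy <- ys[j, 2] - xs[i, 2]; dz <- ys[j, 3] - xs[i, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    sel <- r2 <= cfg$cutoff^2 & r2 > 1e-12
    if (!any(sel)) next
    r2 <- r2[sel]; jj <- j[sel]
    sig <- (sig_x[i] + sig_y[jj]) / 2
    eps <- sqrt(eps_x[i] * eps_y[jj])
    sr6 <- (sig * sig / r2)^3
    e_lj <- 4 * eps * (sr6 * sr6 - sr6)
    e_c <- 332 * qx[i] * qy[jj] / (cfg$dielectric_factor * r2)
    e_total <- e_total + sum(e_lj) + sum(e_c)
  }
  e_total
}

structure_energy <- function(s, cfg = energy_config()) {
  X <- coords_matrix(s)
  pair_energy(X, atom_charges(s), s$element, cfg = cfg)
}

#' Binding energy of a complex
#'
#' `E_bind = E(complex) - E(receptor alone) - E(ligand alone)` with each
#' term a single-point evaluation of the simplified nonbonded energy
#' (optionally after steepest-descent relaxation). With the burial term
#' enabled, `-burial_coef * buried interface area` is added.
#'
#' @param cx A `flap_complex`.
#' @param cfg An [energy_config()] list.
#' @return Binding energy in model energy units (negative = favourable).
#' @export
interaction_energy <- function(cx, cfg = energy_config()) {
  stopifnot(inherits(cx, "flap_complex"))
  s <- cx$structure
  rec <- s[s$chain %in% cx$receptor_chains, ]
  lig <- s[s$chain %in% cx$ligand_chains, ]
  Xr <- coords_matrix(rec); Xl <- coords_matrix(lig)
  # steric-clash guard across the interface
  for (i in seq_len(nrow(Xl))) {
    d2 <- (Xr[, 1] - Xl[i, 1])^2 + (Xr[, 2] - Xl[i, 2])^2 + (Xr[, 3] - Xl[i, 3])^2
    if (any(d2 < cfg$clash_dist^2))
      stop("steric clash across the interface (< ", cfg$clash_dist,
           " A), relax first")
  }
  if (cfg$relax == "sd") {
    s <- relax_sd(s, cfg)
    rec <- s[s$chain %in% cx$receptor_chains, ]
    lig <- s[s$chain %in% cx$ligand_chains, ]
  }
  # single-point pairwise energy: intra-chain terms cancel in the
  # difference, so E_bind reduces to the receptor-ligand cross term
  e_cross <- pair_energy(coords_matrix(rec), atom_charges(rec), rec$element,
                         coords_matrix(lig), atom_charges(lig), lig$element,
                         cfg = cfg)
  e_bind <- e_cross
  if (isTRUE(cfg$burial)) {
    sas_c <- attr(compute_sasa(s, n_points = 240), "total_sasa")
    sas_r <- attr(compute_sasa(rec, n_points = 240), "total_sasa")
    sas_l <- attr(compute_sasa(lig, n_points = 240), "total_sasa")
    buried <- sas_r + sas_l - sas_c
    e_bind <- e_bind - cfg$burial_coef * buried
  }
  e_bind
}

# Fixed-step steepest descent on all heavy atoms under the nonbonded energy
# (numerically simple, deterministic; iteration-capped).
relax_sd <- function(s, cfg) {
  X <- coords_matrix(s)
  q <- atom_charges(s)
  sig <- lj_sigma(s$element); eps <- lj_eps(s$element)
  n <- nrow(X)
  for (step in seq_len(cfg$sd_steps)) {
    G <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      dx <- X[, 1] - X[i, 1]; dy <- X[, 2] - X[i, 2]; dz <- X[, 3] - X[i, 3]
      r2 <- dx * dx + dy * dy + dz * dz
      sel <- r2 <= cfg$cutoff^2 & r2 > 1e-12
      if (!any(sel)) next
      r2s <- r2[sel]
      sgm <- (sig[i] + sig[sel]) / 2
      ep <- sqrt(eps[i] * eps[sel])
      sr6 <- (sgm * sgm / r2s)^3
      # dE/dr2 terms
      dlj <- 4 * ep * (-6 * sr6 * sr6 + 3 * sr6) / r2s
      dc <- -332 * q[i] * q[sel] / (cfg$dielectric_factor * r2s * r2s)
      coef <- 2 * (dlj + dc)
      G[i, ] <- G[i, ] - c(sum(coef * dx[sel]), sum(coef * dy[sel]),
                           sum(coef * dz[sel]))
    }
    gn <- sqrt(sum(G^2))
    if (gn < 1e-8) break
    X <- X + cfg$sd_step * G / gn
  }
  s$x <- X[, 1]; s$y <- X[, 2]; s$z <- X[, 3]
  s
}

#' Alanine-hexapeptide scan of CDR windows
#'
#' For each window: the wild-type binding energy, the binding energy after
#' grafting AAAAAA into the window, and the loss (ala6 minus wild type;
#' positive = binding lost). Selection is either rank mode (`top_k` windows
#' by loss, ties broken N to C) or threshold mode (`loss >= threshold`).
#'
#' @param cx A `flap_complex`.
#' @param windows A window tibble from [enumerate_cdr_windows()].
#' @param top_k Rank-mode selection count (default 3, mirroring a heavy-chain
#'   top-three selection). Ignored when `threshold` is given.
#' @param threshold Threshold-mode minimum loss in model energy units.
#' @param cfg An [energy_config()] list.
#' @return A `flap_scan` tibble: window columns plus `dG_wt`, `dG_ala6`,
#'   `loss`, `selected`. Windows whose mutation fails are flagged in
#'   `mutation_ok` and never selected.
#' @export
alanine_hexapeptide_scan <- function(cx, windows, top_k = 3, threshold = NULL,
                                     cfg = energy_config()) {
  stopifnot(inherits(cx, "flap_complex"))
  if (nrow(windows) == 0L)
    return(dplyr::mutate(windows, dG_wt = numeric(0), dG_ala6 = numeric(0),
                         loss = numeric(0), mutation_ok = logical(0),
                         selected = logical(0)))
  bad_chain <- setdiff(unique(windows$chain), cx$ligand_chains)
  if (length(bad_chain)) stop("windows on non-ligand chain(s): ",
                              paste(bad_chain, collapse = ", "))
  dG_wt <- interaction_energy(cx, cfg)
  out <- windows
  out$dG_wt <- dG_wt
  out$dG_ala6 <- NA_real_
  out$mutation_ok <- TRUE
  for (i in seq_len(nrow(out))) {
    res <- tryCatch({
      mut <- mutate_window(cx$structure, out[i, c("chain", "start")], "AAAAAA")
      mcx <- complex_spec(mut, cx$receptor_chains, cx$ligand_chains,
                          cdr = cx$cdr, chain_prefix = cx$chain_prefix)
      interaction_energy(mcx, cfg)
    }, error = function(e) NA_real_)
    if (is.na(res)) out$mutation_ok[i] <- FALSE else out$dG_ala6[i] <- res
  }
  out$loss <- out$dG_ala6 - out$dG_wt
  out$selected <- FALSE
  ok <- which(out$mutation_ok)
  if (!is.null(threshold)) {
    out$selected[ok] <- out$loss[ok] >= threshold
  } else {
    ord <- ok[order(-out$loss[ok], out$chain[ok], out$start[ok])]
    out$selected[utils::head(ord, top_k)] <- TRUE
  }
  class(out) <- unique(c("flap_scan", class(out)))
  attr(out, "mode") <- if (!is.null(threshold)) "threshold" else "rank"
  out
}

#' Write a scan report as TSV
#'
#' @param scan A `flap_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- dplyr::mutate(tibble::as_tibble(scan),
                       dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write selected peptides as FASTA
#'
#' @param scan A `flap_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selected_fasta <- function(scan, path) {
  sel <- scan[scan$selected, , drop = FALSE]
  lines <- as.vector(rbind(paste0(">", sel$name), sel$seq))
  writeLines(lines, path)
  invisible(path)
}
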