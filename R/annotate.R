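# Secondary-structure assignment (Kabsch-Sander hydrogen-bond energies,
# collapsed to three states) and disulfide detection.

# Backbone (N, CA, C, O) coordinates per residue, NA rows where atoms are
# missing. Returns list of matrices aligned with residue_table(s).
backbone_coords <- function(s) {
  rt <- residue_table(s)
  get1 <- function(i, nm) {
    v <- atom_coord(s, rt$chain[i], rt$resno[i], nm, rt$ins[i])
    if (is.null(v)) rep(NA_real_, 3) else v
  }
  n <- nrow(rt)
  out <- list(N = matrix(NA_real_, n, 3), CA = matrix(NA_real_, n, 3),
              C = matrix(NA_real_, n, 3), O = matrix(NA_real_, n, 3))
  for (i in seq_len(n)) {
    out$N[i, ] <- get1(i, "N"); out$CA[i, ] <- get1(i, "CA")
    out$C[i, ] <- get1(i, "C"); out$O[i, ] <- get1(i, "O")
  }
  out
}

#' Assign three-state secondary structure
#'
#' Kabsch-Sander hydrogen-bond energies (electrostatic model, bond when the
#' energy is below -0.5 kcal/mol) drive helix-turn and bridge pattern
#' recognition; helix classes (alpha, 3-10, pi) collapse to `H`, strand and
#' isolated bridge to `E`, everything else to `C`. Amide hydrogens, absent
#' from heavy-atom structures, are reconstructed from the preceding peptide
#' unit. Residues with incomplete backbones are labelled `C` with a warning.
#'
#' @param s A structure tibble.
#' @return A per-residue tibble: `chain`, `resno`, `ins`, `resname`, `aa`,
#'   `ss` (one of `"H"`, `"E"`, `"C"`).
#' @examples
#' helix <- fixture_structure("helix", n = 12)
#' table(assign_secondary_structure(helix)$ss)
#' @export
assign_secondary_structure <- function(s) {
  rt <- residue_table(s)
  bb <- backbone_coords(s)
  n <- nrow(rt)
  complete <- stats::complete.cases(cbind(bb$N, bb$CA, bb$C, bb$O))
  if (any(!complete))
    warning(sum(!complete), " residue(s) with missing backbone atoms labelled C")
  # sequence adjacency: consecutive rows of the same chain
  prev_ok <- c(FALSE, rt$chain[-1] == rt$chain[-n])
  # reconstructed amide H: N + unit(C_prev - O_prev); PRO and chain starts donate nothing
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!prev_ok[i] || rt$resname[i] == "PRO") next
    if (!complete[i] || !complete[i - 1L]) next
    H[i, ] <- bb$N[i, ] + unit(bb$C[i - 1L, ] - bb$O[i - 1L, ])
  }
  # hb[d, a]: N-H of residue d donates to C=O of residue a
  hb <- matrix(FALSE, n, n)
  if (n >= 2L) {
    ca_ok <- which(complete)
    for (d in ca_ok) {
      if (anyNA(H[d, ])) next
      for (a in ca_ok) {
        if (a == d || (rt$chain[a] == rt$chain[d] && abs(a - d) < 2L)) next
        if (vec_norm(bb$CA[d, ] - bb$CA[a, ]) > 9) next
        dON <- vec_norm(bb$O[a, ] - bb$N[d, ])
        dCH <- vec_norm(bb$C[a, ] - H[d, ])
        dOH <- vec_norm(bb$O[a, ] - H[d, ])
        dCN <- vec_norm(bb$C[a, ] - bb$N[d, ])
        if (min(dON, dCH, dOH, dCN) < 0.5) { hb[d, a] <- TRUE; next }
        e <- 0.084 * 332 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
        hb[d, a] <- e < -0.5
      }
    }
  }
  seq_adj <- function(i, k) { # i+k within same chain, consecutive rows
    j <- i + k
    ok <- j >= 1L & j <= n
    ok[ok] <- rt$chain[i[ok]] == rt$chain[j[ok]]
    ok
  }
  turn_at <- function(len) {
    vapply(seq_len(n), function(i) {
      j <- i + len
      j <= n && rt$chain[i] == rt$chain[j] && hb[j, i]
    }, logical(1))
  }
  t3 <- turn_at(3L); t4 <- turn_at(4L); t5 <- turn_at(5L)
  helix <- logical(n)
  mark_helix <- function(tn, len) {
    for (i in seq_len(n)) {
      if (i >= 2L && tn[i] && tn[i - 1L]) helix[i:(i + len - 1L)] <<- TRUE
    }
  }
  mark_helix(t4, 4L); mark_helix(t3, 3L); mark_helix(t5, 5L)
  # bridges: ho(i, j) = CO of i accepts from NH of j = hb[j, i]
  bridge <- logical(n)
  ho <- t(hb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2L && rt$chain[i] == rt$chain[j]) next
      im1 <- i - 1L; ip1 <- i + 1L; jm1 <- j - 1L; jp1 <- j + 1L
      ok_im1 <- im1 >= 1L && rt$chain[im1] == rt$chain[i]
      ok_ip1 <- ip1 <= n && rt$chain[ip1] == rt$chain[i]
      ok_jm1 <- jm1 >= 1L && rt$chain[jm1] == rt$chain[j]
      ok_jp1 <- jp1 <= n && rt$chain[jp1] == rt$chain[j]
      par <- (ok_im1 && ok_ip1 && ho[im1, j] && ho[j, ip1]) ||
             (ok_jm1 && ok_jp1 && ho[jm1, i] && ho[i, jp1])
      anti <- (ho[i, j] && ho[j, i]) ||
              (ok_im1 && ok_jp1 && ok_jm1 && ok_ip1 &&
               ho[im1, jp1] && ho[jm1, ip1])
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  ss <- rep("C", n)
  ss[bridge] <- "E"
  ss[helix] <- "H"
  ss[!complete] <- "C"
  dplyr::mutate(rt[, c("chain", "resno", "ins", "resname", "aa")], ss = ss)
}

#' Detect disulfide bridges
#'
#' All cysteine SG-SG pairs within a distance cutoff, matched greedily
#' nearest-first so each cysteine appears in at most one pair.
#'
#' @param s A structure tibble.
#' @param sg_cutoff SG-SG distance cutoff in Angstrom (default 2.5).
#' @return A tibble of pairs: `chain1`, `resno1`, `ins1`, `chain2`, `resno2`,
#'   `ins2`, `distance`. Zero rows when no disulfides are present.
#' @export
find_disulfides <- function(s, sg_cutoff = 2.5) {
  stopifnot(sg_cutoff > 0)
  sg <- s[s$resname == "CYS" & s$atom == "SG", , drop = FALSE]
  empty <- tibble::tibble(chain1 = character(), resno1 = integer(),
                          ins1 = character(), chain2 = character(),
                          resno2 = integer(), ins2 = character(),
                          distance = numeric())
  if (nrow(sg) < 2L) return(empty)
  D <- as.matrix(stats::dist(coords_matrix(sg)))
  cand <- which(upper.tri(D) & D <= sg_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chain1 = sg$chain[i], resno1 = sg$resno[i], ins1 = sg$ins[i],
      chain2 = sg$chain[j], resno2 = sg$resno[j], ins2 = sg$ins[j],
      distance = D[i, j])
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

# Residue keys (chain|resno|ins) participating in any disulfide.
disulfide_residues <- function(ss_pairs) {
  if (nrow(ss_pairs) == 0L) return(character(0))
  c(paste(ss_pairs$chain1, ss_pairs$resno1, ss_pairs$ins1, sep = "|"),
    paste(ss_pairs$chain2, ss_pairs$resno2, ss_pairs$ins2, sep = "|"))
}

res_key <- function(chain, resno, ins = "") paste(chain, resno, ins, sep = "|")
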