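# In-silico mutagenesis: homo-hexapeptide RMSF profiling (graft-acceptor
# calls), CDR-hexapeptide grafting, and graft evaluation.

#' The 20 homo-hexapeptides
#'
#' One six-residue homopolymer per standard amino acid, in alphabetical
#' one-letter order (A6 first, Y6 last). These stress-test a candidate graft
#' site against the extremes of the hexapeptide sequence space: smallest
#' (G6), bulkiest (W6), most hydrophobic (I6), most acidic (E6) and most
#' basic (R6).
#'
#' @return A tibble with columns `name` (e.g. `"A6"`) and `seq`
#'   (e.g. `"AAAAAA"`).
#' @export
enumerate_homohexapeptides <- function() {
  aa <- sort(.aa1)
  tibble::tibble(name = paste0(aa, "6"),
                 seq = vapply(aa, function(a) strrep(a, 6L), character(1),
                              USE.NAMES = FALSE))
}

#' Size of the hexapeptide sequence space
#'
#' @param alphabet Number of residue types (default 20).
#' @param length Peptide length (default 6).
#' @return `alphabet ^ length` (6.4e7 for the standard hexapeptide space).
#' @export
hexapeptide_space_size <- function(alphabet = 20, length = 6) {
  stopifnot(alphabet >= 1, length >= 1,
            alphabet == round(alphabet), length == round(length))
  alphabet^length
}

#' Graft a hexapeptide sequence into a site
#'
#' Replaces the six residues of a site with the residues of `new_seq`,
#' keeping the backbone fixed: side chains are rebuilt from idealized
#' templates and relaxed by a discrete rotamer search minimising the
#' heavy-atom clash count. Residues are mutated N to C, so each later
#' placement sees the earlier ones.
#'
#' @param s A structure tibble.
#' @param site A one-row site tibble (`chain`, `start`).
#' @param new_seq Six one-letter amino-acid codes, e.g. `"YFDDGW"`.
#' @return The grafted structure tibble.
#' @export
mutate_window <- function(s, site, new_seq) {
  stopifnot(nrow(site) == 1L, nchar(new_seq) == 6L)
  res3 <- aa_1to3(strsplit(toupper(new_seq), "")[[1]])
  out <- s
  for (k in 0:5) {
    out <- mutate_residue(out, site$chain, site$start + k, res3[k + 1L])
  }
  out
}

#' RMSF-profile a candidate site with the 20 homo-hexapeptides
#'
#' Grafts each homo-hexapeptide into the site, recomputes the fluctuation
#' profile with the supplied backend, and records the grafted window's mean
#' heavy-atom RMSF. The site is a graft acceptor (GA) when every one of the
#' 20 means stays below the constraint threshold.
#'
#' @param s A structure tibble containing the site.
#' @param site A one-row site tibble (`chain`, `start`; a `site_name` column
#'   is carried through if present). Sites that have not passed the CSA
#'   filter are profiled with a warning.
#' @param backend A function mapping a structure tibble to a per-atom RMSF
#'   tibble, e.g. `function(s) rmsf_from_enm(s, calibration = cal)`.
#' @param rmsf_constrained GA threshold in Angstrom (default 1.5).
#' @param csa_checked Set `FALSE` to warn that the site skipped CSA filtering.
#' @return A `flap_ga_profile`: list with `site`, `entries` (20-row tibble
#'   `name`, `seq`, `mean_rmsf`), `max_rmsf`, `threshold`, `verdict`
#'   (`"GA"` or `"not-GA"`), `complete`.
#' @export
profile_site <- function(s, site, backend, rmsf_constrained = 1.5,
                         csa_checked = TRUE) {
  stopifnot(nrow(site) == 1L, is.function(backend))
  if (!isTRUE(csa_checked))
    warning("profiling a site that did not pass the CSA filter")
  peps <- enumerate_homohexapeptides()
  means <- rep(NA_real_, nrow(peps))
  for (i in seq_len(nrow(peps))) {
    m <- tryCatch({
      mut <- mutate_window(s, site, peps$seq[i])
      prof <- backend(mut)
      site_mean_rmsf(prof, site)
    }, error = function(e) NA_real_)
    means[i] <- m
  }
  complete <- !anyNA(means)
  out <- list(
    site = site,
    entries = dplyr::mutate(peps, mean_rmsf = means),
    max_rmsf = if (complete) max(means) else NA_real_,
    threshold = rmsf_constrained,
    verdict = if (!complete) NA_character_
              else if (max(means) < rmsf_constrained) "GA" else "not-GA",
    complete = complete)
  class(out) <- "flap_ga_profile"
  out
}

#' @export
print.flap_ga_profile <- function(x, ...) {
  nm <- x$site$site_name %||% paste0(x$site$chain, ":", x$site$start)
  cat("# GA profile for site ", nm, "\n", sep = "")
  if (x$complete)
    cat("  max homo-hexapeptide mean RMSF: ", round(x$max_rmsf, 3),
        " A (threshold ", x$threshold, " A) -> ", x$verdict, "\n", sep = "")
  else cat("  incomplete profile: no verdict\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname profile_site
#' @param x A `flap_ga_profile`.
#' @param ... Unused.
#' @method tidy flap_ga_profile
#' @export
tidy.flap_ga_profile <- function(x, ...) {
  dplyr::mutate(x$entries,
                site_name = x$site$site_name %||%
                  paste0(x$site$chain, ":", x$site$start),
                pass = .data$mean_rmsf < x$threshold)
}

#' @rdname profile_site
#' @method glance flap_ga_profile
#' @export
glance.flap_ga_profile <- function(x, ...) {
  tibble::tibble(
    site_name = x$site$site_name %||% paste0(x$site$chain, ":", x$site$start),
    max_rmsf = x$max_rmsf, threshold = x$threshold,
    verdict = x$verdict, complete = x$complete)
}

#' Build grafted designs from GA sites and CDR peptides
#'
#' Full cross product of graft-acceptor sites and CDR hexapeptides, named
#' `<site name>-<peptide name>` (e.g. `Sca8-1-TH3`). When the scaffold
#' structures and a fluctuation backend are supplied, each design is built
#' by [mutate_window()] and carries its grafted-window mean RMSF.
#'
#' @param ga_sites Site tibble with `site_name`, `scaffold`, `chain`, `start`.
#' @param cdr_peptides Tibble with `name` and `seq` (6 letters each).
#' @param scaffolds Optional named list of structure tibbles, keyed by
#'   scaffold id.
#' @param backend Optional backend function (see [profile_site()]).
#' @return A design tibble: `design`, `scaffold`, `site_name`, `peptide`,
#'   `seq`, and `mean_rmsf` when evaluated.
#' @export
build_designs <- function(ga_sites, cdr_peptides, scaffolds = NULL,
                          backend = NULL) {
  stopifnot(nrow(ga_sites) > 0L, nrow(cdr_peptides) > 0L)
  bad <- nchar(cdr_peptides$seq) != 6L
  if (any(bad)) stop("CDR peptides must be hexapeptides: ",
                     paste(cdr_peptides$name[bad], collapse = ", "))
  designs <- tidyr::crossing(
    ga_sites %>% dplyr::select("site_name", "scaffold", "chain", "start"),
    cdr_peptides %>% dplyr::rename(peptide = "name")) %>%
    dplyr::mutate(design = paste0(.data$site_name, "-", .data$peptide)) %>%
    dplyr::arrange(match(.data$site_name, ga_sites$site_name),
                   match(.data$peptide, cdr_peptides$name)) %>%
    dplyr::select("design", "scaffold", "site_name", "chain", "start",
                  "peptide", "seq")
  if (anyDuplicated(designs$design))
    stop("duplicate design names; site or peptide names are not unique")
  if (!is.null(scaffolds) && !is.null(backend)) {
    designs$mean_rmsf <- vapply(seq_len(nrow(designs)), function(i) {
      sc <- scaffolds[[designs$scaffold[i]]]
      if (is.null(sc)) return(NA_real_)
      site <- designs[i, c("chain", "start")]
      mut <- mutate_window(sc, site, designs$seq[i])
      site_mean_rmsf(backend(mut), site)
    }, numeric(1))
  }
  designs
}

#' Heavy-atom RMSD between two hexapeptide windows
#'
#' Optimal (Kabsch) superposition of the two windows on their shared heavy
#' atoms, then RMSD over those atoms. Sequences must match; shared atoms are
#' matched by window position and atom name and must include the backbone.
#'
#' @param s1,s2 Structure tibbles.
#' @param site1,site2 One-row site tibbles (`chain`, `start`) locating the
#'   windows in `s1` and `s2`.
#' @return RMSD in Angstrom.
#' @export
graft_rmsd <- function(s1, site1, s2, site2) {
  w1 <- s1[window_atom_idx(s1, site1$chain, site1$start, site1$start + 5L), ]
  w2 <- s2[window_atom_idx(s2, site2$chain, site2$start, site2$start + 5L), ]
  r1 <- residue_table(w1); r2 <- residue_table(w2)
  if (nrow(r1) != 6L || nrow(r2) != 6L)
    stop("both windows must span six residues")
  if (!identical(r1$resname, r2$resname))
    stop("sequence mismatch between windows: ",
         paste(aa_3to1(r1$resname), collapse = ""), " vs ",
         paste(aa_3to1(r2$resname), collapse = ""))
  w1$pos <- match(res_key(w1$chain, w1$resno, w1$ins),
                  res_key(r1$chain, r1$resno, r1$ins))
  w2$pos <- match(res_key(w2$chain, w2$resno, w2$ins),
                  res_key(r2$chain, r2$resno, r2$ins))
  k1 <- paste(w1$pos, w1$atom); k2 <- paste(w2$pos, w2$atom)
  shared <- intersect(k1, k2)
  bb <- as.vector(outer(1:6, c("N", "CA", "C", "O"), paste))
  if (!all(bb %in% shared))
    stop("shared atoms must include the full backbone of both windows")
  X <- coords_matrix(w1)[match(shared, k1), , drop = FALSE]
  Y <- coords_matrix(w2)[match(shared, k2), , drop = FALSE]
  superposed_rmsd(X, Y)
}
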