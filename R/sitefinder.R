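# Candidate hexapeptide graft sites: loop enumeration and the
# solvent-accessibility (SA) and constrained (RMSF) filters.

#' Criteria for graft-site selection
#'
#' @param sasa_min Per-residue SASA that must be strictly exceeded
#'   (Angstrom^2, default 15).
#' @param rmsf_constrained Mean-RMSF bound for a "constrained" site
#'   (Angstrom, default 1.5).
#' @param rmsf_csa Stricter bound defining constrained-and-solvent-accessible
#'   (CSA) sites (Angstrom, default 1.0).
#' @param mode Loop enumeration mode: `"windowed"` (overlapping 6-mer windows
#'   inside loops, the default) or `"strict"` (whole loops of length exactly
#'   six).
#' @param flank_reach In windowed mode, the maximum number of loop residues
#'   allowed between a window end and its anchoring flank (default 2).
#' @return A validated criteria list.
#' @export
site_criteria <- function(sasa_min = 15, rmsf_constrained = 1.5,
                          rmsf_csa = 1.0, mode = c("windowed", "strict"),
                          flank_reach = 2L) {
  mode <- match.arg(mode)
  stopifnot(sasa_min >= 0, rmsf_csa > 0, rmsf_csa <= rmsf_constrained,
            flank_reach >= 0)
  list(sasa_min = sasa_min, rmsf_constrained = rmsf_constrained,
       rmsf_csa = rmsf_csa, mode = mode, flank_reach = as.integer(flank_reach))
}

# Flank letter of an anchoring residue: secondary structure wins over
# disulfide (S/H before C), so SLC/CLH-type motifs only arise from
# coil cysteines that are disulfide-bonded.
flank_letter <- function(ss, is_ds_cys) {
  if (ss == "E") "S" else if (ss == "H") "H" else if (is_ds_cys) "C" else NA_character_
}

#' Enumerate candidate loop hexapeptides
#'
#' Finds 6-residue windows in loop (coil) regions that are sequentially
#' flanked by alpha-helices, beta-strands, or disulfide-bonded cysteines.
#' In strict mode each maximal loop of length exactly six yields one site;
#' in windowed mode every 6-mer window inside a longer loop is emitted
#' provided an anchoring element lies within `flank_reach` loop residues of
#' each window end.
#'
#' @param s A structure tibble.
#' @param ss Per-residue secondary structure from
#'   [assign_secondary_structure()].
#' @param disulfides Disulfide pair tibble from [find_disulfides()].
#' @param criteria A [site_criteria()] list.
#' @return A site tibble: `scaffold`, `chain`, `start`, `end`, `seq`,
#'   `flank_n`, `flank_c`, `motif`, `ca1_ca6_dist`.
#' @export
enumerate_loop_hexapeptides <- function(s, ss,
                                        disulfides = find_disulfides(s),
                                        criteria = site_criteria()) {
  ds_keys <- disulfide_residues(disulfides)
  ss <- dplyr::mutate(ss,
    key = res_key(.data$chain, .data$resno, .data$ins),
    is_ds = .data$key %in% ds_keys & .data$resname == "CYS",
    anchor = .data$ss %in% c("H", "E") | .data$is_ds)
  sites <- list()
  for (ch in unique(ss$chain)) {
    cs <- ss[ss$chain == ch, , drop = FALSE]
    n <- nrow(cs)
    r <- rle(cs$ss == "C" & !cs$anchor)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      a <- starts[k]; b <- ends[k]; len <- b - a + 1L
      if (a == 1L || b == n) next            # loop touches a chain terminus
      if (!cs$anchor[a - 1L] || !cs$anchor[b + 1L]) next
      fn <- flank_letter(cs$ss[a - 1L], cs$is_ds[a - 1L])
      fc <- flank_letter(cs$ss[b + 1L], cs$is_ds[b + 1L])
      if (is.na(fn) || is.na(fc)) next
      win_starts <- if (criteria$mode == "strict") {
        if (len == 6L) a else integer(0)
      } else {
        if (len < 6L) integer(0) else {
          w <- a:(b - 5L)
          w[(w - a) <= criteria$flank_reach &
            (b - (w + 5L)) <= criteria$flank_reach]
        }
      }
      for (w in win_starts) {
        idx <- w:(w + 5L)
        sites[[length(sites) + 1L]] <- tibble::tibble(
          scaffold = structure_id(s), chain = ch,
          start = cs$resno[w], end = cs$resno[w + 5L],
          seq = paste(cs$aa[idx], collapse = ""),
          flank_n = fn, flank_c = fc,
          motif = paste0(fn, "L", fc))
      }
    }
  }
  out <- if (length(sites)) dplyr::bind_rows(sites) else
    tibble::tibble(scaffold = character(), chain = character(),
                   start = integer(), end = integer(), seq = character(),
                   flank_n = character(), flank_c = character(),
                   motif = character())
  if (nrow(out))
    out$ca1_ca6_dist <- vapply(seq_len(nrow(out)), function(i)
      ca_distance(s, out[i, ]), numeric(1))
  else out$ca1_ca6_dist <- numeric(0)
  out
}

#' Filter sites for solvent accessibility
#'
#' Keeps sites where all six residues have SASA strictly greater than
#' `sasa_min` (the solvent-accessible, "SA", reduction).
#'
#' @param sites A site tibble.
#' @param sasa A per-residue SASA tibble from [compute_sasa()].
#' @param criteria A [site_criteria()] list.
#' @return The passing sites, with a `min_res_sasa` column added.
#' @export
filter_solvent_accessible <- function(sites, sasa, criteria = site_criteria()) {
  if (nrow(sites) == 0L) return(dplyr::mutate(sites, min_res_sasa = numeric(0)))
  min_sasa <- vapply(seq_len(nrow(sites)), function(i) {
    v <- sasa$sasa[sasa$chain == sites$chain[i] &
                   sasa$resno >= sites$start[i] & sasa$resno <= sites$end[i]]
    if (length(v) != 6L)
      stop("site ", sites$chain[i], ":", sites$start[i],
           " has residues missing from the SASA profile")
    min(v)
  }, numeric(1))
  sites$min_res_sasa <- min_sasa
  sites[min_sasa > criteria$sasa_min, , drop = FALSE]
}

#' Filter sites by mean fluctuation
#'
#' Splits sites into "constrained" (mean heavy-atom RMSF below
#' `rmsf_constrained`) and the stricter "CSA" subset (below `rmsf_csa`).
#'
#' @param sites A site tibble.
#' @param profile A per-atom RMSF tibble.
#' @param criteria A [site_criteria()] list.
#' @return A list with tibbles `constrained` and `csa` (the latter a subset
#'   of the former), each with a `mean_rmsf` column.
#' @export
filter_constrained <- function(sites, profile, criteria = site_criteria()) {
  if (nrow(sites) == 0L) {
    s0 <- dplyr::mutate(sites, mean_rmsf = numeric(0))
    return(list(constrained = s0, csa = s0))
  }
  sites$mean_rmsf <- vapply(seq_len(nrow(sites)), function(i)
    site_mean_rmsf(profile, sites[i, ]), numeric(1))
  list(constrained = sites[sites$mean_rmsf < criteria$rmsf_constrained, , drop = FALSE],
       csa = sites[sites$mean_rmsf < criteria$rmsf_csa, , drop = FALSE])
}

#' Distance between the first and sixth C-alpha of a site
#'
#' @param s A structure tibble.
#' @param site A one-row site tibble (`chain`, `start`).
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(s, site) {
  stopifnot(nrow(site) == 1L)
  a <- atom_coord(s, site$chain, site$start, "CA")
  b <- atom_coord(s, site$chain, site$start + 5L, "CA")
  if (is.null(a) || is.null(b))
    stop("missing C-alpha atom for site ", site$chain, ":", site$start)
  vec_norm(a - b)
}

#' Assign stable site names
#'
#' Names sites `<scaffold>-<ordinal>` with ordinals counted from the
#' N-terminus, so re-running the pipeline reproduces identical names.
#'
#' @param sites A site tibble.
#' @return The tibble with a `site_name` column, ordered N to C.
#' @export
name_sites <- function(sites) {
  if (nrow(sites) == 0L) return(dplyr::mutate(sites, site_name = character(0)))
  sites <- dplyr::arrange(sites, .data$scaffold, .data$chain, .data$start)
  sites %>%
    dplyr::group_by(.data$scaffold) %>%
    dplyr::mutate(site_name = paste0(.data$scaffold, "-", dplyr::row_number())) %>%
    dplyr::ungroup()
}
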