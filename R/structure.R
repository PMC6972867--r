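#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

# Standard amino acids, three-letter and one-letter codes.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_3to1 <- function(x) {
  out <- .aa1[match(toupper(x), .aa3)]
  out[is.na(out)] <- "X"
  out
}

aa_1to3 <- function(x) {
  out <- .aa3[match(toupper(x), .aa1)]
  if (anyNA(out)) stop("unknown amino-acid letter(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Fixed heavy-atom van der Waals radii (Angstrom). The pipeline is
# hydrogen-free throughout, so no H radius is defined.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

new_structure <- function(atoms, id = "structure") {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("chain", "resno", "ins", "resname", "atom", "element",
              "x", "y", "z", "radius")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stop("structure tibble lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  attr(atoms, "id") <- id
  class(atoms) <- unique(c("flap_structure", class(atoms)))
  atoms
}

#' @export
print.flap_structure <- function(x, ...) {
  cat("# A protein structure: ", structure_id(x), " (",
      length(unique(x$chain)), " chain(s), ",
      nrow(dplyr::distinct(x, .data$chain, .data$resno, .data$ins)),
      " residues, ", nrow(x), " heavy atoms)\n", sep = "")
  NextMethod()
}

#' Identifier of a structure tibble
#' @param s A structure tibble from [read_structure()] or [build_structure()].
#' @return A character scalar.
#' @export
structure_id <- function(s) attr(s, "id") %||% "structure"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a one-row-per-heavy-atom tibble.
#' Hydrogens and water are discarded, alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by altloc label order), and fixed
#' element van der Waals radii are attached. Chains containing no standard
#' amino-acid residue are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @param id Structure identifier; defaults to the file base name.
#' @return A structure tibble with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `radius`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(fixture_structure("helix", n = 8), pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("pdb"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(trimws(at$elety[bad]), 1L, 1L)
  at$element <- elem
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard residues in '", path, "'")
  # resolve ALTLOC: keep the highest-occupancy conformer per atom slot
  at <- at %>%
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) %>%
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(match(.data$eleno, at$eleno))
  at <- at[order(match(at$chain, unique(at$chain))), , drop = FALSE]
  keep_chain <- vapply(split(at$resid, at$chain),
                       function(r) any(r %in% .aa3), logical(1))
  dropped <- names(keep_chain)[!keep_chain]
  if (length(dropped)) {
    warning("chain(s) without standard residues skipped: ",
            paste(dropped, collapse = ", "))
    at <- at[at$chain %in% names(keep_chain)[keep_chain], , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no standard residues in '", path, "'")
  atoms <- tibble::tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    ins = at$insert,
    resname = at$resid,
    atom = trimws(at$elety),
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    radius = vdw_radius(at$element)
  )
  new_structure(atoms, id = id %||% sub("\\.(pdb|ent)$", "", basename(path)))
}

format_pdb_lines <- function(atoms, serial_start = 1L) {
  nm <- ifelse(nchar(atoms$atom) < 4L, sprintf(" %-3s", atoms$atom),
               substr(atoms$atom, 1L, 4L))
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(atoms)) + serial_start - 1L, nm,
          substr(atoms$resname, 1L, 3L), substr(atoms$chain, 1L, 1L),
          atoms$resno, ifelse(atoms$ins == "", " ", substr(atoms$ins, 1L, 1L)),
          atoms$x, atoms$y, atoms$z, atoms$element)
}

#' Write a structure (or ensemble) to a PDB file
#'
#' Uses a fixed-format writer so identical inputs always produce
#' byte-identical files.
#'
#' @param s A structure tibble, or an ensemble from [read_ensemble()] /
#'   [fixture_ensemble()] (written as a multi-model PDB).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  if (inherits(s, "flap_ensemble")) {
    ref <- s$structure
    lines <- character(0)
    for (f in seq_len(dim(s$xyz)[1])) {
      fr <- ref
      fr$x <- s$xyz[f, , 1]; fr$y <- s$xyz[f, , 2]; fr$z <- s$xyz[f, , 3]
      lines <- c(lines, sprintf("MODEL     %4d", f),
                 format_pdb_lines(fr), "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  } else {
    writeLines(c(format_pdb_lines(s), "END"), path)
  }
  invisible(path)
}

#' Per-residue table of a structure
#'
#' One row per residue, in structure order, with the residue's one-letter
#' code and atom count.
#'
#' @param s A structure tibble.
#' @return A tibble with columns `chain`, `resno`, `ins`, `resname`, `aa`,
#'   `n_atoms`.
#' @export
residue_table <- function(s) {
  s %>%
    dplyr::mutate(.ord = dplyr::row_number()) %>%
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$resname) %>%
    dplyr::summarise(aa = aa_3to1(.data$resname[1]),
                     n_atoms = dplyr::n(),
                     .ord = min(.data$.ord), .groups = "drop") %>%
    dplyr::arrange(.data$.ord) %>%
    dplyr::select(-".ord")
}

# Coordinates of a structure as an (n x 3) matrix.
coords_matrix <- function(s) {
  cbind(x = s$x, y = s$y, z = s$z)
}

# Named coordinate lookup: one atom by residue and atom name, or NULL.
atom_coord <- function(s, chain, resno, atom, ins = "") {
  i <- which(s$chain == chain & s$resno == resno & s$ins == ins & s$atom == atom)
  if (length(i) == 0L) return(NULL)
  c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
}

# Logical index of the atoms belonging to a residue window (inclusive,
# author numbering) on one chain.
window_atom_idx <- function(s, chain, start, end) {
  s$chain == chain & s$resno >= start & s$resno <= end
}
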