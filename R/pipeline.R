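# Pipeline orchestration: scaffold scanning (site funnel), GA profiling,
# CDR extraction, and design generation, with reproducible TSV/JSON reports.

pkg_version <- function() {
  as.character(utils::packageVersion("flapr"))
}

config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small deterministic polynomial hash; avoids extra digest dependencies
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a report TSV with provenance header
#'
#' Prepends `#`-prefixed metadata lines (tool version, config hash, backend
#' calibration) so re-runs are auditable, then the tab-separated table.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("flapr ", pkg_version())), meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(x) paste(format(x), collapse = " "),
                        character(1)))
  body <- utils::capture.output(
    utils::write.table(df, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Scan scaffolds for graft-candidate sites
#'
#' Runs the full site funnel per scaffold: loop enumeration (flanked by
#' helix/strand/disulfide-cysteine), the solvent-accessibility filter
#' (per-residue SASA strictly above threshold), and the fluctuation filters
#' (constrained and CSA). Failures are isolated per scaffold.
#'
#' @param scaffolds Named list of structure tibbles.
#' @param criteria A [site_criteria()] list.
#' @param backend Fluctuation backend function (structure -> RMSF tibble).
#' @param sasa_n_points Point density for SASA (default 240 for speed).
#' @return A list: `sites` (all enumerated sites with filter flags and
#'   `site_name` for CSA survivors), `funnel` (per-scaffold and total
#'   counts: `enumerated`, `sa`, `constrained`, `csa`), `errors` (named
#'   character), class `flap_scan_result`.
#' @export
scan_scaffolds <- function(scaffolds, criteria = site_criteria(), backend,
                           sasa_n_points = 240) {
  stopifnot(is.list(scaffolds), length(scaffolds) > 0, is.function(backend))
  if (is.null(names(scaffolds)) || any(names(scaffolds) == ""))
    names(scaffolds) <- vapply(scaffolds, structure_id, character(1))
  all_sites <- list()
  funnels <- list()
  errors <- character(0)
  for (nm in names(scaffolds)) {
    res <- tryCatch({
      s <- scaffolds[[nm]]
      ss <- assign_secondary_structure(s)
      ds <- find_disulfides(s)
      sites <- enumerate_loop_hexapeptides(s, ss, ds, criteria)
      sasa <- compute_sasa(s, n_points = sasa_n_points)
      sa <- filter_solvent_accessible(sites, sasa, criteria)
      prof <- backend(s)
      fl <- filter_constrained(sa, prof, criteria)
      csa <- name_sites(fl$csa)
      key <- function(d) paste(d$chain, d$start)
      sites$sa_pass <- key(sites) %in% key(sa)
      sites$constrained <- key(sites) %in% key(fl$constrained)
      sites$csa <- key(sites) %in% key(csa)
      sites$mean_rmsf <- fl$constrained$mean_rmsf[
        match(key(sites), key(fl$constrained))]
      sites$min_res_sasa <- sa$min_res_sasa[match(key(sites), key(sa))]
      sites$site_name <- csa$site_name[match(key(sites), key(csa))]
      list(sites = sites,
           funnel = tibble::tibble(scaffold = nm, enumerated = nrow(sites),
                                   sa = nrow(sa),
                                   constrained = nrow(fl$constrained),
                                   csa = nrow(csa)))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[nm] <- res
      next
    }
    all_sites[[nm]] <- res$sites
    funnels[[nm]] <- res$funnel
  }
  out <- list(
    sites = if (length(all_sites)) dplyr::bind_rows(all_sites) else
      tibble::tibble(),
    funnel = if (length(funnels)) dplyr::bind_rows(funnels) else
      tibble::tibble(),
    errors = errors)
  class(out) <- "flap_scan_result"
  out
}

#' @export
print.flap_scan_result <- function(x, ...) {
  cat("# Scaffold scan:", nrow(x$funnel), "scaffold(s)\n")
  print(x$funnel)
  if (length(x$errors)) cat("failed:", paste(names(x$errors), collapse = ", "),
                            "\n")
  invisible(x)
}

#' @rdname scan_scaffolds
#' @param x A `flap_scan_result`.
#' @param ... Unused.
#' @method tidy flap_scan_result
#' @export
tidy.flap_scan_result <- function(x, ...) x$sites

#' @rdname scan_scaffolds
#' @method glance flap_scan_result
#' @export
glance.flap_scan_result <- function(x, ...) {
  dplyr::summarise(x$funnel,
                   scaffolds = dplyr::n(),
                   enumerated = sum(.data$enumerated), sa = sum(.data$sa),
                   constrained = sum(.data$constrained), csa = sum(.data$csa))
}

#' Profile CSA sites with the 20 homo-hexapeptides
#'
#' @param scan A `flap_scan_result` (or a site tibble with `site_name`,
#'   `scaffold`, `chain`, `start`).
#' @param scaffolds Named list of structure tibbles.
#' @param backend Fluctuation backend function.
#' @param rmsf_constrained GA threshold in Angstrom.
#' @return A list: `profiles` (named list of `flap_ga_profile`), `matrix`
#'   (site x amino-acid tibble of means), `summary` (site, motif, distance,
#'   max RMSF, verdict), class `flap_ga_report`.
#' @export
profile_ga <- function(scan, scaffolds, backend, rmsf_constrained = 1.5) {
  sites <- if (inherits(scan, "flap_scan_result"))
    scan$sites[scan$sites$csa, , drop = FALSE] else scan
  stopifnot(nrow(sites) > 0)
  profiles <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    s <- scaffolds[[site$scaffold]]
    profiles[[site$site_name]] <- profile_site(
      s, site, backend, rmsf_constrained = rmsf_constrained)
  }
  mat <- purrr::map_dfr(profiles, function(p)
    tidyr::pivot_wider(
      dplyr::mutate(p$entries[, c("name", "mean_rmsf")],
                    site_name = p$site$site_name),
      names_from = "name", values_from = "mean_rmsf"))
  summary <- purrr::map_dfr(profiles, glance)
  if ("motif" %in% names(sites))
    summary <- dplyr::left_join(
      summary, sites[, c("site_name", "motif", "ca1_ca6_dist")],
      by = "site_name")
  out <- list(profiles = profiles, matrix = mat, summary = summary)
  class(out) <- "flap_ga_report"
  out
}

#' @export
print.flap_ga_report <- function(x, ...) {
  cat("# GA profiling of", length(x$profiles), "site(s):",
      sum(x$summary$verdict == "GA", na.rm = TRUE), "GA\n")
  print(x$summary)
  invisible(x)
}

#' @rdname profile_ga
#' @param x A `flap_ga_report`.
#' @param ... Unused.
#' @method tidy flap_ga_report
#' @export
tidy.flap_ga_report <- function(x, ...) purrr::map_dfr(x$profiles, tidy)

#' @rdname profile_ga
#' @method glance flap_ga_report
#' @export
glance.flap_ga_report <- function(x, ...) x$summary

#' Extract antigen-binding CDR hexapeptides from a complex
#'
#' Contact mapping, CDR window enumeration and the alanine-hexapeptide
#' binding-energy-loss scan, in one call.
#'
#' @param cx A `flap_complex`.
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom.
#' @param require_contact Keep only windows with contacts.
#' @param top_k,threshold Selection mode (see [alanine_hexapeptide_scan()]).
#' @param cfg An [energy_config()] list.
#' @return A list: `contacts`, `windows`, `scan` (a `flap_scan`),
#'   `selected` (tibble `name`, `seq`), class `flap_cdr_report`.
#' @export
extract_cdr <- function(cx, contact_cutoff = 4.5, require_contact = TRUE,
                        top_k = 3, threshold = NULL, cfg = energy_config()) {
  contacts <- find_contact_residues(cx, cutoff = contact_cutoff)
  windows <- enumerate_cdr_windows(cx, contacts,
                                   require_contact = require_contact)
  scan <- alanine_hexapeptide_scan(cx, windows, top_k = top_k,
                                   threshold = threshold, cfg = cfg)
  out <- list(contacts = contacts, windows = windows, scan = scan,
              selected = tibble::as_tibble(
                scan[scan$selected, c("name", "seq")]))
  class(out) <- "flap_cdr_report"
  out
}

#' @export
print.flap_cdr_report <- function(x, ...) {
  cat("# CDR extraction:", nrow(x$windows), "window(s),",
      nrow(x$selected), "selected\n")
  print(tibble::as_tibble(x$scan)[, c("name", "seq", "loss", "selected")])
  invisible(x)
}

#' Generate and evaluate grafted designs
#'
#' Cross product of GA sites and selected CDR hexapeptides; each design is
#' built by backbone-preserving residue replacement, its grafted-window mean
#' RMSF computed with the backend, and (when `sources` provides the original
#' CDR conformation) the heavy-atom RMSD of the grafted hexapeptide versus
#' its source.
#'
#' @param ga_report A `flap_ga_report`, or a site tibble of GA sites.
#' @param peptides Tibble `name`, `seq` of CDR hexapeptides.
#' @param scaffolds Named list of structure tibbles.
#' @param backend Fluctuation backend function.
#' @param sources Optional named list (by peptide name) of
#'   `list(structure =, site =)` giving the source CDR window.
#' @param out_dir Optional directory to write one grafted PDB per design.
#' @return A design tibble with `mean_rmsf` (and `rmsd` where sources are
#'   available), class `flap_designs`.
#' @export
design_grafts <- function(ga_report, peptides, scaffolds, backend,
                          sources = NULL, out_dir = NULL) {
  ga_sites <- if (inherits(ga_report, "flap_ga_report")) {
    ok <- ga_report$summary$site_name[ga_report$summary$verdict == "GA"]
    sites <- purrr::map_dfr(ga_report$profiles[ok], "site")
    sites
  } else ga_report
  stopifnot(nrow(ga_sites) > 0, nrow(peptides) > 0)
  designs <- build_designs(ga_sites, peptides)
  designs$mean_rmsf <- NA_real_
  designs$rmsd <- NA_real_
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(nrow(designs))) {
    sc <- scaffolds[[designs$scaffold[i]]]
    site <- designs[i, c("chain", "start")]
    mut <- mutate_window(sc, site, designs$seq[i])
    designs$mean_rmsf[i] <- site_mean_rmsf(backend(mut), site)
    src <- sources[[designs$peptide[i]]]
    if (!is.null(src))
      designs$rmsd[i] <- graft_rmsd(mut, site, src$structure, src$site)
    if (!is.null(out_dir))
      write_structure(mut, file.path(out_dir,
                                     paste0(designs$design[i], ".pdb")))
  }
  designs <- dplyr::arrange(designs, .data$mean_rmsf)
  class(designs) <- unique(c("flap_designs", class(designs)))
  designs
}

#' Run summary as JSON
#'
#' @param path Output path.
#' @param ... Named summary entries (funnel counts, selections, timings).
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, ...) {
  jsonlite::write_json(list(tool = paste0("flapr ", pkg_version()), ...),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration file
#'
#' Plain YAML configuration; all selection thresholds appear explicitly.
#' Returns the validated config with defaults filled in.
#'
#' @param path YAML file path.
#' @return A named list with elements `criteria` ([site_criteria()]),
#'   `energy` ([energy_config()]), `backend` (list with `type`, `cutoff`,
#'   `temperature`, `calibration_target`), `selection`, `seed`, plus any
#'   input paths given.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  crit <- do.call(site_criteria, raw$criteria %||% list())
  energy <- do.call(energy_config, raw$energy %||% list())
  backend <- utils::modifyList(
    list(type = "enm", cutoff = 7.5, temperature = 300,
         calibration_target = 0.8), raw$backend %||% list())
  selection <- raw$selection %||% list(top_k = 3)
  out <- utils::modifyList(raw, list(criteria = crit, energy = energy,
                                     backend = backend,
                                     selection = selection,
                                     seed = raw$seed %||% 1L))
  out$hash <- config_hash(out)
  out
}
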