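# Contact mapping, CDR window enumeration and the alanine-hexapeptide
# binding-energy scan.

toy_cx <- function(contacts = 10:15, n = 28) {
  tc <- fixture_structure("toy_complex", contacts = contacts, n = n)
  complex_spec(tc, receptor_chains = "R", ligand_chains = "L",
               cdr = tibble::tibble(chain = "L", name = c("C1", "C2"),
                                    start = c(8L, 21L), end = c(18L, 27L)),
               chain_prefix = c(L = "TH"))
}

test_that("designed contacts are recovered exactly (all-pairs oracle)", {
  cx <- toy_cx(contacts = 10:13)
  got <- find_contact_residues(cx, cutoff = 4.5)
  expect_setequal(got$resno, 10:13)
  # all-pairs distance oracle
  s <- cx$structure
  rec <- coords_matrix(s[s$chain == "R", ])
  lig <- s[s$chain == "L", ]
  oracle <- sort(unique(lig$resno[apply(
    coords_matrix(lig), 1,
    function(p) min(sqrt(colSums((t(rec) - p)^2))) <= 4.5)]))
  expect_equal(sort(unique(got$resno)), oracle)
})

test_that("residues far from the receptor are excluded; empty interfaces warn", {
  cx <- toy_cx()
  got <- find_contact_residues(cx, cutoff = 4.5)
  expect_false(1 %in% got$resno)
  expect_false(28 %in% got$resno)
  # pull the chains apart: no contacts, with a warning
  s <- cx$structure
  s$x[s$chain == "R"] <- s$x[s$chain == "R"] + 500
  far <- complex_spec(s, "R", "L", cdr = cx$cdr, chain_prefix = cx$chain_prefix)
  expect_warning(none <- find_contact_residues(far), "no interface")
  expect_equal(nrow(none), 0)
})

test_that("longest contact runs are scanned exhaustively", {
  mk <- function(v) tibble::tibble(chain = "L", resno = v, ins = "",
                                   resname = "ALA")
  expect_equal(longest_contact_run(mk(c(3, 4, 5, 9)), "L"), 3)
  expect_equal(longest_contact_run(mk(integer(0)), "L"), 0)
  cx <- toy_cx(contacts = 10:15)
  got <- find_contact_residues(cx)
  expect_equal(longest_contact_run(got, "L"), 6)
  # exhaustive-scan oracle on random sets
  set.seed(4)
  for (i in 1:5) {
    v <- sort(sample(1:30, 12))
    runs <- rle(diff(v) == 1)
    oracle <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1 else 1
    expect_equal(longest_contact_run(mk(v), "L"), oracle)
  }
})

test_that("CDR windows match exhaustive enumeration and honour contacts", {
  cx <- toy_cx()
  contacts <- find_contact_residues(cx)
  w_all <- enumerate_cdr_windows(cx, contacts, require_contact = FALSE)
  # oracle: every 6-window overlapping a CDR range
  rt <- residue_table(cx$structure[cx$structure$chain == "L", ])
  oracle <- integer(0)
  for (s0 in rt$resno[seq_len(nrow(rt) - 5)]) {
    e0 <- s0 + 5
    if ((e0 >= 8 && s0 <= 18) || (e0 >= 21 && s0 <= 27))
      oracle <- c(oracle, s0)
  }
  expect_equal(sort(w_all$start), sort(oracle))
  w_con <- enumerate_cdr_windows(cx, contacts, require_contact = TRUE)
  expect_true(all(w_con$n_contacts >= 1))
  expect_true(all(w_con$start %in% w_all$start))
  # no contacts at all -> empty under require_contact
  empty <- enumerate_cdr_windows(cx, contacts[0, ], require_contact = TRUE)
  expect_equal(nrow(empty), 0)
  # names are prefix + N-to-C ordinal
  expect_equal(w_all$name, paste0("TH", seq_len(nrow(w_all))))
})

test_that("the LJ minimum and screened Coulomb match closed forms", {
  cfg <- energy_config()
  # two carbons at the LJ minimum 2^(1/6) sigma: energy exactly -eps
  sig <- flapr:::lj_sigma("C"); eps <- flapr:::lj_eps("C")
  r <- 2^(1/6) * sig
  xs <- matrix(c(0, 0, 0), 1); ys <- matrix(c(r, 0, 0), 1)
  e <- flapr:::pair_energy(xs, 0, "C", ys, 0, "C", cfg = cfg)
  expect_equal(e, -eps, tolerance = 1e-12)
  # +1/-1 charges at 3 A: Coulomb = 332*q1*q2/(4*r^2), on top of LJ
  e2 <- flapr:::pair_energy(matrix(0, 1, 3), 1, "N",
                            matrix(c(3, 0, 0), 1), -1, "O", cfg = cfg)
  lj <- local({
    s <- (flapr:::lj_sigma("N") + flapr:::lj_sigma("O")) / 2
    ep <- sqrt(flapr:::lj_eps("N") * flapr:::lj_eps("O"))
    4 * ep * ((s / 3)^12 - (s / 3)^6)
  })
  expect_equal(e2 - lj, 332 * 1 * (-1) / (4 * 3 * 3), tolerance = 1e-10)
})

test_that("binding energy vanishes at infinite separation and is rigid-invariant", {
  cx <- toy_cx()
  s <- cx$structure
  s$x[s$chain == "R"] <- s$x[s$chain == "R"] + 500
  far <- complex_spec(s, "R", "L", cdr = cx$cdr, chain_prefix = cx$chain_prefix)
  expect_equal(interaction_energy(far), 0, tolerance = 1e-9)
  e0 <- interaction_energy(cx)
  moved <- complex_spec(transform_structure(cx$structure, seed = 12),
                        "R", "L", cdr = cx$cdr, chain_prefix = cx$chain_prefix)
  expect_equal(interaction_energy(moved), e0, tolerance = 1e-8)
})

test_that("interface steric clashes are refused", {
  cx <- toy_cx()
  s <- cx$structure
  # move one receptor atom onto a ligand atom
  i <- which(s$chain == "R")[1]
  j <- which(s$chain == "L")[1]
  s$x[i] <- s$x[j] + 0.1; s$y[i] <- s$y[j]; s$z[i] <- s$z[j]
  bad <- complex_spec(s, "R", "L", cdr = cx$cdr, chain_prefix = cx$chain_prefix)
  expect_error(interaction_energy(bad), "steric clash")
})

test_that("the alanine scan zeroes identity and non-interface windows", {
  cx <- toy_cx()
  w <- enumerate_cdr_windows(cx, find_contact_residues(cx),
                             require_contact = FALSE)
  scan <- alanine_hexapeptide_scan(cx, w, top_k = 1)
  # windows already AAAAAA and far from the interface: loss exactly 0
  ala_far <- scan$seq == "AAAAAA" & scan$start >= 21
  expect_true(any(ala_far))
  expect_true(all(abs(scan$loss[ala_far]) < 1e-6))
  # identity windows are never selected under a positive threshold
  scan_t <- alanine_hexapeptide_scan(cx, w, threshold = 1)
  expect_false(any(scan_t$selected[scan_t$seq == "AAAAAA"]))
})

test_that("the designed hot window is top-ranked for any threshold between loss levels", {
  cx <- toy_cx(contacts = 10:15)
  w <- enumerate_cdr_windows(cx, find_contact_residues(cx),
                             require_contact = FALSE)
  scan <- alanine_hexapeptide_scan(cx, w, top_k = 1)
  hot <- scan[scan$selected, ]
  expect_equal(hot$start, 10) # the window holding all six designed contacts
  expect_equal(hot$loss, max(scan$loss))
  # threshold mode: hot selected, zero-contact windows never, for any
  # threshold between the cold (0) and hot loss levels
  for (tau in c(max(scan$loss) * 0.5, max(scan$loss) * 0.9)) {
    st <- alanine_hexapeptide_scan(cx, w, threshold = tau)
    expect_true(st$selected[st$start == 10])
    expect_false(any(st$selected[st$n_contacts == 0]))
  }
})

test_that("scan results are window-order invariant and ties break N to C", {
  cx <- toy_cx()
  w <- enumerate_cdr_windows(cx, find_contact_residues(cx),
                             require_contact = FALSE)
  s1 <- alanine_hexapeptide_scan(cx, w, top_k = 2)
  s2 <- alanine_hexapeptide_scan(cx, w[rev(seq_len(nrow(w))), ], top_k = 2)
  m1 <- dplyr::arrange(tibble::as_tibble(s1), start)
  m2 <- dplyr::arrange(tibble::as_tibble(s2), start)
  expect_equal(m1$loss, m2$loss)
  expect_equal(m1$selected, m2$selected)
})

test_that("scan reports and FASTA export round-trip", {
  cx <- toy_cx()
  w <- enumerate_cdr_windows(cx, find_contact_residues(cx))
  scan <- alanine_hexapeptide_scan(cx, w, top_k = 2)
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  write_scan_tsv(scan, tsv)
  tab <- read.delim(tsv)
  expect_true(all(c("name", "seq", "dG_wt", "dG_ala6", "loss", "selected")
                  %in% names(tab)))
  write_selected_fasta(scan, fa)
  lines <- readLines(fa)
  expect_equal(sum(grepl("^>", lines)), 2)
})
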