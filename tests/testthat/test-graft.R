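# In-silico mutagenesis, homo-hexapeptide profiling, design generation and
# graft RMSD.

test_that("the homo-hexapeptide panel is the 20 standard homopolymers", {
  hp <- enumerate_homohexapeptides()
  expect_equal(nrow(hp), 20)
  expect_equal(hp$name[1], "A6")
  expect_equal(hp$seq[1], "AAAAAA")
  expect_true(all(c("GGGGGG", "WWWWWW", "IIIIII", "EEEEEE", "RRRRRR")
                  %in% hp$seq))
  expect_equal(hp$name, paste0(sort(unique(substr(hp$seq, 1, 1))), "6"))
})

test_that("the hexapeptide space size is the closed-form power", {
  expect_equal(hexapeptide_space_size(20, 6), 6.4e7)
  expect_equal(hexapeptide_space_size(1, 6), 1)
  expect_equal(hexapeptide_space_size(4, 3), 64)
})

test_that("identity grafts keep the backbone and clash count", {
  s <- fixture_structure("hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  mut <- mutate_window(s, site, "AAAAAA") # fixture loop is already poly-A
  bb <- s$atom %in% c("N", "CA", "C", "O")
  bb2 <- mut$atom %in% c("N", "CA", "C", "O")
  expect_equal(coords_matrix(s[bb, ]), coords_matrix(mut[bb2, ]))
  expect_equal(nrow(mut), nrow(s))
  expect_equal(coords_matrix(s), coords_matrix(mut), tolerance = 1e-9)
})

test_that("glycine grafts have no side-chain heavy atoms", {
  s <- fixture_structure("hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  mut <- mutate_window(s, site, "GGGGGG")
  win <- mut[mut$resno %in% 10:15, ]
  expect_true(all(win$resname == "GLY"))
  expect_true(all(win$atom %in% c("N", "CA", "C", "O")))
})

test_that("bulky grafts pick the least-clashing rotamer (exhaustive oracle)", {
  s <- fixture_structure("clamped_hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  mut <- mutate_window(s, site, "WWWWWW")
  expect_equal(sum(mut$resname[mut$resno %in% 10:15] == "TRP") > 0, TRUE)
  # oracle: re-run the first mutated residue over every rotamer explicitly
  # and confirm no rotamer does better than the chosen one
  first_res <- mut[mut$resno == 10, ]
  env <- mut[mut$resno != 10, ]
  env_xyz <- coords_matrix(env)
  bbN <- flapr:::atom_coord(mut, "A", 10, "N")
  bbCA <- flapr:::atom_coord(mut, "A", 10, "CA")
  bbC <- flapr:::atom_coord(mut, "A", 10, "C")
  rots <- flapr:::rotamer_set("TRP")
  oracle_best <- Inf
  for (r in seq_len(nrow(rots))) {
    sc <- flapr:::build_sidechain("TRP", bbN, bbCA, bbC, chis = rots[r, ])
    cl <- flapr:::clash_count(cbind(sc$x, sc$y, sc$z),
                              flapr:::vdw_radius(sc$element),
                              env_xyz, env$radius)
    oracle_best <- min(oracle_best, cl)
  }
  sc_now <- first_res[!(first_res$atom %in% c("N", "CA", "C", "O")), ]
  chosen <- flapr:::clash_count(coords_matrix(sc_now), sc_now$radius,
                                env_xyz, env$radius)
  expect_lte(chosen, oracle_best)
})

test_that("GA verdicts follow the max rule and a controllable backend", {
  s <- fixture_structure("clamped_hairpin")
  site <- tibble::tibble(chain = "A", start = 10L, site_name = "clamp-1")
  flat <- function(val) function(str)
    flapr:::profile_tibble(str, rep(val, nrow(str)), backend = "enm")
  ga <- profile_site(s, site, flat(0.7))
  expect_equal(nrow(ga$entries), 20)
  expect_equal(ga$verdict, "GA")
  not_ga <- profile_site(s, site, flat(1.8))
  expect_equal(not_ga$verdict, "not-GA")
  # 19 of 20 passing is still not-GA: spike only the W6 variant
  spiky <- function(str) {
    v <- if (any(str$resname == "TRP")) 1.8 else 0.7
    flapr:::profile_tibble(str, rep(v, nrow(str)), backend = "enm")
  }
  expect_equal(profile_site(s, site, spiky)$verdict, "not-GA")
  # tightening the threshold never converts not-GA into GA
  for (thr in c(1.4, 1.0, 0.6)) {
    v <- profile_site(s, site, spiky, rmsf_constrained = thr)$verdict
    expect_true(v == "not-GA")
  }
})

test_that("backend failures leave the profile incomplete without verdict", {
  s <- fixture_structure("clamped_hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  failing <- function(str) {
    if (any(str$resname == "TRP")) stop("backend boom")
    flapr:::profile_tibble(str, rep(0.7, nrow(str)), backend = "enm")
  }
  ga <- profile_site(s, site, failing)
  expect_false(ga$complete)
  expect_true(is.na(ga$verdict))
})

test_that("profiling is invariant to the order of the 20 sequences", {
  # the entries are keyed by name, so a permuted evaluation gives the same
  # table after sorting
  s <- fixture_structure("clamped_hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  res_dependent <- function(str) {
    v <- 0.5 + 0.01 * (nrow(str) %% 7)
    flapr:::profile_tibble(str, rep(v, nrow(str)), backend = "enm")
  }
  a <- profile_site(s, site, res_dependent)
  b <- profile_site(s, site, res_dependent)
  expect_equal(a$entries, b$entries)
  expect_equal(dplyr::arrange(a$entries, .data$name),
               dplyr::arrange(b$entries[sample(20), ], .data$name))
})

test_that("designs are the full named cross product", {
  sites <- tibble::tibble(
    site_name = paste0("Sca", rep(4:9, length.out = 13), "-",
                       c(1, 1, 1, 2, 1, 2, 3, 1, 2, 1, 2, 3, 4)),
    scaffold = paste0("Sca", rep(4:9, length.out = 13)),
    chain = "A", start = 10L)
  sites$site_name <- make.unique(sites$site_name)
  peps <- tibble::tibble(name = c("TH3", "TH4", "TH5", "PH5", "PH6"),
                         seq = c("SRWGGD", "RWGGDG", "WGGDGF", "KTPAYL",
                                 "TPAYLG"))
  designs <- build_designs(sites, peps)
  expect_equal(nrow(designs), 65)
  expect_false(anyDuplicated(designs$design) > 0)
  expect_true("Sca8-1-TH3" %in% designs$design ||
              any(grepl("-TH3$", designs$design)))
  expect_equal(nrow(build_designs(sites[1, ], peps[1, ])), 1)
  expect_equal(nrow(build_designs(sites[1:3, ], peps[1:2, ])), 6)
  # count invariant
  for (ns in c(2, 5)) for (np in c(1, 3))
    expect_equal(nrow(build_designs(sites[seq_len(ns), ],
                                    peps[seq_len(np), ])), ns * np)
})

test_that("graft RMSD is zero for identical and rigidly moved windows", {
  s <- fixture_structure("hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  expect_equal(graft_rmsd(s, site, s, site), 0, tolerance = 1e-9)
  moved <- transform_structure(s, seed = 8)
  expect_equal(graft_rmsd(s, site, moved, site), 0, tolerance = 1e-6)
})

test_that("graft RMSD matches the quaternion superposition oracle and is symmetric", {
  s1 <- fixture_structure("hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  s2 <- s1
  set.seed(31)
  idx <- flapr:::window_atom_idx(s2, "A", 10L, 15L)
  s2$x[idx] <- s2$x[idx] + rnorm(sum(idx), 0, 0.4)
  s2$y[idx] <- s2$y[idx] + rnorm(sum(idx), 0, 0.4)
  s2$z[idx] <- s2$z[idx] + rnorm(sum(idx), 0, 0.4)
  r <- graft_rmsd(s1, site, s2, site)
  X <- coords_matrix(s1[idx, ]); Y <- coords_matrix(s2[idx, ])
  expect_equal(r, quaternion_rmsd(X, Y), tolerance = 1e-8)
  expect_equal(graft_rmsd(s2, site, s1, site), r, tolerance = 1e-9)
})

test_that("sequence mismatches are rejected", {
  s <- fixture_structure("hairpin")
  site <- tibble::tibble(chain = "A", start = 10L)
  mut <- mutate_window(s, site, "GGGGGG")
  expect_error(graft_rmsd(s, site, mut, site), "mismatch")
})
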