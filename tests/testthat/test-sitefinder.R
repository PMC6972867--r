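# Loop enumeration and the SA / constrained filters.

test_that("a 6-loop between strands yields one SLS site in strict mode", {
  cs <- ss_case("EEEECCCCCCEEEE")
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                       criteria = site_criteria(mode = "strict"))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$motif, "SLS")
  expect_equal(sites$start, 5)
})

test_that("a 5-residue loop yields nothing in strict mode", {
  cs <- ss_case("EEEECCCCCEEEE")
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                       criteria = site_criteria(mode = "strict"))
  expect_equal(nrow(sites), 0)
})

test_that("windowed mode matches exhaustive window enumeration", {
  # 8-residue loop, reach 2: all three windows qualify
  cs <- ss_case("EEEECCCCCCCCEEEE")
  crit <- site_criteria(mode = "windowed", flank_reach = 2)
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss, criteria = crit)
  # oracle: enumerate every 6-window inside the loop and apply the reach rule
  loop <- 5:12
  oracle <- integer(0)
  for (w in loop[1]:(loop[length(loop)] - 5)) {
    n_before <- w - loop[1]
    n_after <- loop[length(loop)] - (w + 5)
    if (n_before <= 2 && n_after <= 2) oracle <- c(oracle, w)
  }
  expect_equal(sort(sites$start), sort(oracle))
  expect_equal(nrow(sites), 3)
})

test_that("strict-mode sites are a subset of windowed-mode sites", {
  for (str in c("EEEECCCCCCEEEE", "HHHHCCCCCCHHHH", "EEEECCCCCCCEEE",
                "CCEEECCCCCCEEECC")) {
    cs <- ss_case(str)
    strict <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                          criteria = site_criteria(mode = "strict"))
    wind <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                        criteria = site_criteria(mode = "windowed"))
    expect_true(all(strict$start %in% wind$start))
  }
})

test_that("helix flanks give HLH motifs and mixed flanks mixed motifs", {
  cs <- ss_case("HHHHCCCCCCEEEE")
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                       criteria = site_criteria(mode = "strict"))
  expect_equal(sites$motif, "HLS")
})

test_that("disulfide-bonded coil cysteines anchor loops; SS letters win over C", {
  cs <- ss_case("CCCCCCCC")
  cs$ss$resname[c(1, 8)] <- "CYS"
  ds <- tibble::tibble(chain1 = "A", resno1 = 1L, ins1 = "",
                       chain2 = "A", resno2 = 8L, ins2 = "", distance = 2.0)
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss, disulfides = ds,
                                       criteria = site_criteria(mode = "strict"))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$motif, "CLC")
  # if the same cysteines sit in strands, the strand letter wins
  cs$ss$ss[c(1, 8)] <- "E"
  sites2 <- enumerate_loop_hexapeptides(cs$s, cs$ss, disulfides = ds,
                                        criteria = site_criteria(mode = "strict"))
  expect_equal(sites2$motif, "SLS")
})

test_that("the SA filter keeps only sites with every residue strictly above threshold", {
  cs <- ss_case("EEEECCCCCCEEEE")
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                       criteria = site_criteria(mode = "strict"))
  mk_sasa <- function(vals) tibble::tibble(
    chain = "A", resno = 1:14, ins = "", resname = "ALA",
    sasa = c(rep(50, 4), vals, rep(50, 4)))
  crit <- site_criteria()
  expect_equal(nrow(filter_solvent_accessible(
    sites, mk_sasa(c(20, 30, 25, 18, 40, 16)), crit)), 1)
  expect_equal(nrow(filter_solvent_accessible(
    sites, mk_sasa(c(20, 30, 3, 18, 40, 16)), crit)), 0)
  # the boundary is strict: exactly 15.0 is dropped
  expect_equal(nrow(filter_solvent_accessible(
    sites, mk_sasa(c(15, 30, 25, 18, 40, 16)), crit)), 0)
})

test_that("the constrained filter splits by 1.5 and 1.0 thresholds", {
  cs <- ss_case("EEEECCCCCCEEEE")
  sites <- enumerate_loop_hexapeptides(cs$s, cs$ss,
                                       criteria = site_criteria(mode = "strict"))
  mk_prof <- function(val) {
    s <- cs$s
    flapr:::profile_tibble(s, rep(val, nrow(s)), backend = "enm")
  }
  crit <- site_criteria()
  r1 <- filter_constrained(sites, mk_prof(0.8), crit)
  expect_equal(nrow(r1$constrained), 1); expect_equal(nrow(r1$csa), 1)
  r2 <- filter_constrained(sites, mk_prof(1.2), crit)
  expect_equal(nrow(r2$constrained), 1); expect_equal(nrow(r2$csa), 0)
  r3 <- filter_constrained(sites, mk_prof(1.7), crit)
  expect_equal(nrow(r3$constrained), 0); expect_equal(nrow(r3$csa), 0)
  # csa is always a subset of constrained
  expect_true(all(r2$csa$start %in% r2$constrained$start))
})

test_that("SA and CSA filters commute", {
  s <- fixture_structure("clamped_hairpin")
  ss <- assign_secondary_structure(s)
  sites <- enumerate_loop_hexapeptides(s, ss)
  sasa <- compute_sasa(s, n_points = 240)
  prof <- rmsf_from_enm(s, calibration = enm_calibration(s))
  crit <- site_criteria()
  a <- filter_constrained(filter_solvent_accessible(sites, sasa, crit),
                          prof, crit)$csa
  b <- filter_solvent_accessible(filter_constrained(sites, prof, crit)$csa,
                                 sasa, crit)
  expect_equal(a$start, b$start)
})

test_that("C-alpha distances are Euclidean", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0),
               c(3, 4, 0))
  s <- ca_only_structure(xyz)
  site <- tibble::tibble(chain = "A", start = 1L)
  expect_equal(ca_distance(s, site), 5) # 3-4-5 triangle
  xyz2 <- xyz; xyz2[6, ] <- xyz2[1, ]
  expect_equal(ca_distance(ca_only_structure(xyz2), site), 0)
  # matches direct coordinate arithmetic on the hairpin fixture
  hp <- fixture_structure("hairpin")
  site_hp <- tibble::tibble(chain = "A", start = 10L)
  ca1 <- unlist(hp[hp$resno == 10 & hp$atom == "CA", c("x", "y", "z")])
  ca6 <- unlist(hp[hp$resno == 15 & hp$atom == "CA", c("x", "y", "z")])
  expect_equal(ca_distance(hp, site_hp), sqrt(sum((ca1 - ca6)^2)))
})

test_that("site names are deterministic ordinals from the N-terminus", {
  sites <- tibble::tibble(scaffold = "Sca8", chain = "A",
                          start = c(40L, 12L, 25L), end = c(45L, 17L, 30L))
  named <- name_sites(sites)
  expect_equal(named$site_name[order(named$start)],
               c("Sca8-1", "Sca8-2", "Sca8-3"))
  # stable under re-run and input order
  named2 <- name_sites(sites[c(2, 3, 1), ])
  expect_equal(dplyr::arrange(named, start)$site_name,
               dplyr::arrange(named2, start)$site_name)
})

test_that("emitted sites satisfy their own invariants on fixtures", {
  for (kind in c("hairpin", "clamped_hairpin")) {
    s <- fixture_structure(kind)
    ss <- assign_secondary_structure(s)
    sites <- enumerate_loop_hexapeptides(s, ss, find_disulfides(s))
    if (nrow(sites) == 0) next
    expect_true(all(sites$end - sites$start == 5))
    expect_true(all(nchar(sites$seq) == 6))
    expect_true(all(sites$flank_n %in% c("S", "H", "C")))
    expect_true(all(sites$flank_c %in% c("S", "H", "C")))
    expect_equal(sites$motif,
                 paste0(sites$flank_n, "L", sites$flank_c))
  }
})
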