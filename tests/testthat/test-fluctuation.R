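# RMSF backends: ensemble statistics, Gaussian-network model, calibration.

test_that("identical frames give zero RMSF", {
  s <- fixture_structure("linear_peptide")
  e <- fixture_ensemble(s, frames = 10, sigma = 0, seed = 1)
  prof <- rmsf_from_ensemble(e)
  expect_true(all(prof$rmsf < 1e-12))
})

test_that("isotropic Gaussian jitter is recovered as sqrt(3)*sigma", {
  # a structure with enough residues that the 6 rigid-fit degrees of
  # freedom absorb a negligible share of the injected variance
  s <- fixture_structure("hairpin")
  e <- fixture_ensemble(s, frames = 500, sigma = 0.5, seed = 3)
  prof <- rmsf_from_ensemble(e, window = seq_len(500)) # use all frames
  expected <- 0.5 * sqrt(3)
  expect_equal(mean(prof$rmsf), expected, tolerance = 0.05)
  # Monte-Carlo oracle: fresh draws from the same model, no superposition
  set.seed(777)
  mc <- replicate(2000, sqrt(sum(rnorm(3, 0, 0.5)^2)))
  expect_equal(sqrt(mean(mc^2)), expected, tolerance = 0.05)
  expect_true(all(abs(prof$rmsf - expected) / expected < 0.2))
})

test_that("rigid-body motion is removed by superposition", {
  s <- fixture_structure("hairpin")
  e <- fixture_ensemble(s, frames = 20, sigma = 0, seed = 5,
                        rigid_noise = TRUE)
  prof <- rmsf_from_ensemble(e, window = seq_len(20))
  expect_true(all(prof$rmsf < 1e-6))
})

test_that("a single frame has no defined RMSF", {
  s <- fixture_structure("linear_peptide")
  e <- flapr:::new_ensemble(s, array(coords_matrix(s),
                                     c(1, nrow(s), 3)))
  expect_error(rmsf_from_ensemble(e), "single frame")
})

test_that("injected per-residue amplitudes are recovered across residues", {
  s <- fixture_structure("hairpin")
  nres <- nrow(residue_table(s))
  amp <- seq(0.2, 1.2, length.out = nres)
  e <- fixture_ensemble(s, frames = 500, sigma = amp, seed = 11)
  prof <- rmsf_from_ensemble(e, window = seq_len(500))
  per_res <- prof %>%
    dplyr::group_by(.data$resno) %>%
    dplyr::summarise(rmsf = mean(.data$rmsf))
  expect_gt(stats::cor(per_res$rmsf, amp * sqrt(3)), 0.95)
})

test_that("the 3-node path graph has fluctuations proportional to 5/9, 2/9, 5/9", {
  # nodes 6 A apart in a line; 7.5 A cutoff links only neighbours
  s <- ca_only_structure(cbind(c(0, 6, 12), 0, 0))
  prof <- rmsf_from_enm(s, cutoff = 7.5, calibration = 1)
  msf <- prof$rmsf^2
  expect_equal(msf / msf[2], c(5, 2, 5) / 2, tolerance = 1e-8)
  # closed form from the dense eigendecomposition oracle
  K <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3)
  expect_equal(msf, ginv_msf(K), tolerance = 1e-8)
})

test_that("a fully connected graph fluctuates uniformly", {
  s <- ca_only_structure(cbind(c(0, 4, 0, 4), c(0, 0, 4, 4), 0))
  prof <- rmsf_from_enm(s, cutoff = 7.5, calibration = 1)
  expect_equal(max(prof$rmsf) - min(prof$rmsf), 0, tolerance = 1e-10)
})

test_that("network fluctuations match the dense pseudoinverse oracle on random graphs", {
  set.seed(99)
  for (rep in 1:3) {
    n <- sample(10:50, 1)
    xyz <- matrix(runif(n * 3, 0, 15), n, 3)
    K <- flapr:::kirchhoff_matrix(xyz, cutoff = 9)
    if (max(flapr:::graph_components(K)) > 1) next
    expect_equal(flapr:::gnm_msf(K), ginv_msf(K), tolerance = 1e-8)
  }
})

test_that("cross-loop contacts lower the loop fluctuation", {
  cal <- enm_calibration(fixture_structure("hairpin"))
  open <- rmsf_from_enm(fixture_structure("hairpin"), calibration = cal)
  clamp <- rmsf_from_enm(fixture_structure("clamped_hairpin"),
                         calibration = cal)
  site <- tibble::tibble(chain = "A", start = 10L)
  expect_lt(site_mean_rmsf(clamp, site), site_mean_rmsf(open, site))
})

test_that("a free linear hexapeptide fluctuates more than one clamped in a hairpin", {
  cal <- enm_calibration(fixture_structure("hairpin"))
  lin <- rmsf_from_enm(fixture_structure("linear_peptide", n = 8),
                       cutoff = 7.5, calibration = cal)
  emb <- rmsf_from_enm(fixture_structure("clamped_hairpin"),
                       calibration = cal)
  site_lin <- tibble::tibble(chain = "A", start = 2L)
  site_emb <- tibble::tibble(chain = "A", start = 10L)
  expect_gt(site_mean_rmsf(lin, site_lin), site_mean_rmsf(emb, site_emb))
})

test_that("disconnected contact graphs are reported", {
  s <- ca_only_structure(cbind(c(0, 4, 50, 54, 58), 0, 0))
  expect_error(rmsf_from_enm(s), "disconnected.*2 components")
})

test_that("site mean RMSF averages heavy atoms of the six residues", {
  s <- fixture_structure("hairpin")
  prof <- rmsf_from_enm(s, calibration = 1)
  prof$rmsf <- rep(1.2, nrow(prof))
  site <- tibble::tibble(chain = "A", start = 10L)
  expect_equal(site_mean_rmsf(prof, site), 1.2)
  # six residues with equal atom counts and atom means 0.5,0.5,1,1,1.5,1.5
  vals <- c(0.5, 0.5, 1, 1, 1.5, 1.5)
  idx <- prof$resno %in% 10:15
  prof$rmsf[idx] <- vals[match(prof$resno[idx], 10:15)]
  expect_equal(site_mean_rmsf(prof, site), 1.0)
  expect_error(site_mean_rmsf(prof, tibble::tibble(chain = "A", start = 100L)),
               "not fully covered")
})

test_that("calibration pins the median C-alpha RMSF to the target", {
  s <- fixture_structure("hairpin")
  cal <- enm_calibration(s, target = 0.8)
  prof <- rmsf_from_enm(s, calibration = cal)
  expect_equal(stats::median(prof$rmsf[prof$atom == "CA"]), 0.8,
               tolerance = 1e-9)
})

test_that("external RMSF tables import by atom index", {
  s <- fixture_structure("linear_peptide")
  path <- tempfile(fileext = ".txt")
  write.table(data.frame(atom_index = seq_len(nrow(s)),
                         rmsf_A = seq_len(nrow(s)) * 0.01),
              path, row.names = FALSE)
  prof <- read_rmsf_table(s, path)
  expect_equal(prof$rmsf, seq_len(nrow(s)) * 0.01)
})
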