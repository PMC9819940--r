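test_that("energy/wavelength conversion inverts exactly and rejects bad input", {
  for (e in c(1.0, 2.753, 6.2))
    expect_equal(nm_to_ev(ev_to_nm(e)), e, tolerance = 1e-12)
  expect_error(ev_to_nm(0), "> 0")
  expect_error(nm_to_ev(-450), "> 0")
})

test_that("transition weight is f/dE, linear in f and zero for forbidden lines", {
  expect_equal(transition_weight(2.0, 0.1), 0.05)
  expect_equal(transition_weight(2.0, 0.2), 0.10)
  expect_identical(transition_weight(c(1.5, 3.3, 5.1), c(0, 0, 0)), c(0, 0, 0))
  expect_error(transition_weight(0, 0.1), "> 0")
  expect_error(transition_weight(2.0, -0.1), ">= 0")
})

test_that("squared transition dipole inverts the oscillator-strength relation", {
  expect_identical(dipole_sq_from_f(2.0, 0), 0)
  # one hartree excitation with f = 2/3 has unit squared dipole in a.u.
  expect_equal(dipole_sq_from_f(27.211386, 2 / 3), 1, tolerance = 1e-12)
  expect_equal(dipole_sq_from_f(2.0, 0.1), 2.0409, tolerance = 1e-4)
})

test_that("raw spectrum accumulates hand-computed f/dE bin weights", {
  sp <- build_spectrum(two_snapshot_fixture(), c(1.75, 2.25, 2.75))
  expect_equal(sp$intensity, c(0.05, 0.08))
  expect_identical(sp$n_records, 2L)
  expect_false(sp$normalized)
  spn <- build_spectrum(two_snapshot_fixture(), c(1.75, 2.25, 2.75),
                        normalize = TRUE)
  expect_equal(spn$intensity, c(0.625, 1.0))
  expect_true(spn$normalized)
})

test_that("degenerate spectra are all zero", {
  sp0 <- build_spectrum(list(), seq(1, 7, 0.5))
  expect_identical(sp0$n_records, 0L)
  expect_true(all(sp0$intensity == 0))
  forb <- list(snapshot_record("s", 0, excitation_entry(1L, 2.5, 0)))
  expect_true(all(build_spectrum(forb, seq(1, 7, 0.5))$intensity == 0))
  # normalization is skipped for an identically-zero spectrum
  expect_false(build_spectrum(forb, seq(1, 7, 0.5), normalize = TRUE)$normalized)
})

test_that("raw binning matches a brute-force double loop on small fixtures", {
  set.seed(21)
  for (rep in 1:5) {
    records <- random_records(4, max_states = 3L)
    tab <- excitation_table(records)
    edges <- sort(c(1, runif(9, 1.1, 6.9), 7))
    sp <- build_spectrum(records, edges)
    expect_equal(sp$intensity,
                 brute_force_spectrum(tab$delta_e_ev, tab$osc_strength, edges),
                 tolerance = 1e-10)
  }
})

test_that("total weight is conserved under bin refinement", {
  set.seed(22)
  records <- random_records(40)
  tab <- excitation_table(records)
  total <- sum(tab$osc_strength / tab$delta_e_ev)
  for (bw in c(0.4, 0.2, 0.1, 0.05))
    expect_equal(sum(build_spectrum(records, seq(1, 7, by = bw))$intensity),
                 total, tolerance = 1e-10)
})

test_that("state filtering keeps only the requested band", {
  recs <- list(snapshot_record("s", 0,
                               excitation_entry(c(1L, 2L), c(2.2, 4.1),
                                                c(0.05, 0.8))))
  s1 <- build_spectrum(recs, seq(1, 7, 0.1), state_filter = 1L)
  expect_equal(sum(s1$intensity), 0.05 / 2.2, tolerance = 1e-12)
  expect_identical(s1$n_excitations, 1L)
})

test_that("Gaussian broadening approximately conserves deposited weight", {
  records <- two_snapshot_fixture()
  sp <- build_spectrum(records, seq(0.5, 7, by = 0.01), kernel_width_ev = 0.05)
  expect_equal(sum(sp$intensity), 0.05 + 0.08, tolerance = 1e-3)
  expect_error(build_spectrum(records, seq(1, 7, 0.1), kernel_width_ev = -1),
               "non-negative")
})

test_that("a uniform red shift of all excitation energies is bathochromic", {
  set.seed(23)
  base <- generate_ensemble(substituent_config("F", n_snapshots = 400,
                                               seed = 31))$records
  shift <- lapply(base, function(r) {
    r$excitations$delta_e_ev <- r$excitations$delta_e_ev - 0.3
    r
  })
  edges <- seq(1, 7, by = 0.01)
  win <- c(200, 1100)
  l0 <- band_maximum(build_spectrum(base, edges, kernel_width_ev = 0.08,
                                    state_filter = 1L), win)$lambda_max_nm
  l1 <- band_maximum(build_spectrum(shift, edges, kernel_width_ev = 0.08,
                                    state_filter = 1L), win)$lambda_max_nm
  expect_gt(l1, l0)
})

test_that("band maxima are located with the longer-wavelength tie rule", {
  edges <- seq(2.5, 2.9, by = 0.01)
  one <- list(snapshot_record("s", 0, excitation_entry(1L, 2.695, 0.04)))
  rep1 <- band_maximum(build_spectrum(one, edges), c(400, 500))
  expect_equal(rep1$lambda_max_nm, ev_to_nm(2.695), tolerance = 0.5)

  # equal weight in two bins: the red (longer-wavelength) one wins
  two <- list(snapshot_record("s", 0,
                              excitation_entry(c(1L, 2L), c(2.605, 2.755),
                                               c(0.2605, 0.2755))))
  rep2 <- band_maximum(build_spectrum(two, seq(2.5, 2.9, by = 0.05)),
                       c(400, 500))
  expect_equal(rep2$energy_max_ev, 2.625, tolerance = 1e-9)

  # the hand fixture: 2.5 eV bin carries 0.08 > 0.05
  rep3 <- band_maximum(build_spectrum(two_snapshot_fixture(),
                                      c(1.75, 2.25, 2.75)), c(400, 700))
  expect_equal(rep3$energy_max_ev, 2.5, tolerance = 1e-12)
  expect_error(band_maximum(build_spectrum(two_snapshot_fixture(),
                                           c(1.75, 2.25, 2.75)), c(100, 120)),
               "empty window")
})

test_that("spectrum CSV export carries both axes", {
  sp <- build_spectrum(two_snapshot_fixture(), c(1.75, 2.25, 2.75))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  df <- read.csv(path)
  expect_identical(names(df), c("bin_center_ev", "bin_center_nm", "intensity"))
  expect_equal(df$bin_center_nm, ev_to_nm(df$bin_center_ev), tolerance = 1e-9)
})
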