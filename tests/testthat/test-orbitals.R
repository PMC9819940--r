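test_that("atom-type weight reproduces hand-evaluated cases", {
  # two N atoms, one AO each with coefficients 0.6 and 0.8, plus a C atom
  block <- coeff_block(matrix(c(0.6, 0.8, 0.0), ncol = 1,
                              dimnames = list(NULL, "HOMO")),
                       ao_atom = c(1L, 2L, 3L),
                       atom_type = c("N", "N", "C"))
  expect_equal(ao_weight(block, "HOMO", "N"), 0.5)
  expect_equal(ao_weight(block, "HOMO", "C"), 0)
  expect_error(ao_weight(block, "HOMO", "Xe"), "no atoms of type")
  expect_error(ao_weight(block, "SOMO", "N"), "unknown MO")
})

test_that("one-AO-per-atom orthonormal MOs satisfy sum(N_a * omega_a) = 1", {
  set.seed(31)
  types <- c("N", "N", "C", "C", "C", "F")
  c0 <- rnorm(6); c0 <- c0 / sqrt(sum(c0^2))
  block <- coeff_block(matrix(c0, ncol = 1), seq_along(types), types)
  total <- sum(vapply(unique(types), function(a)
    sum(types == a) * ao_weight(block, 1, a), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("atom-type weight matches a per-AO brute-force loop on random blocks", {
  set.seed(32)
  for (rep in 1:10) {
    n_atoms <- sample(2:6, 1)
    types <- sample(c("N", "C", "Cl"), n_atoms, replace = TRUE)
    ao_atom <- sample(seq_len(n_atoms), sample(5:20, 1), replace = TRUE)
    co <- matrix(rnorm(length(ao_atom) * 2), ncol = 2)
    block <- coeff_block(co, ao_atom, types)
    for (a in unique(types)) {
      expect_equal(ao_weight(block, 1, a), brute_force_ao_weight(block, 1, a),
                   tolerance = 1e-12)
      expect_equal(ao_weight(block, 2, a), brute_force_ao_weight(block, 2, a),
                   tolerance = 1e-12)
    }
    # permuting AO rows and flipping a column sign leave the weights unchanged
    perm <- sample(length(ao_atom))
    co2 <- co[perm, , drop = FALSE]; co2[, 2] <- -co2[, 2]
    block2 <- coeff_block(co2, ao_atom[perm], types)
    for (a in unique(types)) {
      expect_equal(ao_weight(block2, 1, a), ao_weight(block, 1, a),
                   tolerance = 1e-12)
      expect_equal(ao_weight(block2, 2, a), ao_weight(block, 2, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("coefficient blocks survive the long-format CSV round trip", {
  block <- generate_coeff_block(list(HOMO = c(N = 0.42, Br = 0.22),
                                     LUMO = c(N = 0.56, Br = 0.12)),
                                n_atoms = c(N = 2L, Br = 4L), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coeff_block_csv(block, path)
  back <- read_coeff_block_csv(path)
  for (mo in c("HOMO", "LUMO"))
    for (a in c("N", "Br"))
      expect_equal(ao_weight(back, mo, a), ao_weight(block, mo, a),
                   tolerance = 1e-9)
})

test_that("MO-energy statistics summarize the available entries", {
  recs <- list(
    snapshot_record("a", 0, excitation_entry(1L, 2.6, 0.05, -8.0, -1.6)),
    snapshot_record("b", 10, excitation_entry(1L, 2.7, 0.04, -8.4, -1.7)),
    snapshot_record("c", 20, excitation_entry(1L, 2.5, 0.06)))
  st <- mo_energy_stats(recs, "initial", 1L)
  expect_equal(st$mean, -8.2)
  expect_identical(st$n, 2L)
  same <- lapply(1:4, function(i)
    snapshot_record(paste0("s", i), 0,
                    excitation_entry(1L, 2.6, 0.05, -8.357, -1.606)))
  st2 <- mo_energy_stats(same, "initial", 1L)
  expect_equal(st2$mean, -8.357)
  expect_equal(st2$sd, 0)
  expect_error(mo_energy_stats(recs, "initial", 5L), "no initial MO energies")
})

test_that("MO-energy histogram is a plain counting histogram", {
  one <- list(snapshot_record("a", 0, excitation_entry(1L, 2.6, 0.05, -8.2, -1.6)))
  h1 <- mo_energy_histogram(one, "initial")
  expect_identical(sum(h1$counts), 1L)
  two <- list(
    snapshot_record("a", 0, excitation_entry(1L, 2.6, 0.05, -8.25, -1.6)),
    snapshot_record("b", 10, excitation_entry(1L, 2.6, 0.05, -8.15, -1.6)))
  h2 <- mo_energy_histogram(two, "initial", bin_width_ev = 0.1)
  expect_identical(h2$counts[h2$counts > 0], c(1L, 1L))
  set.seed(33)
  ens <- generate_ensemble(substituent_config("Cl", n_snapshots = 200, seed = 5))
  h <- mo_energy_histogram(ens$records, "initial")
  expect_identical(sum(h$counts), mo_energy_stats(ens$records, "initial")$n)
})

test_that("the departing-MO / free-halide correlation behaves as designed", {
  collinear <- halide_trend(c(-15, -12, -10), c(-9, -7.5, -6.5))
  expect_lt(abs(collinear$r - 1), 1e-9)
  perfect <- halide_trend(c(-15, -12, -10), -9 + 0.5 * (c(-15, -12, -10) + 15))
  expect_equal(perfect$r, 1)
  expect_true(perfect$monotonic)
  nonmono <- halide_trend(c(-15.2, -11.5, -10.5), c(-8.0, -8.5, -7.6))
  expect_false(nonmono$monotonic)
  expect_error(halide_trend(c(-15, -12, -10), c(-8, -8, -8)), "zero variance")
  expect_error(halide_trend(c(-15, -12), c(-8, -7)), "at least 3")
})
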