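test_that("dihedral reproduces the planar and perpendicular reference cases", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # far bond rotated clockwise from the near bond, sighting p2 -> p3: +90
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), 90)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, -1)), -90)
})

test_that("dihedral agrees with the projection oracle on random quadruples", {
  set.seed(41)
  for (i in 1:1000) {
    p <- random_quadruple()
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is invariant under rigid motion and chain reversal", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_quadruple()
    ref <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    # random rotation (QR of a random matrix, det +1) plus translation
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
    t0 <- runif(3, -5, 5)
    q <- t(R %*% t(p)) + matrix(t0, 4, 3, byrow = TRUE)
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-9)
    expect_equal(dihedral(p[4, ], p[3, ], p[2, ], p[1, ]), ref,
                 tolerance = 1e-9)
  }
})

test_that("degenerate quadruples raise errors instead of returning zero", {
  expect_error(dihedral(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               "collinear")
})

test_that("E/Z classification uses the |angle| >= 90 boundary rule", {
  expect_identical(ez_label(180), "E")
  expect_identical(ez_label(0), "Z")
  expect_identical(ez_label(90), "E")
  expect_identical(ez_label(-90), "E")
  expect_identical(ez_label(c(-179, 5, 89.9)), c("E", "Z", "Z"))
  expect_error(ez_label(181), "180")
})

test_that("dihedral series evaluate frame by frame in order", {
  sp <- toy_dihedral_specs()
  f_trans <- azospectra:::.build_frame(1, 180, 0, 0)
  f_cis <- azospectra:::.build_frame(2, 0, 0, 0)
  s <- dihedral_series(list(f_trans, f_cis), sp$azo)
  expect_equal(s$values, c(180, 0), tolerance = 1e-9)
  const <- dihedral_series(rep(list(f_trans), 4), sp$azo)
  expect_equal(const$values, rep(180, 4), tolerance = 1e-9)
  bad <- dihedral_spec("oob", c(0, 1, 2, 10))
  expect_error(dihedral_series(list(f_trans), bad), "frame 1")
})

test_that("generated trajectories reproduce the configured torsion centers", {
  cfg <- substituent_config("Cl", n_snapshots = 400, seed = 8)
  ens <- generate_ensemble(cfg)
  sp <- toy_dihedral_specs()
  azo <- dihedral_series(ens$trajectory, sp$azo)
  expect_lt(abs(wrap_angle(circ_mean_deg(azo$values) - 180)), 1.5)
  ph <- dihedral_series(ens$trajectory, sp$phenyl_1)
  expect_lt(abs(circ_mean_deg(ph$values)), 2)
  # stored dihedrals agree with the trajectory frame-by-frame
  stored <- vapply(ens$records, function(r) r$dihedrals[["phenyl_1"]],
                   numeric(1))
  expect_equal(ph$values, stored, tolerance = 1e-9)
})

test_that("circular histograms conserve counts and find the expected modes", {
  const <- circular_histogram(rep(180, 37), bin_width_deg = 10)
  expect_identical(sum(const$counts), 37L)
  expect_identical(const$counts[const$counts > 0], 37L)
  expect_equal(const$mode_angles, 180)
  # the 180-bin is circular: angles just past -180 fall into it too
  wrapped <- circular_histogram(c(rep(-179, 5), rep(179, 5)), bin_width_deg = 10)
  expect_identical(wrapped$counts[wrapped$bin_centers == 180], 10L)

  two <- circular_histogram(c(rep(-90, 50), rep(90, 50)), bin_width_deg = 10)
  expect_identical(sum(two$counts), 100L)
  expect_setequal(two$mode_angles, c(-90, 90))

  set.seed(43)
  v <- wrap_angle(rnorm(500, 0, 25))
  expect_identical(sum(circular_histogram(v, 5)$counts), 500L)
  expect_error(circular_histogram(v, 7), "divisor")
})

test_that("coplanarity fractions and the perpendicular-artifact flag behave", {
  mk <- function(name, values)
    structure(list(spec = dihedral_spec(name, c(0, 1, 2, 3),
                                        "phenyl_inclination"),
                   values = values),
              class = "dihedral_series")
  planar <- coplanarity_report(mk("ring1", rep(0, 100)))
  expect_equal(planar$fraction_coplanar, 1)
  expect_false(planar$perpendicular_artifact)

  perp <- coplanarity_report(mk("ring1", rep(90, 100)))
  expect_equal(perp$fraction_coplanar, 0)
  expect_true(perp$perpendicular_artifact)

  # mixture with mass 0.6 near-planar and 0.4 perpendicular: the coplanar
  # fraction recovers the configured near-planar mass
  cfg <- substituent_config("custom", n_snapshots = 2000, seed = 12,
                            phenyl_mix = phenyl_mixture(c(10, 90),
                                                        c(0.6, 0.4),
                                                        sd_deg = 5))
  ens <- generate_ensemble(cfg)
  ph <- vapply(ens$records, function(r) r$dihedrals[["phenyl_1"]], numeric(1))
  rep_ <- coplanarity_report(mk("ring1", ph))
  se <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(rep_$fraction_coplanar - 0.6), 3 * se)
})
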