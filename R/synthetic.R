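# Synthetic snapshot ensembles.
#
# The generator emulates the statistical structure of the QM/MM-MD plus
# excited-state data stream for the tetra-ortho-halogenated azobenzene series:
# an E-configured azo dihedral concentrated near 180 degrees, substituent-
# dependent circular mixtures for the phenyl-ring torsions, Gaussian MO
# energies and S1/S2 excitation energies centered on the ensemble averages of
# the series, a strong S2 oscillator strength, and a weak S1 strength that can
# be coupled to the torsional deviation from planarity so that it vanishes
# exactly at the symmetric planar geometry (the parent compound's case, where
# the vertical S1 transition is dipole-forbidden) yet is positive on ensemble
# average.

# Ensemble-average defaults for the series (eV): S1 excitation energy and the
# energies of the MOs the S1 excitation starts from / ends in, plus a strong
# near-UV S2 location per substituent.
.SUBSTITUENT_DEFAULTS <- data.frame(
  label = c("H", "F", "Cl", "Br"),
  mean_delta_e_s1 = c(2.645, 2.509, 2.114, 2.091),
  mean_e_moi = c(-8.357, -8.376, -7.920, -7.673),
  mean_e_mof = c(-1.606, -1.774, -2.003, -1.939),
  mean_delta_e_s2 = c(3.94, 4.25, 4.44, 4.44),
  stringsAsFactors = FALSE
)

#' Wrap angles into (-180, 180]
#'
#' @param angle_deg Numeric angles in degrees.
#' @return Equivalent angles in (-180, 180].
#' @export
wrap_angle <- function(angle_deg) {
  a <- angle_deg %% 360
  ifelse(a > 180, a - 360, a)
}

#' Phenyl-torsion mixture describing a substituent's ring dynamics
#'
#' Helper constructing the circular-mixture table consumed by
#' [substituent_config()]: one row per wrapped-normal component with its
#' center, spread and mass.
#'
#' @param center_deg Component centers in degrees.
#' @param mass Component masses; must sum to 1.
#' @param sd_deg Component spreads in degrees (recycled).
#' @return Data frame with columns `center_deg`, `sd_deg`, `mass`.
#' @export
phenyl_mixture <- function(center_deg, mass, sd_deg = 12) {
  if (abs(sum(mass) - 1) > 1e-9) stop("mixture masses must sum to 1")
  if (any(mass < 0)) stop("mixture masses must be >= 0")
  if (any(sd_deg < 0)) stop("mixture sds must be >= 0")
  data.frame(center_deg = center_deg, sd_deg = rep_len(sd_deg, length(center_deg)),
             mass = mass)
}

.default_phenyl_mixture <- function(label) {
  switch(label,
    # rings flip between the two coplanar arrangements (equal areas)
    H = phenyl_mixture(c(0, 180), c(0.5, 0.5)),
    F = phenyl_mixture(c(0, 180), c(0.5, 0.5)),
    # rotation fully hindered: single coplanar well
    Cl = phenyl_mixture(0, 1),
    # bulky substituent: staggered wells at +-150 and +-30, unequal areas
    Br = phenyl_mixture(c(150, -150, 30, -30), c(0.35, 0.35, 0.15, 0.15)),
    phenyl_mixture(c(0, 180), c(0.5, 0.5)))
}

#' Perpendicular-ring torsion mixture (force-field artifact mode)
#'
#' The phenyl-torsion mixture produced by a force field that treats the ring
#' C-N bonds as freely rotating sigma bonds: both rings sit perpendicular to
#' the azo plane, at +-90 degrees, and are never coplanar.
#'
#' @param sd_deg Component spread in degrees (default 20, reflecting the loose
#'   torsional restraint of such a force field).
#' @return Mixture table as from [phenyl_mixture()].
#' @export
perpendicular_phenyl_mixture <- function(sd_deg = 20) {
  phenyl_mixture(c(90, -90), c(0.5, 0.5), sd_deg = sd_deg)
}

#' Configuration of a synthetic substituent ensemble
#'
#' Collects every distributional parameter of the generator. Defaults for the
#' H/F/Cl/Br series place the S1 excitation energy and the two MO energies at
#' the ensemble averages of the series and choose torsional mixtures matching
#' each substituent's ring dynamics; distribution widths are synthetic
#' parameters with documented defaults.
#'
#' @param label `"H"`, `"F"`, `"Cl"`, `"Br"` or `"custom"`.
#' @param n_snapshots Number of snapshots (default 3000, one per 10 ps of a
#'   30 ns production run).
#' @param mean_delta_e_s1,sd_delta_e Mean and sd of the S1 excitation energy,
#'   eV.
#' @param mean_delta_e_s2,sd_s2 Mean and sd of the S2 excitation energy, eV.
#' @param mean_e_moi,mean_e_mof,sd_mo Means and common sd of the energies of
#'   the MO the excitation starts from and ends in, eV.
#' @param f_s1_max Peak S1 oscillator strength (amplitude of the torsion
#'   coupling, or the mean when uncoupled).
#' @param f_s2 Mean S2 oscillator strength (sd is 10 percent of the mean).
#' @param phenyl_mix Torsion mixture table from [phenyl_mixture()].
#' @param azo_center_deg,azo_sd_deg Azo-dihedral wrapped-normal parameters
#'   (default 180 and 8 degrees: a stable E configuration).
#' @param coupling_planarity If `TRUE`, f(S1) = f_s1_max * sin^2(theta_dev)
#'   where theta_dev is the mean deviation of the two ring torsions from
#'   planarity, so a perfectly planar frame has a strictly forbidden S1
#'   transition. Default `TRUE` for X = H (the symmetric parent), `FALSE`
#'   otherwise.
#' @param interval_ps Snapshot spacing in ps (default 10).
#' @param seed Integer RNG seed.
#' @return An object of class `substituent_config`.
#' @export
substituent_config <- function(label = "custom", n_snapshots = 3000,
                               mean_delta_e_s1 = NULL, sd_delta_e = 0.15,
                               mean_delta_e_s2 = NULL, sd_s2 = 0.20,
                               mean_e_moi = NULL, mean_e_mof = NULL,
                               sd_mo = 0.30,
                               f_s1_max = 0.05, f_s2 = 0.8,
                               phenyl_mix = NULL,
                               azo_center_deg = 180, azo_sd_deg = 8,
                               coupling_planarity = NULL,
                               interval_ps = 10, seed = 1L) {
  row <- .SUBSTITUENT_DEFAULTS[.SUBSTITUENT_DEFAULTS$label == label, ]
  pick <- function(x, col, fallback) {
    if (!is.null(x)) x else if (nrow(row)) row[[col]] else fallback
  }
  cfg <- structure(list(
    label = label,
    n_snapshots = as.integer(n_snapshots),
    mean_delta_e_s1 = pick(mean_delta_e_s1, "mean_delta_e_s1", 2.6),
    sd_delta_e = sd_delta_e,
    mean_delta_e_s2 = pick(mean_delta_e_s2, "mean_delta_e_s2", 4.2),
    sd_s2 = sd_s2,
    mean_e_moi = pick(mean_e_moi, "mean_e_moi", -8.3),
    mean_e_mof = pick(mean_e_mof, "mean_e_mof", -1.7),
    sd_mo = sd_mo,
    f_s1_max = f_s1_max, f_s2 = f_s2,
    phenyl_mix = if (is.null(phenyl_mix)) .default_phenyl_mixture(label)
                 else phenyl_mix,
    azo_center_deg = azo_center_deg, azo_sd_deg = azo_sd_deg,
    coupling_planarity = if (is.null(coupling_planarity)) label == "H"
                         else coupling_planarity,
    interval_ps = interval_ps,
    seed = as.integer(seed)), class = "substituent_config")
  if (cfg$n_snapshots < 1L) stop("n_snapshots must be >= 1")
  if (cfg$sd_delta_e < 0 || cfg$sd_s2 < 0 || cfg$sd_mo < 0 ||
      cfg$azo_sd_deg < 0)
    stop("distribution widths must be >= 0")
  if (abs(sum(cfg$phenyl_mix$mass) - 1) > 1e-9)
    stop("phenyl mixture masses must sum to 1")
  cfg
}

# Sample a circular (wrapped-normal) mixture.
.sample_mixture <- function(n, mix) {
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$mass)
  wrap_angle(stats::rnorm(n, mix$center_deg[comp], mix$sd_deg[comp]))
}

# Normal truncated to positive values by rejection.
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Place atom d at the given internal coordinates relative to chain a-b-c, so
# that |d-c| = bond, angle(d,c,b) = angle_deg and dihedral(d,c,b,a) = dih_deg.
.place_atom <- function(a, b, c, bond, angle_deg, dih_deg) {
  ang <- angle_deg * pi / 180
  dih <- dih_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Toy 6-site frame carrying the three dihedrals of interest: an azo core
# C1-N1=N2-C2 plus one ortho-carbon probe per ring. Atom order (0-based):
# 0 C1, 1 N1, 2 N2, 3 C2, 4 CA (ring 1 probe), 5 CB (ring 2 probe).
.build_frame <- function(frame_index, azo_deg, phenyl1_deg, phenyl2_deg) {
  d_nn <- 1.25; d_cn <- 1.41; d_cc <- 1.40
  n1 <- c(0, 0, 0)
  n2 <- c(d_nn, 0, 0)
  th <- 115 * pi / 180
  c1 <- n1 + d_cn * c(cos(th), sin(th), 0)
  c2 <- .place_atom(c1, n1, n2, d_cn, 115, azo_deg)
  ca <- .place_atom(n2, n1, c1, d_cc, 120, phenyl1_deg)
  cb <- .place_atom(n1, n2, c2, d_cc, 120, phenyl2_deg)
  trajectory_frame(frame_index,
                   rbind(c1, n1, n2, c2, ca, cb),
                   c("C1", "N1", "N2", "C2", "CA", "CB"))
}

#' Dihedral specifications matching the generator's toy trajectory
#'
#' @return Named list of three `dihedral_spec` objects: the azo C-N=N-C
#'   torsion and one ring-inclination torsion per phenyl probe, with 0-based
#'   indices into the 6-atom frames produced by [generate_ensemble()].
#' @export
toy_dihedral_specs <- function() {
  list(azo = dihedral_spec("azo", c(0, 1, 2, 3), "azo_EZ"),
       phenyl_1 = dihedral_spec("phenyl_1", c(4, 0, 1, 2), "phenyl_inclination"),
       phenyl_2 = dihedral_spec("phenyl_2", c(5, 3, 2, 1), "phenyl_inclination"))
}

# Fast internal two-state excitation table (avoids data.frame() overhead in
# the per-snapshot loop).
.exc2 <- function(de1, f1, moi, mof, de2, f2) {
  structure(list(state_index = c(1L, 2L),
                 delta_e_ev = c(de1, de2),
                 osc_strength = c(f1, f2),
                 e_mo_initial_ev = c(moi, NA_real_),
                 e_mo_final_ev = c(mof, NA_real_)),
            class = "data.frame", row.names = c(NA, -2L))
}

#' Generate a synthetic snapshot ensemble
#'
#' Draws `n_snapshots` geometries and excited-state records from the
#' distributions in the configuration: the azo dihedral from a wrapped normal
#' at 180 degrees, each phenyl torsion independently from the configured
#' circular mixture, MO energies and excitation energies from normals
#' (excitation energies truncated positive), the S2 oscillator strength from a
#' positive-truncated normal, and the S1 strength either sin^2-coupled to the
#' torsional deviation from planarity or drawn as a capped |normal|. A toy
#' 6-atom trajectory frame is built for every snapshot so that evaluating the
#' [toy_dihedral_specs()] torsions on the trajectory reproduces the stored
#' dihedrals. Output is bit-identical under a fixed seed.
#'
#' @param config A `substituent_config`.
#' @return An object of class `generated_ensemble`: list with `records`
#'   (snapshot records, MO energies attached to S1), `trajectory` (list of
#'   `trajectory_frame`) and `config`.
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "substituent_config"))
  n <- config$n_snapshots
  set.seed(config$seed)
  azo <- wrap_angle(stats::rnorm(n, config$azo_center_deg, config$azo_sd_deg))
  ph1 <- .sample_mixture(n, config$phenyl_mix)
  ph2 <- .sample_mixture(n, config$phenyl_mix)
  e_moi <- stats::rnorm(n, config$mean_e_moi, config$sd_mo)
  e_mof <- stats::rnorm(n, config$mean_e_mof, config$sd_mo)
  while (any(bad <- e_moi >= e_mof)) {  # occupied must stay below virtual
    e_moi[bad] <- stats::rnorm(sum(bad), config$mean_e_moi, config$sd_mo)
    e_mof[bad] <- stats::rnorm(sum(bad), config$mean_e_mof, config$sd_mo)
  }
  de1 <- .rnorm_pos(n, config$mean_delta_e_s1, config$sd_delta_e)
  de2 <- .rnorm_pos(n, config$mean_delta_e_s2, config$sd_s2)
  if (config$coupling_planarity) {
    dev <- (planarity_deviation(ph1) + planarity_deviation(ph2)) / 2
    f1 <- config$f_s1_max * sin(dev * pi / 180)^2
  } else {
    f1 <- pmin(abs(stats::rnorm(n, config$f_s1_max, 0.1 * config$f_s1_max)), 1)
  }
  f2 <- .rnorm_pos(n, config$f_s2, 0.1 * config$f_s2)
  ids <- sprintf("%s_%05d", config$label, seq_len(n))
  times <- seq_len(n) * config$interval_ps
  records <- vector("list", n)
  trajectory <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- structure(
      list(snapshot_id = ids[i], time_ps = times[i],
           excitations = .exc2(de1[i], f1[i], e_moi[i], e_mof[i], de2[i], f2[i]),
           dihedrals = c(azo = azo[i], phenyl_1 = ph1[i], phenyl_2 = ph2[i]),
           coeff_block_id = NULL),
      class = "snapshot_record")
    trajectory[[i]] <- .build_frame(i, azo[i], ph1[i], ph2[i])
  }
  structure(list(records = records, trajectory = trajectory, config = config),
            class = "generated_ensemble")
}

#' @export
print.generated_ensemble <- function(x, ...) {
  cat(sprintf("<generated_ensemble> X=%s, %d snapshots (seed %d)\n",
              x$config$label, length(x$records), x$config$seed))
  invisible(x)
}

#' Generate an LCAO coefficient block with prescribed atom-type weights
#'
#' Constructs random real coefficients and rescales, per atom type and MO, so
#' that [ao_weight()] reproduces each target weight essentially exactly. A
#' target of zero zeroes every coefficient on that type.
#'
#' @param targets Named list, one element per MO label (e.g. `"HOMO"`), each a
#'   named numeric vector of target weights per atom type. Types present in
#'   `n_atoms` but absent from a target get zero coefficients in that MO.
#' @param n_atoms Named integer vector: atoms per type (e.g. `c(N = 2, Br = 4)`).
#' @param aos_per_atom AOs carried by each atom (default 4).
#' @param seed Integer RNG seed.
#' @return A `coeff_block` whose columns are the names of `targets`.
#' @export
generate_coeff_block <- function(targets, n_atoms, aos_per_atom = 4,
                                 seed = 1L) {
  if (any(n_atoms < 1L)) stop("every atom type needs at least one atom")
  set.seed(seed)
  atom_type <- rep(names(n_atoms), times = n_atoms)
  n_at <- length(atom_type)
  ao_atom <- rep(seq_len(n_at), each = aos_per_atom)
  n_ao <- length(ao_atom)
  co <- matrix(0, nrow = n_ao, ncol = length(targets),
               dimnames = list(NULL, names(targets)))
  for (j in seq_along(targets)) {
    tg <- targets[[j]]
    if (any(tg < 0)) stop("target weights must be >= 0")
    if (any(!names(tg) %in% names(n_atoms)))
      stop("target names an atom type with zero AOs")
    for (ty in names(tg)) {
      rows <- which(atom_type[ao_atom] == ty)
      if (tg[[ty]] == 0) next
      c0 <- stats::rnorm(length(rows))
      co[rows, j] <- c0 * sqrt(tg[[ty]] * n_atoms[[ty]] / sum(c0^2))
    }
  }
  coeff_block(co, ao_atom, atom_type)
}

#' Four-compound synthetic scenario (H, F, Cl, Br)
#'
#' Generates one ensemble per substituent at the series defaults, with
#' per-substituent seeds derived deterministically from a single top-level
#' seed. Because the configured S1 excitation-energy means decrease along
#' H > F > Cl > Br, the S1 band maxima extracted downstream shift to longer
#' wavelength along the series.
#'
#' @param seed Top-level integer seed.
#' @param n_snapshots Snapshots per compound (default 3000).
#' @return Named list of `generated_ensemble` objects (`H`, `F`, `Cl`, `Br`).
#' @export
four_compound_scenario <- function(seed = 1L, n_snapshots = 3000) {
  labels <- c("H", "F", "Cl", "Br")
  out <- lapply(seq_along(labels), function(i) {
    sub_seed <- as.integer((as.numeric(seed) * 16807 + i * 104729) %% 2147483647)
    generate_ensemble(substituent_config(labels[i], n_snapshots = n_snapshots,
                                         seed = sub_seed))
  })
  names(out) <- labels
  out
}
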