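# Dihedral-angle diagnostics of trajectory geometry: E/Z configuration of the
# azo N=N bond and the inclination of the phenyl rings relative to the azo
# plane. Circular distributions of these torsions distinguish the physically
# coplanar ring arrangement from the perpendicular-ring artifact produced by
# force fields that treat the C-N bonds as freely rotating sigma bonds.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion about the p2-p3 axis: positive when, sighting from
#' p2 toward p3, the far bond (p3 to p4) is rotated clockwise from the near
#' bond (p2 to p1). Anti-periplanar chains give 180 degrees, syn-periplanar 0.
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10) stop("degenerate dihedral: p2 and p3 coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate dihedral: three consecutive points are collinear")
  y <- sum(.cross3(n1, n2) * b2) / nb2
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify E/Z configuration from the azo dihedral
#'
#' @param angle_deg Dihedral angle(s) in degrees, each in (-180, 180].
#' @return Character vector: `"E"` when |angle| >= 90 (boundary assigned to
#'   E), `"Z"` otherwise.
#' @export
ez_label <- function(angle_deg) {
  if (any(angle_deg <= -180) || any(angle_deg > 180))
    stop("angles must lie in (-180, 180]")
  ifelse(abs(angle_deg) >= 90, "E", "Z")
}

#' Evaluate one dihedral along a trajectory
#'
#' @param frames List of `trajectory_frame` objects.
#' @param spec A `dihedral_spec` (0-based atom indices).
#' @return An object of class `dihedral_series`: the spec plus one angle per
#'   frame, in frame order.
#' @export
dihedral_series <- function(frames, spec) {
  idx <- spec$atom_indices + 1L
  values <- vapply(seq_along(frames), function(i) {
    co <- frames[[i]]$coordinates
    if (any(idx > nrow(co)))
      stop(sprintf("frame %d: dihedral '%s' needs atom index %d but frame has %d atoms",
                   i, spec$name, max(spec$atom_indices), nrow(co)))
    dihedral(co[idx[1], ], co[idx[2], ], co[idx[3], ], co[idx[4], ])
  }, numeric(1))
  structure(list(spec = spec, values = values), class = "dihedral_series")
}

#' Circular histogram of a dihedral series
#'
#' Bins the angles into circular bins centered on the multiples of the bin
#' width (so 0, +-90 and 180 are bin centers, where these torsion
#' distributions peak), and reports the local maxima (modes) of the circular
#' count sequence. Counts always sum to the number of frames. The bin centered
#' at 180 wraps across the branch point and also collects angles near -180.
#'
#' @param series A `dihedral_series`, or a bare numeric vector of angles in
#'   (-180, 180].
#' @param bin_width_deg Bin width in degrees; must divide 360 (default 10).
#' @param prominence Minimum height of a mode, as a fraction of the maximum
#'   count (default 0.1); bins below it are not reported as modes.
#' @return An object of class `circular_histogram` with `bin_centers`
#'   (ascending, in (-180, 180]), `bin_edges` (centers -/+ half a width; the
#'   outer edges describe the wrapping 180-bin), `counts` and `mode_angles`
#'   (bin centers of the local maxima).
#' @export
circular_histogram <- function(series, bin_width_deg = 10, prominence = 0.1) {
  v <- if (inherits(series, "dihedral_series")) series$values else series
  if (any(v <= -180) || any(v > 180)) stop("angles must lie in (-180, 180]")
  if (bin_width_deg <= 0 || 360 %% bin_width_deg != 0)
    stop("bin_width_deg must be a positive divisor of 360")
  nb <- as.integer(360 / bin_width_deg)
  k <- as.integer(round(v / bin_width_deg)) %% nb  # nearest center, circular
  counts_raw <- tabulate(k + 1L, nbins = nb)       # centers 0, w, ..., 360-w
  centers_raw <- wrap_angle((seq_len(nb) - 1L) * bin_width_deg)
  ord <- order(centers_raw)
  centers <- centers_raw[ord]
  counts <- counts_raw[ord]
  left <- counts[c(nb, seq_len(nb - 1L))]
  right <- counts[c(seq.int(2L, nb), 1L)]
  is_mode <- counts >= left & counts >= right &
    (counts > left | counts > right) &
    counts >= prominence * max(counts) & counts > 0L
  structure(list(bin_centers = centers,
                 bin_edges = c(centers - bin_width_deg / 2,
                               centers[nb] + bin_width_deg / 2),
                 counts = counts,
                 mode_angles = centers[is_mode]),
            class = "circular_histogram")
}

#' Angular deviation from coplanarity
#'
#' Distance, in degrees, of a torsion from the nearest planar arrangement
#' (0 or +-180 degrees).
#'
#' @param angle_deg Angles in degrees.
#' @return Deviations in [0, 90].
#' @export
planarity_deviation <- function(angle_deg) {
  pmin(abs(angle_deg), 180 - abs(angle_deg))
}

#' Phenyl-ring coplanarity report
#'
#' For each phenyl-torsion series, the fraction of frames in which the ring is
#' within `threshold_deg` of coplanarity with the azo group (torsion near 0 or
#' +-180). A "perpendicular artifact" flag fires when essentially no frame is
#' coplanar (fraction below `artifact_fraction`) and the circular distribution
#' has a mode near +-90 -- the signature of a force field that lets the rings
#' rotate freely about the C-N bonds.
#'
#' @param phenyl_series List of `dihedral_series` (one per ring), or a single
#'   series.
#' @param threshold_deg Coplanarity threshold in degrees (default 30).
#' @param artifact_fraction Coplanar-fraction ceiling below which the artifact
#'   flag may fire (default 0.05).
#' @param bin_width_deg Bin width used for mode detection (default 10).
#' @return Data frame with one row per ring: `name`, `fraction_coplanar`,
#'   `perpendicular_artifact`.
#' @export
coplanarity_report <- function(phenyl_series, threshold_deg = 30,
                               artifact_fraction = 0.05, bin_width_deg = 10) {
  if (inherits(phenyl_series, "dihedral_series"))
    phenyl_series <- list(phenyl_series)
  if (!length(phenyl_series)) stop("need at least one dihedral series")
  rows <- lapply(phenyl_series, function(s) {
    if (!length(s$values)) stop("empty dihedral series: ", s$spec$name)
    dev <- planarity_deviation(s$values)
    frac <- mean(dev <= threshold_deg)
    ch <- circular_histogram(s, bin_width_deg = bin_width_deg)
    perp_mode <- any(abs(abs(ch$mode_angles) - 90) <= 15)
    data.frame(name = s$spec$name, fraction_coplanar = frac,
               perpendicular_artifact = frac < artifact_fraction && perp_mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
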