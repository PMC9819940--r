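# Independent oracles and tiny fixture builders shared across the suite.

# Brute-force f/dE-weighted histogram: explicit double loop over excitations
# and bins, bins [e_k, e_{k+1}) with the last bin closed on the right.
brute_force_spectrum <- function(delta_e, osc, edges) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (k in seq_along(delta_e)) {
    for (b in seq_len(nb)) {
      inside <- if (b < nb)
        delta_e[k] >= edges[b] && delta_e[k] < edges[b + 1]
      else
        delta_e[k] >= edges[b] && delta_e[k] <= edges[b + 1]
      if (inside) out[b] <- out[b] + osc[k] / delta_e[k]
    }
  }
  out
}

# Brute-force per-AO loop for the atom-type weight.
brute_force_ao_weight <- function(block, mo, atom_type) {
  j <- if (is.character(mo)) match(mo, colnames(block$coefficients)) else mo
  total <- 0
  for (ao in seq_len(nrow(block$coefficients))) {
    atom <- block$ao_atom[ao]
    if (block$atom_type[atom] == atom_type)
      total <- total + block$coefficients[ao, j]^2
  }
  total / sum(block$atom_type == atom_type)
}

# Independent signed-torsion oracle: project the outer bonds onto the plane
# perpendicular to the central bond and take the signed angle between the
# projections around the central-bond axis.
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
  v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  ang <- atan2(sum(cr * u), sum(v1 * v2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Non-degenerate random point quadruple for torsion tests.
random_quadruple <- function() {
  repeat {
    p <- matrix(stats::runif(12, -2, 2), nrow = 4)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    n1 <- sqrt(sum((b1[c(2,3,1)] * b2[c(3,1,2)] - b1[c(3,1,2)] * b2[c(2,3,1)])^2))
    n2 <- sqrt(sum((b2[c(2,3,1)] * b3[c(3,1,2)] - b2[c(3,1,2)] * b3[c(2,3,1)])^2))
    if (sqrt(sum(b2^2)) > 0.3 && n1 > 0.1 && n2 > 0.1) return(p)
  }
}

# Two-snapshot hand fixture used across spectrum and pipeline tests:
# S1 states at (2.0 eV, f 0.1) and (2.5 eV, f 0.2).
two_snapshot_fixture <- function() {
  list(
    snapshot_record("snap_a", 10, excitation_entry(1L, 2.0, 0.1, -8.3, -1.6)),
    snapshot_record("snap_b", 20, excitation_entry(1L, 2.5, 0.2, -8.1, -1.7)))
}

# Random small record set (valid by construction).
random_records <- function(n_snapshots, max_states = 3L) {
  lapply(seq_len(n_snapshots), function(i) {
    k <- sample.int(max_states, 1)
    snapshot_record(sprintf("r%03d", i), i * 10,
                    excitation_entry(seq_len(k),
                                     stats::runif(k, 1.2, 6.5),
                                     stats::runif(k, 0, 1)))
  })
}

# Circular mean of angles in degrees.
circ_mean_deg <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}
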