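---
title: "Ensemble absorption band shapes: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble absorption band shapes: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azospectra)
```

## The model

A vertical-excitation calculation at the ground-state minimum predicts a
single excitation energy and oscillator strength per state. That is a good
estimate of a band maximum only when the transition dipole is roughly
constant over the thermally accessible geometries and the band is allowed at
the minimum. Azobenzene derivatives violate both conditions for their weak
nπ\* (S1) band: at the planar minimum of the parent compound the transition
is dipole-forbidden by symmetry, and the torsional motion of the phenyl
rings modulates the transition dipole strongly.

The ensemble construction implemented here replaces the single geometry with
a thermal sample. For every snapshot geometry and every excited state one
record carries the excitation energy $\Delta E_{if}$ (eV) and oscillator
strength $f_{if}$. Since

$$f_{if} = \frac{2 m_e}{3 \hbar^2 e^2}\, \Delta E_{if}\, |\mu_{if}|^2 ,$$

the transition probability is proportional to $f_{if} / \Delta E_{if}$, and
the absorption band is the histogram of excitation energies in which each
excitation deposits that weight instead of a count of one
(`build_spectrum()`). The resulting intensity is in arbitrary units and is
by default reported normalized to a unit maximum. `dipole_sq_from_f()`
recovers $|\mu_{if}|^2$ in atomic units, where the relation reduces to
$f = \tfrac{2}{3}\, \Delta E_\mathrm{Ha}\, |\mu|^2$.

Assumptions inherited from the construction: snapshots are uncorrelated
(one per 10 ps by default, the decorrelation interval used for this class of
solutes), the electronic structure at each snapshot is accurate, and no
vibronic fine structure is resolved — the band shape comes entirely from the
geometric spread of the ensemble. Franck–Condon/Herzberg–Teller expansions
and lifetime (Lorentzian) broadening are out of scope.

## Units and axes

Energies are carried in eV everywhere; wavelengths come from
$\lambda = hc/E$ with $hc = 1239.84198$ eV·nm. The histogram is accumulated
on the energy axis and only the *axis labels* are converted to nm for
reporting — no Jacobian $d\lambda/dE$ re-weighting is applied when plotting
versus wavelength, so a spectrum is one object regardless of the axis it is
shown on. Atomic units appear only inside the transition-dipole conversion
(1 Ha = 27.211386 eV).

## Spectrum parameters

| parameter | default | why |
|---|---|---|
| grid | 1–7 eV, 0.05 eV bins | covers the visible S1 band and near-UV S2 band of the series with ~25 bins across a band |
| `kernel_width_ev` | 0 (raw); 0.05 eV for presentation | raw histograms for all quantitative totals; a modest Gaussian for figures |
| `normalize` | off in the builder, on in exported spectra | intensities are arbitrary units; unit-maximum is the field's plotting convention |
| band-maximum extraction | 0.01 eV bins, 0.08 eV kernel | see below |

Binning convention: bins are $[e_k, e_{k+1})$ with the last bin closed;
excitations outside the grid are dropped from the raw histogram. With a
positive kernel width each excitation deposits a Gaussian evaluated at bin
centers and scaled by the bin width, so the deposited mass approximates the
f/ΔE weight when the grid comfortably contains the line.

**Band maxima.** `band_maximum()` reports the bin center of the most intense
bin inside a wavelength window, breaking ties toward *longer* wavelength
(the red edge is what matters for the tissue optical window).
`summarize_ensemble()` extracts maxima from a finely binned (0.01 eV),
kernel-smoothed (0.08 eV) spectrum of the single state rather than from the
raw 0.05 eV histogram. The reason is resolution versus noise: the configured
S1 means of the Cl and Br compounds differ by only 0.023 eV, below the
default bin width, while at a few thousand snapshots the raw fine-binned
histogram is too noisy for a stable mode. For a near-Gaussian band a
Gaussian kernel does not displace the mode, so the smoothed fine grid gives
a mode estimator that resolves the Cl/Br gap and is stable at n = 3000.

## The synthetic generator

`generate_ensemble()` emulates the statistical skeleton of a
QM/MM-MD + TD-DFT snapshot stream; it makes no attempt at physical dynamics.
Per snapshot it draws:

- **azo dihedral** — wrapped normal at 180° (sd 8°): a stable *E*
  configuration;
- **phenyl torsions** — each ring independently from a circular mixture of
  wrapped normals. Defaults per substituent: H and F bimodal at 0°/180° with
  equal masses (rings flip between coplanar wells); Cl unimodal at 0°
  (rotation fully hindered); Br at ±150° (mass 0.35 each) and ±30°
  (mass 0.15 each) — staggered wells with unequal areas, reflecting the
  steric bulk. `perpendicular_phenyl_mixture()` gives the ±90° mode of a
  force field that treats the ring C–N bonds as freely rotating σ bonds;
- **MO energies** — normals with means at the series ensemble averages
  (H: −8.357/−1.606; F: −8.376/−1.774; Cl: −7.920/−2.003;
  Br: −7.673/−1.939 eV) and common sd 0.30 eV, redrawn in the (practically
  impossible) event the occupied level lands above the virtual one;
- **ΔE(S1)** — normal at the series means (2.645/2.509/2.114/2.091 eV),
  sd 0.15 eV, truncated positive. ΔE is drawn directly rather than as
  MOf − MOi because the ensemble-average excitation energy is not the
  orbital gap;
- **ΔE(S2)** — normal, sd 0.20 eV, means 3.94/4.25/4.44/4.44 eV (the last
  set equal to Cl), truncated positive;
- **f(S1)** — when `coupling_planarity` is on (default for X = H, the one
  compound whose planar geometry has the symmetry that forbids S1),
  $f = f_{S1,\max}\,\sin^2\theta_\mathrm{dev}$ with $\theta_\mathrm{dev}$
  the mean deviation of the two ring torsions from the nearest planar
  arrangement. $\sin^2$ is the simplest form that vanishes exactly at the
  symmetric geometry and is positive elsewhere. Otherwise f(S1) is a capped
  |normal| around $f_{S1,\max} = 0.05$;
- **f(S2)** — positive-truncated normal around 0.8 (sd 10 %): a generically
  strong ππ\* band.

The distribution widths are synthetic parameters: the reference data for
this series publishes ensemble *means* and figure shapes, not widths. The
S1 width of 0.15 eV makes the band's low-intensity wings span roughly
±80 nm around a 570 nm maximum, consistent with the reported spread, and
keeps S1 and S2 well separated; the MO width of 0.30 eV gives
distributions about 1 eV wide at the base. They were chosen once, on those
grounds.

Each snapshot also gets a toy 6-atom trajectory frame (azo core C–N=N–C plus
one ortho-carbon probe per ring) built by internal-coordinate placement so
that evaluating `toy_dihedral_specs()` on the trajectory reproduces the
stored dihedrals to floating-point accuracy. Snapshot times start at
t = interval (not t = 0), so 10 ns sampled every 10 ps gives exactly 1000
snapshots — `sample_count()` encodes that convention.

What the generator does **not** emulate: solvent coordinates, time
correlation between snapshots, anharmonicity, coupling between the azo and
ring torsions, state crossings, or any dependence of the MO energies on the
instantaneous geometry. Tests that pass on synthetic ensembles therefore
validate the *analysis machinery* — weighting, binning, statistics,
diagnostics — not the physics of any particular compound.

## Orbital analysis

`ao_weight()` implements
$\omega_{\alpha i} = \frac{1}{N_\alpha} \sum_j |c_{ji}|^2 \delta_{j\alpha}$
over real LCAO coefficients. Because the AO basis is non-orthonormal this is
an approximate weight — bounded below by 0 but not above by 1 — and it is
reported exactly as defined, with no Löwdin orthogonalization.
`halide_trend()` uses Pearson correlation: with only three or four
substituents a rank correlation is meaningless, so the correlation
coefficient is descriptive and the *monotonicity flag* carries the
scientific claim. The free-halide sHOMO energies are a fixed three-entry
input table (`halide_shomo_ev`), never computed.

## Geometry analysis

`dihedral()` returns the standard signed torsion in (−180°, 180°]
(anti-periplanar = 180°), positive when, sighting along the central bond,
the far bond is rotated clockwise from the near bond. Degenerate (collinear)
quadruples raise errors rather than returning 0 — a silent zero would
contaminate a torsion distribution at its most meaningful value.
`ez_label()` assigns the |φ| = 90° boundary to *E* (documented tie rule).

Circular histograms use bins *centered* on multiples of the bin width, so
0°, ±90° and 180° — where these torsion distributions actually peak — are
bin centers rather than bin edges; the 180° bin wraps across the branch
point. Modes are local maxima of the circular count sequence above a
configurable prominence (default 10 % of the peak count).

`coplanarity_report()` operationalizes "coplanar" as a torsion within 30° of
0° or 180° (configurable). The perpendicular-artifact flag fires when the
coplanar fraction is below 0.05 *and* the distribution has a mode within 15°
of ±90° — both conditions together are the signature of the free-σ-rotation
force-field failure, and neither alone suffices (a Br-like staggered
ensemble has a sub-unity coplanar fraction but no ±90° mode).

## Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed, and the pipeline
splits one top-level seed into per-substituent streams deterministically, so
identical configurations give byte-identical outputs. The test suite runs
its Monte-Carlo checks at 3000 snapshots per compound — the size at which
the reference ensembles were analyzed and large enough that 3-standard-error
recovery bounds are tight — and smaller sizes (tens to hundreds) everywhere
a structural property rather than a statistical one is under test.

## Known limitations

- The interchange format stores one initiating and one receiving MO energy
  per excitation; multi-configurational excitations have no representation.
- The spectrum builder assumes the grid covers the band; out-of-grid
  excitations are silently dropped from raw histograms (by design, but worth
  knowing when choosing grids).
- PDB input is limited to single-model files, and XYZ parsing expects the
  strict count/comment/atoms layout.
- The artifact detector is tuned to the ±90° failure mode; other force-field
  pathologies (e.g. a wrong *E/Z* balance) surface in the E-fraction column
  instead.
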