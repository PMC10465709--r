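---
title: "Phase-field crystal modeling of collagen fibril self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field crystal modeling of collagen fibril self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilpfc)
```

## The model and its assumptions

`fibrilpfc` treats the sudden appearance of ordered collagen fibril bundles
in embryonic tendon as a crystallization (phase-transition) event rather
than a cell-directed construction process. The assumptions inherited from
that framing are worth stating plainly:

* **Two dimensions.** Fibrils are long parallel rods; the model describes
  the cross-sectional plane only, assuming nematic alignment along the
  tendon axis is enforced by confinement, protomer stiffness and axial
  loading. Axial variation and 3D defect structures are outside the model.
* **Conserved, deterministic dynamics.** Collagen protomer is secreted
  before the simulation window opens; during the window the total amount in
  a closed inter-cellular space is fixed. Randomness enters only through
  the initial condition; the subsequent evolution is a deterministic
  gradient flow. Glassy multiplicity of metastable end states makes a
  statistical reading of any single run essential.
* **Canonical free energy.** No collagen-specific free energy is derived;
  the canonical Swift-Hohenberg-type PFC functional with a single selected
  wavenumber `q*` stands in for all protomer-protomer interactions.

The phase field `phi` lives on a regular grid (`grid_spec()`), with
`phi ~ -1` dense fibril and `phi ~ +1` protomer medium, and concentration
proxy `c = (1 - phi)/2`; `c >= 1/2` defines the fibrillar class everywhere
in the package (ties at exactly 1/2 are counted as fibrillar; they are
measure-zero in practice).

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `r` | destabilization strength (dimensionless) | 0.8 | dense filling of the domain; patterns require `r > 3 phi0^2` |
| `phi0` | mean phase field = initial protomer abundance | 0.4 | with `r = 0.8`, representative of complete filling |
| `qstar` | selected wavenumber (1/length) | 1 (dimensionless runs) | physical runs calibrate `q* = 0.1209`/nm so the hexagonal lattice constant `4*pi/(sqrt(3)*q*)` is 60.0 nm, the observed median fibril spacing |
| `m2` | initial fluctuation variance | 0.01 | small perturbation; equilibrium states are insensitive to it |
| `lam` | initial correlation length (grid units) | 10 | the reported value; equilibria are statistically insensitive to it |
| `dt` | time step | 0.5 | stable and accurate for the stabilized scheme at these parameters |
| `t_end` | final time | 1000 | past the slow-maturation window |
| `stab` | linear stabilization constant | 1.5 | see below |

`lam` is interpreted in grid units because the reported value is a bare
number; `sample_grf(lam_units = "physical")` switches to the units of
`dx`. Time is dimensionless throughout: the physical time scale depends on
an unknown free-energy density and mobility, so only ratios of times are
meaningful.

## Numerical scheme

The conserved dynamics `dphi/dt = div(M grad mu)` are integrated
pseudospectrally. The linear operator is diagonal in Fourier space with
symbol `(q*^2 - k^2)^2 - r`; the cubic term is explicit. Two choices
deserve explanation:

* **Linear stabilization.** The plain semi-implicit splitting is not
  energy-stable at `dt = 0.5`: in test runs the discrete free energy fell
  to a spurious minimum during pattern formation and then *rose* by more
  than 10% of its total range, and the end states were far from
  equilibrium. Moving a term `stab * phi` into the implicit operator (and
  subtracting it from the explicit part) restores monotone energy decay at
  `dt = 0.5` with no change to the continuum equation. `stab = 1.5` is
  roughly `3 * max(phi)^2 / 2` over the working range of states; all
  energy-monotonicity tests run at this default.
* **Smoothed-boundary masked domains.** Irregular inter-cellular spaces are
  handled with a variable mobility `M = psi`, where `psi` is a tanh profile
  (half-width 2 px) of the signed distance to the mask boundary, clamped to
  exactly 0/1 outside the interface band. This form is dissipative by
  construction (`dF/dt = -int psi |grad mu|^2`), conserves total mass
  exactly in the spectral discretization, and freezes the exterior. A
  simpler alternative - relaxing the field toward `phi0` outside the mask
  each step - was implemented first and rejected: it acts as an infinite
  protomer reservoir, drifting the in-mask mean by several percent over a
  run and pumping free energy through the boundary. A small residual
  exchange across the interface band remains with the mobility form, so
  each step ends with a uniform in-mask correction that pins the in-mask
  mass exactly (a projection onto the closed-domain constraint; the
  corrected residual is of order 1e-5 per step).

The stability precondition `1 + dt k^2 ((q*^2-k^2)^2 - r + stab) > 0` is
checked before integration; a field that loses finiteness aborts with the
failing time attached. Blow-up checks run every 50 steps to keep the hot
loop at two FFTs per periodic step.

Resolution: `q* dx` of about 0.7-1.2 (at least ~6 grid points per pattern
wavelength). The physical calibration enters only through
`pfc_calibration()`: simulations run with `q* = 1` in dimensionless units
and one length unit equals `1/q*` nm.

## Observables

`free_energy()` integrates the energy density (psi-weighted on masked
domains); `protomer_availability()` integrates `c` over the in-mask region
with `c < 1/2` (an estimate of free protomer); `crystallized_fraction()`
is the in-mask area fraction with `c >= 1/2`. Availability plus the
complementary fibril-region integral equals the total `c` integral by
construction, and the identity is tested. Two characteristic times
summarize a run (`characteristic_times()`): the time at which availability
completes 90% of its total decline (pattern formation; ~45-60 in study
runs) and the time at which free energy completes 99% of its decline
(maturation; ~800 in study runs) - the two-timescale structure of rapid
crystallization followed by slow defect annealing.

## Defect analysis

Fibril centers are concentration-weighted centroids of connected
`c >= 1/2` components. Components are labeled on the full grid - the
exterior of a masked domain is frozen below threshold, and clipping with
the binary mask would cut boundary-row fibrils into fragments - and
centroids beyond the smoothed boundary are dropped. `min_area` (default: a
quarter of the area of a disk of radius one quarter of the one-mode
spacing) suppresses sub-fibril debris. An independent local-maxima
detector is kept as a cross-check; the two agree to within ~1% on
equilibrium states.

The Delaunay triangulation (via `deldir`) is pruned at
`prune_factor * median(edge length)`. The default is **1.8**, not 2: a
clipped lattice's flat boundary runs produce chords that skip one point
and measure exactly twice the median edge, so a 2x cutoff lands on a
knife-edge tie. 1.8 sits safely between genuine edges (below ~1.3x the
median even for strongly jittered packings) and those 2x chords, while the
sqrt(3) ~ 1.732x rim diagonals of a vacancy hole remain just inside the
cutoff, preserving the classic 5/7 vacancy signature.
Periphery is parameter-free: a fibril is peripheral iff it touches an edge
bounding at most one surviving triangle. The defect proportion `d` counts
interior fibrils whose neighbor count differs from six.

Degenerate (cocircular) configurations are resolved by the triangulation
library's deterministic tie-break; the synthetic lattice generator
therefore always applies a 1e-4 nm seeded jitter, which is far below any
physical scale but breaks exact cocircularity robustly for both the
production pipeline and the exhaustive oracle.

## Synthetic data: what it emulates and what it does not

The generators replace the study's raw electron micrographs and mass
spectrometry data so that every stage is testable offline:

* **Domain masks** (`gen_domain_mask()`): star-convex blobs with a seeded
  random Fourier perturbation of the boundary radius. They reproduce the
  size and lobed outline of inter-cellular spaces (default 881 nm across,
  roughness 0.15, 8 angular modes) but not concave, branched or
  multi-lobed spaces, nor the pixel noise of segmented micrographs.
* **Planted lattices** (`gen_hex_lattice()`, `plant_defects()`): jittered
  triangular lattices with known vacancies, interstitials and voids. The
  patch is a parallelogram spanned by the lattice vectors, so clipping
  introduces no artificial under-coordinated "interior" points. Ground
  truth comes from an exhaustive empty-circumcircle triangulation (the
  incircle determinant predicate, robust to the near-collinear boundary
  triples whose circumcircles are enormous), computed at generation time
  and entirely independent of the `deldir` pipeline it later validates.
* **Abundance tables** (`gen_abundance_table()`): five fixed time points,
  three trend families (peak-at-E13.5 with relative profile 1,2,4,2,1;
  monotone doubling; flat), multiplicative log-normal noise (positive
  support, like MS intensities) and independent Bernoulli missingness.
  Real LCM-MS data add structured missingness (intensity-dependent),
  between-animal variance and shared normalization errors that the
  generator does not emulate - passing recovery tests here demonstrates
  the correctness of the filtering/normalization logic, not robustness to
  those effects.

## Proteomics stage

The post-processing is deliberately minimal, mirroring the figure
pipeline it reproduces: complete-case filtering across the five time
points (no imputation), log2 fold change against E12.5, and per-protein
argmax peak calling with ties broken toward the earliest time point (so a
flat trajectory "peaks" at E12.5). No significance testing is performed;
the statistical test behind the published significance claims is not part
of this package's scope. Matrisome category annotation is read from a
user-supplied two-column CSV rather than bundling a versioned external
database.

## Problem sizes and reproducibility

Study-scale runs use a 128x128 grid (10 nm pixels, 881-nm domain),
`dt = 0.5` to `t = 1000`, about ten seconds each on one CPU; the test
suite uses 32-96 px grids and shorter horizons for properties that do not
need full equilibrium. Every stochastic stage takes an explicit integer
seed, expanded per stage/cell through a small deterministic hash
(`run_sweep()` documents the scheme), so sweeps are reproducible cell by
cell and the end-to-end pipeline is byte-reproducible (tested on the CSV
outputs). Pipeline output directories include a provenance YAML with the
package version, global seed, stage seeds and all parameters.

## Known limitations

* The defect proportion of simulated equilibria (~0.14-0.24) is reported
  as-is; micrograph-derived patterns are typically more disordered, and no
  attempt is made to tune the model toward them.
* Simulated fibril patterns on small domains retain a few percent of
  lattice strain (median spacing ~2-4% above the one-mode value) - a real
  feature of confined, boundary-nucleated patterns under conserved mass,
  not a solver artifact (periodic equilibria match the one-mode constant
  to ~2%).
* The smoothed-boundary method needs ~2 px of exterior clearance; masks
  touching the grid border are rejected.
* `reference_triangulation()` is an oracle, not a tool: exhaustive and
  limited to 250 points.
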