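# fibrilpfc

Collagen fibrils appear in the inter-cellular spaces of embryonic mouse
tendon within a single day (between embryonic days E13.5 and E14.5), already
arranged as near-hexagonal bundles of ~60 nm circles in cross-section. That
speed and order are hard to reconcile with purely cell-directed assembly.
`fibrilpfc` implements a phase-transition account of this event: protomeric
collagen secreted into the inter-cellular space crystallizes into a fibril
lattice, modeled with a conserved **phase-field crystal (PFC)** equation
solved on the irregular 2D domains formed by the inter-cellular spaces. The
package is aimed at quantitative biologists and modelers who want to
simulate the process, quantify lattice defects in either simulated or
micrograph-derived fibril positions, and post-process developmental protein
abundance time series.

## Model

A scalar phase field `phi(x, t)` in `[-1, 1]` distinguishes dense fibrillar
collagen (`phi ~ -1`) from protomer-rich medium (`phi ~ +1`);
`c = (1 - phi)/2` serves as a concentration proxy. The dynamics are the
conserved gradient flow

    dphi/dt = div( M(x) grad mu ),      mu = [ (q*^2 + lap)^2 - r ] phi + phi^3

of the free energy

    F[phi] = integral{ 1/2 phi [ (q*^2 + lap)^2 - r ] phi + 1/4 phi^4 } dx,

where `r` is the destabilizing strength (patterns grow from a uniform state
`phi0` when `r > 3 phi0^2`), `phi0` the mean phase field (initial collagen
abundance), and `q*` the selected wavenumber; the one-mode hexagonal
lattice constant is `4 pi / (sqrt(3) q*)`, so `q* = 0.1209 /nm` places the
fibril spacing at 60.0 nm. The solver is a linearly stabilized,
semi-implicit pseudospectral scheme; irregular domains enter through a
smoothed-boundary mobility `M = psi` built from the domain mask, which
makes the boundary impermeable and dissipation exact. Initial conditions
are seeded Gaussian random fields with mean `phi0`, variance `m2`, and
correlation length `lam`.

Downstream analysis mirrors the standard defect pipeline for crystalline
packings: fibril centers are detected as centroids of connected `c >= 1/2`
components, Delaunay-triangulated (long edges pruned), peripheral fibrils
excluded, and each interior fibril labeled by its neighbor count (5 and 7 =
disclinations). The defect proportion `d` is the fraction of interior
fibrils without six neighbors. A proteomics stage reproduces the abundance
post-processing used with laser-capture time series: complete-case
filtering across E12.5 ... E14.5, log2 fold change against E12.5, and
per-protein peak calling.

## Worked example

Simulate one seeded synthetic inter-cellular space (881 nm across, 10 nm
pixels) at the dense-filling parameters `r = 0.8`, `phi0 = 0.4`, `lam = 10`
to `t = 1000`, then detect and analyze the fibril pattern:

```r
library(fibrilpfc)

res <- fibril_pipeline(seed = 1)
res$report
#> <defect_report> 213 fibrils (169 interior), d = 0.142, median edge 61.31 nm

characteristic_times(res$trajectory)
#> # A tibble: 1 x 2
#>   formation_time maturation_time
#>            <dbl>           <dbl>
#> 1             45             875
```

The detected lattice has a median interior fibril spacing of 61.3 nm
(matching the ~60 nm spacing of embryonic tendon cross-sections and the
`q*` calibration), a sharp six-neighbor mode, and a defect proportion of
0.14 carried by 5/7 disclinations. Protomer availability completes 90% of
its decline by `t ~ 45` (fast formation), while the free energy needs until
`t ~ 875` to complete 99% of its decline (slow maturation) - the
two-timescale picture of rapid crystallization followed by gradual defect
annealing. `autoplot(res$trajectory)`, `autoplot(res$trajectory$final,
res$mask)` and `autoplot(res$report)` draw the observable series, the phase
field, and the Voronoi defect map (5 red / 7 blue / 6 clear).

The proteomics stage works on plain tibbles:

```r
tab <- gen_abundance_table(6, trend = "peak", noise_cv = 0.2,
                           missing_rate = 0.1, seed = 2)
fc <- log2_fold_change(filter_complete(tab))
peak_timepoint(fc)
#> # A tibble: 3 x 3
#>   protein trend peak
#>   <chr>   <chr> <fct>
#> 1 P0003   peak  E13.5
#> 2 P0004   peak  E13.5
#> 3 P0006   peak  E13.5
```

Proteins with any missing time point are dropped (here 3 of 6), fold
changes are zero at E12.5 by construction, and planted E13.5 peaks are
recovered.

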