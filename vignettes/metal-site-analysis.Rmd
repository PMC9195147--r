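---
title: "Quantifying protein-metal binding from X-ray absorption and CD melting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-metal binding from X-ray absorption and CD melting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xasmelt)
```

## The problem

When a divalent metal ion such as Co^2+^ is titrated into a protein
solution, three questions decide whether a proposed binding site is real
and functionally meaningful:

1. **How much of the metal actually binds?** The X-ray absorption
   near-edge structure (XANES) of a sample is, to good approximation, a
   concentration-weighted sum of the spectra of the species present. If
   reference spectra of the fully bound complex and of the free aquo ion
   are available, the bound fraction follows from a two-component
   linear-combination fit (LCF).
2. **What does the first coordination shell look like?** The extended
   fine structure (EXAFS) above the edge encodes the distances and
   numbers of the atoms surrounding the absorber. Fitting a
   single-scattering shell model to the extracted oscillation
   $\chi(k)$ refines those distances to hundredths of an Angstrom.
3. **What does binding do to the protein?** Thermal stability, monitored
   by circular dichroism at 222 nm, shifts when a metal binds: the
   melting temperature $T_m$, read from the first derivative of
   $\Theta_{222}(T)$, moves up for stabilizing and down for
   destabilizing interactions.

`xasmelt` implements all three analyses behind one consistent set of data
types, together with a synthetic-data module that generates every input
with known ground truth. Beamline spectra and spectropolarimeter scans of
this kind are rarely deposited, so the package's correctness argument is
parameter recovery: generate data from known parameters under realistic
conditions, run the full analysis, and require that the generating values
come back within stated tolerances.

## XANES: normalization, pre-edge, linear-combination fitting

Raw spectra arrive as $\mu(E)$ in arbitrary units. `normalize_xanes()`
applies the standard edge-step procedure: a straight line fitted on a
pre-edge range (default $[E_0-150, E_0-30]$ eV) is subtracted everywhere,
a quadratic fitted on a post-edge range (default $[E_0+50, E_0+300]$ eV)
defines the edge step at $E_0$, and the spectrum is divided by the step
and flattened above the edge. The edge energy $E_0$ itself is the maximum
of the first derivative, refined by quadratic interpolation
(`edge_energy()`). Normalization makes spectra recorded on different
scales directly comparable, which is what lets mixing fractions survive
the round trip through it: `lcf()` recovers a noiseless synthetic mixing
fraction to well under 0.005 across the whole $[0,1]$ range.

The LCF model is deliberately the two-component constrained form
$\mu_t = f\,\mu_A + (1-f)\,\mu_B$: with the complementary-fraction
constraint the least-squares optimum has the closed form
$f^* = \sum(t-b)(a-b) / \sum(a-b)^2$, clipped to $[0,1]$. The fit window
(default $[E_0-20, E_0+80]$ eV) and the normalization ranges are exposed
as arguments because neither is a settled convention; the defaults follow
common XAS practice. The test suite checks the closed form against an
exhaustive grid search at $10^{-4}$ resolution on randomized noisy
instances.

Octahedral first-row transition-metal sites show a weak $1s \to 3d$
pre-edge feature. `pre_edge_peak()` fits the pre-edge window
($[E_0-25, E_0-2]$ eV) with the standard model -- Gaussian peak on a
straight line plus an arctangent edge onset. The explicit edge term
matters: with only a linear base, the rising tail of the main edge
systematically biases both the fitted center and height. A candidate
center must first exist as an interior local maximum of the straight-line
residual; the monotone edge tail can never produce one, so a spectrum
without a genuine feature is reported as such rather than fitted to the
edge. Detection requires the fitted height to exceed three times the fit
residual standard deviation.

## EXAFS: background removal, forward model, constrained refinement

The fine structure is defined by $\mu(E) = b(E)\,[1 + \chi(k)]$ above the
edge, with $k = \sqrt{c\,(E - E_0)}$ and $c = 2m_e/\hbar^2 = 0.262468$
eV$^{-1}$Å$^{-2}$. `extract_chi()` determines the smooth atomic
background $b$ as a cubic B-spline in $k$ whose coefficient count,
$\lfloor 2\,\Delta k\, r_{bkg}/\pi \rfloor + 1$, caps its information
content at distances below `rbkg` (default 1.0 Å). The coefficients are
found by linear least squares on the magnitude of the Fourier transform
of the $k$-weighted residual below `rbkg`: the background can absorb
anything slow enough to look like spectral weight below 1 Å, and nothing
else. Two consequences are documented limits rather than defects:

* components of $\mu$ outside the spline's span -- the edge transition
  itself and the normalization flattening, both confined to low $k$ --
  leave residuals of order $10^{-3}$ at $k < 3$ Å$^{-1}$, which is why
  the default fitting window starts at $k = 3$;
* a first shell near 1.8 Å has genuine spectral weight whose tail
  reaches below `rbkg`, so a small part of it is absorbed into the
  background. Across randomized one-to-three-shell models the
  generate-extract-refine round trip returns radii typically within
  0.01 Å and never worse than 0.03 Å in our sweeps; refinement against a
  signal that has not passed through background removal recovers radii
  essentially exactly.

`forward_chi()` evaluates the standard plane-wave single-scattering
EXAFS equation
$$\chi(k) = S_0^2 \sum_i \frac{N_i\,f_i(k')}{k' R_i^2}
  \, e^{-2k'^2\sigma_i^2}\, e^{-2R_i/\lambda(k')}
  \sin\!\big(2k'R_i + \phi_i(k')\big),
  \qquad k' = \sqrt{k^2 + c\,\Delta E_F},$$
where $N_i$, $R_i$ and $\sigma_i^2$ are the coordination number, distance
and Debye-Waller factor of shell $i$, $S_0^2$ the many-body amplitude
reduction, and $\Delta E_F$ the Fermi-energy shift that re-references the
photoelectron energy zero. The oxygen scattering ingredients default to a
smooth phenomenological table ($f(k) = 0.90\,e^{-0.15k}$,
$\phi(k) = \pi - 0.90k$, $\lambda(k) = 4 + 0.8k$) used by both the
generator and the fitter. This self-consistency is a design decision:
absolute phase shifts live inside ab-initio codes and are not the
package's contribution; what is tested and guaranteed is parameter
recovery under a shared table, and measured or computed tables can be
substituted as four-column text (`read_scatter_table()`).

`refine_site()` performs bounded Levenberg-Marquardt least squares on the
$k$-weighted misfit (default $k \in [3, 12]$ Å$^{-1}$, $k$-weight 2,
cost tolerance $10^{-10}$, single start for determinism). Only the
Fermi shift and shell radii are refined by default; coordination numbers
and $\sigma^2$ (default 0.003 Å$^2$) stay fixed, mirroring the practice
of refining distances only when data quality does not support more. The
rigid-body idea -- a chelating residue moves as a unit -- is realized in
its minimal distance-only form: shells sharing a rigid-group label share
a single radial offset, one parameter per group. Box constraints keep
every shell inside its validity bounds ($R \in (1,6)$ Å,
$|\Delta E_F| \le 15$ eV). Fit quality is reported as the misfit
R-factor, $100\sum|k^w\chi_{obs} - k^w\chi_{mod}| / \sum|k^w\chi_{obs}|$.

Site geometries enter as PDB files (`read_site_pdb()`), are cut down to
the physically relevant cluster with `excise_sphere()` (closed boundary,
default 5 Å -- the range XAS is actually sensitive to), and grouped into
shells with `group_shells()`: distances sorted ascending and clustered
greedily, starting a new shell when the next distance exceeds the running
shell mean by more than `tol` (default 0.1 Å). Rigid-group labels are
carried from residue identity when a shell comes from a single residue.

## Melting curves: two-state model and derivative read-out

The generator (`make_melting_curve()`) sums one or two two-state van't
Hoff transitions with $\Delta C_p = 0$:
$$\Theta(T) = \sum_j a_j \big[\theta_{N,j}(T) +
  (\theta_{U,j}(T) - \theta_{N,j}(T))\, f_{U,j}(T)\big], \qquad
  f_U = \frac{K}{1+K}, \quad
  K = e^{-\frac{\Delta H}{R}\left(\frac1T - \frac1{T_m}\right)},$$
with temperatures in kelvin. The equilibrium (reversible, no-hysteresis)
treatment is appropriate for scans whose heating and cooling branches
coincide; `check_reversibility()` makes that check explicit. Default
baselines are flat at $-20000$ and $-2000$ deg cm$^2$ dmol$^{-1}$,
typical 222 nm values for a folded helical protein and its unfolded
state.

`extract_tms()` reads $T_m$ from the first derivative: Savitzky-Golay
smoothing (order 3, default window 11 points = 5.5 °C at the standard
0.5 °C sampling), central differences, then local maxima of
$|d\Theta/dT|$ filtered by prominence (default 5% of the global
maximum). Working on the absolute derivative makes the result invariant
to the sign convention and to affine rescaling of the ellipticity. At
most two peaks are returned, ranked by prominence with ties resolved
toward lower temperature.

How to read two *overlapping* transitions is genuinely open: the raw
local maxima of a sum of two two-state derivatives sit measurably closer
together than the generating midpoints (for equal-amplitude transitions
8 °C apart with $\Delta H = 400$ kJ/mol, by about 0.6 °C on the upper
peak). The package resolves this by refining peak positions with a joint
fit of the derivative as a sum of sech$^2$-shaped components on a linear
base -- sech$^2$ being the exact shape of a single two-state derivative
in the van't Hoff variable -- and falls back to the plain interpolated
maxima if that fit fails or wanders by more than 2.5 °C. With this
refinement, noiseless flat-baseline melts return generating midpoints to
within half a grid step for single transitions across 40-80 °C and for
double transitions down to 8 °C spacing.

The smoothing window must stay below the inter-peak spacing; 11 points
leaves margin for the closest two-step case considered (8 °C). The
window, polynomial order and prominence threshold are all arguments.

## The synthetic-data module

`make_reference_xanes()` builds near-edge references from an arctangent
unit edge step plus Gaussian features (pre-edge and post-edge); the
arctangent rather than error-function edge is a documented convention
choice. `make_exafs_spectrum()` inverts the extraction model: a natural
cubic spline through stated control points carries the forward-model
oscillation multiplicatively above the edge; the oscillation is ramped in
below $k = 1$ Å$^{-1}$ where the EXAFS equation is singular.
`make_site_geometry()` places ligands on octahedral axes in the fixed
order $+x, -x, +y, -y, +z, -z$, filling shells by descending coordination
number, so geometry fixtures are bit-reproducible.

What the generators emulate: edge position and shape, the 1s→3d
pre-edge, species mixing, smooth atomic backgrounds with embedded
single-scattering fine structure, one- and two-step equilibrium melts,
and additive Gaussian noise (default sd 0.002 in normalized absorption
units -- a deliberate, realistic choice, as source papers rarely state
spectral noise levels -- and 0 for recovery runs). What they do not
emulate: instrument response and monochromator glitches, multiple
scattering, thermal/structural disorder beyond the Debye-Waller factor,
correlated noise, aggregation artifacts in melts, and $\Delta C_p \ne 0$
baselines. Passing recovery tests therefore demonstrates correctness of
the analysis chain, not robustness to every pathology of real beamline
data.

All generators are pure functions of (parameters, seed): they restore
the session RNG state, and the same seed always reproduces the same
output.

## The pipeline

`run_pipeline()` executes melt → XANES-LCF → EXAFS stages from a single
YAML configuration with one global seed, joins the per-sample outputs
into `stability_record`s, and writes a TSV report plus a provenance
block (package version, seed, full configuration echo). Reruns are
byte-identical. `rank_stability()` orders samples by first melting
temperature, breaking ties by Tm shift (less destabilized first) and
then name. The bundled demo configuration
(`system.file("extdata", "demo_config.yaml", package = "xasmelt")`)
regenerates the full synthetic study: two wild-type fragment lengths and
three destabilizing variants, with and without metal, including both
two-step melts and the partially bound long-fragment sample whose XANES
is 43% bound complex and 57% free ion. Variant samples follow the
report-table naming convention (`D104G_90_*` etc.) even though sample
tables sometimes list variants under the other fragment column; the
demo keeps the report-table names and notes the inconsistency here.

Thin command-line wrappers over these functions are installed under
`system.file("scripts", package = "xasmelt")` (`simulate.R`,
`xanes_lcf.R`, `exafs_fit.R`, `melt.R`, `pipeline.R`); logs go to stderr,
numeric outputs to files.

## Numerical choices and degenerate inputs

* Duplicated abscissae in XY files are averaged, not rejected
  (multi-scan merges produce them); rows are sorted; files below 16
  points are refused.
* LCF refuses component pairs whose difference has squared norm below
  $10^{-12}$ (indistinguishable references).
* `r_factor()` normalizes by the observed signal and refuses an all-zero
  observation; identical signals give exactly 0, a zero model exactly
  100.
* `refine_site()` reports a convergence flag from the optimizer status
  and never returns a model outside the shell bounds.
* Problem sizes used throughout the tests: energy grids of 500-1000
  points at 0.5-1 eV, k-grids of ~260 points at 0.05 Å$^{-1}$, melt
  scans of 151 points, 10-25 randomized instances per property sweep.
  The full suite runs in seconds on one core.

## Known limitations

* Two-component LCF only; more species would need a constrained
  multi-component solver.
* Single-scattering EXAFS with one absorber; no multiple-scattering
  paths, no Fourier-domain fitting, no coordination-number refinement.
* The default scatter table is phenomenological; absolute distances from
  real beamline data require tables from an ab-initio code.
* Melting analysis extracts midpoints only; it does not fit
  $\Delta H$ or $\Delta C_p$ to data (the generator's $\Delta H$ is a
  simulation input, not an estimate).
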