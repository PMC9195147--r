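# xasmelt

Quantitative analysis of divalent-metal binding to proteins from two
complementary experiments: Co K-edge X-ray absorption spectroscopy
(XANES + EXAFS) and circular-dichroism thermal denaturation. The package
is aimed at structural-biology and bio-XAS practitioners who need a
scripted, reproducible version of a workflow usually spread across
beamline GUIs: bound-fraction quantification, first-shell geometry
refinement, and melting-temperature extraction, joined into one stability
report.

## What it computes

**Bound vs. free metal (XANES LCF).** After Athena-style edge-step
normalization, a sample spectrum is decomposed as
`mu_t = f mu_bound + (1-f) mu_free` by constrained least squares; the
closed-form optimum `f* = sum((t-b)(a-b)) / sum((a-b)^2)` (clipped to
[0, 1]) gives the bound fraction, with the residual and difference
spectrum for diagnostics. A Gaussian-plus-edge model quantifies the
weak 1s→3d pre-edge feature that fingerprints octahedral coordination.

**First-shell geometry (EXAFS).** The fine structure is extracted by
AUTOBK-style spline background removal and fitted with the standard
single-scattering equation

    chi(k) = S0^2 * sum_i  N_i f_i(k') / (k' R_i^2)
             * exp(-2 k'^2 sigma_i^2) * exp(-2 R_i / lambda(k'))
             * sin(2 k' R_i + phi_i(k')),      k' = sqrt(k^2 + c dE_F)

refining shell distances `R_i` and the Fermi-energy shift `dE_F` under
rigid-group constraints (shells of one residue share a radial offset),
with bounded Levenberg-Marquardt and an R-factor misfit metric. Site
geometries come from PDB files, cut to a sphere around the absorber and
grouped into shells by distance clustering.

**Thermal stability (CD melts).** Melting temperatures are read from the
first derivative of the 222 nm ellipticity: Savitzky-Golay smoothing,
prominence-filtered derivative maxima (at most two, for two-step
unfolding), and sech^2 component refinement that keeps closely spaced
transitions from reading too close together. Tm shifts against a
metal-free partner quantify (de)stabilization; a reversibility check
compares heating and cooling branches.

A synthetic-data module generates all inputs with known ground truth —
reference XANES profiles, mixtures, mu(E) with embedded EXAFS riding on a
spline background, octahedral site fixtures, and one- or two-transition
van't Hoff melts — so every analysis above is validated by parameter
recovery. A YAML-configured pipeline (`run_pipeline()`) runs the stages
end to end, byte-reproducibly under a fixed seed.

## Worked example

```r
library(xasmelt)

## 1. how much metal is bound? ------------------------------------------
grid <- seq(7500, 8050, by = 0.5)
bound  <- make_reference_xanes(reference_profile(
  e0 = 7720, width = 1.5,
  pre_edge = list(center = 7710, height = 0.05, width = 1.5),
  features = list(list(center = 7728, height = 0.40, width = 4))), grid)
buffer <- make_reference_xanes(reference_profile(
  e0 = 7721, width = 1.8,
  features = list(list(center = 7727, height = 0.55, width = 3.5))), grid)
sample <- make_mixture(list(bound, buffer), c(0.43, 0.57),
                       noise_sd = 0, seed = 42)
lcf(normalize_xanes(sample), normalize_xanes(bound), normalize_xanes(buffer))
#> <lcf_result> bound = 0.431, free = 0.569, RMS residual = 1.503e-05 over [7701, 7801] eV

## 2. what does binding do to stability? --------------------------------
scan_free  <- make_melting_curve(list(transition_model(66, 300)), seed = 1)
scan_metal <- make_melting_curve(list(transition_model(60, 300)), seed = 2)
res <- extract_tms(scan_metal)
res
#> <melting_result> 59.95 degC
delta_tm(res, extract_tms(scan_free))
#> [1] -5.996347   # destabilization on metal binding, degC

## 3. what does the site look like? -------------------------------------
site  <- make_site_geometry(list(c(4, 2.02), c(1, 2.21), c(1, 1.85)))
truth <- group_shells(excise_sphere(site, "Co", 5), "Co", e0 = 7709, ef = 3)
obs   <- forward_chi(truth, default_scatter_table(), seq(1, 14, by = 0.05))
start <- truth; start$ef <- 0
for (i in seq_along(start$shells))
  start$shells[[i]]$r <- start$shells[[i]]$r + 0.10
refine_site(obs, start)
#> <exafs_fit> R-factor = 0.000% over k = [3, 12] 1/A (k-weight 2)
#> <metal_site_model> Co edge at 7709.0 eV, dE_F = 3.00 eV, S0^2 = 0.90
#>   shell 1 [LG34]: 1 O at R = 1.850 A, sigma2 = 0.0030 A^2
#>   shell 2 [LG12]: 4 O at R = 2.020 A, sigma2 = 0.0030 A^2
#>   shell 3 [LG23]: 1 O at R = 2.210 A, sigma2 = 0.0030 A^2
```

The LCF returns the mixing fraction used to build the sample (43% bound);
the melt analysis reads a 60 degC midpoint and a -6 degC shift against
the metal-free scan; the EXAFS refinement, started 0.10 A and 3 eV away
from the generating site, recovers all three shell distances and the
Fermi shift of the octahedral Co-O model.

The bundled demo configuration runs the whole study in one call:

```r
rep <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "xasmelt"),
                    out_dir = "demo_out")
rank_stability(Filter(function(r) r$equivalents != "none", rep$records))
```

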