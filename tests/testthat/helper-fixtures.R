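# Shared fixture builders. Everything is generated in code; no binary data.

co_edge <- 7709    # Co K-edge, eV
xanes_edge <- 7720 # edge position used for the reference-profile fixtures

# the refined octahedral Co-O site: 4 O at 2.02 A, 1 O at 2.21 A (carboxylate
# partner), 1 O at 1.85 A (water), Fermi shift +3 eV
table4_shells <- list(c(4, 2.02), c(1, 2.21), c(1, 1.85))
table4_model <- function(ef = 3) {
  metal_site_model(list(scattering_shell(4, 2.02),
                        scattering_shell(1, 2.21),
                        scattering_shell(1, 1.85)),
                   e0 = co_edge, ef = ef)
}

ref_grid <- function() seq(xanes_edge - 220, xanes_edge + 330, by = 0.5)

bound_profile <- function() {
  reference_profile(
    e0 = xanes_edge, width = 1.5,
    pre_edge = list(center = 7710, height = 0.05, width = 1.5),
    features = list(list(center = xanes_edge + 8, height = 0.40, width = 4),
                    list(center = xanes_edge + 25, height = 0.10, width = 8)))
}

buffer_profile <- function() {
  reference_profile(
    e0 = xanes_edge + 1, width = 1.8,
    features = list(list(center = xanes_edge + 7, height = 0.55, width = 3.5),
                    list(center = xanes_edge + 31, height = 0.05, width = 10)))
}

exafs_grid <- function() seq(co_edge - 259, co_edge + 691, by = 1)

# mu(E) whose post-edge background is a gentle polynomial in k (well inside
# the extraction spline's span), with the edge transition confined to k < 1
smooth_k_spectrum <- function(e0 = co_edge) {
  g <- exafs_grid()
  kk <- sqrt(pmax(0.262468 * (g - e0), 0))
  pre <- 0.10 + 1e-4 * (g - e0)
  post <- 1 - 0.015 * kk + 8e-4 * kk^2
  w <- 0.5 + atan((g - e0) / 2) / pi
  xas_spectrum(g, pre * (1 - w) + post * w, "smooth-k background")
}

flat_melt_transition <- function(tm, dh = 300, amplitude = 1) {
  transition_model(tm, dh, amplitude,
                   native = c(-20000, 0), unfolded = c(-2000, 0))
}
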