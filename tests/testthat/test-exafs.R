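test_that("forward_chi is zero without shells and linear in N and S0^2", {
  tab <- default_scatter_table()
  kg <- seq(2, 13, by = 0.05)
  m0 <- metal_site_model(list(), e0 = co_edge)
  expect_equal(forward_chi(m0, tab, kg)$chi, rep(0, length(kg)))
  m1 <- metal_site_model(scattering_shell(1, 2.02), e0 = co_edge)
  m2 <- metal_site_model(scattering_shell(2, 2.02), e0 = co_edge)
  expect_equal(forward_chi(m2, tab, kg)$chi, 2 * forward_chi(m1, tab, kg)$chi,
               tolerance = 1e-12)
  mA <- metal_site_model(scattering_shell(1, 2.02), e0 = co_edge, s02 = 0.55)
  mB <- metal_site_model(scattering_shell(1, 2.02), e0 = co_edge, s02 = 1.1)
  expect_equal(forward_chi(mB, tab, kg)$chi, 2 * forward_chi(mA, tab, kg)$chi,
               tolerance = 1e-12)
})

test_that("increasing the Debye-Waller factor never increases |chi|", {
  tab <- default_scatter_table()
  kg <- seq(2, 13, by = 0.1)
  mlo <- metal_site_model(scattering_shell(4, 2.02, sigma2 = 0.002),
                          e0 = co_edge)
  mhi <- metal_site_model(scattering_shell(4, 2.02, sigma2 = 0.004),
                          e0 = co_edge)
  expect_true(all(abs(forward_chi(mhi, tab, kg)$chi) <=
                    abs(forward_chi(mlo, tab, kg)$chi) + 1e-15))
})

test_that("forward_chi zero crossings solve the sine-argument equation", {
  # with phase pi - 0.9 k the argument is 2kR + pi - 0.9k = m*pi, so the
  # positive crossings sit at k = (m - 1) * pi / (2R - 0.9)
  R <- 2.02
  tab <- default_scatter_table()
  kg <- seq(1, 13, by = 0.002)
  chi <- forward_chi(metal_site_model(scattering_shell(1, R), e0 = co_edge),
                     tab, kg)$chi
  sgn <- which(diff(sign(chi)) != 0)
  crossings <- vapply(sgn, function(i)
    uniroot(function(k) forward_chi(
      metal_site_model(scattering_shell(1, R), e0 = co_edge), tab,
      c(k, k + 20))$chi[1],
      lower = kg[i], upper = kg[i + 1], tol = 1e-12)$root,
    numeric(1))
  m <- round(crossings * (2 * R - 0.9) / pi) + 1
  expected <- (m - 1) * pi / (2 * R - 0.9)
  expect_equal(crossings, expected, tolerance = 1e-6)
})

test_that("the Fermi shift re-references the wavenumber and guards k'", {
  tab <- default_scatter_table()
  m <- metal_site_model(scattering_shell(1, 2.0), e0 = co_edge, ef = -15)
  expect_error(forward_chi(m, tab, seq(0.5, 10, by = 0.1)), "imaginary")
  # positive shift: chi(k) equals the unshifted chi evaluated at k'
  mp <- metal_site_model(scattering_shell(1, 2.0), e0 = co_edge, ef = 5)
  m0 <- metal_site_model(scattering_shell(1, 2.0), e0 = co_edge, ef = 0)
  kg <- seq(3, 10, by = 0.5)
  kp <- sqrt(kg^2 + 0.262468 * 5)
  expect_equal(forward_chi(mp, tab, kg)$chi, forward_chi(m0, tab, kp)$chi,
               tolerance = 1e-12)
})

test_that("sphere excision uses a closed boundary around a unique absorber", {
  at <- atom_records(c("Co", "O", "O", "N"),
                     x = c(0, 5.0, 5.1, 1.0), y = 0, z = 0,
                     resname = c("ION", "HOH", "HOH", "GLY"))
  kept <- excise_sphere(at, "Co", 5.0)
  expect_equal(nrow(kept), 3)           # 5.1 excluded, 5.0 kept
  expect_false(5.1 %in% kept$x)
  solo <- excise_sphere(at, "Co", 0)
  expect_equal(nrow(solo), 1)
  expect_equal(solo$elem, "Co")
  at2 <- atom_records(c("Co", "Co"), x = c(0, 3), y = 0, z = 0)
  expect_error(excise_sphere(at2, "Co", 5), "exactly one")
})

test_that("the octahedral fixture keeps exactly its six oxygens within 2.5 A", {
  site <- make_site_geometry(table4_shells)
  kept <- excise_sphere(site, "Co", 2.5)
  expect_equal(sum(kept$elem == "O"), 6)
})

test_that("greedy shell grouping reproduces the refined site multiset", {
  site <- make_site_geometry(table4_shells)
  m <- group_shells(site, "Co", tol = 0.1, e0 = co_edge)
  ns <- vapply(m$shells, `[[`, integer(1), "n")
  rs <- vapply(m$shells, `[[`, numeric(1), "r")
  expect_equal(ns[order(rs)], c(1L, 4L, 1L))
  expect_equal(sort(rs), c(1.85, 2.02, 2.21), tolerance = 1e-9)
})

test_that("shell splitting follows the greedy mean-distance rule", {
  mk <- function(d) atom_records(c("Co", rep("O", length(d))),
                                 x = c(0, d), y = 0, z = 0)
  # hand-trace: 2.09 - 2.00 = 0.09 <= 0.1 so one shell of mean 2.045
  m1 <- group_shells(mk(c(2.00, 2.09)), "Co", tol = 0.1, e0 = co_edge)
  expect_length(m1$shells, 1)
  expect_equal(m1$shells[[1]]$r, 2.045)
  # 0.09 > 0.05 so the tighter tolerance splits them
  m2 <- group_shells(mk(c(2.00, 2.09)), "Co", tol = 0.05, e0 = co_edge)
  expect_length(m2$shells, 2)
  m3 <- group_shells(mk(2.0), "Co", e0 = co_edge)
  expect_length(m3$shells, 1)
  expect_equal(m3$shells[[1]]$n, 1L)
  expect_error(group_shells(mk(numeric(0)), "Co", e0 = co_edge), "ligand")
})

test_that("rigid-group labels come from residue identity", {
  at <- atom_records(c("Co", "O", "O", "O"),
                     x = c(0, 1.95, 2.21, 2.50), y = 0, z = 0,
                     resname = c("ION", "HOH", "GLU", "GLU"),
                     resno = c(1L, 2L, 101L, 101L))
  m <- group_shells(at, "Co", tol = 0.1, e0 = co_edge)
  expect_equal(m$groups, c("HOH2", "GLU101", "GLU101"))
})

test_that("r_factor matches its closed forms and scaling invariance", {
  k <- seq(3, 12, by = 0.05)
  obs <- exafs_signal(k, sin(2 * k * 2.02) * exp(-0.1 * k))
  expect_equal(r_factor(obs, obs), 0)
  zero <- exafs_signal(k, rep(0, length(k)))
  expect_equal(r_factor(obs, zero), 100)
  half <- exafs_signal(k, obs$chi / 2)
  expect_equal(r_factor(obs, half), 50)
  # joint rescaling leaves the ratio untouched
  sobs <- exafs_signal(k, 3.7 * obs$chi)
  shalf <- exafs_signal(k, 3.7 * half$chi)
  expect_equal(r_factor(sobs, shalf), 50)
  expect_error(r_factor(zero, obs), "zero")
})

test_that("refinement is a fixed point when started at the truth", {
  tab <- default_scatter_table()
  m <- table4_model()
  obs <- forward_chi(m, tab, seq(1, 14, by = 0.05))
  fit <- refine_site(obs, m, tab)
  expect_lt(fit$r_factor, 0.1)
  expect_lt(max(abs(fit$deltas)), 1e-4)
  expect_true(fit$converged)
})

test_that("the three-shell site model is recovered from a perturbed start", {
  tab <- default_scatter_table()
  truth <- table4_model(ef = 3)
  obs <- forward_chi(truth, tab, seq(1, 14, by = 0.05))
  start <- truth
  for (i in seq_along(start$shells))
    start$shells[[i]]$r <- start$shells[[i]]$r + 0.10
  start$ef <- 0
  fit <- refine_site(obs, start, tab, free = c("ef", "radii"),
                     k_range = c(3, 12), k_weight = 2)
  r_hat <- vapply(fit$model$shells, `[[`, numeric(1), "r")
  r_true <- vapply(truth$shells, `[[`, numeric(1), "r")
  expect_lt(max(abs(r_hat - r_true)), 0.01)
  expect_lte(abs(fit$model$ef - 3), 0.3)
  expect_true(fit$converged)
})

test_that("shells sharing a rigid group move by one common offset", {
  tab <- default_scatter_table()
  truth <- metal_site_model(list(scattering_shell(2, 2.00),
                                 scattering_shell(1, 2.30)),
                            e0 = co_edge, groups = c("GLU", "GLU"))
  obs <- forward_chi(truth, tab, seq(1, 14, by = 0.05))
  start <- truth
  start$shells[[1]]$r <- 2.06
  start$shells[[2]]$r <- 2.36
  fit <- refine_site(obs, start, tab, free = "radii")
  d1 <- fit$model$shells[[1]]$r - 2.06
  d2 <- fit$model$shells[[2]]$r - 2.36
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(fit$model$shells[[1]]$r, 2.00, tolerance = 1e-3)
})

test_that("refinement respects shell bounds and validates the free mask", {
  tab <- default_scatter_table()
  truth <- metal_site_model(scattering_shell(1, 1.10), e0 = co_edge)
  obs <- forward_chi(truth, tab, seq(1, 14, by = 0.05))
  start <- metal_site_model(scattering_shell(1, 1.30), e0 = co_edge)
  fit <- refine_site(obs, start, tab, free = "radii")
  expect_gt(fit$model$shells[[1]]$r, 1.0)  # box constraint held
  expect_error(refine_site(obs, start, tab, free = character(0)))
})

test_that("extraction absorbs a background that is smooth on the spline scale", {
  n <- normalize_xanes(smooth_k_spectrum(), e0 = co_edge)
  sig <- extract_chi(n, rbkg = 1.0, k_weight = 2)
  sel <- sig$k >= 3 & sig$k <= 10
  expect_lt(max(abs(sig$chi[sel])), 1e-3)
  # near-edge terms outside the spline span leave sub-percent residuals
  expect_lt(max(abs(sig$chi[sig$k >= 2 & sig$k < 3])), 5e-3)
})

test_that("extraction round-trips the embedded fine structure", {
  tab <- default_scatter_table()
  m <- table4_model()
  mu <- make_exafs_spectrum(m, tab, exafs_grid(), default_bkg_knots(co_edge),
                            noise_sd = 0, seed = 1)
  sig <- extract_chi(normalize_xanes(mu, e0 = co_edge))
  sel <- sig$k >= 3 & sig$k <= 10
  truth <- forward_chi(m, tab, sig$k[sel])
  expect_gt(cor(sig$chi[sel], truth$chi), 0.99)
})

test_that("extraction rejects degenerate requests", {
  n <- normalize_xanes(smooth_k_spectrum(), e0 = co_edge)
  expect_error(extract_chi(n, rbkg = 0), "positive")
  short <- xas_spectrum(seq(co_edge - 100, co_edge + 300, by = 1),
                        0.5 + atan((seq(co_edge - 100, co_edge + 300, by = 1)
                                    - co_edge) / 2) / pi, "short")
  expect_error(extract_chi(normalize_xanes(short, e0 = co_edge,
                                           post_range = c(50, 290))),
               "400 eV")
})

test_that("radii survive the full generate-extract-refine round trip", {
  # background removal leaks a little of the first-shell signal below rbkg,
  # so recovery through extraction is looser than from the bare model:
  # typically within 0.01 A, never worse than 0.03 A under these conditions
  tab <- default_scatter_table()
  g <- exafs_grid()
  set.seed(7)
  errs <- numeric(0)
  for (i in 1:20) {
    ns <- sample(1:3, 1)
    rs <- sort(runif(ns, 1.8, 2.5))
    if (ns > 1) rs <- rs + cumsum(c(0, rep(0.15, ns - 1)))
    shells <- lapply(rs, function(r)
      scattering_shell(sample(1:4, 1), min(r, 2.8)))
    m <- metal_site_model(shells, e0 = co_edge, ef = runif(1, -5, 5))
    mu <- make_exafs_spectrum(m, tab, g, default_bkg_knots(co_edge),
                              noise_sd = 0, seed = i)
    sig <- extract_chi(normalize_xanes(mu, e0 = co_edge))
    start <- m
    for (j in seq_along(start$shells))
      start$shells[[j]]$r <- start$shells[[j]]$r + 0.05
    start$ef <- 0
    fit <- refine_site(sig, start, tab)
    errs <- c(errs, max(abs(vapply(fit$model$shells, `[[`, numeric(1), "r") -
                              vapply(m$shells, `[[`, numeric(1), "r"))))
  }
  expect_lte(median(errs), 0.01)
  expect_lte(max(errs), 0.03)
})

test_that("scatter tables read from text override the built-in one", {
  f <- withr::local_tempfile(fileext = ".tsv")
  k <- seq(0.5, 15, by = 0.5)
  writeLines(c("# k f phi lambda",
               sprintf("%g %g %g %g", k, 0.9 * exp(-0.15 * k),
                       pi - 0.9 * k, 4 + 0.8 * k)), f)
  tab <- read_scatter_table(f)
  kg <- seq(3, 10, by = 0.5)
  m <- metal_site_model(scattering_shell(1, 2.02), e0 = co_edge)
  expect_equal(forward_chi(m, tab, kg)$chi,
               forward_chi(m, default_scatter_table(), kg)$chi,
               tolerance = 1e-5)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%g %g %g", k, 1, 1), bad)
  expect_error(read_scatter_table(bad), "4 columns")
})
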