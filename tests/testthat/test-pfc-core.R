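test_that("free energy matches the closed form for uniform states", {
  # A * (0.5 (q*^4 - r) phi0^2 + 0.25 phi0^4) with A = 1
  g <- grid_spec(32, 32, dx = 1 / 32)
  p <- pfc_params(r = 0.8, phi0 = 0.4, qstar = 1)
  f <- phase_field(matrix(0.4, 32, 32), g)
  expect_equal(free_energy(f, params = p), 0.0224, tolerance = 1e-12)
  f0 <- phase_field(matrix(0, 32, 32), g)
  expect_equal(free_energy(f0, params = p), 0)
})

test_that("free energy matches the closed form for a single resonant mode", {
  # phi = a cos(q* x) on a commensurate box: F = A (-r a^2 / 4 + 3 a^4 / 32)
  n <- 64; dx <- 2 * pi / n  # k = 1 is the first Fourier mode
  g <- grid_spec(n, n, dx = dx)
  a <- 0.3; r <- 0.8
  x <- ((1:n) - 0.5) * dx
  f <- phase_field(matrix(a * cos(x), n, n), g)
  A <- (n * dx)^2
  expect_equal(free_energy(f, params = pfc_params(r = r, qstar = 1)),
               A * (-r * a^2 / 4 + 3 * a^4 / 32), tolerance = 1e-10)
})

test_that("chemical potential matches its closed forms", {
  n <- 64; dx <- 2 * pi / n
  g <- grid_spec(n, n, dx = dx)
  p <- pfc_params(r = 0.8, phi0 = 0.4, qstar = 1)
  mu_u <- chemical_potential(phase_field(matrix(0.4, n, n), g), p)
  expect_equal(max(abs(mu_u - ((1 - 0.8) * 0.4 + 0.4^3))), 0, tolerance = 1e-12)
  x <- ((1:n) - 0.5) * dx
  phi <- matrix(cos(x), n, n)
  mu <- chemical_potential(phase_field(phi, g), p)
  expect_equal(mu - phi^3, -0.8 * phi, tolerance = 1e-10)
  expect_equal(max(abs(chemical_potential(phase_field(matrix(0, n, n), g), p))),
               0, tolerance = 1e-14)
})

test_that("the dispersion relation has the expected structure", {
  p <- pfc_params(r = 0.8, phi0 = 0.4, qstar = 1)
  expect_equal(dispersion_rate(0, p), 0)
  expect_equal(dispersion_rate(1, p), 0.32)
  # below threshold r = 3 phi0^2 all rates are non-positive
  psub <- pfc_params(r = 0.1, phi0 = 0.4)
  expect_true(all(dispersion_rate(seq(0, 3, by = 0.01), psub) <= 1e-14))
})

test_that("uniform states are fixed points and mass is conserved exactly", {
  g <- grid_spec(32, 32)
  p <- pfc_params(r = 0.8, phi0 = 0.4, dt = 0.5)
  f <- phase_field(matrix(0.4, 32, 32), g)
  f1 <- pfc_step(f, params = p)
  expect_equal(max(abs(f1$values - 0.4)), 0, tolerance = 1e-13)
  # 1e4 steps of a fluctuating field: the k = 0 mode is exactly preserved
  ic <- sample_grf(g, phi0 = 0.4, m2 = 0.01, lam = 3, seed = 1)
  tr <- pfc_run(ic, params = pfc_params(t_end = 1000, dt = 0.1,
                                        save_stride = 1000))
  expect_lt(abs(mean(tr$final$values) / 0.4 - 1), 1e-10)
})

test_that("measured linear growth rates match the dispersion relation", {
  n <- 64; dx <- 1
  g <- grid_spec(n, n, dx = dx)
  p <- pfc_params(r = 0.8, phi0 = 0.4, qstar = 1, dt = 0.01)
  x <- ((1:n) - 0.5) * dx
  for (m in c(6L, 10L, 13L)) {
    k <- 2 * pi * m / (n * dx)
    eps <- 1e-5
    phi <- matrix(0.4 + eps * cos(k * x), n, n)
    f <- phase_field(phi, g)
    nsteps <- 200L
    amp <- numeric(nsteps)
    for (s in seq_len(nsteps)) {
      f <- pfc_step(f, params = p)
      amp[s] <- 2 * Mod(fft(f$values)[m + 1, 1]) / length(phi)
    }
    fit <- stats::lm(log(amp) ~ seq_len(nsteps))
    sigma_hat <- unname(coef(fit)[2]) / p$dt
    expect_lt(abs(sigma_hat / dispersion_rate(k, p) - 1), 0.02)
  }
})

test_that("the semi-implicit stepper agrees with a tiny-dt explicit integrator", {
  n <- 32; dx <- 1
  g <- grid_spec(n, n, dx = dx)
  ic <- sample_grf(g, phi0 = 0.4, m2 = 1e-4, lam = 2, seed = 3)
  r <- 0.8; qstar <- 1
  # independent explicit Euler reference in Fourier space
  k2 <- outer(fibrilpfc:::spectral_k(n, dx)^2, fibrilpfc:::spectral_k(n, dx)^2, `+`)
  B <- (qstar^2 - k2)^2 - r
  dte <- 1e-4
  phi <- ic$values
  for (s in seq_len(round(1 / dte))) {
    mu_h <- B * fft(phi) + fft(phi^3)
    phi <- phi - dte * Re(fft(k2 * mu_h, inverse = TRUE)) / length(phi)
  }
  # package integrator at a small (but 50x larger) step
  tr <- pfc_run(ic, params = pfc_params(r = r, phi0 = 0.4, qstar = qstar,
                                        dt = 0.005, t_end = 1, save_stride = 200))
  expect_lt(max(abs(tr$final$values - phi)), 1e-4)
})

test_that("subcritical dynamics decay back to the uniform state", {
  g <- grid_spec(64, 64, dx = 1.209)
  ic <- sample_grf(g, phi0 = 0.4, m2 = 1e-6, lam = 5, seed = 2)
  tr <- pfc_run(ic, params = pfc_params(r = 0.1, phi0 = 0.4, t_end = 400,
                                        dt = 0.5, save_stride = 200))
  expect_lt(sd(as.vector(tr$final$values)), 1e-4)
})

test_that("free energy decreases monotonically along periodic trajectories", {
  tr <- periodic_eq_run()
  fe <- tr$series$free_energy
  expect_true(all(diff(fe) <= 1e-6 * abs(fe[-length(fe)])))
  # and the end state is a nontrivial crystal
  expect_gt(tail(tr$series$crystallized_fraction, 1), 0.1)
})

test_that("equilibrium spacing matches the one-mode lattice constant", {
  tr <- periodic_eq_run()
  fs <- detect_fibrils(tr$final, qstar = 1)
  rep <- defect_report(fs)
  expect_lt(abs(rep$median_edge_nm / ONE_MODE_SPACING - 1), 0.05)
})

test_that("masked runs conserve the in-mask mean and nucleate at the boundary", {
  run <- masked_propagation_run()
  traj <- run$traj; mask <- run$mask
  means <- vapply(traj$snapshots, function(f) mean(f$values[mask$mask]), 0)
  expect_lt(max(abs(means - 0.4)), 1e-10)
  dmap <- EBImage::distmap(matrix(as.numeric(mask$mask), nrow(mask$mask)))
  mdist <- vapply(traj$snapshots, function(f) {
    sel <- mask$mask & concentration(f) >= 0.5
    if (sum(sel) < 5) NA_real_ else mean(dmap[sel])
  }, 0)
  mdist <- mdist[!is.na(mdist)]
  # crystallization starts in a thin shell near the boundary and the front
  # advances monotonically inward until it reaches the domain center
  expect_gt(length(mdist), 3)
  expect_lt(mdist[1], 0.25 * max(dmap))
  rise <- mdist[1:which.max(mdist)]
  expect_gt(length(rise), 2)
  expect_true(all(diff(rise) > 0))
  expect_gt(max(mdist), 2 * mdist[1])
})

test_that("identical seeds give identical trajectories", {
  g <- grid_spec(48, 48, dx = 1.209)
  mask <- gen_domain_mask(g, 18, 0.2, seed = 1)
  run_once <- function() {
    ic <- sample_grf(g, mask, phi0 = 0.4, m2 = 0.01, lam = 5, seed = 6)
    pfc_run(ic, mask, pfc_params(t_end = 20, dt = 0.5, save_stride = 10))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$series, b$series)
  expect_identical(a$final$values, b$final$values)
})

test_that("invalid parameters are rejected before integration", {
  expect_error(pfc_params(dt = 0), "dt")
  expect_error(pfc_params(qstar = -1), "qstar")
  expect_error(pfc_params(phi0 = 1.2), "phi0")
  # unstable configuration: huge dt makes the implicit denominator negative
  g <- grid_spec(32, 32, dx = 0.3)
  f <- phase_field(matrix(0.4, 32, 32), g)
  expect_error(pfc_step(f, params = pfc_params(r = 30, dt = 50, stab = 0)),
               "unstable")
})
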