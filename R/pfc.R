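# Spectral helpers -----------------------------------------------------------

# angular wavenumbers of the DFT, in the reciprocal units of dx
spectral_k <- function(n, dx) {
  2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dx)
}

spectral_k2 <- function(grid) {
  outer(spectral_k(grid$nx, grid$dx)^2, spectral_k(grid$ny, grid$dx)^2, `+`)
}

# precomputed operators for one (grid, params) combination
pfc_operators <- function(grid, params) {
  kx <- spectral_k(grid$nx, grid$dx)
  ky <- spectral_k(grid$ny, grid$dx)
  KX <- matrix(kx, grid$nx, grid$ny)
  KY <- matrix(ky, grid$nx, grid$ny, byrow = TRUE)
  k2 <- KX^2 + KY^2
  B <- (params$qstar^2 - k2)^2 - params$r   # linear symbol of mu
  den <- 1 + params$dt * k2 * (B + params$stab)
  if (any(den <= 0)) {
    abort(paste0("unstable configuration: the implicit denominator ",
                 "1 + dt k^2 ((q*^2 - k^2)^2 - r + stab) is not positive; ",
                 "reduce dt or increase stab."))
  }
  list(KX = KX, KY = KY, k2 = k2, B = B, den = den)
}

# PFC parameters --------------------------------------------------------------

#' Phase-field crystal model parameters
#'
#' The conserved PFC dynamics `dphi/dt = div(M grad mu)` with
#' `mu = ((q*^2 + lap)^2 - r) phi + phi^3`, driven by the free energy
#' `F[phi] = integral( phi ((q*^2 + lap)^2 - r) phi / 2 + phi^4 / 4 )`.
#' `r` is the destabilizing strength (patterns grow from a uniform state
#' `phi0` when `r > 3 phi0^2`), `qstar` sets the selected wavenumber, and
#' the one-mode hexagonal lattice constant is `4 pi / (sqrt(3) qstar)`.
#'
#' `stab` is the linear stabilization constant of the semi-implicit
#' splitting: the cubic term is integrated as `phi^3 - stab * phi` explicit
#' with `stab * phi` moved into the implicit operator, which keeps the
#' discrete free energy non-increasing at practical step sizes
#' (`dt = 0.5`). It does not change the continuum dynamics.
#'
#' @param r Destabilization strength (dimensionless).
#' @param phi0 Mean phase field, `|phi0| < 1`.
#' @param qstar Pattern wavenumber, in the reciprocal units of the grid `dx`.
#' @param dt Time step (dimensionless).
#' @param t_end Final simulation time.
#' @param save_stride Steps between recorded snapshots/observables.
#' @param stab Linear stabilization constant (>= 0).
#' @return A `pfc_params` object.
#' @examples
#' pfc_params(r = 0.8, phi0 = 0.4)
#' @export
pfc_params <- function(r = 0.8, phi0 = 0.4, qstar = 1, dt = 0.5,
                       t_end = 1000, save_stride = 10, stab = 1.5) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (qstar <= 0) abort("`qstar` must be positive.")
  if (abs(phi0) >= 1) abort("`phi0` must satisfy |phi0| < 1.")
  if (t_end < dt) abort("`t_end` must be at least one time step.")
  if (stab < 0) abort("`stab` must be non-negative.")
  if (save_stride < 1 || save_stride != round(save_stride)) {
    abort("`save_stride` must be a positive integer.")
  }
  structure(list(r = r, phi0 = phi0, qstar = qstar, dt = dt, t_end = t_end,
                 save_stride = as.integer(save_stride), stab = stab),
            class = "pfc_params")
}

#' @export
print.pfc_params <- function(x, ...) {
  cat(sprintf(paste0("<pfc_params> r = %g, phi0 = %g, q* = %g, dt = %g, ",
                     "t_end = %g, stride = %d, stab = %g\n"),
              x$r, x$phi0, x$qstar, x$dt, x$t_end, x$save_stride, x$stab))
  invisible(x)
}

# Energetics ------------------------------------------------------------------

#' Free energy of a phase field
#'
#' Evaluates `F[phi] = integral( phi ((q*^2 + lap)^2 - r) phi / 2 +
#' phi^4 / 4 ) dx^2`, with the differential operator applied spectrally.
#' On a masked domain the energy density is weighted by the smoothed
#' indicator `psi`, i.e. only the inter-cellular space contributes.
#'
#' @param field A [phase_field()].
#' @param mask Optional [domain_mask()].
#' @param params A [pfc_params()] (only `r` and `qstar` are used).
#' @return A scalar (dimensionless energy).
#' @export
free_energy <- function(field, mask = NULL, params = pfc_params()) {
  stopifnot(inherits(field, "phase_field"))
  phi <- field$values
  k2 <- spectral_k2(field$grid)
  B <- (params$qstar^2 - k2)^2 - params$r
  Lphi <- Re(fft(B * fft(phi), inverse = TRUE)) / length(phi)
  e <- 0.5 * phi * Lphi + 0.25 * phi^4
  if (!is.null(mask)) e <- e * mask$psi
  sum(e) * field$grid$dx^2
}

#' Chemical potential of a phase field
#'
#' `mu = dF/dphi = ((q*^2 + lap)^2 - r) phi + phi^3`, evaluated spectrally.
#'
#' @inheritParams free_energy
#' @return A numeric matrix the size of the field.
#' @export
chemical_potential <- function(field, params = pfc_params()) {
  stopifnot(inherits(field, "phase_field"))
  phi <- field$values
  k2 <- spectral_k2(field$grid)
  B <- (params$qstar^2 - k2)^2 - params$r
  Re(fft(B * fft(phi), inverse = TRUE)) / length(phi) + phi^3
}

#' Linear growth rate of the conserved PFC dynamics
#'
#' Dispersion relation of the dynamics linearized about the uniform state
#' `phi0`: `sigma(k) = -k^2 ((q*^2 - k^2)^2 - r + 3 phi0^2)`. Perturbations
#' grow for some band of `k` iff `r > 3 phi0^2`.
#'
#' @param k Wavenumber(s).
#' @param params A [pfc_params()].
#' @return Growth rate(s), same length as `k`.
#' @examples
#' dispersion_rate(1, pfc_params(r = 0.8, phi0 = 0.4, qstar = 1))  # 0.32
#' @export
dispersion_rate <- function(k, params = pfc_params()) {
  -k^2 * ((params$qstar^2 - k^2)^2 - params$r + 3 * params$phi0^2)
}

# Time stepping ---------------------------------------------------------------

# One semi-implicit update. ops from pfc_operators(); st carries masked-mode
# state (psi, mask, target in-mask mass). Returns the new field matrix.
step_matrix <- function(phi, ops, params, st = NULL) {
  dt <- params$dt
  N <- length(phi)
  ph <- fft(phi)
  if (is.null(st)) {
    # periodic: fully diagonal update; the k = 0 mode is exactly preserved
    nl <- fft(phi^3 - params$stab * phi)
    phi <- Re(fft((ph - dt * ops$k2 * nl) / ops$den, inverse = TRUE)) / N
  } else {
    # smoothed-boundary mode: variable mobility M = psi in the flux form
    # dphi/dt = div(psi grad mu); the constant-mobility stiff part is
    # implicit, the remainder explicit
    mu <- Re(fft(ops$B * ph, inverse = TRUE)) / N + phi^3
    muh <- fft(mu)
    gx <- st$psi * (Re(fft(1i * ops$KX * muh, inverse = TRUE)) / N)
    gy <- st$psi * (Re(fft(1i * ops$KY * muh, inverse = TRUE)) / N)
    G <- 1i * ops$KX * fft(gx) + 1i * ops$KY * fft(gy)
    phi <- Re(fft((ph + dt * (G + ops$k2 * (ops$B + params$stab) * ph)) /
                    ops$den, inverse = TRUE)) / N
    # project back onto the in-mask mass constraint (closed-domain budget);
    # the residual corrected here is the controlled boundary leak
    phi[st$mask] <- phi[st$mask] + (st$M0 - sum(phi[st$mask])) / st$n_in
  }
  phi
}

#' Advance a phase field by one time step
#'
#' Performs a single update of the conserved PFC dynamics using the
#' stabilized semi-implicit pseudospectral scheme; in masked mode the
#' smoothed-boundary (variable-mobility) form is used and the in-mask mass
#' is held fixed. Uniform fields are exact fixed points.
#'
#' @param field A [phase_field()].
#' @param mask Optional [domain_mask()].
#' @param params A [pfc_params()].
#' @return The updated [phase_field()] with `time` advanced by `dt`.
#' @export
pfc_step <- function(field, mask = NULL, params = pfc_params()) {
  stopifnot(inherits(field, "phase_field"))
  ops <- pfc_operators(field$grid, params)
  st <- if (!is.null(mask)) {
    list(psi = mask$psi, mask = mask$mask, M0 = sum(field$values[mask$mask]),
         n_in = sum(mask$mask))
  }
  vals <- step_matrix(field$values, ops, params, st)
  if (!all(is.finite(vals))) {
    abort(sprintf("numerical blow-up at t = %g.", field$time + params$dt))
  }
  phase_field(vals, field$grid, time = field$time + params$dt)
}

#' Run the conserved PFC dynamics
#'
#' Integrates from the initial condition to `t_end`, recording the
#' observable series (free energy, protomer availability, crystallized
#' fraction, and optionally the defect proportion) every `save_stride`
#' steps, starting at `t = 0`.
#'
#' @param ic Initial [phase_field()] (typically from [sample_grf()]).
#' @param mask Optional [domain_mask()] for an irregular domain; `NULL`
#'   runs on the periodic rectangle.
#' @param params A [pfc_params()].
#' @param keep_fields `"last"` (default), `"all"` (keep every recorded
#'   snapshot), or `"none"`.
#' @param defect_every If a positive integer, the defect proportion is
#'   computed (via [detect_fibrils()] and [defect_report()]) at every
#'   `defect_every`-th recorded snapshot; `NA` (default) skips it.
#' @return A `pfc_trajectory`: list with `series` (tibble of observables vs
#'   time), `final` (last [phase_field()]), `snapshots` (list, may be
#'   empty), `params`, `mask`.
#' @examples
#' g <- grid_spec(32, 32, dx = 1)
#' ic <- sample_grf(g, phi0 = 0.4, m2 = 1e-4, lam = 2, seed = 1)
#' tr <- pfc_run(ic, params = pfc_params(t_end = 10, dt = 0.5))
#' tail(tidy(tr), 2)
#' @export
pfc_run <- function(ic, mask = NULL, params = pfc_params(),
                    keep_fields = c("last", "all", "none"),
                    defect_every = NA) {
  stopifnot(inherits(ic, "phase_field"))
  keep_fields <- match.arg(keep_fields)
  grid <- ic$grid
  inside <- if (is.null(mask)) matrix(TRUE, grid$nx, grid$ny) else mask$mask
  mean_ic <- mean(ic$values[inside])
  if (abs(mean_ic - params$phi0) > 1e-8) {
    warn(sprintf("in-mask mean of the initial field (%.6f) differs from phi0 (%g).",
                 mean_ic, params$phi0))
  }
  ops <- pfc_operators(grid, params)
  st <- if (!is.null(mask)) {
    list(psi = mask$psi, mask = mask$mask, M0 = sum(ic$values[mask$mask]),
         n_in = sum(mask$mask))
  }
  nsteps <- round(params$t_end / params$dt)
  stride <- params$save_stride
  n_rec <- nsteps %/% stride + 1L
  times <- fe <- avail <- cfrac <- dprop <- numeric(n_rec)
  dprop[] <- NA_real_
  snapshots <- if (keep_fields == "all") vector("list", n_rec) else list()

  phi <- ic$values
  record <- function(slot, phi, t) {
    f <- phase_field(phi, grid, time = t)
    times[slot] <<- t
    fe[slot] <<- free_energy(f, mask, params)
    avail[slot] <<- protomer_availability(f, mask)
    cfrac[slot] <<- crystallized_fraction(f, mask)
    if (!is.na(defect_every) && (slot - 1L) %% defect_every == 0L) {
      dprop[slot] <<- tryCatch({
        fs <- detect_fibrils(f, mask, qstar = params$qstar)
        defect_report(fs)$defect_proportion
      }, error = function(e) NA_real_)
    }
    if (keep_fields == "all") snapshots[[slot]] <<- f
  }
  record(1L, phi, 0)
  slot <- 1L
  for (n in seq_len(nsteps)) {
    phi <- step_matrix(phi, ops, params, st)
    if (n %% 50L == 0L && !all(is.finite(phi))) {
      abort(sprintf("numerical blow-up at t = %g.", n * params$dt))
    }
    if (n %% stride == 0L) {
      slot <- slot + 1L
      record(slot, phi, n * params$dt)
    }
  }
  if (!all(is.finite(phi))) abort("numerical blow-up at final time.")
  series <- tibble(time = times[1:slot], free_energy = fe[1:slot],
                   availability = avail[1:slot],
                   crystallized_fraction = cfrac[1:slot],
                   defect_proportion = dprop[1:slot])
  structure(list(
    series = series,
    final = phase_field(phi, grid, time = nsteps * params$dt),
    snapshots = snapshots[seq_len(if (keep_fields == "all") slot else 0L)],
    params = params,
    mask = mask
  ), class = "pfc_trajectory")
}

#' @export
print.pfc_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(paste0("<pfc_trajectory> %d snapshots to t = %g; final free ",
                     "energy %.4g, crystallized fraction %.3f\n"),
              nrow(s), max(s$time), tail(s$free_energy, 1),
              tail(s$crystallized_fraction, 1)))
  invisible(x)
}

#' @method tidy pfc_trajectory
#' @export
tidy.pfc_trajectory <- function(x, ...) x$series

#' @method glance pfc_trajectory
#' @export
glance.pfc_trajectory <- function(x, ...) {
  s <- x$series
  tibble(
    t_end = max(s$time),
    n_snapshots = nrow(s),
    free_energy_final = tail(s$free_energy, 1),
    availability_final = tail(s$availability, 1),
    crystallized_fraction_final = tail(s$crystallized_fraction, 1)
  )
}
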