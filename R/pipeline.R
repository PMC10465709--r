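#' Physical calibration of the dimensionless model
#'
#' The model is integrated in dimensionless units with `qstar = 1`; physical
#' scale enters only through the calibrated pattern wavenumber (per nm) and
#' the pixel size. One simulation length unit is `1 / qstar_per_nm` nm, and
#' the one-mode hexagonal lattice constant is
#' `4 pi / (sqrt(3) * qstar_per_nm)` nm.
#'
#' @param qstar_per_nm Calibrated pattern wavenumber, 1/nm. The default
#'   0.1209 places the one-mode lattice constant at 60.0 nm, the median
#'   fibril spacing seen in embryonic tendon cross-sections.
#' @param dx_nm Pixel size of the raster the domain mask is defined on, nm.
#' @return List with `dx_sim` (dimensionless pixel size), `nm_per_unit`,
#'   `spacing_nm` (one-mode lattice constant).
#' @export
pfc_calibration <- function(qstar_per_nm = 0.1209, dx_nm = 10) {
  list(qstar_per_nm = qstar_per_nm,
       dx_nm = dx_nm,
       dx_sim = qstar_per_nm * dx_nm,
       nm_per_unit = 1 / qstar_per_nm,
       spacing_nm = 4 * pi / (sqrt(3) * qstar_per_nm))
}

#' End-to-end fibrillogenesis pipeline on one synthetic domain
#'
#' Runs the complete analysis on a single seeded synthetic inter-cellular
#' space: domain generation, Gaussian-random-field initial condition,
#' conserved PFC integration, fibril-center detection, and defect analysis,
#' with all stage seeds expanded deterministically from one global seed.
#' Optionally writes the observable series, detected points, defect report
#' and a provenance file to `out_dir`.
#'
#' @param seed Global integer seed.
#' @param out_dir Optional output directory; created if needed. An existing
#'   completed run (provenance file present) is not overwritten unless
#'   `overwrite = TRUE`.
#' @param domain_diameter_nm Mean diameter of the synthetic domain, nm.
#' @param boundary_roughness,n_modes Domain-shape parameters, see
#'   [gen_domain_mask()].
#' @param calibration A [pfc_calibration()].
#' @param r,phi0 PFC parameters (defaults: the dense-filling regime).
#' @param lam,m2 Initial-condition parameters ([sample_grf()]; `lam` in
#'   grid units).
#' @param dt,t_end,save_stride Time stepping, see [pfc_params()].
#' @param grid_n Grid size in pixels; default: the smallest power of two
#'   at least 1.4 times the domain diameter in pixels.
#' @param defect_every Defect-proportion sampling interval in snapshots
#'   (`NA` to skip the defect time series).
#' @param keep_fields Passed to [pfc_run()].
#' @param overwrite Allow overwriting a completed output directory.
#' @return List with `trajectory`, `fibrils` (a [fibril_set()], nm),
#'   `report` (a [defect_report()], nm), `mask`, `calibration`, `seeds`,
#'   and `paths` (when `out_dir` is given).
#' @export
fibril_pipeline <- function(seed = 1, out_dir = NULL,
                            domain_diameter_nm = 881,
                            boundary_roughness = 0.15, n_modes = 8,
                            calibration = pfc_calibration(),
                            r = 0.8, phi0 = 0.4, lam = 10, m2 = 0.01,
                            dt = 0.5, t_end = 1000, save_stride = 10,
                            grid_n = NULL, defect_every = NA,
                            keep_fields = "last", overwrite = FALSE) {
  npix <- domain_diameter_nm / calibration$dx_nm
  if (is.null(grid_n)) grid_n <- 2^ceiling(log2(npix * 1.4))
  grid <- grid_spec(grid_n, grid_n, dx = calibration$dx_sim)
  seeds <- list(mask = derive_seed(seed, 101),
                ic = derive_seed(seed, 202))
  mask <- gen_domain_mask(
    grid,
    mean_radius = domain_diameter_nm / 2 / calibration$nm_per_unit,
    boundary_roughness = boundary_roughness, n_modes = n_modes,
    seed = seeds$mask)
  params <- pfc_params(r = r, phi0 = phi0, qstar = 1, dt = dt, t_end = t_end,
                       save_stride = save_stride)
  ic <- sample_grf(grid, mask, phi0 = phi0, m2 = m2, lam = lam,
                   seed = seeds$ic)
  traj <- pfc_run(ic, mask, params, keep_fields = keep_fields,
                  defect_every = defect_every)
  fib_sim <- detect_fibrils(traj$final, mask, qstar = 1)
  fibrils <- fibril_set(tibble(
    x_nm = fib_sim$x_nm * calibration$nm_per_unit,
    y_nm = fib_sim$y_nm * calibration$nm_per_unit))
  report <- if (nrow(fibrils) >= 3) defect_report(fibrils) else NULL
  out <- list(trajectory = traj, fibrils = fibrils, report = report,
              mask = mask, calibration = calibration, seeds = seeds,
              params = params)
  if (!is.null(out_dir)) {
    prov_path <- file.path(out_dir, "provenance.yml")
    if (file.exists(prov_path) && !overwrite) {
      abort(sprintf("completed run already present in %s (use overwrite = TRUE).",
                    out_dir))
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series(traj, file.path(out_dir, "series.csv"))
    write_points(fibrils, file.path(out_dir, "points.csv"))
    write_mask(mask, file.path(out_dir, "mask.png"))
    if (!is.null(report)) {
      jsonlite::write_json(
        list(summary = glance(report), points = tidy(report)),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    }
    yaml::write_yaml(list(
      package = "fibrilpfc",
      version = as.character(utils::packageVersion("fibrilpfc")),
      seed = seed, stage_seeds = seeds,
      domain = list(diameter_nm = domain_diameter_nm,
                    boundary_roughness = boundary_roughness,
                    n_modes = n_modes, grid_n = grid_n),
      calibration = calibration[c("qstar_per_nm", "dx_nm")],
      pfc = list(r = r, phi0 = phi0, lam = lam, m2 = m2, dt = dt,
                 t_end = t_end, save_stride = save_stride)
    ), prov_path)
    out$paths <- list(
      series = file.path(out_dir, "series.csv"),
      points = file.path(out_dir, "points.csv"),
      mask = file.path(out_dir, "mask.png"),
      report = file.path(out_dir, "report.json"),
      provenance = prov_path)
  }
  out
}

#' Formation and maturation times of a run
#'
#' Two characteristic times of a crystallizing trajectory: `formation_time`,
#' when protomer availability has completed the given fraction (default
#' 90%) of its total decline, and `maturation_time`, when the free energy
#' has completed its fraction (default 99%) of its total decline over the
#' recorded window.
#'
#' @param trajectory A `pfc_trajectory`.
#' @param availability_frac,energy_frac Completion fractions.
#' @return A tibble with `formation_time` and `maturation_time`.
#' @export
characteristic_times <- function(trajectory, availability_frac = 0.9,
                                 energy_frac = 0.99) {
  s <- trajectory$series
  drop_a <- s$availability[1] - s$availability
  drop_f <- s$free_energy[1] - s$free_energy
  t_form <- if (max(drop_a) > 0) {
    s$time[which(drop_a >= availability_frac * max(drop_a))[1]]
  } else NA_real_
  t_mat <- if (max(drop_f) > 0) {
    s$time[which(drop_f >= energy_frac * max(drop_f))[1]]
  } else NA_real_
  tibble(formation_time = t_form, maturation_time = t_mat)
}
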