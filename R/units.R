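#' Convert a lattice volume fraction to molar concentration
#'
#' A volume fraction `c` (molecules per lattice site) corresponds to
#' `c / (N_A * d0^3)` mol/L, with `d0` the lattice spacing.  The lattice
#' spacing is the physical size of one binding site.
#'
#' @param c Volume fraction (dimensionless, `>= 0`).
#' @param d0 Lattice spacing in nanometres.
#' @return Molar concentration (mol/L).
#' @export
#' @examples
#' volume_fraction_to_molar(0.01, d0 = 10)  # ~1.66e-5 M
volume_fraction_to_molar <- function(c, d0) {
  if (any(d0 <= 0)) abort("lattice spacing d0 must be positive")
  site_litres <- (d0 * 1e-8)^3   # nm -> dm, cubed -> litres
  c / (AVOGADRO * site_litres)
}

#' @rdname volume_fraction_to_molar
#' @param molar Molar concentration (mol/L).
#' @export
molar_to_volume_fraction <- function(molar, d0) {
  if (any(d0 <= 0)) abort("lattice spacing d0 must be positive")
  molar * AVOGADRO * (d0 * 1e-8)^3
}

#' Fit a diffusion constant from an MSD series
#'
#' Fits the linear regime of mean-squared displacement versus sweeps (second
#' half of the curve by default, skipping transients) and returns
#' `D = slope / 6` (3D).  Sub-linear curves (log-log slope well below 1) are
#' flagged as non-diffusive rather than silently fitted.
#'
#' @param sweep Sweep indices.
#' @param msd Mean-squared displacements (lattice units squared).
#' @param fit_fraction Trailing fraction of the curve used for the fit.
#' @return A tibble: `D` (lattice^2/sweep), `slope`, `r_squared`,
#'   `loglog_exponent`, `diffusive` (logical flag).
#' @export
fit_diffusion <- function(sweep, msd, fit_fraction = 0.5) {
  stopifnot(length(sweep) == length(msd), length(sweep) >= 4)
  keep <- seq(from = max(1, floor(length(sweep) * (1 - fit_fraction))),
              to = length(sweep))
  fit <- lm(msd[keep] ~ sweep[keep])
  slope <- unname(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((msd[keep] - mean(msd[keep]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  pos <- msd > 0 & sweep > 0
  expo <- if (sum(pos) >= 3) {
    unname(coef(lm(log(msd[pos]) ~ log(sweep[pos])))[2])
  } else {
    0
  }
  tibble(
    D = slope / 6, slope = slope, r_squared = r2, loglog_exponent = expo,
    diffusive = is.finite(slope) && slope > 0 && expo > 0.8
  )
}

#' Measure the model diffusion constant
#'
#' Runs the MC engine and fits the mean-squared displacement of either the
#' free molecules or the polymer centres of mass to extract the model
#' diffusion constant `D_mc` in lattice units squared per sweep.  For a
#' single free molecule the exact value is 1/6 (simple random walk).
#'
#' @param params A [model_params()] object.
#' @param what `"molecules"` or `"polymer"` (centre of mass).
#' @param sweeps,record_every Run controls.
#' @param state Optional starting state (defaults to an open state; use a
#'   state without polymers for the free-molecule calibration).
#' @param seed RNG seed.
#' @return A tibble as [fit_diffusion()], plus `what` and `sweeps`.
#' @export
measure_model_diffusion <- function(params, what = c("molecules", "polymer"),
                                    sweeps = 20000, record_every = 100,
                                    state = NULL, seed = NULL) {
  what <- match.arg(what)
  if (is.null(state)) state <- init_state(params, "open", seed = seed)
  run <- run_mc(state, params, sweeps = sweeps, record_every = record_every,
                seed = seed)
  msd <- if (what == "molecules") run$series$msd_molecules else {
    rowMeans(cbind(run$series$msd_com1, run$series$msd_com2), na.rm = TRUE)
  }
  out <- fit_diffusion(run$series$sweep, msd)
  out$what <- what
  out$sweeps <- sweeps
  out
}

#' Physical time calibration
#'
#' Matches the model diffusion constant to a target chromatin diffusion
#' constant: one sweep corresponds to
#' `seconds_per_sweep = d0^2 * D_mc / D_real` (with `d0` converted to
#' micrometres).
#'
#' @param d0 Lattice spacing in nanometres.
#' @param D_real Target diffusion constant in um^2/s.
#' @param D_mc Measured model diffusion constant in lattice^2/sweep.
#' @return An object of class `physical_calibration`.
#' @export
physical_calibration <- function(d0, D_real, D_mc) {
  if (d0 <= 0 || D_real <= 0 || D_mc <= 0) {
    abort("calibration inputs must all be positive")
  }
  structure(
    list(d0 = d0, D_real = D_real, D_mc = D_mc,
         seconds_per_sweep = (d0 * 1e-3)^2 * D_mc / D_real),
    class = "physical_calibration"
  )
}

#' @export
print.physical_calibration <- function(x, ...) {
  cat("<physical_calibration> d0 =", x$d0, "nm, D_real =", x$D_real,
      "um^2/s, D_mc =", x$D_mc, "lattice^2/sweep\n")
  cat("  1 sweep =", format(x$seconds_per_sweep, digits = 4), "s\n")
  invisible(x)
}

#' Convert MC sweeps to physical seconds
#'
#' @param sweeps Sweep count(s).
#' @param calibration A [physical_calibration()] object.
#' @return Seconds.
#' @export
sweeps_to_seconds <- function(sweeps, calibration) {
  if (!inherits(calibration, "physical_calibration")) {
    abort("`calibration` must be a physical_calibration object")
  }
  sweeps * calibration$seconds_per_sweep
}
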