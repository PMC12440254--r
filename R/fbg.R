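## Fiber Bragg grating (FBG) sensor model.
##
## An FBG reflects a narrow band centered at the Bragg wavelength
## lambda_B = 2 * n_eff * Lambda. Applied force strains the grating and
## shifts the reflected wavelength linearly:
## delta_lambda_B = 2 * n_eff * Lambda * (1 + Pe) * eta * F,
## where Pe is the photo-elastic coefficient and eta converts force to
## strain. Only the lumped slope (the calibration, nm/N) enters any
## computation; the four physical constants are optional and, when all are
## given, validated against the slope.

#' Bragg wavelength of a grating
#'
#' @param n_eff Effective refractive index of the guided mode; > 0.
#' @param grating_period_nm Grating period Lambda in nm; > 0.
#' @return The Bragg wavelength `2 * n_eff * grating_period_nm` in nm.
#' @export
bragg_wavelength <- function(n_eff, grating_period_nm) {
  if (!is.finite(n_eff) || n_eff <= 0)
    stop("bragg_wavelength: n_eff must be > 0")
  if (!is.finite(grating_period_nm) || grating_period_nm <= 0)
    stop("bragg_wavelength: grating_period_nm must be > 0")
  2 * n_eff * grating_period_nm
}

#' Construct an FBG force-sensor model
#'
#' The tactile sensor used throughout this package is calibrated at
#' 0.082 nm of Bragg-wavelength shift per newton of gripping force. If all
#' four physical constants are supplied, the lumped sensitivity must equal
#' `2 * n_eff * grating_period * (1 + photo_elastic) * force_to_strain`
#' (relative tolerance 1e-9); if the sensitivity is omitted it is computed
#' from them.
#'
#' @param sensitivity Lumped calibration in nm/N; > 0.
#' @param n_eff,grating_period,photo_elastic,force_to_strain Optional
#'   physical constants (dimensionless except `grating_period` in nm).
#' @param base_wavelength Nominal Bragg wavelength in nm (metadata only).
#' @return An object of class `fbg_sensor_model`.
#' @export
fbg_sensor_model <- function(sensitivity = 0.082, n_eff = NULL,
                             grating_period = NULL, photo_elastic = NULL,
                             force_to_strain = NULL,
                             base_wavelength = 1550) {
  have_all <- !is.null(n_eff) && !is.null(grating_period) &&
    !is.null(photo_elastic) && !is.null(force_to_strain)
  if (have_all) {
    implied <- 2 * n_eff * grating_period * (1 + photo_elastic) *
      force_to_strain
    if (is.null(sensitivity)) sensitivity <- implied
    else if (abs(sensitivity - implied) > 1e-9 * abs(implied))
      stop("fbg_sensor_model: sensitivity ", sensitivity,
           " nm/N is inconsistent with the physical constants (implied ",
           implied, " nm/N)")
  }
  if (is.null(sensitivity) || !is.finite(sensitivity) || sensitivity <= 0)
    stop("fbg_sensor_model: sensitivity must be a positive number (nm/N)")
  if (base_wavelength <= 0)
    stop("fbg_sensor_model: base_wavelength must be > 0")
  structure(list(sensitivity = sensitivity, n_eff = n_eff,
                 grating_period = grating_period,
                 photo_elastic = photo_elastic,
                 force_to_strain = force_to_strain,
                 base_wavelength = base_wavelength),
            class = "fbg_sensor_model")
}

#' @export
print.fbg_sensor_model <- function(x, ...) {
  cat(sprintf("<fbg_sensor_model> sensitivity %.4g nm/N, base %.1f nm\n",
              x$sensitivity, x$base_wavelength))
  invisible(x)
}

#' Convert force to Bragg-wavelength shift
#'
#' @param force Applied force in N (numeric vector, finite).
#' @param model An `fbg_sensor_model`.
#' @return Wavelength shift(s) in nm, `sensitivity * force`.
#' @export
force_to_shift <- function(force, model = fbg_sensor_model()) {
  if (!all(is.finite(force))) stop("force_to_shift: force must be finite")
  model$sensitivity * force
}

#' Convert Bragg-wavelength shift back to force
#'
#' Exact inverse of [force_to_shift()].
#'
#' @param delta_lambda Wavelength shift(s) in nm.
#' @param model An `fbg_sensor_model` with positive sensitivity.
#' @return Force(s) in N.
#' @export
shift_to_force <- function(delta_lambda, model = fbg_sensor_model()) {
  if (model$sensitivity <= 0)
    stop("shift_to_force: model sensitivity must be > 0")
  delta_lambda / model$sensitivity
}

#' Construct a Bragg wavelength-shift trace
#'
#' @param shifts Wavelength shifts in nm.
#' @param fs Sampling rate in Hz; > 0.
#' @param base_wavelength Nominal Bragg wavelength in nm; > 0.
#' @return An object of class `wavelength_trace`.
#' @export
wavelength_trace <- function(shifts, fs, base_wavelength = 1550) {
  if (fs <= 0) stop("wavelength_trace: fs must be > 0")
  if (base_wavelength <= 0)
    stop("wavelength_trace: base_wavelength must be > 0")
  structure(list(shifts = as.numeric(shifts), fs = as.numeric(fs),
                 base_wavelength = base_wavelength),
            class = "wavelength_trace")
}

#' @export
print.wavelength_trace <- function(x, ...) {
  cat(sprintf("<wavelength_trace> %d samples @ %g Hz around %.1f nm\n",
              length(x$shifts), x$fs, x$base_wavelength))
  invisible(x)
}

#' Render a force signal as an interrogated wavelength trace
#'
#' Applies [force_to_shift()] elementwise and adds optional white
#' interrogator noise on the wavelength readout.
#'
#' @param signal A `force_signal`.
#' @param model An `fbg_sensor_model`.
#' @param wavelength_noise_sd Readout noise sd in nm (0 = noiseless).
#' @param seed Seed for the readout noise (required if noise > 0).
#' @return A `wavelength_trace` at the signal's sampling rate.
#' @export
interrogate <- function(signal, model = fbg_sensor_model(),
                        wavelength_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(signal, "force_signal"))
  shifts <- force_to_shift(signal$samples, model)
  if (wavelength_noise_sd > 0) {
    if (is.null(seed))
      stop("interrogate: seed required when wavelength_noise_sd > 0")
    shifts <- shifts + with_seed(seed, stats::rnorm(length(shifts), 0,
                                                    wavelength_noise_sd))
  }
  wavelength_trace(shifts, fs = signal$fs,
                   base_wavelength = model$base_wavelength)
}

#' Demodulate a wavelength trace back into a force signal
#'
#' @param trace A `wavelength_trace`.
#' @param model The `fbg_sensor_model` used to interrogate it.
#' @return A `force_signal`.
#' @export
trace_to_force <- function(trace, model = fbg_sensor_model()) {
  stopifnot(inherits(trace, "wavelength_trace"))
  force_signal(shift_to_force(trace$shifts, model), fs = trace$fs)
}
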