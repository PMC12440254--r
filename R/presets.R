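## Condition tables for the six vessel/tissue models.
## Group-mean PCFF values (N) per condition; one classification task per
## model. Conditions are listed in the order used for class indexing.

.vessel_conditions <- local({
  tab <- rbind(
    # phantom I: silicone vessels of increasing wall hardness
    data.frame(model_id = "phantom_I",
               condition_label = c("20A", "30A", "40A"),
               pulse_amplitude = c(0.162, 0.130, 0.010)),
    # phantom II: 30A vessel under tissue of increasing thickness
    data.frame(model_id = "phantom_II",
               condition_label = c("0.5mm", "1.0mm", "1.5mm", "2.0mm",
                                   "2.5mm", "3.0mm"),
               pulse_amplitude = c(0.223, 0.172, 0.141, 0.081, 0.050, 0.026)),
    # phantom III: 30A vessel under 1 mm tissue of increasing hardness
    data.frame(model_id = "phantom_III",
               condition_label = c("10A", "20A", "30A"),
               pulse_amplitude = c(0.141, 0.100, 0.058)),
    # porcine I: bare abdominal artery vs abdominal vein
    data.frame(model_id = "porcine_I",
               condition_label = c("artery", "vein"),
               pulse_amplitude = c(0.047, 0.022)),
    # porcine II: carotid artery under adipose of increasing thickness
    data.frame(model_id = "porcine_II",
               condition_label = c("1.0mm", "2.0mm", "3.0mm"),
               pulse_amplitude = c(0.122, 0.066, 0.046)),
    # porcine III: carotid artery under adipose vs muscle
    data.frame(model_id = "porcine_III",
               condition_label = c("adipose", "muscle"),
               pulse_amplitude = c(0.059, 0.032))
  )
  idx <- stats::ave(seq_len(nrow(tab)), tab$model_id, FUN = seq_along)
  tab$class_index <- as.integer(idx - 1L)
  tab
})

#' Table of vessel-model conditions
#'
#' One row per condition of the six vessel/tissue models, in class-index
#' order: model id, condition label, the group-mean peak clamping force
#' fluctuation (PCFF, in newtons) that condition produces, and the 0-based
#' class index within its model's classification task.
#'
#' @param model_id Optional model id to filter by.
#' @return A data frame with columns `model_id`, `condition_label`,
#'   `pulse_amplitude`, `class_index`.
#' @export
vessel_conditions <- function(model_id = NULL) {
  tab <- .vessel_conditions
  if (!is.null(model_id)) {
    if (!model_id %in% tab$model_id)
      stop("vessel_conditions: unknown model_id '", model_id, "'; valid: ",
           paste(unique(tab$model_id), collapse = ", "))
    tab <- tab[tab$model_id == model_id, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Create a vessel-model generator preset
#'
#' Looks up the group-mean PCFF for a named condition and assembles the
#' full set of generator parameters for [simulate_grip_trial()]. The
#' pulsatile rate defaults to 90 pulses/min (peristaltic pump at
#' 30 rev/min with three rollers), the static clamp hold to 15 s.
#'
#' @param model_id One of `"phantom_I"`, `"phantom_II"`, `"phantom_III"`,
#'   `"porcine_I"`, `"porcine_II"`, `"porcine_III"`.
#' @param condition_label Condition within the model, e.g. `"artery"`,
#'   `"0.5mm"`, `"20A"` (see [vessel_conditions()]).
#' @param pulse_rate Pulses per minute.
#' @param baseline_force Static clamp force component (N).
#' @param amplitude_cv Trial-to-trial coefficient of variation of the pulse
#'   amplitude (dimensionless, in \[0, 1)).
#' @param noise_sd Additive white sensor noise (N).
#' @param hold_duration Clamp hold duration (s).
#' @return An object of class `vessel_model_spec`.
#' @export
make_preset <- function(model_id, condition_label,
                        pulse_rate = 90, baseline_force = 0.5,
                        amplitude_cv = 0.15, noise_sd = 0.003,
                        hold_duration = 15) {
  tab <- vessel_conditions(model_id)
  row <- tab[tab$condition_label == condition_label, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("make_preset: unknown condition '", condition_label, "' for ",
         model_id, "; valid: ", paste(tab$condition_label, collapse = ", "))
  vessel_model_spec(model_id = model_id, condition_label = condition_label,
                    pulse_amplitude = row$pulse_amplitude,
                    baseline_force = baseline_force,
                    pulse_rate = pulse_rate, amplitude_cv = amplitude_cv,
                    noise_sd = noise_sd, hold_duration = hold_duration,
                    class_index = row$class_index)
}

#' Construct a vessel-model spec directly
#'
#' Lower-level constructor behind [make_preset()], useful for custom
#' conditions not in the printed tables.
#'
#' @param model_id,condition_label Identification strings.
#' @param pulse_amplitude Mean pulse amplitude = group-mean PCFF (N); > 0.
#' @param baseline_force Static clamp component (N).
#' @param pulse_rate Pulses per minute; > 0.
#' @param amplitude_cv Trial-to-trial CV in \[0, 1).
#' @param noise_sd Additive noise sd (N); >= 0.
#' @param hold_duration Hold duration (s); > 0.
#' @param class_index 0-based class index.
#' @return An object of class `vessel_model_spec`.
#' @export
vessel_model_spec <- function(model_id, condition_label, pulse_amplitude,
                              baseline_force = 0.5, pulse_rate = 90,
                              amplitude_cv = 0.15, noise_sd = 0.003,
                              hold_duration = 15, class_index = 0L) {
  if (pulse_amplitude <= 0) stop("vessel_model_spec: pulse_amplitude must be > 0")
  if (pulse_rate <= 0) stop("vessel_model_spec: pulse_rate must be > 0")
  if (amplitude_cv < 0 || amplitude_cv >= 1)
    stop("vessel_model_spec: amplitude_cv must be in [0, 1)")
  if (noise_sd < 0) stop("vessel_model_spec: noise_sd must be >= 0")
  if (hold_duration <= 0) stop("vessel_model_spec: hold_duration must be > 0")
  structure(list(model_id = model_id, condition_label = condition_label,
                 pulse_amplitude = pulse_amplitude,
                 baseline_force = baseline_force, pulse_rate = pulse_rate,
                 amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                 hold_duration = hold_duration,
                 class_index = as.integer(class_index)),
            class = "vessel_model_spec")
}

#' @export
print.vessel_model_spec <- function(x, ...) {
  cat(sprintf(paste0("<vessel_model_spec> %s/%s: amplitude %.3f N, baseline ",
                     "%.2f N, %g pulses/min, cv %.2f, noise %.3g N, hold %g s\n"),
              x$model_id, x$condition_label, x$pulse_amplitude,
              x$baseline_force, x$pulse_rate, x$amplitude_cv, x$noise_sd,
              x$hold_duration))
  invisible(x)
}
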