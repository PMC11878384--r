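# Ultrasound dose arithmetic for pulsed transcranial focused-ultrasound
# protocols: duty cycle of a nested pulse/train scheme, time-averaged
# acoustic power, the cranial thermal index (TIC), and a configurable
# ITRUSST sonication-duration advisory. All functions return full-precision
# values; rounding to reporting precision is left to the caller.

#' Pulsed-sonication scheme
#'
#' Describes a two-level pulsing scheme: short pulses repeated at a fast
#' pulse repetition frequency inside a train, with trains repeated at a slow
#' rate across a stimulation block. Cosine ramps applied to individual
#' pulses are recorded as metadata and do not enter the duty-cycle
#' arithmetic.
#'
#' @param pulse_duration Pulse length in seconds.
#' @param fast_prf Pulse repetition frequency within a train, Hz.
#' @param train_duration Train length in seconds.
#' @param slow_rate Train repetition rate, Hz.
#' @param block_duration Stimulation block length in seconds.
#' @param ramp_duration Per-pulse ramp duration in seconds (metadata only).
#' @return An object of class `pulse_scheme`.
#' @examples
#' pulse_scheme(0.5e-3, 1000, 0.5, 0.5)
#' @export
pulse_scheme <- function(pulse_duration, fast_prf, train_duration, slow_rate,
                         block_duration = 16, ramp_duration = 50e-6) {
  check_scalar(pulse_duration, "pulse_duration", lower = 0, allow_equal_lower = FALSE)
  check_scalar(fast_prf, "fast_prf", lower = 0, allow_equal_lower = FALSE)
  check_scalar(train_duration, "train_duration", lower = 0, allow_equal_lower = FALSE)
  check_scalar(slow_rate, "slow_rate", lower = 0, allow_equal_lower = FALSE)
  check_scalar(block_duration, "block_duration", lower = 0, allow_equal_lower = FALSE)
  check_scalar(ramp_duration, "ramp_duration", lower = 0)
  if (pulse_duration > 1 / fast_prf)
    stop_invalid("pulse_duration", "exceeds the fast-PRF period 1/fast_prf")
  if (train_duration > 1 / slow_rate)
    stop_invalid("train_duration", "exceeds the slow-rate period 1/slow_rate")
  if (block_duration < train_duration)
    stop_invalid("block_duration", "shorter than one pulse train")
  structure(list(pulse_duration = pulse_duration, fast_prf = fast_prf,
                 train_duration = train_duration, slow_rate = slow_rate,
                 block_duration = block_duration, ramp_duration = ramp_duration),
            class = "pulse_scheme")
}

#' Transducer electrical and geometric specification
#'
#' @param electrical_power Peak electrical drive power, W.
#' @param efficiency Electro-acoustic conversion efficiency, fraction in (0, 1].
#' @param equivalent_aperture Equivalent active aperture at the skull, cm.
#' @param tic_coefficient Cranial thermal-index normalisation, mW/cm
#'   (IEC convention, 40 mW/cm).
#' @param transmission Estimated skull transmission fraction (metadata).
#' @param target_pressure Target in vivo pressure, kPa (metadata).
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(electrical_power, efficiency, equivalent_aperture,
                            tic_coefficient = 40, transmission = 0.39,
                            target_pressure = NA_real_) {
  check_scalar(electrical_power, "electrical_power", lower = 0)
  check_scalar(efficiency, "efficiency", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_scalar(equivalent_aperture, "equivalent_aperture", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(tic_coefficient, "tic_coefficient", lower = 0,
               allow_equal_lower = FALSE)
  structure(list(electrical_power = electrical_power, efficiency = efficiency,
                 equivalent_aperture = equivalent_aperture,
                 tic_coefficient = tic_coefficient, transmission = transmission,
                 target_pressure = target_pressure),
            class = "transducer_spec")
}

#' Duty cycle of a nested pulse scheme
#'
#' Fraction of the stimulation block during which ultrasound is on:
#' (pulse on-fraction within a train) times (train on-fraction within the
#' block), i.e. `pulse_duration * fast_prf * train_duration * slow_rate`.
#'
#' @param scheme A [pulse_scheme()].
#' @return Dimensionless fraction in \[0, 1\].
#' @examples
#' duty_cycle(pulse_scheme(0.5e-3, 1000, 0.5, 0.5))  # 0.125
#' @export
duty_cycle <- function(scheme) {
  stopifnot(inherits(scheme, "pulse_scheme"))
  (scheme$pulse_duration * scheme$fast_prf) *
    (scheme$train_duration * scheme$slow_rate)
}

#' Time-averaged acoustic power
#'
#' @param spec A [transducer_spec()].
#' @param duty Duty cycle fraction in \[0, 1\].
#' @return Time-averaged acoustic power in watts:
#'   `electrical_power * efficiency * duty`.
#' @export
time_averaged_power <- function(spec, duty) {
  stopifnot(inherits(spec, "transducer_spec"))
  check_scalar(duty, "duty", lower = 0, upper = 1)
  spec$electrical_power * spec$efficiency * duty
}

#' Thermal index for cranial bone (TIC)
#'
#' TIC = time-averaged acoustic power in mW divided by
#' (coefficient in mW/cm times equivalent aperture in cm).
#'
#' @param acoustic_power Time-averaged acoustic power, W.
#' @param aperture Equivalent active aperture, cm.
#' @param coefficient Normalisation coefficient, mW/cm (default 40).
#' @return Dimensionless thermal index, full precision.
#' @export
thermal_index_cranial <- function(acoustic_power, aperture, coefficient = 40) {
  check_scalar(acoustic_power, "acoustic_power", lower = 0)
  check_scalar(aperture, "aperture", lower = 0, allow_equal_lower = FALSE)
  check_scalar(coefficient, "coefficient", lower = 0, allow_equal_lower = FALSE)
  (acoustic_power * 1000) / (coefficient * aperture)
}

# Default advisory table: only the band the ITRUSST guidance quotes for
# TIC between 5 and 6 is pre-populated; other bands are user configuration.
default_itrusst_bands <- function() {
  data.frame(tic_min = 5.0, tic_max = 6.0, duration_limit_s = 10)
}

#' ITRUSST sonication-duration advisory
#'
#' Looks a TIC value up in a band table of recommended maximum sonication
#' durations and reports whether a planned duration complies. Only the
#' 5.0--6.0 band (10-s limit) ships as a default; additional bands are
#' supplied by the user.
#'
#' @param tic Thermal index value, >= 0.
#' @param sonication_duration Planned sonication duration, s.
#' @param bands Data frame with columns `tic_min`, `tic_max`,
#'   `duration_limit_s`.
#' @return List with `band` (matched row or NULL), `duration_limit`
#'   (s, NA if no band matched), and `compliant` (logical; NA when the TIC
#'   falls outside every configured band).
#' @examples
#' itrusst_advisory(5.6, 16)$compliant  # FALSE
#' @export
itrusst_advisory <- function(tic, sonication_duration,
                             bands = default_itrusst_bands()) {
  check_scalar(tic, "tic", lower = 0)
  check_scalar(sonication_duration, "sonication_duration", lower = 0,
               allow_equal_lower = FALSE)
  hit <- which(tic >= bands$tic_min & tic <= bands$tic_max)
  if (length(hit) == 0L)
    return(list(band = NULL, duration_limit = NA_real_, compliant = NA))
  row <- bands[hit[1L], , drop = FALSE]
  limit <- row$duration_limit_s
  list(band = row, duration_limit = limit,
       compliant = sonication_duration <= limit)
}

#' One-call dose report for a pulsed protocol
#'
#' @inheritParams duty_cycle
#' @inheritParams time_averaged_power
#' @param sonication_duration Block duration used for the advisory, s
#'   (defaults to the scheme's block duration).
#' @return List with `duty`, `tap_w`, `tic`, `advisory`.
#' @export
acoustic_report <- function(scheme, spec,
                            sonication_duration = scheme$block_duration) {
  duty <- duty_cycle(scheme)
  tap <- time_averaged_power(spec, duty)
  tic <- thermal_index_cranial(tap, spec$equivalent_aperture,
                               spec$tic_coefficient)
  list(duty = duty, tap_w = tap, tic = tic,
       advisory = itrusst_advisory(tic, sonication_duration))
}
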