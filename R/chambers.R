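#' Time-varying elastance heart chamber
#'
#' Constructs the parameter set of one heart chamber. Diastolic behaviour is an
#' exponential end-diastolic pressure-volume relationship `P = a * exp(b * V)`;
#' systolic behaviour is a linear end-systolic relationship
#' `P = E_s * (V - V_0)` scaled by the activation value. The instantaneous
#' chamber pressure blends the two laws with the activation waveform (see
#' [chamber_pressure()]).
#'
#' @param a diastolic pressure scale (mmHg), `a >= 0`
#' @param b diastolic volume sensitivity (1/ml), `b > 0`
#' @param E_s end-systolic elastance (mmHg/ml), `E_s > 0`
#' @param V_0 zero-pressure filling volume (ml), `V_0 >= 0`
#' @param activation_onset onset of activation as a fraction of the cardiac
#'   cycle in `[0, 1)`
#' @param activation_duration duration of activation as a fraction of the
#'   cycle in `(0, 1)`
#' @param label optional chamber name used in diagnostics
#' @return an object of class `elastance_chamber`
#' @examples
#' lv <- elastance_chamber(a = 0.5, b = 0.03, E_s = 2, V_0 = 10)
#' diastolic_pressure(lv, 93)
#' systolic_pressure(lv, 90, vc = 1)
#' @export
elastance_chamber <- function(a, b, E_s, V_0,
                              activation_onset = 0,
                              activation_duration = 0.3,
                              label = "chamber") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(E_s), is.numeric(V_0))
  if (a < 0) stop("'a' must be >= 0")
  if (b <= 0) stop("'b' must be > 0")
  if (E_s <= 0) stop("'E_s' must be > 0")
  if (V_0 < 0) stop("'V_0' must be >= 0")
  if (activation_onset < 0 || activation_onset >= 1)
    stop("'activation_onset' must be in [0, 1)")
  if (activation_duration <= 0 || activation_duration >= 1)
    stop("'activation_duration' must be in (0, 1)")
  structure(
    list(a = a, b = b, E_s = E_s, V_0 = V_0,
         activation_onset = activation_onset,
         activation_duration = activation_duration,
         label = label),
    class = "elastance_chamber"
  )
}

#' @export
print.elastance_chamber <- function(x, ...) {
  cat(sprintf(
    "<elastance_chamber '%s'> a=%.4g mmHg, b=%.4g /ml, E_s=%.4g mmHg/ml, V_0=%.4g ml\n",
    x$label, x$a, x$b, x$E_s, x$V_0))
  cat(sprintf("  activation: onset %.3f, duration %.3f (cycle fractions)\n",
              x$activation_onset, x$activation_duration))
  invisible(x)
}

#' Diastolic (passive) chamber pressure
#'
#' Exponential end-diastolic pressure-volume relationship
#' `P = a * exp(b * V)`, strictly increasing and convex in the volume.
#'
#' @param chamber an [elastance_chamber()]
#' @param V chamber volume (ml), `V >= 0`; vectorised
#' @return pressure (mmHg)
#' @export
diastolic_pressure <- function(chamber, V) {
  if (any(V < 0)) stop("volume must be >= 0")
  chamber$a * exp(chamber$b * V)
}

#' Systolic (active) chamber pressure
#'
#' Linear end-systolic pressure-volume relationship scaled by the activation
#' value: `P = E_s * vc * (V - V_0)`.
#'
#' @inheritParams diastolic_pressure
#' @param vc activation value in `[0, 1]`
#' @return pressure (mmHg)
#' @export
systolic_pressure <- function(chamber, V, vc) {
  if (any(vc < 0 | vc > 1)) stop("activation value must be in [0, 1]")
  chamber$E_s * vc * (V - chamber$V_0)
}

#' Instantaneous chamber pressure
#'
#' Convex combination of the systolic and diastolic laws weighted by the
#' activation value: `P = vc * E_s * (V - V_0) + (1 - vc) * a * exp(b * V)`.
#' Reduces exactly to the diastolic law at `vc = 0` and to the end-systolic
#' law at `vc = 1`, the standard time-varying elastance construction.
#'
#' @inheritParams systolic_pressure
#' @return pressure (mmHg)
#' @export
chamber_pressure <- function(chamber, V, vc) {
  vc * systolic_pressure(chamber, V, 1) + (1 - vc) * diastolic_pressure(chamber, V)
}

#' Activation (contraction) waveform
#'
#' Dimensionless periodic activation `v_C(t)` driving the time-varying
#' elastance: 0 throughout diastolic filling, rising to exactly 1 at peak
#' systole along a raised cosine (half-cosine up, half-cosine down) over the
#' activation window.
#'
#' @param t time (s), vectorised
#' @param period cardiac cycle length (s), `60 / HR`
#' @param onset activation onset as a fraction of the cycle in `[0, 1)`
#' @param duration activation duration as a fraction of the cycle in `(0, 1)`
#' @return activation value(s) in `[0, 1]`
#' @examples
#' activation(0.15, period = 1, onset = 0, duration = 0.3) # peak: 1
#' activation(0.60, period = 1, onset = 0, duration = 0.3) # filling: 0
#' @export
activation <- function(t, period, onset = 0, duration = 0.3) {
  if (any(t < 0)) stop("time must be >= 0")
  phase <- (t / period - onset) %% 1
  v <- ifelse(phase < duration, 0.5 * (1 - cos(2 * pi * phase / duration)), 0)
  # clamp residual floating error so the invariant 0 <= v <= 1 is exact
  pmin(pmax(v, 0), 1)
}

#' Default systolic duration
#'
#' Systolic activation interval in seconds, `0.3 * sqrt(60 / HR)`, the usual
#' heart-rate correction of systolic time (Bazett-type scaling).
#'
#' @param HR heart rate (bpm)
#' @return duration (s)
#' @export
systolic_duration <- function(HR) 0.3 * sqrt(60 / HR)

#' Diode heart valve
#'
#' @param R_open resistance when open (mmHg s/ml), `> 0`
#' @param label optional name
#' @return an object of class `valve_model`
#' @export
valve_model <- function(R_open, label = "valve") {
  if (R_open <= 0) stop("'R_open' must be > 0")
  structure(list(R_open = R_open, label = label), class = "valve_model")
}

#' Flow through a diode valve
#'
#' Ohmic flow `(P_up - P_down) / R_open` when the upstream pressure exceeds
#' the downstream pressure, zero otherwise; never negative.
#'
#' @param P_up,P_down upstream / downstream pressures (mmHg); vectorised
#' @param valve a [valve_model()]
#' @return flow (ml/s), `>= 0`
#' @export
valve_flow <- function(P_up, P_down, valve) {
  if (any(!is.finite(P_up)) || any(!is.finite(P_down)))
    stop("pressures must be finite")
  ifelse(P_up > P_down, (P_up - P_down) / valve$R_open, 0)
}
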