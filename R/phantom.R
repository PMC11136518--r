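#' Virtual soft robotic left-ventricle phantom
#'
#' Passive compliant chamber described by a quadratic transmural
#' pressure-volume law on the stressed volume `x = V - V_0`:
#' `Pint - Pext = c0 + c1 x + c2 x^2`, plus a scalar compliance `C`
#' (ml/mmHg) used by the literal external-pressure command (see
#' [external_pressure_command()]). `V_0` is the unstressed phantom volume,
#' set to the patient's end-systolic LV volume by construction of the mold.
#'
#' @param c2,c1,c0 quadratic law coefficients (mmHg/ml^2, mmHg/ml, mmHg)
#' @param V_0 unstressed volume (ml)
#' @param C scalar compliance (ml/mmHg); if `NULL`, taken as the reciprocal
#'   of the mean tangent slope of the law over the 0-100 ml operating range
#' @param operating_range fill-volume range (ml) used for the mean-slope
#'   compliance and monotonicity check
#' @param label optional name
#' @return an object of class `phantom_model`
#' @examples
#' ph <- phantom_model(c2 = 0.002, c1 = 0.4, V_0 = 32)
#' phantom_transmural(ph, 50)
#' @export
phantom_model <- function(c2, c1, c0 = 0, V_0 = 0, C = NULL,
                          operating_range = c(0, 100), label = "phantom") {
  slope <- function(x) c1 + 2 * c2 * x
  xs <- seq(operating_range[1], operating_range[2], length.out = 101)
  if (any(slope(xs) <= 0))
    stop("transmural law must be monotone increasing on the operating range")
  mean_slope <- c1 + c2 * (operating_range[1] + operating_range[2])
  if (is.null(C)) C <- 1 / mean_slope
  if (C <= 0) stop("'C' must be > 0")
  structure(
    list(c2 = c2, c1 = c1, c0 = c0, V_0 = V_0, C = C,
         operating_range = operating_range, label = label),
    class = "phantom_model"
  )
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf(
    "<phantom_model '%s'> Pint-Pext = %.4g + %.4g x + %.4g x^2 (x = V - %.4g ml)\n",
    x$label, x$c0, x$c1, x$c2, x$V_0))
  cat(sprintf("  scalar compliance C = %.4g ml/mmHg\n", x$C))
  invisible(x)
}

#' Transmural pressure of the phantom wall
#'
#' @param phantom a [phantom_model()]
#' @param x stressed volume `V - V_0` (ml); vectorised
#' @return transmural pressure `Pint - Pext` (mmHg)
#' @export
phantom_transmural <- function(phantom, x) {
  phantom$c0 + phantom$c1 * x + phantom$c2 * x^2
}

#' Pump actuator model
#'
#' First-order lag plus saturation model of one gear-pump/DC-motor unit. The
#' default flow limit of 633 ml/s corresponds to the 38 l/min pump design
#' flow.
#'
#' @param flow_limit maximum |flow| (ml/s)
#' @param rate_limit maximum |dflow/dt| (ml/s^2), `Inf` to disable
#' @param tau first-order lag time constant (s), `>= 0`
#' @param noise_sd additive Gaussian measurement-noise SD on Pint (mmHg)
#' @param seed RNG seed; mandatory when `noise_sd > 0`
#' @return an object of class `actuator_model`
#' @export
actuator_model <- function(flow_limit = 633, rate_limit = Inf, tau = 0.002,
                           noise_sd = 0, seed = NULL) {
  if (flow_limit <= 0) stop("'flow_limit' must be > 0")
  if (tau < 0) stop("'tau' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("a 'seed' is mandatory when measurement noise is enabled")
  structure(list(flow_limit = flow_limit, rate_limit = rate_limit, tau = tau,
                 noise_sd = noise_sd, seed = seed),
            class = "actuator_model")
}

#' @rdname actuator_model
#' @details `ideal_actuator()` returns a lag-free, unlimited, noise-free
#'   actuator, the perfect-tracking limit used in equivalence checks.
#' @export
ideal_actuator <- function() actuator_model(flow_limit = Inf, tau = 0)

#' External pressure command of the activation controller
#'
#' Computes the hydraulic-chamber pressure `Pext` that makes the passive
#' phantom display the target left-ventricular pressure at the target volume.
#' In `"scalar"` mode the command uses the scalar compliance,
#' `Pext = Plv - (Vlv - V_0) / C`. In `"local"` mode (default) the full
#' quadratic wall law is inverted instead,
#' `Pext = Plv - transmural(Vlv - V_0)`, i.e. the compliance is evaluated
#' locally at the commanded volume; the two coincide for a linear wall law
#' with slope `1 / C`.
#'
#' @param Plv_target target left-ventricular pressure (mmHg)
#' @param Vlv_target target left-ventricular volume (ml)
#' @param phantom a [phantom_model()]
#' @param mode `"local"` or `"scalar"`
#' @return commanded external pressure (mmHg)
#' @examples
#' ph <- phantom_model(c2 = 0, c1 = 0.5, V_0 = 32) # C = 2 ml/mmHg
#' external_pressure_command(157, 93, ph, mode = "scalar") # 126.5
#' @export
external_pressure_command <- function(Plv_target, Vlv_target, phantom,
                                      mode = c("local", "scalar")) {
  mode <- match.arg(mode)
  x <- Vlv_target - phantom$V_0
  if (mode == "scalar") Plv_target - x / phantom$C
  else Plv_target - phantom_transmural(phantom, x)
}

#' Simulate the static characterization protocol
#'
#' Virtual bench protocol measuring the phantom wall law: starting from the
#' unstressed volume, the phantom is filled in 10-ml steps up to 100 ml; at
#' each fill the internal pressure is recorded, and the whole sweep is
#' repeated for external chamber pressures from -50 to 150 mmHg in 25-mmHg
#' steps. Optionally adds seeded Gaussian measurement noise on Pint.
#'
#' @param phantom a [phantom_model()]
#' @param actuator an [actuator_model()]; only its `noise_sd`/`seed` are used
#'   (the protocol is static)
#' @param fill_grid fill volumes above `V_0` (ml)
#' @param pext_grid external pressure levels (mmHg)
#' @return a `data.frame` of class `characterization_data` with columns
#'   `pext_mmHg`, `fill_ml`, `pint_mmHg`
#' @export
simulate_characterization <- function(phantom, actuator = actuator_model(),
                                      fill_grid = seq(0, 100, by = 10),
                                      pext_grid = seq(-50, 150, by = 25)) {
  if (length(fill_grid) < 1 || length(pext_grid) < 1) stop("empty grid")
  grid <- expand.grid(fill_ml = fill_grid, pext_mmHg = pext_grid,
                      KEEP.OUT.ATTRS = FALSE)
  pint <- grid$pext_mmHg + phantom_transmural(phantom, grid$fill_ml)
  if (actuator$noise_sd > 0) {
    if (is.null(actuator$seed))
      stop("a 'seed' is mandatory when measurement noise is enabled")
    pint <- pint + local({
      set.seed(actuator$seed)
      stats::rnorm(nrow(grid), 0, actuator$noise_sd)
    })
  }
  out <- data.frame(pext_mmHg = grid$pext_mmHg, fill_ml = grid$fill_ml,
                    pint_mmHg = pint)
  class(out) <- c("characterization_data", "data.frame")
  out
}

#' Fit the phantom compliance from characterization data
#'
#' Least-squares second-order regression of the transmural pressure
#' `Pint - Pext` on the fill volume, pooled over all external-pressure
#' levels. The scalar compliance `C` is the reciprocal of the mean tangent
#' slope of the fitted quadratic over the operating range.
#'
#' @param data a `data.frame` with columns `pext_mmHg`, `fill_ml`,
#'   `pint_mmHg` (column order free)
#' @param V_0 unstressed volume (ml) recorded in the fitted model
#' @return a [phantom_model()]
#' @export
fit_compliance <- function(data, V_0 = 0) {
  need <- c("pext_mmHg", "fill_ml", "pint_mmHg")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (length(unique(data$fill_ml)) < 3)
    stop("need at least 3 distinct fill volumes")
  ptm <- data$pint_mmHg - data$pext_mmHg
  if (stats::sd(ptm) == 0) stop("degenerate characterization data: constant pressure")
  fit <- stats::lm(ptm ~ fill_ml + I(fill_ml^2), data = data.frame(
    ptm = ptm, fill_ml = data$fill_ml))
  cf <- stats::coef(fit)
  rng <- range(data$fill_ml)
  phantom_model(c2 = unname(cf[3]), c1 = unname(cf[2]), c0 = unname(cf[1]),
                V_0 = V_0, operating_range = rng, label = "fitted")
}

#' Run the hybrid loop with the virtual phantom in place of the LV
#'
#' Couples the closed-loop circulation to the virtual soft robotic phantom at
#' every integration tick: the elastance laws supply the target LV pressure
#' and volume, one pump tracks the target volume with a proportional
#' controller, the second pump applies the external pressure command of
#' [external_pressure_command()], and the achieved internal phantom pressure
#' replaces the LV pressure in the in-silico valve-flow computation (the
#' mitral and aortic valves act in silico; the phantom has none).
#'
#' @inheritParams simulate_loop
#' @param phantom a [phantom_model()]
#' @param actuator an [actuator_model()]
#' @param gain proportional volume-tracking gain in `(0, 1]` (fraction of the
#'   volume error commanded per tick)
#' @param mode external pressure command mode, see
#'   [external_pressure_command()]
#' @return a `cv_run` whose trace carries the additional columns
#'   `Plv_target`, `Vlv_target`, `Pint`, `Pext`, `Q_pump`, `V_ph`,
#'   `saturated`
#' @export
simulate_hybrid <- function(model, phantom, actuator = actuator_model(),
                            n_cycles = 20, transient = 10, gain = 0.8,
                            mode = c("local", "scalar")) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(actuator, "actuator_model"))
  if (gain <= 0 || gain > 1) stop("'gain' must be in (0, 1]")
  run <- simulate_loop(model, n_cycles = n_cycles, transient = transient,
                       integrator = "euler",
                       hybrid = list(phantom = phantom, actuator = actuator,
                                     gain = gain, mode = mode))
  if (isTRUE(run$diagnostics$saturation_flagged))
    warning(sprintf("actuator saturated on %d of %d steps; run flagged",
                    run$diagnostics$saturation_steps, nrow(run$trace)))
  run
}
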