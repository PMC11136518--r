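#' Windkessel vascular bed
#'
#' Three-element Windkessel for one circulation (systemic or pulmonary): a
#' characteristic resistance `R_c` in series upstream of the arterial
#' compliance `C_a`, a peripheral resistance `R_p` draining into a venous
#' compliance `C_v`, and a venous return segment back to the downstream
#' atrium. `R_c + R_p` equals the bed's total resistance implied by the
#' clinical SVR/PVR (unit-converted); a fraction `venous_fraction` of `R_p`
#' is placed downstream of the venous node so that the mean arterial-to-atrial
#' pressure drop recovers the configured total resistance exactly in periodic
#' steady state.
#'
#' @param R_c characteristic resistance (mmHg s/ml)
#' @param R_p peripheral resistance (mmHg s/ml)
#' @param C_a arterial compliance (ml/mmHg)
#' @param C_v venous compliance (ml/mmHg)
#' @param V_u total unstressed volume (ml); bookkeeping only, the integrator
#'   tracks stressed volumes
#' @param venous_fraction fraction of `R_p` placed between the venous node and
#'   the atrium
#' @param label optional name
#' @return an object of class `vascular_bed`
#' @export
vascular_bed <- function(R_c, R_p, C_a, C_v, V_u = 0,
                         venous_fraction = 0.05, label = "bed") {
  if (any(c(R_c, R_p, C_a, C_v) <= 0))
    stop("resistances and compliances must be > 0")
  if (venous_fraction <= 0 || venous_fraction >= 1)
    stop("'venous_fraction' must be in (0, 1)")
  structure(
    list(R_c = R_c, R_p = R_p, C_a = C_a, C_v = C_v, V_u = V_u,
         venous_fraction = venous_fraction, label = label),
    class = "vascular_bed"
  )
}

#' @export
print.vascular_bed <- function(x, ...) {
  cat(sprintf(
    "<vascular_bed '%s'> R_c=%.4g, R_p=%.4g mmHg s/ml; C_a=%.4g, C_v=%.4g ml/mmHg\n",
    x$label, x$R_c, x$R_p, x$C_a, x$C_v))
  invisible(x)
}

#' Cardiac cycle timing
#'
#' @param HR heart rate (bpm), in `[30, 200]`
#' @param dt integration step (s); 0.001 s by default, mirroring the 1-ms
#'   real-time tick of the hybrid bench
#' @return an object of class `cycle_timing`
#' @export
cycle_timing <- function(HR, dt = 0.001) {
  if (HR < 30 || HR > 200) stop("'HR' must be in [30, 200] bpm")
  if (dt <= 0) stop("'dt' must be > 0")
  structure(list(HR = HR, dt = dt, period = 60 / HR), class = "cycle_timing")
}

#' Assemble a closed-loop cardiovascular model
#'
#' Collects the four elastance chambers, the two Windkessel beds, the four
#' diode valves, the cycle timing and the initial compartment volumes into a
#' single parameter object consumed by [simulate_loop()]. Compliance
#' compartments are initialised with *stressed* volumes (pressure = V / C).
#'
#' @param lv,rv,la,ra [elastance_chamber()] objects
#' @param sys,pul [vascular_bed()] objects (systemic, pulmonary)
#' @param valves named list with [valve_model()] entries `mv`, `av`, `tv`, `pv`
#' @param timing a [cycle_timing()]
#' @param init named numeric vector of initial volumes (ml) with names
#'   `Vla, Vlv, Vsa, Vsv, Vra, Vrv, Vpa, Vpv`
#' @return an object of class `cv_model`
#' @export
cv_model <- function(lv, rv, la, ra, sys, pul, valves, timing, init) {
  need <- c("Vla", "Vlv", "Vsa", "Vsv", "Vra", "Vrv", "Vpa", "Vpv")
  if (!all(need %in% names(init)))
    stop("'init' must name all of: ", paste(need, collapse = ", "))
  if (any(init < 0)) stop("initial volumes must be >= 0")
  stopifnot(inherits(timing, "cycle_timing"))
  for (nm in c("mv", "av", "tv", "pv"))
    if (!inherits(valves[[nm]], "valve_model"))
      stop("valves$", nm, " must be a valve_model")
  structure(
    list(lv = lv, rv = rv, la = la, ra = ra, sys = sys, pul = pul,
         valves = valves, timing = timing, init = init[need]),
    class = "cv_model"
  )
}

#' @export
print.cv_model <- function(x, ...) {
  cat(sprintf("<cv_model> HR %.0f bpm, dt %.4g s\n", x$timing$HR, x$timing$dt))
  cat(sprintf("  LV E_s %.3g, RV E_s %.3g mmHg/ml; SVR %.3g, PVR %.3g mmHg min/l\n",
              x$lv$E_s, x$rv$E_s, implied_svr(x), implied_pvr(x)))
  invisible(x)
}

#' Total bed resistance in clinical units
#'
#' `(R_c + R_p)` of the systemic (or pulmonary) bed converted from
#' mmHg s/ml back to the clinical mmHg min/l convention.
#'
#' @param model a [cv_model()]
#' @return resistance (mmHg min/l)
#' @export
implied_svr <- function(model) (model$sys$R_c + model$sys$R_p) / 0.06

#' @rdname implied_svr
#' @export
implied_pvr <- function(model) (model$pul$R_c + model$pul$R_p) / 0.06

trace_columns <- c("time_s", "Plv", "Pao", "Pla", "Prv", "Pra", "PAP",
                   "Psv", "Ppv", "Vlv", "Vrv", "Vla", "Vra",
                   "Q_mv", "Q_av", "Q_pv", "Q_tv", "vc", "Vtot")
hybrid_columns <- c("Plv_target", "Vlv_target", "Pint", "Pext", "Q_pump",
                    "V_ph", "saturated")

#' Advance the closed loop
#'
#' Runs the fixed-step closed-loop simulation for `transient + n_cycles`
#' cardiac cycles and returns the full-resolution traces. The integrator is
#' explicit Euler at the configured step (1 ms by default), mirroring the
#' real-time tick of the hybrid bench; a classical Runge-Kutta 4 option is
#' provided for step-refinement checks. Volume exchange is bookkept exactly:
#' every flow leaves one compartment and enters another, so total blood
#' volume is conserved to rounding error.
#'
#' When `hybrid` is supplied (see [simulate_hybrid()]), the in-silico left
#' ventricle is replaced at every tick by the virtual soft robotic phantom:
#' the elastance laws provide the target pressure for the current LV volume,
#' the two-pump controller drives the phantom, and the *achieved* internal
#' phantom pressure replaces the LV pressure in the mitral/aortic valve-flow
#' computation.
#'
#' @param model a [cv_model()]
#' @param n_cycles number of analysis cycles (`>= 1`)
#' @param transient number of start-up cycles run before the analysis window
#'   (default 10); they are kept in the trace and skipped by [summarize_run()]
#' @param integrator `"euler"` (default) or `"rk4"`; the hybrid loop supports
#'   only `"euler"` (it models a sampled real-time controller)
#' @param hybrid `NULL` for a pure in-silico run, otherwise the context built
#'   by [simulate_hybrid()]
#' @return an object of class `cv_run`: list with `trace` (one row per step),
#'   `model`, `n_cycles`, `transient`, `n_per` (steps per cycle), and
#'   `diagnostics`
#' @examples
#' \donttest{
#' rec <- load_fixture("healthy")
#' run <- simulate_loop(personalize(rec)$model, n_cycles = 2, transient = 3)
#' summarize_run(run, n_cycles = 2)
#' }
#' @export
simulate_loop <- function(model, n_cycles = 20, transient = 10,
                          integrator = c("euler", "rk4"), hybrid = NULL) {
  stopifnot(inherits(model, "cv_model"))
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  if (transient < 0) stop("'transient' must be >= 0")
  integrator <- match.arg(integrator)
  if (!is.null(hybrid) && integrator != "euler")
    stop("the hybrid loop models a sampled real-time controller; use 'euler'")

  dt <- model$timing$dt
  period <- model$timing$period
  n_per <- round(period / dt)
  n_steps <- n_per * (transient + n_cycles)

  # unpack scalars once; the inner loop runs tens of thousands of times
  lv <- model$lv; rv <- model$rv; la <- model$la; ra <- model$ra
  v_on <- lv$activation_onset; v_du <- lv$activation_duration
  a_on <- la$activation_onset; a_du <- la$activation_duration
  R_mv <- model$valves$mv$R_open; R_av <- model$valves$av$R_open
  R_tv <- model$valves$tv$R_open; R_pv <- model$valves$pv$R_open
  Rc_s <- model$sys$R_c; Rc_p <- model$pul$R_c
  Rp1_s <- model$sys$R_p * (1 - model$sys$venous_fraction)
  Rp2_s <- model$sys$R_p * model$sys$venous_fraction
  Rp1_p <- model$pul$R_p * (1 - model$pul$venous_fraction)
  Rp2_p <- model$pul$R_p * model$pul$venous_fraction
  C_sa <- model$sys$C_a; C_sv <- model$sys$C_v
  C_pa <- model$pul$C_a; C_pv <- model$pul$C_v

  chamber_p <- function(ch, V, vc)
    vc * ch$E_s * (V - ch$V_0) + (1 - vc) * ch$a * exp(ch$b * V)

  derivs <- function(t, v, plv_over = NULL) {
    ph_v <- (t / period - v_on) %% 1
    vc_v <- if (ph_v < v_du) 0.5 * (1 - cos(2 * pi * ph_v / v_du)) else 0
    ph_a <- (t / period - a_on) %% 1
    vc_a <- if (ph_a < a_du) 0.5 * (1 - cos(2 * pi * ph_a / a_du)) else 0

    Pla <- chamber_p(la, v[1L], vc_a)
    Plv_native <- chamber_p(lv, v[2L], vc_v)
    Plv <- if (is.null(plv_over)) Plv_native else plv_over
    Psa <- v[3L] / C_sa; Psv <- v[4L] / C_sv
    Pra <- chamber_p(ra, v[5L], vc_a)
    Prv <- chamber_p(rv, v[6L], vc_v)
    Ppa <- v[7L] / C_pa; Ppv <- v[8L] / C_pv

    Q_mv <- if (Pla > Plv) (Pla - Plv) / R_mv else 0
    Q_av <- if (Plv > Psa) (Plv - Psa) / (R_av + Rc_s) else 0
    Q_sa <- (Psa - Psv) / Rp1_s
    Q_sv <- (Psv - Pra) / Rp2_s
    Q_tv <- if (Pra > Prv) (Pra - Prv) / R_tv else 0
    Q_pv <- if (Prv > Ppa) (Prv - Ppa) / (R_pv + Rc_p) else 0
    Q_pa <- (Ppa - Ppv) / Rp1_p
    Q_pu <- (Ppv - Pla) / Rp2_p

    list(dv = c(Q_pu - Q_mv, Q_mv - Q_av, Q_av - Q_sa, Q_sa - Q_sv,
                Q_sv - Q_tv, Q_tv - Q_pv, Q_pv - Q_pa, Q_pa - Q_pu),
         Plv = Plv, Plv_native = Plv_native, Pla = Pla, Pra = Pra, Prv = Prv,
         Pao = Psa + Q_av * Rc_s, PAP = Ppa + Q_pv * Rc_p,
         Psv = Psv, Ppv = Ppv,
         Q_mv = Q_mv, Q_av = Q_av, Q_tv = Q_tv, Q_pv = Q_pv, vc = vc_v)
  }

  # hybrid controller / actuator / phantom state
  hy <- hybrid
  if (!is.null(hy)) {
    V_ph <- model$init[["Vlv"]]          # phantom starts level with the LV
    Q_ach <- 0; Pext_ach <- 0
    sat_count <- 0L
    noise <- if (hy$actuator$noise_sd > 0) {
      if (is.null(hy$actuator$seed))
        stop("a seed is mandatory when actuator noise is enabled")
      rng <- local({ set.seed(hy$actuator$seed)
                     stats::rnorm(n_steps + 1L, 0, hy$actuator$noise_sd) })
      rng
    } else numeric(n_steps + 1L)
  }

  ncol_tr <- length(trace_columns) + if (is.null(hy)) 0L else length(hybrid_columns)
  trace <- matrix(NA_real_, nrow = n_steps + 1L, ncol = ncol_tr)
  colnames(trace) <- c(trace_columns,
                       if (!is.null(hy)) hybrid_columns else NULL)

  v <- unname(model$init)
  for (i in 0:n_steps) {
    t <- i * dt
    if (is.null(hy)) {
      d <- derivs(t, v)
      trace[i + 1L, ] <- c(t, d$Plv, d$Pao, d$Pla, d$Prv, d$Pra, d$PAP,
                           d$Psv, d$Ppv, v[2L], v[6L], v[1L], v[5L],
                           d$Q_mv, d$Q_av, d$Q_pv, d$Q_tv, d$vc, sum(v))
      if (i < n_steps) {
        if (integrator == "euler") {
          v <- v + dt * d$dv
        } else {
          k1 <- d$dv
          k2 <- derivs(t + dt / 2, v + dt / 2 * k1)$dv
          k3 <- derivs(t + dt / 2, v + dt / 2 * k2)$dv
          k4 <- derivs(t + dt, v + dt * k3)$dv
          v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }
    } else {
      # (i) target pressure/volume from the elastance laws at the current LV volume
      ph_v <- (t / period - v_on) %% 1
      vc_v <- if (ph_v < v_du) 0.5 * (1 - cos(2 * pi * ph_v / v_du)) else 0
      Plv_target <- chamber_p(lv, v[2L], vc_v)
      Vlv_target <- v[2L]
      # (ii) two-pump controller: volume-tracking internal pump + Pext command
      Pext_cmd <- external_pressure_command(Plv_target, Vlv_target, hy$phantom,
                                            mode = hy$mode)
      Q_cmd <- hy$gain * (Vlv_target - V_ph) / dt
      act <- hy$actuator
      if (is.finite(act$rate_limit)) {
        dQ <- Q_cmd - Q_ach
        Q_cmd <- Q_ach + sign(dQ) * min(abs(dQ), act$rate_limit * dt)
      }
      if (act$tau > 0) {
        Q_ach <- Q_ach + dt / act$tau * (Q_cmd - Q_ach)
        Pext_ach <- Pext_ach + dt / act$tau * (Pext_cmd - Pext_ach)
      } else {
        Q_ach <- Q_cmd
        Pext_ach <- Pext_cmd
      }
      saturated <- abs(Q_ach) > act$flow_limit
      if (saturated) {
        Q_ach <- sign(Q_ach) * act$flow_limit
        sat_count <- sat_count + 1L
      }
      # (iii) passive phantom: pump flow moves volume, wall law sets Pint
      V_ph <- V_ph + Q_ach * dt
      Pint <- Pext_ach + phantom_transmural(hy$phantom, V_ph - hy$phantom$V_0) +
        noise[i + 1L]
      if (abs(V_ph - Vlv_target) > 20)
        stop(sprintf(paste0("hybrid tracking diverged at t=%.3f s: ",
                            "|V_phantom - V_target| = %.1f ml"),
                     t, abs(V_ph - Vlv_target)))
      # (iv) achieved Pint replaces the virtual LV pressure in the loop
      d <- derivs(t, v, plv_over = Pint)
      trace[i + 1L, ] <- c(t, d$Plv, d$Pao, d$Pla, d$Prv, d$Pra, d$PAP,
                           d$Psv, d$Ppv, v[2L], v[6L], v[1L], v[5L],
                           d$Q_mv, d$Q_av, d$Q_pv, d$Q_tv, d$vc, sum(v),
                           Plv_target, Vlv_target, Pint, Pext_cmd, Q_ach,
                           V_ph, as.numeric(saturated))
      if (i < n_steps) v <- v + dt * d$dv
    }
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      bad <- c("Vla", "Vlv", "Vsa", "Vsv", "Vra", "Vrv", "Vpa", "Vpv")[
        which(!is.finite(v) | v < 0)]
      stop(sprintf("integration failed at t = %.3f s: invalid volume in %s",
                   t + dt, paste(bad, collapse = ", ")))
    }
  }

  diagnostics <- list()
  if (!is.null(hy)) {
    diagnostics$saturation_steps <- sat_count
    diagnostics$saturation_flagged <- sat_count > 0L
  }
  res <- structure(
    list(trace = trace, model = model, n_cycles = n_cycles,
         transient = transient, n_per = n_per, dt = dt,
         hybrid = !is.null(hy), diagnostics = diagnostics),
    class = "cv_run"
  )
  conv <- beat_convergence(res)
  res$diagnostics$max_edv_rel_change <- conv
  if (is.finite(conv) && conv > 0.01)
    warning(sprintf(
      "beat-to-beat EDV still changing by %.2f%% after the transient", conv * 100))
  res
}

#' @export
print.cv_run <- function(x, ...) {
  cat(sprintf("<cv_run%s> %d transient + %d analysis cycles, dt %.4g s (%d samples)\n",
              if (x$hybrid) " hybrid" else "", x$transient, x$n_cycles, x$dt,
              nrow(x$trace)))
  invisible(x)
}

# max relative beat-to-beat change of EDV across post-transient cycles
beat_convergence <- function(run) {
  edv <- per_beat(run, "Vlv", max)
  if (length(edv) < 2) return(NA_real_)
  max(abs(diff(edv)) / edv[-length(edv)])
}

# split the post-transient trace into beats and apply f to column `col`
per_beat <- function(run, col, f) {
  n_per <- run$n_per
  x <- run$trace[, col]
  start <- run$transient * n_per
  vapply(seq_len(run$n_cycles), function(k) {
    idx <- (start + (k - 1L) * n_per + 1L):(start + k * n_per)
    f(x[idx])
  }, numeric(1))
}
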