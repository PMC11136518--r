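#' Clinical hemodynamic record of one patient
#'
#' The measurement set needed to personalize the simulator: heart rate,
#' cardiac output, systemic and pulmonary arterial pressures
#' (systolic/diastolic/mean), right atrial pressure, pulmonary capillary
#' wedge pressure, and CMR-derived ventricular volumes.
#'
#' @param label profile name (e.g. `"HFpEF"`, `"Healthy"`, `"DCM"`)
#' @param HR heart rate (bpm)
#' @param CO cardiac output (l/min)
#' @param sap_sys,sap_dia,sap_mean systemic arterial pressures (mmHg)
#' @param pap_sys,pap_dia,pap_mean pulmonary arterial pressures (mmHg)
#' @param RAP right atrial pressure (mmHg)
#' @param Pwedge pulmonary capillary wedge pressure (mmHg); `NA` if not
#'   measured
#' @param lv_esv,lv_edv left ventricular end-systolic/diastolic volumes (ml)
#' @param rv_esv,rv_edv right ventricular end-systolic/diastolic volumes (ml)
#' @return an object of class `patient_record`
#' @export
patient_record <- function(label, HR, CO, sap_sys, sap_dia, sap_mean,
                           pap_sys, pap_dia, pap_mean, RAP, Pwedge = NA,
                           lv_esv, lv_edv, rv_esv, rv_edv) {
  rec <- list(label = label, HR = HR, CO = CO,
              sap_sys = sap_sys, sap_dia = sap_dia, sap_mean = sap_mean,
              pap_sys = pap_sys, pap_dia = pap_dia, pap_mean = pap_mean,
              RAP = RAP, Pwedge = Pwedge,
              lv_esv = lv_esv, lv_edv = lv_edv,
              rv_esv = rv_esv, rv_edv = rv_edv)
  problems <- character()
  num <- setdiff(names(rec), c("label", "Pwedge"))
  missing_f <- num[!vapply(rec[num], function(x)
    length(x) == 1 && is.numeric(x) && is.finite(x), logical(1))]
  if (length(missing_f))
    problems <- c(problems, paste0("missing or non-numeric field(s): ",
                                   paste(missing_f, collapse = ", ")))
  if (!length(missing_f)) {
    if (rec$CO <= 0) problems <- c(problems, "CO must be > 0")
    if (rec$sap_sys <= rec$sap_dia)
      problems <- c(problems, "systemic systolic pressure must exceed diastolic")
    if (rec$pap_sys <= rec$pap_dia)
      problems <- c(problems, "pulmonary systolic pressure must exceed diastolic")
    if (rec$lv_edv <= rec$lv_esv)
      problems <- c(problems, "LV EDV must exceed LV ESV")
    if (rec$rv_edv <= rec$rv_esv)
      problems <- c(problems, "RV EDV must exceed RV ESV")
    if (rec$HR < 30 || rec$HR > 200)
      problems <- c(problems, "HR must be in [30, 200] bpm")
  }
  if (length(problems))
    stop("invalid patient record '", label, "':\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(rec, class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record '%s'> HR %g bpm, CO %g l/min\n", x$label, x$HR, x$CO))
  cat(sprintf("  SAP %g/%g (%g), PAP %g/%g (%g), RAP %g, Pwedge %s mmHg\n",
              x$sap_sys, x$sap_dia, x$sap_mean, x$pap_sys, x$pap_dia,
              x$pap_mean, x$RAP, ifelse(is.na(x$Pwedge), "/", x$Pwedge)))
  cat(sprintf("  LV %g/%g ml, RV %g/%g ml (ESV/EDV)\n",
              x$lv_esv, x$lv_edv, x$rv_esv, x$rv_edv))
  invisible(x)
}

#' Systemic vascular resistance from a clinical record
#'
#' `SVR = (MAP - RAP) / CO` in the clinical mmHg min/l convention.
#'
#' @param record a [patient_record()]
#' @return resistance (mmHg min/l)
#' @examples
#' rec <- load_fixture("hfpef")
#' compute_svr(rec) # (102 - 15) / 4.1
#' @export
compute_svr <- function(record) {
  if (record$CO <= 0) stop("CO must be > 0")
  (record$sap_mean - record$RAP) / record$CO
}

#' Pulmonary vascular resistance from a clinical record
#'
#' `PVR = (PAPm - Pwedge) / CO` in mmHg min/l.
#'
#' @inheritParams compute_svr
#' @return resistance (mmHg min/l)
#' @export
compute_pvr <- function(record) {
  if (record$CO <= 0) stop("CO must be > 0")
  if (is.na(record$Pwedge))
    stop("Pwedge is missing: supply a left atrial pressure estimate ",
         "(set 'Pwedge' in the record) to compute PVR")
  (record$pap_mean - record$Pwedge) / record$CO
}

#' Fit one ventricle's elastance parameters from a clinical record
#'
#' End-systolic elastance is `E_s = P_es / (ESV - V_0)` with the
#' end-systolic pressure approximated by the side's systolic arterial
#' pressure (systemic for the left ventricle, pulmonary for the right). The
#' diastolic exponential `(a, b)` is solved so that the curve passes through
#' the end-diastolic point `(EDV, EDP)` - EDP approximated by Pwedge (left)
#' or RAP (right) - and through the anchor `(V_0, p_floor)` that makes the
#' two-point exponential fit well-posed. All approximations are recorded in
#' the returned provenance attribute.
#'
#' @inheritParams compute_svr
#' @param side `"left"` or `"right"`
#' @param V_0 zero-pressure filling volume (ml); not clinically identifiable,
#'   defaults to 5 ml
#' @param p_floor diastolic pressure at `V_0` (mmHg), the second anchor of
#'   the exponential fit
#' @return an [elastance_chamber()] with a `provenance` attribute
#' @examples
#' fit_ventricle(load_fixture("hfpef"), "left") # E_s = 172 / (32 - 5)
#' @export
fit_ventricle <- function(record, side = c("left", "right"), V_0 = 5,
                          p_floor = 0.5) {
  side <- match.arg(side)
  if (side == "left") {
    P_es <- record$sap_sys; ESV <- record$lv_esv; EDV <- record$lv_edv
    EDP <- record$Pwedge
    if (is.na(EDP))
      stop("Pwedge is missing: supply a left atrial pressure estimate ",
           "to anchor the LV diastolic fit")
  } else {
    P_es <- record$pap_sys; ESV <- record$rv_esv; EDV <- record$rv_edv
    EDP <- record$RAP
  }
  if (ESV <= V_0) stop("ESV must exceed V_0 (", ESV, " <= ", V_0, ")")
  if (EDP <= p_floor) stop("EDP must exceed the diastolic anchor p_floor")
  E_s <- P_es / (ESV - V_0)
  b <- log(EDP / p_floor) / (EDV - V_0)
  a <- p_floor * exp(-b * V_0)
  T_cycle <- 60 / record$HR
  ch <- elastance_chamber(
    a = a, b = b, E_s = E_s, V_0 = V_0,
    activation_onset = 0,
    activation_duration = systolic_duration(record$HR) / T_cycle,
    label = paste0(record$label, " ", side, " ventricle"))
  attr(ch, "provenance") <- data.frame(
    parameter = c("E_s", "a", "b", "V_0", "P_es", "EDP"),
    provenance = c("fitted", "fitted", "fitted", "literature",
                   "measured (systolic arterial proxy)",
                   if (side == "left") "measured (Pwedge proxy)"
                   else "measured (RAP proxy)"),
    stringsAsFactors = FALSE)
  ch
}

#' Personalize the full simulator on one clinical record
#'
#' Deterministic mapping from a [patient_record()] to a complete simulator
#' parameterization: vascular resistances from the SVR/PVR relations,
#' arterial compliances initialised from stroke volume over pulse pressure,
#' ventricular elastances from [fit_ventricle()], cycle timing from the
#' measured heart rate, and every parameter not identifiable from the record
#' taken from the literature registry. Initial compartment volumes are set so
#' the loop starts near the target operating point. The bed totals satisfy
#' the SVR/PVR closure exactly: `implied_svr(model)` returns
#' `compute_svr(record)` to rounding error.
#'
#' @inheritParams compute_svr
#' @param registry literature-default parameter registry, see
#'   [load_registry()]
#' @return an object of class `personalized_params`: list with `model`
#'   (a [cv_model()]), `record`, `svr`, `pvr` (mmHg min/l), and a
#'   `provenance` data frame tagging every parameter as
#'   measured / fitted / literature
#' @export
personalize <- function(record, registry = load_registry()) {
  stopifnot(inherits(record, "patient_record"))
  reg <- registry
  svr <- compute_svr(record)
  pvr <- compute_pvr(record)

  # clinical mmHg min/l -> mmHg s/ml
  R_tot_s <- svr * 0.06
  R_tot_p <- pvr * 0.06
  sv_l <- record$lv_edv - record$lv_esv
  sv_r <- record$rv_edv - record$rv_esv
  sys_bed <- vascular_bed(
    R_c = reg$rc_fraction * R_tot_s,
    R_p = (1 - reg$rc_fraction) * R_tot_s,
    C_a = sv_l / (record$sap_sys - record$sap_dia),
    C_v = reg$venous_compliance$systemic,
    venous_fraction = reg$venous_fraction, label = "systemic")
  pul_bed <- vascular_bed(
    R_c = reg$rc_fraction * R_tot_p,
    R_p = (1 - reg$rc_fraction) * R_tot_p,
    C_a = sv_r / (record$pap_sys - record$pap_dia),
    C_v = reg$venous_compliance$pulmonary,
    venous_fraction = reg$venous_fraction, label = "pulmonary")

  lv <- fit_ventricle(record, "left",
                      V_0 = reg$ventricle$V_0, p_floor = reg$ventricle$p_floor)
  rv <- fit_ventricle(record, "right",
                      V_0 = reg$ventricle$V_0, p_floor = reg$ventricle$p_floor)

  T_cycle <- 60 / record$HR
  atr <- reg$atrium
  atrial_onset <- (1 - atr$lead) %% 1
  la <- elastance_chamber(a = atr$a, b = atr$b, E_s = atr$E_s, V_0 = atr$V_0,
                          activation_onset = atrial_onset,
                          activation_duration = atr$duration,
                          label = "left atrium")
  ra <- elastance_chamber(a = atr$a, b = atr$b, E_s = atr$E_s, V_0 = atr$V_0,
                          activation_onset = atrial_onset,
                          activation_duration = atr$duration,
                          label = "right atrium")

  valves <- list(mv = valve_model(reg$valves$mitral, "mitral"),
                 av = valve_model(reg$valves$aortic, "aortic"),
                 tv = valve_model(reg$valves$tricuspid, "tricuspid"),
                 pv = valve_model(reg$valves$pulmonary, "pulmonary"))

  off <- reg$venous_pressure_offset
  init <- c(
    Vla = log(max(record$Pwedge, 2) / atr$a) / atr$b,
    Vlv = record$lv_edv,
    Vsa = sys_bed$C_a * record$sap_mean,
    Vsv = sys_bed$C_v * (record$RAP + off),
    Vra = log(max(record$RAP, 2) / atr$a) / atr$b,
    Vrv = record$rv_edv,
    Vpa = pul_bed$C_a * record$pap_mean,
    Vpv = pul_bed$C_v * (record$Pwedge + off))

  model <- cv_model(lv = lv, rv = rv, la = la, ra = ra,
                    sys = sys_bed, pul = pul_bed, valves = valves,
                    timing = cycle_timing(record$HR, reg$dt), init = init)

  prov <- rbind(
    data.frame(parameter = c("HR", "SVR", "PVR"),
               provenance = c("measured", "measured", "measured")),
    data.frame(parameter = c("sys.C_a", "pul.C_a"),
               provenance = "fitted (SV / pulse pressure)"),
    data.frame(parameter = c("sys.C_v", "pul.C_v", "sys.R_c/R_p split",
                             "pul.R_c/R_p split", "valve resistances",
                             "atrial parameters", "ventricle V_0", "p_floor",
                             "dt"),
               provenance = "literature"),
    data.frame(parameter = paste0("lv.", c("E_s", "a", "b")),
               provenance = "fitted"),
    data.frame(parameter = paste0("rv.", c("E_s", "a", "b")),
               provenance = "fitted"))

  structure(list(model = model, record = record, svr = svr, pvr = pvr,
                 provenance = prov, registry = reg, tuning = NULL),
            class = "personalized_params")
}

#' @export
print.personalized_params <- function(x, ...) {
  cat(sprintf("<personalized_params '%s'> SVR %.2f, PVR %.2f mmHg min/l%s\n",
              x$record$label, x$svr, x$pvr,
              if (is.null(x$tuning)) "" else " (tuned)"))
  print(x$model)
  invisible(x)
}

#' Automated tuning of the personalized model
#'
#' Coordinate-descent refinement of the parameters that are not directly
#' identifiable from the clinical record: total circulating stressed volume
#' (split over the venous reservoirs) is adjusted to bring the simulated mean
#' left atrial pressure to the wedge-pressure target, and each arterial
#' compliance is rescaled to match the measured pulse pressure. Ventricular
#' elastances and vascular resistances are measured quantities and are never
#' touched. The loop is deterministic.
#'
#' @param pp a [personalize()]d parameter set
#' @param max_iter maximum coordinate-descent sweeps
#' @param cycles analysis cycles per trial run (short, for speed)
#' @param transient start-up cycles per trial run
#' @param volume_gain update gain (ml per mmHg of wedge-pressure error)
#' @param tol relative tolerance on pulse pressures and wedge target
#' @return the updated `personalized_params` with a `tuning` log
#' @export
tune_model <- function(pp, max_iter = 10, cycles = 3, transient = 6,
                       volume_gain = 30, tol = 0.02) {
  stopifnot(inherits(pp, "personalized_params"))
  rec <- pp$record
  pw_t <- rec$Pwedge
  pp_sys_t <- rec$sap_sys - rec$sap_dia
  pp_pap_t <- rec$pap_sys - rec$pap_dia
  log_rows <- list()
  for (it in seq_len(max_iter)) {
    run <- simulate_loop(pp$model, n_cycles = cycles, transient = transient)
    s <- summarize_run(run, n_cycles = cycles)
    e_pw <- pw_t - s$Pwedge
    e_pps <- (s$sap_sys - s$sap_dia) / pp_sys_t - 1
    e_ppp <- (s$pap_sys - s$pap_dia) / pp_pap_t - 1
    log_rows[[it]] <- data.frame(iter = it, pwedge = s$Pwedge,
                                 pp_sys = s$sap_sys - s$sap_dia,
                                 pp_pap = s$pap_sys - s$pap_dia,
                                 co = s$CO)
    if (abs(e_pw) < max(0.5, tol * pw_t) &&
        abs(e_pps) < tol && abs(e_ppp) < tol) break
    dV <- max(min(volume_gain * e_pw, 150), -150)
    cv_s <- pp$model$sys$C_v; cv_p <- pp$model$pul$C_v
    init <- pp$model$init
    init[["Vsv"]] <- max(init[["Vsv"]] + dV * cv_s / (cv_s + cv_p), 1)
    init[["Vpv"]] <- max(init[["Vpv"]] + dV * cv_p / (cv_s + cv_p), 1)
    pp$model$init <- init
    pp$model$sys$C_a <- pp$model$sys$C_a * max(min(1 + e_pps, 2), 0.5)
    pp$model$pul$C_a <- pp$model$pul$C_a * max(min(1 + e_ppp, 2), 0.5)
  }
  pp$tuning <- do.call(rbind, log_rows)
  pp$provenance <- rbind(pp$provenance, data.frame(
    parameter = c("total stressed volume", "sys.C_a (retuned)",
                  "pul.C_a (retuned)"),
    provenance = "fitted (automated tuning)"))
  pp
}
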