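#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention under
#' which the reported error tables are reproduced; base R's `round()` rounds
#' half to even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Nominal percentage error
#'
#' `|simulated - clinical| / clinical * 100`, reported to one decimal
#' (half-up). Undefined when the clinical value is missing or zero, in which
#' case `NA` is returned (rendered as `"/"` in tables).
#'
#' @param clinical reference clinical value(s)
#' @param simulated simulated/measured value(s)
#' @param digits decimals in the reported error
#' @return percentage error(s); `NA` where undefined
#' @examples
#' nominal_error(4.1, 4.4) # 7.3
#' @export
nominal_error <- function(clinical, simulated, digits = 1) {
  out <- ifelse(is.na(clinical) | clinical == 0 | is.na(simulated),
                NA_real_,
                abs(simulated - clinical) / clinical * 100)
  round_half_up(out, digits)
}

#' Beat-averaged hemodynamic summary
#'
#' Reduces a [simulate_loop()] run to the per-profile summary used for
#' clinical comparison: per-beat extrema and means of the post-transient
#' cycles, averaged across `n_cycles` beats. Cardiac output is the mean
#' aortic valve flow; end-diastolic/end-systolic volumes are the averaged
#' per-beat maxima/minima of the ventricular volume; the wedge-pressure
#' surrogate is the mean left atrial pressure.
#'
#' @param run a `cv_run`
#' @param n_cycles number of post-transient beats to average (default 20)
#' @return an object of class `hemo_summary`
#' @export
summarize_run <- function(run, n_cycles = 20) {
  stopifnot(inherits(run, "cv_run"))
  if (run$n_cycles < n_cycles)
    stop("run contains only ", run$n_cycles,
         " post-transient cycles; need ", n_cycles)
  sub <- run
  sub$transient <- run$transient + (run$n_cycles - n_cycles)
  sub$n_cycles <- n_cycles
  bavg <- function(col, f) mean(per_beat(sub, col, f))
  HR <- run$model$timing$HR
  s <- list(
    CO = bavg("Q_av", mean) * 60 / 1000,                   # l/min
    sap_sys = bavg("Pao", max), sap_dia = bavg("Pao", min),
    sap_mean = bavg("Pao", mean),
    pap_sys = bavg("PAP", max), pap_dia = bavg("PAP", min),
    pap_mean = bavg("PAP", mean),
    Pwedge = bavg("Pla", mean),
    RAP = bavg("Pra", mean),
    lvp_sys = bavg("Plv", max), lvp_dia = bavg("Plv", min),
    rvp_sys = bavg("Prv", max), rvp_dia = bavg("Prv", min),
    lv_esv = bavg("Vlv", min), lv_edv = bavg("Vlv", max),
    rv_esv = bavg("Vrv", min), rv_edv = bavg("Vrv", max),
    n_cycles = n_cycles, HR = HR)
  s$CO_sv <- (s$lv_edv - s$lv_esv) * HR / 1000             # SV x HR cross-check
  structure(s, class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf("<hemo_summary> %d beats averaged, HR %g bpm\n", x$n_cycles, x$HR))
  cat(sprintf("  CO %.2f l/min (SVxHR %.2f)\n", x$CO, x$CO_sv))
  cat(sprintf("  SAP %.0f/%.0f (%.0f), PAP %.0f/%.0f (%.0f) mmHg\n",
              x$sap_sys, x$sap_dia, x$sap_mean,
              x$pap_sys, x$pap_dia, x$pap_mean))
  cat(sprintf("  Pwedge %.1f, RAP %.1f mmHg\n", x$Pwedge, x$RAP))
  cat(sprintf("  LV %.0f/%.0f ml, RV %.0f/%.0f ml (ESV/EDV)\n",
              x$lv_esv, x$lv_edv, x$rv_esv, x$rv_edv))
  invisible(x)
}

#' Recover end-systolic elastance from simulated signals
#'
#' Standard time-varying elastance measurement: the maximum over the
#' post-transient samples of the instantaneous pressure-to-stressed-volume
#' ratio `P(t) / (V(t) - V_0)`, attained at peak activation.
#'
#' @param run a `cv_run`
#' @param side `"left"` or `"right"`
#' @param V_0 zero-pressure filling volume (ml); defaults to the run's
#'   chamber parameter
#' @return elastance (mmHg/ml)
#' @export
recover_elastance <- function(run, side = c("left", "right"), V_0 = NULL) {
  side <- match.arg(side)
  ch <- if (side == "left") run$model$lv else run$model$rv
  if (is.null(V_0)) V_0 <- ch$V_0
  cols <- if (side == "left") c("Plv", "Vlv") else c("Prv", "Vrv")
  tr <- run$trace[-seq_len(run$transient * run$n_per), , drop = FALSE]
  max(tr[, cols[1]] / (tr[, cols[2]] - V_0))
}

summary_quantities <- function() {
  data.frame(
    quantity = c("CO", "sap_sys", "sap_dia", "sap_mean",
                 "pap_sys", "pap_dia", "pap_mean", "Pwedge", "RAP",
                 "lvp_sys", "lvp_dia", "rvp_sys", "rvp_dia",
                 "lv_esv", "lv_edv", "rv_esv", "rv_edv"),
    unit = c("l/min", rep("mmHg", 12), rep("ml", 4)),
    category = c("flow", rep("pressure", 12), rep("volume", 4)),
    systemic_arterial = c(FALSE, TRUE, TRUE, TRUE, rep(FALSE, 13)),
    stringsAsFactors = FALSE)
}

record_values <- function(record) {
  c(CO = record$CO, sap_sys = record$sap_sys, sap_dia = record$sap_dia,
    sap_mean = record$sap_mean, pap_sys = record$pap_sys,
    pap_dia = record$pap_dia, pap_mean = record$pap_mean,
    Pwedge = if (is.na(record$Pwedge)) NA_real_ else record$Pwedge,
    RAP = record$RAP, lvp_sys = NA_real_, lvp_dia = NA_real_,
    rvp_sys = record$pap_sys, rvp_dia = NA_real_,
    lv_esv = record$lv_esv, lv_edv = record$lv_edv,
    rv_esv = record$rv_esv, rv_edv = record$rv_edv)
}

#' Clinical-vs-simulated comparison table
#'
#' Builds the per-profile grid of clinical value, simulated value, and
#' nominal percentage error for every summary quantity. Missing clinical
#' values propagate as `NA` errors (printed `"/"`). Right-ventricular
#' systolic pressure is compared against the pulmonary systolic pressure
#' (same clinical catheter); clinical left-ventricular pressures are not
#' measured and carry no error.
#'
#' @param records named list of [patient_record()]s (names = profile labels)
#' @param summaries named list of [summarize_run()] results (or lists with
#'   the same fields), matching `records` by name
#' @return a `data.frame` with columns `profile`, `quantity`, `unit`,
#'   `category`, `clinical`, `simulated`, `error_pct`
#' @export
build_table <- function(records, summaries) {
  if (!setequal(names(records), names(summaries)) || is.null(names(records)))
    stop("profile labels of 'records' and 'summaries' do not match")
  q <- summary_quantities()
  out <- lapply(names(records), function(lab) {
    rec <- records[[lab]]; s <- summaries[[lab]]
    cl <- record_values(rec)[q$quantity]
    sim <- vapply(q$quantity, function(nm)
      if (is.null(s[[nm]])) NA_real_ else s[[nm]], numeric(1))
    data.frame(profile = lab, q,
               clinical = unname(cl), simulated = unname(sim),
               error_pct = nominal_error(unname(cl), unname(sim)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pretty-print a comparison table
#'
#' @param table output of [build_table()]
#' @return invisibly, the formatted character matrix
#' @export
format_table <- function(table) {
  fmt <- function(x) ifelse(is.na(x), "/", formatC(x, format = "g"))
  m <- cbind(profile = table$profile, quantity = table$quantity,
             unit = table$unit, clinical = fmt(table$clinical),
             simulated = fmt(round_half_up(table$simulated, 1)),
             `error %` = fmt(table$error_pct))
  print(as.data.frame(m), row.names = FALSE)
  invisible(m)
}

#' KPI pass/fail ledger
#'
#' Checks every comparable error against the agreement thresholds: 20% for
#' volumetric quantities and 10% for pressures and flows. Systemic arterial
#' pressure is excluded from the pass/fail decision (it is simulated in a
#' single lumped compartment while the clinical reference is a radial-artery
#' measurement) and listed explicitly as excluded, as are rows without a
#' clinical reference.
#'
#' @param table output of [build_table()]
#' @param pressure_threshold percent threshold for pressures/flows
#' @param volume_threshold percent threshold for volumes
#' @return a `data.frame` ledger with columns `profile`, `quantity`,
#'   `error_pct`, `threshold`, `excluded`, `pass`, plus an attribute
#'   `overall` (TRUE when every non-excluded comparison passes)
#' @export
kpi_check <- function(table, pressure_threshold = 10, volume_threshold = 20) {
  thr <- ifelse(table$category == "volume", volume_threshold,
                pressure_threshold)
  excluded <- table$systemic_arterial | is.na(table$error_pct)
  pass <- ifelse(excluded, NA, table$error_pct <= thr)
  ledger <- data.frame(profile = table$profile, quantity = table$quantity,
                       error_pct = table$error_pct, threshold = thr,
                       excluded = excluded, pass = pass,
                       stringsAsFactors = FALSE)
  attr(ledger, "overall") <- all(ledger$pass[!ledger$excluded])
  ledger
}
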