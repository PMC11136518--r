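#' Locate a packaged data file
#'
#' @param ... path components under `inst/extdata`
#' @return absolute path
#' @keywords internal
extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "hemoloop", mustWork = FALSE)
  if (p == "") stop("packaged file not found: ", file.path(...))
  p
}

# stable short hash of a plain configuration object (polynomial over the
# serialized bytes); embedded in every output file for reproducibility checks
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 7
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a patient record from YAML
#'
#' Expected schema (units in key names):
#' `label`, `hr_bpm`, `co_l_min`, `systemic_arterial_mmHg`
#' (`systolic`/`diastolic`/`mean`), `pulmonary_arterial_mmHg` (same),
#' `rap_mmHg`, `pwedge_mmHg` (optional), `lv_ml` (`esv`/`edv`),
#' `rv_ml` (`esv`/`edv`). Schema violations are reported with field-level
#' messages.
#'
#' @param path YAML file
#' @return a [patient_record()]
#' @export
load_record <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("label", "hr_bpm", "co_l_min", "systemic_arterial_mmHg",
            "pulmonary_arterial_mmHg", "rap_mmHg", "lv_ml", "rv_ml")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("record file '", basename(path), "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sub <- function(block, keys, nm) {
    m <- setdiff(keys, names(y[[block]]))
    if (length(m))
      stop("record file '", basename(path), "': '", block,
           "' is missing subfield(s): ", paste(m, collapse = ", "),
           call. = FALSE)
    y[[block]][keys]
  }
  sa <- sub("systemic_arterial_mmHg", c("systolic", "diastolic", "mean"))
  pa <- sub("pulmonary_arterial_mmHg", c("systolic", "diastolic", "mean"))
  lv <- sub("lv_ml", c("esv", "edv"))
  rv <- sub("rv_ml", c("esv", "edv"))
  patient_record(
    label = y$label, HR = y$hr_bpm, CO = y$co_l_min,
    sap_sys = sa$systolic, sap_dia = sa$diastolic, sap_mean = sa$mean,
    pap_sys = pa$systolic, pap_dia = pa$diastolic, pap_mean = pa$mean,
    RAP = y$rap_mmHg,
    Pwedge = if (is.null(y$pwedge_mmHg)) NA else y$pwedge_mmHg,
    lv_esv = lv$esv, lv_edv = lv$edv, rv_esv = rv$esv, rv_edv = rv$edv)
}

#' Write a patient record to YAML
#'
#' Inverse of [load_record()]; `load_record(write_record(x, f))` restores
#' `x` exactly.
#'
#' @param record a [patient_record()]
#' @param path output YAML file
#' @return `path`, invisibly
#' @export
write_record <- function(record, path) {
  y <- list(
    label = record$label, hr_bpm = record$HR, co_l_min = record$CO,
    systemic_arterial_mmHg = list(systolic = record$sap_sys,
                                  diastolic = record$sap_dia,
                                  mean = record$sap_mean),
    pulmonary_arterial_mmHg = list(systolic = record$pap_sys,
                                   diastolic = record$pap_dia,
                                   mean = record$pap_mean),
    rap_mmHg = record$RAP,
    lv_ml = list(esv = record$lv_esv, edv = record$lv_edv),
    rv_ml = list(esv = record$rv_esv, edv = record$rv_edv))
  if (!is.na(record$Pwedge)) y$pwedge_mmHg <- record$Pwedge
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Packaged patient profiles
#'
#' The three reference profiles shipped with the package (`"hfpef"`,
#' `"healthy"`, `"dcm"`), holding the clinical measurement sets of the bench
#' validation: a heart-failure-with-preserved-ejection-fraction patient, a
#' healthy volunteer, and a dilated-cardiomyopathy patient. The healthy
#' profile's wedge pressure was not measured clinically; the record carries
#' the bench personalization target of 10 mmHg.
#'
#' @param name one of `"hfpef"`, `"healthy"`, `"dcm"`
#' @return a [patient_record()]
#' @export
load_fixture <- function(name = c("hfpef", "healthy", "dcm")) {
  name <- match.arg(name)
  load_record(extdata_path(paste0(name, ".yaml")))
}

#' @rdname load_fixture
#' @return `list_fixtures()`: character vector of available profile names
#' @export
list_fixtures <- function() c("hfpef", "healthy", "dcm")

#' Literature parameter registry
#'
#' Versioned registry of the simulator parameters not identifiable from a
#' clinical record (valve resistances, atrial properties, venous
#' compliances, resistance split fractions, numerical step). Values are
#' tagged `literature` in the personalization provenance.
#'
#' @param path optional path to a registry YAML; defaults to the packaged one
#' @return named list
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("registry.yaml")
  reg <- yaml::read_yaml(path)
  need <- c("dt", "rc_fraction", "venous_fraction", "venous_pressure_offset",
            "valves", "venous_compliance", "atrium", "ventricle")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry is missing field(s): ", paste(miss, collapse = ", "))
  reg
}

#' Read / write a phantom model as JSON
#'
#' @param path JSON file
#' @return [read_phantom()]: a [phantom_model()]
#' @export
read_phantom <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_model(c2 = y$c2, c1 = y$c1, c0 = y$c0, V_0 = y$V_0, C = y$C,
                label = if (is.null(y$label)) "phantom" else y$label)
}

#' @rdname read_phantom
#' @param phantom a [phantom_model()]
#' @export
write_phantom <- function(phantom, path) {
  jsonlite::write_json(
    list(label = phantom$label, c2 = phantom$c2, c1 = phantom$c1,
         c0 = phantom$c0, V_0 = phantom$V_0, C = phantom$C,
         config_hash = config_hash(unclass(phantom))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Packaged synthetic phantom models
#'
#' One synthetic quadratic wall law per profile (the bench phantoms'
#' individual regression coefficients are not published; these are
#' constructed to sit in the measured compliance range, with the unstressed
#' volume equal to the profile's end-systolic LV volume). Filenames carry
#' the `_synthetic` suffix.
#'
#' @inheritParams load_fixture
#' @return a [phantom_model()]
#' @export
load_phantom_fixture <- function(name = c("hfpef", "healthy", "dcm")) {
  name <- match.arg(name)
  read_phantom(extdata_path(paste0("phantom_", name, "_synthetic.json")))
}

#' Read / write characterization data as CSV
#'
#' Columns `pext_mmHg`, `fill_ml`, `pint_mmHg`; order-free (parsed by
#' header). Lines starting with `#` are metadata comments.
#'
#' @param path CSV file
#' @return [read_characterization()]: a `characterization_data` data frame
#' @export
read_characterization <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  need <- c("pext_mmHg", "fill_ml", "pint_mmHg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("characterization CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- d[, need]
  class(out) <- c("characterization_data", "data.frame")
  out
}

#' @rdname read_characterization
#' @param data a `characterization_data` data frame
#' @export
write_characterization <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", config_hash(as.list(data))), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' Write simulation traces as CSV
#'
#' One row per integration step with header
#' `time_s,Plv,Pao,Pla,Prv,Pra,PAP,Vlv,Vrv,Q_mv,Q_av,Q_pv,Q_tv` (hybrid runs
#' append the phantom/controller columns). The first line is a `#` comment
#' embedding the configuration hash.
#'
#' @param run a `cv_run`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(run, path) {
  cols <- c("time_s", "Plv", "Pao", "Pla", "Prv", "Pra", "PAP",
            "Vlv", "Vrv", "Q_mv", "Q_av", "Q_pv", "Q_tv")
  if (run$hybrid) cols <- c(cols, hybrid_columns)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", config_hash(run$model[
    c("timing", "init")])), con)
  utils::write.csv(as.data.frame(run$trace[, cols]), con, row.names = FALSE)
  invisible(path)
}

#' Write / read a beat-averaged summary as JSON
#'
#' @param summary a `hemo_summary`
#' @param path JSON file
#' @return `path` invisibly; [read_summary()] returns a `hemo_summary`
#' @export
write_summary <- function(summary, path) {
  x <- unclass(summary)
  x$config_hash <- config_hash(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config_hash <- NULL
  structure(x, class = "hemo_summary")
}

#' Reference bench-validation tables
#'
#' The published clinical / bench comparison for the three profiles:
#' `"hemodynamics"` is the full clinical-vs-simulated grid (clinical value,
#' simulated value, reported one-decimal error), `"echo"` the
#' echocardiographic LV volume comparison. The `determinable` column flags
#' cells whose reported error is exactly reproducible from the two printed
#' values under half-up rounding; the few cells where it is not (the source
#' rounded internal values before reporting) are flagged `FALSE`.
#'
#' @param which `"hemodynamics"` or `"echo"`
#' @return a `data.frame`
#' @export
load_reference_table <- function(which = c("hemodynamics", "echo")) {
  which <- match.arg(which)
  utils::read.csv(extdata_path(paste0("reference_", which, ".csv")),
                  stringsAsFactors = FALSE)
}
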