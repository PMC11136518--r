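# shared fixtures built in code; short runs keep the suite fast

fixture_records <- function() {
  recs <- lapply(list_fixtures(), load_fixture)
  names(recs) <- vapply(recs, `[[`, "", "label")
  recs
}

# personalized model for one profile, memoised across tests
.model_cache <- new.env(parent = emptyenv())
cached_personalized <- function(name) {
  if (is.null(.model_cache[[name]]))
    .model_cache[[name]] <- personalize(load_fixture(name))
  .model_cache[[name]]
}

cached_run <- function(name, n_cycles = 6, transient = 8) {
  key <- paste(name, n_cycles, transient, sep = "_")
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- simulate_loop(cached_personalized(name)$model,
                                         n_cycles = n_cycles,
                                         transient = transient)
  .model_cache[[key]]
}

# linear-law phantom with known scalar compliance
linear_phantom <- function(C = 2, V_0 = 0)
  phantom_model(c2 = 0, c1 = 1 / C, c0 = 0, V_0 = V_0)

# summary-shaped named vector holding a record's clinical values, used to
# exercise the comparison table with known-zero errors
record_values_for_test <- function(record) {
  c(CO = record$CO, sap_sys = record$sap_sys, sap_dia = record$sap_dia,
    sap_mean = record$sap_mean, pap_sys = record$pap_sys,
    pap_dia = record$pap_dia, pap_mean = record$pap_mean,
    Pwedge = record$Pwedge, RAP = record$RAP,
    rvp_sys = record$pap_sys,
    lv_esv = record$lv_esv, lv_edv = record$lv_edv,
    rv_esv = record$rv_esv, rv_edv = record$rv_edv)
}

# a tiny standalone chamber for closed-form checks
demo_chamber <- function()
  elastance_chamber(a = 0.5, b = 0.03, E_s = 2, V_0 = 10)
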