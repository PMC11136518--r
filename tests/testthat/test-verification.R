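test_that("nominal error matches the reported arithmetic and conventions", {
  expect_equal(nominal_error(4.1, 4.1), 0)
  expect_equal(nominal_error(4.1, 4.4), 7.3)    # reported CO error, HFpEF
  expect_equal(nominal_error(32, 44), 37.5)     # reported echo ESV error
  expect_true(is.na(nominal_error(NA, 5)))
  expect_true(is.na(nominal_error(0, 5)))
  # symmetric under sign of deviation, scale invariant
  expect_equal(nominal_error(100, 90), nominal_error(100, 110))
  expect_equal(nominal_error(7 * 4.1, 7 * 4.4), nominal_error(4.1, 4.4))
  # half-up convention at one decimal
  expect_equal(round_half_up(1.75, 1), 1.8)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(nominal_error(113, 115), 1.8)    # 1.7699 -> 1.8
})

test_that("rounding convention reproduces every determinable reference cell", {
  for (which in c("hemodynamics", "echo")) {
    ref <- load_reference_table(which)
    sim_col <- if (which == "echo") "echo" else "simulated"
    det <- ref[ref$determinable & !is.na(ref$clinical), ]
    got <- nominal_error(det$clinical, det[[sim_col]])
    expect_equal(got, det$printed_error,
                 info = paste(which, "cells:",
                              paste(det$quantity, collapse = ",")))
  }
})

test_that("summaries reduce traces to per-beat extrema and means", {
  run <- cached_run("healthy", n_cycles = 6, transient = 8)
  s <- summarize_run(run, 6)
  expect_s3_class(s, "hemo_summary")
  expect_gt(s$sap_sys, s$sap_dia)
  expect_gt(s$lv_edv, s$lv_esv)
  expect_gt(s$rv_edv, s$rv_esv)
  expect_error(summarize_run(run, 21), "only")
  # constant and sinusoidal closed forms through the same reduction path
  fake <- run
  n <- nrow(fake$trace)
  tt <- fake$trace[, "time_s"]
  fake$trace[, "Pao"] <- 100
  fake$trace[, "Vlv"] <- 80 + 30 * sin(2 * pi * tt / fake$model$timing$period)
  sf <- summarize_run(fake, 6)
  expect_equal(sf$sap_sys, 100); expect_equal(sf$sap_dia, 100)
  expect_equal(sf$sap_mean, 100)
  expect_equal(sf$lv_edv, 110, tolerance = 1e-4)
  expect_equal(sf$lv_esv, 50, tolerance = 1e-4)
})

test_that("summaries are invariant to whole-cycle shifts of the window", {
  run <- cached_run("healthy", n_cycles = 6, transient = 8)
  s1 <- summarize_run(run, 4)               # last 4 beats
  shifted <- run
  shifted$transient <- run$transient + 1    # same beats, shifted by one cycle
  shifted$n_cycles <- run$n_cycles - 1
  s2 <- summarize_run(shifted, 4)
  expect_equal(s1$CO, s2$CO)
  expect_equal(s1$lv_edv, s2$lv_edv)
})

test_that("comparison tables propagate errors and missing clinical cells", {
  recs <- fixture_records()
  # identical simulated and clinical values: all defined errors are zero
  selfsum <- lapply(recs, function(r) {
    v <- as.list(record_values_for_test(r))
    v$lvp_sys <- 120; v$lvp_dia <- 8; v$rvp_dia <- 5
    v
  })
  tab <- build_table(recs, selfsum)
  defined <- !is.na(tab$clinical)
  expect_true(all(tab$error_pct[defined] == 0))
  # clinical "/" rows (LV pressures; healthy Pwedge is present in fixture)
  expect_true(all(is.na(tab$error_pct[tab$quantity %in%
                                        c("lvp_sys", "lvp_dia")])))
  expect_error(build_table(recs, unname(selfsum)), "labels")
})

test_that("KPI ledger applies 10/20% thresholds with the stated exclusions", {
  recs <- fixture_records()["HFpEF"]
  s <- as.list(record_values_for_test(recs$HFpEF))
  s$lv_esv <- recs$HFpEF$lv_esv * 1.199     # 19.9% volume error: pass
  s$RAP <- recs$HFpEF$RAP * 1.15            # 15% pressure error: fail
  s$sap_sys <- recs$HFpEF$sap_sys * 1.5     # excluded despite 50% error
  tab <- build_table(recs, list(HFpEF = s))
  led <- kpi_check(tab)
  expect_true(led$pass[led$quantity == "lv_esv"])
  expect_false(led$pass[led$quantity == "RAP"])
  expect_true(led$excluded[led$quantity == "sap_sys"])
  expect_false(attr(led, "overall"))
  s$lv_esv <- recs$HFpEF$lv_esv * 1.201     # 20.1%: fail
  led2 <- kpi_check(build_table(recs, list(HFpEF = s)))
  expect_false(led2$pass[led2$quantity == "lv_esv"])
  # all-zero errors pass overall
  led3 <- kpi_check(build_table(recs, list(HFpEF =
    as.list(record_values_for_test(recs$HFpEF)))))
  expect_true(attr(led3, "overall"))
})

test_that("reference bench columns pass volume KPIs and flag systemic pressures", {
  ref <- load_reference_table("hemodynamics")
  recs <- fixture_records()
  sums <- lapply(names(recs), function(lab) {
    sub <- ref[ref$profile == lab, ]
    stats::setNames(as.list(sub$simulated), sub$quantity)
  })
  names(sums) <- names(recs)
  led <- kpi_check(build_table(recs, sums))
  vol <- led[grepl("esv|edv", led$quantity) & !led$excluded, ]
  expect_true(all(vol$pass))
  expect_true(all(led$excluded[led$quantity %in%
                                 c("sap_sys", "sap_dia", "sap_mean")]))
})
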