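test_that("SVR and PVR match the clinical arithmetic", {
  recs <- fixture_records()
  expect_equal(compute_svr(recs$HFpEF), (102 - 15) / 4.1)    # 21.22
  expect_equal(compute_svr(recs$Healthy), (94 - 11) / 4.9)   # 16.94
  expect_equal(compute_pvr(recs$HFpEF), (39 - 23) / 4.1)     # 3.90
  expect_equal(compute_pvr(recs$DCM), (17 - 10) / 4.3)       # 1.63
  r0 <- recs$HFpEF; r0$RAP <- r0$sap_mean
  expect_equal(compute_svr(r0), 0)
  r0$Pwedge <- r0$pap_mean
  expect_equal(compute_pvr(r0), 0)
  r0$Pwedge <- NA
  expect_error(compute_pvr(r0), "left atrial pressure")
})

test_that("ventricular elastance fit follows the stated rule", {
  rec <- load_fixture("hfpef")
  lv <- fit_ventricle(rec, "left", V_0 = 5)
  expect_equal(lv$E_s, 172 / (32 - 5))        # 6.37 mmHg/ml
  expect_equal(lv$E_s, 6.37, tolerance = 1e-3)
  # diastolic curve passes through both anchors
  expect_equal(diastolic_pressure(lv, rec$lv_edv), rec$Pwedge)
  expect_equal(diastolic_pressure(lv, lv$V_0), 0.5)
  # unit stressed volume: E_s equals P_es
  r1 <- rec; r1$lv_esv <- 6; r1$lv_edv <- 93
  expect_equal(fit_ventricle(r1, "left", V_0 = 5)$E_s, r1$sap_sys)
  r2 <- rec; r2$lv_esv <- 4
  expect_error(fit_ventricle(r2, "left", V_0 = 5), "ESV")
})

test_that("fit recovers known parameters from generated PV points", {
  # generate end-systolic / end-diastolic points from a known chamber whose
  # diastolic law passes through the p_floor anchor, then fit
  for (b in c(0.02, 0.035, 0.05)) {
    V_0 <- 5; E_s <- 2.4; ESV <- 60; EDV <- 150
    a <- 0.5 * exp(-b * V_0)
    rec <- patient_record(
      label = "synthetic", HR = 70, CO = 5,
      sap_sys = E_s * (ESV - V_0), sap_dia = 60,
      sap_mean = 90, pap_sys = 30, pap_dia = 10, pap_mean = 18,
      RAP = 8, Pwedge = a * exp(b * EDV),
      lv_esv = ESV, lv_edv = EDV, rv_esv = 60, rv_edv = 140)
    fit <- fit_ventricle(rec, "left", V_0 = V_0)
    expect_equal(fit$E_s, E_s, tolerance = 1e-10)
    expect_equal(fit$a, a, tolerance = 1e-10)
    expect_equal(fit$b, b, tolerance = 1e-10)
  }
})

test_that("personalization is deterministic and closes on SVR/PVR exactly", {
  rec <- load_fixture("dcm")
  p1 <- personalize(rec)
  p2 <- personalize(rec)
  expect_identical(p1$model, p2$model)
  expect_equal(implied_svr(p1$model), compute_svr(rec), tolerance = 1e-12)
  expect_equal(implied_pvr(p1$model), compute_pvr(rec), tolerance = 1e-12)
})

test_that("every personalized parameter carries a provenance tag", {
  pp <- cached_personalized("hfpef")
  expect_true(all(nzchar(pp$provenance$provenance)))
  expect_setequal(unique(sub(" .*", "", pp$provenance$provenance)),
                  c("measured", "fitted", "literature"))
})

test_that("invalid records are rejected with all problems enumerated", {
  expect_error(
    patient_record("bad", HR = 70, CO = -1, sap_sys = 80, sap_dia = 90,
                   sap_mean = 85, pap_sys = 30, pap_dia = 10, pap_mean = 18,
                   RAP = 8, Pwedge = 12, lv_esv = 90, lv_edv = 80,
                   rv_esv = 50, rv_edv = 120),
    "CO must be > 0.*systolic pressure must exceed.*EDV must exceed")
})

test_that("increasing SVR at fixed elastances raises simulated MAP", {
  pp <- cached_personalized("healthy")
  m_hi <- pp$model
  m_hi$sys$R_c <- m_hi$sys$R_c * 1.4
  m_hi$sys$R_p <- m_hi$sys$R_p * 1.4
  s_lo <- summarize_run(cached_run("healthy", 4, 6), 4)
  s_hi <- summarize_run(simulate_loop(m_hi, 4, transient = 6), 4)
  expect_gt(s_hi$sap_mean, s_lo$sap_mean)
})

test_that("simulated signals recover the personalization inputs within 5%", {
  pp <- cached_personalized("hfpef")
  run <- cached_run("hfpef")
  s <- summarize_run(run, 6)
  expect_equal((s$sap_mean - s$RAP) / s$CO, pp$svr, tolerance = 0.05)
  expect_equal((s$pap_mean - s$Pwedge) / s$CO, pp$pvr, tolerance = 0.05)
  expect_equal(recover_elastance(run, "left"), pp$model$lv$E_s,
               tolerance = 0.05)
  expect_equal(recover_elastance(run, "right"), pp$model$rv$E_s,
               tolerance = 0.05)
})

test_that("automated tuning drives wedge pressure and pulse pressures to target", {
  pp <- tune_model(cached_personalized("dcm"), max_iter = 10)
  rec <- pp$record
  s <- summarize_run(simulate_loop(pp$model, 4, transient = 6), 4)
  expect_lt(abs(s$Pwedge - rec$Pwedge), 1.5)
  expect_lt(abs((s$sap_sys - s$sap_dia) / (rec$sap_sys - rec$sap_dia) - 1), 0.1)
  # measured quantities are never touched by tuning
  expect_identical(pp$model$lv$E_s, cached_personalized("dcm")$model$lv$E_s)
  expect_equal(implied_svr(pp$model), pp$svr, tolerance = 1e-12)
})
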