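# independent oracle: locate a downward threshold crossing by exhaustive scan
# over a very dense resampled grid (no interpolation)
brute_crossing <- function(time, series, thr, after, dt = 0.005) {
  tt <- seq(min(time), max(time), by = dt)
  ss <- approx(time, series, xout = tt)$y
  idx <- which(tt > after & ss <= thr)
  if (!length(idx)) NA_real_ else tt[idx[1]]
}

test_that("piecewise-linear fixtures yield their constructed AP biomarkers", {
  fx <- make_trace_fixtures(seed = 1)
  ap <- ap_biomarkers(fx$linear_ap)
  # geometry: rise -85 -> +35 over 0.2 ms, linear fall over 300 ms
  expect_equal(ap$APD90, 270, tolerance = 0.5 / 270)
  expect_equal(ap$APD40, 120, tolerance = 0.5 / 120)
  expect_equal(ap$APD50, 150, tolerance = 0.5 / 150)
  expect_equal(ap$Tri90_40, ap$APD90 - ap$APD40)   # identity, exact
  expect_equal(ap$Vpeak, 35, tolerance = 1e-6)
  expect_equal(ap$RMP, -85, tolerance = 1e-6)
  ct <- cat_biomarkers(fx$linear_ap)
  expect_equal(ct$CTD50, 250, tolerance = 0.5 / 250)
  expect_equal(ct$CTD90, 450, tolerance = 0.5 / 450)
  bm <- trace_biomarkers(fx$linear_ap)
  expect_equal(bm$EMw, bm$CTD90 - bm$APD90)        # identity, exact
  expect_equal(bm$EMw, 180, tolerance = 1 / 180)
})

test_that("interpolated crossings agree with a brute-force dense scan", {
  fx <- make_trace_fixtures(seed = 2)
  for (tr in fx[c("linear_ap", "noisy")]) {
    ap <- ap_biomarkers(tr)
    up <- which.max(diff(tr$v) / diff(tr$time))
    t_up <- tr$time[up]
    vpeak <- max(tr$v); rmp <- tr$v[1]
    for (xx in c(40, 90)) {
      thr <- vpeak - xx / 100 * (vpeak - rmp)
      t_brute <- brute_crossing(tr$time, tr$v, thr, tr$time[which.max(tr$v)])
      expect_equal(ap[[paste0("APD", xx)]], t_brute - t_up,
                   tolerance = 0.2 / 100)  # within one sample spacing
    }
    ct <- cat_biomarkers(tr)
    ca_pk <- max(tr$cai); dia <- tr$cai[1]
    thr <- ca_pk - 0.9 * (ca_pk - dia)
    t_brute <- brute_crossing(tr$time, tr$cai, thr,
                              tr$time[which.max(tr$cai)])
    expect_equal(ct$CTD90, t_brute - t_up, tolerance = 0.2 / 450)
  }
})

test_that("EMw arithmetic and undefinedness rules hold", {
  expect_equal(emw(data.frame(APD90 = 270, CTD90 = 450)), 180)
  expect_equal(emw(data.frame(APD90 = 300, CTD90 = 300)), 0)
  expect_equal(emw(data.frame(APD90 = 450, CTD90 = 270)), -180) # may be negative
  expect_true(is.na(emw(data.frame(APD90 = NA_real_, CTD90 = 450))))
  # EMw is NA on abnormal beats even when the durations exist
  fx <- make_trace_fixtures()
  bm <- trace_biomarkers(fx$ead)
  expect_true(bm$RA)
  expect_true(is.na(bm$EMw))
})

test_that("abnormality detector classifies the constructed phenotypes", {
  fx <- make_trace_fixtures(seed = 3)
  expect_false(detect_abnormalities(fx$linear_ap)$ra)
  expect_false(detect_abnormalities(fx$linear_ap)$da)
  # small-amplitude noise must not trigger the detector
  expect_false(detect_abnormalities(fx$noisy)$ra)
  expect_false(detect_abnormalities(fx$noisy)$da)
  # a 15-mV secondary depolarisation at 80% repolarisation is an RA
  expect_true(detect_abnormalities(fx$ead)$ra)
  expect_false(detect_abnormalities(fx$ead)$da)
  # failure to repolarise before the next stimulus is an RA
  expect_true(detect_abnormalities(fx$non_repolarising)$ra)
  # no upstroke is a DA, not an RA
  ab <- detect_abnormalities(fx$no_upstroke)
  expect_true(ab$da); expect_false(ab$ra)
  # an elevated diastolic start vs control is a carried-over RA
  elev <- fx$linear_ap
  elev$v <- elev$v + 40
  expect_true(detect_abnormalities(elev, control_rmp = -85)$ra)
  expect_false(detect_abnormalities(elev, control_rmp = -85)$da)
})

test_that("biomarkers are invariant to time shift and common voltage offset", {
  fx <- make_trace_fixtures(seed = 4)
  base <- trace_biomarkers(fx$linear_ap)
  shifted <- as_paced_trace(fx$linear_ap$time + 137, fx$linear_ap$v,
                            cai = fx$linear_ap$cai, cl = 1000)
  bs <- trace_biomarkers(shifted)
  offset <- as_paced_trace(fx$linear_ap$time, fx$linear_ap$v + 12,
                           cai = fx$linear_ap$cai, cl = 1000)
  bo <- trace_biomarkers(offset)
  for (nm in c("APD40", "APD50", "APD90", "Tri90_40", "CTD50", "CTD90", "EMw")) {
    expect_equal(bs[[nm]], base[[nm]], tolerance = 1e-8)
    expect_equal(bo[[nm]], base[[nm]], tolerance = 1e-8)
  }
  expect_equal(bo$RMP, base$RMP + 12)
})

test_that("delta biomarkers use the model's own control with sign convention", {
  ctrl <- data.frame(APD90 = 300, CTD90 = 500, EMw = 200)
  drug <- data.frame(APD90 = 390, CTD90 = 510, EMw = 120)
  d <- delta_biomarkers(ctrl, drug)
  expect_equal(d$dAPD90, 30)
  expect_equal(d$dEMw, -40)      # shortening is negative
  expect_equal(d$dCTD90, 2)
  # invalid inputs and degenerate denominators give NA
  expect_true(is.na(delta_biomarkers(ctrl, data.frame(APD90 = NA, CTD90 = 1,
                                                      EMw = NA))$dEMw))
  tiny <- data.frame(APD90 = 300, CTD90 = 300.5, EMw = 0.5)
  expect_true(is.na(delta_biomarkers(tiny, drug)$dEMw))
})
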