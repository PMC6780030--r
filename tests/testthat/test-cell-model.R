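test_that("constructors validate their invariants", {
  expect_error(ionic_scalings(sKr = -0.1), ">= 0")
  expect_error(block_fractions(IKr = 1.2), "\\[0,1\\]")
  expect_error(stimulus_protocol(cl = 0), "> 0")
  expect_error(stimulus_protocol(beats = 0), "beat")
  expect_error(solver_settings(dt_min = 0), "solver")
  expect_equal(unname(ionic_scalings()), rep(1, 9))
  expect_equal(unname(block_fractions()), rep(0, 7))
})

test_that("the resting model is near a fixed point and errors on bad states", {
  st <- baseline_control()$final_state   # diastolic, post steady-state pacing
  d <- ord_rhs(st)
  # no stimulus: every state derivative is tiny on its own scale
  expect_lt(abs(d[["v"]]), 0.05)              # mV/ms
  expect_lt(max(abs(d[10:38])), 1e-3)         # gates, per ms
  expect_lt(abs(d[["cai"]]), 1e-6)            # mM/ms
  bad <- st; bad[["cai"]] <- NaN
  expect_error(ord_rhs(bad), "cai")
})

test_that("conductance scaling and block act multiplicatively on the currents", {
  st <- baseline_control()$final_state
  st[["v"]] <- -20  # mid-repolarisation state where all currents flow
  cur0 <- attr(ord_rhs(st), "currents")
  # full L-type block zeroes the ICaL family exactly
  curb <- attr(ord_rhs(st, blocks = block_fractions(ICaL = 1)), "currents")
  expect_identical(unname(curb[c("ICaL", "ICaNa", "ICaK")]), c(0, 0, 0))
  # s_X * (1 - b_X) scales the targeted current linearly, leaves others alone
  cur2 <- attr(ord_rhs(st, scalings = ionic_scalings(sKr = 0.8),
                       blocks = block_fractions(IKr = 0.5)), "currents")
  expect_equal(cur2[["IKr"]], 0.4 * cur0[["IKr"]])
  expect_equal(cur2[["IK1"]], cur0[["IK1"]])
  cur3 <- attr(ord_rhs(st, scalings = ionic_scalings(sNCX = 1.7)), "currents")
  expect_equal(cur3[["INaCa_i"]], 1.7 * cur0[["INaCa_i"]])
})

test_that("paced simulation is deterministic and respects state invariants", {
  r1 <- simulate_paced(protocol = stimulus_protocol(beats = 3),
                       solver = fast_solver())
  r2 <- simulate_paced(protocol = stimulus_protocol(beats = 3),
                       solver = fast_solver())
  expect_identical(r1$v, r2$v)           # bit-reproducible
  expect_identical(r1$final_state, r2$final_state)
  fs <- r1$final_state
  gates <- fs[10:38]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(fs[c("cai", "cass", "cansr", "cajsr", "nai", "ki")] > 0))
  expect_true(all(diff(r1$time) > 0))
  expect_equal(length(r1$time), length(r1$v))
  expect_equal(length(r1$time), length(r1$cai))
})

test_that("zero-amplitude stimulus leaves the membrane at rest", {
  st <- baseline_control()$final_state
  r <- simulate_paced(protocol = stimulus_protocol(beats = 2, stim_amp = 0),
                      init = st, solver = fast_solver())
  expect_lt(max(abs(r$v - r$v[1])), 3)  # stays within a few mV of rest
})

test_that("IKr block prolongs and ICaL block shortens the baseline APD90", {
  ctrl <- baseline_control()
  a0 <- baseline_biomarkers()$APD90
  prot <- stimulus_protocol(beats = 20)
  apd_under <- function(b) {
    ap_biomarkers(simulate_paced(blocks = b, protocol = prot,
                                 init = ctrl$final_state,
                                 solver = fast_solver()))$APD90
  }
  kr <- sapply(c(0, 0.25, 0.5), function(x) apd_under(block_fractions(IKr = x)))
  expect_true(all(diff(kr) > 0))         # monotone prolongation
  cal <- sapply(c(0, 0.5), function(x) apd_under(block_fractions(ICaL = x)))
  expect_true(all(diff(cal) < 0))        # monotone shortening
  expect_gt(kr[3], a0)
})

test_that("two integration routes agree: Rush-Larsen adaptive vs plain Euler", {
  # forward-Euler reference driven entirely through the exported RHS at a
  # tiny fixed step, over the upstroke and early plateau of one beat
  st <- baseline_control()$final_state
  dt <- 0.002; t_end <- 60
  x <- as.numeric(st)
  nm <- names(st)
  for (k in seq_len(t_end / dt)) {
    tnow <- (k - 1) * dt
    d <- ord_rhs(stats::setNames(x, nm), Ist = if (tnow < 0.5) -80 else 0)
    x <- x + dt * as.numeric(d)
  }
  ref_v <- x[1]
  r <- simulate_paced(protocol = stimulus_protocol(beats = 1),
                      init = st,
                      solver = solver_settings(0.001, 0.1, 0.02))
  v60 <- approx(r$time, r$v, xout = t_end)$y
  expect_lt(abs(v60 - ref_v), 0.5)  # mV, at the plateau
})

test_that("halving the step bounds moves APD90 by less than 1 ms", {
  st <- baseline_control()$final_state
  prot <- stimulus_protocol(beats = 20)  # let solver-transition transients settle
  b1 <- trace_biomarkers(simulate_paced(protocol = prot, init = st,
                                        solver = solver_settings()))
  b2 <- trace_biomarkers(simulate_paced(protocol = prot, init = st,
                                        solver = solver_settings(0.0025, 0.5, 0.1)))
  expect_lt(abs(b1$APD90 - b2$APD90), 1)
  expect_lt(abs(b1$CTD90 - b2$CTD90), 1)
})

test_that("integration failures are flagged, never silent", {
  expect_warning(
    r <- simulate_paced(scalings = ionic_scalings(sNa = 1e8, sCaL = 1e6),
                        protocol = stimulus_protocol(beats = 3),
                        model_id = "doomed"),
    "doomed")
  expect_false(r$ok)
  expect_gt(r$fail_beat, 0)
})

test_that("traces round-trip through the CSV + JSON sidecar format", {
  tr <- simulate_paced(protocol = stimulus_protocol(beats = 2),
                       solver = fast_solver(), model_id = "rt")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$v, tr$v, tolerance = 1e-12)
  expect_equal(back$cai, tr$cai, tolerance = 1e-12)
  expect_equal(back$model_id, "rt")
  expect_equal(back$protocol$cl, tr$protocol$cl)
})

test_that("model states round-trip through JSON", {
  st <- baseline_control()$final_state
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_model_state(st, path)
  back <- read_model_state(path)
  expect_equal(back, st, tolerance = 1e-12)
  expect_identical(names(back), names(st))
})
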