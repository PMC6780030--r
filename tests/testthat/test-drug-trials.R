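test_that("pore-block arithmetic matches the Hill model", {
  expect_equal(block_fraction(1, 1, 1), 0.5)       # C = IC50, any h
  expect_equal(block_fraction(5, 5, 3.7), 0.5)
  expect_equal(block_fraction(0, 2, 1), 0)         # no drug, no block
  expect_equal(block_fraction(3, 1, 1), 0.75)      # 1 - 1/(1+3)
  expect_error(block_fraction(1, 0, 1), "> 0")
  expect_error(block_fraction(1, 1, -2), "> 0")
  # monotone in concentration; monotone in h above the IC50
  cs <- c(0, 0.5, 1, 2, 4, 8, 100)
  expect_true(all(diff(block_fraction(cs, 2, 1.3)) >= 0))
  hs <- c(0.5, 1, 2, 4)
  expect_true(all(diff(sapply(hs, function(h) block_fraction(3, 1, h))) > 0))
  expect_true(all(diff(sapply(hs, function(h) block_fraction(0.3, 1, h))) < 0))
})

test_that("drug records convert to per-channel blocks at EFTPCmax multiples", {
  inert <- drug_record("water", eftpc_max = 1, category = "unlisted")
  expect_equal(unname(drug_to_blocks(inert, 100)), rep(0, 7))
  # verapamil-like balance: ~25% IKr and ~40% ICaL block at 3x EFTPCmax
  vera <- drug_record("verapamil-like",
                      channels = list(IKr = c(ic50 = 9, h = 1),
                                      ICaL = c(ic50 = 4.5, h = 1)),
                      eftpc_max = 1, category = "NC")
  b3 <- drug_to_blocks(vera, 3)
  expect_equal(b3[["IKr"]], 0.25, tolerance = 0.01)
  expect_equal(b3[["ICaL"]], 0.40, tolerance = 0.01)
  # Hill monotonicity carries over: 100x blocks at least as much as 1x
  b1 <- drug_to_blocks(vera, 1); b100 <- drug_to_blocks(vera, 100)
  expect_true(all(b100 >= b1))
  expect_error(drug_record("x", channels = list(IKr = c(ic50 = -1, h = 1)),
                           eftpc_max = 1, category = "known"), "> 0")
  expect_error(drug_record("x", channels = list(IKx = c(ic50 = 1, h = 1)),
                           eftpc_max = 1, category = "known"), "unknown")
})

test_that("compendia round-trip through the long CSV schema", {
  comp <- make_compendium(seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_compendium(comp, path)
  back <- read_compendium(path)
  expect_setequal(names(back), names(comp))
  for (nm in names(comp)) {
    expect_equal(back[[nm]]$eftpc_max, comp[[nm]]$eftpc_max)
    expect_equal(back[[nm]]$category, comp[[nm]]$category)
    expect_equal(back[[nm]]$channels, comp[[nm]]$channels, tolerance = 1e-9)
  }
  df <- read.csv(path)
  expect_true(all(c("name", "channel", "ic50_uM", "hill", "eftpc_max_uM",
                    "tdp_category") %in% names(df)))
  expect_error(read_compendium(textConnection("a,b\n1,2")), "columns")
})

test_that("an inert compound leaves the population untouched", {
  pop <- tiny_population()
  inert <- drug_record("inert", eftpc_max = 1, category = "unlisted")
  tr <- run_drug_trial(pop, inert, multiples = c(1, 10), beats = 10)
  expect_equal(tr$summary$nRA, c(0, 0))
  expect_equal(tr$summary$nEMw, c(0, 0))
  # only residual pacing drift: medians indistinguishable from zero
  expect_lt(max(abs(tr$summary$median_dEMw)), 1.5)
  expect_lt(max(abs(tr$summary$median_dAPD90)), 1.5)
  expect_equal(classify_risk(tr, "RA_plus_EMw", multiple = 10)$call, "safe")
  expect_equal(classify_risk(tr, "RA_only", multiple = 10)$call, "safe")
})

test_that("a single-model trial equals a direct paced simulation", {
  pop <- tiny_population()
  one <- structure(list(scalings = pop$scalings[1, , drop = FALSE],
                        biomarkers = pop$biomarkers[1, , drop = FALSE],
                        states = pop$states[1, , drop = FALSE],
                        accepted = TRUE, reject_reason = "accepted",
                        provenance = pop$provenance),
                   class = "ap_population")
  drug <- drug_record("herg", channels = list(IKr = c(ic50 = 1, h = 1)),
                      eftpc_max = 1, category = "known")
  trial <- run_drug_trial(one, drug, multiples = 3, beats = 25)
  direct <- simulate_paced(
    scalings = as.numeric(one$scalings[1, names(sampling_ranges())]),
    blocks = drug_to_blocks(drug, 3),
    protocol = stimulus_protocol(beats = 25),
    init = one$states[1, ])
  bm <- trace_biomarkers(direct, control_rmp = one$biomarkers$RMP[1])
  expect_equal(trial$per_model$APD90, bm$APD90, tolerance = 1e-10)
  expect_equal(trial$per_model$EMw, bm$EMw, tolerance = 1e-10)
  dl <- delta_biomarkers(one$biomarkers[1, ], bm)
  expect_equal(trial$per_model$dEMw, dl$dEMw, tolerance = 1e-10)
})

test_that("trial bookkeeping partitions the population exactly", {
  pop <- tiny_population()
  herg <- drug_record("herg", channels = list(IKr = c(ic50 = 1, h = 1)),
                      eftpc_max = 1, category = "known")
  tr <- run_drug_trial(pop, herg, multiples = c(1, 30), beats = 40)
  for (k in seq_len(nrow(tr$summary))) {
    s <- tr$summary[k, ]
    pm <- tr$per_model[tr$per_model$multiple == s$multiple, ]
    # RA models + models with a valid EMw + other-invalid models = n_tot
    expect_equal(s$nRA + sum(!is.na(pm$EMw)) +
                   sum(is.na(pm$EMw) & !(pm$RA %in% TRUE)), s$n_tot)
    expect_lte(s$nRA + s$nEMw, s$n_tot)
  }
  # RA models never contribute an EMw value (disjoint counts)
  expect_true(all(is.na(tr$per_model$EMw[tr$per_model$RA])))
})

test_that("IKr block dominance and ICaL compensation shape the trial outcome", {
  pop <- tiny_population()
  herg <- drug_record("pure_herg", channels = list(IKr = c(ic50 = 1, h = 1)),
                      eftpc_max = 1, category = "known")
  mixed <- drug_record("herg_cal",
                       channels = list(IKr = c(ic50 = 1, h = 1),
                                       ICaL = c(ic50 = 1, h = 1)),
                       eftpc_max = 1, category = "NC")
  t_h <- run_drug_trial(pop, herg, multiples = c(1, 3), beats = 80)
  t_m <- run_drug_trial(pop, mixed, multiples = c(1, 3), beats = 80)
  # a pure hERG blocker prolongs APD90 and shortens the EMw
  expect_gt(t_h$summary$median_dAPD90[1], 0)
  expect_lt(t_h$summary$median_dEMw[1], 0)
  # matched ICaL block attenuates the EMw shortening at every multiple
  expect_true(all(t_m$summary$median_dEMw > t_h$summary$median_dEMw))
})

test_that("the block grid marks undefined summaries instead of dropping them", {
  pop <- tiny_population()
  g <- block_scan(pop, levels = c(0, 1), channels = "ICaL", beats = 10)
  # full L-type block abolishes the Ca2+ transient: EMw medians undefined
  row1 <- g[g$bICaL == 1, ]
  expect_true(is.na(row1$median_dEMw))
  expect_equal(row1$n_valid_emw, 0)
  # the control cell is present with (near-)zero medians
  row0 <- g[g$bICaL == 0, ]
  expect_equal(row0$frac_RA, 0)
  expect_lt(abs(row0$median_dAPD90), 1.5)
})
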