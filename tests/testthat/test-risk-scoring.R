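test_that("TdP score reproduces the hand-evaluated worked example and extremes", {
  # two concentrations {1x, 10x}, n_tot = 4, weights {1, 0.1}:
  # (1*1 + 0.1*4) / (4 * 1.1) = 7/22
  expect_equal(tdp_score(n_ra = c(0, 2), n_emw = c(1, 2),
                         multiples = c(1, 10), n_tot = 4), 7 / 22)
  # no model ever affected -> 0; every model affected at every dose -> 1
  m <- c(1, 3, 10, 30, 100)
  expect_equal(tdp_score(rep(0, 5), rep(0, 5), m, 107), 0)
  expect_equal(tdp_score(c(50, 80, 100, 107, 107), c(57, 27, 7, 0, 0), m, 107), 1)
})

test_that("TdP score is monotone, bounded, and weight-scale invariant", {
  m <- c(1, 3, 10, 30, 100)
  set.seed(11)
  for (rep in 1:25) {
    n_tot <- sample(4:107, 1)
    n_ra <- sapply(seq_along(m), function(i) sample(0:n_tot, 1))
    n_emw <- sapply(seq_along(m), function(i) sample(0:(n_tot - n_ra[i]), 1))
    s <- tdp_score(n_ra, n_emw, m, n_tot)
    expect_gte(s, 0); expect_lte(s, 1)
    # monotone non-decreasing in every count that can still grow
    i <- sample(seq_along(m), 1)
    if (n_ra[i] + n_emw[i] < n_tot) {
      bump <- n_ra; bump[i] <- bump[i] + 1
      expect_gte(tdp_score(bump, n_emw, m, n_tot), s)
    }
    # rescaling all concentrations rescales all weights: score invariant
    expect_equal(tdp_score(n_ra, n_emw, 10 * m, n_tot), s)
    # combined criterion never scores below RA-only on identical trials
    expect_gte(s, tdp_score(n_ra, rep(0, 5), m, n_tot))
  }
  expect_error(tdp_score(c(5), c(6), 1, 10), "exceeds")
})

test_that("prediction metrics recompute exactly from the confusion counts", {
  calls <- data.frame(
    drug = sprintf("d%02d", 1:40),
    call = c(rep("risky", 27), rep("safe", 3),     # 30 true positives' worth
             rep("safe", 9), rep("risky", 1)),     # 10 truly safe compounds
    category = c(rep("known", 22), rep("possible", 4), rep("conditional", 4),
                 rep("NC", 3), rep("unlisted", 7)))
  mt <- prediction_metrics(calls)
  expect_equal(mt$TP, 27); expect_equal(mt$FN, 3)
  expect_equal(mt$TN, 9); expect_equal(mt$FP, 1)
  expect_equal(mt$accuracy, 0.90)
  expect_equal(mt$sensitivity, 27 / 30)
  expect_equal(mt$specificity, 9 / 10)
  expect_equal(mt$ppv, 27 / 28)
  expect_equal(mt$npv, 9 / 12)
  # exact integer identity, no floating slack
  expect_identical(mt$accuracy * (mt$TP + mt$TN + mt$FP + mt$FN),
                   as.numeric(mt$TP + mt$TN))
  # a perfect classifier scores 1 on all five metrics
  perfect <- data.frame(drug = c("a", "b"), call = c("risky", "safe"),
                        category = c("known", "NC"))
  pm <- prediction_metrics(perfect)
  expect_true(all(unlist(pm[c("sensitivity", "specificity", "accuracy",
                              "ppv", "npv")]) == 1))
  expect_error(prediction_metrics(data.frame(drug = "x", call = "safe",
                                             category = NA)), "truth")
})

test_that("log-modulus transform is odd, zero-fixing and base-10", {
  expect_equal(log_modulus(0), 0)
  expect_equal(log_modulus(99), 2)
  x <- c(0.5, 3, 42, 1234)
  expect_equal(log_modulus(-x), -log_modulus(x))
  expect_true(all(diff(log_modulus(c(-100, -10, 0, 10, 100))) > 0))
})

test_that("risk classification follows the stated criteria and boundaries", {
  fake_trial <- function(n_ra, med, n_tot = 107, multiple = 10) {
    structure(list(
      drug = drug_record("x", eftpc_max = 1, category = "known"),
      multiples = multiple,
      per_model = NULL,
      summary = data.frame(n_tot = n_tot, nRA = n_ra, nDA = 0,
                           n_valid_emw = n_tot - n_ra,
                           nEMw = 0, frac_RA = n_ra / n_tot,
                           frac_EMw_short = 0, frac_APD90_long = 0,
                           median_dEMw = med, median_dAPD90 = 0,
                           median_dCTD90 = 0, multiple = multiple,
                           concentration_uM = multiple)),
      class = "trial_result")
  }
  # -10% exactly is safe: the criterion is a strict inequality
  expect_equal(classify_risk(fake_trial(0, -10))$call, "safe")
  expect_equal(classify_risk(fake_trial(0, -10.001))$call, "risky")
  # the combined criterion is a disjunction: RA in one model suffices
  tr <- fake_trial(1, -5)
  expect_equal(classify_risk(tr, "RA_plus_EMw")$call, "risky")
  expect_equal(classify_risk(tr, "RA_only")$call, "risky")
  expect_equal(classify_risk(tr, "EMw_only")$call, "safe")
  # >97% RA is risky by construction even without a computable median
  sat <- fake_trial(106, NA_real_)
  expect_equal(classify_risk(sat, "RA_plus_EMw")$call, "risky")
  # degenerate: no median, no RA, below saturation -> explicit error
  degen <- fake_trial(0, NA_real_)
  expect_error(classify_risk(degen, "EMw_only"), "degenerate")
  expect_error(classify_risk(fake_trial(0, -5), multiple = 30), "multiple")
})
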