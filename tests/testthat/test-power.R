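test_that("ceiling effect multiplies gap by recoverable fraction", {
  expect_equal(ceiling_effect(5.92, 0.5), 2.96)
  expect_equal(ceiling_effect(4.2, 1.0), 4.2)
  expect_equal(ceiling_effect(0, 0.5), 0)
  expect_error(ceiling_effect(-1, 0.5), "gap")
  expect_error(ceiling_effect(5, 1.5), "fraction")
  expect_error(ceiling_effect(5, 0), "fraction")
})

test_that("ANCOVA n matches the closed-form z oracle", {
  res <- ancova_total_n(delta = 0.5, sd_followup = 1, rho = 0, power = 0.8)
  oracle <- 2 * (qnorm(0.975) + qnorm(0.8))^2 * 1 * (1 - 0) / 0.25
  expect_equal(res$n_unrounded, oracle)
  expect_equal(res$n_per_arm, 63L)
  expect_equal(res$n_total, 126L)
  # t correction adds one per arm
  expect_equal(ancova_total_n(0.5, 1, 0, power = 0.8, t_correction = TRUE)$n_total, 128L)
  # rho = 0 equals the classical two-sample normal-approximation size
  expect_equal(ancova_total_n(1, 2, 0, power = 0.9)$n_unrounded,
               2 * (qnorm(0.975) + qnorm(0.9))^2 * 4)
})

test_that("sample size is monotone in delta, rho^2, alpha, power and sd", {
  base <- function(...) ancova_total_n(...)$n_unrounded
  expect_lt(base(0.6, 1, 0), base(0.5, 1, 0))
  expect_lt(base(0.5, 1, 0.99), base(0.5, 1, 0))
  expect_lt(base(0.5, 1, -0.8), base(0.5, 1, 0))   # rho enters squared
  expect_lt(base(0.5, 1, 0, alpha = 0.1), base(0.5, 1, 0, alpha = 0.05))
  expect_lt(base(0.5, 1, 0, power = 0.8), base(0.5, 1, 0, power = 0.9))
  expect_lt(base(0.5, 1, 0), base(0.5, 1.5, 0))
})

test_that("90%/80% pre-rounding ratio equals the z-ratio oracle", {
  zr <- (qnorm(0.975) + qnorm(0.9))^2 / (qnorm(0.975) + qnorm(0.8))^2
  for (delta in seq(1.3, 1.8, by = 0.1)) {
    r <- ancova_total_n(delta, 2.5, 0.6, power = 0.9)$n_unrounded /
      ancova_total_n(delta, 2.5, 0.6, power = 0.8)$n_unrounded
    expect_equal(r, zr, tolerance = 1e-12)
  }
  expect_equal(zr, 1.3386, tolerance = 1e-3)
})

test_that("a delta sweep yields strictly decreasing totals at both power levels", {
  tab <- power_table(deltas = seq(1.3, 1.8, by = 0.1), sd_followup = 2.2, rho = 0.7)
  expect_true(all(diff(tab$total_n_power_80) < 0))
  expect_true(all(diff(tab$total_n_power_90) < 0))
  expect_true(all(tab$total_n_power_90 > tab$total_n_power_80))
  expect_true(all(tab$total_n_power_80 %% 2 == 0))  # totals are 2 x per-arm
})

test_that("patient-averaged metrics reduce correctly and recover generator moments", {
  # one lesion per patient: the patient metric equals that lesion's value
  tab <- data.frame(patient_id = sprintf("P%d", 1:8),
                    arm = rep(c("placebo", "active"), 4),
                    tissue = "cgm",
                    baseline = rnorm(8, 30), followup = rnorm(8, 30))
  pam <- patient_average_metric(tab, tissues = "cgm")
  expect_equal(pam$patients$baseline, tab$baseline[match(pam$patients$patient_id, tab$patient_id)])
  expect_equal(pam$n_excluded, 0)

  # identical baseline/follow-up vectors give correlation 1
  tab$followup <- tab$baseline
  expect_equal(patient_average_metric(tab, "cgm")$rho, 1.0)

  # patients without qualifying lesions are excluded, empty errors
  tab$tissue[1:2] <- "wm"
  expect_equal(patient_average_metric(tab, "cgm")$n_excluded, 2)
  expect_error(patient_average_metric(tab, "dgm"), "no qualifying")
})

test_that("placebo (sd, rho) recovered from a simulated cohort match generator-implied values", {
  cfg <- scaled_trial_config(seed = 91, n_patients = 24)
  tr <- simulate_trial(cfg)
  lt <- lesion_unit_table(tr)
  pam <- patient_average_metric(lt, tissues = c("cgm", "dgm"))
  expect_true(is.finite(pam$sd_followup) && pam$sd_followup > 0)
  expect_gt(pam$rho, 0.3)  # shared intercepts force positive correlation
  expect_lt(pam$rho, 1)
  n <- ancova_total_n(1.4, pam$sd_followup, pam$rho)
  expect_gte(n$n_total, 2)
  expect_equal(n$n_total, 2 * n$n_per_arm)
})
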