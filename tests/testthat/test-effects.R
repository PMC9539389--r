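# A small reusable simulated lesion table (degenerate random effects so
# the OLS oracle applies exactly to the data-generating process).
make_flat_table <- function(seed, n_pat = 16, n_les = 4, tau = 0.8, sd = 1) {
  set.seed(seed)
  pat <- data.frame(patient_id = sprintf("P%02d", 1:n_pat),
                    arm = rep(c("placebo", "active"), length.out = n_pat),
                    age_band = rbinom(n_pat, 1, 0.5),
                    gender = rbinom(n_pat, 1, 0.5),
                    centre = rbinom(n_pat, 1, 0.5),
                    edss_band = rbinom(n_pat, 1, 0.5))
  rows <- do.call(rbind, lapply(1:n_pat, function(i) {
    base <- rnorm(n_les, 30, 2)
    fup <- base + tau * (pat$arm[i] == "active") + rnorm(n_les, 0, sd)
    data.frame(as.list(pat[i, ]), lesion_id = sprintf("P%02d_L%d", i, 1:n_les),
               baseline = base, followup = fup)
  }))
  rows
}

test_that("estimates agree with a normal-equations OLS oracle when random effects vanish", {
  tab <- make_flat_table(81)
  eff <- fit_adjusted_difference(tab)
  X <- cbind(1, tab$arm == "active", tab$baseline, tab$age_band,
             tab$gender, tab$centre, tab$edss_band)
  beta <- oracle_ols(tab$followup, X)
  # mixed model with near-zero patient variance approaches the OLS fit
  expect_equal(eff$estimate, beta[2], tolerance = 0.05)
  # forcing the degenerate path reproduces OLS exactly
  eff_ols <- fit_adjusted_difference(tab[!duplicated(tab$patient_id), ],
                                     lesion_intercept = FALSE)
  X1 <- X[!duplicated(tab$patient_id), ]
  y1 <- tab$followup[!duplicated(tab$patient_id)]
  expect_equal(eff_ols$estimate, oracle_ols(y1, X1)[2], tolerance = 1e-8)
  expect_equal(eff_ols$method, "ols")
})

test_that("adjusted difference is invariant to location shifts and row order", {
  tab <- make_flat_table(82)
  eff <- fit_adjusted_difference(tab)
  tab2 <- tab
  tab2$baseline <- tab2$baseline + 12.34
  tab2$followup <- tab2$followup + 12.34
  expect_equal(fit_adjusted_difference(tab2)$estimate, eff$estimate,
               tolerance = 1e-6)
  tab3 <- tab[sample(nrow(tab)), ]
  expect_equal(fit_adjusted_difference(tab3)$estimate, eff$estimate,
               tolerance = 1e-6)
})

test_that("single-arm tables and too-few patients are rejected", {
  tab <- make_flat_table(83)
  expect_error(fit_adjusted_difference(tab[tab$arm == "active", ]), "both arms")
  few <- tab[tab$patient_id %in% c("P01", "P02", "P03"), ]
  expect_error(fit_adjusted_difference(few), ">= 2 patients")
})

test_that("constant covariates are dropped instead of breaking the fit", {
  tab <- make_flat_table(84)
  tab$centre <- 0
  eff <- fit_adjusted_difference(tab)
  expect_true(is.finite(eff$estimate))
  expect_false(grepl("centre", eff$formula))
})

test_that("interaction on two identical subgroups gives equal estimates and p near 1", {
  tab <- make_flat_table(85)
  tab$stratum <- 1L
  dup <- tab
  dup$stratum <- 2L
  dup$lesion_id <- paste0(dup$lesion_id, "b")
  both <- rbind(tab, dup)
  res <- fit_subgroup_interaction(both, "stratum")
  expect_equal(res$subgroups$estimate[1], res$subgroups$estimate[2],
               tolerance = 1e-6)
  expect_gt(res$p_interaction, 0.95)
})

test_that("planted subgroup difference is recovered by the contrasts", {
  set.seed(86)
  tab <- make_flat_table(86, n_pat = 24, n_les = 8, tau = 0)
  tab$stratum <- rep(1:2, length.out = nrow(tab))
  sel <- tab$arm == "active" & tab$stratum == 2
  tab$followup[sel] <- tab$followup[sel] + 2
  res <- fit_subgroup_interaction(tab, "stratum")
  expect_lt(abs(res$subgroups$estimate[1] - 0), 0.6)
  expect_lt(abs(res$subgroups$estimate[2] - 2), 0.6)
  expect_lt(res$p_interaction, 0.01)
})

test_that("subgroups observed in one arm only are flagged", {
  tab <- make_flat_table(87)
  tab$stratum <- rep(1:2, length.out = nrow(tab))
  tab <- tab[!(tab$stratum == 2 & tab$arm == "placebo"), ]
  res <- fit_subgroup_interaction(tab, "stratum")
  expect_false(res$subgroups$flagged[res$subgroups$subgroup == "1"])
  expect_true(res$subgroups$flagged[res$subgroups$subgroup == "2"])
})

test_that("unadjusted summaries match a direct group-by oracle", {
  tab <- make_flat_table(88)
  un <- summarise_unadjusted(tab)
  for (arm in c("placebo", "active")) {
    ch <- tab$followup[tab$arm == arm] - tab$baseline[tab$arm == arm]
    expect_equal(un$mean_change[un$arm == arm], mean(ch))
    expect_equal(un$sd_change[un$arm == arm], sd(ch))
    expect_equal(un$n[un$arm == arm], length(ch))
  }
  one <- summarise_unadjusted(tab[1, ])
  expect_true(is.na(one$sd_change))
  const <- tab
  const$followup <- const$baseline + 1
  uc <- summarise_unadjusted(const)
  expect_equal(uc$mean_change, c(1, 1))
  expect_equal(uc$sd_change, c(0, 0))
})

test_that("effect objects expose coef, confint and printing", {
  tab <- make_flat_table(89)
  eff <- fit_adjusted_difference(tab)
  expect_equal(unname(coef(eff)), eff$estimate)
  ci <- confint(eff)
  expect_equal(unname(ci[1, ]), eff$ci)
  expect_lte(ci[1, 1], eff$estimate)
  expect_gte(ci[1, 2], eff$estimate)
  expect_output(print(eff), "Adjusted active-placebo difference")
  expect_output(print(summary(eff)), "Unadjusted change")
})
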