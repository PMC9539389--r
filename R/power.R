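# ANCOVA sample-size planning for patient-averaged lesional MTR metrics,
# and the remyelination ceiling-effect calculation. Baseline adjustment
# deflates the follow-up variance by (1 - rho^2), rho being the placebo
# baseline/follow-up correlation of the patient-averaged metric.

#' Maximum plausible treatment effect (remyelination ceiling)
#'
#' Complete remyelination cannot raise lesional MTR past normal-appearing
#' white matter, and ex-vivo data suggest only a fraction of the
#' lesion-to-NAWM gap is recoverable; the ceiling is `gap * fraction`.
#'
#' @param lesion_nawm_gap pu difference between mean NAWM and mean
#'   lesional MTR (> 0).
#' @param remyelination_fraction recoverable fraction in (0, 1].
#' @return Maximum treatment effect in pu.
#' @export
ceiling_effect <- function(lesion_nawm_gap, remyelination_fraction) {
  if (!is.finite(lesion_nawm_gap) || lesion_nawm_gap < 0) {
    stop("lesion_nawm_gap must be >= 0", call. = FALSE)
  }
  if (!is.finite(remyelination_fraction) ||
      remyelination_fraction <= 0 || remyelination_fraction > 1) {
    stop("remyelination_fraction must be in (0, 1]", call. = FALSE)
  }
  lesion_nawm_gap * remyelination_fraction
}

ancova_n_unrounded <- function(delta, sd_followup, rho, alpha = 0.05, power = 0.8) {
  stopifnot(delta > 0, sd_followup > 0, rho > -1, rho < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  2 * (za + zb)^2 * sd_followup^2 * (1 - rho^2) / delta^2
}

#' ANCOVA sample size for a two-arm baseline-adjusted comparison
#'
#' Per-arm n is `ceiling(2 (z_{1-alpha/2} + z_power)^2 sigma^2 (1 - rho^2)
#' / delta^2)` using normal-approximation z-values; the total is twice
#' the per-arm ceiling. `t_correction` adds the standard +1 per arm to
#' offset the t-distribution's heavier tails.
#'
#' @param delta target treatment effect (pu, > 0).
#' @param sd_followup placebo follow-up SD of the metric (pu).
#' @param rho placebo baseline/follow-up Pearson correlation.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param t_correction add 1 participant per arm.
#' @return List: `n_per_arm`, `n_total`, `n_unrounded` (pre-rounding
#'   per-arm size) and the inputs.
#' @export
ancova_total_n <- function(delta, sd_followup, rho, alpha = 0.05,
                           power = 0.8, t_correction = FALSE) {
  raw <- ancova_n_unrounded(delta, sd_followup, rho, alpha, power)
  n_arm <- as.integer(ceiling(raw)) + if (isTRUE(t_correction)) 1L else 0L
  list(n_per_arm = n_arm, n_total = 2L * n_arm, n_unrounded = raw,
       delta = delta, sd_followup = sd_followup, rho = rho,
       alpha = alpha, power = power, t_correction = isTRUE(t_correction))
}

#' Sample-size table over a sweep of treatment effects
#'
#' @inheritParams ancova_total_n
#' @param deltas treatment effects to tabulate (pu).
#' @param powers power levels (columns).
#' @return Data frame: one row per delta, total-n column per power level.
#' @export
power_table <- function(deltas = seq(1.3, 1.8, by = 0.1), sd_followup, rho,
                        alpha = 0.05, powers = c(0.8, 0.9),
                        t_correction = FALSE) {
  out <- data.frame(delta = deltas)
  for (p in powers) {
    out[[sprintf("total_n_power_%d", round(100 * p))]] <-
      vapply(deltas, function(d)
        ancova_total_n(d, sd_followup, rho, alpha, p, t_correction)$n_total, 1L)
  }
  out
}

#' Patient-averaged lesional metrics for sample-size planning
#'
#' Averages whole-lesion baseline and follow-up values over each
#' patient's qualifying lesions (patients, not lesions, are randomised),
#' and extracts the placebo arm's follow-up SD and baseline/follow-up
#' Pearson correlation, ready for [ancova_total_n()].
#'
#' @param lesion_tab a [lesion_unit_table()] data frame.
#' @param tissues lesion tissue classes that qualify (default pure GM).
#' @return List: `patients` (per-patient means with arm), `n_excluded`
#'   (patients with no qualifying lesion), `sd_followup`, `rho` (placebo
#'   arm).
#' @export
patient_average_metric <- function(lesion_tab, tissues = c("cgm", "dgm")) {
  tab <- lesion_tab[lesion_tab$tissue %in% tissues, , drop = FALSE]
  all_pat <- unique(lesion_tab$patient_id)
  if (nrow(tab) == 0L) stop("no qualifying lesions in any patient", call. = FALSE)
  sp <- split(tab, tab$patient_id)
  pat <- do.call(rbind, lapply(sp, function(g) {
    data.frame(patient_id = g$patient_id[1L], arm = g$arm[1L],
               n_lesions = nrow(g),
               baseline = mean(g$baseline), followup = mean(g$followup),
               change = mean(g$followup - g$baseline),
               stringsAsFactors = FALSE)
  }))
  rownames(pat) <- NULL
  n_excl <- length(setdiff(all_pat, pat$patient_id))
  if (n_excl > 0L) {
    lmtr_log("power", "%d patient(s) with no qualifying lesion excluded", n_excl)
  }
  plc <- pat[pat$arm == "placebo", , drop = FALSE]
  if (nrow(plc) < 3L) stop("too few placebo patients with qualifying lesions", call. = FALSE)
  list(patients = pat, n_excluded = n_excl,
       sd_followup = stats::sd(plc$followup),
       rho = stats::cor(plc$baseline, plc$followup))
}
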