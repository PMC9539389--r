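# Baseline-adjusted treatment-effect estimation: linear mixed models with
# patient and (for units nested within lesions) lesion random intercepts,
# REML estimation with graceful degradation (ML, then dropping boundary
# variance components, then ordinary least squares), and Satterthwaite
# t / F inference, which reduces to the normal approximation at the large
# unit counts of voxel-level analyses but keeps small-sample type-I error
# calibrated at the patient-level end of the hierarchy.

`%||%` <- function(a, b) if (is.null(a)) b else a

prep_unit_table <- function(table) {
  need <- c("followup", "baseline", "arm", "patient_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("unit table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(table)
  ok <- is.finite(df$followup) & is.finite(df$baseline)
  if (any(!ok)) {
    lmtr_log("fit", "%d unit(s) with non-finite outcome removed", sum(!ok))
    df <- df[ok, , drop = FALSE]
  }
  df$arm <- factor(df$arm, levels = c("placebo", "active"))
  if (nlevels(droplevels(df$arm)) < 2L) {
    stop("both arms must be present in the unit table", call. = FALSE)
  }
  for (arm in levels(df$arm)) {
    if (length(unique(df$patient_id[df$arm == arm])) < 2L) {
      stop(sprintf("need >= 2 patients in the %s arm", arm), call. = FALSE)
    }
  }
  df
}

active_covariates <- function(df) {
  covs <- intersect(unit_covariates, names(df))
  keep <- covs[vapply(covs, function(v) length(unique(df[[v]])) > 1L, TRUE)]
  dropped <- setdiff(covs, keep)
  if (length(dropped)) {
    lmtr_log("fit", "constant covariate(s) dropped: %s", paste(dropped, collapse = ", "))
  }
  keep
}

random_terms <- function(df, lesion_intercept = NULL) {
  terms <- character(0)
  if (anyDuplicated(df$patient_id)) terms <- c(terms, "(1 | patient_id)")
  use_lesion <- lesion_intercept %||%
    ("lesion_id" %in% names(df) &&
       anyDuplicated(df$lesion_id) > 0L &&
       length(unique(df$lesion_id)) > length(unique(df$patient_id)))
  if (isTRUE(use_lesion) && "lesion_id" %in% names(df)) {
    terms <- c(terms, "(1 | lesion_id)")
  }
  terms
}

# Fit with degradation ladder: lmer REML -> lmer ML -> drop boundary
# variance components -> OLS. Returns list(fit, method, notes).
fit_ladder <- function(fixed, rand, df, reml = TRUE) {
  notes <- character(0)
  make_formula <- function(rt) stats::as.formula(
    paste(fixed, if (length(rt)) paste("+", paste(rt, collapse = " + ")) else ""))
  quiet_lmer <- function(fml, use_reml) {
    withCallingHandlers(
      tryCatch(suppressMessages(lmerTest::lmer(fml, data = df, REML = use_reml)),
               error = function(e) e),
      warning = function(w) {
        notes <<- c(notes, paste("lmer:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  rt <- rand
  while (length(rt)) {
    fml <- make_formula(rt)
    fit <- quiet_lmer(fml, reml)
    if (inherits(fit, "error") && reml) {
      notes <- c(notes, "REML fit failed; retrying with ML")
      fit <- quiet_lmer(fml, FALSE)
    }
    if (inherits(fit, "error")) {
      notes <- c(notes, sprintf("mixed fit failed (%s); dropping '%s'",
                                conditionMessage(fit), rt[length(rt)]))
      rt <- rt[-length(rt)]
      next
    }
    if (lme4::isSingular(fit, tol = 1e-5)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      zero <- vc$grp[vc$sdcor < 1e-5 & vc$grp != "Residual"]
      if (length(zero)) {
        drop <- vapply(rt, function(t) any(vapply(zero, function(z)
          grepl(z, t, fixed = TRUE), TRUE)), TRUE)
        if (any(drop)) {
          notes <- c(notes, sprintf("boundary variance component(s) %s at zero; refitting reduced model",
                                    paste(zero, collapse = ", ")))
          rt <- rt[!drop]
          next
        }
      }
      notes <- c(notes, "singular fit retained (no identifiable zero component)")
    }
    return(list(fit = fit, method = if (isTRUE(reml)) "lmer-reml" else "lmer-ml",
                notes = notes))
  }
  fit <- stats::lm(stats::as.formula(fixed), data = df)
  list(fit = fit, method = "ols",
       notes = c(notes, if (length(rand)) "all random terms dropped; ordinary least squares"))
}

# Inference for a single contrast L'beta. Satterthwaite df for mixed
# fits, residual df for OLS. Handles rank-deficient fits by dropping
# inestimable coefficients from L (error if a nonzero weight is dropped).
contrast_inference <- function(res, L_named) {
  fit <- res$fit
  if (inherits(fit, "lm")) {
    b <- stats::coef(fit)
    est_names <- names(b)[!is.na(b)]
    bad <- setdiff(names(L_named)[L_named != 0], est_names)
    if (length(bad)) return(NULL)
    L <- numeric(length(est_names))
    names(L) <- est_names
    L[names(L_named)[names(L_named) %in% est_names]] <-
      L_named[names(L_named) %in% est_names]
    est <- sum(L * b[est_names])
    V <- suppressWarnings(stats::vcov(fit))[est_names, est_names, drop = FALSE]
    se <- sqrt(drop(t(L) %*% V %*% L))
    df <- stats::df.residual(fit)
  } else {
    bn <- names(lme4::fixef(fit))
    bad <- setdiff(names(L_named)[L_named != 0], bn)
    if (length(bad)) return(NULL)
    L <- numeric(length(bn))
    names(L) <- bn
    L[names(L_named)[names(L_named) %in% bn]] <- L_named[names(L_named) %in% bn]
    ct <- tryCatch(lmerTest::contest1D(fit, L, ddf = "Satterthwaite"),
                   error = function(e) NULL)
    if (!is.null(ct)) {
      return(list(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df))
    }
    est <- sum(L * lme4::fixef(fit))
    se <- sqrt(drop(t(L) %*% as.matrix(stats::vcov(fit)) %*% L))
    df <- Inf
  }
  list(estimate = est, se = se, df = df)
}

finish_inference <- function(inf, conf_level) {
  if (!is.finite(inf$se) || inf$se <= 0) {
    return(c(inf, list(lo = inf$estimate, hi = inf$estimate, p = NA_real_)))
  }
  df <- if (is.finite(inf$df) && inf$df > 0) inf$df else Inf
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tval <- inf$estimate / inf$se
  c(inf, list(lo = inf$estimate - tcrit * inf$se,
              hi = inf$estimate + tcrit * inf$se,
              p = 2 * stats::pt(-abs(tval), df)))
}

#' Adjusted treatment difference from a unit table
#'
#' Fits `followup ~ arm + baseline + age_band + gender + centre +
#' edss_band` with a patient random intercept (and a lesion random
#' intercept when units are nested within lesions), REML by default, and
#' returns the active-minus-placebo coefficient with a Satterthwaite
#' t-based 95% CI and two-sided p. Constant covariates are dropped with a
#' log entry; boundary (zero) variance components trigger a logged refit
#' of the reduced model, degrading to ordinary least squares when no
#' grouping structure remains.
#'
#' @param table unit table (see [lesion_unit_table()] and friends):
#'   needs `followup`, `baseline`, `arm`, `patient_id`, optionally
#'   `lesion_id` and the four minimisation covariates.
#' @param lesion_intercept force the lesion random intercept on/off
#'   (`NULL`: include it when units are nested within lesions).
#' @param reml use REML (default) or ML.
#' @param conf_level confidence level.
#' @return Object of class `mtr_effect`.
#' @export
fit_adjusted_difference <- function(table, lesion_intercept = NULL,
                                    reml = TRUE, conf_level = 0.95) {
  df <- prep_unit_table(table)
  covs <- active_covariates(df)
  fixed <- paste("followup ~ arm + baseline",
                 if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "")
  rand <- random_terms(df, lesion_intercept)
  res <- fit_ladder(fixed, rand, df, reml)
  L <- c(armactive = 1)
  inf <- contrast_inference(res, L)
  if (is.null(inf)) stop("arm effect inestimable in this table", call. = FALSE)
  inf <- finish_inference(inf, conf_level)
  structure(list(estimate = inf$estimate, se = inf$se, df = inf$df,
                 ci = c(inf$lo, inf$hi), p = inf$p,
                 conf_level = conf_level,
                 n_active = sum(df$arm == "active"),
                 n_placebo = sum(df$arm == "placebo"),
                 method = res$method, notes = res$notes,
                 formula = fixed, random = rand,
                 unadjusted = summarise_unadjusted(df)),
            class = "mtr_effect")
}

#' @export
print.mtr_effect <- function(x, digits = 3, ...) {
  cat(sprintf("Adjusted active-placebo difference: %.*f pu (%d%% CI %.*f to %.*f), p = %s\n",
              digits, x$estimate, round(100 * x$conf_level),
              digits, x$ci[1], digits, x$ci[2],
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = digits)))
  cat(sprintf("  units: %d active / %d placebo; model: %s%s\n",
              x$n_active, x$n_placebo, x$method,
              if (length(x$random) && x$method != "ols")
                paste0(" with ", paste(x$random, collapse = " + ")) else ""))
  invisible(x)
}

#' @export
coef.mtr_effect <- function(object, ...) c(arm_active = object$estimate)

#' @export
confint.mtr_effect <- function(object, parm, level, ...) {
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("arm_active",
                              sprintf("%.1f %%", 100 * c((1 - object$conf_level) / 2,
                                                         1 - (1 - object$conf_level) / 2))))
  m
}

#' @export
summary.mtr_effect <- function(object, ...) {
  print(object)
  if (!is.null(object$unadjusted)) {
    cat("Unadjusted change (followup - baseline):\n")
    print(object$unadjusted, row.names = FALSE)
  }
  if (length(object$notes)) cat("Notes:", paste(object$notes, collapse = "; "), "\n")
  invisible(object)
}

#' Treatment-by-subgroup interaction analysis
#'
#' Extends the [fit_adjusted_difference()] model with subgroup main
#' effects and arm-by-subgroup terms. Per-subgroup adjusted differences
#' are linear contrasts (arm coefficient plus the subgroup's interaction
#' coefficient); the interaction p-value is the joint Satterthwaite F (or
#' OLS F) test that all arm-by-subgroup terms vanish. Subgroups observed
#' in only one arm are estimated but flagged and excluded from the joint
#' test.
#'
#' @inheritParams fit_adjusted_difference
#' @param factor_col name of the column defining subgroups.
#' @return Object of class `mtr_interaction`: per-subgroup estimates
#'   (`$subgroups` data frame) and `$p_interaction`.
#' @export
fit_subgroup_interaction <- function(table, factor_col,
                                     lesion_intercept = NULL,
                                     reml = TRUE, conf_level = 0.95) {
  df <- prep_unit_table(table)
  if (!factor_col %in% names(df)) {
    stop(sprintf("column '%s' not found", factor_col), call. = FALSE)
  }
  df <- df[!is.na(df[[factor_col]]), , drop = FALSE]
  df$subgroup <- droplevels(factor(df[[factor_col]]))
  if (nlevels(df$subgroup) < 2L) {
    stop("need >= 2 subgroups with units", call. = FALSE)
  }
  covs <- active_covariates(df)
  fixed <- paste("followup ~ arm * subgroup + baseline",
                 if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "")
  rand <- random_terms(df, lesion_intercept)
  res <- fit_ladder(fixed, rand, df, reml)

  levs <- levels(df$subgroup)
  both_arms <- vapply(levs, function(g)
    length(unique(df$arm[df$subgroup == g])) == 2L, TRUE)
  rows <- list()
  joint_names <- character(0)
  for (g in levs) {
    L <- c(armactive = 1)
    iname <- paste0("armactive:subgroup", g)
    if (g != levs[1L]) L[iname] <- 1
    inf <- contrast_inference(res, L)
    flagged <- !both_arms[[g]]
    if (is.null(inf)) {
      rows[[g]] <- data.frame(subgroup = g, estimate = NA_real_, se = NA_real_,
                              df = NA_real_, lo = NA_real_, hi = NA_real_,
                              p = NA_real_, n_active = sum(df$arm == "active" & df$subgroup == g),
                              n_placebo = sum(df$arm == "placebo" & df$subgroup == g),
                              flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    inf <- finish_inference(inf, conf_level)
    rows[[g]] <- data.frame(subgroup = g, estimate = inf$estimate, se = inf$se,
                            df = inf$df, lo = inf$lo, hi = inf$hi, p = inf$p,
                            n_active = sum(df$arm == "active" & df$subgroup == g),
                            n_placebo = sum(df$arm == "placebo" & df$subgroup == g),
                            flagged = flagged, stringsAsFactors = FALSE)
    if (g != levs[1L] && both_arms[[g]] && both_arms[[1L]]) {
      joint_names <- c(joint_names, paste0("armactive:subgroup", g))
    }
  }
  subgroups <- do.call(rbind, rows)
  rownames(subgroups) <- NULL

  joint <- joint_wald(res, joint_names)
  structure(list(factor = factor_col,
                 p_interaction = joint$p, f_value = joint$f,
                 ndf = joint$ndf, ddf = joint$ddf,
                 subgroups = subgroups,
                 method = res$method, notes = res$notes,
                 conf_level = conf_level),
            class = "mtr_interaction")
}

# Joint test that the named coefficients are all zero.
joint_wald <- function(res, coef_names) {
  fit <- res$fit
  est_names <- if (inherits(fit, "lm")) {
    names(stats::coef(fit))[!is.na(stats::coef(fit))]
  } else {
    names(lme4::fixef(fit))
  }
  coef_names <- intersect(coef_names, est_names)
  q <- length(coef_names)
  if (q == 0L) return(list(p = NA_real_, f = NA_real_, ndf = 0L, ddf = NA_real_))
  Lmat <- matrix(0, nrow = q, ncol = length(est_names),
                 dimnames = list(coef_names, est_names))
  for (nm in coef_names) Lmat[nm, nm] <- 1
  if (inherits(fit, "lm")) {
    b <- stats::coef(fit)[est_names]
    V <- suppressWarnings(stats::vcov(fit))[est_names, est_names, drop = FALSE]
    M <- Lmat %*% V %*% t(Lmat)
    w <- tryCatch(drop(t(Lmat %*% b) %*% solve(M, Lmat %*% b)),
                  error = function(e) NA_real_)
    if (!is.finite(w)) return(list(p = NA_real_, f = NA_real_, ndf = q, ddf = NA_real_))
    fstat <- w / q
    ddf <- stats::df.residual(fit)
    return(list(p = stats::pf(fstat, q, ddf, lower.tail = FALSE),
                f = fstat, ndf = q, ddf = ddf))
  }
  ct <- tryCatch(lmerTest::contest(fit, Lmat, joint = TRUE, ddf = "Satterthwaite"),
                 error = function(e) NULL)
  if (!is.null(ct)) {
    return(list(p = ct$`Pr(>F)`, f = ct$`F value`, ndf = ct$NumDF, ddf = ct$DenDF))
  }
  b <- lme4::fixef(fit)[est_names]
  V <- as.matrix(stats::vcov(fit))[est_names, est_names, drop = FALSE]
  M <- Lmat %*% V %*% t(Lmat)
  w <- drop(t(Lmat %*% b) %*% solve(M, Lmat %*% b))
  list(p = stats::pchisq(w, q, lower.tail = FALSE), f = w / q, ndf = q, ddf = Inf)
}

#' @export
print.mtr_interaction <- function(x, digits = 3, ...) {
  cat(sprintf("Treatment-by-%s interaction: p = %s (F = %.3f on %s, %s df)\n",
              x$factor,
              if (is.na(x$p_interaction)) "NA" else format.pval(x$p_interaction, digits = digits),
              x$f_value, format(x$ndf), format(round(x$ddf, 1))))
  print(x$subgroups[, c("subgroup", "estimate", "lo", "hi", "p",
                        "n_active", "n_placebo", "flagged")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mtr_interaction <- function(object, ...) {
  print(object)
  if (length(object$notes)) cat("Notes:", paste(object$notes, collapse = "; "), "\n")
  invisible(object)
}

#' Unadjusted per-arm change summaries
#'
#' Arithmetic mean and SD of `followup - baseline` by arm (and optionally
#' by a subgroup column), with unit counts. SD is `NA` for single-unit
#' groups.
#'
#' @param table unit table with `followup`, `baseline`, `arm`.
#' @param by optional subgroup column name.
#' @return Data frame with `arm` (and `by`), `n`, `mean_change`, `sd_change`.
#' @export
summarise_unadjusted <- function(table, by = NULL) {
  df <- as.data.frame(table)
  df$change <- df$followup - df$baseline
  groups <- if (is.null(by)) list(arm = df$arm) else
    list(arm = df$arm, subgroup = df[[by]])
  agg <- aggregate(df$change, by = groups, FUN = function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n = as.integer(agg$x[, "n"]),
                    mean_change = agg$x[, "mean"],
                    sd_change = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  out
}
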