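# Full analysis grid: whole-lesion, component/segment and voxel levels,
# each by tissue and by stratifying factor, with per-subgroup adjusted
# differences and treatment-by-subgroup interaction tests. Strata with
# insufficient units are skipped and listed, mirroring how sparse strata
# (e.g. DGM distance bands) are handled in practice.

result_row <- function(level, tissue, factor, subgroup, eff, p_int = NA_real_) {
  un <- eff$unadjusted
  g <- function(arm, col) {
    v <- un[un$arm == arm, col]
    if (length(v)) v else NA_real_
  }
  data.frame(level = level, tissue = tissue, factor = factor,
             subgroup = as.character(subgroup),
             n_active = eff$n_active, n_placebo = eff$n_placebo,
             mean_change_active = g("active", "mean_change"),
             sd_change_active = g("active", "sd_change"),
             mean_change_placebo = g("placebo", "mean_change"),
             sd_change_placebo = g("placebo", "sd_change"),
             estimate = eff$estimate, lo = eff$ci[1], hi = eff$ci[2],
             p = eff$p, p_interaction = p_int,
             stringsAsFactors = FALSE)
}

interaction_rows <- function(level, tissue, factor, tab, subgroup_col,
                             lesion_intercept = NULL) {
  res <- fit_subgroup_interaction(tab, subgroup_col,
                                  lesion_intercept = lesion_intercept)
  un <- summarise_unadjusted(tab, by = subgroup_col)
  rows <- lapply(seq_len(nrow(res$subgroups)), function(j) {
    sg <- res$subgroups[j, ]
    g <- function(arm, col) {
      v <- un[un$arm == arm & as.character(un$subgroup) == sg$subgroup, col]
      if (length(v)) v else NA_real_
    }
    data.frame(level = level, tissue = tissue, factor = factor,
               subgroup = sg$subgroup,
               n_active = sg$n_active, n_placebo = sg$n_placebo,
               mean_change_active = g("active", "mean_change"),
               sd_change_active = g("active", "sd_change"),
               mean_change_placebo = g("placebo", "mean_change"),
               sd_change_placebo = g("placebo", "sd_change"),
               estimate = sg$estimate, lo = sg$lo, hi = sg$hi, p = sg$p,
               p_interaction = res$p_interaction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Drop subgroups with too few units or a missing arm; returns the table
# plus a character vector describing removals.
filter_subgroups <- function(tab, subgroup_col, min_units = 4L) {
  sk <- character(0)
  tab <- tab[!is.na(tab[[subgroup_col]]), , drop = FALSE]
  for (g in unique(tab[[subgroup_col]])) {
    sel <- tab[[subgroup_col]] == g
    if (sum(sel) < min_units ||
        length(unique(tab$arm[sel])) < 2L) {
      sk <- c(sk, sprintf("%s=%s (%d units)", subgroup_col, g, sum(sel)))
      tab <- tab[!sel, , drop = FALSE]
    }
  }
  list(tab = tab, skipped = sk)
}

lesion_level_strata <- function(tab, variable, tissue) {
  vals <- switch(variable, mtr = tab$baseline, t1 = tab$t1_baseline,
                 size = as.numeric(tab$size))
  scheme <- if (tissue == "wm") "quartiles" else "median"
  strata <- fit_cutpoints(vals, scheme)
  assign_stratum(vals, strata)
}

#' Run the full treatment-effect analysis grid over a trial
#'
#' Executes whole-lesion analyses (overall by tissue, and stratified by
#' baseline MTR, baseline T1-weighted intensity, lesion size and distance
#' band), component analyses (core, rim, three cuffs), MTR- and
#' T1-defined segment analyses, and voxel-level analyses (overall, by
#' baseline MTR quartile, T1 quartile and band), each with per-subgroup
#' adjusted differences and interaction tests. Pure-WM voxel- and
#' segment-level analyses use outer-layer-stripped voxels; WM lesions use
#' quartile strata and CGM/DGM lesions median splits at the whole-lesion
#' level; DGM band analyses are not run.
#'
#' @param trial an [simulate_trial()] result.
#' @param voxel_cap subsampling cap per voxel table.
#' @param min_units minimum units per subgroup; sparser subgroups are
#'   skipped and listed.
#' @return Object of class `mtr_report`: `$results` data frame (one row
#'   per level x tissue x factor x subgroup) and `$skipped` character
#'   vector of analyses or strata not run.
#' @export
run_analysis_suite <- function(trial, voxel_cap = 20000L, min_units = 4L) {
  band_map <- trial$band_map %||% build_bands(trial$atlas)
  results <- list()
  skipped <- character(0)
  add <- function(x) results[[length(results) + 1L]] <<- x
  skip <- function(what, e) skipped <<- c(skipped,
                                          sprintf("%s: %s", what, conditionMessage(e)))

  lesion_tab <- lesion_unit_table(trial, band_map = band_map)

  # ---- whole-lesion level -------------------------------------------
  overall_groups <- list(wm = "wm", gm = c("cgm", "dgm"),
                         cgm = "cgm", dgm = "dgm")
  for (gname in names(overall_groups)) {
    tab <- lesion_tab[lesion_tab$tissue %in% overall_groups[[gname]], , drop = FALSE]
    if (nrow(tab) == 0L) next
    tryCatch(add(result_row("lesion", gname, "overall", "all",
                            fit_adjusted_difference(tab))),
             error = function(e) skip(paste("lesion", gname, "overall"), e))
  }
  for (tissue in c("wm", "cgm", "dgm")) {
    tab0 <- lesion_tab[lesion_tab$tissue == tissue, , drop = FALSE]
    if (nrow(tab0) < 4L) next
    for (variable in c("mtr", "t1", "size")) {
      what <- paste("lesion", tissue, variable)
      tryCatch({
        tab <- tab0
        tab$stratum <- lesion_level_strata(tab, variable, tissue)
        fs <- filter_subgroups(tab, "stratum", min_units)
        skipped <- c(skipped, if (length(fs$skipped))
          paste(what, fs$skipped))
        add(interaction_rows("lesion", tissue, variable, fs$tab, "stratum"))
      }, error = function(e) skip(what, e))
    }
    # distance band (not for DGM: too few lesions for band analyses)
    if (tissue %in% c("wm", "cgm")) {
      what <- paste("lesion", tissue, "band")
      tryCatch({
        fs <- filter_subgroups(tab0, "band", min_units)
        skipped <- c(skipped, if (length(fs$skipped)) paste(what, fs$skipped))
        add(interaction_rows("lesion", tissue, "band", fs$tab, "band"))
      }, error = function(e) skip(what, e))
    }
  }

  # ---- component level ----------------------------------------------
  comp_tab <- component_unit_table(trial)
  for (tissue in c("wm", "cgm", "dgm")) {
    tab <- comp_tab[comp_tab$tissue == tissue, , drop = FALSE]
    if (is.null(tab) || nrow(tab) == 0L) next
    what <- paste("component", tissue)
    tryCatch({
      tab$component <- factor(tab$component,
                              levels = c("core", "rim", "cuff1", "cuff2", "cuff3"))
      fs <- filter_subgroups(tab, "component", min_units)
      skipped <- c(skipped, if (length(fs$skipped)) paste(what, fs$skipped))
      add(interaction_rows("component", tissue, "component", fs$tab, "component"))
    }, error = function(e) skip(what, e))
  }

  # ---- segment level ------------------------------------------------
  for (tissue in c("wm", "cgm", "dgm")) {
    for (variable in c("mtr", "t1")) {
      what <- paste("segment", tissue, variable)
      tryCatch({
        tab <- segment_unit_table(trial, tissue, variable)
        if (is.null(tab) || nrow(tab) == 0L) stop("no segments")
        fs <- filter_subgroups(tab, "stratum", min_units)
        skipped <- c(skipped, if (length(fs$skipped)) paste(what, fs$skipped))
        add(interaction_rows("segment", tissue, paste0(variable, "_segment"),
                             fs$tab, "stratum"))
      }, error = function(e) skip(what, e))
    }
  }

  # ---- voxel level --------------------------------------------------
  vox_tabs <- list()
  for (tissue in c("wm", "cgm", "dgm")) {
    vox_tabs[[tissue]] <- voxel_unit_table(trial, tissue, cap = voxel_cap,
                                           band_map = band_map)
  }
  gm_tab <- do.call(rbind, vox_tabs[c("cgm", "dgm")])
  for (gname in c("wm", "gm", "cgm", "dgm")) {
    tab <- if (gname == "gm") gm_tab else vox_tabs[[gname]]
    if (is.null(tab) || nrow(tab) == 0L) next
    tryCatch(add(result_row("voxel", gname, "overall", "all",
                            fit_adjusted_difference(tab))),
             error = function(e) skip(paste("voxel", gname, "overall"), e))
  }
  for (tissue in c("wm", "cgm", "dgm")) {
    tab0 <- vox_tabs[[tissue]]
    if (is.null(tab0) || nrow(tab0) < 8L) next
    for (variable in c("mtr", "t1")) {
      what <- paste("voxel", tissue, variable)
      tryCatch({
        tab <- tab0
        vals <- if (variable == "mtr") tab$baseline else tab$t1_baseline
        strata <- fit_cutpoints(vals, "quartiles")
        tab$stratum <- assign_stratum(vals, strata)
        fs <- filter_subgroups(tab, "stratum", min_units)
        skipped <- c(skipped, if (length(fs$skipped)) paste(what, fs$skipped))
        add(interaction_rows("voxel", tissue, paste0(variable, "_quartile"),
                             fs$tab, "stratum"))
      }, error = function(e) skip(what, e))
    }
    if (tissue %in% c("wm", "cgm")) {
      what <- paste("voxel", tissue, "band")
      tryCatch({
        fs <- filter_subgroups(tab0, "band", min_units)
        skipped <- c(skipped, if (length(fs$skipped)) paste(what, fs$skipped))
        add(interaction_rows("voxel", tissue, "band", fs$tab, "band"))
      }, error = function(e) skip(what, e))
    }
  }

  results <- do.call(rbind, results)
  rownames(results) <- NULL
  structure(list(results = results, skipped = skipped),
            class = "mtr_report")
}

#' @export
print.mtr_report <- function(x, digits = 3, ...) {
  cat(sprintf("mtr_report: %d result row(s), %d skipped analysis/strata\n",
              if (is.null(x$results)) 0L else nrow(x$results), length(x$skipped)))
  if (!is.null(x$results)) {
    print(x$results[, c("level", "tissue", "factor", "subgroup",
                        "estimate", "lo", "hi", "p", "p_interaction")],
          digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Render a report as aligned text mirroring the trial-table layout
#'
#' @param report an [run_analysis_suite()] result.
#' @param file optional path; when given the text is written there.
#' @return The text lines, invisibly.
#' @export
render_report <- function(report, file = NULL) {
  r <- report$results
  fmt <- function(v, d = 2) ifelse(is.na(v), "NA", formatC(v, digits = d, format = "f"))
  lines <- c("Adjusted active-placebo differences (pu) by analysis level",
             sprintf("%-9s %-6s %-14s %-10s %6s/%-6s %22s %8s %8s",
                     "level", "tissue", "factor", "subgroup", "n_act", "n_plc",
                     "difference (95% CI)", "p", "p_int"))
  for (j in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%-9s %-6s %-14s %-10s %6d/%-6d %8s (%s, %s) %8s %8s",
      r$level[j], r$tissue[j], r$factor[j], r$subgroup[j],
      r$n_active[j], r$n_placebo[j],
      fmt(r$estimate[j]), fmt(r$lo[j]), fmt(r$hi[j]),
      fmt(r$p[j], 4), fmt(r$p_interaction[j], 4)))
  }
  if (length(report$skipped)) {
    lines <- c(lines, "", "Skipped:", paste(" -", report$skipped))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
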