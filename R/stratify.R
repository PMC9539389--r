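# Cohort-level stratification by baseline MTR or T1-weighted intensity:
# tissue-specific quartile cutpoints (WM) or a median split (CGM/DGM,
# which have too few lesions for quartiles), applied at lesion, segment
# and voxel level. Cutpoints always come from baseline values only.

#' Fit cohort-level stratum cutpoints
#'
#' Empirical quantiles (linear interpolation between order statistics,
#' quantile type 7) at 0.25/0.5/0.75 for quartiles, or 0.5 for a median
#' split, pooled over the cohort within tissue.
#'
#' @param values numeric vector of baseline values.
#' @param scheme `"quartiles"` or `"median"`.
#' @return Object of class `strata_definition`: list with `cuts`
#'   (increasing numeric vector of length 3 or 1), `scheme`, `n`.
#' @export
fit_cutpoints <- function(values, scheme = c("quartiles", "median")) {
  scheme <- match.arg(scheme)
  values <- values[is.finite(values)]
  need <- if (scheme == "quartiles") 4L else 2L
  if (length(values) < need) {
    stop(sprintf("too few values (%d) to fit %s cutpoints",
                 length(values), scheme), call. = FALSE)
  }
  probs <- if (scheme == "quartiles") c(0.25, 0.5, 0.75) else 0.5
  cuts <- unname(stats::quantile(values, probs = probs, type = 7))
  if (any(duplicated(cuts)) || length(unique(values)) == 1L) {
    warning("degenerate cutpoints (tied values); lower strata will absorb ties",
            call. = FALSE)
  }
  structure(list(cuts = cuts, scheme = scheme, n = length(values)),
            class = "strata_definition")
}

#' @export
print.strata_definition <- function(x, ...) {
  cat(sprintf("strata_definition (%s, n = %d): cuts %s\n", x$scheme, x$n,
              paste(signif(x$cuts, 5), collapse = ", ")))
  invisible(x)
}

#' Assign values to strata
#'
#' Strata are half-open: a value equal to a cutpoint goes to the lower
#' stratum. Returns quartile 1-4 (1 = lowest) under the quartile scheme,
#' or 1 (submedian) / 2 (supramedian) under the median scheme. Non-finite
#' values return `NA` and are logged.
#'
#' @param values numeric vector.
#' @param strata a [fit_cutpoints()] result.
#' @return Integer vector of stratum ids.
#' @export
assign_stratum <- function(values, strata) {
  stopifnot(inherits(strata, "strata_definition"))
  out <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  if (any(!ok)) lmtr_log("stratify", "%d non-finite value(s) excluded", sum(!ok))
  if (any(ok)) {
    out[ok] <- 1L + as.integer(rowSums(outer(values[ok], strata$cuts, `>`)))
  }
  out
}

#' Group a lesion's voxels into baseline-defined segments
#'
#' Voxels of one lesion are grouped by their baseline stratum (e.g.
#' baseline-MTR quartile); empty segments are omitted. Each segment
#' carries its mean baseline and follow-up value.
#'
#' @param voxels integer linear indices of the lesion's eligible voxels
#'   (already outer-layer-stripped where that applies).
#' @param baseline,followup numeric 3D arrays of voxel values.
#' @param strata a [fit_cutpoints()] result for the stratifying variable.
#' @param strat_values optional numeric array of the stratifying variable
#'   (defaults to `baseline`; pass the T1-weighted volume for T1 segments).
#' @param lesion_id id recorded in the output rows.
#' @return Data frame: one row per non-empty segment with `lesion_id`,
#'   `stratum`, `n_vox`, `baseline`, `followup`.
#' @export
build_segments <- function(voxels, baseline, followup, strata,
                           strat_values = NULL, lesion_id = NA_integer_) {
  if (is.null(strat_values)) strat_values <- baseline
  s <- assign_stratum(strat_values[voxels], strata)
  keep <- !is.na(s)
  voxels <- voxels[keep]
  s <- s[keep]
  if (length(voxels) == 0L) {
    return(data.frame(lesion_id = integer(0), stratum = integer(0),
                      n_vox = integer(0), baseline = numeric(0),
                      followup = numeric(0)))
  }
  sp <- split(voxels, s)
  data.frame(lesion_id = lesion_id,
             stratum = as.integer(names(sp)),
             n_vox = vapply(sp, length, 1L),
             baseline = vapply(sp, function(v) mean(baseline[v]), 1.0),
             followup = vapply(sp, function(v) mean(followup[v]), 1.0),
             row.names = NULL)
}
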