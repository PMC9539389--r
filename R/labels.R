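# Tissue label codes shared by the atlas, geometry and banding stages.

#' Tissue label codes
#'
#' Integer codes used in tissue atlas volumes. Two CSF compartments are
#' distinguished because distance banding measures from the ventricular
#' surface (for WM/DGM) and from the outer (pial) surface (for cortex).
#'
#' @format Named integer vector with elements `vcsf` (ventricular CSF),
#'   `ocsf` (outer CSF), `wm` (white matter), `cgm` (cortical grey matter),
#'   `dgm` (deep grey matter), `cbgm` (cerebellar grey matter).
#' @export
TISSUE_LABELS <- c(vcsf = 1L, ocsf = 2L, wm = 3L, cgm = 4L, dgm = 5L, cbgm = 6L)

#' @rdname TISSUE_LABELS
#' @export
CSF_LABELS <- c(1L, 2L)

tissue_name <- function(code) {
  names(TISSUE_LABELS)[match(code, TISSUE_LABELS)]
}

#' @keywords internal
is_csf <- function(atlas) {
  array(atlas %in% CSF_LABELS, dim = dim(atlas))
}

assert_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Lightweight structured logging: messages to stderr, prefixed by stage.
lmtr_log <- function(stage, fmt, ..., verbose = getOption("lesionmtr.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}
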