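#' Baseline variability: BMAD
#'
#' The baseline median absolute deviation (BMAD) is the scaled MAD
#' (consistency constant 1.4826) of all responses in wells taken to represent
#' baseline, pooled across every sample of the endpoint. Two selection methods
#' are supported: `"lowconc_twells"` uses treatment wells at the two lowest
#' distinct concentrations; `"neutral_ctrl"` uses wells labeled as neutral
#' controls (`wllt == "n"`).
#'
#' @param tbl data.frame with columns `conc`, `resp`, and (for the neutral
#'   control method) `wllt`; typically all rows of one endpoint.
#' @param method baseline selection method.
#' @return scaled MAD of the selected baseline responses (response units).
#' @export
cr_bmad <- function(tbl, method = c("lowconc_twells", "neutral_ctrl")) {
  method <- match.arg(method)
  base <- .cr_baseline_resp(tbl, method)
  if (length(base) < 1L)
    stop("no baseline wells found: endpoint cannot be configured with method '",
         method, "'", call. = FALSE)
  stats::mad(base, constant = 1.4826)
}

.cr_baseline_resp <- function(tbl, method) {
  if (method == "neutral_ctrl") {
    if (is.null(tbl$wllt)) return(numeric(0))
    return(tbl$resp[tbl$wllt == "n"])
  }
  trt <- if (is.null(tbl$wllt)) tbl else tbl[tbl$wllt == "t", , drop = FALSE]
  cc <- sort(unique(trt$conc))
  if (length(cc) < 2L)
    stop("need at least two distinct concentrations for lowconc_twells",
         call. = FALSE)
  trt$resp[trt$conc %in% cc[1:2]]
}

#' Baseline variability: pooled one-SD
#'
#' Sample standard deviation of treatment-well responses at the two lowest
#' distinct concentrations, pooled across all samples of the endpoint. The
#' benchmark response (BMR) is defined as 1.349 times this value.
#'
#' @inheritParams cr_bmad
#' @return pooled sample SD (response units).
#' @export
cr_onesd <- function(tbl) {
  base <- .cr_baseline_resp(tbl, "lowconc_twells")
  if (length(base) < 2L)
    stop("need >= 2 baseline observations to estimate onesd", call. = FALSE)
  stats::sd(base)
}

#' Efficacy cutoff from assigned methods
#'
#' Each assigned method yields a candidate cutoff; the endpoint cutoff is the
#' maximum over candidates. Available methods: `"bmad3"` (3 x BMAD), `"pc20"`
#' (a fixed 20, for percent-of-control scales), and `"fc1.2"` (log2(1.2), for
#' log2 fold-change scales).
#'
#' @param methods character vector of at least one method name.
#' @param bmad baseline MAD (needed by `"bmad3"`).
#' @return cutoff in response units.
#' @export
cr_coff <- function(methods, bmad = NULL) {
  if (length(methods) < 1L) stop("at least one cutoff method required",
                                 call. = FALSE)
  cand <- vapply(methods, function(m) {
    switch(m,
      bmad3 = {
        if (is.null(bmad)) stop("method 'bmad3' requires bmad", call. = FALSE)
        3 * bmad
      },
      pc20 = 20,
      fc1.2 = log2(1.2),
      stop("unknown cutoff method: ", m, call. = FALSE))
  }, numeric(1))
  max(cand)
}

#' Endpoint cutoff specification
#'
#' Bundles the baseline statistics of one endpoint: BMAD, the pooled baseline
#' SD (`onesd`), the benchmark response `bmr = 1.349 * onesd`, and the
#' efficacy cutoff `coff` (maximum over the assigned cutoff methods).
#'
#' @param tbl endpoint data.frame (columns `conc`, `resp`, optional `wllt`),
#'   or `NULL` when `bmad` and `onesd` are given directly.
#' @param cutoff_methods methods passed to [cr_coff()].
#' @param bmad_method baseline selection for the BMAD, see [cr_bmad()].
#' @param bmad,onesd direct values overriding estimation from `tbl`.
#' @param scale response scale of the endpoint, `"pc"` (percent-of-control)
#'   or `"log2"`; used by downstream efficacy flags.
#' @return object of class `cr_cutoff`: list with `bmad`, `onesd`, `bmr`,
#'   `coff`, `bmad_method`, `cutoff_methods`, `scale`.
#' @examples
#' cr_cutoff(bmad = 2, onesd = 1.5)  # coff = 6, bmr = 2.0235
#' @export
cr_cutoff <- function(tbl = NULL, cutoff_methods = "bmad3",
                      bmad_method = c("lowconc_twells", "neutral_ctrl"),
                      bmad = NULL, onesd = NULL, scale = c("pc", "log2")) {
  bmad_method <- match.arg(bmad_method)
  scale <- match.arg(scale)
  if (is.null(bmad))  bmad  <- cr_bmad(tbl, bmad_method)
  if (is.null(onesd)) onesd <- cr_onesd(tbl)
  structure(list(
    bmad = bmad, onesd = onesd, bmr = 1.349 * onesd,
    coff = cr_coff(cutoff_methods, bmad),
    bmad_method = bmad_method, cutoff_methods = cutoff_methods,
    scale = scale
  ), class = "cr_cutoff")
}

#' @export
print.cr_cutoff <- function(x, ...) {
  cat("Endpoint cutoff specification\n")
  cat(sprintf("  bmad:  %.4g  (method: %s)\n", x$bmad, x$bmad_method))
  cat(sprintf("  onesd: %.4g   bmr (1.349*onesd): %.4g\n", x$onesd, x$bmr))
  cat(sprintf("  coff:  %.4g  (methods: %s)\n", x$coff,
              paste(x$cutoff_methods, collapse = ", ")))
  invisible(x)
}
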