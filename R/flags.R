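#' Cautionary flags for a fitted series
#'
#' Programmatic annotations signaling curve behavior that deserves scrutiny.
#' Flags never alter the hit call or potency estimates. Each flag is tested
#' independently:
#' \describe{
#'   \item{low.nrep}{average replicates per concentration below 2.}
#'   \item{low.nconc}{fewer than 4 distinct concentrations.}
#'   \item{bmd.high}{BMD above the AC50 (high baseline variability).}
#'   \item{singlept.hit.high}{active, and only the highest concentration's
#'     median exceeds baseline (3 x BMAD).}
#'   \item{singlept.hit.mid}{active, and exactly one concentration exceeds
#'     baseline, not the highest.}
#'   \item{multipoint.neg}{inactive, yet two or more concentration medians
#'     exceed baseline.}
#'   \item{gnls.lowconc}{gain-loss winner whose gain AC50 is below the
#'     lowest tested concentration or whose loss AC50 exceeds the mean
#'     tested concentration (mean of the distinct concentrations).}
#'   \item{noise}{RMSE of the winning fit above the cutoff.}
#'   \item{border}{|top| within the borderline band `[0.8, 1.2] x coff`.}
#'   \item{efficacy.50}{|top| below the 50%-efficacy level for the endpoint
#'     scale: 50 response units on percent scales, log2(1.5) on log2
#'     fold-change scales.}
#'   \item{ac50.lowconc}{AC50 below the lowest tested concentration.}
#'   \item{modl.directionality.fail}{concentration medians exceed +coff/2
#'     and -coff/2 in both directions (curve direction questionable).}
#'   \item{viability.gnls}{cell-viability endpoint fit with a gain-loss
#'     winning model.}
#' }
#' Flags whose inputs are absent (e.g. no BMD) are simply not emitted.
#'
#' @param fit a [cr_fit()] object.
#' @param hit a [cr_hitcall()] result.
#' @param potency a [cr_potency()] result.
#' @param cutoff a [cr_cutoff()] object.
#' @param endpoint_meta list with optional `cell_viability` (logical) and
#'   `scale` (`"pc"` or `"log2"`, defaulting to the cutoff's scale).
#' @return character vector of flag names (possibly empty), class `cr_flags`.
#' @export
cr_flags <- function(fit, hit, potency, cutoff,
                     endpoint_meta = list()) {
  meta <- utils::modifyList(
    list(cell_viability = FALSE,
         scale = if (!is.null(cutoff$scale)) cutoff$scale else "pc"),
    endpoint_meta)
  conc <- fit$data$conc; resp <- fit$data$resp
  cc <- sort(unique(conc))
  med <- tapply(resp, conc, stats::median)
  med <- med[as.character(cc)]
  w <- .cr_winner_fit(fit)
  active <- isTRUE(hit$active)
  coff <- cutoff$coff
  baseline <- 3 * cutoff$bmad
  above <- abs(med) > baseline
  flags <- character(0)
  add <- function(fl, cond) if (isTRUE(cond)) c(fl, flags) else flags

  flags <- add("low.nrep", mean(tabulate(match(conc, cc))) < 2)
  flags <- add("low.nconc", length(cc) < 4)
  flags <- add("bmd.high",
               !is.na(potency$bmd) && !is.na(potency$ac50) &&
                 potency$bmd > potency$ac50)
  n_above <- sum(above)
  hi_above <- above[length(above)]
  flags <- add("singlept.hit.high", active && n_above == 1 && hi_above)
  flags <- add("singlept.hit.mid", active && n_above == 1 && !hi_above)
  flags <- add("multipoint.neg", !active && n_above >= 2)
  if (!is.null(w)) {
    flags <- add("gnls.lowconc",
                 w$model == "gnls" &&
                   (w$params$ga < cc[1] || w$params$la > mean(cc)))
    flags <- add("noise", w$rmse > coff)
    atop <- abs(w$top)
    flags <- add("border", atop >= 0.8 * coff && atop <= 1.2 * coff)
    eff50 <- if (identical(meta$scale, "log2")) log2(1.5) else 50
    flags <- add("efficacy.50", atop < eff50)
    flags <- add("ac50.lowconc", !is.na(potency$ac50) &&
                   potency$ac50 < cc[1])
    flags <- add("modl.directionality.fail",
                 any(med > coff / 2) && any(med < -coff / 2))
    flags <- add("viability.gnls",
                 isTRUE(meta$cell_viability) && w$model == "gnls")
  }
  structure(sort(flags), class = "cr_flags")
}

#' @export
print.cr_flags <- function(x, ...) {
  if (!length(x)) cat("no cautionary flags\n")
  else cat("cautionary flags:", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}
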