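#' Fit category lookup table
#'
#' The hierarchical fit-category tree first splits curves into active,
#' inactive, or cannot-determine; actives are then split on efficacy
#' (modeled |top| vs 1.2 x cutoff) and placed by the AC50 and AC95 relative
#' to the tested concentration range. The numeric codes of the active leaves
#' (36-38 borderline, 40-42 moderate) are conserved from earlier pipeline
#' versions; the cannot-determine and inactive leaves carry package-assigned
#' codes (2, 13, 15) with the symbolic labels authoritative.
#'
#' @return data.frame with columns `code` and `label`.
#' @export
cr_fitc_table <- function() {
  data.frame(
    code = c(2L, 13L, 15L, 36L, 37L, 38L, 40L, 41L, 42L),
    label = c("cannot_determine", "inactive_clear", "inactive_borderline",
              "active_borderline_ac50_below", "active_borderline_informative",
              "active_borderline_ac95_above", "active_moderate_ac50_below",
              "active_moderate_informative", "active_moderate_ac95_above"),
    stringsAsFactors = FALSE
  )
}

#' Assign the fit category
#'
#' Walks the hierarchical tree: winner `"none"` (e.g. fewer than 4
#' concentrations) is cannot-determine; inactive series (`hitc < 0.90`) are
#' split on |top| < 0.8 x cutoff (clear) versus >= 0.8 x cutoff (borderline
#' inactive); actives are split on |top| <= 1.2 x cutoff (borderline) versus
#' above (moderate), then placed by AC50 <= cmin (codes 36/40), else AC95 >=
#' cmax (38/42), else both inside the range (37/41, the most quantitatively
#' informative AC50 values). An absent AC95 for an active curve is treated
#' as beyond the tested range. Comparisons use the sign-free |top|, so the
#' category is invariant under response direction.
#'
#' @param hit a [cr_hitcall()] result (or a list with `active`).
#' @param fit a [cr_fit()] object (supplies the winner and top).
#' @param potency a [cr_potency()] result (AC50/AC95).
#' @param cutoff a [cr_cutoff()] object.
#' @param conc_range tested range; defaults to the fit's.
#' @return one row of [cr_fitc_table()] (list with `code`, `label`).
#' @export
cr_fitcat <- function(hit, fit, potency, cutoff, conc_range = NULL) {
  tab <- cr_fitc_table()
  pick <- function(code) as.list(tab[tab$code == code, ])
  w <- .cr_winner_fit(fit)
  if (is.null(w)) return(pick(2L))
  if (is.null(conc_range)) conc_range <- fit$conc_range
  atop <- abs(w$top)
  coff <- cutoff$coff
  if (!isTRUE(hit$active))
    return(pick(if (atop < 0.8 * coff) 13L else 15L))
  if (is.na(potency$ac50))
    stop("active series without an AC50: inconsistent inputs", call. = FALSE)
  borderline <- atop <= 1.2 * coff
  code <- if (potency$ac50 <= conc_range[1]) {
    if (borderline) 36L else 40L
  } else if (is.na(potency$ac95) || potency$ac95 >= conc_range[2]) {
    if (borderline) 38L else 42L
  } else {
    if (borderline) 37L else 41L
  }
  pick(code)
}
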