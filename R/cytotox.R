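# Cytotoxicity "burst" threshold: per-chemical median AC50 across
# cytotoxicity-relevant endpoints, a global MAD over a highly tested
# chemical set, and the lower bound median - 3 * global MAD.

#' Filter a burst table
#'
#' Removes rows unusable for the cytotoxicity point: gain-loss winning
#' fits, and rows in the cell-proliferation (gain) direction, so that only
#' losses in cell viability contribute.
#'
#' @param tbl data.frame with columns `chemical_id`, `endpoint_id`,
#'   `tested`, `active`, `ac50` (uM), `winning_model`, and either
#'   `proliferation_direction` (logical) or `top` (its sign is used when
#'   the annotation is missing).
#' @return the filtered data.frame.
#' @export
cr_burst_filter <- function(tbl) {
  prolif <- tbl$proliferation_direction
  if (is.null(prolif)) {
    prolif <- if (!is.null(tbl$top)) tbl$top > 0 else rep(FALSE, nrow(tbl))
  }
  prolif[is.na(prolif)] <- FALSE
  keep <- !(tbl$winning_model %in% "gnls") & !prolif
  tbl[keep, , drop = FALSE]
}

#' Per-chemical cytotoxicity burst point
#'
#' The burst point is the median log10 AC50 over a chemical's active burst
#' endpoints. When fewer than `min_active` endpoints qualify, the default
#' of 1000 uM (3 log10-uM) is reported instead.
#'
#' @param tbl filtered burst rows for one chemical (see [cr_burst_filter()]).
#' @param min_active minimum qualifying endpoints for a non-default value.
#' @return list with `cyto_pt` (log10-uM), `used_default`, `n_tested`,
#'   `n_active`.
#' @export
cr_burst_point <- function(tbl, min_active = 3) {
  act <- tbl$active & !is.na(tbl$ac50)
  n_active <- sum(act)
  n_tested <- sum(tbl$tested)
  if (n_active >= min_active) {
    list(cyto_pt = stats::median(log10(tbl$ac50[act])), used_default = FALSE,
         n_tested = n_tested, n_active = n_active)
  } else {
    list(cyto_pt = 3, used_default = TRUE,
         n_tested = n_tested, n_active = n_active)
  }
}

#' Global MAD of the burst chemical set
#'
#' For every chemical tested in at least `min_tested` burst endpoints with
#' an active hit rate above `min_hit_rate`, the scaled MAD of its active
#' log10 AC50 values is computed; the global MAD is the median of these
#' per-chemical MADs.
#'
#' @param tbl filtered burst table (all chemicals).
#' @param min_tested minimum number of tested burst endpoints.
#' @param min_hit_rate minimum active/tested ratio (exclusive).
#' @return global MAD in log10-uM.
#' @export
cr_global_mad <- function(tbl, min_tested = 60, min_hit_rate = 0.05) {
  mads <- unlist(lapply(split(tbl, tbl$chemical_id), function(d) {
    n_tested <- sum(d$tested)
    act <- d$active & !is.na(d$ac50)
    if (n_tested < min_tested || sum(act) / n_tested <= min_hit_rate)
      return(NULL)
    stats::mad(log10(d$ac50[act]), constant = 1.4826)
  }))
  if (!length(mads))
    stop("no chemical qualifies for the global MAD: burst set unusable",
         call. = FALSE)
  stats::median(mads)
}

#' Burst lower bound
#'
#' @param cyto_pt chemical burst point (log10-uM).
#' @param global_mad global MAD (log10-uM).
#' @return `cyto_pt - 3 * global_mad` (log10-uM).
#' @export
cr_lower_bound <- function(cyto_pt, global_mad) cyto_pt - 3 * global_mad

#' Cytotoxicity burst summary for a chemical set
#'
#' Filters the burst table, computes each chemical's burst point, the
#' global MAD over the qualifying set, and per-chemical lower bounds.
#'
#' @inheritParams cr_burst_filter
#' @inheritParams cr_burst_point
#' @inheritParams cr_global_mad
#' @return data.frame with one row per chemical: `chemical_id`, `n_tested`,
#'   `n_active`, `cyto_pt` (log10-uM), `cyto_pt_um`, `used_default`,
#'   `global_mad`, `lower_bound` (log10-uM).
#' @export
cr_burst <- function(tbl, min_active = 3, min_tested = 60,
                     min_hit_rate = 0.05) {
  ftbl <- cr_burst_filter(tbl)
  gmad <- cr_global_mad(ftbl, min_tested, min_hit_rate)
  rows <- lapply(split(ftbl, ftbl$chemical_id), function(d) {
    bp <- cr_burst_point(d, min_active)
    data.frame(chemical_id = d$chemical_id[1], n_tested = bp$n_tested,
               n_active = bp$n_active, cyto_pt = bp$cyto_pt,
               cyto_pt_um = 10^bp$cyto_pt, used_default = bp$used_default,
               global_mad = gmad,
               lower_bound = cr_lower_bound(bp$cyto_pt, gmad),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
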