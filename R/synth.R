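# Synthetic concentration-response data with known ground truth.
# Emulates plate-style screening series: half-log concentration spacing,
# a few replicates, Student-t or normal noise, both response directions.

.cr_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate one concentration-response series
#'
#' Responses are the generating model evaluated at a half-log concentration
#' grid plus noise. Defaults mirror a common screening design: 8
#' concentrations from 0.03 uM at 0.5 log10 spacing, 3 replicates.
#'
#' @param model generating model id (see [cr_models()]).
#' @param params named list of true shape parameters.
#' @param n_conc number of distinct concentrations.
#' @param conc_min lowest concentration (uM).
#' @param spacing log10 step between concentrations.
#' @param n_rep replicates per concentration.
#' @param noise `"t4"` (Student-t, df 4) or `"normal"`.
#' @param noise_scale scale of the noise distribution (response units).
#' @param seed optional integer; identical seeds give identical series, and
#'   the caller's RNG state is restored.
#' @return list with `conc`, `resp`, `model`, `params`, `n_rep`.
#' @examples
#' s <- cr_sim_series("exp4", list(tp = 50, ga = 1), noise_scale = 5,
#'                    seed = 7)
#' @export
cr_sim_series <- function(model, params, n_conc = 8, conc_min = 0.03,
                          spacing = 0.5, n_rep = 3,
                          noise = c("t4", "normal"), noise_scale = 5,
                          seed = NULL) {
  noise <- match.arg(noise)
  .cr_check_model(model)
  if (model != "constant") .cr_check_params(model, params)
  stopifnot(n_conc >= 1, conc_min > 0, n_rep >= 1, noise_scale >= 0)
  conc <- rep(conc_min * 10^(spacing * (seq_len(n_conc) - 1)), each = n_rep)
  mu <- cr_evaluate(model, params, conc, check = FALSE)
  eps <- .cr_with_seed(seed, {
    if (noise_scale == 0) rep(0, length(conc))
    else if (noise == "t4") noise_scale * stats::rt(length(conc), df = 4)
    else stats::rnorm(length(conc), sd = noise_scale)
  })
  list(conc = conc, resp = mu + eps, model = model, params = params,
       n_rep = n_rep)
}

#' Simulate a multi-sample endpoint table
#'
#' Generates a long-format level-3-style table for one endpoint: `n_samples`
#' series with generating models drawn round-robin from `generators`, all
#' sharing the concentration design, plus the two low-concentration baseline
#' groups needed for BMAD/onesd estimation (the two lowest concentrations of
#' every series).
#'
#' @param n_samples number of samples (series).
#' @param generators list of generator specs, each a list with `model` and
#'   `params`; recycled across samples.
#' @param aeid endpoint identifier.
#' @param seed integer seed; per-sample seeds are derived from it.
#' @inheritParams cr_sim_series
#' @return list with `mc3` (data.frame `spid`, `aeid`, `conc`, `resp`,
#'   `wllt`) and `truth` (one row per sample: `spid`, `model`, true
#'   parameters as JSON).
#' @export
cr_sim_endpoint <- function(n_samples, generators, aeid = "aeid_1",
                            n_conc = 8, conc_min = 0.03, spacing = 0.5,
                            n_rep = 3, noise = "t4", noise_scale = 5,
                            seed = 1) {
  stopifnot(n_samples >= 1, length(generators) >= 1)
  rows <- vector("list", n_samples)
  truth <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    g <- generators[[((i - 1L) %% length(generators)) + 1L]]
    s <- cr_sim_series(g$model, g$params, n_conc = n_conc,
                       conc_min = conc_min, spacing = spacing,
                       n_rep = n_rep, noise = noise,
                       noise_scale = noise_scale,
                       seed = seed * 10000L + i)
    spid <- sprintf("spid_%03d", i)
    rows[[i]] <- data.frame(spid = spid, aeid = aeid, conc = s$conc,
                            resp = s$resp, wllt = "t",
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      spid = spid, model = g$model,
      params = as.character(jsonlite::toJSON(g$params, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  list(mc3 = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Simulate a cytotoxicity burst table
#'
#' Builds a chemical x endpoint burst table with a controllable
#' per-chemical median and dispersion of the log10 AC50.
#'
#' @param n_chem number of chemicals.
#' @param n_endpoints burst endpoints each chemical is tested in (recycled
#'   per chemical).
#' @param median_l10 per-chemical true median log10 AC50 (recycled).
#' @param dispersion per-chemical SD of log10 AC50 around the median
#'   (recycled; 0 gives identical AC50s).
#' @param active_rate fraction of tested endpoints that are active
#'   (recycled).
#' @param seed integer seed.
#' @return data.frame with `chemical_id`, `endpoint_id`, `tested`,
#'   `active`, `ac50` (uM, `NA` when inactive), `winning_model`,
#'   `proliferation_direction`.
#' @export
cr_sim_burst <- function(n_chem, n_endpoints, median_l10 = 1,
                         dispersion = 0.2, active_rate = 0.5, seed = 1) {
  stopifnot(n_chem >= 1, all(n_endpoints >= 1))
  n_endpoints <- rep_len(n_endpoints, n_chem)
  median_l10 <- rep_len(median_l10, n_chem)
  dispersion <- rep_len(dispersion, n_chem)
  active_rate <- rep_len(active_rate, n_chem)
  .cr_with_seed(seed, {
    rows <- lapply(seq_len(n_chem), function(i) {
      ne <- n_endpoints[i]
      n_act <- round(active_rate[i] * ne)
      act <- rep(c(TRUE, FALSE), c(n_act, ne - n_act))
      l10 <- median_l10[i] + if (dispersion[i] > 0)
        stats::rnorm(ne, sd = dispersion[i]) else rep(0, ne)
      data.frame(
        chemical_id = sprintf("chem_%03d", i),
        endpoint_id = sprintf("burst_ep_%03d", seq_len(ne)),
        tested = TRUE, active = act,
        ac50 = ifelse(act, 10^l10, NA_real_),
        winning_model = "hill", proliferation_direction = FALSE,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
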