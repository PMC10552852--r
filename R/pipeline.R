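# Level 4 -> 6 orchestration over a long-format series table, with
# long-format outputs mirroring the mc4/mc4_param/mc5/mc5_param/mc6 layout
# (m4id, aeid, spid, model, model_param/model_val, hit_param/hit_val, flag).

#' Run configuration
#'
#' Per-endpoint method assignments with package defaults. Unknown endpoints
#' inherit the defaults; per-endpoint overrides live under `endpoints` keyed
#' by endpoint id.
#'
#' @param bmad_method baseline selection for BMAD (see [cr_bmad()]).
#' @param cutoff_methods cutoff methods (see [cr_coff()]).
#' @param direction fitting direction (see [cr_fit()]).
#' @param scale endpoint response scale (`"pc"` or `"log2"`).
#' @param cell_viability is the endpoint a cell-viability readout.
#' @param hitc_threshold activity threshold on the continuous hit call.
#' @param dialect `w_median` dialect (see [cr_hitcall()]).
#' @param seed integer seed recorded with the run.
#' @param endpoints named list of per-endpoint overrides (same fields).
#' @return list of class `cr_config`.
#' @export
cr_config <- function(bmad_method = "lowconc_twells",
                      cutoff_methods = "bmad3",
                      direction = "bidirectional",
                      scale = "pc", cell_viability = FALSE,
                      hitc_threshold = 0.90, dialect = "v4.1_median",
                      seed = NULL, endpoints = list()) {
  structure(list(bmad_method = bmad_method, cutoff_methods = cutoff_methods,
                 direction = direction, scale = scale,
                 cell_viability = cell_viability,
                 hitc_threshold = hitc_threshold, dialect = dialect,
                 seed = seed, endpoints = endpoints),
            class = "cr_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys override the package defaults; an `endpoints` mapping
#' holds per-endpoint overrides.
#'
#' @param path YAML file path.
#' @return a [cr_config()] object.
#' @export
cr_read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cr_config))
  do.call(cr_config, raw[intersect(names(raw), known)])
}

# effective settings for one endpoint: defaults overridden per endpoint
.cr_endpoint_config <- function(config, aeid) {
  base <- unclass(config)
  base$endpoints <- NULL
  ov <- config$endpoints[[aeid]]
  if (!is.null(ov)) base <- utils::modifyList(base, ov)
  base
}

#' Run the multiple-concentration pipeline (levels 4-6)
#'
#' For every endpoint: estimate BMAD/onesd and the cutoff; then for every
#' sample series: fit all models and pick the AIC winner, compute the
#' continuous hit call, potency set with BMD bounds, fit category, and
#' cautionary flags. Per-series failures are recorded in the run log and
#' never abort the run. The whole pass is deterministic for a given input.
#'
#' @param mc3 long-format data.frame with columns `spid`, `aeid`, `conc`
#'   (uM), `resp`, and optional `wllt` (`"t"` treatment, `"n"` neutral
#'   control; only treatment wells are fit).
#' @param config a [cr_config()] object.
#' @return list of class `cr_pipeline` with data.frames `mc4`, `mc4_param`,
#'   `mc5`, `mc5_param`, `mc6`, and `log` (character vector of the methods
#'   applied per endpoint and any per-series failures). Every row carries
#'   the stable series identifier `m4id` (input order of first appearance).
#' @export
cr_pipeline <- function(mc3, config = cr_config()) {
  need <- c("spid", "aeid", "conc", "resp")
  miss <- setdiff(need, names(mc3))
  if (length(miss))
    stop("mc3 input lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(mc3$conc) | mc3$conc <= 0 | !is.finite(mc3$resp)
  if (any(bad))
    stop("malformed mc3 rows (non-positive conc or non-finite resp): rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  if (is.null(mc3$wllt)) mc3$wllt <- "t"

  mc4 <- mc4p <- mc5 <- mc5p <- mc6 <- list()
  logl <- character(0)
  m4id <- 0L
  for (aeid in unique(mc3$aeid)) {
    ep <- mc3[mc3$aeid == aeid, , drop = FALSE]
    cfg <- .cr_endpoint_config(config, aeid)
    cut <- cr_cutoff(ep, cutoff_methods = cfg$cutoff_methods,
                     bmad_method = cfg$bmad_method, scale = cfg$scale)
    logl <- c(logl, sprintf(
      "aeid=%s bmad_method=%s cutoff_methods=%s direction=%s dialect=%s bmad=%.6g onesd=%.6g bmr=%.6g coff=%.6g",
      aeid, cfg$bmad_method, paste(cfg$cutoff_methods, collapse = "+"),
      cfg$direction, cfg$dialect, cut$bmad, cut$onesd, cut$bmr, cut$coff))
    trt <- ep[ep$wllt == "t", , drop = FALSE]
    for (spid in unique(trt$spid)) {
      m4id <- m4id + 1L
      d <- trt[trt$spid == spid, , drop = FALSE]
      res <- tryCatch(
        .cr_process_series(d$conc, d$resp, cut, cfg, m4id, aeid, spid),
        error = function(e) e)
      if (inherits(res, "error")) {
        logl <- c(logl, sprintf("m4id=%d aeid=%s spid=%s FAILED: %s",
                                m4id, aeid, spid, conditionMessage(res)))
        next
      }
      mc4[[m4id]] <- res$mc4; mc4p[[m4id]] <- res$mc4_param
      mc5[[m4id]] <- res$mc5; mc5p[[m4id]] <- res$mc5_param
      mc6[[m4id]] <- res$mc6
    }
  }
  bind <- function(l) {
    l <- Filter(Negate(is.null), l)
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  structure(list(mc4 = bind(mc4), mc4_param = bind(mc4p), mc5 = bind(mc5),
                 mc5_param = bind(mc5p), mc6 = bind(mc6), log = logl,
                 config = config),
            class = "cr_pipeline")
}

.cr_process_series <- function(conc, resp, cut, cfg, m4id, aeid, spid) {
  fit <- cr_fit(conc, resp, direction = cfg$direction)
  hit <- cr_hitcall(fit, cut, dialect = cfg$dialect)
  hit$active <- cr_binarize(hit$hitc, cfg$hitc_threshold)
  pot <- cr_potency(fit, cut)
  if (!is.na(pot$bmd)) {
    w <- .cr_winner_fit(fit)
    b <- cr_bmd_bounds(fit, bmr = sign(.cr_max_resp(w)) * cut$bmr,
                       bmd = pot$bmd)
    pot$bmdl <- b$bmdl; pot$bmdu <- b$bmdu
  }
  fitc <- cr_fitcat(hit, fit, pot, cut)
  flags <- cr_flags(fit, hit, pot, cut,
                    endpoint_meta = list(cell_viability = cfg$cell_viability,
                                         scale = cfg$scale))

  mc4 <- if (length(fit$fits)) do.call(rbind, lapply(fit$fits, function(f) {
    data.frame(m4id = m4id, aeid = aeid, spid = spid, model = f$model,
               loglik = f$loglik, aic = f$aic, rmse = f$rmse, top = f$top,
               top_conc = f$top_conc, success = f$success,
               stringsAsFactors = FALSE)
  })) else data.frame(m4id = m4id, aeid = aeid, spid = spid, model = "none",
                      loglik = NA_real_, aic = NA_real_, rmse = NA_real_,
                      top = NA_real_, top_conc = NA_real_, success = FALSE,
                      stringsAsFactors = FALSE)
  mc4_param <- if (length(fit$fits)) do.call(rbind, lapply(
    fit$fits, function(f) {
      if (is.null(f$params)) return(NULL)
      data.frame(m4id = m4id, aeid = aeid, spid = spid, model = f$model,
                 model_param = names(f$params),
                 model_val = unlist(f$params, use.names = FALSE),
                 stringsAsFactors = FALSE)
    })) else NULL
  w <- .cr_winner_fit(fit)
  mc5 <- data.frame(m4id = m4id, aeid = aeid, spid = spid,
                    modl = fit$winner, hitc = hit$hitc,
                    fitc = fitc$code, fitc_label = fitc$label,
                    coff = cut$coff,
                    top = if (is.null(w)) NA_real_ else w$top,
                    stringsAsFactors = FALSE)
  hp <- c(list(w_aic = hit$w_aic, w_median = hit$w_median,
               w_top = hit$w_top, bmr = cut$bmr),
          pot[c("ac5", "ac10", "ac50", "ac95", "acb", "acc",
                "bmd", "bmdl", "bmdu")])
  mc5_param <- data.frame(m4id = m4id, aeid = aeid, spid = spid,
                          hit_param = names(hp),
                          hit_val = unlist(hp, use.names = FALSE),
                          stringsAsFactors = FALSE)
  mc6 <- if (length(flags)) data.frame(m4id = m4id, aeid = aeid,
                                       spid = spid,
                                       flag = unclass(flags),
                                       stringsAsFactors = FALSE) else NULL
  list(mc4 = mc4, mc4_param = mc4_param, mc5 = mc5, mc5_param = mc5_param,
       mc6 = mc6)
}

#' @export
print.cr_pipeline <- function(x, ...) {
  n_series <- if (is.null(x$mc5)) 0L else nrow(x$mc5)
  cat(sprintf("Pipeline run: %d series, %d endpoints\n", n_series,
              if (n_series) length(unique(x$mc5$aeid)) else 0L))
  if (n_series) {
    act <- sum(cr_binarize(x$mc5$hitc, x$config$hitc_threshold))
    cat(sprintf("  active: %d (%.1f%%); winners: %s\n", act,
                100 * act / n_series,
                paste(names(sort(table(x$mc5$modl), decreasing = TRUE)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write pipeline tables to CSV
#'
#' Writes `mc4.csv`, `mc4_param.csv`, `mc5.csv`, `mc5_param.csv`,
#' `mc6.csv`, plus `run_log.txt` (the methods applied per endpoint, with
#' the configuration echoed) into a directory. Numeric columns are written
#' at full precision so a write/read round trip reproduces values exactly.
#'
#' @param run a [cr_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
cr_write_tables <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("mc4", "mc4_param", "mc5", "mc5_param", "mc6")) {
    tb <- run[[nm]]
    if (is.null(tb)) tb <- data.frame()
    for (cl in names(tb))
      if (is.double(tb[[cl]]))
        tb[[cl]] <- ifelse(is.na(tb[[cl]]), NA_character_,
                           sprintf("%.17g", tb[[cl]]))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  lg <- file.path(dir, "run_log.txt")
  cfg <- run$config
  writeLines(c("# run configuration",
               paste0(names(unclass(cfg))[names(cfg) != "endpoints"], ": ",
                      vapply(unclass(cfg)[names(cfg) != "endpoints"],
                             function(v) paste(format(v), collapse = ","),
                             character(1))),
               "# methods applied", run$log), lg)
  invisible(c(paths, lg))
}

#' Read a level-3 style series table from CSV
#'
#' @param path CSV with columns `spid`, `aeid`, `conc`, `resp`, optional
#'   `wllt`.
#' @return data.frame.
#' @export
cr_read_mc3 <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path,
                               call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
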