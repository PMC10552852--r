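# Robust curve fitting under a Student-t(4) likelihood.
#
# Internal optimizer parameterization: concentration-scale parameters
# (ga, la, b) are handled on log10; the gnls loss AC50 is la =
# ga * 10^(1.5 + dw) with dw >= 0, which makes the 1.5 log10 minimum-width
# constraint a simple box bound.

.CR_T_DF <- 4

# negative log-likelihood of residuals under t(df=4) with scale exp(er)
.cr_negll <- function(resid, er) {
  s <- exp(er)
  -sum(stats::dt(resid / s, df = .CR_T_DF, log = TRUE) - er)
}

.cr_theta_names <- function(model) {
  switch(model,
    constant = "er",
    poly1 = c("a", "er"),
    poly2 = c("a", "lb", "er"),
    power = c("a", "p", "er"),
    hill  = c("tp", "lga", "p", "er"),
    gnls  = c("tp", "lga", "p", "dw", "q", "er"),
    exp2  = c("a", "lb", "er"),
    exp3  = c("a", "lb", "p", "er"),
    exp4  = c("tp", "lga", "er"),
    exp5  = c("tp", "lga", "p", "er"))
}

# internal theta -> natural named parameter list (including er)
.cr_theta2params <- function(model, theta) {
  th <- as.list(theta)
  names(th) <- .cr_theta_names(model)
  out <- th
  if (!is.null(th$lga)) { out$ga <- 10^th$lga; out$lga <- NULL }
  if (!is.null(th$lb))  { out$b  <- 10^th$lb;  out$lb  <- NULL }
  if (model == "gnls")  { out$la <- out$ga * 10^(1.5 + th$dw); out$dw <- NULL }
  out[c(.cr_param_names[[model]], "er")]
}

# box bounds for the internal parameterization
.cr_bounds <- function(model, cmin, cmax, rmax, direction) {
  M <- 1.2 * max(rmax, 1e-3) * 10
  sc <- switch(direction,
               bidirectional = c(-M, M),
               gain_only = c(0, M),
               loss_only = c(-M, 0))
  lc <- c(log10(cmin) - 1, log10(cmax) + 1)
  er <- c(-20, log(max(rmax, 1e-3)) + 3)
  b <- list(er = er, p = c(0.3, 8), q = c(0.3, 8),
            a = sc, tp = sc, lga = lc, lb = lc, dw = c(0, 5))
  nm <- .cr_theta_names(model)
  list(lower = vapply(nm, function(n) b[[n]][1], numeric(1)),
       upper = vapply(nm, function(n) b[[n]][2], numeric(1)))
}

# three deterministic starting points, clamped strictly inside the bounds
.cr_starts <- function(model, conc, resp, bounds) {
  cc <- sort(unique(conc))
  cmin <- cc[1]; cmax <- cc[length(cc)]
  mhi <- stats::median(resp[conc == cmax])
  s0 <- if (mhi < 0) -1 else 1
  amp <- max(abs(resp), 1e-3)
  er0 <- log(max(stats::sd(resp), 1e-3))
  gmid <- log10(stats::median(cc))
  ggeo <- mean(log10(c(cmin, cmax)))
  mk <- function(a = NULL, tp = NULL, lga = NULL, lb = NULL, p = NULL,
                 dw = NULL, q = NULL, er = er0) {
    v <- c(a = a, tp = tp, lga = lga, lb = lb, p = p, dw = dw, q = q, er = er)
    v[.cr_theta_names(model)]
  }
  st <- switch(model,
    poly1 = list(mk(a = mhi / cmax), mk(a = -mhi / cmax),
                 mk(a = s0 * amp / cmax, er = er0 - 1)),
    poly2 = list(mk(a = mhi / 2, lb = log10(cmax)),
                 mk(a = -mhi / 2, lb = log10(cmax)),
                 mk(a = s0 * amp / 2, lb = ggeo, er = er0 - 1)),
    power = list(mk(a = mhi / cmax, p = 1), mk(a = -mhi / cmax, p = 1),
                 mk(a = s0 * amp / cmax^0.5, p = 0.5, er = er0 - 1)),
    hill  = list(mk(tp = mhi, lga = gmid, p = 1.2),
                 mk(tp = -mhi, lga = gmid, p = 1.2),
                 mk(tp = s0 * amp, lga = ggeo, p = 0.6, er = er0 - 1)),
    gnls  = list(mk(tp = mhi, lga = gmid, p = 1.2, dw = 0.5, q = 1.2),
                 mk(tp = -mhi, lga = gmid, p = 1.2, dw = 0.5, q = 1.2),
                 mk(tp = s0 * amp, lga = log10(cmin) + 0.25, p = 2, dw = 0,
                    q = 2, er = er0 - 1)),
    exp2  = list(mk(a = mhi / (exp(1) - 1), lb = log10(cmax)),
                 mk(a = -mhi / (exp(1) - 1), lb = log10(cmax)),
                 mk(a = s0 * amp / 10, lb = ggeo, er = er0 - 1)),
    exp3  = list(mk(a = mhi / (exp(1) - 1), lb = log10(cmax), p = 1),
                 mk(a = -mhi / (exp(1) - 1), lb = log10(cmax), p = 1),
                 mk(a = s0 * amp / 10, lb = ggeo, p = 0.6, er = er0 - 1)),
    exp4  = list(mk(tp = mhi, lga = gmid), mk(tp = -mhi, lga = gmid),
                 mk(tp = s0 * amp, lga = ggeo, er = er0 - 1)),
    exp5  = list(mk(tp = mhi, lga = gmid, p = 1.2),
                 mk(tp = -mhi, lga = gmid, p = 1.2),
                 mk(tp = s0 * amp, lga = ggeo, p = 0.6, er = er0 - 1)))
  eps <- 1e-6
  lapply(st, function(v) pmin(pmax(v, bounds$lower + eps), bounds$upper - eps))
}

.cr_objective <- function(model, conc, resp) {
  k <- length(.cr_theta_names(model))
  function(theta) {
    pars <- .cr_theta2params(model, theta)
    mu <- cr_evaluate(model, pars, conc, check = FALSE)
    v <- .cr_negll(resp - mu, theta[k])
    if (!is.finite(v)) 1e10 else v
  }
}

# fit one model by bounded quasi-Newton from multiple deterministic starts
.cr_optim_multi <- function(fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  best
}

#' Fit a single concentration-response model
#'
#' Maximum-likelihood fit of one model to a series under Student-t(df = 4)
#' residuals with scale `exp(er)`. Optimization is bounded quasi-Newton
#' (L-BFGS-B) restarted from three deterministic starting points derived from
#' the data, so fits are fully reproducible. Under `direction = "gain_only"`
#' the scale parameter is constrained non-negative (`"loss_only"`:
#' non-positive). Gain-loss fits respect the hard minimum-width bound
#' `log10(la) - log10(ga) >= 1.5`.
#'
#' @param conc,resp numeric vectors (uM, response units); replicates are
#'   repeated `conc` values.
#' @param model model id (see [cr_models()]).
#' @param direction `"bidirectional"`, `"gain_only"`, or `"loss_only"`.
#' @return list of class `cr_modelfit`: `model`, `params` (named, incl.
#'   `er`), `loglik`, `aic` (`2 k - 2 loglik` with `k` counting `er`),
#'   `rmse`, `top`, `top_conc`, `n_params`, `success`.
#' @export
cr_fit_one <- function(conc, resp, model,
                       direction = c("bidirectional", "gain_only",
                                     "loss_only")) {
  direction <- match.arg(direction)
  .cr_check_model(model)
  stopifnot(length(conc) == length(resp), all(conc > 0))
  minfo <- cr_models()
  k <- minfo$n_params[minfo$model == model]
  crange <- range(conc)
  fail <- structure(list(model = model, params = NULL, loglik = NA_real_,
                         aic = NA_real_, rmse = NA_real_, top = NA_real_,
                         top_conc = NA_real_, n_params = k, success = FALSE),
                    class = "cr_modelfit")

  if (model == "constant") {
    bb <- .cr_bounds("constant", crange[1], crange[2], max(abs(resp)),
                     direction)
    op <- stats::optimize(function(er) .cr_negll(resp, er),
                          lower = bb$lower, upper = bb$upper)
    ll <- -op$objective
    return(structure(list(
      model = "constant", params = list(er = op$minimum), loglik = ll,
      aic = 2 * k - 2 * ll, rmse = sqrt(mean(resp^2)), top = 0,
      top_conc = crange[2], n_params = k, success = TRUE),
      class = "cr_modelfit"))
  }

  bb <- .cr_bounds(model, crange[1], crange[2], max(abs(resp)), direction)
  starts <- .cr_starts(model, conc, resp, bb)
  best <- .cr_optim_multi(.cr_objective(model, conc, resp), starts,
                          bb$lower, bb$upper)
  if (is.null(best)) return(fail)
  pars <- .cr_theta2params(model, best$par)
  mu <- cr_evaluate(model, pars, conc, check = FALSE)
  tt <- cr_top(model, pars, crange, check = FALSE)
  ll <- -best$value
  structure(list(model = model, params = pars, loglik = ll,
                 aic = 2 * k - 2 * ll, rmse = sqrt(mean((resp - mu)^2)),
                 top = tt$top, top_conc = tt$top_conc, n_params = k,
                 success = TRUE, theta = best$par),
            class = "cr_modelfit")
}

#' Fit all concentration-response models and select a winner
#'
#' Fits the nine non-constant parametric models plus the constant model
#' (AIC reference only) to one concentration-response series, bidirectionally
#' by default. The winning model is the successful non-constant fit with the
#' lowest AIC; the constant model never wins. Exact AIC ties go to the model
#' with fewer parameters, and any remaining tie is broken by a fixed,
#' documented model order (`tie_rank` in [cr_models()]). Series with fewer
#' than 4 distinct concentrations cannot be fit and return winner `"none"`
#' with no fits.
#'
#' @inheritParams cr_fit_one
#' @param models which non-constant models to fit (default: all nine).
#' @return object of class `cr_fit`: list with `data` (data.frame
#'   `conc`/`resp`), `conc_range`, `n_conc`, `direction`, `fits` (named list
#'   of `cr_modelfit`, including `"constant"`), `winner` (model id or
#'   `"none"`), `aic_constant`.
#' @examples
#' s <- cr_sim_series("hill", list(tp = 40, ga = 1, p = 2),
#'                    noise_scale = 2, seed = 1)
#' fit <- cr_fit(s$conc, s$resp)
#' fit$winner
#' @export
cr_fit <- function(conc, resp,
                   direction = c("bidirectional", "gain_only", "loss_only"),
                   models = setdiff(cr_models()$model, "constant")) {
  direction <- match.arg(direction)
  stopifnot(length(conc) == length(resp), length(conc) >= 1L,
            all(is.finite(conc)), all(conc > 0), all(is.finite(resp)))
  out <- structure(list(
    data = data.frame(conc = conc, resp = resp),
    conc_range = range(conc), n_conc = length(unique(conc)),
    direction = direction, fits = list(), winner = "none",
    aic_constant = NA_real_), class = "cr_fit")
  if (out$n_conc < 4L) return(out)

  fit_models <- unique(c(models, "constant"))
  fits <- lapply(fit_models, function(m) cr_fit_one(conc, resp, m, direction))
  names(fits) <- fit_models
  out$fits <- fits
  out$aic_constant <- fits[["constant"]]$aic

  minfo <- cr_models()
  cand <- names(fits)[vapply(fits, function(f) {
    f$model != "constant" && isTRUE(f$success) && is.finite(f$aic)
  }, logical(1))]
  if (length(cand)) {
    aic <- vapply(fits[cand], `[[`, numeric(1), "aic")
    np <- minfo$n_params[match(cand, minfo$model)]
    tr <- minfo$tie_rank[match(cand, minfo$model)]
    out$winner <- cand[order(aic, np, tr)][1]
  }
  out
}

# winning-model fit (or NULL when winner is "none")
.cr_winner_fit <- function(object) {
  if (object$winner == "none") NULL else object$fits[[object$winner]]
}
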