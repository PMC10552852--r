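# Continuous hit calling: the product of three proportional confidence
# weights. The constant model never wins, but its AIC anchors the first
# weight, so a constant AIC below the winner drives the hit call toward 0.

# maximized log-likelihood with the scale parameter tied to a constraint:
# scale_fn(unit_params) must return the scale (tp or a) that satisfies the
# constraint given the unit-scale shape parameters.
.cr_profile_ll <- function(conc, resp, model, scale_fn, fit) {
  nm <- .cr_theta_names(model)
  k <- length(nm)
  shape_idx <- seq(2L, k)  # drop the scale entry; keep shape + er
  crange <- range(conc)
  bb <- .cr_bounds(model, crange[1], crange[2], max(abs(resp)),
                   "bidirectional")
  lower <- bb$lower[shape_idx]; upper <- bb$upper[shape_idx]
  obj <- function(th) {
    theta <- numeric(k)
    theta[shape_idx] <- th
    theta[1] <- 1
    up <- .cr_theta2params(model, theta)
    sc <- scale_fn(up)
    if (!is.finite(sc)) return(1e10)
    theta[1] <- sc
    pars <- .cr_theta2params(model, theta)
    mu <- cr_evaluate(model, pars, conc, check = FALSE)
    v <- .cr_negll(resp - mu, theta[k])
    if (!is.finite(v)) 1e10 else v
  }
  eps <- 1e-6
  st1 <- pmin(pmax(fit$theta[shape_idx], lower + eps), upper - eps)
  st0 <- .cr_starts(model, conc, resp, bb)[[1]][shape_idx]
  st0 <- pmin(pmax(st0, lower + eps), upper - eps)
  if (length(st1) == 1L) {
    # one free parameter (er): golden-section is enough
    op <- stats::optimize(obj, lower = lower, upper = upper)
    return(-op$objective)
  }
  best <- .cr_optim_multi(obj, list(st1, st0), lower, upper)
  if (is.null(best)) return(-Inf)
  -best$value
}

# profile log-likelihood with the in-range |top| pinned at the cutoff
.cr_ll_top_at <- function(conc, resp, model, fit, target) {
  crange <- range(conc)
  scale_fn <- function(up) {
    ut <- cr_top(model, up, crange, check = FALSE)$top
    if (!is.finite(ut) || abs(ut) < 1e-300) return(NA_real_)
    target / ut
  }
  .cr_profile_ll(conc, resp, model, scale_fn, fit)
}

#' Continuous hit call
#'
#' The continuous hit call `hitc` is the product of three proportional
#' weights, each a confidence in `[0, 1]`:
#' \describe{
#'   \item{`w_aic`}{the winning model beats the constant model on AIC:
#'     the Akaike weight `1 / (1 + exp((AIC_win - AIC_const) / 2))`.}
#'   \item{`w_median`}{at least one concentration has a median response
#'     exceeding the cutoff in absolute value: the maximum over
#'     concentration groups of the two-sided t(4) exceedance probability of
#'     the observed group median, with scale `exp(er) / sqrt(n_i)`.}
#'   \item{`w_top`}{the modeled |top| exceeds the cutoff: the signed
#'     likelihood-root probability `pnorm(sign(|top| - coff) *
#'     sqrt(2 * LR))`, where `LR` is the log-likelihood drop when the model
#'     top is profiled at the cutoff.}
#' }
#' A series that could not be fit (winner `"none"`, e.g. fewer than 4
#' concentrations) has `hitc = 0`.
#'
#' @param fit a [cr_fit()] object.
#' @param cutoff a [cr_cutoff()] object (`coff > 0` required).
#' @param dialect `"v4.1_median"` (default) scores group medians;
#'   `"v4.0_replicate"` scores each replicate individually. Identical when
#'   there is one replicate per concentration.
#' @return list of class `cr_hitcall`: `hitc`, `w_aic`, `w_median`,
#'   `w_top`, `active` (at the 0.90 default threshold).
#' @export
cr_hitcall <- function(fit, cutoff,
                       dialect = c("v4.1_median", "v4.0_replicate")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(fit, "cr_fit"), inherits(cutoff, "cr_cutoff"),
            cutoff$coff > 0)
  w <- .cr_winner_fit(fit)
  if (is.null(w)) {
    return(structure(list(hitc = 0, w_aic = 0, w_median = 0, w_top = 0,
                          active = FALSE, dialect = dialect),
                     class = "cr_hitcall"))
  }
  coff <- cutoff$coff
  conc <- fit$data$conc; resp <- fit$data$resp
  s <- exp(w$params$er)

  w_aic <- 1 / (1 + exp((w$aic - fit$aic_constant) / 2))

  if (dialect == "v4.1_median") {
    med <- tapply(resp, conc, stats::median)
    n_i <- tapply(resp, conc, length)
  } else {
    med <- resp
    n_i <- rep(1L, length(resp))
  }
  se <- s / sqrt(n_i)
  p_i <- (1 - stats::pt((coff - med) / se, df = .CR_T_DF)) +
    stats::pt((-coff - med) / se, df = .CR_T_DF)
  w_median <- max(pmin(pmax(p_i, 0), 1))

  ll_con <- .cr_ll_top_at(conc, resp, w$model, w,
                          target = if (w$top < 0) -coff else coff)
  lr <- max(w$loglik - ll_con, 0)
  w_top <- stats::pnorm(sign(abs(w$top) - coff) * sqrt(2 * lr))

  hitc <- w_aic * w_median * w_top
  structure(list(hitc = hitc, w_aic = w_aic, w_median = w_median,
                 w_top = w_top, active = cr_binarize(hitc),
                 dialect = dialect),
            class = "cr_hitcall")
}

#' Binarize a continuous hit call
#'
#' A continuous hit call at or above the threshold (default 0.90) is labeled
#' active; anything below is inactive.
#'
#' @param hitc continuous hit call(s) in `[0, 1]`.
#' @param threshold activity threshold; user-settable.
#' @return logical vector.
#' @export
cr_binarize <- function(hitc, threshold = 0.90) {
  if (any(!is.finite(hitc)) || any(hitc < 0) || any(hitc > 1))
    stop("hitc must lie in [0, 1]", call. = FALSE)
  hitc >= threshold
}

#' @export
print.cr_hitcall <- function(x, ...) {
  cat(sprintf("hitc = %.4f (%s)  [w_aic %.3f x w_median %.3f x w_top %.3f]\n",
              x$hitc, if (x$active) "active" else "inactive",
              x$w_aic, x$w_median, x$w_top))
  invisible(x)
}
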