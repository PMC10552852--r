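# Potency estimation from the winning fit: ACxx, ACC, ACB, BMD, and a
# 90% profile-likelihood interval on the BMD.

# maximal modeled response used to anchor percent-of-maximum potencies:
# the asymptote (tp) for hill/exp4/exp5, the interior peak for gnls, and the
# in-range top for the unbounded monotone models.
.cr_max_resp <- function(fit_model) {
  m <- fit_model$model
  p <- fit_model$params
  if (m %in% c("hill", "exp4", "exp5")) return(p$tp)
  if (m == "gnls") {
    # global peak: search well beyond the tested range
    rng <- c(p$ga / 100, p$la * 100)
    return(cr_top("gnls", p, rng, check = FALSE)$top)
  }
  fit_model$top
}

#' Potency estimates from a winning model fit
#'
#' Computes the potency set of the winning model: AC5/AC10/AC50/AC95 (the
#' concentrations producing 5/10/50/95% of the maximal modeled response),
#' ACB (first concentration reaching 3 x BMAD), ACC (concentration at the
#' efficacy cutoff), and BMD (concentration at the benchmark response
#' `bmr = 1.349 * onesd`). For models with a response asymptote (hill,
#' exp4, exp5, gnls) the maximal response is the asymptote/peak, so e.g.
#' AC50 of a hill fit equals `ga` exactly; for the unbounded monotone models
#' it is the modeled top within the tested range. Levels never attained are
#' reported absent (`NA`), not clamped. Inversion searches a log-spaced
#' window extending beyond the tested range (down to `cmin/1e4`, up to
#' `100 * cmax`), so potencies such as an AC50 below the lowest tested
#' concentration are representable.
#'
#' @param fit a [cr_fit()] object with a winning model, or a single
#'   `cr_modelfit`.
#' @param cutoff a [cr_cutoff()] object supplying `bmad`, `bmr`, `coff`.
#' @param conc_range tested concentration range; defaults to the fit's.
#' @return list of class `cr_potency` with elements `ac5`, `ac10`, `ac50`,
#'   `ac95`, `acb`, `acc`, `bmd`, `bmdl`, `bmdu` (all uM, possibly `NA`)
#'   and `bmr` (response units). `bmdl`/`bmdu` are filled by
#'   [cr_bmd_bounds()]; here they start absent.
#' @export
cr_potency <- function(fit, cutoff, conc_range = NULL) {
  w <- if (inherits(fit, "cr_fit")) .cr_winner_fit(fit) else fit
  if (is.null(conc_range) && inherits(fit, "cr_fit"))
    conc_range <- fit$conc_range
  empty <- structure(list(ac5 = NA_real_, ac10 = NA_real_, ac50 = NA_real_,
                          ac95 = NA_real_, acb = NA_real_, acc = NA_real_,
                          bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                          bmr = cutoff$bmr), class = "cr_potency")
  if (is.null(w) || !isTRUE(w$success) || w$model == "constant") return(empty)
  M <- .cr_max_resp(w)
  if (!is.finite(M) || M == 0) return(empty)
  s <- sign(M)
  win <- c(conc_range[1] / 1e4, conc_range[2] * 100)
  inv <- function(target) cr_inverse(w$model, w$params, target, win,
                                     check = FALSE)
  out <- empty
  out$ac5  <- inv(0.05 * M)
  out$ac10 <- inv(0.10 * M)
  out$ac50 <- inv(0.50 * M)
  out$ac95 <- inv(0.95 * M)
  out$acb  <- inv(s * 3 * cutoff$bmad)
  out$acc  <- inv(s * cutoff$coff)
  out$bmd  <- inv(s * cutoff$bmr)
  out
}

#' Profile-likelihood confidence bounds on the benchmark dose
#'
#' The winning model is reparameterized so that the BMD is explicit: for a
#' candidate BMD the scale parameter is pinned by the constraint
#' `f(BMD) = +/- BMR` and all remaining parameters (shape and error scale)
#' are re-optimized. A bound is the concentration at which this profiled
#' log-likelihood drops `qchisq(level, 1) / 2` (about 1.3528 at the default
#' 90% level) below the maximum. Bounds are searched outward on
#' log10-concentration within `[cmin/100, 100 * cmax]`; when no crossing is
#' bracketed (very noisy, near-flat data) the bound is reported absent.
#'
#' @param fit a [cr_fit()] object with a winning model.
#' @param bmr signed benchmark response used for the BMD constraint.
#' @param bmd the BMD point estimate (uM).
#' @param level confidence level, default 0.90.
#' @return list with `bmdl` and `bmdu` (uM or `NA`).
#' @export
cr_bmd_bounds <- function(fit, bmr, bmd, level = 0.90) {
  w <- .cr_winner_fit(fit)
  if (is.null(w) || !is.finite(bmd)) return(list(bmdl = NA_real_,
                                                 bmdu = NA_real_))
  conc <- fit$data$conc; resp <- fit$data$resp
  crit <- stats::qchisq(level, df = 1) / 2
  model <- w$model
  pll <- function(lb) {
    x0 <- 10^lb
    scale_fn <- function(up) {
      g <- cr_evaluate(model, up, x0, check = FALSE)
      if (!is.finite(g) || abs(g) < 1e-300) return(NA_real_)
      bmr / g
    }
    .cr_profile_ll(conc, resp, model, scale_fn, w)
  }
  thr <- w$loglik - crit
  lbmd <- log10(bmd)
  lims <- log10(c(fit$conc_range[1] / 100, fit$conc_range[2] * 100))
  search <- function(dir) {
    step <- 0.2 * dir
    lo <- lbmd
    f_lo <- min(pll(lo), w$loglik)  # clip tiny numerical excess
    if (f_lo < thr) return(NA_real_)  # profile already below at the estimate
    repeat {
      hi <- lo + step
      if ((dir < 0 && hi < lims[1]) || (dir > 0 && hi > lims[2]))
        return(NA_real_)
      f_hi <- pll(hi)
      if (is.finite(f_hi) && f_hi < thr) {
        r <- stats::uniroot(function(z) min(pll(z), w$loglik) - thr,
                            lower = min(lo, hi), upper = max(lo, hi),
                            f.lower = if (dir < 0) f_hi - thr else f_lo - thr,
                            f.upper = if (dir < 0) f_lo - thr else f_hi - thr,
                            tol = 1e-4)$root
        return(10^r)
      }
      if (is.finite(f_hi) && f_hi >= thr) f_lo <- f_hi else return(NA_real_)
      lo <- hi
    }
  }
  list(bmdl = search(-1), bmdu = search(+1))
}

#' @export
print.cr_potency <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.4g", v)
  cat("Potency estimates (uM):\n")
  cat(sprintf("  ac5 %s  ac10 %s  ac50 %s  ac95 %s\n",
              fmt(x$ac5), fmt(x$ac10), fmt(x$ac50), fmt(x$ac95)))
  cat(sprintf("  acb %s  acc %s\n", fmt(x$acb), fmt(x$acc)))
  cat(sprintf("  bmd %s [bmdl %s, bmdu %s] at bmr %.4g\n",
              fmt(x$bmd), fmt(x$bmdl), fmt(x$bmdu), x$bmr))
  invisible(x)
}
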