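#' Concentration-response model definitions
#'
#' The package fits ten parametric concentration-response models. All curves
#' pass through the origin in the limit of zero concentration, and all are
#' parameterized so that a single scale parameter (`tp` or `a`) carries the
#' response direction: positive for gain of signal, negative for loss.
#'
#' The model equations (concentration `x` in uM):
#' \describe{
#'   \item{constant}{\eqn{f(x) = 0}}
#'   \item{poly1}{\eqn{f(x) = a x}}
#'   \item{poly2}{\eqn{f(x) = a (x/b + (x/b)^2)}}
#'   \item{power}{\eqn{f(x) = a x^p}}
#'   \item{hill}{\eqn{f(x) = tp / (1 + (ga/x)^p)}}
#'   \item{gnls}{\eqn{f(x) = tp / [(1 + (ga/x)^p)(1 + (x/la)^q)]}}
#'   \item{exp2}{\eqn{f(x) = a (e^{x/b} - 1)}}
#'   \item{exp3}{\eqn{f(x) = a (e^{(x/b)^p} - 1)}}
#'   \item{exp4}{\eqn{f(x) = tp (1 - 2^{-x/ga})}}
#'   \item{exp5}{\eqn{f(x) = tp (1 - 2^{-(x/ga)^p})}}
#' }
#'
#' Shape parameters: `tp` top asymptote (response units), `ga` gain AC50 (uM),
#' `p` gain power, `la` loss AC50 (uM), `q` loss power, `a` scale (response
#' units), `b` concentration scale (uM). Every model additionally carries an
#' error-scale parameter `er` (the log of the Student-t residual scale), which
#' counts toward the parameter total used in the AIC.
#'
#' For gain-loss (`gnls`) fits a hard minimum-width constraint is imposed:
#' `log10(la) - log10(ga) >= 1.5`, deterring aberrant single-point hits on
#' designs with 0.5 log10 concentration spacing.
#'
#' @return `cr_models()` returns a data.frame with one row per model:
#'   `model` (id), `n_params` (shape parameters plus `er`), and `tie_rank`
#'   (fixed precedence used to break exact AIC ties after parameter count).
#' @examples
#' cr_models()
#' @export
cr_models <- function() {
  data.frame(
    model = c("constant", "poly1", "power", "exp2", "exp4",
              "hill", "exp3", "exp5", "poly2", "gnls"),
    n_params = c(1L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 3L, 6L),
    tie_rank = c(99L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
    stringsAsFactors = FALSE
  )
}

# shape-parameter names per model (er excluded; appended everywhere by fitters)
.cr_param_names <- list(
  constant = character(0),
  poly1 = "a",
  poly2 = c("a", "b"),
  power = c("a", "p"),
  hill  = c("tp", "ga", "p"),
  gnls  = c("tp", "ga", "p", "la", "q"),
  exp2  = c("a", "b"),
  exp3  = c("a", "b", "p"),
  exp4  = c("tp", "ga"),
  exp5  = c("tp", "ga", "p")
)

.cr_check_model <- function(model) {
  if (length(model) != 1L || !model %in% names(.cr_param_names))
    stop("unknown model id: ", paste(model, collapse = ", "), call. = FALSE)
  model
}

.cr_check_params <- function(model, params) {
  need <- .cr_param_names[[model]]
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("model '", model, "' needs parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- intersect(c("ga", "la", "b", "p", "q"), need)
  bad <- pos[vapply(pos, function(nm) !is.finite(params[[nm]]) || params[[nm]] <= 0,
                    logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (model == "gnls" &&
      log10(params[["la"]]) - log10(params[["ga"]]) < 1.5 - 1e-9)
    stop("gnls requires log10(la) - log10(ga) >= 1.5", call. = FALSE)
  invisible(params)
}

# exp() with the exponent capped to avoid Inf overflow inside the optimizer
.safe_exp <- function(z) exp(pmin(z, 700))

#' Evaluate a concentration-response model
#'
#' @param model model id, one of the rows of [cr_models()].
#' @param params named list or numeric vector of shape parameters (see
#'   [cr_models()]); the error parameter `er` is ignored if present.
#' @param conc numeric vector of strictly positive concentrations (uM).
#' @param check validate parameters before evaluating (set `FALSE` inside
#'   tight optimization loops).
#' @return numeric vector of modeled responses, one per concentration.
#' @examples
#' cr_evaluate("hill", list(tp = 50, ga = 1, p = 2), c(0.1, 1, 10))
#' @export
cr_evaluate <- function(model, params, conc, check = TRUE) {
  if (check) {
    .cr_check_model(model)
    if (any(!is.finite(conc)) || any(conc <= 0))
      stop("conc must be strictly positive and finite", call. = FALSE)
    params <- as.list(params)
    .cr_check_params(model, params)
  } else {
    params <- as.list(params)
  }
  x <- conc
  with(params, switch(model,
    constant = rep(0, length(x)),
    poly1 = a * x,
    poly2 = a * (x / b + (x / b)^2),
    power = a * x^p,
    hill  = tp / (1 + (ga / x)^p),
    gnls  = tp / ((1 + (ga / x)^p) * (1 + (x / la)^q)),
    exp2  = a * (.safe_exp(x / b) - 1),
    exp3  = a * (.safe_exp((x / b)^p) - 1),
    exp4  = tp * (1 - 2^(-x / ga)),
    exp5  = tp * (1 - 2^(-(x / ga)^p))
  ))
}

#' Modeled top of a curve over a concentration range
#'
#' The top is the signed modeled response of maximal absolute value over the
#' tested range. All models except `gnls` are monotone in |response| for
#' positive shape parameters, so their top sits at the maximum concentration;
#' the `gnls` interior peak is located by golden-section search on
#' log10-concentration seeded by a 100-point grid.
#'
#' @inheritParams cr_evaluate
#' @param conc_range length-2 numeric, `c(cmin, cmax)`, both positive.
#' @return list with `top` (signed response) and `top_conc` (uM).
#' @examples
#' cr_top("poly1", list(a = 2), c(0.1, 10))
#' @export
cr_top <- function(model, params, conc_range, check = TRUE) {
  if (check) {
    .cr_check_model(model)
    stopifnot(length(conc_range) == 2L, all(conc_range > 0),
              conc_range[1] < conc_range[2])
    .cr_check_params(model, as.list(params))
  }
  if (model == "constant") return(list(top = 0, top_conc = conc_range[2]))
  if (model != "gnls") {
    top <- cr_evaluate(model, params, conc_range[2], check = FALSE)
    return(list(top = top, top_conc = conc_range[2]))
  }
  lr <- log10(conc_range)
  grid <- 10^seq(lr[1], lr[2], length.out = 100)
  v <- abs(cr_evaluate("gnls", params, grid, check = FALSE))
  i <- which.max(v)
  lo <- log10(grid[max(1L, i - 1L)]); hi <- log10(grid[min(100L, i + 1L)])
  opt <- stats::optimize(function(lx) {
    abs(cr_evaluate("gnls", params, 10^lx, check = FALSE))
  }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  tc <- 10^opt$maximum
  list(top = cr_evaluate("gnls", params, tc, check = FALSE), top_conc = tc)
}

#' Invert a model: concentration producing a target response
#'
#' Finds the smallest concentration in `conc_range` at which the model equals
#' `target`, by bisection on log10-concentration. The target must have the
#' same sign as the curve. Returns `NA` (absent) when the level is never
#' attained inside the range.
#'
#' @inheritParams cr_top
#' @param target response level to invert at (same sign as the curve's top).
#' @return concentration in uM, or `NA_real_` when unattained.
#' @examples
#' cr_inverse("hill", list(tp = 50, ga = 1, p = 2), 25, c(1e-3, 100)) # == ga
#' @export
cr_inverse <- function(model, params, target, conc_range, check = TRUE) {
  if (check) {
    .cr_check_model(model)
    stopifnot(length(conc_range) == 2L, all(conc_range > 0),
              conc_range[1] < conc_range[2])
    .cr_check_params(model, as.list(params))
  }
  if (model == "constant" || !is.finite(target)) return(NA_real_)
  s <- sign(target)
  if (s == 0) return(NA_real_)
  g <- function(lx) s * cr_evaluate(model, params, 10^lx, check = FALSE) - s * target
  lr <- log10(conc_range)
  # scan a log-spaced grid for the first upcrossing (handles gnls non-monotony)
  grid <- seq(lr[1], lr[2], length.out = 200)
  v <- vapply(grid, g, numeric(1))
  if (v[1] >= 0) return(10^lr[1])
  i <- which(v >= 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  root <- stats::uniroot(g, lower = grid[i - 1L], upper = grid[i],
                         tol = 1e-10)$root
  10^root
}
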