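#' @export
print.cr_fit <- function(x, ...) {
  cat("Concentration-response fit (", x$direction, ")\n", sep = "")
  cat(sprintf("  %d observations, %d distinct concentrations in [%.4g, %.4g] uM\n",
              nrow(x$data), x$n_conc, x$conc_range[1], x$conc_range[2]))
  if (x$winner == "none") {
    cat("  winning model: none (unable to fit)\n")
  } else {
    w <- .cr_winner_fit(x)
    cat(sprintf("  winning model: %s (AIC %.2f; constant AIC %.2f)\n",
                x$winner, w$aic, x$aic_constant))
    cat(sprintf("  top: %.4g at %.4g uM; rmse: %.4g\n",
                w$top, w$top_conc, w$rmse))
  }
  invisible(x)
}

#' Summarize a concentration-response fit
#'
#' @param object a [cr_fit()] object.
#' @param ... unused.
#' @return data.frame with one row per fitted model: `model`, `n_params`,
#'   `loglik`, `aic`, `rmse`, `top`, `success`, `winner` flag, sorted by AIC.
#' @export
summary.cr_fit <- function(object, ...) {
  if (!length(object$fits)) {
    out <- data.frame(model = character(0), n_params = integer(0),
                      loglik = numeric(0), aic = numeric(0),
                      rmse = numeric(0), top = numeric(0),
                      success = logical(0), winner = logical(0))
  } else {
    out <- do.call(rbind, lapply(object$fits, function(f) {
      data.frame(model = f$model, n_params = f$n_params, loglik = f$loglik,
                 aic = f$aic, rmse = f$rmse, top = f$top, success = f$success)
    }))
    out$winner <- out$model == object$winner
    out <- out[order(out$aic), ]
    rownames(out) <- NULL
  }
  class(out) <- c("summary.cr_fit", "data.frame")
  out
}

#' @export
coef.cr_fit <- function(object, model = object$winner, ...) {
  if (model == "none" || is.null(object$fits[[model]])) return(NULL)
  unlist(object$fits[[model]]$params)
}

#' @export
predict.cr_fit <- function(object, newdata = NULL, model = object$winner,
                           ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  if (model == "none") return(rep(NA_real_, length(conc)))
  cr_evaluate(model, object$fits[[model]]$params, conc)
}

#' @export
residuals.cr_fit <- function(object, model = object$winner, ...) {
  if (model == "none") return(rep(NA_real_, nrow(object$data)))
  object$data$resp - predict(object, model = model)
}

#' Simulate responses from a fitted curve
#'
#' Draws new response vectors at the observed concentrations from the winning
#' model with Student-t(4) noise at the fitted error scale.
#'
#' @param object a [cr_fit()] object with a winning model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed (caller RNG state is restored).
#' @param ... unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.cr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  w <- .cr_winner_fit(object)
  if (is.null(w)) stop("no winning model to simulate from", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- predict(object)
  s <- exp(w$params$er)
  out <- as.data.frame(replicate(
    nsim, mu + s * stats::rt(length(mu), df = .CR_T_DF), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Plot a concentration-response fit
#'
#' Base-graphics plot of the observed responses on a log10 concentration
#' axis, the winning model curve, and (optionally) the remaining fitted
#' models in gray.
#'
#' @param x a [cr_fit()] object.
#' @param all_models draw non-winning models too.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cr_fit <- function(x, all_models = TRUE, ...) {
  d <- x$data
  graphics::plot(d$conc, d$resp, log = "x", xlab = "concentration (uM)",
                 ylab = "response", ...)
  if (!length(x$fits)) return(invisible(x))
  grid <- 10^seq(log10(x$conc_range[1]), log10(x$conc_range[2]),
                 length.out = 120)
  if (all_models) {
    for (f in x$fits) {
      if (f$model %in% c("constant", x$winner) || !f$success) next
      graphics::lines(grid, cr_evaluate(f$model, f$params, grid,
                                        check = FALSE), col = "gray70")
    }
  }
  w <- .cr_winner_fit(x)
  if (!is.null(w))
    graphics::lines(grid, cr_evaluate(w$model, w$params, grid,
                                      check = FALSE), col = "blue", lwd = 2)
  invisible(x)
}

#' @export
print.cr_modelfit <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$model,
              if (x$success) "converged" else "FAILED"))
  if (x$success) {
    cat(sprintf("  aic %.3f  loglik %.3f  rmse %.4g  top %.4g @ %.4g uM\n",
                x$aic, x$loglik, x$rmse, x$top, x$top_conc))
    cat("  params:", paste(names(x$params),
                           sprintf("%.4g", unlist(x$params)),
                           sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
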