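# Shared fixtures: all test data is generated in code.

# a minimal fit-like object for unit tests of downstream logic (fitcat,
# flags) that only need a winner, its top, and the tested range
fake_fit <- function(winner = "hill", top = 40, top_conc = 100,
                     conc_range = c(0.03, 94.87), params = list(),
                     rmse = 1, conc = NULL, resp = NULL) {
  if (is.null(conc)) {
    conc <- rep(10^seq(log10(conc_range[1]), log10(conc_range[2]),
                       length.out = 8), each = 3)
    resp <- rep(0, length(conc))
  }
  wfit <- structure(list(model = winner, params = params, loglik = 0,
                         aic = 0, rmse = rmse, top = top,
                         top_conc = top_conc, n_params = 4, success = TRUE),
                    class = "cr_modelfit")
  fits <- list()
  fits[[winner]] <- wfit
  structure(list(data = data.frame(conc = conc, resp = resp),
                 conc_range = conc_range, n_conc = length(unique(conc)),
                 direction = "bidirectional", fits = fits, winner = winner,
                 aic_constant = 100), class = "cr_fit")
}

fake_hit <- function(active = TRUE, hitc = if (active) 0.99 else 0.1) {
  structure(list(hitc = hitc, w_aic = 1, w_median = 1, w_top = hitc,
                 active = active), class = "cr_hitcall")
}

fake_potency <- function(ac50 = 1, ac95 = 10, bmd = NA_real_, ...) {
  out <- structure(list(ac5 = NA_real_, ac10 = NA_real_, ac50 = ac50,
                        ac95 = ac95, acb = NA_real_, acc = NA_real_,
                        bmd = bmd, bmdl = NA_real_, bmdu = NA_real_,
                        bmr = 5), class = "cr_potency")
  utils::modifyList(out, list(...))
}

std_cutoff <- function(bmad = 2, onesd = 1.5, coff = 3 * bmad) {
  out <- cr_cutoff(bmad = bmad, onesd = onesd)
  out$coff <- coff
  out
}

# random series with a random generating model, for property fuzzing
random_series <- function(seed) {
  set.seed(seed)
  model <- sample(setdiff(cr_models()$model, "constant"), 1)
  dir <- sample(c(-1, 1), 1)
  params <- switch(model,
    poly1 = list(a = dir * runif(1, 0.1, 2)),
    poly2 = list(a = dir * runif(1, 1, 30), b = 10^runif(1, -0.5, 2)),
    power = list(a = dir * runif(1, 0.5, 10), p = runif(1, 0.5, 2)),
    hill  = list(tp = dir * runif(1, 10, 80), ga = 10^runif(1, -1, 1.5),
                 p = runif(1, 0.7, 4)),
    gnls  = list(tp = dir * runif(1, 10, 80), ga = 10^runif(1, -1, 0.5),
                 p = runif(1, 1, 4), la = NA, q = runif(1, 1, 4)),
    exp2  = list(a = dir * runif(1, 1, 20), b = 10^runif(1, 0.5, 2)),
    exp3  = list(a = dir * runif(1, 1, 20), b = 10^runif(1, 0.5, 2),
                 p = runif(1, 0.5, 1.5)),
    exp4  = list(tp = dir * runif(1, 10, 80), ga = 10^runif(1, -1, 1.5)),
    exp5  = list(tp = dir * runif(1, 10, 80), ga = 10^runif(1, -1, 1.5),
                 p = runif(1, 0.7, 4)))
  if (model == "gnls")
    params$la <- params$ga * 10^runif(1, 1.5, 2.5)
  n_conc <- sample(4:10, 1)
  n_rep <- sample(1:3, 1)
  cr_sim_series(model, params, n_conc = n_conc, n_rep = n_rep,
                noise_scale = runif(1, 1, 8), seed = seed + 100000L)
}
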