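test_that("noiseless data recover the generating parameters", {
  s <- cr_sim_series("hill", list(tp = 50, ga = 1, p = 2), noise_scale = 0)
  f <- cr_fit_one(s$conc, s$resp, "hill")
  expect_true(f$success)
  expect_lt(abs(f$params$ga - 1), 0.01)
  expect_lt(abs(f$params$tp - 50) / 50, 0.01)
  expect_lt(f$rmse, 0.05)
})

test_that("an all-zero series fits poly1 with zero slope and zero rmse", {
  conc <- rep(c(0.1, 0.3, 1, 3, 10), each = 2)
  f <- cr_fit_one(conc, rep(0, 10), "poly1")
  expect_lt(abs(f$params$a), 1e-4)
  expect_lt(f$rmse, 1e-4)
})

test_that("gnls fits always respect the 1.5 log10 minimum width", {
  for (seed in c(2, 5, 9)) {
    s <- random_series(seed)
    f <- cr_fit_one(s$conc, s$resp, "gnls")
    if (!f$success) next
    expect_gte(log10(f$params$la) - log10(f$params$ga), 1.5 - 1e-9)
  }
})

test_that("aic is 2k - 2 loglik and the winner minimizes it", {
  s <- cr_sim_series("exp4", list(tp = -40, ga = 2), noise_scale = 3,
                     seed = 21)
  fit <- cr_fit(s$conc, s$resp)
  for (f in fit$fits)
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik)
  w <- fit$fits[[fit$winner]]
  ok <- vapply(fit$fits, function(f) f$model == "constant" || !f$success ||
                 f$aic >= w$aic, logical(1))
  expect_true(all(ok))
  expect_false(fit$winner %in% c("none", "constant"))
})

test_that("series with fewer than 4 concentrations cannot be fit", {
  fit <- cr_fit(rep(c(0.1, 1, 10), each = 3), rnorm(9, 0, 1))
  expect_equal(fit$winner, "none")
  expect_length(fit$fits, 0)
  # 4 distinct concentrations is enough
  fit4 <- cr_fit(c(0.1, 1, 10, 100), c(0, 1, 5, 10))
  expect_false(fit4$winner == "none")
})

test_that("equal-AIC ties go to the fixed model precedence", {
  # all-zero responses: every model collapses to the zero curve with the
  # same likelihood, so equal-parameter-count models tie exactly
  conc <- rep(c(0.1, 0.3, 1, 3, 10), each = 2)
  resp <- rep(0, 10)
  f1 <- cr_fit(conc, resp, models = c("exp2", "power", "exp4"))
  f2 <- cr_fit(conc, resp, models = c("exp4", "exp2", "power"))
  aics <- vapply(f1$fits[c("power", "exp2", "exp4")], `[[`, numeric(1),
                 "aic")
  expect_equal(diff(range(aics)), 0, tolerance = 1e-6)
  expect_equal(f1$winner, "power")
  expect_equal(f2$winner, "power")
  # fewer parameters beat more at equal likelihood
  f3 <- cr_fit(conc, resp)
  expect_equal(f3$winner, "poly1")
})

test_that("direction constraints pin the response sign", {
  s <- cr_sim_series("hill", list(tp = -50, ga = 1, p = 2),
                     noise_scale = 2, seed = 31)
  f_loss <- cr_fit(s$conc, s$resp, direction = "loss_only")
  expect_lte(f_loss$fits[[f_loss$winner]]$top, 0)
  f_gain <- cr_fit(s$conc, s$resp, direction = "gain_only")
  if (f_gain$winner != "none")
    expect_gte(f_gain$fits[[f_gain$winner]]$top, 0)
})

test_that("bidirectional fitting mirrors under response sign flip", {
  for (seed in c(3, 17)) {
    s <- random_series(seed)
    fa <- cr_fit(s$conc, s$resp)
    fb <- cr_fit(s$conc, -s$resp)
    expect_equal(fa$winner, fb$winner)
    wa <- fa$fits[[fa$winner]]; wb <- fb$fits[[fb$winner]]
    expect_lt(abs(wa$aic - wb$aic), 1e-6)
    expect_equal(wa$top, -wb$top, tolerance = 1e-6)
  }
})

test_that("the generating model stays AIC-competitive under 5% noise", {
  # identifiable generator shapes only: poly2 and exp3 are routinely
  # mimicked within noise by power/exp2-type rivals, so the property does
  # not hold for them (see the methods vignette); scaled-down sample size
  gens <- list(poly1 = list(a = 0.5), power = list(a = 5, p = 0.5),
               hill = list(tp = 50, ga = 1, p = 2),
               gnls = list(tp = 50, ga = 0.3, p = 2, la = 30, q = 2),
               exp2 = list(a = 2, b = 30), exp4 = list(tp = 50, ga = 1),
               exp5 = list(tp = 50, ga = 1, p = 1.5))
  cmax <- 0.03 * 10^3.5
  n_ok <- 0L; n <- 0L
  for (model in names(gens)) {
    topm <- abs(cr_top(model, gens[[model]], c(0.03, cmax))$top)
    for (seed in 1:25) {
      s <- cr_sim_series(model, gens[[model]],
                         noise_scale = 0.05 * topm / sqrt(2), seed = seed)
      fit <- cr_fit(s$conc, s$resp)
      n <- n + 1L
      if (fit$fits[[model]]$aic <= fit$fits[[fit$winner]]$aic + 2)
        n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  s <- cr_sim_series("hill", list(tp = 50, ga = 1, p = 2), noise_scale = 2,
                     seed = 41)
  fit <- cr_fit(s$conc, s$resp)
  expect_named(coef(fit, model = "hill"), c("tp", "ga", "p", "er"))
  pr <- predict(fit, newdata = c(1e-4))
  expect_lt(abs(pr), 1)
  expect_equal(residuals(fit), s$resp - predict(fit))
  sm <- summary(fit)
  expect_true(sm$winner[1])  # sorted by AIC, winner first
  sims <- simulate(fit, nsim = 2, seed = 5)
  sims2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sims, sims2)
  expect_equal(dim(sims), c(24L, 2L))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
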