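test_that("model equations evaluate to their closed forms", {
  expect_equal(cr_evaluate("constant", list(), 10), 0)
  expect_equal(cr_evaluate("hill", list(tp = 50, ga = 1, p = 2), 1), 25)
  expect_equal(cr_evaluate("exp4", list(tp = 40, ga = 1), 1), 20)
  expect_equal(cr_evaluate("poly1", list(a = 2), 3), 6)
  expect_equal(cr_evaluate("poly2", list(a = 3, b = 2), 4), 3 * (2 + 4))
  expect_equal(cr_evaluate("power", list(a = 2, p = 3), 2), 16)
  expect_equal(cr_evaluate("exp2", list(a = 5, b = 2), 2), 5 * (exp(1) - 1))
  expect_equal(cr_evaluate("exp3", list(a = 5, b = 2, p = 2), 4),
               5 * (exp(4) - 1))
  expect_equal(cr_evaluate("exp5", list(tp = 50, ga = 3, p = 1.2), 3), 25)
  expect_equal(
    cr_evaluate("gnls", list(tp = 48, ga = 1, p = 2, la = 100, q = 2), 1),
    48 / (2 * (1 + 1e-4)))
})

test_that("all curves pass through the origin in the conc -> 0 limit", {
  pars <- list(constant = list(), poly1 = list(a = -3),
               poly2 = list(a = 2, b = 1), power = list(a = 2, p = 0.5),
               hill = list(tp = 50, ga = 1, p = 1),
               gnls = list(tp = 50, ga = 1, p = 1, la = 1000, q = 1),
               exp2 = list(a = 2, b = 1), exp3 = list(a = 2, b = 1, p = 1),
               exp4 = list(tp = -50, ga = 1), exp5 = list(tp = 50, ga = 1,
                                                          p = 1))
  for (m in names(pars))
    expect_lt(abs(cr_evaluate(m, pars[[m]], 1e-12)), 1e-5)
})

test_that("invalid model ids, parameters and concentrations are rejected", {
  expect_error(cr_evaluate("spline", list(), 1), "unknown model")
  expect_error(cr_evaluate("hill", list(tp = 50, ga = 1, p = 2), -1),
               "positive")
  expect_error(cr_evaluate("hill", list(tp = 50, ga = -1, p = 2), 1),
               "positive")
  expect_error(cr_evaluate("hill", list(tp = 50, p = 2), 1), "needs")
  # gnls minimum-width constraint is part of parameter validity
  expect_error(
    cr_evaluate("gnls", list(tp = 1, ga = 1, p = 1, la = 10, q = 1), 1),
    "1.5")
})

test_that("monotone models are monotone in concentration", {
  grid <- 10^seq(-2, 2, length.out = 60)
  cases <- list(
    list("poly1", list(a = -2)), list("power", list(a = 3, p = 1.5)),
    list("hill", list(tp = -40, ga = 0.5, p = 2)),
    list("exp2", list(a = 1, b = 10)),
    list("exp3", list(a = 1, b = 10, p = 0.8)),
    list("exp4", list(tp = 40, ga = 2)),
    list("exp5", list(tp = 40, ga = 2, p = 3)),
    list("poly2", list(a = 2, b = 5)))
  for (cs in cases) {
    v <- cr_evaluate(cs[[1]], cs[[2]], grid)
    expect_true(all(diff(abs(v)) >= -1e-12), label = cs[[1]])
  }
})

test_that("model top sits at cmax for monotone models", {
  expect_equal(cr_top("poly1", list(a = 2), c(0.1, 10)),
               list(top = 20, top_conc = 10))
  tt <- cr_top("hill", list(tp = -30, ga = 1, p = 1), c(0.001, 100))
  expect_equal(tt$top_conc, 100)
  expect_equal(tt$top, -30 / (1 + 1 / 100))  # about -29.7
})

test_that("gnls interior peak matches a dense-grid brute-force oracle", {
  params <- list(tp = 50, ga = 0.1, p = 4, la = 30, q = 4)
  rng <- c(0.001, 100)
  tt <- cr_top("gnls", params, rng)
  expect_gt(tt$top_conc, rng[1])
  expect_lt(tt$top_conc, rng[2])
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 20000)
  v <- cr_evaluate("gnls", params, grid)
  i <- which.max(abs(v))
  expect_equal(tt$top, v[i], tolerance = 1e-6)
  expect_equal(log10(tt$top_conc), log10(grid[i]), tolerance = 1e-3)
})

test_that("inversion recovers closed-form potencies", {
  expect_equal(cr_inverse("hill", list(tp = 50, ga = 1, p = 2), 25,
                          c(1e-3, 100)), 1, tolerance = 1e-9)
  expect_equal(cr_inverse("exp5", list(tp = 50, ga = 3, p = 1.2), 25,
                          c(1e-3, 100)), 3, tolerance = 1e-9)
  expect_equal(cr_inverse("exp4", list(tp = 40, ga = 1), 20,
                          c(1e-3, 100)), 1, tolerance = 1e-9)
  expect_equal(cr_inverse("poly1", list(a = 1), 7, c(0.1, 10)), 7,
               tolerance = 1e-8)
})

test_that("targets beyond the attainable response are absent, not errors", {
  expect_true(is.na(cr_inverse("hill", list(tp = 50, ga = 1, p = 2), 60,
                               c(1e-3, 100))))
  expect_true(is.na(cr_inverse("poly1", list(a = 1), 100, c(0.1, 10))))
  expect_true(is.na(cr_inverse("constant", list(), 5, c(0.1, 10))))
})

test_that("inverse is the left inverse of evaluate over random draws", {
  # property: inverse(evaluate(x)) == x to 1e-6 relative, random models
  set.seed(42)
  n_bad <- 0L
  for (i in 1:250) {
    s <- random_series(i)
    if (s$model %in% c("gnls")) next  # non-injective; checked via potency
    x <- 10^runif(1, log10(min(s$conc)), log10(max(s$conc)))
    y <- cr_evaluate(s$model, s$params, x)
    if (abs(y) < 1e-12) next
    # skip the numerically flat asymptote plateau, where inversion is
    # ill-posed by construction
    if (!is.null(s$params$tp) && abs(y) > 0.99 * abs(s$params$tp)) next
    xr <- cr_inverse(s$model, s$params, y, range(s$conc))
    if (is.na(xr) || abs(xr - x) / x > 1e-6) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})
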