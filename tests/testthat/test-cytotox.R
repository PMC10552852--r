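burst_row <- function(chem = "c1", ep = "e1", tested = TRUE, active = TRUE,
                      ac50 = 10, model = "hill", prolif = FALSE) {
  data.frame(chemical_id = chem, endpoint_id = ep, tested = tested,
             active = active, ac50 = ac50, winning_model = model,
             proliferation_direction = prolif, stringsAsFactors = FALSE)
}

test_that("burst filtering drops gain-loss fits and proliferation rows", {
  tbl <- rbind(burst_row(ep = "e1", model = "gnls"),
               burst_row(ep = "e2", prolif = TRUE),
               burst_row(ep = "e3", model = "hill"))
  kept <- cr_burst_filter(tbl)
  expect_equal(kept$endpoint_id, "e3")
  # direction inferred from the top sign when the annotation is missing
  tbl2 <- data.frame(chemical_id = "c", endpoint_id = c("a", "b"),
                     tested = TRUE, active = TRUE, ac50 = 1,
                     winning_model = "hill", top = c(5, -5))
  expect_equal(cr_burst_filter(tbl2)$endpoint_id, "b")
})

test_that("the burst point is the median log10 AC50, with a 1000 uM default", {
  # fewer than 3 qualifying endpoints -> default
  two <- rbind(burst_row(ep = "e1", ac50 = 1), burst_row(ep = "e2", ac50 = 2))
  bp <- cr_burst_point(two)
  expect_true(bp$used_default)
  expect_equal(10^bp$cyto_pt, 1000)
  one <- burst_row(ac50 = 5)
  expect_true(cr_burst_point(one)$used_default)
  # median of log10 {1, 10, 100} uM is 1 log10-uM
  three <- rbind(burst_row(ep = "e1", ac50 = 1),
                 burst_row(ep = "e2", ac50 = 10),
                 burst_row(ep = "e3", ac50 = 100))
  bp <- cr_burst_point(three)
  expect_false(bp$used_default)
  expect_equal(bp$cyto_pt, 1)
  # invariant to row order
  expect_equal(cr_burst_point(three[c(3, 1, 2), ])$cyto_pt, 1)
})

# a chemical tested in n endpoints whose active log10 AC50s have an exact
# scaled MAD: values m, m +/- target/1.4826 (5 actives)
mad_chem <- function(chem, n_tested, m, target_mad) {
  d <- target_mad / 1.4826
  l10 <- c(m - d, m - d, m, m + d, m + d)
  act <- c(rep(TRUE, 5), rep(FALSE, n_tested - 5))
  data.frame(chemical_id = chem,
             endpoint_id = sprintf("e%03d", seq_len(n_tested)),
             tested = TRUE, active = act,
             ac50 = c(10^l10, rep(NA_real_, n_tested - 5)),
             winning_model = "hill", proliferation_direction = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the global MAD is the median of qualifying per-chemical MADs", {
  tbl <- rbind(mad_chem("c1", 60, 0.5, 0.1), mad_chem("c2", 70, 1, 0.2),
               mad_chem("c3", 80, 1.5, 0.3))
  expect_equal(cr_global_mad(tbl), 0.2)
  # chemicals below 60 tested endpoints are excluded even at high hit rates
  low <- mad_chem("c4", 59, 0, 0.9)
  low$active <- rep(c(TRUE, FALSE), length.out = 59)
  low$ac50[low$active] <- 10^rnorm(sum(low$active))
  expect_equal(cr_global_mad(rbind(tbl, low)), 0.2)
  # a 3/60 hit rate is not "above 5%"
  borderline <- mad_chem("c5", 60, 0, 0)
  borderline$active[4:5] <- FALSE
  expect_equal(cr_global_mad(rbind(tbl, borderline)), 0.2)
  # identical actives give zero dispersion
  flat <- rbind(mad_chem("c1", 60, 1, 0), mad_chem("c2", 60, 2, 0))
  expect_equal(cr_global_mad(flat), 0)
  expect_error(cr_global_mad(mad_chem("c9", 10, 0, 0.1)), "unusable")
})

test_that("the lower bound is the burst point minus 3 global MADs", {
  expect_equal(cr_lower_bound(1, 0), 1)
  expect_equal(cr_lower_bound(0.05, 0.163), -0.439)
  expect_equal(cr_lower_bound(2, 0.5), 0.5)
  # strictly decreasing in the global MAD
  g <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(cr_lower_bound(1, g)) < 0))
})

test_that("the burst summary ties the pieces together", {
  tbl <- rbind(mad_chem("c1", 60, 0.5, 0.2), mad_chem("c2", 70, 1, 0.2),
               burst_row(chem = "c3", ep = "e1"),
               burst_row(chem = "c3", ep = "e2"))
  res <- cr_burst(tbl)
  expect_equal(nrow(res), 3)
  c3 <- res[res$chemical_id == "c3", ]
  expect_true(c3$used_default)
  expect_equal(c3$cyto_pt_um, 1000)
  c1 <- res[res$chemical_id == "c1", ]
  expect_false(c1$used_default)
  expect_equal(c1$cyto_pt, 0.5)
  expect_equal(c1$lower_bound, 0.5 - 3 * 0.2)
  expect_equal(unique(res$global_mad), 0.2)
})

test_that("simulated burst tables plant recoverable medians", {
  tbl <- cr_sim_burst(3, n_endpoints = 60, median_l10 = c(0.5, 1, 1.5),
                      dispersion = 0, active_rate = 0.2, seed = 2)
  res <- cr_burst(tbl)
  expect_equal(res$cyto_pt, c(0.5, 1, 1.5))
  expect_equal(unique(res$global_mad), 0)
  # identical seeds give identical tables
  expect_identical(tbl, cr_sim_burst(3, 60, c(0.5, 1, 1.5), 0, 0.2,
                                     seed = 2))
})
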