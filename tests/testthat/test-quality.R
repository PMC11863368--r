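# Quality metrics: signed errors, MAD/Max, bidirectional R^2, Kendall
# concordance and its significance-filtered variant, bootstrap uncertainties.

test_that("signed errors reproduce the printed error rows", {
  p <- fixture_predictions("brd4", "VIS")
  e <- signed_errors(p)
  expect_printed(e[["L4->L2"]], 1.78)
  expect_printed(e[["L1->L3"]], 0.17)
  # calc == exp gives zero; reversal flips the sign
  p0 <- prediction_set("A->B", 2, 0.1, 2)
  expect_identical(unname(signed_errors(p0)), 0)
  p1 <- prediction_set("A->B", 3, 0.1, 2)
  p1r <- prediction_set("B->A", -3, 0.1, -2)
  expect_identical(unname(signed_errors(p1)), -unname(signed_errors(p1r)))
})

test_that("MAD and Max cover the degenerate cases", {
  expect_identical(mad_max(c(0, 0)), c(mad = 0, max = 0))
  expect_identical(mad_max(-5), c(mad = 5, max = 5))
  expect_error(mad_max(numeric(0)), "at least one")
  mm <- mad_max(c(-2.14, 1.51, -1.57, 6.52, -8.91, -2.56))
  expect_printed(mm[["mad"]], 3.9, digits = 1)
  expect_printed(mm[["max"]], 8.9, digits = 1)
})

test_that("bidirectional R^2 matches an independent mirrored correlation", {
  p <- fixture_predictions("lysozyme", "VIS")
  r2 <- r2_bidirectional(p)
  # independent route: plain Pearson correlation on the mirrored point set
  expect_equal(r2, cor(c(p$calc, -p$calc), c(p$exp, -p$exp))^2,
               tolerance = 1e-12)
  # perfect agreement
  pp <- prediction_set(c("a", "b"), c(1, 2), c(0, 0), c(1, 2))
  expect_equal(r2_bidirectional(pp), 1)
  expect_error(r2_bidirectional(prediction_set(c("a", "b"), c(0, 0),
                                               c(0, 0), c(1, 2))),
               "zero variance")
})

test_that("Kendall tau matches stats::cor on untied data and honours ties", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    p <- prediction_set(paste0("t", 1:8), x, rep(0.1, 8), y)
    expect_equal(kendall_tau_r(p), cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
  conc <- prediction_set(c("a", "b", "c"), c(1, 2, 3), rep(0, 3), c(4, 5, 6))
  expect_identical(kendall_tau_r(conc), 1)
  anti <- prediction_set(c("a", "b", "c"), c(1, 2, 3), rep(0, 3), c(6, 5, 4))
  expect_identical(kendall_tau_r(anti), -1)
  # one experimental tie: counted in the denominator by default, dropped by flag
  tied <- prediction_set(c("a", "b", "c"), c(1, 2, 3), rep(0, 3), c(4, 4, 6))
  expect_equal(kendall_tau_r(tied, ties = "count"), 2 / 3)
  expect_equal(kendall_tau_r(tied, ties = "drop"), 1)
})

test_that("tau monotonicity: breaking a concordant pair lowers tau", {
  p <- prediction_set(paste0("t", 1:4), c(1, 2, 3, 4), rep(0, 4), c(1, 2, 3, 4))
  tau0 <- kendall_tau_r(p)
  swapped <- p
  swapped$calc <- c(2, 1, 3, 4)
  expect_lt(kendall_tau_r(swapped), tau0)
})

test_that("tau_r90 applies the 90% significance filter", {
  # SIS Tol->Ben: |-0.26| < 1.645 * 0.19 -> excluded
  sis <- fixture_predictions("lysozyme", "SIS")
  t_sis <- tau_r90(sis)
  expect_true("Tol->Ben" %in% t_sis$excluded)
  # VIS Tol->Ben: |-0.19| >= 1.645 * 0.04 -> retained
  vis <- fixture_predictions("lysozyme", "VIS")
  t_vis <- tau_r90(vis)
  expect_true("Tol->Ben" %in% t_vis$retained)
  expect_identical(length(t_vis$excluded), 0L)
  # enormous values, fully concordant -> 1
  big <- prediction_set(c("a", "b", "c"), c(10, 20, 30), rep(0.1, 3),
                        c(1, 2, 3))
  expect_identical(tau_r90(big)$tau, 1)
  # fewer than two survivors -> undefined, not an error
  tiny <- prediction_set(c("a", "b"), c(0.01, 0.02), c(1, 1), c(1, 2))
  expect_true(is.na(tau_r90(tiny)$tau))
})

test_that("error metrics and R2 are invariant under direction flips", {
  # MAD, Max and the bidirectional R^2 are exactly direction-free; Kendall
  # concordance over relative values is not (it compares values across
  # transformations, so flipping one changes its pair orderings) -- that
  # direction dependence is the very reason the mirrored R^2 exists.
  p <- fixture_predictions("lysozyme", "VIS")
  base <- c(mad_max(abs(signed_errors(p))), r2 = r2_bidirectional(p))
  set.seed(7)
  for (i in 1:10) {
    flip <- runif(nrow(p)) < 0.5
    q <- p
    q$transformation[flip] <- paste0("r:", q$transformation[flip])
    q$calc[flip] <- -q$calc[flip]
    q$exp[flip] <- -q$exp[flip]
    got <- c(mad_max(abs(signed_errors(q))), r2 = r2_bidirectional(q))
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("bootstrap uncertainties behave structurally", {
  p <- prediction_set(paste0("t", 1:5), c(1, -2, 3, -4, 5), rep(0, 5),
                      c(1.2, -1.8, 2.5, -4.4, 5.2))
  q0 <- quality_report(p, sets = 100, seed = 1)
  expect_identical(unname(q0$sd[c("mad", "max", "r2")]), c(0, 0, 0))
  # point estimates are the unperturbed metrics
  expect_equal(q0$estimates[["mad"]], mad_max(signed_errors(p))[["mad"]])
  # doubling all SEs roughly doubles the MAD bootstrap sd (same seed)
  p1 <- p; p1$calc_se <- rep(0.3, 5)
  p2 <- p; p2$calc_se <- rep(0.6, 5)
  s1 <- quality_report(p1, sets = 400, seed = 5)$sd[["mad"]]
  s2 <- quality_report(p2, sets = 400, seed = 5)$sd[["mad"]]
  expect_lt(abs(s2 / s1 - 2), 0.35)
})

test_that("experimental sigmas join the bootstrap when provided", {
  p <- prediction_set(c("a", "b", "c"), c(1, 2, 3), c(0, 0, 0), c(1, 2, 3),
                      exp_sigma = c(0.5, 0.5, 0.5))
  q <- quality_report(p, sets = 300, seed = 2)
  expect_gt(q$sd[["mad"]], 0)
})
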