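# Replicate aggregation, leg combination, precision ratios, cycles.

test_that("aggregation reproduces the printed ensemble rows", {
  recs <- data.frame(transformation = "L1->L3", condition = "VIS",
                     replicate = 1:5,
                     ddg_kjmol = c(1.45, 1.18, 1.80, 1.30, 1.40),
                     sigma_kjmol = rep(0.10, 5))
  s <- aggregate_replicates(recs)
  expect_printed(s$mean_kjmol, 1.43)
  expect_printed(s$se_kjmol, 0.10)
  recs2 <- data.frame(transformation = "Tol->Ben", condition = "SIS",
                      replicate = 1:5,
                      ddg_kjmol = c(-0.38, -0.51, -0.07, -0.72, 0.39),
                      sigma_kjmol = rep(0.07, 5))
  s2 <- aggregate_replicates(recs2)
  expect_printed(s2$mean_kjmol, -0.26)
  expect_printed(s2$se_kjmol, 0.19)
})

test_that("degenerate and invalid replicate sets are handled", {
  same <- data.frame(transformation = "A->B", condition = "VIS",
                     replicate = 1:5, ddg_kjmol = rep(2, 5),
                     sigma_kjmol = rep(0.1, 5))
  expect_identical(aggregate_replicates(same)$se_kjmol, 0)
  one <- same[1, ]
  expect_error(aggregate_replicates(one), "at least 2")
  dup <- same; dup$replicate <- c(1, 1, 2, 3, 4)
  expect_error(aggregate_replicates(dup), "duplicate")
})

test_that("leg combination uses quadrature and is antisymmetric", {
  expect_equal(combine_legs(c(10, 0.3), c(2, 0.4)), c(ddg = 8, se = 0.5))
  expect_equal(combine_legs(c(5, 0.2), c(5, 0.2))[["ddg"]], 0)
  a <- combine_legs(c(3, 0.1), c(1, 0.2))
  b <- combine_legs(c(1, 0.2), c(3, 0.1))
  expect_equal(a[["ddg"]], -b[["ddg"]])
  expect_equal(a[["se"]], b[["se"]])
})

test_that("precision ratio behaves linearly in the replicate spread", {
  vals <- c(9.01, 8.11, 7.24, 6.47, 9.66)          # SIS L3->L2
  se <- sd(vals) / sqrt(5)
  ratio <- precision_ratio(se, mean(c(0.16, 0.16, 0.17, 0.17, 0.16)))
  expect_printed(ratio, 3.5, digits = 1)
  expect_identical(precision_ratio(0.2, 0.2), 1)
  # doubling every deviation from the mean doubles the ratio
  stretched <- mean(vals) + 2 * (vals - mean(vals))
  expect_equal(precision_ratio(sd(stretched) / sqrt(5), 0.164),
               2 * precision_ratio(sd(vals) / sqrt(5), 0.164))
  expect_error(precision_ratio(0.2, 0), "positive")
})

test_that("transformation reversal flips ids and signs, not sigmas", {
  recs <- data.frame(transformation = "A->B", condition = "VIS",
                     replicate = 1:2, ddg_kjmol = c(1.5, 2),
                     sigma_kjmol = c(0.1, 0.2))
  rev <- reverse_transformation(recs)
  expect_identical(rev$transformation, rep("B->A", 2))
  expect_identical(rev$ddg_kjmol, c(-1.5, -2))
  expect_identical(rev$sigma_kjmol, recs$sigma_kjmol)
})

test_that("cycle definitions validate the ligand path", {
  cy <- cycle_definition(c("L3->L2", "L4->L2", "L3->L4"), c(1, -1, -1))
  expect_identical(cy$ligands, c("L3", "L2", "L4"))
  expect_error(cycle_definition(c("L3->L2", "L4->L2", "L3->L4"), c(1, 1, -1)),
               "does not close")
  expect_error(cycle_definition("A->B", 1), "at least two")
})

test_that("cycle closure enumerates the full Cartesian product", {
  fx <- fep_fixture("brd4")
  vis <- fx$replicates[fx$replicates$condition == "VIS", ]
  cc <- cycle_closure(fx$cycles[[1]], vis)
  expect_identical(cc$n_combinations, 125)
  # linearity: mean closure equals the signed sum of the ensemble means
  s <- aggregate_replicates(vis)
  expected_mean <- s$mean_kjmol[s$transformation == "L3->L2"] -
    s$mean_kjmol[s$transformation == "L4->L2"] -
    s$mean_kjmol[s$transformation == "L3->L4"]
  expect_equal(cc$mean, expected_mean, tolerance = 1e-12)
  # extrema equal the signed combination of per-transformation extrema
  get <- function(tr) vis$ddg_kjmol[vis$transformation == tr]
  expect_equal(cc$min, min(get("L3->L2")) - max(get("L4->L2")) - max(get("L3->L4")))
  expect_equal(cc$max, max(get("L3->L2")) - min(get("L4->L2")) - min(get("L3->L4")))
  # brute-force enumeration oracle for the extrema and the mean
  sums <- c()
  for (i in get("L3->L2")) for (j in get("L4->L2")) for (k in get("L3->L4")) {
    sums <- c(sums, i - j - k)
  }
  expect_equal(c(cc$min, cc$max, cc$mean), c(min(sums), max(sums), mean(sums)))
})

test_that("a transformation and its exact reverse close trivially", {
  recs <- data.frame(transformation = c("A->B", "B->A"), condition = "VIS",
                     replicate = c(1, 1), ddg_kjmol = c(1.7, -1.7),
                     sigma_kjmol = c(0.1, 0.1))
  cy <- cycle_definition(c("A->B", "B->A"), c(1, 1))
  cc <- cycle_closure(cy, recs)
  expect_identical(cc$n_combinations, 1)
  expect_equal(cc$mean, 0)
})

test_that("cycle closure names missing transformations", {
  cy <- cycle_definition(c("A->B", "B->A"), c(1, 1))
  recs <- data.frame(transformation = "A->B", condition = "VIS",
                     replicate = 1, ddg_kjmol = 1, sigma_kjmol = 0.1)
  expect_error(cycle_closure(cy, recs), "B->A")
})
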