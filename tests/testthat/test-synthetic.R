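# Synthetic generators: exact free energies, reproducibility, geometry.

test_that("harmonic generator carries the closed-form free energies", {
  # identical states
  s0 <- gen_harmonic_alchemy(c(1, 1), n_samples = 50, seed = 1)
  expect_equal(s0$exact$f, c(0, 0))
  # stiffness ratio: delta f = log(k1/k0)/2, independent of offsets
  s1 <- gen_harmonic_alchemy(c(1, 4), offset = c(0, 2), n_samples = 50, seed = 1)
  expect_equal(s1$exact$f[2], 0.5 * log(4))
  s2 <- gen_harmonic_alchemy(c(2, 3, 8), offset = c(0, -1, 5),
                             n_samples = 20, seed = 1)
  expect_equal(s2$exact$f, 0.5 * log(c(2, 3, 8) / 2))
})

test_that("harmonic generator validates its inputs", {
  expect_error(gen_harmonic_alchemy(c(1, -2), n_samples = 10), "positive")
  expect_error(gen_harmonic_alchemy(c(1, 2), n_samples = 0), "positive sample")
  expect_error(gen_harmonic_alchemy(c(1, 2), offset = c(0, 0, 0),
                                    n_samples = 10), "per state")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_harmonic_alchemy(c(1, 3), n_samples = 200, seed = 42)
  b <- gen_harmonic_alchemy(c(1, 3), n_samples = 200, seed = 42)
  expect_identical(a$potentials$u, b$potentials$u)
  r1 <- gen_replicate_study(c("A->B" = 2.82), seed = 7)
  r2 <- gen_replicate_study(c("A->B" = 2.82), seed = 7)
  expect_identical(r1$records, r2$records)
  w1 <- gen_water_box(18.6, 216, seed = 3)
  w2 <- gen_water_box(18.6, 216, seed = 3)
  expect_identical(w1$atoms, w2$atoms)
  expect_false(identical(w1$atoms,
                         gen_water_box(18.6, 216, seed = 4)$atoms))
})

test_that("replicate study draws have the requested structure", {
  # degenerate noise: every replicate equals the truth
  r0 <- gen_replicate_study(c("A->B" = 1.5, "B->C" = -2), sigma_rep = 0,
                            seed = 1)
  expect_true(all(r0$records$ddg_kjmol ==
                    r0$truth$ddg_true_kjmol[match(r0$records$transformation,
                                                  r0$truth$transformation)]))
  expect_error(gen_replicate_study(c("A->B" = 1), n_replicates = 1), ">= 2")
  # parameter recovery: pooled sd -> sigma_rep, means -> truth over many seeds
  reps <- vapply(1:200, function(s) {
    r <- gen_replicate_study(c("A->B" = 2.82), sigma_rep = 0.39,
                             n_replicates = 5, seed = s)
    c(mean(r$records$ddg_kjmol), stats::sd(r$records$ddg_kjmol))
  }, numeric(2))
  expect_lt(abs(mean(reps[1, ]) - 2.82), 0.02)
  expect_lt(abs(mean(reps[2, ]) - 0.39), 0.02)
})

test_that("condition offset shifts one condition's mean by the offset", {
  d <- vapply(1:300, function(s) {
    r <- gen_replicate_study(c("A->B" = 2.82), sigma_rep = 0.39,
                             offset = 0.6, offset_condition = "SIS", seed = s)
    rec <- r$records
    mean(rec$ddg_kjmol[rec$condition == "SIS"]) -
      mean(rec$ddg_kjmol[rec$condition == "VIS"])
  }, numeric(1))
  # mean difference distribution centred at the offset, se = 0.39*sqrt(2/5)/sqrt(300)
  expect_lt(abs(mean(d) - 0.6), 4 * 0.39 * sqrt(2 / 5) / sqrt(300))
})

test_that("water boxes sit on the jittered lattice with sane geometry", {
  # jitter 0: oxygens exactly on the lattice
  w <- gen_water_box(24.8, 512, jitter = 0, seed = 1)
  o <- w$atoms[w$atoms$name == "O", c("x", "y", "z")]
  spacing <- 24.8 / 8
  expected <- (as.matrix(expand.grid(1:8, 1:8, 1:8)) - 0.5) * spacing
  expect_equal(as.matrix(o), expected, ignore_attr = TRUE, tolerance = 1e-12)
  # oxygens inside the box; O-O >= 2.4 A for two different seeds
  for (s in c(5, 6)) {
    ww <- gen_water_box(24.8, 512, seed = s)
    oo <- as.matrix(ww$atoms[ww$atoms$name == "O", c("x", "y", "z")])
    expect_true(all(oo >= 0 & oo <= 24.8))
    expect_gte(min(dist(oo)), 2.4)
  }
  # density of the 24.8 A / 512-water box close to liquid water
  dens <- 512 * 18.01528 / 6.02214076e23 / (24.8e-8)^3
  expect_lt(abs(dens - 0.997) / 0.997, 0.15)
  # O-H geometry within 1% of the rigid model
  a <- gen_water_box(18.6, 216, seed = 2)$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  oh1 <- sqrt(rowSums((xyz[a$name == "H1", ] - xyz[a$name == "O", ])^2))
  expect_true(all(abs(oh1 - 0.9572) / 0.9572 < 0.01))
})

test_that("over-dense water boxes are refused", {
  expect_error(gen_water_box(10, 512), "2.4")
})
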