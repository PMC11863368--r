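# Solvation replicas: overlay, tiling, culling, manifests, PDB round trips.

make_solute <- function(xyz, element = "C") {
  data.frame(name = paste0(element, seq_len(nrow(xyz))), resid = "LIG",
             resno = 1L, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("empty solute with one box image conserves the water count", {
  box <- gen_water_box(18.6, 216, seed = 1)
  sys <- solvate(NULL, box, margin = 6, cutoff = 2.4, transform = "identity")
  expect_identical(sys$n_waters, 216L)
  expect_identical(sys$n_removed, 0L)
  # random transform also conserves counts for an empty solute
  sys2 <- solvate(NULL, box, margin = 6, cutoff = 2.4, seed = 4)
  expect_identical(sys2$n_waters, 216L)
})

test_that("culling matches a brute-force distance scan", {
  box <- gen_water_box(18.6, 216, seed = 2)
  solute <- make_solute(matrix(c(9.3, 9.3, 9.3), 1))
  sys <- solvate(solute, box, margin = 6, cutoff = 2.4, seed = 1,
                 transform = "identity")
  # oracle: count pre-cull waters with any atom within the cutoff, by loops
  pre <- solvate(solute, box, margin = 6, cutoff = 1e-9, seed = 1,
                 transform = "identity")
  removed_oracle <- 0L
  for (w in unique(pre$waters$water)) {
    aw <- pre$waters[pre$waters$water == w, c("x", "y", "z")]
    d <- apply(aw, 1, function(r) sqrt(sum((r - c(9.3, 9.3, 9.3))^2)))
    if (any(d < 2.4)) removed_oracle <- removed_oracle + 1L
  }
  expect_identical(sys$n_removed, removed_oracle)
})

test_that("the post-cull clash invariant holds by exhaustive scan", {
  box <- gen_water_box(18.6, 216, seed = 3)
  solute <- make_solute(rbind(c(8, 9, 10), c(10, 9, 8), c(9, 10, 9)))
  for (s in c(1, 2)) {
    sys <- solvate(solute, box, margin = 5, cutoff = 2.4, seed = s)
    expect_gte(min_solute_water_distance(sys), 2.4)
  }
})

test_that("water count is monotone non-increasing in the cutoff", {
  box <- gen_water_box(18.6, 216, seed = 5)
  solute <- make_solute(matrix(c(9.3, 9.3, 9.3), 1))
  counts <- vapply(c(0.5, 1.5, 2.4, 3.5, 5), function(cut) {
    solvate(solute, box, margin = 6, cutoff = cut, seed = 9)$n_waters
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("distinct snapshots or seeds give distinct solvated systems", {
  solute <- make_solute(matrix(c(9.3, 9.3, 9.3), 1))
  box_a <- gen_water_box(18.6, 216, seed = 11, id = 6)
  box_b <- gen_water_box(18.6, 216, seed = 12, id = 8)
  s_a <- solvate(solute, box_a, margin = 6, cutoff = 2.4, seed = 1)
  s_b <- solvate(solute, box_b, margin = 6, cutoff = 2.4, seed = 1)
  expect_false(isTRUE(all.equal(s_a$waters, s_b$waters)) &&
                 s_a$n_waters == s_b$n_waters)
  s_c <- solvate(solute, box_a, margin = 6, cutoff = 2.4, seed = 2)
  expect_false(isTRUE(all.equal(s_a$waters, s_c$waters)) &&
                 s_a$n_waters == s_c$n_waters)
  # same snapshot, same seed: bit-identical
  s_d <- solvate(solute, box_a, margin = 6, cutoff = 2.4, seed = 1)
  expect_identical(s_a$waters, s_d$waters)
})

test_that("the target box encloses the solute with the margin", {
  solute <- make_solute(rbind(c(0, 0, 0), c(4, 2, 1)))
  box <- gen_water_box(18.6, 216, seed = 6)
  sys <- solvate(solute, box, margin = 12, cutoff = 2.4, seed = 1)
  expect_gte(sys$box_edge, 4 + 2 * 12)
  lo <- apply(as.matrix(solute[, c("x", "y", "z")]), 2, min)
  hi <- apply(as.matrix(solute[, c("x", "y", "z")]), 2, max)
  expect_true(all(lo - sys$origin >= 12 - 1e-9))
  expect_true(all(sys$origin + sys$box_edge - hi >= 12 - 1e-9))
  expect_warning(solvate(solute, box, margin = 2, cutoff = 2.4), "cutoff")
})

test_that("PDB round trips preserve coordinates to PDB precision", {
  box <- gen_water_box(18.6, 216, seed = 7)
  f <- tempfile(fileext = ".pdb")
  write_water_box_pdb(box, f)
  back <- read_water_box_pdb(f)
  expect_equal(back$edge, 18.6, tolerance = 1e-3)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(box$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # solvated system round trip
  solute <- make_solute(matrix(c(9.3, 9.3, 9.3), 1))
  sys <- solvate(solute, box, margin = 5, cutoff = 2.4, seed = 1)
  f2 <- tempfile(fileext = ".pdb")
  write_solvated_pdb(sys, f2)
  back2 <- read_solute_pdb(f2)
  expect_identical(nrow(back2), nrow(solute) + nrow(sys$waters))
  expect_equal(attr(back2, "box_edge"), sys$box_edge, tolerance = 1e-3)
  expect_equal(back2$x[1], 9.3, tolerance = 1e-3)
  unlink(c(f, f2))
})

test_that("ensemble manifests encode the two replica modes", {
  vis <- ensemble_manifest("VIS", 5, snapshot_ids = 1, seed = 3)
  expect_identical(vis$n_structures, 1L)
  expect_identical(length(unique(vis$entries$velocity_seed)), 5L)
  sis <- ensemble_manifest("SIS", 5, snapshot_ids = c(6, 8, 16, 26, 36),
                           seed = 3)
  expect_identical(sis$n_structures, 5L)
  expect_identical(sis$entries$snapshot_id, c(6, 8, 16, 26, 36))
  expect_identical(length(unique(sis$entries$velocity_seed)), 5L)
  one <- ensemble_manifest("VIS", 1)
  expect_identical(nrow(one$entries), 1L)
  expect_error(ensemble_manifest("SIS", 3, snapshot_ids = c(1, 1, 2)),
               "duplicate")
  expect_error(ensemble_manifest("SIS", 3, snapshot_ids = c(1, 2)),
               "one snapshot id per replica")
  # manifest JSON round trip keeps every seed and snapshot id
  f <- tempfile(fileext = ".json")
  write_manifest_json(sis, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$replicas$snapshot_id, c(6, 8, 16, 26, 36))
  expect_equal(back$replicas$velocity_seed, sis$entries$velocity_seed)
  unlink(f)
})
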