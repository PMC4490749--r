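# Phantom generator: construction-forced counts, determinism, phase partition,
# analytic bone volume, validation and placement errors.

test_that("ground truth contains exactly the requested objects", {
  vol <- generate_phantom(phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 60,
    n_lacunae = 50, lacuna_semi_axes = c(5, 2, 2), n_canals = 2,
    noise_sigma = 0, seed = 42
  ))
  objs <- vol$truth$objects
  expect_equal(sum(objs$class == "lacuna"), 50)
  expect_equal(sum(objs$class == "canal"), 2)
  expect_setequal(unique(as.vector(vol$truth$phase)), c(0L, 1L, 2L, 3L))
  # object_id consistent with per-object voxel counts
  expect_equal(
    sort(tabulate(vol$truth$object_id[vol$truth$object_id > 0])),
    sort(objs$voxel_count)
  )
})

test_that("empty phantom is a clean digital hollow cylinder", {
  Ro <- 40; Ri <- 30; h <- 50
  vol <- generate_phantom(phantom_spec(
    outer_radius = Ro, inner_radius = Ri, height = h,
    n_lacunae = 0, n_canals = 0, noise_sigma = 0, seed = 1
  ))
  expect_false(any(vol$truth$phase %in% c(2L, 3L)))
  # independent digital-cylinder count from the voxel-centre inclusion rule
  nx <- dim(vol$data)[1]
  ctr <- (nx + 1) / 2
  r2 <- outer((seq_len(nx) - ctr)^2, (seq_len(nx) - ctr)^2, `+`)
  ring <- sum(r2 <= Ro^2 & r2 > Ri^2)
  expect_equal(sum(vol$truth$phase == 1L), ring * h)
  # analytic continuous volume within 2% for Ro >= 30
  analytic <- pi * (Ro^2 - Ri^2) * h
  expect_lt(abs(ring * h - analytic) / analytic, 0.02)
  # noise-free histogram holds exactly the two specified intensities
  expect_setequal(unique(as.vector(vol$data)), c(20, 200))
})

test_that("identical spec and seed give bit-identical volumes", {
  sp <- phantom_spec(n_lacunae = 10, n_canals = 1, noise_sigma = 5, seed = 7)
  v1 <- generate_phantom(sp)
  v2 <- generate_phantom(sp)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$truth$phase, v2$truth$phase)
  expect_identical(v1$truth$objects, v2$truth$objects)
})

test_that("phase partition covers every voxel exactly once", {
  vol <- generate_phantom(phantom_spec(n_lacunae = 20, n_canals = 2, seed = 3))
  counts <- table(factor(vol$truth$phase, levels = 0:3))
  expect_equal(sum(counts), length(vol$truth$phase))
})

test_that("invalid geometry and impossible placement raise errors", {
  expect_error(phantom_spec(outer_radius = 30, inner_radius = 30),
               "inner_radius")
  expect_error(phantom_spec(lacuna_semi_axes = c(2, 3, 1)), "a >= b >= c")
  expect_error(phantom_spec(lacuna_placement = c(-1, 2, 2)), "placement")
  # far too many lacunae for the wall volume -> placement error naming the gap
  sp <- phantom_spec(outer_radius = 12, inner_radius = 8, height = 12,
                     n_lacunae = 400, lacuna_semi_axes = c(2, 1, 1),
                     n_canals = 0, seed = 1)
  expect_error(generate_phantom(sp), "placement failed")
})

test_that("lattice placement accepts a feasible grid and rejects overflow", {
  sp <- phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 40,
    n_lacunae = 12, lacuna_semi_axes = c(3, 1.5, 1.5),
    lacuna_orientation = c(0, 0, 1),
    lacuna_placement = c(4, 4, 8), n_canals = 0, seed = 2
  )
  vol <- generate_phantom(sp)
  expect_equal(sum(vol$truth$objects$class == "lacuna"), 12)
  sp_bad <- phantom_spec(
    outer_radius = 20, inner_radius = 15, height = 20,
    n_lacunae = 5000, lacuna_placement = c(4, 4, 8),
    lacuna_semi_axes = c(3, 1.5, 1.5), lacuna_orientation = c(0, 0, 1),
    n_canals = 0, seed = 2
  )
  expect_error(generate_phantom(sp_bad), "lattice admits only")
})
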