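# Phase segmentation and component labeling: ground-truth equality on clean
# phantoms, Otsu robustness under noise, conservation, translation invariance,
# the truth-component bijection, and border flagging.

make_default_phantom <- function(noise = 0, seed = 3) {
  generate_phantom(phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 60,
    n_lacunae = 50, lacuna_semi_axes = c(5, 2, 2), n_canals = 2,
    noise_sigma = noise, seed = seed
  ))
}

test_that("noise-free segmentation equals ground truth voxel-for-voxel", {
  vol <- make_default_phantom()
  seg <- label_components(segment_phases(vol, bone_threshold = 110))
  expect_identical(seg$phase, vol$truth$phase)
  expect_equal(seg$bone_voxel_count, sum(vol$truth$phase == 1L))
})

test_that("otsu segmentation of a noisy phantom agrees >= 99% with truth", {
  vol <- make_default_phantom(noise = 10)
  seg <- label_components(segment_phases(vol))
  agreement <- mean(seg$phase == vol$truth$phase)
  expect_gte(agreement, 0.99)
})

test_that("uniform volumes are rejected", {
  flat <- voxel_volume(array(0, dim = c(8, 8, 8)), 1.4)
  expect_error(segment_phases(flat, bone_threshold = 10), "no bone phase")
})

test_that("pore voxels are conserved across classification", {
  vol <- make_default_phantom()
  # plant a 3-voxel speckle inside the wall (below the lacuna volume range),
  # at a spot whose whole neighbourhood is bone in the ground truth
  v <- vol
  spot <- NULL
  for (z in 5:50) {
    for (x in 5:14) {
      if (all(vol$truth$phase[(x - 2):(x + 2), 42:46, (z - 2):(z + 4)] == 1L)) {
        spot <- c(x, z)
        break
      }
    }
    if (!is.null(spot)) break
  }
  v$data[spot[1], 44, spot[2]:(spot[2] + 2)] <- 20
  seg <- label_components(segment_phases(v, bone_threshold = 110))
  pore_total <- sum(seg$phase %in% c(2L, 3L, 4L))
  expect_equal(sum(seg$components$voxel_count), pore_total)
  speck <- dplyr::filter(seg$components, class == "speckle")
  expect_equal(nrow(speck), 1)
  expect_equal(speck$voxel_count, 3)
})

test_that("whole-voxel translation permutes IDs but preserves volumes", {
  vol <- make_default_phantom()
  shifted <- vol
  shifted$data <- vol$data[c(4:dim(vol$data)[1], 1:3), , ] # cyclic x-shift
  # background wraps, objects stay clear of the border, so volumes persist
  s1 <- label_components(segment_phases(vol, 110))
  s2 <- label_components(segment_phases(shifted, 110))
  expect_equal(
    sort(s1$components$voxel_count[s1$components$class == "lacuna"]),
    sort(s2$components$voxel_count[s2$components$class == "lacuna"])
  )
  expect_equal(sum(s1$components$class == "canal"),
               sum(s2$components$class == "canal"))
})

test_that("ground-truth objects map one-to-one onto detected components", {
  vol <- make_default_phantom()
  seg <- label_components(segment_phases(vol, 110))
  truth_ids <- vol$truth$object_id
  det <- seg$components
  matched <- vapply(seq_len(nrow(det)), function(r) {
    tv <- unique(truth_ids[det$voxels[[r]]])
    length(tv) == 1 && tv > 0
  }, logical(1))
  expect_true(all(matched))
  expect_equal(nrow(det), nrow(vol$truth$objects))
})

test_that("a pore clipped by the volume face is flagged border_touching", {
  # hand-built block: bone slab with an ellipsoid clipped by the z = 1 face
  # (a pore cut by an in-plane face is no longer slice-enclosed, so the
  # clippable face under slice-stack filling is the axial one)
  dims <- c(30, 30, 30)
  phaseless <- array(200, dim = dims)
  g <- expand.grid(x = 1:30, y = 1:30, z = 1:30)
  inside <- ((g$x - 15) / 3)^2 + ((g$y - 15) / 3)^2 + ((g$z - 2) / 6)^2 <= 1
  phaseless[cbind(g$x, g$y, g$z)[inside, ]] <- 20
  vol <- voxel_volume(phaseless, 1.4)
  seg <- segment_phases(vol, bone_threshold = 110)
  seg <- label_components(seg, lacuna_volume_range_um3 = c(10, 2000) * 1.4^3,
                          min_canal_volume_um3 = 2000 * 1.4^3)
  lac <- dplyr::filter(seg$components, class == "lacuna")
  expect_equal(nrow(lac), 1)
  # brute-force border scan oracle
  dims_arr <- dim(seg$phase)
  coords <- which(seg$phase == 3L, arr.ind = TRUE)
  on_border <- any(coords[, 1] == 1L | coords[, 1] == dims_arr[1] |
                     coords[, 2] == 1L | coords[, 2] == dims_arr[2] |
                     coords[, 3] == 1L | coords[, 3] == dims_arr[3])
  expect_true(on_border)
  expect_true(lac$border_touching)
  # flagged objects are excluded from shape metrics but counted in densities
  expect_equal(nrow(object_shape_metrics(seg)), 0)
  expect_equal(number_densities(seg)$n_lacunae, 1)
})

test_that("overlapping or inverted volume ranges are rejected", {
  vol <- make_default_phantom()
  seg <- segment_phases(vol, 110)
  expect_error(label_components(seg, lacuna_volume_range_um3 = c(10, 5)),
               "lo < hi")
  expect_error(
    label_components(seg, lacuna_volume_range_um3 = c(10, 5000),
                     min_canal_volume_um3 = 1000),
    "overlap"
  )
})
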