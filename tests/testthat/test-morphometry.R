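# Morphometry: stretch on analytic solids, volume arithmetic, invariances,
# densities, distribution oblateness signs against the brute-force tensor
# oracle, radial thickness against analytic and continuous-geometry oracles,
# and phenotype assembly.

stretch_of_mask <- function(mask, vox = 1.4) {
  seg <- label_wide(seg_from_pore_mask(mask, vox))
  object_shape_metrics(seg)
}

test_that("a digital sphere is read as nearly isotropic", {
  m <- stretch_of_mask(ellipsoid_mask(c(8, 8, 8)))
  expect_equal(nrow(m), 1)
  expect_lte(m$stretch, 0.05)
})

test_that("ellipsoid (10,4,4) stretch matches the analytic 1 - c/a", {
  m <- stretch_of_mask(ellipsoid_mask(c(10, 4, 4)))
  expect_equal(m$stretch, 0.60, tolerance = 0.05 / 0.60)
  # principal half-lengths recover the semi-axes within half a voxel
  expect_equal(m$L1_um / 1.4, 10, tolerance = 0.05)
  expect_equal(m$L3_um / 1.4, 4, tolerance = 0.125)
})

test_that("stretch is invariant to rotation and isotropic scaling", {
  base <- stretch_of_mask(ellipsoid_mask(c(10, 4, 4)))$stretch
  for (R in list(rot_z(pi / 5), rot_y(pi / 3), rot_z(0.4) %*% rot_y(1.1))) {
    st <- stretch_of_mask(ellipsoid_mask(c(10, 4, 4), R))$stretch
    expect_equal(st, base, tolerance = 0.05 / base)
  }
  # voxel size scales lengths but not stretch
  sc <- stretch_of_mask(ellipsoid_mask(c(10, 4, 4)), vox = 0.7)$stretch
  expect_equal(sc, base, tolerance = 1e-12)
})

test_that("volume is voxel count times voxel volume", {
  mask <- array(FALSE, dim = c(30, 30, 30))
  mask[11:20, 11:20, 11:20] <- TRUE # 1000 voxels
  m <- stretch_of_mask(mask)
  expect_equal(m$volume_um3, 1000 * 1.4^3) # 2744
})

test_that("a single-voxel object degenerates gracefully", {
  mask <- array(FALSE, dim = c(9, 9, 9))
  mask[5, 5, 5] <- TRUE
  seg <- label_wide(seg_from_pore_mask(mask))
  m <- object_shape_metrics(seg)
  expect_true(m$degenerate)
  expect_equal(m$stretch, 0)
  expect_gte(m$L1_um / 1.4, 0.5) # at least half a voxel
})

test_that("number densities follow count / bone volume", {
  vol <- generate_phantom(phantom_spec(n_lacunae = 20, n_canals = 0, seed = 4))
  seg <- label_components(segment_phases(vol, 110))
  d <- number_densities(seg)
  expect_equal(d$ca_dn_per_mm3, 0)
  expect_equal(d$lc_dn_per_mm3, 20 / d$bone_volume_mm3)
  expect_equal(d$bone_volume_mm3,
               seg$bone_voxel_count * (1.4e-3)^3)
  # ground-truth density oracle: N / true bone volume within 2%
  true_bone <- sum(vol$truth$phase == 1L) * (1.4e-3)^3
  expect_equal(d$lc_dn_per_mm3, 20 / true_bone, tolerance = 0.02)
})

test_that("oblateness signs on planted lattices are deterministic and match the tensor oracle", {
  # the close direction(s) need enough lattice extent that nearest-neighbour
  # displacements express the planted spacing rather than the lattice edge
  prolate <- as.matrix(expand.grid(x = 2 * (1:10), y = 2 * (1:10),
                                   z = 10 * (1:3))) # close in x,y
  oblate <- as.matrix(expand.grid(x = 10 * (1:4), y = 10 * (1:4),
                                  z = 2 * (1:30))) # close only in z
  cubic <- as.matrix(expand.grid(x = 4 * (1:5), y = 4 * (1:5), z = 4 * (1:5)))

  ob_p <- distribution_oblateness(prolate, 6)
  ob_o <- distribution_oblateness(oblate, 6)
  ob_c <- distribution_oblateness(cubic, 6)
  expect_lt(ob_p$lc_dt_ob, 0)
  expect_gt(ob_o$lc_dt_ob, 0)
  expect_true(ob_c$isotropic)
  expect_equal(ob_c$lc_dt_ob, 0)

  # independent brute-force tensor confirms both signs
  for (case in list(list(prolate, -1), list(oblate, +1))) {
    mu <- sort(eigen(knn_tensor_oracle(case[[1]], 6), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ob_oracle <- 1 - 2 * (mu[2] - mu[3]) / (mu[1] - mu[3])
    expect_equal(sign(ob_oracle), case[[2]])
  }

  # determinism
  expect_identical(distribution_oblateness(prolate, 6),
                   distribution_oblateness(prolate, 6))
  # too few points -> missing
  expect_true(is.na(distribution_oblateness(prolate[1:4, ], 6)$lc_dt_ob))
})

test_that("concentric cylinder thickness matches the analytic wall", {
  vol <- generate_phantom(phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 30,
    n_lacunae = 0, n_canals = 0, seed = 1
  ))
  seg <- segment_phases(vol, 110)
  th <- radial_cortical_thickness(seg, n_theta_bins = 360)
  expect_equal(th$ct_th_r_um / 1.4, 10, tolerance = 0.05) # +-0.5 voxel
  expect_lte(th$ct_th_r_sd_um / 1.4, 0.5)
  # angular-bin invariance for >= 16 bins
  for (nb in c(16, 64, 180)) {
    thb <- radial_cortical_thickness(seg, n_theta_bins = nb)
    expect_lt(abs(thb$ct_th_r_um - th$ct_th_r_um) / 1.4, 0.5)
  }
})

test_that("eccentric cylinder profile matches the continuous ray-casting oracle", {
  off <- c(5, 0)
  vol <- generate_phantom(phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 12,
    shell_center_offset = off, n_lacunae = 0, n_canals = 0, seed = 1
  ))
  seg <- segment_phases(vol, 110)
  th <- radial_cortical_thickness(seg, n_theta_bins = 72, profile = TRUE)
  expect_gt(th$ct_th_r_sd_um / 1.4, 1)
  prof <- attr(th, "profile")
  prof1 <- dplyr::filter(prof, z == 6)
  # ray origin: centroid of the continuous annulus (area-weighted)
  Ro <- 40; Ri <- 30
  origin <- -off * Ri^2 / (Ro^2 - Ri^2)
  for (r in seq_len(nrow(prof1))) {
    oracle <- cont_thickness_oracle(Ro, Ri, off, origin, prof1$theta_rad[r])
    expect_lt(abs(prof1$thickness_um[r] / 1.4 - oracle), 1)
  }
})

test_that("a missing wedge invalidates only its bins and warns", {
  vol <- generate_phantom(phantom_spec(
    outer_radius = 40, inner_radius = 30, height = 10,
    n_lacunae = 0, n_canals = 0, seed = 1
  ))
  nx <- dim(vol$data)[1]
  ctr <- (nx + 1) / 2
  ang <- atan2(col(vol$data[, , 1]) - ctr, row(vol$data[, , 1]) - ctr)
  wedge <- ang > 0 & ang < pi / 6 # 30 degrees
  for (z in seq_len(dim(vol$data)[3])) {
    sl <- vol$data[, , z]
    sl[wedge] <- 20
    vol$data[, , z] <- sl
  }
  seg <- segment_phases(vol, 110)
  expect_warning(th <- radial_cortical_thickness(seg, n_theta_bins = 360),
                 "skipped")
  expect_lt(th$n_valid_bins, th$n_bins)
  expect_equal(th$ct_th_r_um / 1.4, 10, tolerance = 0.1)
})

test_that("lacuna pore volume is conserved through the phenotype summary", {
  vol <- generate_phantom(phantom_spec(n_lacunae = 30, n_canals = 0, seed = 6))
  seg <- label_components(segment_phases(vol, 110))
  shapes <- object_shape_metrics(seg)
  # mean Lc.V x count = total lacuna pore volume (exact in voxel units)
  expect_equal(
    mean(shapes$volume_um3) * nrow(shapes),
    sum(seg$phase == 3L) * 1.4^3
  )
})

test_that("phenotype assembly handles uniform and empty lacuna sets", {
  # lattice placement with a fixed orientation: every lacuna is rasterised
  # with the same sub-voxel offset, so per-object stretch has no dispersion
  vol <- generate_phantom(phantom_spec(
    n_lacunae = 10, n_canals = 0, lacuna_orientation = c(0, 0, 1),
    lacuna_semi_axes = c(4, 2, 2), lacuna_placement = c(4, 4, 10), seed = 8
  ))
  seg <- label_components(segment_phases(vol, 110))
  ph <- assemble_phenotypes(seg, n_theta_bins = 60)
  shapes <- object_shape_metrics(seg)
  expect_equal(ph$lc_st, mean(shapes$stretch))
  expect_lt(sd(shapes$stretch), 1e-10) # identical lacunae, no dispersion

  empty <- generate_phantom(phantom_spec(n_lacunae = 0, n_canals = 1, seed = 8))
  seg0 <- label_components(segment_phases(empty, 110))
  ph0 <- assemble_phenotypes(seg0, n_theta_bins = 60)
  expect_true(is.na(ph0$lc_v_um3) && is.na(ph0$lc_st) && is.na(ph0$lc_dt_ob))
  expect_equal(ph0$n_canals, 1)
  expect_gt(ph0$ca_dn_per_mm3, 0)

  # two specimens stay independent rows
  both <- dplyr::bind_rows(
    assemble_phenotypes(seg, specimen = "a", n_theta_bins = 60),
    assemble_phenotypes(seg0, specimen = "b", n_theta_bins = 60)
  )
  expect_equal(both$specimen, c("a", "b"))
  expect_equal(both$n_lacunae, c(10, 0))
})
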