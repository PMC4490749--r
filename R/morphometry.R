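# Per-object and per-specimen morphometry of a labeled segmentation:
# lacuna volume (Lc.V), stretch (Lc.St), number densities (Lc.Dn, Ca.Dn),
# lacuna distribution oblateness (Lc.Dt.Ob), and the radial cortical thickness
# statistics (Ct.Th.R, Ct.Th.R.sd).

#' Shape metrics of labeled pore objects
#'
#' For each non-border component of the requested class, computes volume
#' (voxel count times voxel volume), the physical centroid, principal half
#' lengths, and the stretch anisotropy score. The principal half-lengths are
#' `L_i = sqrt(5 * lambda_i)` where `lambda_i` are the eigenvalues of the
#' voxel-coordinate covariance (exact for a solid ellipsoid of uniform
#' density); each voxel additionally contributes its own cubic second moment
#' (1/12 per axis), so a single voxel has half-length `sqrt(5/12)` voxels
#' rather than zero. Stretch is `1 - L3/L1`: 0 for a sphere, approaching 1 for
#' extreme rods (a >> b = c) and extreme plates (a = b >> c) alike.
#'
#' @param seg A labeled `phase_segmentation`.
#' @param classes Character vector of component classes to measure
#'   (default `"lacuna"`).
#' @param include_border Include border-touching components? Default `FALSE`
#'   (clipped objects have biased shapes).
#' @return A tibble with one row per object: `id`, `class`, `voxel_count`,
#'   `volume_um3`, `cx_um`, `cy_um`, `cz_um`, `L1_um`, `L2_um`, `L3_um`,
#'   `stretch`, `degenerate`.
#' @export
object_shape_metrics <- function(seg, classes = "lacuna",
                                 include_border = FALSE) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (is.null(seg$components)) abort("components not labeled; run label_components() first")
  comps <- dplyr::filter(seg$components, .data$class %in% classes)
  if (!include_border) comps <- dplyr::filter(comps, !.data$border_touching)
  vox <- seg$voxel_size_um
  rows <- purrr::map(seq_len(nrow(comps)), function(r) {
    xyz <- component_coords(seg, comps$id[r])
    n <- nrow(xyz)
    ctr <- colMeans(xyz)
    if (n == 1L) {
      lam <- rep(1 / 12, 3)
      degenerate <- TRUE
    } else {
      centred <- sweep(xyz, 2, ctr)
      covm <- crossprod(centred) / n + diag(1 / 12, 3)
      lam <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
                  decreasing = TRUE)
      lam <- pmax(lam, 1e-12)
      degenerate <- FALSE
    }
    L <- sqrt(5 * lam) * vox
    tibble(
      id = comps$id[r], class = comps$class[r], voxel_count = n,
      volume_um3 = n * vox^3,
      cx_um = (ctr[1] - 0.5) * vox, cy_um = (ctr[2] - 0.5) * vox,
      cz_um = (ctr[3] - 0.5) * vox,
      L1_um = L[1], L2_um = L[2], L3_um = L[3],
      stretch = if (degenerate) 0 else 1 - L[3] / L[1],
      degenerate = degenerate
    )
  })
  if (length(rows)) dplyr::bind_rows(rows) else tibble(
    id = integer(), class = character(), voxel_count = integer(),
    volume_um3 = numeric(), cx_um = numeric(), cy_um = numeric(),
    cz_um = numeric(), L1_um = numeric(), L2_um = numeric(), L3_um = numeric(),
    stretch = numeric(), degenerate = logical()
  )
}

#' Number densities of canals and lacunae
#'
#' Counts of distinct objects per cubic millimetre of calcified bone tissue.
#' Border-touching objects are included in the counts (their existence is
#' certain even if their shapes are clipped).
#'
#' @param seg A labeled `phase_segmentation`.
#' @return A one-row tibble: `ca_dn_per_mm3`, `lc_dn_per_mm3`,
#'   `bone_volume_mm3`, `n_lacunae`, `n_canals`.
#' @export
number_densities <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  if (is.null(seg$components)) abort("components not labeled; run label_components() first")
  if (seg$bone_voxel_count <= 0) abort("zero bone volume; densities undefined")
  bone_mm3 <- seg$bone_voxel_count * (seg$voxel_size_um * 1e-3)^3
  n_lac <- sum(seg$components$class == "lacuna")
  n_can <- sum(seg$components$class == "canal")
  tibble(
    ca_dn_per_mm3 = n_can / bone_mm3,
    lc_dn_per_mm3 = n_lac / bone_mm3,
    bone_volume_mm3 = bone_mm3,
    n_lacunae = n_lac,
    n_canals = n_can
  )
}

#' Oblateness of the lacuna spatial distribution
#'
#' Characterises the anisotropy of lacuna spacing from the second-moment tensor
#' of displacement vectors to each lacuna's `k` nearest neighbours (all
#' neighbours tied at the k-th distance are included, which keeps the
#' estimator symmetric on regular lattices). With tensor
#' eigenvalues `mu1 >= mu2 >= mu3`, the score is
#' `Ob = 1 - 2 * (mu2 - mu3) / (mu1 - mu3)`, in `[-1, 1]`:
#' negative values indicate prolate spacing (lacunae close in two orthogonal
#' directions and far apart in the third, so nearest-neighbour displacements
#' concentrate on a plane), positive values oblate spacing (far apart in two
#' directions, close in only one, so displacements concentrate on a line). If
#' the tensor is nearly isotropic (`(mu1 - mu3)/mu1 < 0.05`) the distribution
#' is flagged isotropic and `Ob = 0` is reported.
#'
#' @param centroids Numeric matrix (n x 3) of lacuna centroid coordinates (any
#'   consistent physical unit).
#' @param k_neighbors Number of nearest neighbours per lacuna (default 6).
#' @return A one-row tibble: `lc_dt_ob`, `isotropic`, `n_points`, `k`.
#' @export
distribution_oblateness <- function(centroids, k_neighbors = 6) {
  centroids <- as.matrix(centroids)
  k <- as.integer(k_neighbors)
  n <- nrow(centroids)
  if (n < k + 1L) {
    return(tibble(lc_dt_ob = NA_real_, isotropic = NA, n_points = n, k = k))
  }
  D <- as.matrix(stats::dist(centroids))
  M <- matrix(0, 3, 3)
  n_disp <- 0L
  for (i in seq_len(n)) {
    d <- D[i, -i]
    kth <- sort(d, partial = k)[k]
    # all neighbours tied at the k-th distance are included, so the estimator
    # stays symmetric on regular lattices
    nb <- which(d <= kth * (1 + 1e-9))
    nb_idx <- seq_len(n)[-i][nb]
    disp <- centroids[nb_idx, , drop = FALSE] -
      matrix(centroids[i, ], length(nb_idx), 3, byrow = TRUE)
    M <- M + crossprod(disp)
    n_disp <- n_disp + length(nb_idx)
  }
  M <- M / n_disp
  mu <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if ((mu[1] - mu[3]) / mu[1] < 0.05) {
    return(tibble(lc_dt_ob = 0, isotropic = TRUE, n_points = n, k = k))
  }
  ob <- 1 - 2 * (mu[2] - mu[3]) / (mu[1] - mu[3])
  tibble(lc_dt_ob = ob, isotropic = FALSE, n_points = n, k = k)
}

#' Radial cortical thickness
#'
#' Measures shell thickness in polar coordinates about the bone axis (Z). For
#' every Z slice the bone-phase centroid is found, and `n_theta_bins` equally
#' spaced rays are cast outward; the thickness at `(theta, z)` is the distance
#' from the innermost to the outermost bone crossing along the ray, with
#' sub-voxel precision from bilinear interpolation of the bone mask (crossings
#' at the 0.5 level). The mean (Ct.Th.R) and standard deviation (Ct.Th.R.sd)
#' are taken over all valid `(theta, z)` bins with equal weight per bin, i.e.
#' weighted by angle rather than by volume, so thick sectors are not
#' over-represented.
#'
#' By default intracortical pores count as bone (the thickness of the shell
#' envelope); set `solid_thickness = TRUE` to measure only through calcified
#' bone at the crossing boundaries.
#'
#' @param seg A `phase_segmentation` (components need not be labeled).
#' @param n_theta_bins Number of angular bins per slice (default 360).
#' @param solid_thickness If `TRUE`, pores are excluded from the mask.
#' @param profile If `TRUE`, also return the per-bin thickness profile as a
#'   `profile` attribute (tibble: `z`, `theta_rad`, `thickness_um`).
#' @return A one-row tibble: `ct_th_r_um`, `ct_th_r_sd_um`, `n_valid_bins`,
#'   `n_bins`.
#' @export
radial_cortical_thickness <- function(seg, n_theta_bins = 360,
                                      solid_thickness = FALSE,
                                      profile = FALSE) {
  stopifnot(inherits(seg, "phase_segmentation"))
  nbins <- as.integer(n_theta_bins)
  if (nbins < 4L) abort("`n_theta_bins` must be at least 4.")
  dims <- dim(seg$phase)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox <- seg$voxel_size_um
  theta <- (seq_len(nbins) - 0.5) / nbins * 2 * pi
  step <- 0.25
  rmax <- sqrt(nx^2 + ny^2) / 2
  rs <- seq(0, rmax, by = step)

  thicknesses <- c()
  prof <- list()
  n_bins_total <- 0L
  n_valid <- 0L
  some_invalid <- FALSE

  for (z in seq_len(nz)) {
    sl <- seg$phase[, , z]
    mask <- if (solid_thickness) sl == PHASE_BONE else
      matrix(sl %in% c(PHASE_BONE, PHASE_CANAL, PHASE_LACUNA, PHASE_PORE),
             nrow(sl))
    bone_sl <- sl == PHASE_BONE
    if (!any(bone_sl)) next
    n_bins_total <- n_bins_total + nbins
    ctr <- c(mean(row(sl)[bone_sl]), mean(col(sl)[bone_sl]))
    maskn <- mask * 1

    # sample points: for each theta, all radii
    px <- ctr[1] + outer(cos(theta), rs)
    py <- ctr[2] + outer(sin(theta), rs)
    # bilinear interpolation at (px, py); outside -> 0
    i0 <- floor(px); j0 <- floor(py)
    fx <- px - i0; fy <- py - j0
    val <- matrix(0, nbins, length(rs))
    inb <- i0 >= 1 & i0 + 1 <= nx & j0 >= 1 & j0 + 1 <= ny
    idx <- function(ii, jj) maskn[cbind(ii, jj)]
    w <- which(inb)
    if (length(w)) {
      v00 <- idx(i0[w], j0[w]); v10 <- idx(i0[w] + 1L, j0[w])
      v01 <- idx(i0[w], j0[w] + 1L); v11 <- idx(i0[w] + 1L, j0[w] + 1L)
      val[w] <- v00 * (1 - fx[w]) * (1 - fy[w]) + v10 * fx[w] * (1 - fy[w]) +
        v01 * (1 - fx[w]) * fy[w] + v11 * fx[w] * fy[w]
    }

    above <- val >= 0.5
    nr <- length(rs)
    has <- rowSums(above) > 0
    if (!all(has)) some_invalid <- TRUE
    if (!any(has)) next
    first <- max.col(above, ties.method = "first")
    last <- nr + 1L - max.col(above[, nr:1, drop = FALSE], ties.method = "first")
    rows <- which(has)
    f <- first[rows]; l <- last[rows]
    r_in <- rs[f]
    refine_in <- f > 1
    if (any(refine_in)) {
      v0 <- val[cbind(rows[refine_in], f[refine_in] - 1L)]
      v1 <- val[cbind(rows[refine_in], f[refine_in])]
      ok <- v1 > v0
      r_in[refine_in][ok] <- rs[f[refine_in] - 1L][ok] +
        step * (0.5 - v0[ok]) / (v1[ok] - v0[ok])
    }
    r_out <- rs[l]
    refine_out <- l < nr
    if (any(refine_out)) {
      v0 <- val[cbind(rows[refine_out], l[refine_out])]
      v1 <- val[cbind(rows[refine_out], l[refine_out] + 1L)]
      ok <- v0 > v1
      r_out[refine_out][ok] <- rs[l[refine_out]][ok] +
        step * (v0[ok] - 0.5) / (v0[ok] - v1[ok])
    }
    thicknesses <- c(thicknesses, r_out - r_in)
    if (profile) {
      prof[[length(prof) + 1L]] <- tibble(
        z = z, theta_rad = theta[rows], thickness_um = (r_out - r_in) * vox
      )
    }
    n_valid <- n_valid + length(rows)
  }

  if (n_bins_total == 0L) abort("no slice contains bone; thickness undefined")
  if (n_valid < 0.5 * n_bins_total) abort("shell not closed")
  if (some_invalid) {
    warn(sprintf(
      "%d of %d (theta, z) bins had no bone crossing and were skipped",
      n_bins_total - n_valid, n_bins_total
    ))
  }
  out <- tibble(
    ct_th_r_um = mean(thicknesses) * vox,
    ct_th_r_sd_um = sd(thicknesses) * vox,
    n_valid_bins = n_valid,
    n_bins = n_bins_total
  )
  if (profile) attr(out, "profile") <- dplyr::bind_rows(prof)
  out
}

#' Assemble the per-specimen phenotype vector
#'
#' Combines densities, per-object shape metrics, distribution oblateness and
#' radial thickness into the specimen's phenotype row. Lc.V and Lc.St are means
#' over non-border lacunae; with zero measurable lacunae the lacuna-derived
#' fields are `NA` while densities are still reported.
#'
#' @param seg A labeled `phase_segmentation`.
#' @param specimen Optional specimen identifier (default `"specimen"`).
#' @param k_neighbors Nearest-neighbour count for oblateness (default 6).
#' @param n_theta_bins Angular bins for radial thickness (default 360).
#' @return A one-row tibble with columns `specimen`, `ct_th_r_um`,
#'   `ct_th_r_sd_um`, `ca_dn_per_mm3`, `lc_dn_per_mm3`, `lc_v_um3`, `lc_st`,
#'   `lc_dt_ob`, `n_lacunae`, `n_canals`, `bone_volume_mm3`.
#' @export
assemble_phenotypes <- function(seg, specimen = "specimen", k_neighbors = 6,
                                n_theta_bins = 360) {
  dens <- number_densities(seg)
  shapes <- object_shape_metrics(seg, classes = "lacuna")
  thick <- radial_cortical_thickness(seg, n_theta_bins = n_theta_bins)
  ob <- if (nrow(shapes) >= k_neighbors + 1) {
    distribution_oblateness(
      as.matrix(shapes[, c("cx_um", "cy_um", "cz_um")]), k_neighbors
    )$lc_dt_ob
  } else {
    NA_real_
  }
  tibble(
    specimen = specimen,
    ct_th_r_um = thick$ct_th_r_um,
    ct_th_r_sd_um = thick$ct_th_r_sd_um,
    ca_dn_per_mm3 = dens$ca_dn_per_mm3,
    lc_dn_per_mm3 = dens$lc_dn_per_mm3,
    lc_v_um3 = if (nrow(shapes)) mean(shapes$volume_um3) else NA_real_,
    lc_st = if (nrow(shapes)) mean(shapes$stretch) else NA_real_,
    lc_dt_ob = ob,
    n_lacunae = dens$n_lacunae,
    n_canals = dens$n_canals,
    bone_volume_mm3 = dens$bone_volume_mm3
  )
}

#' Write a specimen phenotype table as CSV
#'
#' One row per specimen, columns exactly as produced by
#' [assemble_phenotypes()].
#'
#' @param phenotypes Tibble of phenotype rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}
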