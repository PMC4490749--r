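# Synthetic cortical-bone phantoms: a hollow (optionally eccentric) cylindrical
# shell of "bone" voxels containing ellipsoidal lacunae and straight Z-parallel
# canals, with voxel-exact ground truth. Stand-in for reconstructed SRXTM
# volumes of the mouse femur mid-diaphysis.

#' Specify a synthetic cortical-bone phantom
#'
#' Defines the geometry, object content, intensities and noise of a synthetic
#' tomographic volume. The phantom is a hollow cylinder (the cortical shell)
#' whose wall carries solid ellipsoidal pores (osteocyte lacunae) and straight
#' Z-parallel tubes (vascular canals). All geometric parameters are in voxels;
#' `voxel_size_um` fixes the physical scale (default 1.4 um, the resolution
#' regime of synchrotron scans of mouse cortical bone).
#'
#' @param outer_radius,inner_radius Outer/inner shell radii in voxels
#'   (`inner_radius < outer_radius`; `inner_radius = 0` gives a solid rod).
#' @param height Number of Z slices.
#' @param shell_center_offset Length-2 offset (voxels) of the inner bore centre
#'   relative to the outer centre (eccentricity).
#' @param n_lacunae Number of ellipsoidal lacunae to plant.
#' @param lacuna_semi_axes Semi-axes `(a, b, c)` in voxels with `a >= b >= c > 0`.
#' @param lacuna_orientation Either a length-3 vector giving the common long-axis
#'   direction of all lacunae, or `"random"` for an independent random
#'   orientation per lacuna.
#' @param lacuna_placement Either `"poisson"` (rejection sampling with a minimum
#'   gap of 2 voxels between bounding spheres) or a length-3 lattice spacing
#'   `(dx, dy, dz)` in voxels for regular-grid placement.
#' @param n_canals Number of straight Z-parallel canals.
#' @param canal_radius Canal tube radius in voxels (default 3; tubes keep a
#'   clearance of 1.5 voxels from both shell boundaries).
#' @param intensity_bone,intensity_pore Grayscale values for calcified bone and
#'   for pore/background voxels.
#' @param noise_sigma Standard deviation of additive Gaussian grayscale noise
#'   (0 for a noise-free phantom).
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param seed Integer master seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(outer_radius = 40,
                         inner_radius = 30,
                         height = 60,
                         shell_center_offset = c(0, 0),
                         n_lacunae = 50,
                         lacuna_semi_axes = c(5, 2, 2),
                         lacuna_orientation = "random",
                         lacuna_placement = "poisson",
                         n_canals = 2,
                         canal_radius = 3,
                         intensity_bone = 200,
                         intensity_pore = 20,
                         noise_sigma = 0,
                         voxel_size_um = 1.4,
                         seed = 1L) {
  stopifnot_scalar_number(outer_radius, "outer_radius", 0, strict = TRUE)
  stopifnot_scalar_number(inner_radius, "inner_radius", 0)
  if (inner_radius >= outer_radius) {
    abort("`inner_radius` must be smaller than `outer_radius`.")
  }
  stopifnot_scalar_number(height, "height", 1)
  if (length(shell_center_offset) != 2L || !is.numeric(shell_center_offset)) {
    abort("`shell_center_offset` must be a numeric length-2 vector.")
  }
  stopifnot_scalar_number(n_lacunae, "n_lacunae", 0)
  stopifnot_scalar_number(n_canals, "n_canals", 0)
  ax <- lacuna_semi_axes
  if (length(ax) != 3L || any(!is.finite(ax)) || any(ax <= 0) ||
      !(ax[1] >= ax[2] && ax[2] >= ax[3])) {
    abort("`lacuna_semi_axes` must satisfy a >= b >= c > 0.")
  }
  if (is.character(lacuna_orientation)) {
    if (!identical(lacuna_orientation, "random")) {
      abort('`lacuna_orientation` must be "random" or a length-3 vector.')
    }
  } else if (length(lacuna_orientation) != 3L ||
             sum(lacuna_orientation^2) == 0) {
    abort('`lacuna_orientation` must be "random" or a nonzero length-3 vector.')
  }
  if (is.character(lacuna_placement)) {
    if (!identical(lacuna_placement, "poisson")) {
      abort('`lacuna_placement` must be "poisson" or a length-3 spacing.')
    }
  } else if (length(lacuna_placement) != 3L || any(lacuna_placement <= 0)) {
    abort('`lacuna_placement` must be "poisson" or positive spacings (dx, dy, dz).')
  }
  stopifnot_scalar_number(canal_radius, "canal_radius", 0, strict = TRUE)
  stopifnot_scalar_number(noise_sigma, "noise_sigma", 0)
  stopifnot_scalar_number(voxel_size_um, "voxel_size_um", 0, strict = TRUE)
  structure(
    list(
      outer_radius = outer_radius, inner_radius = inner_radius,
      height = as.integer(height), shell_center_offset = shell_center_offset,
      n_lacunae = as.integer(n_lacunae), lacuna_semi_axes = ax,
      lacuna_orientation = lacuna_orientation,
      lacuna_placement = lacuna_placement,
      n_canals = as.integer(n_canals), canal_radius = canal_radius,
      intensity_bone = intensity_bone, intensity_pore = intensity_pore,
      noise_sigma = noise_sigma, voxel_size_um = voxel_size_um,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> shell R_o=%g R_i=%g h=%d | %d lacunae (%g,%g,%g) | %d canals r=%g | noise sd=%g | %g um/voxel | seed %d\n",
    x$outer_radius, x$inner_radius, x$height, x$n_lacunae,
    x$lacuna_semi_axes[1], x$lacuna_semi_axes[2], x$lacuna_semi_axes[3],
    x$n_canals, x$canal_radius, x$noise_sigma, x$voxel_size_um, x$seed
  ))
  invisible(x)
}

# Orthonormal frame whose first column is the (normalised) direction u.
orient_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  e <- diag(3)[, which.min(abs(u))]
  v <- e - sum(e * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  cbind(u, v, w)
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# support half-width of an ellipsoid (semi-axes ax, frame R) along direction d:
# the ellipsoid lies within the slab of this half-width about its centre.
ellipsoid_support <- function(R, ax, d) {
  sqrt(sum((ax * as.vector(crossprod(R, d)))^2))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Rasterises the phantom described by a [phantom_spec()]: the shell is drawn at
#' `intensity_bone`, lacunae and canals are carved out of the wall at
#' `intensity_pore`, the exterior and the medullary bore are background (also at
#' `intensity_pore`), and optional Gaussian noise is added. The returned volume
#' carries voxel-exact ground truth: a phase label array (0 background, 1 bone,
#' 2 canal, 3 lacuna), a per-object ID array, and a tibble of true object
#' parameters (centroids, semi-axes, orientations).
#'
#' Voxels are rasterised by the centre-of-voxel inclusion test; the physical
#' coordinate of voxel `i` (1-based array index) along an axis is
#' `(i - 0.5) * voxel_size_um`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `voxel_volume`: a list with `data` (3D grayscale
#'   array), `voxel_size_um`, and `truth` (list with `phase`, `object_id`,
#'   `objects`).
#' @examples
#' vol <- generate_phantom(phantom_spec(n_lacunae = 5, n_canals = 1, seed = 7))
#' dim(vol$data)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  Ro <- spec$outer_radius
  Ri <- spec$inner_radius
  nz <- spec$height
  margin <- 3L
  nx <- ny <- as.integer(2 * ceiling(Ro) + 2 * margin + 1)
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  cin <- c(cx, cy) + spec$shell_center_offset

  xs <- seq_len(nx)
  ys <- seq_len(ny)
  r2_out <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  r2_in <- outer((xs - cin[1])^2, (ys - cin[2])^2, `+`)
  bone2d <- r2_out <= Ro^2 & r2_in > Ri^2

  phase <- array(0L, dim = c(nx, ny, nz))
  phase[rep(bone2d, nz)] <- 1L
  object_id <- array(0L, dim = c(nx, ny, nz))

  ax <- spec$lacuna_semi_axes
  a_max <- ax[1]
  vox <- spec$voxel_size_um

  # --- canals: Z-parallel tubes fully inside the wall ---------------------
  canal_xy <- matrix(numeric(0), ncol = 2)
  cr <- spec$canal_radius
  if (spec$n_canals > 0) {
    with_seed(derive_seed(spec$seed, "canals"), {
      attempts <- 0L
      while (nrow(canal_xy) < spec$n_canals) {
        attempts <- attempts + 1L
        if (attempts > 500L * spec$n_canals) {
          abort(paste(
            "canal placement failed: cannot fit", spec$n_canals,
            "non-overlapping tubes of radius", cr, "inside the shell wall"
          ))
        }
        p <- c(runif(1, cx - Ro, cx + Ro), runif(1, cy - Ro, cy + Ro))
        d_out <- sqrt(sum((p - c(cx, cy))^2))
        d_in <- sqrt(sum((p - cin)^2))
        if (d_out + cr + 1.5 > Ro || d_in - cr - 1.5 < Ri) next
        if (nrow(canal_xy) > 0 &&
            any(sqrt(rowSums((canal_xy - matrix(p, nrow(canal_xy), 2,
                                                byrow = TRUE))^2)) < 2 * cr + 2)) next
        canal_xy <- rbind(canal_xy, p)
      }
    })
  }

  # --- lacuna centres and orientations ------------------------------------
  # Containment and pairwise separation use the ellipsoid support function
  # (separating-slab tests), so elongated lacunae may sit tangentially in a
  # wall thinner than their long axis. Margins of ~1 voxel absorb both
  # rasterisation and the curvature of the shell boundaries.
  draw_orientation <- function() {
    if (is.character(spec$lacuna_orientation)) {
      random_unit_vector()
    } else {
      spec$lacuna_orientation / sqrt(sum(spec$lacuna_orientation^2))
    }
  }
  lac_ok <- function(p, Rf) {
    e_out <- p[1:2] - c(cx, cy)
    d_out <- sqrt(sum(e_out^2))
    dir_out <- if (d_out > 1e-9) c(e_out / d_out, 0) else c(1, 0, 0)
    if (d_out + ellipsoid_support(Rf, ax, dir_out) + 1 > Ro) return(FALSE)
    if (Ri > 0) {
      e_in <- p[1:2] - cin
      d_in <- sqrt(sum(e_in^2))
      dir_in <- if (d_in > 1e-9) c(e_in / d_in, 0) else c(1, 0, 0)
      if (d_in - ellipsoid_support(Rf, ax, dir_in) - 1.5 < Ri) return(FALSE)
    }
    hz <- ellipsoid_support(Rf, ax, c(0, 0, 1))
    if (p[3] - hz < 1.5 || p[3] + hz > nz - 0.5) return(FALSE)
    if (nrow(canal_xy) > 0) {
      for (kk in seq_len(nrow(canal_xy))) {
        dxy <- p[1:2] - canal_xy[kk, ]
        d <- sqrt(sum(dxy^2))
        dirc <- if (d > 1e-9) c(dxy / d, 0) else c(1, 0, 0)
        if (d < cr + ellipsoid_support(Rf, ax, dirc) + 1.5) return(FALSE)
      }
    }
    TRUE
  }

  centres <- matrix(numeric(0), ncol = 3)
  frames <- list()
  if (spec$n_lacunae > 0) {
    if (is.character(spec$lacuna_placement)) {
      with_seed(derive_seed(spec$seed, "lacunae"), {
        attempts <- 0L
        while (nrow(centres) < spec$n_lacunae) {
          attempts <- attempts + 1L
          if (attempts > 2000L * spec$n_lacunae) {
            abort(paste(
              "lacuna placement failed: cannot fit", spec$n_lacunae,
              "lacunae with a minimum gap of 2 voxels inside the shell wall"
            ))
          }
          u <- draw_orientation()
          Rf <- orient_frame(u)
          p <- c(
            runif(1, cx - Ro, cx + Ro), runif(1, cy - Ro, cy + Ro),
            runif(1, 1.5, nz - 0.5)
          )
          if (!lac_ok(p, Rf)) next
          ok <- TRUE
          if (nrow(centres) > 0) {
            for (kk in seq_len(nrow(centres))) {
              dv <- p - centres[kk, ]
              d <- sqrt(sum(dv^2))
              dir <- dv / d
              if (d < ellipsoid_support(Rf, ax, dir) +
                    ellipsoid_support(frames[[kk]], ax, dir) + 2) {
                ok <- FALSE
                break
              }
            }
          }
          if (!ok) next
          centres <- rbind(centres, p)
          frames[[nrow(centres)]] <- Rf
        }
      })
    } else {
      sp <- spec$lacuna_placement
      gx <- cx + sp[1] * seq(-ceiling(Ro / sp[1]), ceiling(Ro / sp[1]))
      gy <- cy + sp[2] * seq(-ceiling(Ro / sp[2]), ceiling(Ro / sp[2]))
      gz <- seq(1.5 + ax[3], nz - 0.5 - ax[3], by = sp[3])
      cand <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      cand_frames <- lapply(seq_len(nrow(cand)), function(i) {
        with_seed(derive_seed(spec$seed, "orient", i),
                  orient_frame(draw_orientation()))
      })
      keep <- vapply(seq_len(nrow(cand)),
                     function(i) lac_ok(cand[i, ], cand_frames[[i]]),
                     logical(1))
      cand <- cand[keep, , drop = FALSE]
      cand_frames <- cand_frames[keep]
      if (nrow(cand) < spec$n_lacunae) {
        abort(paste(
          "lacuna placement failed: lattice admits only", nrow(cand),
          "positions inside the shell wall but", spec$n_lacunae, "were requested"
        ))
      }
      # pick a compact cluster: nearest candidates to a mid-wall reference
      ref <- c(cx + (Ri + Ro) / 2, cy, (1 + nz) / 2)
      d <- sqrt(rowSums((cand - matrix(ref, nrow(cand), 3, byrow = TRUE))^2))
      pick <- order(d, seq_along(d))[seq_len(spec$n_lacunae)]
      centres <- cand[pick, , drop = FALSE]
      frames <- cand_frames[pick]
    }
  }

  # --- rasterise canals ----------------------------------------------------
  zs <- seq_len(nz)
  objects <- list()
  next_id <- 1L
  if (nrow(canal_xy) > 0) {
    for (k in seq_len(nrow(canal_xy))) {
      p <- canal_xy[k, ]
      in_tube <- outer((xs - p[1])^2, (ys - p[2])^2, `+`) <= cr^2
      idx2 <- which(in_tube)
      for (z in zs) {
        off <- (z - 1L) * nx * ny
        phase[off + idx2] <- 2L
        object_id[off + idx2] <- next_id
      }
      objects[[next_id]] <- tibble(
        id = next_id, class = "canal",
        cx_um = (p[1] - 0.5) * vox, cy_um = (p[2] - 0.5) * vox,
        cz_um = (nz / 2) * vox,
        a_um = nz / 2 * vox, b_um = cr * vox, c_um = cr * vox,
        ux = 0, uy = 0, uz = 1,
        voxel_count = sum(in_tube) * nz
      )
      next_id <- next_id + 1L
    }
  }

  # --- rasterise lacunae ---------------------------------------------------
  if (nrow(centres) > 0) {
    for (k in seq_len(nrow(centres))) {
      p <- centres[k, ]
      R <- frames[[k]]
      u <- R[, 1]
      lo <- pmax(floor(p - a_max - 1), c(1, 1, 1))
      hi <- pmin(ceiling(p + a_max + 1), c(nx, ny, nz))
      bx <- seq(lo[1], hi[1])
      by <- seq(lo[2], hi[2])
      bz <- seq(lo[3], hi[3])
      g <- expand.grid(x = bx, y = by, z = bz)
      d <- cbind(g$x - p[1], g$y - p[2], g$z - p[3]) %*% R
      inside <- (d[, 1] / ax[1])^2 + (d[, 2] / ax[2])^2 + (d[, 3] / ax[3])^2 <= 1
      if (!any(inside)) {
        # degenerate rasterisation (sub-voxel object): keep the centre voxel
        ci <- round(p)
        phase[ci[1], ci[2], ci[3]] <- 3L
        object_id[ci[1], ci[2], ci[3]] <- next_id
        nvox <- 1L
      } else {
        lin <- (g$x[inside]) + (g$y[inside] - 1L) * nx +
          (g$z[inside] - 1L) * nx * ny
        phase[lin] <- 3L
        object_id[lin] <- next_id
        nvox <- sum(inside)
      }
      objects[[next_id]] <- tibble(
        id = next_id, class = "lacuna",
        cx_um = (p[1] - 0.5) * vox, cy_um = (p[2] - 0.5) * vox,
        cz_um = (p[3] - 0.5) * vox,
        a_um = ax[1] * vox, b_um = ax[2] * vox, c_um = ax[3] * vox,
        ux = u[1], uy = u[2], uz = u[3],
        voxel_count = nvox
      )
      next_id <- next_id + 1L
    }
  }

  data <- array(spec$intensity_pore, dim = dim(phase))
  data[phase == 1L] <- spec$intensity_bone
  if (spec$noise_sigma > 0) {
    noise <- with_seed(
      derive_seed(spec$seed, "noise"),
      rnorm(length(data), 0, spec$noise_sigma)
    )
    data <- data + array(noise, dim = dim(data))
  }

  objects <- if (length(objects)) dplyr::bind_rows(objects) else tibble(
    id = integer(), class = character(), cx_um = numeric(), cy_um = numeric(),
    cz_um = numeric(), a_um = numeric(), b_um = numeric(), c_um = numeric(),
    ux = numeric(), uy = numeric(), uz = numeric(), voxel_count = integer()
  )

  structure(
    list(
      data = data,
      voxel_size_um = vox,
      truth = list(phase = phase, object_id = object_id, objects = objects,
                   spec = spec)
    ),
    class = "voxel_volume"
  )
}

#' Construct a voxel volume from a bare array
#'
#' Wraps an existing 3D grayscale array (e.g. read from file) as a
#' `voxel_volume` without ground truth.
#'
#' @param data 3D numeric array.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @return A `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um) {
  if (length(dim(data)) != 3L || any(dim(data) < 1L)) {
    abort("`data` must be a 3D array with positive extents.")
  }
  stopifnot_scalar_number(voxel_size_um, "voxel_size_um", 0, strict = TRUE)
  structure(
    list(data = data, voxel_size_um = voxel_size_um, truth = NULL),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels @ %g um%s\n", d[1], d[2], d[3],
    x$voxel_size_um,
    if (is.null(x$truth)) "" else sprintf(
      " | ground truth: %d objects", nrow(x$truth$objects)
    )
  ))
  invisible(x)
}
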