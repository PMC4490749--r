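# Fixture builders and independent oracles used across the suite.

# --- segmentation fixtures ------------------------------------------------

# phase_segmentation built directly from a pore mask inside a solid bone block
seg_from_pore_mask <- function(pore, voxel_size_um = 1.4) {
  phase <- array(1L, dim = dim(pore))
  phase[pore] <- 4L
  structure(
    list(
      phase = phase, voxel_size_um = voxel_size_um,
      bone_voxel_count = sum(!pore), threshold = NA_real_,
      components = NULL, object_id = NULL
    ),
    class = "phase_segmentation"
  )
}

# solid digital ellipsoid mask (centre of an odd-sized box), optional rotation
ellipsoid_mask <- function(axes, R = diag(3), pad = 3) {
  half <- ceiling(max(axes)) + pad
  n <- 2L * half + 1L
  ctr <- half + 1
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  d <- cbind(g$x - ctr, g$y - ctr, g$z - ctr) %*% R
  inside <- (d[, 1] / axes[1])^2 + (d[, 2] / axes[2])^2 + (d[, 3] / axes[3])^2 <= 1
  array(inside, dim = c(n, n, n))
}

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)

# label a pore-mask segmentation with ranges wide enough for the object
label_wide <- function(seg, max_vox = 1e5) {
  vox3 <- seg$voxel_size_um^3
  label_components(seg, lacuna_volume_range_um3 = c(1, max_vox) * vox3,
                   min_canal_volume_um3 = max_vox * vox3)
}

# --- distribution oblateness oracle ---------------------------------------

# brute-force k-NN displacement tensor (independent of the package internals)
knn_tensor_oracle <- function(pts, k) {
  n <- nrow(pts)
  M <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d2 <- colSums((t(pts) - pts[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    for (j in nb) {
      v <- pts[j, ] - pts[i, ]
      M <- M + outer(v, v)
    }
  }
  M / (n * k)
}

# --- continuous ray-casting thickness oracle ------------------------------

# thickness of the continuous annulus (outer radius Ro at the origin, inner
# radius Ri centred at `offset`) along a ray from `origin` at angle theta,
# by fine sampling of the continuous membership function
cont_thickness_oracle <- function(Ro, Ri, offset, origin, theta, dr = 0.01) {
  rmax <- 2 * Ro
  rs <- seq(0, rmax, by = dr)
  px <- origin[1] + rs * cos(theta)
  py <- origin[2] + rs * sin(theta)
  inside <- (px^2 + py^2 <= Ro^2) &
    ((px - offset[1])^2 + (py - offset[2])^2 > Ri^2)
  if (!any(inside)) return(NA_real_)
  rs[max(which(inside))] - rs[min(which(inside))]
}

# --- exhaustive F2 HMM posterior oracle ------------------------------------

# Posterior genotype probabilities for ONE individual by brute-force
# enumeration over the two independent gamete paths (4^K pair paths), built
# from first principles: gamete transition [[1-r, r], [r, 1-r]].
enum_f2_posterior <- function(obs, pos, error_rate) {
  K <- length(pos)
  gam <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE)
  emis <- function(g, o) {
    if (is.na(o)) return(1)
    if (g == o) 1 - error_rate else error_rate / 2
  }
  # pair states: (a, b) each in 0/1; genotype = a + b
  states <- expand.grid(a = 0:1, b = 0:1)
  paths <- expand.grid(rep(list(seq_len(4)), K))
  post <- matrix(0, K, 3)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    idx <- as.integer(paths[p, ])
    w <- 0.25 # uniform prior over the 4 gamete pairs
    ok <- TRUE
    for (t in seq_len(K)) {
      g <- states$a[idx[t]] + states$b[idx[t]]
      if (t > 1) {
        r <- (1 - exp(-2 * (pos[t] - pos[t - 1]) / 100)) / 2
        G <- gam(r)
        w <- w * G[states$a[idx[t - 1]] + 1, states$a[idx[t]] + 1] *
          G[states$b[idx[t - 1]] + 1, states$b[idx[t]] + 1]
      }
      w <- w * emis(g, obs[t])
      if (w == 0) { ok <- FALSE; break }
    }
    if (!ok) next
    total <- total + w
    for (t in seq_len(K)) {
      g <- states$a[idx[t]] + states$b[idx[t]]
      post[t, g + 1] <- post[t, g + 1] + w
    }
  }
  post / total
}

# small single-chromosome cross built from explicit genotype codes
manual_cross <- function(geno, pos, pheno = NULL, sex = NULL,
                         chr = "1") {
  n <- nrow(geno)
  map <- tibble::tibble(
    chr = chr, marker = sprintf("m%d", seq_along(pos)), pos_cM = pos
  )
  colnames(geno) <- map$marker
  structure(
    list(
      map = map, geno = geno,
      sex = sex %||% rep(0L, n),
      pheno_f2 = pheno %||% rep(0, n),
      pheno_f1 = numeric(0),
      truth = NULL
    ),
    class = "cross_data"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
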