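# Phase segmentation of grayscale volumes and connected-component labeling of
# the pore space. Phase codes used throughout:
#   0 background, 1 bone, 2 canal, 3 lacuna, 4 unclassified pore (speckle).

PHASE_BACKGROUND <- 0L
PHASE_BONE <- 1L
PHASE_CANAL <- 2L
PHASE_LACUNA <- 3L
PHASE_PORE <- 4L

otsu_threshold <- function(data) {
  rng <- range(data)
  if (rng[1] == rng[2]) return(rng[1] + 1) # degenerate: everything below
  # flatten to one frame so a single global threshold is computed
  img <- EBImage::Image(matrix((data - rng[1]) / (rng[2] - rng[1]), nrow = dim(data)[1]))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  rng[1] + th * (rng[2] - rng[1])
}

# 26-connectivity connected components over a set of voxels given by linear
# indices into an array of dimension `dims`. Returns a membership vector
# parallel to `idx`.
label_components_26 <- function(idx, dims) {
  if (length(idx) == 0L) return(integer(0))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- (idx - 1L) %% nx + 1L
  j <- ((idx - 1L) %/% nx) %% ny + 1L
  k <- (idx - 1L) %/% (nx * ny) + 1L
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[with(offs, dk > 0 | (dk == 0 & dj > 0) |
                      (dk == 0 & dj == 0 & di > 0)), ]
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    valid <- i + di >= 1L & i + di <= nx &
      j + dj >= 1L & j + dj <= ny &
      k + dk >= 1L & k + dk <= nz
    nidx <- idx[valid] + di + dj * nx + dk * nx * ny
    m <- match(nidx, idx)
    hit <- !is.na(m)
    edges_from <- c(edges_from, which(valid)[hit])
    edges_to <- c(edges_to, m[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  as.integer(igraph::components(g)$membership)
}

#' Segment a grayscale volume into bone and pore phases
#'
#' Voxels at or above the bone threshold become the bone phase. The bone mask
#' of every Z slice is then hole-filled in 2D, and enclosed non-bone voxels
#' become the pore phase; the medullary cavity (any enclosed component larger
#' than `medullary_min_fraction` of the filled shell, such as the central bore
#' of a hollow diaphysis) is assigned to background, as are all voxels outside
#' the filled shell.
#'
#' @param volume A `voxel_volume`.
#' @param bone_threshold Numeric grayscale threshold, or `"otsu"` (default) for
#'   automatic selection by Otsu's method on the full-volume histogram.
#' @param medullary_min_fraction Minimum fraction of the filled-shell volume an
#'   enclosed component must occupy to be treated as the medullary cavity
#'   (default 0.05).
#' @return An object of class `phase_segmentation` with elements `phase`
#'   (integer array: 0 background, 1 bone, 4 pore), `voxel_size_um`,
#'   `bone_voxel_count`, and empty `components`.
#' @seealso [label_components()]
#' @export
segment_phases <- function(volume, bone_threshold = "otsu",
                           medullary_min_fraction = 0.05) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- volume$data
  thr <- if (identical(bone_threshold, "otsu")) {
    otsu_threshold(d)
  } else {
    stopifnot_scalar_number(bone_threshold, "bone_threshold")
    bone_threshold
  }
  bone <- d >= thr
  if (!any(bone)) abort("no bone phase found")

  dims <- dim(d)
  filled <- bone
  for (z in seq_len(dims[3])) {
    sl <- bone[, , z]
    if (!any(sl)) next
    f <- EBImage::fillHull(EBImage::Image(sl * 1))
    filled[, , z] <- as.array(f) > 0.5
  }
  enclosed <- filled & !bone

  phase <- array(PHASE_BACKGROUND, dim = dims)
  phase[bone] <- PHASE_BONE
  enc_idx <- which(enclosed)
  if (length(enc_idx)) {
    memb <- label_components_26(enc_idx, dims)
    sizes <- tabulate(memb)
    medullary <- which(sizes > medullary_min_fraction * sum(filled))
    pore <- !(memb %in% medullary)
    phase[enc_idx[pore]] <- PHASE_PORE
  }

  structure(
    list(
      phase = phase,
      voxel_size_um = volume$voxel_size_um,
      bone_voxel_count = sum(bone),
      threshold = thr,
      components = NULL,
      object_id = NULL
    ),
    class = "phase_segmentation"
  )
}

#' Label and classify pore components
#'
#' Finds 26-connectivity connected components of the pore phase and classifies
#' each by volume: components inside the lacuna volume range become lacunae,
#' components at or above the canal volume threshold become canals, and
#' anything else stays unclassified (speckle noise). Components touching the
#' volume border are flagged: they still count toward densities (their
#' existence is certain) but are excluded from shape statistics (their shapes
#' are clipped).
#'
#' @param seg A `phase_segmentation` from [segment_phases()].
#' @param lacuna_volume_range_um3 Length-2 numeric `(lo, hi)` lacuna volume
#'   range in cubic micrometres. Default `c(50, 1000) * 1.4^3` (50-1000 voxels
#'   at 1.4 um).
#' @param min_canal_volume_um3 Minimum canal volume in cubic micrometres; must
#'   not overlap the lacuna range. Default `1500 * 1.4^3`.
#' @return The segmentation with `components` (tibble: `id`, `class`,
#'   `voxel_count`, `volume_um3`, `border_touching`, and a `voxels` list-column
#'   of linear indices) and an `object_id` array filled in; phase codes 2/3 are
#'   assigned to canal/lacuna voxels.
#' @export
label_components <- function(seg,
                             lacuna_volume_range_um3 = c(50, 1000) * 1.4^3,
                             min_canal_volume_um3 = 1500 * 1.4^3) {
  stopifnot(inherits(seg, "phase_segmentation"))
  lr <- lacuna_volume_range_um3
  if (length(lr) != 2L || !is.numeric(lr) || lr[1] >= lr[2]) {
    abort("`lacuna_volume_range_um3` must be (lo, hi) with lo < hi.")
  }
  stopifnot_scalar_number(min_canal_volume_um3, "min_canal_volume_um3", 0)
  if (min_canal_volume_um3 < lr[2]) {
    abort("lacuna and canal volume ranges overlap; classification by volume requires disjoint ranges.")
  }

  dims <- dim(seg$phase)
  # reset any previous classification
  seg$phase[seg$phase %in% c(PHASE_CANAL, PHASE_LACUNA)] <- PHASE_PORE
  pore_idx <- which(seg$phase == PHASE_PORE)
  vox3 <- seg$voxel_size_um^3

  if (length(pore_idx) == 0L) {
    seg$components <- tibble(
      id = integer(), class = character(), voxel_count = integer(),
      volume_um3 = numeric(), border_touching = logical(), voxels = list()
    )
    seg$object_id <- array(0L, dim = dims)
    return(seg)
  }

  memb <- label_components_26(pore_idx, dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- (pore_idx - 1L) %% nx + 1L
  j <- ((pore_idx - 1L) %/% nx) %% ny + 1L
  k <- (pore_idx - 1L) %/% (nx * ny) + 1L
  on_border <- i == 1L | i == nx | j == 1L | j == ny | k == 1L | k == nz

  split_idx <- split(seq_along(pore_idx), memb)
  comps <- purrr::imap(split_idx, function(rows, key) {
    n <- length(rows)
    vol <- n * vox3
    cls <- if (vol >= lr[1] && vol <= lr[2]) {
      "lacuna"
    } else if (vol >= min_canal_volume_um3) {
      "canal"
    } else {
      "speckle"
    }
    tibble(
      class = cls, voxel_count = n, volume_um3 = vol,
      border_touching = any(on_border[rows]),
      voxels = list(pore_idx[rows])
    )
  })
  comps <- dplyr::bind_rows(comps)
  # stable IDs: order by class (canal, lacuna, speckle) then first voxel
  ord <- order(match(comps$class, c("canal", "lacuna", "speckle")),
               purrr::map_dbl(comps$voxels, 1))
  comps <- comps[ord, ]
  comps$id <- seq_len(nrow(comps))
  comps <- dplyr::select(comps, "id", dplyr::everything())

  object_id <- array(0L, dim = dims)
  for (r in seq_len(nrow(comps))) {
    v <- comps$voxels[[r]]
    object_id[v] <- comps$id[r]
    seg$phase[v] <- switch(comps$class[r],
      canal = PHASE_CANAL, lacuna = PHASE_LACUNA, PHASE_PORE
    )
  }
  seg$components <- comps
  seg$object_id <- object_id
  seg
}

#' Build a segmentation directly from phantom ground truth
#'
#' Converts the voxel-exact ground truth carried by a generated phantom into a
#' `phase_segmentation`, bypassing thresholding and labeling. Used as the
#' reference ("oracle") segmentation when validating the image pipeline.
#'
#' @param volume A `voxel_volume` with ground truth.
#' @return A `phase_segmentation` with components taken from the true objects.
#' @export
truth_segmentation <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"), !is.null(volume$truth))
  phase <- volume$truth$phase
  object_id <- volume$truth$object_id
  dims <- dim(phase)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox3 <- volume$voxel_size_um^3
  objs <- volume$truth$objects
  comps <- purrr::map(seq_len(nrow(objs)), function(r) {
    v <- which(object_id == objs$id[r])
    i <- (v - 1L) %% nx + 1L
    j <- ((v - 1L) %/% nx) %% ny + 1L
    k <- (v - 1L) %/% (nx * ny) + 1L
    tibble(
      id = objs$id[r], class = objs$class[r], voxel_count = length(v),
      volume_um3 = length(v) * vox3,
      border_touching = any(i == 1L | i == nx | j == 1L | j == ny |
                              k == 1L | k == nz),
      voxels = list(v)
    )
  })
  structure(
    list(
      phase = phase,
      voxel_size_um = volume$voxel_size_um,
      bone_voxel_count = sum(phase == PHASE_BONE),
      threshold = NA_real_,
      components = dplyr::bind_rows(comps),
      object_id = object_id
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "<phase_segmentation> %d x %d x %d | bone %d voxels | %s\n",
    d[1], d[2], d[3], x$bone_voxel_count,
    if (is.null(x$components)) "components not labeled" else sprintf(
      "%d lacunae, %d canals, %d speckles",
      sum(x$components$class == "lacuna"),
      sum(x$components$class == "canal"),
      sum(x$components$class == "speckle")
    )
  ))
  invisible(x)
}

# voxel index coordinates (1-based array indices) of one component
component_coords <- function(seg, id) {
  v <- seg$components$voxels[[match(id, seg$components$id)]]
  dims <- dim(seg$phase)
  nx <- dims[1]; ny <- dims[2]
  cbind(
    i = (v - 1L) %% nx + 1L,
    j = ((v - 1L) %/% nx) %% ny + 1L,
    k = (v - 1L) %/% (nx * ny) + 1L
  )
}

#' Write a labeled segmentation to a directory
#'
#' Writes the phase-label volume as `labels.tif` (16-bit) and the component
#' table as `components.csv` (`id`, `class`, `voxel_count`, `volume_um3`,
#' `border_touching`).
#'
#' @param seg A labeled `phase_segmentation`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "phase_segmentation"), !is.null(seg$components))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- voxel_volume(seg$phase, seg$voxel_size_um)
  write_volume_tiff(lab, file.path(dir, "labels.tif"))
  write.csv(
    dplyr::select(seg$components, -"voxels"),
    file.path(dir, "components.csv"), row.names = FALSE
  )
  invisible(dir)
}
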