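# Volume exchange: multi-page 16-bit TIFF for grayscale and label volumes, CSV
# for ground-truth object tables and per-component tables. Grayscale values are
# stored as 16-bit integers (value = round(gray), so intensities must lie in
# [0, 65535]; noisy volumes are clipped and quantised on write).

#' Write a voxel volume as a multi-page 16-bit TIFF
#'
#' @param volume A `voxel_volume`.
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- volume$data
  d <- pmin(pmax(round(d), 0), 65535) / 65535
  pages <- lapply(seq_len(dim(d)[3]), function(z) t(d[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a voxel volume
#'
#' Inverse of [write_volume_tiff()]; grayscale values are recovered as
#' `pixel * 65535`.
#'
#' @param path TIFF file path.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @return A `voxel_volume` (without ground truth).
#' @export
read_volume_tiff <- function(path, voxel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) data[, , z] <- t(pages[[z]]) * 65535
  voxel_volume(data, voxel_size_um)
}

#' Write a phantom with its ground truth to a directory
#'
#' Writes `volume.tif` (grayscale), `labels.tif` (phase labels as 16-bit
#' integers: 0 background, 1 bone, 2 canal, 3 lacuna), `object_id.tif`
#' (per-object IDs) and `objects.csv` (true object parameters).
#'
#' @param volume A `voxel_volume` carrying ground truth.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(volume, dir) {
  stopifnot(inherits(volume, "voxel_volume"), !is.null(volume$truth))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume_tiff(volume, file.path(dir, "volume.tif"))
  lab <- volume
  lab$data <- volume$truth$phase
  write_volume_tiff(lab, file.path(dir, "labels.tif"))
  ids <- volume
  ids$data <- volume$truth$object_id
  write_volume_tiff(ids, file.path(dir, "object_id.tif"))
  write.csv(volume$truth$objects, file.path(dir, "objects.csv"),
            row.names = FALSE)
  invisible(dir)
}
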