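#' Write a volume or 4-D series as NIfTI-1
#'
#' The affine encodes the voxel size in millimetres.
#'
#' @param arr numeric array (3-D volume or 4-D series).
#' @param voxel_mm voxel size per spatial axis (mm).
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(arr, voxel_mm, path) {
  im <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(im)
  pd[seq_along(voxel_mm)] <- voxel_mm
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return list: `data` array, `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  list(data = as.array(im), voxel_mm = RNifti::pixdim(im))
}

#' Write a complex frame stack as a paired real/imaginary NIfTI with a JSON
#' sidecar
#'
#' @param stack a `perf_framestack`.
#' @param prefix output path prefix; writes `<prefix>_real.nii.gz`,
#'   `<prefix>_imag.nii.gz` and `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
write_framestack <- function(stack, prefix) {
  d <- c(stack$dim_px, ncol(stack$data))
  re <- array(Re(stack$data), d)
  im <- array(Im(stack$data), d)
  vx <- c(stack$pixel_mm, 1)
  write_volume_nifti(re, vx, paste0(prefix, "_real.nii.gz"))
  write_volume_nifti(im, vx, paste0(prefix, "_imag.nii.gz"))
  jsonlite::write_json(list(frame_rate = stack$frame_rate,
                            slice_pos_mm = stack$slice_pos_mm,
                            t_min = stack$t_min,
                            pixel_mm = stack$pixel_mm,
                            dim_px = stack$dim_px),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a frame stack written by [write_framestack()]
#'
#' @param prefix path prefix used when writing.
#' @return a `perf_framestack`.
#' @export
read_framestack <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  re <- read_volume_nifti(paste0(prefix, "_real.nii.gz"))$data
  im <- read_volume_nifti(paste0(prefix, "_imag.nii.gz"))$data
  d <- dim(re)
  framestack(matrix(complex(real = re, imaginary = im), prod(d[1:2]), d[3]),
             dim_px = meta$dim_px, frame_rate = meta$frame_rate,
             slice_pos_mm = meta$slice_pos_mm, t_min = meta$t_min,
             pixel_mm = meta$pixel_mm)
}

#' Write ground-truth or estimated bubble tracks as CSV
#'
#' Columns follow the exchange convention
#' `track_id, frame, x_mm, y_mm, vx, vy`.
#'
#' @param tracks data frame of track points.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}
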