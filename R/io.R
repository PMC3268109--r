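# File interfaces: NIfTI + YAML sidecar for image data, CSV for contours,
# point clouds and ground truth.

#' Write a synthetic study to a directory
#'
#' Tagged series: one NIfTI per slice (rows x cols x frames) plus a YAML
#' sidecar with tag spacing, directions, frame interval and trigger
#' convention.  LGE: intensity and myocardial-mask NIfTI volumes.
#' Contours, EAM cloud and the ground-truth segment table are CSV.
#'
#' @param study a \code{synthetic_study}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tg <- study$tagged
  if (!is.null(tg)) {
    for (sl in seq_len(dim(tg$pixels)[4])) {
      img <- RNifti::asNifti(tg$pixels[, , , sl],
                             pixdim = c(tg$pixel_spacing_mm,
                                        tg$pixel_spacing_mm,
                                        tg$frame_interval_ms))
      RNifti::writeNifti(img, file.path(dir, sprintf("tagged_slice%d.nii.gz",
                                                     sl)))
    }
    yaml::write_yaml(list(
      pixel_spacing_mm = tg$pixel_spacing_mm,
      frame_interval_ms = tg$frame_interval_ms,
      tag_spacing_mm = tg$tag_spacing_mm,
      tag_directions = lapply(seq_len(nrow(tg$tag_directions)),
                              function(i) as.numeric(tg$tag_directions[i, ])),
      trigger = tg$trigger,
      n_slices = dim(tg$pixels)[4]),
      file.path(dir, "tagged_sidecar.yaml"))
  }
  if (!is.null(study$lge)) {
    vx <- study$lge$voxel_mm
    RNifti::writeNifti(RNifti::asNifti(study$lge$intensity, pixdim = vx),
                       file.path(dir, "lge.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(study$lge$myo_mask + 0, pixdim = vx),
                       file.path(dir, "lge_myo_mask.nii.gz"))
    yaml::write_yaml(list(voxel_mm = as.numeric(vx),
                          slice_level = as.integer(study$lge$slice_level)),
                     file.path(dir, "lge_sidecar.yaml"))
  }
  if (!is.null(study$contours))
    utils::write.csv(cbind(subject = study$subject_id,
                           as.data.frame(study$contours)),
                     file.path(dir, "contours.csv"), row.names = FALSE)
  if (!is.null(study$eam))
    utils::write.csv(as.data.frame(study$eam),
                     file.path(dir, "eam.csv"), row.names = FALSE)
  truth <- study$truth$segments
  utils::write.csv(
    data.frame(segment_id = truth$segment_id, region = truth$region,
               peak_ec_pct = truth$peak_ec_pct, ttp_ms = truth$ttp_ms),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a tagged series written by \code{\link{write_study}}
#'
#' @param dir study directory
#' @return a \code{tagged_series}
#' @export
read_tagged <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "tagged_sidecar.yaml"))
  n_slices <- side$n_slices
  vols <- lapply(seq_len(n_slices), function(sl)
    as.array(RNifti::readNifti(file.path(dir,
                                         sprintf("tagged_slice%d.nii.gz", sl)))))
  d <- dim(vols[[1]])
  pix <- array(0, c(d[1], d[2], d[3], n_slices))
  for (sl in seq_len(n_slices)) pix[, , , sl] <- vols[[sl]]
  structure(list(
    pixels = pix,
    pixel_spacing_mm = side$pixel_spacing_mm,
    frame_interval_ms = side$frame_interval_ms,
    tag_spacing_mm = side$tag_spacing_mm,
    tag_directions = do.call(rbind, side$tag_directions),
    times_ms = (0:(d[3] - 1)) * side$frame_interval_ms,
    trigger = side$trigger), class = "tagged_series")
}

#' Read a contour stack CSV written by \code{\link{write_study}}
#' @param path CSV path
#' @param slice_step_mm slice step (thickness + gap)
#' @param frame_interval_ms frame interval
#' @return a \code{contour_stack}
#' @export
read_contours <- function(path, slice_step_mm = 15, frame_interval_ms = 33) {
  d <- utils::read.csv(path)
  d <- d[, c("slice", "frame", "surface", "vertex_index", "x_mm", "y_mm")]
  nf <- max(d$frame)
  structure(d, slice_step_mm = slice_step_mm,
            frame_interval_ms = frame_interval_ms,
            times_ms = (0:(nf - 1)) * frame_interval_ms,
            class = c("contour_stack", "data.frame"))
}

#' Read an EAM point-cloud CSV
#' @param path CSV path
#' @return an \code{eam_cloud}
#' @export
read_eam <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("eam_cloud", "data.frame"))
}
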