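# 16-segment geometry on the image grid, LGE quantification, transmurality
# and infarct / peri-infarct / normal classification.

#' Build per-frame segment geometry from an endo/epi contour stack
#'
#' Converts each slice/frame contour pair to polar radius profiles about
#' the endocardial centroid and rasterizes, on the image grid, the
#' myocardial mask, the AHA sector id of every pixel, and the mid-wall ROI
#' (middle third of the local wall thickness).
#'
#' @param contours a \code{contour_stack}
#' @param image_size image dimension (pixels)
#' @param pixel_spacing_mm pixel spacing
#' @return object of class \code{segment_geometry}: nested list
#'   \code{rois[[slice]][[frame]]} with elements \code{myocardium},
#'   \code{midwall} (logical matrices), \code{sector} (integer matrix,
#'   segment id or 0), \code{center}, \code{endo_r}, \code{epi_r}
#'   (radius profiles on a 1-degree grid).
#' @export
build_segments <- function(contours, image_size = 96L,
                           pixel_spacing_mm = 1.25) {
  stopifnot(inherits(contours, "contour_stack"))
  segs <- aha_segments()
  n <- image_size; dx <- pixel_spacing_mm
  cc <- (n + 1) / 2
  X <- (col(matrix(0, n, n)) - cc) * dx
  Y <- (cc - row(matrix(0, n, n))) * dx
  th_grid <- (0:359) * pi / 180
  slices <- sort(unique(contours$slice))
  frames <- sort(unique(contours$frame))
  rois <- vector("list", length(slices))
  for (sl in slices) {
    rois[[sl]] <- vector("list", length(frames))
    for (fr in frames) {
      en <- contours[contours$slice == sl & contours$frame == fr &
                       contours$surface == "endo", ]
      ep <- contours[contours$slice == sl & contours$frame == fr &
                       contours$surface == "epi", ]
      ctr <- c(mean(en$x_mm), mean(en$y_mm))
      re <- polar_profile(en$x_mm - ctr[1], en$y_mm - ctr[2], th_grid)
      rp <- polar_profile(ep$x_mm - ctr[1], ep$y_mm - ctr[2], th_grid)
      if (any(re >= rp))
        stop("crossing contours: endocardium must lie inside epicardium")
      thp <- wrap_2pi(atan2(Y - ctr[2], X - ctr[1]))
      rpix <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
      re_p <- stats::approx(c(th_grid, 2 * pi), c(re, re[1]), xout = thp)$y
      rp_p <- stats::approx(c(th_grid, 2 * pi), c(rp, rp[1]), xout = thp)$y
      myo <- rpix >= re_p & rpix <= rp_p
      fracw <- (rpix - re_p) / pmax(rp_p - re_p, 1e-9)
      midwall <- myo & fracw >= 1 / 3 & fracw <= 2 / 3
      sector <- matrix(0L, n, n)
      for (s in segs$segment_id[segs$level_index == sl]) {
        mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
        half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
        inside <- ang_dist_deg(thp * 180 / pi, mid) < half + 1e-9
        sector[inside & myo] <- s
      }
      rois[[sl]][[fr]] <- list(myocardium = myo, midwall = midwall,
                               sector = sector, center = ctr,
                               endo_r = re, epi_r = rp)
    }
  }
  structure(list(rois = rois, image_size = n, pixel_spacing_mm = dx,
                 theta_grid = th_grid),
            class = "segment_geometry")
}

# Radius-vs-angle profile of a star-shaped polygon on a uniform angle grid.
polar_profile <- function(x, y, th_grid) {
  th <- wrap_2pi(atan2(y, x))
  r <- sqrt(x^2 + y^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  stats::approx(c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi),
                c(r[length(r)], r, r[1]), xout = th_grid,
                ties = "mean")$y
}

#' @rdname build_segments
#' @param geometry a \code{segment_geometry}
#' @param slice,frame indices
#' @export
segment_rois <- function(geometry, slice, frame) {
  geometry$rois[[slice]][[frame]]
}

#' Quantify late gadolinium enhancement per segment and globally
#'
#' Threshold-based quantification: the threshold is the mean plus
#' \code{sd_mult} standard deviations of a remote-region intensity sample.
#' The remote region is chosen segment-wise: the four segments farthest in
#' 3D from the intensity maximum (angular distance plus a level-distance
#' penalty), which keeps the sample clear of the enhanced wedge and of any
#' border-zone spill-over.  Reports the enhanced fraction of each
#' segment's myocardium and the global enhanced percentage of LV
#' myocardial volume.
#'
#' @param volume an \code{lge_volume}
#' @param sd_mult threshold multiplier (default 5)
#' @return list with \code{segment_table} (data.frame: \code{segment_id},
#'   \code{lge_fraction}, \code{n_voxels}), \code{global_pct},
#'   \code{threshold}, \code{enhanced} (logical array)
#' @export
quantify_lge <- function(volume, sd_mult = 5) {
  stopifnot(inherits(volume, "lge_volume"))
  n <- dim(volume$intensity)[1]
  cc <- (n + 1) / 2
  dx <- volume$voxel_mm[1]
  X <- (col(matrix(0, n, n)) - cc) * dx
  Y <- (cc - row(matrix(0, n, n))) * dx
  th_deg <- wrap_2pi(atan2(Y, X)) * 180 / pi
  myo <- volume$myo_mask
  if (!any(myo)) stop("empty myocardial mask")
  segs <- aha_segments()
  seg_center <- (segs$theta_start + segs$theta_end) / 2
  seg_voxels <- function(s) {
    li <- segs$level_index[s]
    in_sector <- ang_dist_deg(th_deg, seg_center[s]) <
      (segs$theta_end[s] - segs$theta_start[s]) / 2
    sl_sel <- which(volume$slice_level == li)
    m <- myo[, , sl_sel, drop = FALSE] &
      array(in_sector, c(n, n, length(sl_sel)))
    volume$intensity[, , sl_sel, drop = FALSE][m]
  }
  # locate the enhancement by the brightest segment (mean intensity), then
  # sample the four segments farthest from it in 3D (angular distance plus
  # a level-distance penalty)
  seg_mean <- vapply(1:16, function(s) {
    v <- seg_voxels(s); if (length(v)) mean(v) else -Inf
  }, numeric(1))
  s_max <- which.max(seg_mean)
  score <- ang_dist_deg(seg_center, seg_center[s_max]) +
    60 * abs(segs$level_index - segs$level_index[s_max])
  far8 <- segs$segment_id[order(score, decreasing = TRUE)][1:8]
  # of the spatially farthest segments keep the dimmest four, which guards
  # against border-zone spill-over reaching a far sector
  remote_ids <- far8[order(seg_mean[far8])][1:4]
  remote_sample <- unlist(lapply(remote_ids, seg_voxels))
  if (length(remote_sample) < 30)
    stop("no remote region definable for thresholding")
  thr <- mean(remote_sample) + sd_mult * stats::sd(remote_sample)
  enh <- myo & volume$intensity > thr

  seg_tab <- data.frame(segment_id = 1:16, lge_fraction = NA_real_,
                        n_voxels = 0L)
  for (s in 1:16) {
    li <- segs$level_index[s]
    mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
    half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
    in_sector <- ang_dist_deg(th_deg, mid) < half + 1e-9
    sl_sel <- which(volume$slice_level == li)
    m <- myo[, , sl_sel, drop = FALSE] &
      array(in_sector, c(n, n, length(sl_sel)))
    e <- enh[, , sl_sel, drop = FALSE] &
      array(in_sector, c(n, n, length(sl_sel)))
    seg_tab$n_voxels[s] <- sum(m)
    seg_tab$lge_fraction[s] <- if (sum(m)) sum(e) / sum(m) else NA_real_
  }
  list(segment_table = seg_tab,
       global_pct = 100 * sum(enh) / sum(myo),
       threshold = thr,
       enhanced = enh)
}

#' Transmural extent of enhancement per segment
#'
#' For every radial chord (3-degree angular bin per slice) the ratio of the
#' enhanced radial extent to the wall radial extent is computed; a
#' segment's transmurality is the mean over its chords, and it is flagged
#' transmural at >= 0.90.
#'
#' @param volume an \code{lge_volume}
#' @param enhanced enhanced-voxel mask; default: threshold-quantified via
#'   \code{\link{quantify_lge}}
#' @return data.frame: \code{segment_id}, \code{transmurality},
#'   \code{transmural}
#' @export
transmurality <- function(volume, enhanced = NULL) {
  if (is.null(enhanced)) enhanced <- quantify_lge(volume)$enhanced
  n <- dim(volume$intensity)[1]
  cc <- (n + 1) / 2
  dx <- volume$voxel_mm[1]
  X <- (col(matrix(0, n, n)) - cc) * dx
  Y <- (cc - row(matrix(0, n, n))) * dx
  th_deg <- wrap_2pi(atan2(Y, X)) * 180 / pi
  rr <- sqrt(X^2 + Y^2)
  bin <- floor(th_deg / 3)               # 120 chords per slice
  segs <- aha_segments()
  out <- data.frame(segment_id = 1:16, transmurality = NA_real_,
                    transmural = NA)
  for (s in 1:16) {
    li <- segs$level_index[s]
    mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
    half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
    sl_sel <- which(volume$slice_level == li)
    ratios <- c()
    for (sl in sl_sel) {
      myo_sl <- volume$myo_mask[, , sl]
      enh_sl <- enhanced[, , sl]
      sel <- myo_sl & ang_dist_deg(th_deg, mid) < half + 1e-9
      if (!any(sel)) next
      for (b in unique(bin[sel])) {
        ray <- sel & bin == b
        if (sum(ray) < 2) next           # zero-thickness chord skipped
        # 1/r-weighted voxel counts estimate radial lengths: the number of
        # voxels in an angular bin grows with radius, so weighting by 1/r
        # recovers the chord-length ratio without edge discretization bias
        wall_len <- sum(1 / rr[ray])
        enh_len <- sum(1 / rr[ray & enh_sl])
        ratios <- c(ratios, min(enh_len / wall_len, 1))
      }
    }
    if (length(ratios)) {
      out$transmurality[s] <- mean(ratios)
      out$transmural[s] <- out$transmurality[s] >= 0.90
    }
  }
  out
}

#' Classify segments as infarct, peri-infarct or normal
#'
#' A segment is infarct (mi) when its enhanced fraction exceeds
#' \code{lge_thresh} AND the magnitude of its peak circumferential strain
#' is below \code{strain_thresh} percent; peri-infarct when it is not mi
#' but is adjacent (3D adjacency) to at least one mi segment; normal
#' otherwise.  Segments with missing (quality-failed) strain are excluded
#' from labelling and reported in the \code{excluded} attribute.
#'
#' @param lge_fraction numeric[16], enhanced fraction per segment
#' @param peak_ec numeric[16], peak strain (percent) per segment; NA =
#'   quality failed
#' @param adjacency an \code{aha_adjacency}; default
#'   \code{\link{default_adjacency}()}
#' @param lge_thresh enhancement threshold (fraction of segment volume)
#' @param strain_thresh strain-magnitude threshold (percent)
#' @return data.frame: \code{segment_id}, \code{region} (mi / peri_mi /
#'   normal, NA when excluded); attribute \code{excluded}
#' @export
classify_segments <- function(lge_fraction, peak_ec,
                              adjacency = default_adjacency(),
                              lge_thresh = 0.25, strain_thresh = 10) {
  stopifnot(length(lge_fraction) == 16L, length(peak_ec) == 16L)
  excluded <- which(is.na(peak_ec))
  mi <- !is.na(peak_ec) & lge_fraction > lge_thresh &
    abs(peak_ec) < strain_thresh
  label <- rep("normal", 16)
  if (any(mi)) {
    near <- rowSums(unclass(adjacency)[, mi, drop = FALSE]) > 0
    label[near & !mi] <- "peri_mi"
    label[mi] <- "mi"
  }
  label[excluded] <- NA_character_
  structure(data.frame(segment_id = 1:16, region = label,
                       stringsAsFactors = FALSE),
            excluded = excluded)
}
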