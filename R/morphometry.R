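# Chamber morphometry from contour stacks: Simpson volumes, ejection
# fraction, wall thickness, ventricular diameters.

# Shoelace area of a closed polygon (mm^2), vertices in order.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' LV cavity volume at one frame (Simpson slice summation)
#'
#' Sum over slices of endocardial polygon area times the slice step
#' (thickness + gap), converted to mL.  No partial-slice correction at the
#' apex or base is applied (the phantom has flat caps).
#'
#' @param contours a \code{contour_stack}
#' @param frame frame index
#' @return volume in mL
#' @export
lv_volume <- function(contours, frame) {
  step <- attr(contours, "slice_step_mm")
  slices <- sort(unique(contours$slice))
  if (length(slices) < 2) stop("at least 2 slices required")
  v <- 0
  for (sl in slices) {
    en <- contours[contours$slice == sl & contours$frame == frame &
                     contours$surface == "endo", ]
    if (!nrow(en)) next
    if (any(duplicated(en$vertex_index))) stop("malformed contour")
    v <- v + polygon_area(en$x_mm, en$y_mm) * step
  }
  v / 1000
}

#' LV volume curve, end-diastolic/systolic volumes and ejection fraction
#'
#' End-diastole is the frame of maximal volume, end-systole of minimal.
#'
#' @param contours a \code{contour_stack}
#' @return list: \code{volume_ml} (per frame), \code{edv_ml},
#'   \code{esv_ml}, \code{ef_pct}, \code{ed_frame}, \code{es_frame}
#' @export
lv_volumes <- function(contours) {
  frames <- sort(unique(contours$frame))
  v <- vapply(frames, function(f) lv_volume(contours, f), numeric(1))
  ed <- frames[which.max(v)]; es <- frames[which.min(v)]
  list(volume_ml = v, edv_ml = max(v), esv_ml = min(v),
       ef_pct = ef(max(v), min(v)), ed_frame = ed, es_frame = es)
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param edv_ml end-diastolic volume (mL), > 0
#' @param esv_ml end-systolic volume (mL), in [0, edv]
#' @return EF in percent: \code{100 * (EDV - ESV) / EDV}
#' @export
#' @examples
#' ef(42, 20)  # 52.4
ef <- function(edv_ml, esv_ml) {
  if (edv_ml <= 0) stop("EDV must be positive")
  if (esv_ml < 0 || esv_ml > edv_ml)
    stop("ESV must lie in [0, EDV]")
  100 * (edv_ml - esv_ml) / edv_ml
}

#' Per-segment wall thickness at one frame
#'
#' Mean radial endocardium-to-epicardium distance over 3-degree rays in
#' each segment's sector.
#'
#' @param contours a \code{contour_stack}
#' @param frame frame index (end-diastole for reporting)
#' @return data.frame: \code{segment_id}, \code{thickness_mm}
#' @export
wall_thickness <- function(contours, frame) {
  segs <- aha_segments()
  th_grid <- (0:119) * 3 * pi / 180
  out <- data.frame(segment_id = 1:16, thickness_mm = NA_real_)
  for (sl in sort(unique(contours$slice))) {
    en <- contours[contours$slice == sl & contours$frame == frame &
                     contours$surface == "endo", ]
    ep <- contours[contours$slice == sl & contours$frame == frame &
                     contours$surface == "epi", ]
    if (!nrow(en) || !nrow(ep)) next
    ctr <- c(mean(en$x_mm), mean(en$y_mm))
    re <- polar_profile(en$x_mm - ctr[1], en$y_mm - ctr[2], th_grid)
    rp <- polar_profile(ep$x_mm - ctr[1], ep$y_mm - ctr[2], th_grid)
    wt <- rp - re
    for (s in segs$segment_id[segs$level_index == sl]) {
      mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
      half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
      sel <- ang_dist_deg(th_grid * 180 / pi, mid) < half
      ok <- is.finite(wt[sel]) & wt[sel] > 0
      if (!any(ok)) { warning("segment ", s, ": no valid rays"); next }
      out$thickness_mm[s] <- mean(wt[sel][ok])
    }
  }
  out
}

#' LV and RV end-diastolic diameters at the mid-ventricular level
#'
#' LV diameter: the endocardial chord through the centroid along the
#' septal-lateral axis (perpendicular to the septal wall).  RV diameter:
#' the chord of the RV contour along the same axis, flagged absent when no
#' RV contour exists.
#'
#' @param contours a \code{contour_stack}
#' @param frame frame index
#' @param mid_slice mid-ventricular slice index (default 2)
#' @param septum_deg angular position of the septum centre (default 180)
#' @return list: \code{lvedd_mm}, \code{rvedd_mm} (NA when absent)
#' @export
chamber_diameters <- function(contours, frame, mid_slice = 2L,
                              septum_deg = 180) {
  en <- contours[contours$slice == mid_slice & contours$frame == frame &
                   contours$surface == "endo", ]
  if (!nrow(en)) stop("no mid-ventricular slice")
  ctr <- c(mean(en$x_mm), mean(en$y_mm))
  th_grid <- (0:359) * pi / 180
  re <- polar_profile(en$x_mm - ctr[1], en$y_mm - ctr[2], th_grid)
  i1 <- which.min(ang_dist_deg(th_grid * 180 / pi, septum_deg))
  i2 <- which.min(ang_dist_deg(th_grid * 180 / pi, septum_deg - 180))
  lvedd <- re[i1] + re[i2]

  rv <- contours[contours$slice == mid_slice & contours$frame == frame &
                   contours$surface == "rv", ]
  rvedd <- NA_real_
  if (nrow(rv)) {
    # chord of the RV polygon along the line through the LV centroid and
    # the septum centre: radial extent of vertices near that direction
    thv <- wrap_2pi(atan2(rv$y_mm - ctr[2], rv$x_mm - ctr[1])) * 180 / pi
    rr <- sqrt((rv$x_mm - ctr[1])^2 + (rv$y_mm - ctr[2])^2)
    sel <- ang_dist_deg(thv, septum_deg) < 4
    if (any(sel)) rvedd <- max(rr[sel]) - min(rr[sel])
  }
  list(lvedd_mm = lvedd, rvedd_mm = rvedd)
}

#' Morphometry table for one study
#'
#' @param contours a \code{contour_stack}
#' @return data.frame with one row: EDV, ESV, EF, LVEDD, RVEDD, mean MI /
#'   normal segment thickness at end-diastole (regions from
#'   \code{region_labels}, defaulting to all-normal when absent)
#' @param region_labels optional data.frame \code{segment_id},
#'   \code{region}
#' @export
morphometry_summary <- function(contours, region_labels = NULL) {
  vol <- lv_volumes(contours)
  wt <- wall_thickness(contours, vol$ed_frame)
  dia <- chamber_diameters(contours, vol$ed_frame)
  if (is.null(region_labels))
    region_labels <- data.frame(segment_id = 1:16, region = "normal")
  wt <- merge(wt, region_labels, by = "segment_id")
  data.frame(
    edv_ml = vol$edv_ml, esv_ml = vol$esv_ml, ef_pct = vol$ef_pct,
    lvedd_mm = dia$lvedd_mm, rvedd_mm = dia$rvedd_mm,
    mi_thickness_mm = if (any(wt$region == "mi", na.rm = TRUE))
      mean(wt$thickness_mm[wt$region == "mi"], na.rm = TRUE) else NA_real_,
    normal_thickness_mm = if (any(wt$region == "normal", na.rm = TRUE))
      mean(wt$thickness_mm[wt$region == "normal"], na.rm = TRUE)
      else NA_real_)
}
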