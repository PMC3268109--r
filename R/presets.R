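# Scenario presets: generator parameters encoding the study conditions of a
# closed-chest porcine LAD-occlusion infarct model at three imaging
# time-points (pre-MI baseline, ~10 days early post-MI, ~34 days late
# post-MI).

#' Build a scenario preset for the synthetic porcine-infarct phantom
#'
#' A preset bundles every parameter the phantom generator needs:
#' region-specific peak circumferential strain and time-to-peak (TTP)
#' distributions, the infarct segment set and its enhancement targets,
#' electrical conduction speeds per zone, the annular LV geometry, and the
#' acquisition parameters of the simulated tagged series.
#'
#' Field provenance (porcine infarct reference values):
#' \itemize{
#'   \item \code{region_peak_ec}: peak eC (mean +/- SD, \%) per region --
#'     baseline all-normal -27 +/- 2; early post-MI normal -24 +/- 4,
#'     peri-MI -18 +/- 2, MI -6 +/- 2; late -21 +/- 2 / -17 +/- 1 / -8 +/- 2.
#'   \item \code{region_ttp}: TTP (ms from QRS) -- baseline 300 +/- 46;
#'     early 329 +/- 40 / 332 +/- 36 / 440 +/- 40; late 321 +/- 40 /
#'     355 +/- 61 / 442 +/- 63.
#'   \item \code{sd16_target}: dyssynchrony index (SD of 16 segment TTPs):
#'     28 / 50 / 54 ms.  The within-subject TTP scatter
#'     \code{ttp_within_sd} is calibrated from it (see Details).
#'   \item \code{lge_fraction_target}: infarct volume as a fraction of LV
#'     myocardial volume: 0 / 0.21 / 0.20; \code{transmurality} 0.95
#'     (all MI segments transmural, >= 90\% wall thickness).
#'   \item \code{zone_speed}: conduction velocity (cm/s) 5.7 (infarct),
#'     18.7 (border zone), 39 (remote).
#'   \item \code{mi_segment_ids}: apical-to-mid anterior wall and anterior
#'     septum: mid-anterior (7), mid-anteroseptal (8), apical-anterior (13),
#'     apical-septal (14); empty pre-MI.
#'   \item \code{geometry}: 3-slice annular LV sized to the end-diastolic
#'     volume targets (42 / 56 / 65 mL) with normal wall 9 / 10 / 12 mm and
#'     infarct wall thinned to 6 / 5 mm post-MI.
#' }
#'
#' @details
#' Between-animal TTP variability is modelled as a common per-subject timing
#' offset (\code{ttp_subject_sd}); within a subject, segment TTPs scatter
#' about their region mean with SD \code{ttp_within_sd}, calibrated so the
#' expected SD over the 16 segments matches \code{sd16_target}:
#' \code{ttp_within_sd = sqrt(max(sd16_target^2 - var(region means), 0))}.
#' Peak-strain scatter within a subject is fixed at 40\% of the
#' between-animal region SD.
#'
#' @param name one of \code{"pre_mi"}, \code{"early_post_mi"},
#'   \code{"late_post_mi"}.
#' @return object of class \code{scenario_preset} (a list; see Details).
#' @export
#' @examples
#' p <- make_preset("pre_mi")
#' p$region_peak_ec["normal", "mean"]  # -27
make_preset <- function(name = c("pre_mi", "early_post_mi", "late_post_mi")) {
  if (length(name) != 1L || !name %in% c("pre_mi", "early_post_mi", "late_post_mi"))
    stop("unknown scenario name: ", paste(name, collapse = ", "),
         " (expected pre_mi, early_post_mi or late_post_mi)")

  regions <- c("normal", "peri_mi", "mi")
  tab <- switch(name,
    pre_mi = list(
      ec  = cbind(mean = c(-27, -27, -27), sd = c(2, 2, 2)),
      ttp = cbind(mean = c(300, 300, 300), sd = c(46, 46, 46)),
      sd16 = 28, lge = 0, mi_ids = integer(0),
      edv = 42, esv = 20, endo = c(19.0, 19.0, 13.0),
      wall = 9, mi_wall = 9, dysk = 0, rvedd = 24
    ),
    early_post_mi = list(
      ec  = cbind(mean = c(-24, -18, -6), sd = c(4, 2, 2)),
      ttp = cbind(mean = c(329, 332, 440), sd = c(40, 36, 40)),
      sd16 = 50, lge = 0.21, mi_ids = c(7L, 8L, 13L, 14L),
      edv = 56, esv = 31, endo = c(21.95, 21.95, 15.01),
      wall = 10, mi_wall = 6, dysk = 5, rvedd = 26
    ),
    late_post_mi = list(
      ec  = cbind(mean = c(-21, -17, -8), sd = c(2, 1, 2)),
      ttp = cbind(mean = c(321, 355, 442), sd = c(40, 61, 63)),
      sd16 = 54, lge = 0.20, mi_ids = c(7L, 8L, 13L, 14L),
      edv = 65, esv = 36, endo = c(23.65, 23.65, 16.17),
      wall = 12, mi_wall = 5, dysk = 5, rvedd = 27
    ))

  region_peak_ec <- data.frame(tab$ec, row.names = regions)
  region_ttp <- data.frame(tab$ttp, row.names = regions)

  segs <- aha_segments()
  adj <- default_adjacency()
  region_of <- rep("normal", 16)
  region_of[tab$mi_ids] <- "mi"
  if (length(tab$mi_ids)) {
    peri <- setdiff(unique(unlist(lapply(tab$mi_ids, segment_neighbors,
                                         adjacency = adj))), tab$mi_ids)
    region_of[peri] <- "peri_mi"
  }

  # calibrate within-subject TTP scatter from the SD16 target
  m16 <- region_ttp[region_of, "mean"]
  v_between <- stats::var(m16)
  ttp_within_sd <- sqrt(max(tab$sd16^2 - v_between, 0))

  geometry <- list(
    n_levels = 3L,
    levels = c("basal", "mid", "apical"),
    endo_radius_mm = tab$endo,
    wall_mm = rep(tab$wall, 3),
    mi_wall_mm = rep(tab$mi_wall, 3),
    slice_thickness_mm = 8,
    slice_gap_mm = 7,                      # Simpson step = 15 mm per level
    wedge_taper_deg = 10,
    lge_slices_per_level = 3L,
    lge_slice_mm = 5
  )

  preset <- structure(list(
    name = name,
    region_peak_ec = region_peak_ec,
    region_ttp = region_ttp,
    ttp_subject_sd = region_ttp["normal", "sd"],
    ttp_within_sd = ttp_within_sd,
    ec_within_frac = 0.4,
    sd16_target = tab$sd16,
    mi_dyskinesis_amp = tab$dysk,
    mi_segment_ids = tab$mi_ids,
    segment_region = region_of,
    lge_fraction_target = tab$lge,
    transmurality = if (length(tab$mi_ids)) 0.95 else 0,
    lge_contrast = list(mu_remote = 1, mu_enhanced = 1.8, sigma = 0.1),
    zone_speed = c(remote = 39, border = 18.7, infarct = 5.7),
    geometry = geometry,
    edv_ml = tab$edv,
    esv_ml = tab$esv,
    rvedd_mm = tab$rvedd,
    cycle_ms = 660,
    frame_interval_ms = 33,
    tag_spacing_mm = 6,
    tag_contrast = 0.8,
    pixel_spacing_mm = 1.25,
    image_size = 96L,
    noise_sigma = 0.05,
    eam = list(n_points = 300L, lat_noise_ms = 1.5,
               voltage_median = c(remote = 3.5, border = 0.9, infarct = 0.25),
               voltage_sdlog = 0.3,
               scar_mv = 0.5, border_mv = 1.5,
               border_width_mm = 15, border_width_deg = 30)
  ), class = "scenario_preset")
  validate_preset(preset)
  preset
}

#' Validate a scenario preset
#'
#' Checks the structural invariants of a preset: non-negative SDs, an
#' enhancement target in [0, 1), conduction speeds strictly ordered
#' infarct < border < remote, infarct segment ids within 1..16, at least 15
#' frames per cardiac cycle, and a non-degenerate annulus (endo < epi).
#'
#' @param preset a \code{scenario_preset}
#' @return the preset, invisibly; errors on violation.
#' @export
validate_preset <- function(preset) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (any(preset$region_peak_ec$sd < 0) || any(preset$region_ttp$sd < 0))
    stop("region SDs must be non-negative")
  if (preset$lge_fraction_target < 0 || preset$lge_fraction_target >= 1)
    stop("lge_fraction_target must lie in [0, 1)")
  zs <- preset$zone_speed
  if (any(zs <= 0)) stop("zone speeds must be positive")
  if (!(zs["infarct"] < zs["border"] && zs["border"] < zs["remote"]))
    stop("zone speeds must be strictly ordered infarct < border < remote")
  if (length(preset$mi_segment_ids) &&
      !all(preset$mi_segment_ids %in% 1:16))
    stop("mi_segment_ids must be a subset of 1..16")
  if (preset$cycle_ms / preset$frame_interval_ms < 15)
    stop("frame interval must give at least 15 frames per cycle")
  g <- preset$geometry
  if (any(g$wall_mm <= 0) || any(g$mi_wall_mm <= 0))
    stop("degenerate geometry: wall thickness must be positive (endo < epi)")
  if (preset$tag_spacing_mm < 3 * preset$pixel_spacing_mm)
    stop("tag spacing must be at least 3x the pixel spacing")
  invisible(preset)
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("scenario_preset:", x$name, "\n")
  cat("  MI segments:", if (length(x$mi_segment_ids))
    paste(x$mi_segment_ids, collapse = ", ") else "none", "\n")
  cat("  LGE target:", x$lge_fraction_target,
      " transmurality:", x$transmurality, "\n")
  cat("  SD16 target:", x$sd16_target, "ms (within-subject TTP SD",
      round(x$ttp_within_sd, 1), "ms)\n")
  cat("  zone speeds (cm/s):",
      paste(sprintf("%s=%g", names(x$zone_speed), x$zone_speed),
            collapse = " "), "\n")
  invisible(x)
}

# Reference wall thickness (mm) as a function of material angle (radians)
# at a given level: normal thickness with a smooth (raised-cosine, taper
# width geometry$wedge_taper_deg) dip to the infarct thickness inside the
# MI sector spans.
wall_thickness_ref <- function(preset, level_index, theta) {
  g <- preset$geometry
  wn <- g$wall_mm[level_index]
  wi <- g$mi_wall_mm[level_index]
  ind <- mi_wedge_indicator(preset, level_index, theta, g$wedge_taper_deg)
  wn - (wn - wi) * ind
}

# Smooth indicator (0..1) of the MI wedge at a level, 1 strictly inside the
# MI sector spans, raised-cosine edges of width taper_deg outside them.
mi_wedge_indicator <- function(preset, level_index, theta, taper_deg,
                               extend_deg = 0) {
  spans <- mi_wedge_spans(preset, level_index)
  out <- numeric(length(theta))
  if (is.null(spans)) return(out)
  th <- theta * 180 / pi
  for (k in seq_len(nrow(spans))) {
    s <- spans[k, 1] - extend_deg
    e <- spans[k, 2] + extend_deg
    mid <- (s + e) / 2
    half <- (e - s) / 2
    d <- ang_dist_deg(th, mid)           # distance from span centre
    v <- ifelse(d <= half, 1,
                ifelse(d >= half + taper_deg, 0,
                       0.5 * (1 + cos(pi * (d - half) / taper_deg))))
    out <- pmax(out, v)
  }
  out
}

# Contiguous angular spans (degrees, matrix [start, end]) covered by the MI
# segments at a level, merged when touching; NULL when the level has none.
mi_wedge_spans <- function(preset, level_index) {
  ids <- preset$mi_segment_ids
  if (!length(ids)) return(NULL)
  segs <- aha_segments()
  sel <- segs[segs$segment_id %in% ids & segs$level_index == level_index, ]
  if (!nrow(sel)) return(NULL)
  sp <- cbind(sel$theta_start, sel$theta_end)
  sp <- sp[order(sp[, 1]), , drop = FALSE]
  merged <- sp[1, , drop = FALSE]
  if (nrow(sp) > 1) for (k in 2:nrow(sp)) {
    if (sp[k, 1] <= merged[nrow(merged), 2] + 1e-9)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], sp[k, 2])
    else merged <- rbind(merged, sp[k, ])
  }
  merged
}
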