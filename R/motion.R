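# Analytic LV motion model: per-segment circumferential strain time-courses
# driving an area-preserving annular deformation of each short-axis slice.

#' Analytic circumferential strain time-course
#'
#' Normal segments: engineering strain ramps from 0 at the QRS trigger to
#' its (negative) peak at TTP along a raised cosine, then relaxes back to 0
#' at end-cycle along a raised cosine raised to a shaping exponent (0.7)
#' that keeps strain high in early diastole.  Infarcted segments first
#' stretch (dyskinesis): a positive sine lobe over the first 30\% of the
#' cycle, followed by a shallow raised-cosine descent to the delayed peak.
#' The curve is exactly 0 at t = 0 and t = cycle (periodic), and its unique
#' minimum over the cycle is \code{peak_pct} at \code{ttp_ms}.
#'
#' @param t_ms times (ms from QRS); values are taken modulo the cycle.
#' @param peak_pct peak (most negative) strain, percent.
#' @param ttp_ms time to peak, ms.
#' @param cycle_ms cardiac cycle length, ms.
#' @param dysk_amp_pct amplitude of the early dyskinetic lobe (percent,
#'   positive); 0 disables the lobe.
#' @param lobe_frac fraction of the cycle occupied by the lobe (default 0.3).
#' @param relax_shape exponent shaping the diastolic relaxation.
#' @return strain in percent, same length as \code{t_ms}.
#' @export
strain_timecourse <- function(t_ms, peak_pct, ttp_ms, cycle_ms,
                              dysk_amp_pct = 0, lobe_frac = 0.3,
                              relax_shape = 0.7) {
  t <- t_ms %% cycle_ms
  e <- numeric(length(t))
  relax <- function(tt) {
    (0.5 * (1 + cos(pi * (tt - ttp_ms) / (cycle_ms - ttp_ms))))^relax_shape
  }
  if (dysk_amp_pct <= 0) {
    up <- t <= ttp_ms
    e[up] <- peak_pct * 0.5 * (1 - cos(pi * t[up] / ttp_ms))
    e[!up] <- peak_pct * relax(t[!up])
  } else {
    t1 <- lobe_frac * cycle_ms
    if (ttp_ms <= t1)
      stop("infarct TTP must fall after the dyskinetic lobe (",
           round(t1), " ms)")
    a <- t < t1
    b <- !a & t <= ttp_ms
    e[a] <- dysk_amp_pct * sin(pi * t[a] / t1)
    e[b] <- peak_pct * 0.5 * (1 - cos(pi * (t[b] - t1) / (ttp_ms - t1)))
    e[!a & !b] <- peak_pct * relax(t[!a & !b])
  }
  e
}

#' Build a subject-level motion model from a scenario preset
#'
#' Draws per-segment strain parameters from the preset's region
#' distributions: a per-subject mean for each region's peak strain, segment
#' scatter at 40\% of the region SD, a common per-subject timing offset for
#' TTP, and within-subject TTP scatter calibrated to the preset's SD16
#' target.  Infarct segments additionally receive a positive dyskinetic
#' lobe.  The deformation is identity at frame 0 and periodic over the
#' cycle; the in-plane map preserves local wall area exactly (radial
#' thickening balances circumferential shortening).
#'
#' @param preset a \code{scenario_preset}.
#' @param seed integer seed; identical (preset, seed) give identical models.
#' @return object of class \code{motion_model} with the per-segment
#'   parameter table (\code{$params}) and the preset.
#' @export
build_motion <- function(preset, seed = 1L) {
  validate_preset(preset)
  segs <- aha_segments()
  region <- preset$segment_region
  cyc <- preset$cycle_ms
  lobe_end <- 0.3 * cyc

  params <- with_seed(mix_seed(seed, 101L), {
    regions <- rownames(preset$region_peak_ec)
    subj_ec <- stats::setNames(
      preset$region_peak_ec$mean +
        stats::rnorm(3) * preset$region_peak_ec$sd, regions)
    subj_dt <- stats::rnorm(1) * preset$ttp_subject_sd
    ec_sd <- stats::setNames(
      preset$ec_within_frac * preset$region_peak_ec$sd, regions)
    peak <- subj_ec[region] + stats::rnorm(16) * ec_sd[region]
    peak <- pmin(peak, -0.5)           # keep a negative trough
    ttp <- preset$region_ttp[region, "mean"] + subj_dt +
      stats::rnorm(16) * preset$ttp_within_sd
    ttp <- pmin(pmax(ttp, 90), 0.92 * cyc)
    dysk <- numeric(16)
    if (length(preset$mi_segment_ids)) {
      ids <- preset$mi_segment_ids
      ttp[ids] <- pmax(ttp[ids], lobe_end + 60)
      amp <- preset$mi_dyskinesis_amp
      dysk[ids] <- pmax(amp + stats::rnorm(length(ids)) * 0.2 * amp, 0.5)
    }
    data.frame(segment_id = 1:16,
               level_index = segs$level_index,
               region = region,
               peak_ec_pct = as.numeric(peak),
               ttp_ms = as.numeric(ttp),
               dysk_amp_pct = dysk,
               stringsAsFactors = FALSE)
  })

  structure(list(preset = preset, params = params, seed = seed,
                 smooth_sigma_deg = 5, n_theta = 720L),
            class = "motion_model")
}

# Prescribed strain field (percent) over material angle for one level:
# piecewise-constant per-segment curves smoothed circularly (sigma 5 deg)
# so the stretch field is smooth across segment boundaries.
# Returns a matrix [n_theta + 1, length(times)]; row j is material angle
# theta0 = (j-1) * 2*pi/n_theta (last row duplicates the first).
strain_field <- function(motion, level_index, times) {
  p <- motion$preset
  nth <- motion$n_theta
  segs <- aha_segments()
  sel <- which(segs$level_index == level_index)
  th_deg <- (0:(nth - 1)) * 360 / nth
  seg_of <- integer(nth)
  for (s in sel) {
    inside <- ang_dist_deg(th_deg, (segs$theta_start[s] + segs$theta_end[s]) / 2) <
      (segs$theta_end[s] - segs$theta_start[s]) / 2 + 1e-9
    seg_of[inside] <- s
  }
  # curves per segment at this level
  curves <- matrix(0, length(times), length(sel))
  for (k in seq_along(sel)) {
    pr <- motion$params[sel[k], ]
    curves[, k] <- strain_timecourse(times, pr$peak_ec_pct, pr$ttp_ms,
                                     p$cycle_ms, pr$dysk_amp_pct)
  }
  E <- t(curves[, match(seg_of, sel), drop = FALSE])  # n_theta x n_times
  sigma_bins <- motion$smooth_sigma_deg * nth / 360
  E <- circ_smooth(E, sigma_bins)
  rbind(E, E[1, , drop = FALSE])
}

# Level deformation at one time: returns the angular map and stretch field
# needed for forward/inverse mapping.
level_deformation <- function(motion, level_index, t_ms) {
  make_defs(motion, level_index, t_ms)[[1]]
}

# Forward map material (r0, theta0) -> current (r, theta).
map_forward <- function(def, r0, th0) {
  th0 <- wrap_2pi(th0)
  g0 <- stats::approx(def$th0, def$g, xout = th0, rule = 2)$y
  th <- stats::approx(def$th0, def$theta, xout = th0, rule = 2)$y
  Rm0 <- stats::approx(def$th0, def$Rm, xout = th0, rule = 2)$y
  r2 <- (Rm0 * def$gbar)^2 + (r0^2 - Rm0^2) * def$gbar / g0
  list(r = sqrt(pmax(r2, 0)), theta = wrap_2pi(th))
}

# Inverse map current (r, theta) -> material (r0, theta0).  Points mapping
# inside the cavity return NA radius.
map_inverse <- function(def, r, th) {
  th <- wrap_2pi(th)
  th0 <- stats::approx(def$theta, def$th0, xout = th, rule = 2)$y
  g0 <- stats::approx(def$th0, def$g, xout = th0, rule = 2)$y
  Rm0 <- stats::approx(def$th0, def$Rm, xout = th0, rule = 2)$y
  r02 <- (r^2 - (Rm0 * def$gbar)^2) * g0 / def$gbar + Rm0^2
  r0 <- sqrt(pmax(r02, 0))
  r0[r02 < 0] <- NA_real_
  list(r0 = r0, theta0 = th0)
}

#' Prescribed mid-wall strain curve of a segment
#'
#' The motion model's ground truth for a segment: the sector average of the
#' (boundary-smoothed) mid-wall circumferential strain field, evaluated at
#' the requested times.  At segment centres this equals the analytic
#' time-course to numerical precision; averaged over the sector it is what
#' an ideal segment-ROI estimator would measure.
#'
#' @param motion a \code{motion_model}
#' @param segment_id segment id (1..16)
#' @param times times in ms
#' @return strain in percent at \code{times}
#' @export
prescribed_segment_curve <- function(motion, segment_id, times) {
  segs <- aha_segments()
  li <- segs$level_index[segment_id]
  nth <- motion$n_theta
  E <- strain_field(motion, li, times)[-(nth + 1), , drop = FALSE]
  th_deg <- (0:(nth - 1)) * 360 / nth
  mid <- (segs$theta_start[segment_id] + segs$theta_end[segment_id]) / 2
  half <- (segs$theta_end[segment_id] - segs$theta_start[segment_id]) / 2
  rows <- ang_dist_deg(th_deg, mid) < half + 1e-9
  colMeans(E[rows, , drop = FALSE])
}

# Ground-truth per-segment table (true peak and TTP from the sector-averaged
# prescribed curve on a 1 ms grid) plus true SD16 and global strain.
motion_ground_truth <- function(motion) {
  p <- motion$preset
  tt <- seq(0, p$cycle_ms - 1)
  segs <- aha_segments()
  nth <- motion$n_theta
  th_deg <- (0:(nth - 1)) * 360 / nth
  out <- motion$params[, c("segment_id", "level_index", "region")]
  peak <- numeric(16); ttp <- numeric(16)
  for (li in 1:3) {
    E <- strain_field(motion, li, tt)[-(nth + 1), , drop = FALSE]
    for (s in which(segs$level_index == li)) {
      mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
      half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
      cur <- colMeans(E[ang_dist_deg(th_deg, mid) < half + 1e-9, ,
                        drop = FALSE])
      i <- which.min(cur)
      peak[s] <- cur[i]
      ttp[s] <- tt[i]
    }
  }
  out$peak_ec_pct <- peak
  out$ttp_ms <- ttp
  list(segments = out,
       sd16_ms = stats::sd(ttp),
       global_peak_ec_pct = mean(peak))
}
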