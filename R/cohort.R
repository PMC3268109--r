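# Synthetic study and cohort assembly with ground-truth tables.

# True LV cavity volume curve (mL) from the motion model, closed form on
# the deformed geometry: per level, cavity area = 0.5 * int r_endo^2 dtheta
# evaluated in material coordinates.
truth_volume_curve <- function(motion, times) {
  p <- motion$preset
  nth <- motion$n_theta
  step <- p$geometry$slice_thickness_mm + p$geometry$slice_gap_mm
  V <- numeric(length(times))
  for (li in seq_len(p$geometry$n_levels)) {
    E <- strain_field(motion, li, times)[-(nth + 1), , drop = FALSE]
    Re <- p$geometry$endo_radius_mm[li]
    th0 <- (0:(nth - 1)) * 2 * pi / nth
    Rm <- Re + wall_thickness_ref(p, li, th0) / 2   # local mid-wall anchor
    g <- 1 + E / 100
    gbar <- colMeans(g)
    # r_endo(theta0)^2 = (Rm gbar)^2 + (Re^2 - Rm^2) gbar / g
    r2 <- (Re^2 - Rm^2) * sweep(1 / g, 2, gbar, "*") +
      outer(Rm^2, gbar^2)
    dth_dth0 <- sweep(g, 2, gbar, "/")
    area <- 0.5 * colMeans(r2 * dth_dth0) * 2 * pi     # mm^2
    V <- V + area * step / 1000                        # mL
  }
  V
}

#' Generate one synthetic study (all acquisitions plus ground truth)
#'
#' Bundles the four simulated acquisitions of one animal at one time-point:
#' the tagged short-axis series, the LGE volume, the endo/epi contour stack
#' and the electroanatomic point cloud, together with a ground-truth table
#' of per-segment true peak strain, true TTP and region label, and global
#' truths (SD16, global peak eC, enhanced fraction, EF).
#'
#' @param preset a \code{scenario_preset}
#' @param seed integer seed; identical (preset, seed) give identical studies
#' @param subject_id identifier stored in the outputs
#' @param stages which acquisitions to simulate; the motion model and
#'   ground truth are always built.  Every stage draws from its own seed
#'   stream, so skipping one never changes another.
#' @return object of class \code{synthetic_study}
#' @export
generate_study <- function(preset, seed = 1L, subject_id = 1L,
                           stages = c("tagged", "contours", "lge", "eam")) {
  motion <- build_motion(preset, seed = seed)
  tagged <- if ("tagged" %in% stages) render_tagged(motion, preset, seed = seed)
  contours <- if ("contours" %in% stages) generate_contours(motion)
  lge <- if ("lge" %in% stages) render_lge(preset, seed = seed)
  eam <- if ("eam" %in% stages) render_eam(preset, seed = seed)
  truth <- motion_ground_truth(motion)
  Vt <- truth_volume_curve(motion,
                           seq(0, preset$cycle_ms - preset$frame_interval_ms,
                               by = preset$frame_interval_ms))
  truth$edv_ml <- max(Vt)
  truth$esv_ml <- min(Vt)
  truth$ef_pct <- 100 * (truth$edv_ml - truth$esv_ml) / truth$edv_ml
  truth$lge_fraction <- lge$fraction_true
  truth$segments$subject <- subject_id
  structure(list(subject_id = subject_id, preset = preset, motion = motion,
                 tagged = tagged, contours = contours, lge = lge, eam = eam,
                 truth = truth, seed = seed),
            class = "synthetic_study")
}

#' Generate a cohort of synthetic studies
#'
#' Each subject gets independent subject-level parameter draws (region mean
#' offsets, timing offset, segment scatter) through a per-subject sub-seed
#' derived from the cohort seed, so the cohort is fully reproducible.
#'
#' @param preset a \code{scenario_preset}
#' @param n_subjects number of subjects (>= 1)
#' @param seed cohort master seed
#' @param stages acquisitions to simulate, see \code{\link{generate_study}}
#' @return list of \code{synthetic_study}, one per subject, with class
#'   \code{synthetic_cohort}
#' @export
generate_cohort <- function(preset, n_subjects = 6L, seed = 1L,
                            stages = c("tagged", "contours", "lge", "eam")) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  studies <- lapply(seq_len(n_subjects), function(i)
    generate_study(preset, seed = mix_seed(seed, 7000L + i),
                   subject_id = i, stages = stages))
  structure(studies, class = "synthetic_cohort")
}

#' Ground-truth segment table of a cohort
#' @param cohort a \code{synthetic_cohort}
#' @return data.frame of all subjects' true per-segment rows
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(st) st$truth$segments))
}
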