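# SPAMM-tagged short-axis image rendering from the analytic motion model.

# Deformations for one level at several times, sharing one strain-field
# evaluation.  The prescribed stretch g(theta0, t) is anchored at the LOCAL
# mid-wall radius Rm(theta0) = Re + w(theta0)/2 (w dips in the thinned
# infarct wedge), so the analytic time-course holds exactly where a
# mid-wall ROI measures it; the radial map preserves local wall area for
# any such anchor.
make_defs <- function(motion, level_index, times) {
  p <- motion$preset
  nth <- motion$n_theta
  th0 <- (0:nth) * 2 * pi / nth
  Eall <- strain_field(motion, level_index, times)
  Re <- p$geometry$endo_radius_mm[level_index]
  Rm <- Re + wall_thickness_ref(p, level_index, th0) / 2
  lapply(seq_along(times), function(k) {
    g <- 1 + Eall[, k] / 100
    gbar <- mean(g[-(nth + 1)])
    theta <- cumtrapz_u(g / gbar, 2 * pi / nth)
    theta <- theta * 2 * pi / theta[nth + 1]
    list(th0 = th0, g = g, gbar = gbar, theta = theta,
         Re = Re, Rm = Rm, rm_t = Rm * gbar, level_index = level_index)
  })
}

#' Render a SPAMM-tagged short-axis image series
#'
#' Simulates a 1-1 SPAMM grid: the tag pattern is the product over the two
#' tag directions of \code{1 - c * cos^2(k_i . p / 2)}, where \code{p} is
#' the reference (material) position of each pixel obtained from the inverse
#' motion map, and \code{k_i} are the tag wave-vectors (first spectral
#' harmonic, \code{|k| = 2*pi / tag spacing}).  Intensity is masked to the
#' deforming myocardial annulus and Gaussian noise is added.  Frame 1
#' (t = 0, the QRS trigger) has straight, grid-aligned tags.
#'
#' @param motion a \code{motion_model}
#' @param preset the \code{scenario_preset} the motion was built from
#' @param seed integer seed for the image noise
#' @return object of class \code{tagged_series}: list with \code{pixels}
#'   (array \code{[rows, cols, frames, slices]}), \code{pixel_spacing_mm},
#'   \code{frame_interval_ms}, \code{tag_spacing_mm}, \code{tag_directions}
#'   (2 x 2 matrix of unit wave-vector directions, rows), \code{times_ms}.
#' @export
render_tagged <- function(motion, preset = motion$preset, seed = 1L) {
  n <- preset$image_size
  dx <- preset$pixel_spacing_mm
  s <- preset$tag_spacing_mm
  if (2 * pi / s >= pi / dx)
    stop("tag spacing below the Nyquist limit of the pixel grid")
  nf <- as.integer(preset$cycle_ms / preset$frame_interval_ms)
  times <- (0:(nf - 1)) * preset$frame_interval_ms
  cc <- (n + 1) / 2
  x <- (col(matrix(0, n, n)) - cc) * dx
  y <- (cc - row(matrix(0, n, n))) * dx
  r <- sqrt(x^2 + y^2)
  th <- wrap_2pi(atan2(y, x))
  ctr <- preset$tag_contrast

  pix <- array(0, dim = c(n, n, nf, preset$geometry$n_levels))
  for (li in seq_len(preset$geometry$n_levels)) {
    defs <- make_defs(motion, li, times)
    for (k in seq_len(nf)) {
      inv <- map_inverse(defs[[k]], r, th)
      w <- wall_thickness_ref(preset, li, inv$theta0)
      mask <- !is.na(inv$r0) & inv$r0 >= defs[[k]]$Re &
        inv$r0 <= defs[[k]]$Re + w
      x0 <- inv$r0 * cos(inv$theta0)
      y0 <- inv$r0 * sin(inv$theta0)
      pat <- (1 - ctr * cos(pi * x0 / s)^2) * (1 - ctr * cos(pi * y0 / s)^2)
      img <- matrix(0, n, n)
      img[mask] <- pat[mask]
      pix[, , k, li] <- img
    }
  }
  if (preset$noise_sigma > 0) {
    pix <- pix + with_seed(mix_seed(seed, 202L),
                           array(stats::rnorm(length(pix),
                                              sd = preset$noise_sigma),
                                 dim = dim(pix)))
  }
  structure(list(
    pixels = pix,
    pixel_spacing_mm = dx,
    frame_interval_ms = preset$frame_interval_ms,
    tag_spacing_mm = s,
    tag_directions = rbind(c(1, 0), c(0, 1)),
    tag_contrast = ctr,
    times_ms = times,
    trigger = "frame 1 = QRS"
  ), class = "tagged_series")
}

#' Ground-truth endo/epi contour stack for a motion model
#'
#' Forward-maps the reference endocardial circle and (regionally thinned)
#' epicardial boundary of every slice through the motion model at each
#' frame.  A static crescent-shaped right-ventricular contour is attached
#' to the mid slice so the RV end-diastolic diameter is measurable.
#' Coordinates are mm, centred on the LV axis.
#'
#' @param motion a \code{motion_model}
#' @param n_vertices vertices per contour polygon
#' @return object of class \code{contour_stack}: data.frame with columns
#'   \code{slice}, \code{frame}, \code{surface} (endo/epi/rv),
#'   \code{vertex_index}, \code{x_mm}, \code{y_mm}; attributes
#'   \code{slice_step_mm} (thickness + gap), \code{frame_interval_ms},
#'   \code{times_ms}.
#' @export
generate_contours <- function(motion, n_vertices = 100L) {
  p <- motion$preset
  nf <- as.integer(p$cycle_ms / p$frame_interval_ms)
  times <- (0:(nf - 1)) * p$frame_interval_ms
  th0 <- (0:(n_vertices - 1)) * 2 * pi / n_vertices
  out <- vector("list", 3 * nf + 1)
  idx <- 1L
  for (li in seq_len(p$geometry$n_levels)) {
    defs <- make_defs(motion, li, times)
    Re <- p$geometry$endo_radius_mm[li]
    w <- wall_thickness_ref(p, li, th0)
    for (k in seq_len(nf)) {
      en <- map_forward(defs[[k]], rep(Re, n_vertices), th0)
      ep <- map_forward(defs[[k]], Re + w, th0)
      out[[idx]] <- data.frame(
        slice = li, frame = k,
        surface = rep(c("endo", "epi"), each = n_vertices),
        vertex_index = rep(seq_len(n_vertices), 2),
        x_mm = c(en$r * cos(en$theta), ep$r * cos(ep$theta)),
        y_mm = c(en$r * sin(en$theta), ep$r * sin(ep$theta)),
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  # static RV crescent at the mid slice, every frame
  Rp_mid <- p$geometry$endo_radius_mm[2] + p$geometry$wall_mm[2]
  rv <- rv_crescent(Rp_mid, p$rvedd_mm, n_vertices)
  out[[idx]] <- do.call(rbind, lapply(seq_len(nf), function(k) {
    data.frame(slice = 2L, frame = k, surface = "rv",
               vertex_index = seq_len(nrow(rv)),
               x_mm = rv$x, y_mm = rv$y, stringsAsFactors = FALSE)
  }))
  stack <- do.call(rbind, out)
  structure(stack,
            slice_step_mm = p$geometry$slice_thickness_mm +
              p$geometry$slice_gap_mm,
            frame_interval_ms = p$frame_interval_ms,
            times_ms = times,
            class = c("contour_stack", "data.frame"))
}

# Crescent polygon for the RV cavity: inner boundary hugging the LV epi
# (septal side, 110..250 deg), outer boundary bulging by rvedd_mm at the
# septum centre (180 deg).
rv_crescent <- function(lv_epi_radius, rvedd_mm, n_vertices = 100L) {
  half <- n_vertices %/% 2
  th_in <- seq(110, 250, length.out = half) * pi / 180
  th_out <- rev(th_in)
  r_in <- rep(lv_epi_radius + 0.8, half)
  bump <- rvedd_mm * cos(pi * (th_out * 180 / pi - 180) / 140)^2
  r_out <- lv_epi_radius + 0.8 + bump
  data.frame(x = c(r_in * cos(th_in), r_out * cos(th_out)),
             y = c(r_in * sin(th_in), r_out * sin(th_out)))
}
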