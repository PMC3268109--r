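# Electroanatomic map synthesis: eikonal activation on the mid-wall
# surface with zone-dependent conduction speeds, sampled as a point cloud.

#' First-order fast-sweeping eikonal solver on a 2D grid
#'
#' Solves \code{|grad T| = 1 / speed} with the Godunov upwind discretization
#' and Gauss-Seidel sweeps in alternating orders.  Grid spacing may differ
#' per axis and the column spacing may vary by column (used for surfaces of
#' revolution where the circumferential metric shrinks towards the apex).
#' The first axis can be periodic.
#'
#' @param speed matrix of propagation speeds (distance units per ms), >0.
#' @param t0 matrix of initial times: \code{Inf} everywhere except seeded
#'   nodes (the source region), which hold their activation times.
#' @param hx spacing along the first axis: scalar or per-column vector.
#' @param hy spacing along the second axis (scalar).
#' @param periodic_x wrap the first axis (circumferential direction)?
#' @param tol convergence tolerance (ms); sweeping stops when no node
#'   changes by more than this.
#' @param max_pass maximum passes (each pass = 4 sweep orders).
#' @return matrix of activation times, same shape as \code{speed}.
#' @export
eikonal_solve <- function(speed, t0, hx, hy, periodic_x = FALSE,
                          tol = 1e-4, max_pass = 20L) {
  if (any(speed <= 0)) stop("zone speeds must be positive")
  nx <- nrow(speed); ny <- ncol(speed)
  if (length(hx) == 1L) hx <- rep(hx, ny)
  TT <- t0
  f <- 1 / speed
  orders_x <- list(1:nx, nx:1)
  orders_y <- list(1:ny, ny:1)
  for (pass in seq_len(max_pass)) {
    delta <- 0
    for (ox in 1:2) for (oy in 1:2) {
      for (j in orders_y[[oy]]) {
        hxa <- hx[j]
        for (i in orders_x[[ox]]) {
          im <- if (i > 1) i - 1 else if (periodic_x) nx else NA
          ip <- if (i < nx) i + 1 else if (periodic_x) 1L else NA
          a <- Inf
          if (!is.na(im)) a <- TT[im, j]
          if (!is.na(ip)) a <- min(a, TT[ip, j])
          b <- Inf
          if (j > 1) b <- TT[i, j - 1]
          if (j < ny) b <- min(b, TT[i, j + 1])
          if (!is.finite(a) && !is.finite(b)) next
          fij <- f[i, j]
          # Godunov update with anisotropic spacing
          if (!is.finite(b) || a + fij * hxa <= b) {
            cand <- a + fij * hxa
          } else if (!is.finite(a) || b + fij * hy <= a) {
            cand <- b + fij * hy
          } else {
            # both neighbours active: solve
            # ((T-a)/hxa)^2 + ((T-b)/hy)^2 = fij^2
            wa <- 1 / hxa^2; wb <- 1 / hy^2
            A <- wa + wb
            B <- -2 * (a * wa + b * wb)
            C <- a^2 * wa + b^2 * wb - fij^2
            disc <- B^2 - 4 * A * C
            cand <- if (disc >= 0) (-B + sqrt(disc)) / (2 * A)
                    else min(a + fij * hxa, b + fij * hy)
            if (cand < max(a, b))
              cand <- min(a + fij * hxa, b + fij * hy)
          }
          if (cand < TT[i, j] - tol) {
            delta <- max(delta, TT[i, j] - cand)
            TT[i, j] <- cand
          }
        }
      }
    }
    if (delta <= tol) break
  }
  TT
}

# Mid-wall surface of revolution for a preset: radius profile r(z) from the
# per-level mid-wall radii, tapering to ~1 mm over a 10 mm apical cap.
# The long-axis direction is parameterized by arc length s so the solver
# grid has uniform column spacing; z(s) keeps the geometric coordinate.
eam_surface <- function(preset, n_theta = 120L, n_z = 56L) {
  g <- preset$geometry
  step <- g$slice_thickness_mm + g$slice_gap_mm
  z_lv <- 3 * step                       # base..apical extent covered by slices
  z_cap <- 10
  Rm <- g$endo_radius_mm + g$wall_mm / 2
  zf <- seq(0, z_lv + z_cap, length.out = 2000)
  z_knots <- c(0, step * (1:3) - step / 2, z_lv)
  r_knots <- c(Rm[1], Rm, Rm[3] * 0.95)
  rf <- stats::approx(z_knots, r_knots, xout = pmin(zf, z_lv), rule = 2)$y
  cap <- zf > z_lv
  rf[cap] <- 1 + (Rm[3] * 0.95 - 1) * cos(pi / 2 * (zf[cap] - z_lv) / z_cap)
  dz <- zf[2] - zf[1]
  drdz <- c(diff(rf) / dz, 0)
  sf <- cumtrapz_u(sqrt(1 + drdz^2), dz)  # arc length along the wall
  s_grid <- seq(0, max(sf), length.out = n_z)
  zs <- stats::approx(sf, zf, xout = s_grid, rule = 2)$y
  rz <- stats::approx(zf, rf, xout = zs, rule = 2)$y
  th <- (0:(n_theta - 1)) * 2 * pi / n_theta
  list(theta = th, s = s_grid, z = zs, r = rz,
       z_levels = rbind(c(0, step), c(step, 2 * step),
                        c(2 * step, z_lv + z_cap)),
       z_lv = z_lv)
}

# Zone label grid over (theta, z): infarct inside the MI wedge of the mid
# and apical levels (the apical cap inherits the apical wedge), border in a
# margin around it, remote elsewhere.
eam_zone_grid <- function(preset, surf) {
  nth <- length(surf$theta); nz <- length(surf$z)
  zone <- matrix("remote", nth, nz)
  if (!length(preset$mi_segment_ids)) return(zone)
  e <- preset$eam
  th <- surf$theta
  for (j in seq_len(nz)) {
    zj <- surf$z[j]
    li <- if (zj < surf$z_levels[2, 1]) 1L
          else if (zj < surf$z_levels[3, 1]) 2L else 3L
    ind_inf <- mi_wedge_indicator(preset, li, th, taper_deg = 1e-6) > 0.5
    # border margin: angular widening plus axial reach across level bounds
    ind_bord <- mi_wedge_indicator(preset, li, th, taper_deg = 1e-6,
                                   extend_deg = e$border_width_deg) > 0.5
    for (lj in 1:3) {
      if (lj == li) next
      gap <- max(surf$z_levels[lj, 1] - zj, zj - surf$z_levels[lj, 2], 0)
      if (gap <= e$border_width_mm) {
        ind_bord <- ind_bord |
          mi_wedge_indicator(preset, lj, th, taper_deg = 1e-6,
                             extend_deg = e$border_width_deg) > 0.5
      }
    }
    zone[ind_bord, j] <- "border"
    zone[ind_inf, j] <- "infarct"
  }
  zone
}

#' Render a synthetic electroanatomic point cloud
#'
#' Solves the eikonal activation-time equation on the mid-wall surface of
#' revolution with zone conduction speeds (remote / border / infarct) and a
#' point source in the basal anterior septum, then samples \code{n_points}
#' catheter points uniformly over the surface.  Each point carries its 3D
#' position, local activation time (ms, earliest point = 0, Gaussian
#' measurement jitter), bipolar voltage (zone-specific lognormal: infarct
#' below the 0.5 mV scar cutoff, border intermediate, remote above) and the
#' ground-truth zone label.
#'
#' @param preset a \code{scenario_preset}
#' @param seed integer seed
#' @param n_points number of mapped points (default from preset)
#' @param lat_noise_ms activation-time jitter SD; default from preset,
#'   0 gives noise-free times
#' @param voltage_sdlog lognormal sdlog of voltages; 0 gives each zone its
#'   median voltage exactly
#' @return object of class \code{eam_cloud}: data.frame with columns
#'   \code{point_id}, \code{x_mm}, \code{y_mm}, \code{z_mm}, \code{lat_ms},
#'   \code{voltage_mv}, \code{zone_truth}.
#' @export
render_eam <- function(preset, seed = 1L,
                       n_points = preset$eam$n_points,
                       lat_noise_ms = preset$eam$lat_noise_ms,
                       voltage_sdlog = preset$eam$voltage_sdlog) {
  validate_preset(preset)
  surf <- eam_surface(preset)
  zone <- eam_zone_grid(preset, surf)
  speed_cms <- preset$zone_speed
  sp <- matrix(speed_cms["remote"] / 100, nrow(zone), ncol(zone))  # mm/ms
  sp[zone == "border"] <- speed_cms["border"] / 100
  sp[zone == "infarct"] <- speed_cms["infarct"] / 100

  # source: basal anterior septum
  src_th <- 150 * pi / 180
  src_z <- 5
  i0 <- which.min(ang_dist_deg(surf$theta * 180 / pi, src_th * 180 / pi))
  j0 <- which.min(abs(surf$z - src_z))
  ds <- surf$s[2] - surf$s[1]
  hx <- surf$r * (2 * pi / length(surf$theta))
  # exact activation times on a small disk around the source (local metric,
  # uniform local speed): first-order sweeping errors otherwise originate
  # at the point source and propagate outward
  t0 <- source_disk_times(nrow(sp), ncol(sp), i0, j0, hx[j0], ds,
                          sp[i0, j0], radius_cells = 6, periodic_x = TRUE)
  TT <- eikonal_solve(sp, t0, hx = pmax(hx, 1e-3), hy = ds,
                      periodic_x = TRUE)

  with_seed(mix_seed(seed, 404L), {
    # area-uniform sampling: arc-length density proportional to the local
    # circumference
    dens <- surf$r / sum(surf$r)
    js <- sample(seq_along(surf$s), n_points, replace = TRUE, prob = dens)
    sq <- surf$s[js] + stats::runif(n_points, -ds / 2, ds / 2)
    sq <- pmin(pmax(sq, 0), max(surf$s))
    thq <- stats::runif(n_points, 0, 2 * pi)
    zq <- stats::approx(surf$s, surf$z, xout = sq, rule = 2)$y
    rq <- stats::approx(surf$s, surf$r, xout = sq, rule = 2)$y
    lat <- bilinear_periodic(TT, surf$theta, surf$s, thq, sq)
    zq_lab <- zone[cbind(
      round(thq / (2 * pi / length(surf$theta))) %% length(surf$theta) + 1,
      pmin(pmax(round((sq - surf$s[1]) / ds) + 1, 1), length(surf$s)))]
    if (lat_noise_ms > 0)
      lat <- lat + stats::rnorm(n_points, sd = lat_noise_ms)
    lat <- lat - min(lat)
    med <- preset$eam$voltage_median[zq_lab]
    volt <- med * exp(stats::rnorm(n_points, sd = voltage_sdlog))
    structure(data.frame(
      point_id = seq_len(n_points),
      x_mm = rq * cos(thq), y_mm = rq * sin(thq), z_mm = zq,
      lat_ms = lat, voltage_mv = as.numeric(volt),
      zone_truth = zq_lab, stringsAsFactors = FALSE
    ), class = c("eam_cloud", "data.frame"),
       zone_speed = speed_cms, source = c(theta = src_th, z = src_z))
  })
}

#' Exact-time initialization disk for a point source
#'
#' Seeds the eikonal solver with closed-form times \code{distance / speed}
#' on a small disk around the source node, assuming a locally flat metric
#' and uniform local speed.  Everything else is \code{Inf}.
#'
#' @param nx,ny grid size
#' @param i0,j0 source node
#' @param hx,hy local grid spacings (distance units)
#' @param speed local propagation speed
#' @param radius_cells disk radius in cells
#' @param periodic_x wrap the first axis?
#' @return matrix of initial times
#' @export
source_disk_times <- function(nx, ny, i0, j0, hx, hy, speed,
                              radius_cells = 5, periodic_x = FALSE) {
  t0 <- matrix(Inf, nx, ny)
  for (di in -radius_cells:radius_cells) {
    i <- i0 + di
    if (periodic_x) i <- (i - 1) %% nx + 1
    if (i < 1 || i > nx) next
    for (dj in -radius_cells:radius_cells) {
      j <- j0 + dj
      if (j < 1 || j > ny) next
      if (di^2 + dj^2 > radius_cells^2) next
      t0[i, j] <- sqrt((di * hx)^2 + (dj * hy)^2) / speed
    }
  }
  t0
}

# Bilinear interpolation on a (periodic theta) x z grid.
bilinear_periodic <- function(M, theta, z, thq, zq) {
  nth <- length(theta); nz <- length(z)
  dth <- theta[2] - theta[1]; dz <- z[2] - z[1]
  ti <- (thq %% (2 * pi)) / dth
  i0 <- floor(ti); fi <- ti - i0
  i1 <- (i0 %% nth) + 1; i2 <- ((i0 + 1) %% nth) + 1
  zi <- pmin(pmax((zq - z[1]) / dz, 0), nz - 1 - 1e-9)
  j0 <- floor(zi); fj <- zi - j0
  j1 <- j0 + 1; j2 <- pmin(j1 + 1, nz)
  M[cbind(i1, j1)] * (1 - fi) * (1 - fj) +
    M[cbind(i2, j1)] * fi * (1 - fj) +
    M[cbind(i1, j2)] * (1 - fi) * fj +
    M[cbind(i2, j2)] * fi * fj
}
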