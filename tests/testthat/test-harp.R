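# HARP estimation oracles.

make_series <- function(imgs, s = 6, dx = 1.25) {
  n <- nrow(imgs[[1]])
  pix <- array(0, c(n, n, length(imgs), 1))
  for (k in seq_along(imgs)) pix[, , k, 1] <- imgs[[k]]
  structure(list(pixels = pix, pixel_spacing_mm = dx,
                 frame_interval_ms = 33, tag_spacing_mm = s,
                 tag_directions = rbind(c(1, 0), c(0, 1)),
                 tag_contrast = 0.8,
                 times_ms = (seq_along(imgs) - 1) * 33,
                 trigger = "frame 1 = QRS"),
            class = "tagged_series")
}

grid_pattern <- function(n = 96, dx = 1.25, s = 6, shift = c(0, 0)) {
  cc <- (n + 1) / 2
  x <- (col(matrix(0, n, n)) - cc) * dx - shift[1]
  y <- (cc - row(matrix(0, n, n))) * dx - shift[2]
  (1 - 0.8 * cos(pi * x / s)^2) * (1 - 0.8 * cos(pi * y / s)^2)
}

test_that("frame-0 harmonic phase is a plane with gradient k", {
  ser <- make_series(list(grid_pattern()))
  ph <- extract_harmonic_phase(ser, 1L)
  g <- wrapped_gradient(ph$phase[, , 1], ser$pixel_spacing_mm)
  ctr <- 30:66
  expect_equal(mean(g$gx[ctr, ctr]), 2 * pi / 6, tolerance = 0.01)
  expect_lt(max(abs(g$gy[ctr, ctr])), 0.02)
})

test_that("pure translation shifts the phase by k . d", {
  d <- c(1.7, 0)
  ser <- make_series(list(grid_pattern(), grid_pattern(shift = d)))
  ph <- extract_harmonic_phase(ser, 1L)
  ctr <- 30:66
  dphi <- dyssync:::wrap_pi(ph$phase[ctr, ctr, 2] - ph$phase[ctr, ctr, 1])
  # phase encodes the reference position p = x - d, so a forward motion by
  # d lowers the phase by k . d (Fourier shift theorem)
  expect_equal(mean(dphi), -2 * pi / 6 * d[1], tolerance = 0.01)
})

test_that("degenerate inputs are flagged", {
  ser <- make_series(list(matrix(0, 96, 96)))
  ph <- extract_harmonic_phase(ser, 1L)
  expect_lt(max(ph$magnitude), 1e-10)    # all-zero magnitude flag
  ser2 <- make_series(list(grid_pattern()), s = 80)
  expect_error(extract_harmonic_phase(ser2, 1L), "tag spacing|4 tag")
})

test_that("wrapped gradients cross unwrap seams cleanly", {
  n <- 64
  kx <- 1.9; ky <- -0.7                  # |k| < pi per pixel
  plane <- dyssync:::wrap_pi(outer(seq_len(n), seq_len(n),
                                   function(i, j) -ky * i + kx * j))
  g <- wrapped_gradient(plane, 1)
  expect_equal(max(abs(g$gx - kx)), 0, tolerance = 1e-9)
  expect_equal(max(abs(g$gy - ky)), 0, tolerance = 1e-9)
  # constant phase -> zero gradient; adding a constant changes nothing
  g0 <- wrapped_gradient(matrix(1.2, n, n), 1)
  expect_equal(max(abs(g0$gx)), 0)
  g1 <- wrapped_gradient(plane, 1)
  g2 <- wrapped_gradient(dyssync:::wrap_pi(plane + 0.8), 1)
  expect_equal(g1$gx, g2$gx, tolerance = 1e-9)
})

test_that("strain maps are null under identity and rigid rotation", {
  fx <- uniform_study()
  ph1 <- extract_harmonic_phase(fx$tagged, 1L, slice = 2)
  ph2 <- extract_harmonic_phase(fx$tagged, 2L, slice = 2)
  rois <- segment_rois(fx$geometry, 2, 1)
  sm <- strain_from_phase(ph1, ph2, 1, mask = rois$midwall,
                          center = rois$center)
  expect_lt(abs(mean(sm$ec_pct, na.rm = TRUE)), 0.5)

  # rigid rotation by 5 degrees has unit stretch everywhere
  n <- 96; dx <- 1.25; cc <- (n + 1) / 2; a <- 5 * pi / 180
  x <- (col(matrix(0, n, n)) - cc) * dx
  y <- (cc - row(matrix(0, n, n))) * dx
  x0 <- cos(a) * x + sin(a) * y
  y0 <- -sin(a) * x + cos(a) * y
  rot <- (1 - 0.8 * cos(pi * x0 / 6)^2) * (1 - 0.8 * cos(pi * y0 / 6)^2)
  ser <- make_series(list(grid_pattern(), rot))
  p1 <- extract_harmonic_phase(ser, 1L)
  p2 <- extract_harmonic_phase(ser, 2L)
  ring <- sqrt(x^2 + y^2) > 15 & sqrt(x^2 + y^2) < 30
  smr <- strain_from_phase(p1, p2, 2, mask = ring)
  expect_lt(abs(mean(smr$ec_pct, na.rm = TRUE)), 1)

  # parallel wave-vectors are rejected
  pp <- p1; pp$k_mm <- p1$k_mm
  expect_error(strain_from_phase(p1, pp, 1), "parallel")
})

test_that("oracle equivalence: prescribed peaks recovered within 1.5 strain points", {
  for (peak in c(-30, -20, -10, -5)) {
    fx <- uniform_study(peak = peak)
    cur <- segment_curves(fx$tagged, fx$geometry, smooth_time = FALSE)
    mech <- mechanics_summary(cur)
    expect_lt(max(abs(mech$peak_ec_pct - peak)), 1.5,
              label = sprintf("peak %g", peak))
  }
  # positive (dyskinetic) prescribed strain: compare the full curve
  p <- make_preset("pre_mi"); p$noise_sigma <- 0
  m <- build_motion(p, 13)
  m$params$peak_ec_pct <- -0.51          # negligible trough
  m$params$ttp_ms <- 450
  m$params$dysk_amp_pct <- 10            # +10% early stretch
  tg <- render_tagged(m, p, seed = 13)
  geo <- build_segments(generate_contours(m), p$image_size,
                        p$pixel_spacing_mm)
  cur <- segment_curves(tg, geo, smooth_time = FALSE)
  for (s in c(2, 9, 15)) {
    est <- cur$ec_pct[cur$segment_id == s]
    tru <- prescribed_segment_curve(m, s, tg$times_ms)
    expect_lt(max(abs(est - tru)), 1.5)
  }
})

test_that("estimated peak strain decreases strictly with prescribed shortening", {
  peaks <- c(-5, -10, -15, -20, -25)
  est <- vapply(peaks, function(pk) {
    fx <- uniform_study(peak = pk)
    mech <- mechanics_summary(segment_curves(fx$tagged, fx$geometry))
    attr(mech, "global_peak_ec_pct")
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("estimation stays unbiased at the nominal image noise", {
  # 50 noise realizations of one motion; segment-level bias < 2 points
  fx0 <- uniform_study(peak = -27, ttp = 300, noise = 0, seed = 21)
  p <- fx0$preset
  est <- matrix(NA_real_, 50, 16)
  for (r in 1:50) {
    tg <- fx0$tagged
    noise <- dyssync:::with_seed(dyssync:::mix_seed(1000L + r, 1L),
      array(stats::rnorm(length(tg$pixels), sd = 0.05), dim = dim(tg$pixels)))
    tg$pixels <- tg$pixels + noise
    mech <- mechanics_summary(segment_curves(tg, fx0$geometry))
    est[r, ] <- mech$peak_ec_pct
  }
  bias <- colMeans(est) - (-27)
  expect_lt(max(abs(bias)), 2)
})

test_that("strain calibrates to zero at the QRS frame", {
  fx <- analyzed_cohort("pre_mi")
  for (a in fx$analysis$per_subject[1:2]) {
    f0 <- a$curves$ec_pct[a$curves$t_ms == 0]
    expect_lt(max(abs(f0)), 0.5)
  }
})

test_that("segment curves equal a brute-force masked-pixel average", {
  fx <- uniform_study()
  geo <- fx$geometry
  masks <- array(FALSE, c(96, 96, 20))
  for (t in 1:20) masks[, , t] <- segment_rois(geo, 1, t)$myocardium
  phs <- dyssync:::harp_phases_slice(fx$tagged, 1, masks)
  t <- 8
  segs <- aha_segments()
  roi_mean <- function(t, s) {
    rois <- segment_rois(geo, 1, t)
    sm <- strain_from_phase(phs[[1]], phs[[2]], t, mask = rois$myocardium,
                            center = rois$center)
    core <- dyssync:::sector_core_mask(rois, segs, 1:6, 6, 96, 1.25)
    roi <- rois$midwall & rois$sector == s & core[[as.character(s)]]
    100 * (1 / mean(sm$stretch_inv[roi], na.rm = TRUE) - 1)
  }
  cur <- segment_curves(fx$tagged, fx$geometry, smooth_time = FALSE)
  for (s in c(1, 4)) {
    raw <- roi_mean(t, s)
    ref <- roi_mean(1, s)                # frame-1 reference calibration
    oracle <- 100 * ((1 + raw / 100) / (1 + ref / 100) - 1)
    got <- cur$ec_pct[cur$segment_id == s & cur$t_ms == fx$tagged$times_ms[t]]
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})
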