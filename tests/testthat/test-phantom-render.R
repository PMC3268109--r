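# Rendering oracles: tagged series, LGE volumes, cohort plumbing.

test_that("frame 0 tags are straight with spectral peaks at the tag wave-vectors", {
  fx <- uniform_study()
  img <- fx$tagged$pixels[, , 1, 2]
  n <- nrow(img)
  F <- Mod(stats::fft(img))
  # expected harmonic index: n*dx/s cycles across the field of view
  k_bin <- n * fx$preset$pixel_spacing_mm / fx$preset$tag_spacing_mm
  # along each frequency axis, the spectral maximum in the window around
  # the tag frequency sits within one bin of it
  axis_profile <- F[1, ]                  # row frequency 0, col axis
  win <- (k_bin - 5):(k_bin + 5)
  expect_lt(abs(win[which.max(axis_profile[win + 1])] - k_bin), 1 + 1e-9)
  axis_profile2 <- F[, 1]
  expect_lt(abs(win[which.max(axis_profile2[win + 1])] - k_bin), 1 + 1e-9)
  # and it dominates its off-peak surroundings
  expect_gt(F[1, k_bin + 1], 3 * F[1, k_bin + 7])
})

test_that("zero motion renders identical frames up to noise", {
  p <- make_preset("pre_mi")
  p$noise_sigma <- 0
  m <- build_motion(p, 2)
  m$params$peak_ec_pct <- 0
  m$params$dysk_amp_pct <- 0
  # amplitude 0 makes the time-course identically zero
  tg <- render_tagged(m, p, seed = 2)
  expect_equal(tg$pixels[, , 11, 1], tg$pixels[, , 1, 1], tolerance = 1e-9)
})

test_that("uniform shortening contracts the rendered tag spacing accordingly", {
  # noise-free 10% uniform shortening; geometric oracle: tag-line minima
  # along a mid-wall row move 10% closer circumferentially
  fx <- uniform_study(peak = -10, ttp = 300)
  n <- fx$preset$image_size; dx <- fx$preset$pixel_spacing_mm
  f_peak <- which.min(abs(fx$tagged$times_ms - 300))
  def <- dyssync:::level_deformation(fx$motion, 2,
                                     fx$tagged$times_ms[f_peak])
  r_mid <- mean(def$Rm) * def$gbar       # deformed mid-wall radius
  cc <- (n + 1) / 2
  # sample intensity along the mid-wall circle near the top of the slice
  # (theta ~ 90 deg), where the circumferential direction is ~x
  th <- seq(55, 125, by = 0.2) * pi / 180
  xs <- r_mid * cos(th); ys <- r_mid * sin(th)
  img <- fx$tagged$pixels[, , f_peak, 2]
  # bilinear sampling along the mid-wall arc
  ci <- cc + xs / dx; ri <- cc - ys / dx
  r0 <- floor(ri); c0 <- floor(ci); fr <- ri - r0; fc <- ci - c0
  val <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  arc <- r_mid * (th - min(th))          # arc length coordinate
  sm <- stats::filter(val, rep(1 / 7, 7))
  keep <- !is.na(sm)
  arc <- arc[keep]; sm <- sm[keep]
  ismin <- which(diff(sign(diff(sm))) > 0) + 1
  ismin <- ismin[sm[ismin] < stats::median(sm)]
  spacing <- stats::median(diff(arc[ismin]))
  expect_equal(spacing, 6 * 0.9, tolerance = 0.1)
})

test_that("tag spacing below the pixel Nyquist limit is rejected", {
  p <- make_preset("pre_mi")
  m <- build_motion(p, 1)
  p$tag_spacing_mm <- 2 * p$pixel_spacing_mm * 0.9
  expect_error(render_tagged(m, p), "Nyquist")
})

test_that("LGE volumes meet their enhancement target with a clean margin", {
  p <- make_preset("early_post_mi")
  lv <- render_lge(p, seed = 3)
  expect_lt(abs(lv$fraction_true - p$lge_fraction_target), 0.01)
  expect_true(all(lv$enhanced_truth[lv$enhanced_truth] &
                    lv$myo_mask[lv$enhanced_truth]))  # enh subset of myo
  ct <- p$lge_contrast
  expect_gt(ct$mu_enhanced, ct$mu_remote + 5 * ct$sigma)

  # zero target: empty mask
  q <- make_preset("pre_mi")
  lv0 <- render_lge(q, seed = 1)
  expect_equal(sum(lv0$enhanced_truth), 0)

  # unreachable target errors with the achievable range
  bad <- p; bad$lge_fraction_target <- 0.9
  expect_error(render_lge(bad, seed = 1), "achievable range")
})

test_that("ground-truth LGE fraction matches a counting quantification at the true threshold", {
  p <- make_preset("early_post_mi")
  lv <- render_lge(p, seed = 4)
  thr_true <- (p$lge_contrast$mu_remote + p$lge_contrast$mu_enhanced) / 2
  counted <- sum(lv$myo_mask & lv$intensity > thr_true) / sum(lv$myo_mask)
  expect_equal(counted, lv$fraction_true, tolerance = 0.005)
})

test_that("cohorts are deterministic and carry full ground truth", {
  p <- make_preset("pre_mi")
  c1 <- generate_cohort(p, 2, seed = 5, stages = "contours")
  c2 <- generate_cohort(p, 2, seed = 5, stages = "contours")
  expect_identical(cohort_truth_table(c1), cohort_truth_table(c2))
  expect_error(generate_cohort(p, 0), "n_subjects")

  tt <- cohort_truth_table(analyzed_cohort("pre_mi")$cohort)
  expect_equal(nrow(tt), 96)             # 6 subjects x 16 segments

  # law of large numbers on the drawn peaks (200 subjects)
  p2 <- make_preset("pre_mi")
  peaks <- vapply(1:200, function(s)
    mean(build_motion(p2, s)$params$peak_ec_pct), numeric(1))
  expect_lt(abs(mean(peaks) - p2$region_peak_ec["normal", "mean"]), 0.5)
})
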