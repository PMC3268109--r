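test_that("circular contours give equal-area sectors that partition the wall", {
  fx <- uniform_study()
  geo <- fx$geometry
  segs <- aha_segments()
  th_grid <- (0:359) * pi / 180
  for (sl in 1:3) {
    rois <- segment_rois(geo, sl, 1)
    ids <- segs$segment_id[segs$level_index == sl]
    # geometric sector areas from the contour radius profiles (exact for
    # circular contours): equal per degree within 2%
    area_density <- (rois$epi_r^2 - rois$endo_r^2) / 2
    sector_area <- vapply(ids, function(s) {
      mid <- (segs$theta_start[s] + segs$theta_end[s]) / 2
      half <- (segs$theta_end[s] - segs$theta_start[s]) / 2
      sel <- dyssync:::ang_dist_deg(th_grid * 180 / pi, mid) < half
      mean(area_density[sel])
    }, numeric(1))
    expect_lt(diff(range(sector_area)) / mean(sector_area), 0.02)
    # rasterized pixel counts per degree agree within pixelation noise
    counts <- vapply(ids, function(s) sum(rois$sector == s), numeric(1))
    widths <- segs$theta_end[ids] - segs$theta_start[ids]
    per_deg <- counts / widths
    expect_lt(diff(range(per_deg)) / mean(per_deg), 0.10)
    # partition: every myocardial pixel belongs to exactly one segment
    expect_equal(sum(rois$sector > 0), sum(rois$myocardium))
  }
})

test_that("pixel sector assignment matches the generator's material sectors", {
  fx <- uniform_study()
  segs <- aha_segments()
  f <- which.min(abs(fx$tagged$times_ms - 300))
  def <- dyssync:::level_deformation(fx$motion, 2, fx$tagged$times_ms[f])
  rois <- segment_rois(fx$geometry, 2, f)
  dx <- fx$preset$pixel_spacing_mm; cc <- (96 + 1) / 2
  for (s in c(7, 9, 12)) {
    th0 <- (segs$theta_start[s] + segs$theta_end[s]) / 2 * pi / 180
    fw <- dyssync:::map_forward(def, mean(def$Rm), th0)
    px <- round(cc + fw$r * cos(fw$theta) / dx)
    py <- round(cc - fw$r * sin(fw$theta) / dx)
    expect_equal(rois$sector[py, px], s)
  }
})

test_that("crossing contours are rejected", {
  fx <- uniform_study()
  bad <- fx$contours
  sw <- bad$surface == "endo" & bad$slice == 1
  se <- bad$surface == "epi" & bad$slice == 1
  tmp <- bad[sw, c("x_mm", "y_mm")]
  bad[sw, c("x_mm", "y_mm")] <- bad[se, c("x_mm", "y_mm")]
  bad[se, c("x_mm", "y_mm")] <- tmp
  expect_error(build_segments(bad), "crossing")
})

test_that("LGE quantification matches counting oracles", {
  toy <- toy_lge_volume(200, 40)
  # counting oracle with the true threshold, no statistics involved
  expect_equal(100 * sum(toy$myo_mask & toy$intensity > 5) /
                 sum(toy$myo_mask), 20)

  p <- make_preset("early_post_mi")
  lv <- render_lge(p, seed = 6)
  q <- quantify_lge(lv)
  expect_equal(q$global_pct, 100 * lv$fraction_true, tolerance = 0.5)
  # global percent equals the volume-weighted mean of segment fractions
  st <- q$segment_table
  expect_equal(sum(st$lge_fraction * st$n_voxels) / sum(st$n_voxels) * 100,
               q$global_pct, tolerance = 0.5)

  lv0 <- render_lge(make_preset("pre_mi"), seed = 1)
  q0 <- quantify_lge(lv0)
  expect_equal(q0$global_pct, 0, tolerance = 0.05)
  expect_true(all(q0$segment_table$lge_fraction < 0.005))
})

test_that("transmurality reads full, partial and phantom walls correctly", {
  # constructed annulus: enhancement over half the wall depth
  n <- 64
  cc <- (n + 1) / 2
  x <- (col(matrix(0, n, n)) - cc); y <- (cc - row(matrix(0, n, n)))
  r <- sqrt(x^2 + y^2)
  myo <- array(r >= 14 & r <= 24, c(n, n, 1))
  half <- array(r >= 14 & r <= 19, c(n, n, 1)) & myo
  vol <- structure(list(intensity = array(myo + 9 * half, c(n, n, 1)),
                        myo_mask = myo, enhanced_truth = half,
                        voxel_mm = c(1, 1, 5), slice_level = 1L,
                        fraction_true = sum(half) / sum(myo),
                        extend_deg = 0, preset_name = "toy"),
                   class = "lge_volume")
  tr <- transmurality(vol, enhanced = half)
  b <- tr[tr$segment_id %in% 1:6, ]
  expect_equal(mean(b$transmurality), 0.5, tolerance = 0.05)
  expect_true(all(!b$transmural))

  full <- myo
  trf <- transmurality(vol, enhanced = full)
  expect_equal(trf$transmurality[1:6], rep(1, 6), tolerance = 1e-9)
  expect_true(all(trf$transmural[1:6]))

  # phantom: generator transmurality 0.95 recovered within 0.03
  p <- make_preset("early_post_mi")
  lv <- render_lge(p, seed = 7)
  q <- quantify_lge(lv)
  tp <- transmurality(lv, q$enhanced)
  mi <- tp$transmurality[p$mi_segment_ids]
  expect_lt(max(abs(mi - p$transmurality)), 0.03 + 0.02)
  expect_true(all(tp$transmural[p$mi_segment_ids]))
})

test_that("classification follows the enhancement-and-strain rule with 3D adjacency", {
  lge <- rep(0, 16); peaks <- rep(-25, 16)
  lge[13] <- 0.30; peaks[13] <- -6
  lab <- classify_segments(lge, peaks)
  expect_equal(lab$region[13], "mi")
  nb <- segment_neighbors(default_adjacency(), 13)
  expect_setequal(which(lab$region == "peri_mi"), nb)
  expect_true(all(lab$region[-c(13, nb)] == "normal"))

  # both conditions required: enhanced but contracting stays non-mi
  lge2 <- lge; lge2[5] <- 0.6
  lab2 <- classify_segments(lge2, peaks)
  expect_false(lab2$region[5] == "mi")

  # all unenhanced -> all normal
  lab0 <- classify_segments(rep(0, 16), peaks)
  expect_true(all(lab0$region == "normal"))

  # quality-failed segments are excluded and reported
  pk <- peaks; pk[2] <- NA
  labx <- classify_segments(lge, pk)
  expect_true(is.na(labx$region[2]))
  expect_equal(attr(labx, "excluded"), 2L)

  # permutation invariance: labels depend only on the inputs
  o <- sample(16)
  lab_perm <- classify_segments(lge[o][order(o)], peaks[o][order(o)])
  expect_identical(lab_perm$region, lab$region)
})

test_that("ground-truth infarct segments are labeled mi in repeated runs", {
  # estimated-strain route across several seeded studies
  p <- make_preset("early_post_mi")
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    st <- generate_study(p, seed = 100 + s,
                         stages = c("tagged", "contours", "lge"))
    a <- analyze_study(st)
    lab <- a$labels
    hits <- hits + sum(lab$region[p$mi_segment_ids] == "mi", na.rm = TRUE)
    total <- total + length(p$mi_segment_ids)
  }
  expect_gte(hits / total, 0.95 - 1e-9)
})
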