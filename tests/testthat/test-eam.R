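# Eikonal generator and conduction-velocity estimation.

test_that("fast sweeping matches the closed-form solution on a flat mesh", {
  nx <- 60; ny <- 40; h <- 1
  sp <- matrix(0.4, nx, ny)              # 40 cm/s in mm/ms
  t0 <- matrix(Inf, nx, ny); t0[1, ] <- 0
  TT <- eikonal_solve(sp, t0, hx = h, hy = h)
  # planar source: LAT = distance / speed exactly
  expect_equal(TT[nx, 1], (nx - 1) / 0.4, tolerance = 1e-6)
  expect_equal(max(abs(sweep(TT, 1, ((1:nx) - 1) / 0.4))), 0,
               tolerance = 1e-6)

  # point source: within 2% of Euclidean distance / speed away from origin
  t1 <- source_disk_times(nx, ny, 1, 1, h, h, 0.4, radius_cells = 10)
  T2 <- eikonal_solve(sp, t1, hx = h, hy = h)
  d <- sqrt(outer(((1:nx) - 1)^2, ((1:ny) - 1)^2, "+"))
  far <- d > 10
  expect_lt(max(abs(T2[far] - d[far] / 0.4) / (d[far] / 0.4)), 0.02)

  expect_error(eikonal_solve(matrix(-1, 4, 4), t0[1:4, 1:4], 1, 1),
               "positive")
})

test_that("plane waves are recovered exactly at any orientation", {
  set.seed(31)
  n <- 250
  P <- cbind(runif(n, 0, 60), runif(n, 0, 60), 0)
  for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
    u <- c(cos(ang), sin(ang), 0)
    lat <- P %*% u / 0.4                 # 40 cm/s plane wave
    cl <- data.frame(point_id = 1:n, x_mm = P[, 1], y_mm = P[, 2],
                     z_mm = 0, lat_ms = as.numeric(lat))
    cv <- estimate_cv(cl)
    est <- cv$cv_cms[!is.na(cv$cv_cms)]
    expect_gt(length(est), 100)
    expect_lt(max(abs(est - 40)) / 40, 0.025)
  }
})

test_that("radial waves away from the source are recovered", {
  set.seed(32)
  x <- runif(900, -70, 70); y <- runif(900, -70, 70)
  r <- sqrt(x^2 + y^2)
  keep <- r >= 20
  cl <- data.frame(point_id = seq_len(sum(keep)), x_mm = x[keep],
                   y_mm = y[keep], z_mm = 0, lat_ms = r[keep] / 0.3)
  cv <- estimate_cv(cl)
  est <- cv$cv_cms[!is.na(cv$cv_cms)]
  expect_equal(mean(est), 30, tolerance = 2 / 30)
})

test_that("voltage zone classification uses half-open thresholds", {
  cl <- data.frame(voltage_mv = c(0.3, 0.5, 1.49, 1.5, 3.2))
  z <- classify_zones_by_voltage(cl)
  expect_equal(z, c("infarct", "border", "border", "remote", "remote"))
  expect_error(classify_zones_by_voltage(cl, scar_mv = 2, border_mv = 1),
               "below")
  # noise-free synthetic cloud: voltage labels equal ground truth
  p <- make_preset("early_post_mi")
  cl2 <- render_eam(p, seed = 2, voltage_sdlog = 0)
  expect_equal(classify_zones_by_voltage(cl2), cl2$zone_truth)
})

test_that("zone summary is plain arithmetic over labelled estimates", {
  est <- data.frame(point_id = 1:6, cv_cms = c(5, 7, 20, 18, 40, 36),
                    residual_ms = 0, n_neighbors = 9)
  zones <- c("infarct", "infarct", "border", "border", "remote", "remote")
  zs <- zone_summary(est, zones)
  expect_equal(zs$cv_mean, c(6, 19, 38))
  expect_equal(zs$cv_sd, c(sd(c(5, 7)), sd(c(20, 18)), sd(c(40, 36))))
  zs2 <- zone_summary(est[1:2, ], zones[1:2])
  expect_equal(zs2$n[zs2$zone == "remote"], 0)
  expect_true(is.na(zs2$cv_mean[zs2$zone == "remote"]))
})

test_that("the infarct is the latest-activated region", {
  p <- make_preset("early_post_mi")
  for (s in 1:3) {
    cl <- render_eam(p, seed = s)
    expect_equal(latest_activation(cl)$zone_truth[1], "infarct")
  }
  # uniform speed, single source: the latest point lies among the most
  # distant points from the source (chord distance, allowing for surface
  # curvature)
  u <- p; u$zone_speed <- c(remote = 30, border = 29.99, infarct = 29.98)
  cl <- render_eam(u, seed = 4, lat_noise_ms = 0)
  src <- attr(cl, "source")
  sx <- c(cos(src[["theta"]]), sin(src[["theta"]])) * 27
  d <- sqrt((cl$x_mm - sx[1])^2 + (cl$y_mm - sx[2])^2 +
              (cl$z_mm - src["z"])^2)
  i_last <- which.max(cl$lat_ms)
  expect_gte(d[i_last], quantile(d, 0.8))
  one <- cl[7, , drop = FALSE]
  expect_equal(latest_activation(one)$point_id, one$point_id)
})

test_that("eikonal activation scales inversely with conduction speed", {
  p <- make_preset("early_post_mi")
  cl1 <- render_eam(p, seed = 5, lat_noise_ms = 0)
  p2 <- p; p2$zone_speed <- 2 * p$zone_speed
  cl2 <- render_eam(p2, seed = 5, lat_noise_ms = 0)
  expect_equal(cl2$lat_ms, cl1$lat_ms / 2, tolerance = 1e-6)
  expect_true(all(cl1$lat_ms >= 0))
  expect_true(all(cl1$voltage_mv > 0))
})

test_that("recovered zone means increase with generator speed and stay ordered", {
  p <- make_preset("early_post_mi")
  rec <- vapply(c(5, 10, 20, 40), function(v) {
    q <- p; q$zone_speed <- c(remote = v, border = v * 0.9999,
                              infarct = v * 0.9998)
    cl <- render_eam(q, seed = 6)
    mean(estimate_cv(cl)$cv_cms, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rec) > 0))

  for (s in 1:3) {
    cl <- render_eam(p, seed = 10 + s)
    zs <- zone_summary(estimate_cv(cl), cl$zone_truth)
    expect_true(zs$cv_mean[zs$zone == "infarct"] <
                  zs$cv_mean[zs$zone == "border"])
    expect_true(zs$cv_mean[zs$zone == "border"] <
                  zs$cv_mean[zs$zone == "remote"])
  }
})

test_that("zone means are robust to halved mapping density", {
  p <- make_preset("early_post_mi")
  cl_full <- render_eam(p, seed = 7, n_points = 300)
  cl_half <- render_eam(p, seed = 7, n_points = 150)
  z_full <- zone_summary(estimate_cv(cl_full), cl_full$zone_truth)
  z_half <- zone_summary(estimate_cv(cl_half), cl_half$zone_truth)
  for (z in c("infarct", "remote")) {
    a <- z_full$cv_mean[z_full$zone == z]
    b <- z_half$cv_mean[z_half$zone == z]
    expect_lt(abs(a - b) / a, 0.15)
  }
})

test_that("sparse clouds are rejected", {
  cl <- data.frame(point_id = 1:4, x_mm = 1:4 * 30, y_mm = 0, z_mm = 0,
                   lat_ms = 1:4)
  expect_error(estimate_cv(cl), "estimable|sparse")
})
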