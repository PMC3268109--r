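# Conduction-velocity estimation from electroanatomic point clouds.

#' Estimate per-point conduction velocity from an activation map
#'
#' Local tangent-plane gradient estimator: for each point, the neighbours
#' within \code{radius_mm} are projected onto the tangent plane from a
#' principal-component fit of their positions, a first-order polynomial of
#' local activation time over the two in-plane coordinates is fitted, and
#' the conduction velocity is the inverse in-plane gradient magnitude,
#' converted to cm/s.  Points with fewer than \code{min_neighbors}
#' neighbours, near-zero gradients (< 1e-4 ms/mm), fit RMS residuals above
#' \code{max_residual_ms} (typically mixed-speed neighbourhoods) or
#' velocities above \code{cap_cms} are not estimated.  A second,
#' scale-invariant residual criterion (\code{rel_residual_max}, RMS
#' residual relative to the SD of the fitted plane values) rejects
#' curvature-dominated fits -- e.g. close to the pacing/breakthrough site
#' -- identically at every conduction speed, where a fixed millisecond
#' cutoff would reject them only in slow tissue.
#'
#' @param cloud an \code{eam_cloud} (or data.frame with \code{x_mm},
#'   \code{y_mm}, \code{z_mm}, \code{lat_ms})
#' @param radius_mm neighbourhood radius (default 10)
#' @param min_neighbors minimum neighbourhood size (default 5, the point
#'   itself included)
#' @param max_residual_ms absolute residual cutoff (default 15)
#' @param rel_residual_max relative residual cutoff (default 0.2)
#' @param cap_cms velocity cap (default 200)
#' @return data.frame: \code{point_id}, \code{cv_cms}, \code{residual_ms},
#'   \code{n_neighbors}; \code{cv_cms} is NA where not estimable
#' @export
estimate_cv <- function(cloud, radius_mm = 10, min_neighbors = 5L,
                        max_residual_ms = 15, rel_residual_max = 0.2,
                        cap_cms = 200) {
  P <- cbind(cloud$x_mm, cloud$y_mm, cloud$z_mm)
  n <- nrow(P)
  lat <- cloud$lat_ms
  cv <- rep(NA_real_, n); res <- rep(NA_real_, n); nn <- integer(n)
  d2max <- radius_mm^2
  for (i in seq_len(n)) {
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2 +
      (P[, 3] - P[i, 3])^2
    sel <- which(d2 <= d2max)
    nn[i] <- length(sel)
    if (length(sel) < min_neighbors) next
    Q <- P[sel, , drop = FALSE]
    Qc <- sweep(Q, 2, colMeans(Q))
    ev <- eigen(crossprod(Qc), symmetric = TRUE)$vectors
    uv <- Qc %*% ev[, 1:2]               # in-plane coordinates (mm)
    X <- cbind(1, uv)
    fit <- stats::lm.fit(X, lat[sel])
    g <- fit$coefficients[2:3]           # ms/mm
    gm <- sqrt(sum(g^2))
    rms <- sqrt(mean(fit$residuals^2))
    if (!is.finite(gm) || gm < 1e-4) next
    v <- 100 / gm                        # mm/ms -> cm/s
    sd_fit <- stats::sd(X %*% fit$coefficients)
    if (rms > max_residual_ms || v > cap_cms ||
        (is.finite(sd_fit) && sd_fit > 0 &&
         rms > rel_residual_max * sd_fit)) { res[i] <- rms; next }
    cv[i] <- v; res[i] <- rms
  }
  if (sum(!is.na(cv)) < 5)
    stop("fewer than 5 estimable points: map too sparse for CV analysis")
  data.frame(point_id = if (!is.null(cloud$point_id)) cloud$point_id
             else seq_len(n),
             cv_cms = cv, residual_ms = res, n_neighbors = nn)
}

#' Classify map points into zones by bipolar voltage
#'
#' Scar (infarct) below \code{scar_mv} (default 0.5 mV), border zone in
#' \code{[scar_mv, border_mv)}, remote at or above \code{border_mv}
#' (default 1.5 mV).
#'
#' @param cloud an \code{eam_cloud}
#' @param scar_mv scar cutoff (mV)
#' @param border_mv upper border-zone cutoff (mV)
#' @return character vector of zone labels per point
#' @export
classify_zones_by_voltage <- function(cloud, scar_mv = 0.5,
                                      border_mv = 1.5) {
  if (scar_mv >= border_mv) stop("scar_mv must be below border_mv")
  v <- cloud$voltage_mv
  ifelse(v < scar_mv, "infarct",
         ifelse(v < border_mv, "border", "remote"))
}

#' Zone summary of conduction velocities
#'
#' @param estimates output of \code{\link{estimate_cv}}
#' @param zones zone label per point (e.g. ground truth, or
#'   \code{\link{classify_zones_by_voltage}})
#' @return data.frame: \code{zone}, \code{n}, \code{cv_mean},
#'   \code{cv_sd} (cm/s); zones without estimable points report n = 0 and
#'   NA means
#' @export
zone_summary <- function(estimates, zones) {
  stopifnot(length(zones) == nrow(estimates))
  out <- list()
  for (z in c("infarct", "border", "remote")) {
    v <- estimates$cv_cms[zones == z & !is.na(estimates$cv_cms)]
    out[[z]] <- data.frame(zone = z, n = length(v),
                           cv_mean = if (length(v)) mean(v) else NA_real_,
                           cv_sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Latest-activated point(s) of a map
#'
#' @param cloud an \code{eam_cloud}
#' @return data.frame row(s) of the maximal-LAT point(s) with their zone
#' @export
latest_activation <- function(cloud) {
  if (!nrow(cloud)) stop("empty point cloud")
  mx <- max(cloud$lat_ms)
  cloud[cloud$lat_ms == mx,
        intersect(c("point_id", "lat_ms", "zone_truth"), names(cloud))]
}
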