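# Per-segment mechanics: peak strain, time-to-peak, SD16 dyssynchrony
# index, global strain and regional summaries.

#' Peak circumferential strain of a curve
#'
#' The most negative strain over the full cardiac cycle (the whole cycle is
#' searched because infarct peaks can fall well after systole).  An
#' all-positive (dyskinetic) curve simply returns its minimum.
#'
#' @param ec_pct strain samples (percent)
#' @return peak strain, percent
#' @export
peak_strain <- function(ec_pct) {
  if (!length(ec_pct) || all(is.na(ec_pct)))
    stop("empty strain curve")
  min(ec_pct, na.rm = TRUE)
}

#' Time to peak strain
#'
#' Time of the frame attaining the peak (most negative) strain, measured
#' from the QRS trigger (t = 0 at frame 1).  Ties return the earliest
#' frame; no sub-frame interpolation is performed.  A constant curve
#' returns 0 with a warning.
#'
#' @param ec_pct strain samples (percent)
#' @param t_ms frame times (ms from QRS), same length
#' @return time to peak, ms
#' @export
time_to_peak <- function(ec_pct, t_ms) {
  stopifnot(length(ec_pct) == length(t_ms))
  if (diff(range(ec_pct, na.rm = TRUE)) == 0) {
    warning("constant strain curve: time to peak is degenerate")
    return(0)
  }
  t_ms[which.min(ec_pct)]
}

#' SD16 dyssynchrony index
#'
#' Sample standard deviation (n - 1 denominator) of the 16 segmental
#' times-to-peak.  Quality-failed segments may be missing, but fewer than
#' \code{min_n} available values make the study unusable and raise an
#' error.
#'
#' @param ttp_ms numeric vector of up to 16 TTP values (ms); NAs allowed
#' @param min_n minimum number of available segments (default 14)
#' @return SD16 in ms
#' @export
sd16 <- function(ttp_ms, min_n = 14L) {
  v <- ttp_ms[!is.na(ttp_ms)]
  if (length(v) < min_n)
    stop("fewer than ", min_n, " usable segments: SD16 not computable")
  stats::sd(v)
}

#' Global peak strain
#'
#' Arithmetic mean of the available segmental peak strains (average eC for
#' 16 segments).
#'
#' @param peaks_pct numeric vector of up to 16 peak strains (percent)
#' @param min_n minimum number of available segments
#' @return percent
#' @export
global_strain <- function(peaks_pct, min_n = 14L) {
  v <- peaks_pct[!is.na(peaks_pct)]
  if (length(v) < min_n)
    stop("fewer than ", min_n, " usable segments")
  mean(v)
}

#' Per-segment mechanics summary from strain curves
#'
#' @param curves a \code{strain_curves} data.frame (see
#'   \code{\link{segment_curves}})
#' @return data.frame: \code{segment_id}, \code{peak_ec_pct},
#'   \code{ttp_ms}, \code{quality}; attributes \code{sd16_ms} and
#'   \code{global_peak_ec_pct}
#' @export
mechanics_summary <- function(curves) {
  out <- data.frame(segment_id = 1:16, peak_ec_pct = NA_real_,
                    ttp_ms = NA_real_, quality = FALSE)
  for (s in 1:16) {
    cur <- curves[curves$segment_id == s, ]
    if (!nrow(cur) || !any(is.finite(cur$ec_pct))) next
    q <- isTRUE(cur$quality[1])
    out$quality[s] <- q
    if (!q) next
    out$peak_ec_pct[s] <- peak_strain(cur$ec_pct)
    out$ttp_ms[s] <- time_to_peak(cur$ec_pct, cur$t_ms)
  }
  structure(out,
            sd16_ms = sd16(out$ttp_ms),
            global_peak_ec_pct = global_strain(out$peak_ec_pct))
}

#' Regional mechanics summary across subjects
#'
#' Aggregates subject-first: for each subject the mean peak strain and TTP
#' over that subject's segments of each region, then mean and SD across
#' subjects (matching small-cohort mean +/- SD reporting).  Subjects with
#' an empty region are omitted from that cell.
#'
#' @param mech data.frame with columns \code{subject}, \code{segment_id},
#'   \code{peak_ec_pct}, \code{ttp_ms}
#' @param labels data.frame with columns \code{subject},
#'   \code{segment_id}, \code{region}
#' @return data.frame: \code{region}, \code{n_subjects},
#'   \code{peak_ec_mean}, \code{peak_ec_sd}, \code{ttp_mean}, \code{ttp_sd}
#' @export
regional_summary <- function(mech, labels) {
  d <- merge(mech, labels, by = c("subject", "segment_id"))
  d <- d[!is.na(d$region) & !is.na(d$peak_ec_pct), ]
  out <- list()
  for (rg in c("normal", "peri_mi", "mi")) {
    dr <- d[d$region == rg, ]
    if (!nrow(dr)) {
      out[[rg]] <- data.frame(region = rg, n_subjects = 0L,
                              peak_ec_mean = NA_real_, peak_ec_sd = NA_real_,
                              ttp_mean = NA_real_, ttp_sd = NA_real_)
      next
    }
    pm <- tapply(dr$peak_ec_pct, dr$subject, mean)
    tm <- tapply(dr$ttp_ms, dr$subject, mean)
    out[[rg]] <- data.frame(region = rg, n_subjects = length(pm),
                            peak_ec_mean = mean(pm), peak_ec_sd = sd_na(pm),
                            ttp_mean = mean(tm), ttp_sd = sd_na(tm))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
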