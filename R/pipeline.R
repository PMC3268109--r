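# Orchestration: full analysis of synthetic studies and cohorts, recovery
# reports against ground truth, and study-table rendering.

#' Analyze one synthetic study end-to-end
#'
#' Runs every estimation stage on the study's acquisitions: HARP strain
#' curves and per-segment mechanics from the tagged series, LGE
#' quantification, transmurality and region classification, morphometry
#' from the contours, and conduction-velocity zone summaries from the EAM
#' cloud.  Stages whose inputs were not generated are skipped.
#'
#' @param study a \code{synthetic_study}
#' @param eam_radius_mm CV-estimator neighbourhood radius
#' @param bandwidth_frac HARP band-pass width (fraction of |k|)
#' @param lge_sd_mult LGE threshold multiplier
#' @return list of class \code{study_analysis} with elements
#'   \code{curves}, \code{mechanics}, \code{lge}, \code{transmurality},
#'   \code{labels}, \code{morphometry}, \code{cv}, \code{zone_summary},
#'   \code{latest}, \code{subject_id}
#' @export
analyze_study <- function(study, eam_radius_mm = 10, bandwidth_frac = 0.35,
                          lge_sd_mult = 5) {
  p <- study$preset
  out <- list(subject_id = study$subject_id, preset_name = p$name)
  if (!is.null(study$tagged) && !is.null(study$contours)) {
    geometry <- build_segments(study$contours, p$image_size,
                               p$pixel_spacing_mm)
    out$curves <- segment_curves(study$tagged, geometry,
                                 bandwidth_frac = bandwidth_frac)
    out$mechanics <- mechanics_summary(out$curves)
  }
  if (!is.null(study$lge)) {
    out$lge <- quantify_lge(study$lge, sd_mult = lge_sd_mult)
    out$transmurality <- transmurality(study$lge, out$lge$enhanced)
    if (!is.null(out$mechanics))
      out$labels <- classify_segments(out$lge$segment_table$lge_fraction,
                                      out$mechanics$peak_ec_pct)
  }
  if (!is.null(study$contours))
    out$morphometry <- morphometry_summary(study$contours, out$labels)
  if (!is.null(study$eam)) {
    out$cv <- estimate_cv(study$eam, radius_mm = eam_radius_mm)
    out$zone_summary <- zone_summary(out$cv, study$eam$zone_truth)
    out$latest <- latest_activation(study$eam)
  }
  class(out) <- "study_analysis"
  out
}

#' Analyze a cohort and aggregate subject-level results
#'
#' @param cohort a \code{synthetic_cohort}
#' @param ... passed to \code{\link{analyze_study}}
#' @return list of class \code{cohort_analysis}: \code{per_subject}
#'   (list of \code{study_analysis}), \code{mechanics} (long table),
#'   \code{labels}, \code{summary} (cohort means: SD16, global eC, LGE \%,
#'   EF, zone CVs), \code{regional}, \code{recovery} (bias/RMSE vs ground
#'   truth)
#' @export
analyze_cohort <- function(cohort, ...) {
  per <- lapply(cohort, analyze_study, ...)
  nsub <- length(per)
  mech <- do.call(rbind, lapply(per, function(a) {
    if (is.null(a$mechanics)) return(NULL)
    cbind(subject = a$subject_id, a$mechanics)
  }))
  labels <- do.call(rbind, lapply(per, function(a) {
    if (is.null(a$labels)) return(NULL)
    cbind(subject = a$subject_id, a$labels)
  }))
  truth <- cohort_truth_table(cohort)
  truth_lab <- truth[, c("subject", "segment_id", "region")]

  sd16_v <- vapply(per, function(a)
    if (is.null(a$mechanics)) NA_real_ else attr(a$mechanics, "sd16_ms"),
    numeric(1))
  gec_v <- vapply(per, function(a)
    if (is.null(a$mechanics)) NA_real_
    else attr(a$mechanics, "global_peak_ec_pct"), numeric(1))
  lge_v <- vapply(per, function(a)
    if (is.null(a$lge)) NA_real_ else a$lge$global_pct, numeric(1))
  ef_v <- vapply(per, function(a)
    if (is.null(a$morphometry)) NA_real_ else a$morphometry$ef_pct,
    numeric(1))
  zs <- lapply(per, function(a) a$zone_summary)
  zmean <- function(zone) {
    v <- vapply(zs, function(z)
      if (is.null(z)) NA_real_ else z$cv_mean[z$zone == zone], numeric(1))
    mean(v, na.rm = TRUE)
  }

  summary <- data.frame(
    n_subjects = nsub,
    sd16_ms = mean(sd16_v, na.rm = TRUE),
    global_peak_ec_pct = mean(gec_v, na.rm = TRUE),
    lge_pct = mean(lge_v, na.rm = TRUE),
    ef_pct = mean(ef_v, na.rm = TRUE),
    cv_infarct_cms = zmean("infarct"),
    cv_border_cms = zmean("border"),
    cv_remote_cms = zmean("remote"))

  regional <- if (!is.null(mech))
    regional_summary(mech, if (!is.null(labels)) labels else truth_lab)

  # recovery against ground truth
  t_sd16 <- vapply(cohort, function(st) st$truth$sd16_ms, numeric(1))
  t_gec <- vapply(cohort, function(st) st$truth$global_peak_ec_pct,
                  numeric(1))
  t_lge <- vapply(cohort, function(st)
    if (is.null(st$lge)) NA_real_ else 100 * st$truth$lge_fraction,
    numeric(1))
  t_ef <- vapply(cohort, function(st) st$truth$ef_pct, numeric(1))
  rec_row <- function(name, est, tru) {
    ok <- is.finite(est) & is.finite(tru)
    data.frame(quantity = name,
               estimate = mean(est[ok]), truth = mean(tru[ok]),
               bias = mean(est[ok] - tru[ok]),
               rmse = sqrt(mean((est[ok] - tru[ok])^2)))
  }
  recovery <- rbind(
    rec_row("sd16_ms", sd16_v, t_sd16),
    rec_row("global_peak_ec_pct", gec_v, t_gec),
    rec_row("lge_pct", lge_v, t_lge),
    rec_row("ef_pct", ef_v, t_ef))
  zsp <- attr(cohort[[1]]$eam, "zone_speed")
  if (!is.null(zsp)) {
    for (z in c("infarct", "border", "remote"))
      recovery <- rbind(recovery, rec_row(
        paste0("cv_", z, "_cms"),
        vapply(zs, function(x)
          if (is.null(x)) NA_real_ else x$cv_mean[x$zone == z], numeric(1)),
        rep(zsp[z], nsub)))
  }

  structure(list(per_subject = per, mechanics = mech, labels = labels,
                 truth = truth, summary = summary, regional = regional,
                 recovery = recovery),
            class = "cohort_analysis")
}

#' Run the full pipeline over one or more scenario presets
#'
#' Generates a cohort per preset, analyzes it end-to-end, renders
#' study-shaped tables and (when several time-points are present) the
#' longitudinal statistics: paired t tests on SD16 and global strain
#' between time-points, and a region-by-time repeated-measures ANOVA on
#' the post-infarct time-points.
#'
#' @param presets character vector of preset names
#' @param n_subjects subjects per cohort
#' @param seed master seed (recorded in the result)
#' @param out_dir optional directory: every table is also written as CSV
#' @param stages acquisitions to simulate
#' @param ... passed to \code{\link{analyze_study}}
#' @return list of class \code{pipeline_result}: \code{cohorts} (analysis
#'   per preset), \code{tables}, \code{stats}, \code{config}
#' @export
run_pipeline <- function(presets = c("pre_mi", "early_post_mi",
                                     "late_post_mi"),
                         n_subjects = 6L, seed = 1L, out_dir = NULL,
                         stages = c("tagged", "contours", "lge", "eam"),
                         ...) {
  config <- list(presets = presets, n_subjects = n_subjects, seed = seed,
                 stages = stages)
  analyses <- list()
  for (nm in presets) {
    preset <- make_preset(nm)
    cohort <- generate_cohort(preset, n_subjects,
                              seed = mix_seed(seed, match(nm, presets)),
                              stages = stages)
    analyses[[nm]] <- analyze_cohort(cohort, ...)
  }
  tables <- render_tables(analyses)
  stats_tab <- pipeline_stats(analyses)
  res <- structure(list(cohorts = analyses, tables = tables,
                        stats = stats_tab, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    writeLines(yaml::as.yaml(config), file.path(out_dir, "config.yaml"))
  }
  res
}

# Longitudinal statistics across the presets of a pipeline run.
pipeline_stats <- function(analyses) {
  nms <- names(analyses)
  if (length(nms) < 2) return(NULL)
  rows <- list()
  sd16_of <- function(a) vapply(a$per_subject, function(x)
    attr(x$mechanics, "sd16_ms"), numeric(1))
  gec_of <- function(a) vapply(a$per_subject, function(x)
    attr(x$mechanics, "global_peak_ec_pct"), numeric(1))
  for (i in 1:(length(nms) - 1)) for (j in (i + 1):length(nms)) {
    for (metric in c("sd16", "global_ec")) {
      f <- if (metric == "sd16") sd16_of else gec_of
      a <- f(analyses[[nms[i]]]); b <- f(analyses[[nms[j]]])
      if (length(a) != length(b) || anyNA(c(a, b))) next
      tt <- paired_t(b, a)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(metric, nms[j], "vs", nms[i]),
        statistic = tt$t, p = tt$p)
    }
  }
  # region x time rm-ANOVA on peak eC over post-MI time-points
  post <- intersect(c("early_post_mi", "late_post_mi"), nms)
  if (length(post) == 2) {
    long <- do.call(rbind, lapply(post, function(nm) {
      a <- analyses[[nm]]
      d <- merge(a$mechanics, a$labels, by = c("subject", "segment_id"))
      d <- d[!is.na(d$region) & !is.na(d$peak_ec_pct), ]
      agg <- stats::aggregate(peak_ec_pct ~ subject + region, d, mean)
      cbind(agg, time = nm)
    }))
    counts <- table(long$subject)
    keep <- names(counts)[counts == 6]   # 3 regions x 2 times
    long <- long[long$subject %in% keep, ]
    if (length(unique(long$subject)) >= 3 &&
        length(unique(long$region)) == 3) {
      an <- try(rm_anova(long$peak_ec_pct, long$subject, long$region,
                         long$time), silent = TRUE)
      if (!inherits(an, "try-error"))
        rows[[length(rows) + 1]] <- data.frame(
          comparison = paste("rm_anova peak_ec",
                             c("region", "time", "region:time")),
          statistic = an$F, p = an$p)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Render study-shaped summary tables from cohort analyses
#'
#' \code{table1}: morphometry and LGE (EF, LVEDD, RVEDD, EDV, ESV, MI /
#' normal wall thickness, LGE \%).  \code{table2}: global mechanics (global
#' peak eC, SD16, regional peak eC and TTP).  \code{table3}: regional
#' mechanics per post-infarct time-point.  Every cell is a pass-through of
#' the corresponding cohort-analysis value (mean +/- SD over subjects).
#'
#' @param analyses named list of \code{cohort_analysis} (names = presets)
#' @return named list of data.frames
#' @export
render_tables <- function(analyses) {
  nms <- names(analyses)
  fmt <- function(m, s) ifelse(is.na(m), "",
                               sprintf("%.3g ± %.2g", m, s))
  msd <- function(v) c(mean(v, na.rm = TRUE), sd_na(v))
  col1 <- function(a) {
    mo <- do.call(rbind, lapply(a$per_subject, function(x) x$morphometry))
    lg <- vapply(a$per_subject, function(x)
      if (is.null(x$lge)) NA_real_ else x$lge$global_pct, numeric(1))
    vals <- rbind(msd(mo$ef_pct), msd(mo$lvedd_mm), msd(mo$rvedd_mm),
                  msd(mo$edv_ml), msd(mo$esv_ml),
                  msd(mo$mi_thickness_mm), msd(mo$normal_thickness_mm),
                  msd(lg))
    fmt(vals[, 1], vals[, 2])
  }
  table1 <- data.frame(
    metric = c("LVEF (%)", "LVEDD (mm)", "RVEDD (mm)", "LVEDV (mL)",
               "LVESV (mL)", "MI segment thickness (mm)",
               "Normal segment thickness (mm)",
               "Late gadolinium enhancement %"))
  for (nm in nms) table1[[nm]] <- col1(analyses[[nm]])

  attr_or_na <- function(x, what)
    if (is.null(x)) NA_real_ else attr(x, what)
  col2 <- function(a) {
    g <- vapply(a$per_subject, function(x)
      attr_or_na(x$mechanics, "global_peak_ec_pct"), numeric(1))
    s <- vapply(a$per_subject, function(x)
      attr_or_na(x$mechanics, "sd16_ms"), numeric(1))
    rg <- a$regional
    getr <- function(rgn, colm, cols) {
      i <- if (is.null(rg)) integer(0) else which(rg$region == rgn)
      if (!length(i) || rg$n_subjects[i] == 0) c(NA, NA)
      else c(rg[[colm]][i], rg[[cols]][i])
    }
    vals <- rbind(msd(g), msd(s),
                  getr("normal", "peak_ec_mean", "peak_ec_sd"),
                  getr("normal", "ttp_mean", "ttp_sd"),
                  getr("peri_mi", "peak_ec_mean", "peak_ec_sd"),
                  getr("peri_mi", "ttp_mean", "ttp_sd"),
                  getr("mi", "peak_ec_mean", "peak_ec_sd"),
                  getr("mi", "ttp_mean", "ttp_sd"))
    fmt(vals[, 1], vals[, 2])
  }
  table2 <- data.frame(
    metric = c("Global peak eC", "SD16 segments (dyssynchrony index)",
               "Peak eC Normal", "TTP Normal", "Peak eC Peri-MI",
               "TTP Peri-MI", "Peak eC MI", "TTP MI"))
  for (nm in nms) table2[[nm]] <- col2(analyses[[nm]])

  tables <- list(table1 = table1, table2 = table2)
  post <- intersect(c("early_post_mi", "late_post_mi"), nms)
  if (length(post)) {
    t3 <- list()
    for (nm in post) {
      rg <- analyses[[nm]]$regional
      t3[[length(t3) + 1]] <- data.frame(
        time_point = nm,
        metric = rep(c("Peak eC", "TTP"), each = 3),
        region = rep(c("normal", "peri_mi", "mi"), 2),
        value = c(rg$peak_ec_mean[match(c("normal", "peri_mi", "mi"),
                                        rg$region)],
                  rg$ttp_mean[match(c("normal", "peri_mi", "mi"),
                                    rg$region)]),
        sd = c(rg$peak_ec_sd[match(c("normal", "peri_mi", "mi"),
                                   rg$region)],
               rg$ttp_sd[match(c("normal", "peri_mi", "mi"), rg$region)]))
    }
    tables$table3 <- do.call(rbind, t3)
  }
  tables
}
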