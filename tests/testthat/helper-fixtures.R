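# Shared fixtures, memoised so expensive phantom renders happen once per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# One noise-free pre-MI study with uniform -27% / TTP 300 motion: the
# workhorse for HARP oracle checks.
uniform_study <- function(peak = -27, ttp = 300, noise = 0, seed = 11L) {
  key <- sprintf("uni_%g_%g_%g_%d", peak, ttp, noise, seed)
  fixture(key, {
    p <- make_preset("pre_mi")
    p$noise_sigma <- noise
    m <- build_motion(p, seed)
    m$params$peak_ec_pct <- peak
    m$params$ttp_ms <- ttp
    m$params$dysk_amp_pct <- 0
    tg <- render_tagged(m, p, seed = seed)
    co <- generate_contours(m)
    geo <- build_segments(co, p$image_size, p$pixel_spacing_mm)
    list(preset = p, motion = m, tagged = tg, contours = co, geometry = geo)
  })
}

# Small analyzed cohorts for the acceptance checks.
analyzed_cohort <- function(name, n = 6L, seed = 1L,
                            stages = c("tagged", "contours", "lge")) {
  key <- sprintf("cohort_%s_%d_%d_%s", name, n, seed,
                 paste(substr(stages, 1, 1), collapse = ""))
  fixture(key, {
    preset <- make_preset(name)
    cohort <- generate_cohort(preset, n, seed = seed, stages = stages)
    list(cohort = cohort, analysis = analyze_cohort(cohort))
  })
}

# A toy LGE volume with exact voxel counts for counting oracles.
toy_lge_volume <- function(n_myo = 200L, n_enh = 40L) {
  n <- 20L
  intensity <- array(0, c(n, n, 1))
  myo <- array(FALSE, c(n, n, 1))
  myo[seq_len(n_myo)] <- TRUE
  intensity[myo] <- 1
  enh <- array(FALSE, c(n, n, 1))
  enh[seq_len(n_enh)] <- TRUE
  intensity[enh] <- 10
  structure(list(intensity = intensity, myo_mask = myo,
                 enhanced_truth = enh, voxel_mm = c(1, 1, 5),
                 slice_level = 1L, fraction_true = n_enh / n_myo,
                 extend_deg = 0, preset_name = "toy"),
            class = "lge_volume")
}
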