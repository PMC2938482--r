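# Full synthetic-study pipeline: each stage generates its inputs with the
# synthetic module, runs the corresponding analysis, and returns its results;
# run_pipeline() executes selected stages, writes their outputs and a
# manifest with content checksums, and is byte-reproducible for a fixed seed.

derive_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 1000L + k

#' Binaural-cue stage: simulated cohort, Golay measurement, cue curves
#'
#' Simulates an ear-canal cohort and a jacket-pocket cohort of spherical-head
#' models (per-animal radius and shadow strengths drawn from ranges typical of
#' adult ferret heads), measures every head through the full Golay chain
#' (play both codes through the head's impulse response, re-estimate the
#' response by deconvolution), builds ITD/ILD cue curves over the speaker
#' grid, and summarizes cue half-ranges.
#'
#' @param seed integer seed.
#' @param n_ear,n_jacket cohort sizes (default 16 ear-canal, 3 jacket).
#' @param angles speaker grid, degrees.
#' @param bands ILD analysis bands, Hz.
#' @param fs sample rate, Hz.
#' @param golay_order Golay code order (9 = 512 points).
#' @return list with per-cohort curves and `range_summary` objects.
#' @export
run_cue_stage <- function(seed = 1, n_ear = 16, n_jacket = 3,
                          angles = seq(-150, 150, by = 10),
                          bands = list(c(750, 1500), c(4000, 8000)),
                          fs = 80000, golay_order = 9) {
  pair <- generate_golay_pair(golay_order)
  make_cohort <- function(n, site, radius_range, low_range, high_range, seed) {
    params <- with_fixed_seed(seed, {
      data.frame(radius = stats::runif(n, radius_range[1], radius_range[2]),
                 low = stats::runif(n, low_range[1], low_range[2]),
                 high = stats::runif(n, high_range[1], high_range[2]))
    })
    lapply(seq_len(n), function(i) {
      model <- head_model(effective_radius = params$radius[i],
                         mic_site = site,
                         shadow_low_db = params$low[i],
                         shadow_high_db = params$high[i])
      irs <- lapply(angles, function(a) {
        true_ir <- simulate_head_ir(model, a, fs = fs)
        rec <- record_golay(pair, true_ir)
        estimate_impulse_response(rec$resp_a, rec$resp_b, pair)
      })
      build_cue_curve(irs, bands = bands)
    })
  }
  # radius ranges chosen so ITD half-ranges span roughly 165-255 us
  # (ear canal) and 160-175 us (jacket); shadow ranges span the observed
  # spread of ILD half-ranges in the two analysis bands.
  curves_ear <- make_cohort(n_ear, "ear_canal",
                            c(0.02255, 0.0339), c(3.5, 6.4), c(9.0, 15.9),
                            derive_seed(seed, 11L))
  curves_jacket <- make_cohort(n_jacket, "jacket_pocket",
                               c(0.02175, 0.02322), c(3.8, 4.6), c(9.2, 10.4),
                               derive_seed(seed, 12L))
  list(
    curves_ear = curves_ear,
    curves_jacket = curves_jacket,
    itd_ear = summarize_ranges(curves_ear, "itd"),
    itd_jacket = summarize_ranges(curves_jacket, "itd"),
    ild_low_ear = summarize_ranges(curves_ear, "ild", band = 1),
    ild_high_ear = summarize_ranges(curves_ear, "ild", band = 2),
    ild_low_jacket = summarize_ranges(curves_jacket, "ild", band = 1),
    ild_high_jacket = summarize_ranges(curves_jacket, "ild", band = 2)
  )
}

#' ECAP stage: simulated longitudinal sessions, thresholds, stability
#'
#' Simulates weekly forward-masking ECAP sessions for the seven intracochlear
#' electrode positions (true thresholds highest basally), recovers each
#' session's growth function and threshold, and tests the per-electrode
#' threshold-vs-day regression slopes against zero.
#'
#' @param seed integer seed.
#' @param days recording days (post-operative).
#' @param true_thresholds named per-electrode true thresholds (level units).
#' @param noise_sd recording noise, uV.
#' @param noise_floor_uv growth-function exclusion floor, uV.
#' @return list: `thresholds` (data.frame electrode/ear/day/threshold),
#'   `stability` (see [threshold_stability()]), `true_thresholds`.
#' @export
run_ecap_stage <- function(seed = 1, days = seq(14, 84, by = 14),
                           true_thresholds = c(AE1 = 100, AE2 = 101, AE3 = 103,
                                               AE4 = 105, AE5 = 107, AE6 = 114,
                                               AE7 = 121),
                           noise_sd = 10, noise_floor_uv = 30) {
  rows <- list()
  k <- 0L
  for (e in names(true_thresholds)) {
    for (ear in c("left", "right")) {
      for (d in days) {
        k <- k + 1L
        thr <- true_thresholds[[e]]
        cfg <- ecap_sim_config(threshold_level = thr,
                               levels = seq(thr + 10, thr + 60, by = 10),
                               noise_sd = noise_sd,
                               seed = derive_seed(seed, 100L + k),
                               electrode = e, ear = ear, day = d)
        est <- fit_threshold(measure_growth(simulate_ecap_session(cfg)),
                             noise_floor_uv = noise_floor_uv)
        rows[[k]] <- data.frame(electrode = e, ear = ear, day = d,
                                threshold = est$threshold,
                                slope = est$slope, n_used = est$n_used,
                                excluded = est$excluded)
      }
    }
  }
  thresholds <- do.call(rbind, rows)
  list(thresholds = thresholds,
       stability = threshold_stability(thresholds),
       true_thresholds = true_thresholds)
}

#' Impedance stage: simulated cohort log and bookkeeping summaries
#'
#' Simulates daily common-ground and monopolar impedance for 4 animals x 2
#' ears x 8 electrode positions (AE1-AE7 plus the extracochlear reference;
#' 64 positions in all), with 6 positions in two of the animals going
#' open-circuit from day 43, then computes the early/late epoch summaries,
#' the functional-position percentage and the across-array profile.
#'
#' @param seed integer seed.
#' @param n_days days of monitoring.
#' @param planted_failures see [impedance_sim_config()]; the default plants
#'   the 6 open circuits at day 43.
#' @return list: `log`, `epoch_early`, `epoch_late`, `functional_pct`
#'   (with `measurement_percent` attribute), `profile`.
#' @export
run_impedance_stage <- function(seed = 1, n_days = 90,
                                planted_failures = NULL) {
  if (is.null(planted_failures)) {
    planted_failures <- list(
      list(animal = "F3", ear = "left", electrode = "AE2", day = 43, type = "open"),
      list(animal = "F3", ear = "left", electrode = "AE6", day = 43, type = "open"),
      list(animal = "F3", ear = "right", electrode = "AE4", day = 43, type = "open"),
      list(animal = "F4", ear = "left", electrode = "AE1", day = 43, type = "open"),
      list(animal = "F4", ear = "right", electrode = "AE5", day = 43, type = "open"),
      list(animal = "F4", ear = "right", electrode = "AE7", day = 43, type = "open")
    )
  }
  cfg <- impedance_sim_config(
    electrodes = c(paste0("AE", 1:7), "EC"),
    planted_failures = planted_failures,
    seed = derive_seed(seed, 21L)
  )
  log <- simulate_impedance_log(cfg, n_days = n_days)
  list(log = log,
       epoch_early = epoch_summary(log, c(0, 4), mode = "CG"),
       epoch_late = epoch_summary(log, c(16, 20), mode = "CG"),
       functional_pct = functional_fraction(log),
       profile = per_position_profile(
         log[grepl("^AE", log$electrode), ], mode = "CG"))
}

#' Orienting stage: head vs jacket marker trials
#'
#' Simulates sound-evoked orienting trials recorded from a head marker and,
#' in separate trials, a jacket marker: the jacket follows the same sigmoid
#' sweep to a near-identical final bearing but starts later (the trunk lags
#' the head). Each trial is analyzed for movement latency and final bearing
#' and the two conditions compared.
#'
#' @param seed integer seed.
#' @param n_head,n_jacket trials per condition.
#' @param head_latency_ms,jacket_latency_ms mean latencies.
#' @param head_bearing_deg,jacket_bearing_deg mean final bearings.
#' @param latency_sd_ms,bearing_sd_deg across-trial variability.
#' @param tracker_noise_deg per-frame direction jitter.
#' @return list: `results_head`, `results_jacket`, `comparison`.
#' @export
run_orienting_stage <- function(seed = 1, n_head = 40, n_jacket = 40,
                                head_latency_ms = 200, jacket_latency_ms = 317,
                                head_bearing_deg = 42.96,
                                jacket_bearing_deg = 41.69,
                                latency_sd_ms = 25, bearing_sd_deg = 3,
                                tracker_noise_deg = 0.2) {
  simulate_condition <- function(n, lat, brg, seed0) {
    trial_params <- with_fixed_seed(seed0, {
      data.frame(
        lat = pmax(50, pmin(600, stats::rnorm(n, lat, latency_sd_ms))),
        brg = stats::rnorm(n, brg, bearing_sd_deg)
      )
    })
    lapply(seq_len(n), function(i) {
      cfg <- trajectory_sim_config(latency_ms = trial_params$lat[i],
                                   final_bearing_deg = trial_params$brg[i],
                                   tracker_noise_deg = tracker_noise_deg,
                                   seed = derive_seed(seed0, i))
      analyze_orienting(simulate_trajectory(cfg))
    })
  }
  results_head <- simulate_condition(n_head, head_latency_ms,
                                     head_bearing_deg, derive_seed(seed, 31L))
  results_jacket <- simulate_condition(n_jacket, jacket_latency_ms,
                                       jacket_bearing_deg, derive_seed(seed, 32L))
  list(results_head = results_head, results_jacket = results_jacket,
       comparison = compare_conditions(results_head, results_jacket))
}

#' Ambient-noise stage: RMS levels of simulated chamber noise
#'
#' Generates Gaussian chamber-noise recordings whose calibrated RMS levels are
#' drawn around a nominal level, for an empty-chamber and an in-pocket
#' condition, and measures each with [rms_level_db()].
#'
#' @param seed integer seed.
#' @param n_sessions recordings per condition.
#' @param empty_db,pocket_db nominal levels, dB SPL.
#' @param session_sd_db between-session level spread, dB.
#' @param fs,dur_s recording format.
#' @param reference pressure mapping to 0 dB SPL (20 uPa in Pa).
#' @return list with per-condition mean/sd of measured levels (dB SPL).
#' @export
run_noise_stage <- function(seed = 1, n_sessions = 10,
                            empty_db = 33.6, pocket_db = 33.5,
                            session_sd_db = 0.5, fs = 80000, dur_s = 0.25,
                            reference = 20e-6) {
  measure <- function(nominal, seed0) {
    with_fixed_seed(seed0, {
      vapply(seq_len(n_sessions), function(i) {
        level <- stats::rnorm(1, nominal, session_sd_db)
        x <- stats::rnorm(fs * dur_s)
        x <- x / rms(x) * reference * 10^(level / 20)
        rms_level_db(x, reference)
      }, numeric(1))
    })
  }
  empty <- measure(empty_db, derive_seed(seed, 41L))
  pocket <- measure(pocket_db, derive_seed(seed, 42L))
  list(empty_mean_db = mean(empty), empty_sd_db = stats::sd(empty),
       pocket_mean_db = mean(pocket), pocket_sd_db = stats::sd(pocket))
}

range_summary_row <- function(name, s) {
  data.frame(summary = name, min = s$min, median = s$median, max = s$max)
}

orienting_results_df <- function(rs, condition) {
  data.frame(condition = condition,
             trial = seq_along(rs),
             latency_ms = vapply(rs, function(r) r$latency_ms, numeric(1)),
             final_bearing_deg = vapply(rs, function(r) r$final_bearing_deg,
                                        numeric(1)))
}

#' Run the full synthetic pipeline and write its outputs
#'
#' Executes the selected stages in order, writes every stage's tables (CSV),
#' reports (JSON) and one example impulse-response pair (float WAV + JSON
#' sidecar) under `out_dir`, and finishes with `manifest.json` listing the
#' seed, package version, per-stage record counts and an MD5 checksum of
#' every file written. All outputs are a pure function of `(seed, sizes)`:
#' rerunning with the same arguments reproduces every file byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; every stage derives its own stream.
#' @param stages subset of `c("cues", "ecap", "impedance", "orienting",
#'   "noise")`.
#' @param cue_n_ear,cue_n_jacket,ecap_days,impedance_n_days,orienting_n
#'   stage sizes (defaults match the full synthetic study).
#' @return list of stage results plus the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         stages = c("cues", "ecap", "impedance",
                                    "orienting", "noise"),
                         cue_n_ear = 16, cue_n_jacket = 3,
                         ecap_days = seq(14, 84, by = 14),
                         impedance_n_days = 90,
                         orienting_n = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  counts <- list()
  results <- list()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table_checked(df, path)
    files <<- c(files, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
    path
  }

  if ("cues" %in% stages) {
    cues <- run_cue_stage(seed, n_ear = cue_n_ear, n_jacket = cue_n_jacket)
    results$cues <- cues
    curve_df <- function(curves, site) {
      do.call(rbind, lapply(seq_along(curves), function(i) {
        cbind(data.frame(site = site, animal = i),
              as.data.frame(curves[[i]]))
      }))
    }
    all_curves <- rbind(curve_df(cues$curves_ear, "ear_canal"),
                        curve_df(cues$curves_jacket, "jacket_pocket"))
    emit_csv(all_curves, "cue_curves.csv")
    ranges <- rbind(
      range_summary_row("itd_us_ear_canal", cues$itd_ear),
      range_summary_row("itd_us_jacket", cues$itd_jacket),
      range_summary_row("ild_db_low_ear_canal", cues$ild_low_ear),
      range_summary_row("ild_db_high_ear_canal", cues$ild_high_ear),
      range_summary_row("ild_db_low_jacket", cues$ild_low_jacket),
      range_summary_row("ild_db_high_jacket", cues$ild_high_jacket)
    )
    emit_csv(ranges, "cue_ranges.csv")
    # one example measured impulse-response pair, as stereo float WAV
    example_ir <- simulate_head_ir(head_model(), 90)
    wav_path <- file.path(out_dir, "example_ir_plus90deg.wav")
    write_ir_pair(example_ir, wav_path)
    files <- c(files, wav_path, paste0(wav_path, ".json"))
    counts$cues <- nrow(all_curves)
  }

  if ("ecap" %in% stages) {
    ecap <- run_ecap_stage(seed, days = ecap_days)
    results$ecap <- ecap
    emit_csv(ecap$thresholds, "ecap_thresholds.csv")
    emit_json(ecap$stability[c("slopes", "mean_slope", "t_statistic",
                               "df", "p_value")],
              "ecap_stability.json")
    counts$ecap <- nrow(ecap$thresholds)
  }

  if ("impedance" %in% stages) {
    imp <- run_impedance_stage(seed, n_days = impedance_n_days)
    results$impedance <- imp
    emit_csv(imp$log, "impedance_log.csv")
    emit_csv(imp$profile, "impedance_profile.csv")
    emit_json(list(epoch_early = imp$epoch_early,
                   epoch_late = imp$epoch_late,
                   functional_position_pct = as.numeric(imp$functional_pct),
                   functional_measurement_pct =
                     attr(imp$functional_pct, "measurement_percent")),
              "impedance_summary.json")
    counts$impedance <- nrow(imp$log)
  }

  if ("orienting" %in% stages) {
    orient <- run_orienting_stage(seed, n_head = orienting_n,
                                  n_jacket = orienting_n)
    results$orienting <- orient
    emit_csv(rbind(orienting_results_df(orient$results_head, "head"),
                   orienting_results_df(orient$results_jacket, "jacket")),
             "orienting_results.csv")
    emit_json(orient$comparison, "orienting_comparison.json")
    counts$orienting <- length(orient$results_head) +
      length(orient$results_jacket)
  }

  if ("noise" %in% stages) {
    noise <- run_noise_stage(seed)
    results$noise <- noise
    emit_json(noise, "ambient_noise.json")
    counts$noise <- 1L
  }

  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  manifest <- list(
    seed = seed,
    package = "implantcues",
    version = as.character(utils::packageVersion("implantcues")),
    stages = as.list(counts),
    files = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
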