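# Synthetic longitudinal electrode-impedance logs: a sigmoid rise from a
# post-operative baseline to a tissue-response plateau, a per-position offset
# profile, Gaussian measurement noise, and optionally planted open- or
# closed-circuit failures.

#' Configuration for a synthetic impedance log
#'
#' The noiseless time course for a functional electrode is a normalized
#' logistic anchored at the baseline on day 0:
#' `z(d) = baseline + (plateau + offset_e - baseline) * s(d)`, where
#' `s(d) = (L(d) - L(0)) / (1 - L(0))` and `L(d)` is a logistic with midpoint
#' `rise_midpoint_day` and scale `rise_width_day`. `s(0) = 0` exactly and
#' `s(d) -> 1`, so day 0 reads the baseline and late days read the plateau.
#' `position_offset_kohm` shapes the across-array profile (highest apically,
#' lowest mid-array).
#'
#' @param baseline_kohm impedance on the day of surgery, kOhm.
#' @param plateau_kohm impedance plateau after the tissue response, kOhm
#'   (must exceed the baseline).
#' @param rise_midpoint_day day of the half-rise.
#' @param rise_width_day logistic scale of the rise, days.
#' @param noise_sd measurement noise sd, kOhm.
#' @param position_offset_kohm named numeric, additive plateau offset per
#'   electrode AE1-AE7.
#' @param planted_failures list of failures, each a list with `animal`, `ear`,
#'   `electrode`, `day` (onset, >= 0) and `type` (`"open"` or `"closed"`);
#'   from the onset day onward that position reads > 20 kOhm (open) or
#'   < 1 kOhm (closed).
#' @param n_animals,ears,electrodes,modes layout of the simulated cohort.
#' @param seed integer RNG seed.
#' @return object of class `impedance_sim_config`.
#' @export
impedance_sim_config <- function(baseline_kohm = 1.9,
                                 plateau_kohm = 8.5,
                                 rise_midpoint_day = 9,
                                 rise_width_day = 2.2,
                                 noise_sd = 0.5,
                                 position_offset_kohm = c(
                                   AE1 = 1.2, AE2 = 0.6, AE3 = 0.2,
                                   AE4 = -0.2, AE5 = -0.8, AE6 = -0.3,
                                   AE7 = 0.2),
                                 planted_failures = list(),
                                 n_animals = 4,
                                 ears = c("left", "right"),
                                 electrodes = paste0("AE", 1:7),
                                 modes = c("CG", "MP"),
                                 seed = 1) {
  if (!(baseline_kohm < plateau_kohm)) stop("baseline_kohm must be < plateau_kohm")
  if (rise_width_day <= 0) stop("rise_width_day must be > 0")
  for (f in planted_failures) {
    if (is.null(f$day) || f$day < 0) stop("planted failure days must be >= 0")
    if (!f$type %in% c("open", "closed")) stop("failure type must be 'open' or 'closed'")
  }
  structure(as.list(environment()), class = "impedance_sim_config")
}

# Normalized sigmoid: 0 at day 0, -> 1 as day -> Inf.
impedance_rise <- function(day, midpoint, width) {
  l <- stats::plogis((day - midpoint) / width)
  l0 <- stats::plogis(-midpoint / width)
  (l - l0) / (1 - l0)
}

#' Simulate a longitudinal impedance log
#'
#' One record per (animal, ear, electrode, day, mode). Planted failures
#' replace the sigmoid course from their onset day onward with out-of-range
#' values (open: 25 kOhm, closed: 0.5 kOhm, plus noise bounded away from the
#' 1/20 kOhm classification boundaries).
#'
#' @param cfg an [impedance_sim_config()].
#' @param n_days number of post-operative days to simulate (day 0 .. n_days-1).
#' @return data.frame with columns `animal`, `ear`, `electrode`, `day`,
#'   `mode`, `kohm`.
#' @export
simulate_impedance_log <- function(cfg, n_days) {
  stopifnot(inherits(cfg, "impedance_sim_config"))
  if (n_days < 1) stop("n_days must be >= 1")
  days <- 0:(n_days - 1)
  grid <- expand.grid(animal = paste0("F", seq_len(cfg$n_animals)),
                      ear = cfg$ears, electrode = cfg$electrodes,
                      day = days, mode = cfg$modes,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$animal, grid$ear, grid$electrode, grid$day, grid$mode), ]
  rownames(grid) <- NULL
  offset <- cfg$position_offset_kohm[grid$electrode]
  offset[is.na(offset)] <- 0
  s <- impedance_rise(grid$day, cfg$rise_midpoint_day, cfg$rise_width_day)
  base <- cfg$baseline_kohm + (cfg$plateau_kohm + offset - cfg$baseline_kohm) * s
  kohm <- with_fixed_seed(cfg$seed, {
    z <- base + stats::rnorm(nrow(grid), sd = cfg$noise_sd)
    # functional electrodes stay inside the desired 1-20 kOhm range;
    # out-of-range values come only from planted failures
    pmin(pmax(z, 1), 20)
  })
  for (f in cfg$planted_failures) {
    idx <- grid$animal == f$animal & grid$ear == f$ear &
      grid$electrode == f$electrode & grid$day >= f$day
    if (f$type == "open") {
      kohm[idx] <- 25 + abs(kohm[idx] - base[idx])
    } else {
      kohm[idx] <- pmax(0.05, pmin(0.95, 0.5 + (kohm[idx] - base[idx]) / 10))
    }
  }
  grid$kohm <- as.numeric(kohm)
  grid
}
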