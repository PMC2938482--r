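# Longitudinal electrode-impedance bookkeeping: open/closed/functional
# classification, epoch summaries, per-position profiles and the
# functional-position percentage.

#' Classify an impedance measurement
#'
#' An electrode reading below 1 kOhm is a short (`"closed"` circuit), above
#' 20 kOhm a break (`"open"` circuit); anything in the desired 1-20 kOhm range
#' (boundaries inclusive) is `"functional"`. Vectorized.
#'
#' @param kohm positive impedance value(s), kOhm.
#' @return character vector: `"closed"`, `"open"` or `"functional"`.
#' @export
classify_impedance <- function(kohm) {
  if (any(!is.finite(kohm)) || any(kohm <= 0)) {
    stop("impedance must be positive and finite")
  }
  ifelse(kohm < 1, "closed", ifelse(kohm > 20, "open", "functional"))
}

# validate an impedance log data.frame
check_impedance_log <- function(log) {
  required <- c("animal", "ear", "electrode", "day", "mode", "kohm")
  missing <- setdiff(required, names(log))
  if (length(missing) > 0) {
    stop("impedance log missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(log) == 0) stop("empty impedance log")
  invisible(log)
}

#' Impedance mean and sd over a post-operative epoch
#'
#' Arithmetic mean and sample (n-1) standard deviation of the functional
#' measurements in the inclusive day range, for one measurement mode.
#' Open/closed readings are excluded (they are failure codes, not tissue
#' impedances). A single-record epoch reports sd 0 with `n = 1`.
#'
#' @param log impedance log data.frame (`animal`, `ear`, `electrode`, `day`,
#'   `mode`, `kohm`).
#' @param day_range inclusive `(d0, d1)` day window.
#' @param mode `"CG"` or `"MP"`.
#' @return list: `mean_kohm`, `sd_kohm`, `n`, `n_excluded`.
#' @export
epoch_summary <- function(log, day_range, mode = "CG") {
  check_impedance_log(log)
  sel <- log[log$day >= day_range[1] & log$day <= day_range[2] &
               log$mode == mode, ]
  if (nrow(sel) == 0) stop("no records in days [", day_range[1], ", ",
                           day_range[2], "] for mode ", mode)
  functional <- classify_impedance(sel$kohm) == "functional"
  v <- sel$kohm[functional]
  if (length(v) == 0) stop("no functional measurements in the selected epoch")
  list(mean_kohm = mean(v),
       sd_kohm = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v),
       n_excluded = sum(!functional))
}

#' Percentage of electrode positions that stayed functional
#'
#' A position is an (animal, ear, electrode) triple; it counts as functional
#' only if every one of its measurements classifies as functional. The
#' measurement-level percentage is attached as attribute
#' `measurement_percent`.
#'
#' @param log impedance log data.frame.
#' @return percentage (0-100) of always-functional positions.
#' @export
functional_fraction <- function(log) {
  check_impedance_log(log)
  status <- classify_impedance(log$kohm)
  key <- interaction(log$animal, log$ear, log$electrode, drop = TRUE)
  ok_by_pos <- tapply(status == "functional", key, all)
  pct <- 100 * mean(ok_by_pos)
  attr(pct, "measurement_percent") <- 100 * mean(status == "functional")
  attr(pct, "n_positions") <- length(ok_by_pos)
  pct
}

#' Impedance profile across the electrode array
#'
#' Mean and sd per intracochlear electrode position, pooled over animals,
#' ears and days, for one mode, excluding open/closed readings. Positions with
#' no usable data are absent from the result.
#'
#' @param log impedance log data.frame.
#' @param mode `"CG"` or `"MP"`.
#' @return data.frame with columns `electrode`, `mean_kohm`, `sd_kohm`, `n`,
#'   ordered by electrode.
#' @export
per_position_profile <- function(log, mode = "CG") {
  check_impedance_log(log)
  sel <- log[log$mode == mode, ]
  sel <- sel[classify_impedance(sel$kohm) == "functional", ]
  if (nrow(sel) == 0) stop("no functional records for mode ", mode)
  agg <- do.call(rbind, lapply(split(sel, sel$electrode), function(d) {
    data.frame(electrode = d$electrode[1],
               mean_kohm = mean(d$kohm),
               sd_kohm = if (nrow(d) > 1) stats::sd(d$kohm) else 0,
               n = nrow(d))
  }))
  agg <- agg[order(agg$electrode), ]
  rownames(agg) <- NULL
  agg
}
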