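# Lomb-Scargle seasonality detection for unevenly sampled monthly series.

#' Filter ASVs by occupancy
#'
#' Keeps ASVs detected (count > 0) in at least
#' `ceiling(min_frac * n_samples)` samples.
#'
#' @param table samples x ASVs counts.
#' @param min_frac minimum detection fraction (default 0.10).
#' @return character vector of retained ASV ids.
#' @export
occurrence_filter <- function(table, min_frac = 0.10) {
  need <- ceiling(min_frac * nrow(table))
  colnames(table)[colSums(table > 0) >= need]
}

# Period grid: 2 months to half the span, uniform in frequency with the
# given oversampling factor.
default_period_grid <- function(times, oversample = 4, min_period = 2) {
  span <- diff(range(times))
  if (span <= 2 * min_period) stop("time span too short for a period grid")
  freqs <- seq(1 / span, 0.5, by = 1 / (oversample * span))
  periods <- 1 / freqs
  sort(periods[periods >= min_period & periods <= span / 2])
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classical Lomb periodogram with the time-offset tau, normalised by the
#' total sum of squares of the series so a noiseless sinusoid scores ~1 and
#' power reads as the fraction of variance at each period ("standard"
#' normalisation). The peak normalised power (PN) and its period are the
#' seasonality statistics.
#'
#' @param values numeric series (>= 8 finite observations, variance > 0).
#' @param times observation times in decimal months (see [months_since()]).
#' @param periods period grid in months; defaults to 2 .. span/2 with
#'   4-fold frequency oversampling.
#' @param oversample oversampling factor for the default grid.
#' @return data.frame (period, power) with attributes `PN` and
#'   `period_at_peak`.
#' @export
lomb_scargle <- function(values, times, periods = NULL, oversample = 4) {
  keep <- is.finite(values) & is.finite(times)
  values <- values[keep]; times <- times[keep]
  if (length(values) < 8) stop("need at least 8 observations")
  w <- values - mean(values)
  sst <- sum(w^2)
  if (sst <= 0) stop("constant series")
  if (is.null(periods)) periods <- default_period_grid(times, oversample)
  omega <- 2 * pi / periods
  power <- vapply(omega, function(o) {
    tau <- atan2(sum(sin(2 * o * times)), sum(cos(2 * o * times))) / (2 * o)
    ph <- o * (times - tau)
    c_ <- cos(ph); s_ <- sin(ph)
    (sum(w * c_)^2 / sum(c_^2) + sum(w * s_)^2 / sum(s_^2)) / sst
  }, 0)
  out <- data.frame(period = periods, power = power)
  pk <- which.max(power)
  attr(out, "PN") <- power[pk]
  attr(out, "period_at_peak") <- periods[pk]
  out
}

#' Permutation significance of the periodogram peak
#'
#' Permutes the series values over the fixed observation times and compares
#' peak powers: `p = (#\{PN_perm >= PN_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams lomb_scargle
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @return list: `p`, `PN`, `period_at_peak`.
#' @export
peak_significance <- function(values, times, n_perm = 999, seed = NULL,
                              periods = NULL, oversample = 4) {
  if (n_perm < 19) stop("n_perm must be >= 19")
  keep <- is.finite(values) & is.finite(times)
  values <- values[keep]; times <- times[keep]
  if (is.null(periods)) periods <- default_period_grid(times, oversample)
  obs <- lomb_scargle(values, times, periods)
  pn_obs <- attr(obs, "PN")
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(r) {
      attr(lomb_scargle(sample(values), times, periods), "PN") >= pn_obs
    }, logical(1)))
  })
  list(p = (exceed + 1) / (n_perm + 1), PN = pn_obs,
       period_at_peak = attr(obs, "period_at_peak"))
}

#' Call seasonal ASVs from periodogram records
#'
#' An ASV is seasonal when PN exceeds `pn_min`, the permutation p-value is
#' below `p_max` and the peak period falls inside the annual window
#' (defaults PN > 0.2, p < 0.01, period in [10, 14] months).
#'
#' @param records data.frame with columns `PN`, `p`, `period`.
#' @param pn_min,p_max,period_window the three criteria.
#' @return `records` with a logical `seasonal` column.
#' @export
call_seasonal <- function(records, pn_min = 0.2, p_max = 0.01,
                          period_window = c(10, 14)) {
  records$seasonal <- records$PN > pn_min & records$p < p_max &
    records$period >= period_window[1] & records$period <= period_window[2]
  records
}

#' Calendar month of maximal abundance
#'
#' Averages the series within each calendar month across years and returns
#' the month (1-12) with the largest mean; ties go to the earliest month.
#'
#' @param values numeric series.
#' @param dates matching `Date` vector.
#' @return integer month in 1..12.
#' @export
peak_month <- function(values, dates) {
  stopifnot(length(values) > 0, length(values) == length(dates))
  mo <- as.integer(format(as.Date(dates), "%m"))
  means <- tapply(values, mo, mean)
  as.integer(names(means)[which.max(means)])
}

#' Seasonality screen of a community table
#'
#' Applies the occupancy filter, converts to relative abundances, runs the
#' Lomb-Scargle periodogram with permutation significance per ASV on the
#' decimal-month time axis, calls seasonal ASVs, and records each ASV's
#' peak calendar month.
#'
#' @param table samples x ASVs counts (rarefied recommended).
#' @param meta metadata with `sample_id` and `date`.
#' @param n_perm permutations per ASV.
#' @param seed integer seed.
#' @param min_frac occupancy threshold (see [occurrence_filter()]).
#' @param pn_min,p_max,period_window seasonal-call criteria.
#' @param oversample periodogram grid oversampling.
#' @return data.frame, one row per retained ASV: asv_id, occupancy, PN,
#'   period, p, seasonal, peak_month.
#' @export
seasonality_analysis <- function(table, meta, n_perm = 999, seed = NULL,
                                 min_frac = 0.10, pn_min = 0.2, p_max = 0.01,
                                 period_window = c(10, 14), oversample = 4) {
  idx <- match(rownames(table), meta$sample_id)
  if (anyNA(idx)) stop("table samples missing from metadata")
  dates <- meta$date[idx]
  times <- months_since(dates)
  keep <- occurrence_filter(table, min_frac)
  if (!length(keep)) stop("no ASVs pass the occupancy filter")
  f <- rel_abund(table)
  periods <- default_period_grid(times, oversample)
  rows <- lapply(seq_along(keep), function(i) {
    a <- keep[i]
    y <- f[, a]
    ps <- peak_significance(y, times, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL else sub_seed(seed, i),
                            periods = periods)
    data.frame(asv_id = a, occupancy = mean(table[, a] > 0), PN = ps$PN,
               period = ps$period_at_peak, p = ps$p,
               peak_month = peak_month(y, dates), stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  call_seasonal(rec, pn_min = pn_min, p_max = p_max, period_window = period_window)
}
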