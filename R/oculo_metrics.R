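#' Low-pass filter and differentiate an eye/head trace
#'
#' Position signals are zero-phase low-pass filtered (4th-order
#' Butterworth, 40 Hz cut-off, forward-backward) and differentiated by
#' central differences to velocity in deg/s. Output has the same length as
#' the input; the first and last samples use one-sided differences, and
#' analyses downstream trim a 200 ms edge guard where the zero-phase
#' filter's startup transient lives.
#'
#' @param trace an `oculo_trace` with uniform 1 kHz sampling.
#' @param cutoff_hz low-pass cut-off, Hz.
#' @return the trace with `head_vel` and `eye_vel` (deg/s) added and
#'   `preprocessed = TRUE`.
#' @export
preprocess_trace <- function(trace, cutoff_hz = 40) {
  if (!inherits(trace, "oculo_trace"))
    stop("`trace` must be an oculo_trace", call. = FALSE)
  dt <- diff(trace$time)
  if (max(abs(dt - dt[1])) > 1e-9)
    stop("sampling error: time stamps are not uniform", call. = FALSE)
  fs <- 1 / dt[1]
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  lp <- function(x) as.numeric(signal::filtfilt(bf, x))
  deriv <- function(x) {
    n <- length(x)
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    v[1] <- (x[2] - x[1]) * fs
    v[n] <- (x[n] - x[n - 1]) * fs
    v
  }
  trace$head_pos_f <- lp(trace$head_pos)
  trace$eye_pos_f <- lp(trace$eye_pos)
  trace$head_vel <- deriv(trace$head_pos_f)
  trace$eye_vel <- deriv(trace$eye_pos_f)
  trace$fs <- fs
  trace$preprocessed <- TRUE
  trace
}

edge_guard_s <- 0.2

#' Segment quick phases / saccades out of a velocity trace
#'
#' Samples whose eye velocity deviates from a local slow-phase estimate
#' (running median, 201 ms window) by more than `vel_threshold` are flagged,
#' padded by a guard window on both sides, merged, and excluded; spans
#' shorter than `min_duration_ms` are treated as noise spikes and not
#' excluded. The remainder of the analysed span (which omits a 200 ms
#' filter-transient guard at each end) is retained as slow phase.
#'
#' @param trace a preprocessed `oculo_trace`.
#' @param vel_threshold deviation threshold, deg/s.
#' @param min_duration_ms minimum excluded-interval duration, ms.
#' @param guard_ms padding added around each detection, ms.
#' @return a `slow_phase_segments` object: data.frames `retained` and
#'   `excluded` of `(start_s, end_s)` intervals covering the analysed span.
#' @export
segment_quick_phases <- function(trace, vel_threshold = 50,
                                 min_duration_ms = 10, guard_ms = 20) {
  if (is.null(trace$preprocessed))
    stop("run preprocess_trace() first", call. = FALSE)
  if (vel_threshold <= 0)
    stop("`vel_threshold` must be positive", call. = FALSE)
  fs <- trace$fs
  n <- length(trace$time)
  span <- c(edge_guard_s, max(trace$time) - edge_guard_s)
  idx <- which(trace$time >= span[1] & trace$time <= span[2])
  v <- trace$eye_vel[idx]
  k <- 2L * floor(0.201 * fs / 2) + 1L
  base <- runmed(v, k, endrule = "median")
  bad <- abs(v - base) > vel_threshold
  # guard padding
  g <- round(guard_ms / 1000 * fs)
  if (any(bad) && g > 0) {
    on <- which(bad)
    padded <- unique(unlist(lapply(on, function(i)
      max(1L, i - g):min(length(bad), i + g))))
    bad[padded] <- TRUE
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- round(min_duration_ms / 1000 * fs)
  excl <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= min_len)
      excl <- rbind(excl, data.frame(
        start_s = trace$time[idx[starts[j]]],
        end_s = trace$time[idx[ends[j]]]))
  }
  keep_mask <- rep(TRUE, length(idx))
  for (j in seq_len(nrow(excl)))
    keep_mask[trace$time[idx] >= excl$start_s[j] &
                trace$time[idx] <= excl$end_s[j]] <- FALSE
  rk <- rle(keep_mask)
  ends_k <- cumsum(rk$lengths)
  starts_k <- ends_k - rk$lengths + 1L
  ret <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (j in seq_along(rk$values)) {
    if (rk$values[j])
      ret <- rbind(ret, data.frame(
        start_s = trace$time[idx[starts_k[j]]],
        end_s = trace$time[idx[ends_k[j]]]))
  }
  structure(list(retained = ret, excluded = excl, span_s = span),
            class = "slow_phase_segments")
}

retained_mask <- function(trace, segments) {
  m <- rep(FALSE, length(trace$time))
  for (j in seq_len(nrow(segments$retained)))
    m[trace$time >= segments$retained$start_s[j] &
        trace$time <= segments$retained$end_s[j]] <- TRUE
  m
}

#' aVOR gain and phase from a sinusoidal trial
#'
#' Least-squares fit of the retained eye slow-phase velocity to
#' `a sin + b cos` at the stimulus frequency; gain is the fitted eye
#' velocity amplitude divided by the head velocity amplitude (fitted the
#' same way on the full head trace), phase is the eye-head phase difference
#' after compensation (0 for ideal counter-rotation).
#'
#' @param trace a preprocessed aVOR `oculo_trace`.
#' @param segments matching `slow_phase_segments`.
#' @return a `vor_result`: list with `freq`, `gain`, `phase_deg`,
#'   `n_cycles`.
#' @export
avor_gain <- function(trace, segments) {
  if (trace$kind != "avor") stop("trace kind must be 'avor'", call. = FALSE)
  freq <- trace$stimulus$freq_hz
  m <- retained_mask(trace, segments)
  n_cycles <- floor(sum(m) / trace$fs * freq)
  if (n_cycles < 3)
    stop("insufficient data: fewer than 3 stimulus cycles retained",
         call. = FALSE)
  w <- 2 * pi * freq
  fit_sin <- function(y, t) {
    X <- cbind(1, sin(w * t), cos(w * t))
    cf <- qr.coef(qr(X), y)
    list(amp = sqrt(cf[2]^2 + cf[3]^2), ph = atan2(cf[3], cf[2]))
  }
  span_m <- trace$time >= segments$span_s[1] & trace$time <= segments$span_s[2]
  head <- fit_sin(trace$head_vel[span_m], trace$time[span_m])
  eye <- fit_sin(trace$eye_vel[m], trace$time[m])
  phase <- (eye$ph - head$ph - pi) * 180 / pi
  phase <- ((phase + 180) %% 360) - 180
  structure(list(freq = freq, gain = unname(eye$amp / head$amp),
                 phase_deg = unname(phase), n_cycles = n_cycles),
            class = "vor_result")
}

#' Normalise a lesioned VOR result to a baseline result
#' @param lesioned,baseline `vor_result` objects at the same frequency.
#' @return normalised gain in percent.
#' @export
normalize_gain <- function(lesioned, baseline) {
  if (abs(lesioned$freq - baseline$freq) > 1e-9)
    stop("results are at different stimulus frequencies", call. = FALSE)
  100 * lesioned$gain / baseline$gain
}

#' MOR bias and modulation from an OVAR trial
#'
#' Over whole rotation periods, the retained slow-phase eye velocity is fit
#' to `b0 + a sin + b cos` at the rotation frequency; `bias` is the
#' intercept (steady compensatory component) and `modulation` the amplitude
#' of the periodic component.
#'
#' @param trace a preprocessed OVAR `oculo_trace`.
#' @param segments matching `slow_phase_segments`.
#' @return a `mor_result`: list with `bias_dps`, `modulation_dps`,
#'   `n_periods`.
#' @export
mor_bias <- function(trace, segments) {
  if (trace$kind != "ovar") stop("trace kind must be 'ovar'", call. = FALSE)
  period <- 360 / trace$stimulus$rot_vel_dps
  span <- segments$span_s
  n_periods <- floor((span[2] - span[1]) / period)
  if (n_periods < 3)
    stop("insufficient data: steady-state span shorter than 3 rotation ",
         "periods", call. = FALSE)
  t_end <- span[1] + n_periods * period
  m <- retained_mask(trace, segments) & trace$time <= t_end
  w <- 2 * pi / period
  X <- cbind(1, sin(w * trace$time[m]), cos(w * trace$time[m]))
  cf <- qr.coef(qr(X), trace$eye_vel[m])
  structure(list(bias_dps = unname(cf[1]),
                 modulation_dps = unname(sqrt(cf[2]^2 + cf[3]^2)),
                 n_periods = n_periods),
            class = "mor_result")
}

#' Spontaneous vestibular nystagmus rate
#'
#' Beats per minute is the number of excluded (quick-phase) intervals
#' divided by the trace duration in minutes; the slow-phase direction
#' comes from the sign of the mean retained eye velocity (negative =
#' ipsilesional by the package's sign convention), `"none"` below a 0.5
#' deg/s floor.
#'
#' @param trace a preprocessed spontaneous `oculo_trace`.
#' @param segments matching `slow_phase_segments`.
#' @return a `nystagmus_result`: list with `beats_per_min`,
#'   `slow_phase_direction`, `mean_slow_vel_dps`.
#' @export
svn_rate <- function(trace, segments) {
  if (trace$kind != "spontaneous")
    stop("trace kind must be 'spontaneous'", call. = FALSE)
  dur_min <- (max(trace$time) - min(trace$time)) / 60
  m <- retained_mask(trace, segments)
  mv <- mean(trace$eye_vel[m])
  dir <- if (abs(mv) < 0.5) "none" else
    if (mv < 0) "ipsilesional" else "contralesional"
  structure(list(beats_per_min = nrow(segments$excluded) / dur_min,
                 slow_phase_direction = dir, mean_slow_vel_dps = mv),
            class = "nystagmus_result")
}
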