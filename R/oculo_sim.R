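#' Construct an oculomotor preset
#'
#' Bundles the generating parameters for simulated eye-movement trials of
#' one experimental group: aVOR gain and phase, the steady otolithic
#' (maculo-ocular) slow-phase velocity bias probed by off-vertical axis
#' rotation, the spontaneous-nystagmus beat rate and slow-phase drift, and
#' measurement noise. Post-lesion preset gains are stored as the absolute
#' gain (baseline gain times the group's normalised fraction), so the
#' normalised time course is recovered by dividing by the baseline preset.
#'
#' @param label preset name.
#' @param gain aVOR gain in `[0, 1]`.
#' @param phase_deg aVOR phase lead of the eye response, degrees.
#' @param bias_dps steady MOR slow-phase velocity bias, deg/s.
#' @param mor_modulation_dps amplitude of the periodic OVAR component, deg/s.
#' @param beat_rate_bpm spontaneous nystagmus quick phases per minute.
#' @param slow_phase_vel_dps spontaneous slow-phase drift speed, deg/s.
#' @param quick_phase_amp_deg resetting quick-phase amplitude for aVOR/OVAR
#'   trials, degrees.
#' @param noise_sd_deg Gaussian position noise sd, degrees.
#' @param drift_side `-1` (ipsilesional, negative drift) or `+1`.
#' @return an object of class `oculo_preset`.
#' @export
oculo_preset <- function(label, gain, phase_deg = 0, bias_dps = 0,
                         mor_modulation_dps = 3, beat_rate_bpm = 0,
                         slow_phase_vel_dps = 0, quick_phase_amp_deg = 12,
                         noise_sd_deg = 0.1, drift_side = -1) {
  if (gain < 0) stop("`gain` must be >= 0", call. = FALSE)
  if (beat_rate_bpm < 0) stop("`beat_rate_bpm` must be >= 0", call. = FALSE)
  if (!drift_side %in% c(-1, 1))
    stop("`drift_side` must be -1 or +1", call. = FALSE)
  structure(as.list(environment()), class = "oculo_preset")
}

#' List / load shipped oculomotor presets
#' @return `list_oculo_presets()`: character vector of labels.
#' @export
list_oculo_presets <- function() {
  cfg <- yaml::read_yaml(file.path(preset_dir(), "oculo_presets.yaml"))
  vapply(cfg, function(p) p$label, character(1))
}

#' @rdname list_oculo_presets
#' @param label shipped preset label or path to a YAML file.
#' @export
load_oculo_preset <- function(label) {
  if (file.exists(label)) p <- yaml::read_yaml(label)
  else {
    cfg <- yaml::read_yaml(file.path(preset_dir(), "oculo_presets.yaml"))
    hit <- Filter(function(p) identical(p$label, label), cfg)
    if (length(hit) == 0L)
      stop(sprintf("unknown oculo preset '%s'; shipped presets: %s", label,
                   paste(list_oculo_presets(), collapse = ", ")),
           call. = FALSE)
    p <- hit[[1]]
  }
  do.call(oculo_preset, p)
}

new_trace <- function(time, head_pos, eye_pos, kind, stimulus, seed) {
  structure(list(time = time, head_pos = head_pos, eye_pos = eye_pos,
                 kind = kind, stimulus = stimulus, seed = as.integer(seed),
                 fs = 1000), class = "oculo_trace")
}

#' @export
print.oculo_trace <- function(x, ...) {
  cat(sprintf("<oculo_trace %s: %.1f s at %g Hz>\n", x$kind,
              max(x$time), x$fs))
  invisible(x)
}

# Shared quick-phase injector: integrates slow-phase velocity sample by
# sample and, whenever eye eccentricity exceeds `bound` deg, overrides the
# next `dur_s` with a half-cosine resetting movement of amplitude `amp`
# towards centre.
integrate_with_quick_phases <- function(sp_vel, dt, bound = 15, amp = 12,
                                        dur_s = 0.030) {
  n <- length(sp_vel)
  eye <- numeric(n)
  qp_len <- max(2L, round(dur_s / dt))
  qp_onsets <- integer(0)
  i <- 2L
  while (i <= n) {
    eye[i] <- eye[i - 1L] + 0.5 * (sp_vel[i - 1L] + sp_vel[i]) * dt
    if (abs(eye[i]) > bound) {
      j <- min(n, i + qp_len - 1L)
      len <- j - i + 1L
      prof <- (1 - cos(pi * seq_len(len) / len)) / 2  # smooth 0 -> 1
      eye[i:j] <- eye[i] - sign(eye[i]) * amp * prof
      qp_onsets <- c(qp_onsets, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  list(eye = eye, qp_onsets = qp_onsets)
}

#' Simulate a sinusoidal aVOR trial
#'
#' Head position is sinusoidal at `freq` with peak angular velocity
#' `peak_vel`; the eye slow-phase velocity is `-gain` times the head
#' velocity, phase-shifted, with resetting quick phases injected whenever
#' eye eccentricity exceeds 15 deg, and Gaussian position noise added.
#'
#' @param preset an `oculo_preset`.
#' @param freq stimulus frequency, Hz (0.05-2).
#' @param peak_vel peak head velocity, deg/s.
#' @param duration trial length, s (>= 10).
#' @param seed integer seed.
#' @return an `oculo_trace` (1 kHz sampling).
#' @export
simulate_avor <- function(preset, freq = 0.5, peak_vel = 30, duration = 20,
                          seed = 1L) {
  if (!inherits(preset, "oculo_preset"))
    stop("`preset` must be an oculo_preset", call. = FALSE)
  if (freq < 0.05 || freq > 2)
    stop("`freq` must lie in [0.05, 2] Hz", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  fs <- 1000; dt <- 1 / fs
  t <- seq(0, duration, by = dt)
  w <- 2 * pi * freq
  # cosine velocity profile: head position is a centred sinusoid
  head_vel <- peak_vel * cos(w * t)
  head_pos <- c(0, cumsum(0.5 * (head_vel[-1] + head_vel[-length(head_vel)]) *
                            dt))
  ph <- preset$phase_deg * pi / 180
  sp_vel <- -preset$gain * peak_vel * cos(w * t + ph)
  res <- integrate_with_quick_phases(sp_vel, dt,
                                     amp = preset$quick_phase_amp_deg)
  eye <- res$eye
  with_seed(seed, {
    eye <- eye + rnorm(length(eye), 0, preset$noise_sd_deg)
  })
  tr <- new_trace(t, head_pos, eye, "avor",
                  list(freq_hz = freq, peak_vel_dps = peak_vel), seed)
  tr$qp_onsets_s <- t[res$qp_onsets]
  tr
}

#' Simulate a spontaneous-nystagmus recording
#'
#' No head motion; the eye drifts at the preset slow-phase velocity toward
#' the drift side and is reset to centre by quick phases. The number of
#' quick phases is fixed by construction at `round(beat_rate * duration /
#' 60)`; their times are a jittered regular grid (a dispersed renewal
#' process), which keeps beat amplitudes -- and hence quick-phase peak
#' velocities -- bounded away from zero.
#'
#' @param preset an `oculo_preset`.
#' @param duration recording length, s (>= 60 for rate analysis).
#' @param seed integer seed.
#' @return an `oculo_trace` with the true beat count in `$n_beats`.
#' @export
simulate_spontaneous <- function(preset, duration = 120, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  fs <- 1000; dt <- 1 / fs
  t <- seq(0, duration, by = dt)
  n <- length(t)
  drift <- preset$drift_side * preset$slow_phase_vel_dps
  n_beats <- round(preset$beat_rate_bpm * duration / 60)
  with_seed(seed, {
    beat_t <- if (n_beats > 0) {
      interval <- duration / n_beats
      sort((seq_len(n_beats) - 0.5 + runif(n_beats, -0.25, 0.25)) * interval)
    } else numeric(0)
    eye <- numeric(n)
    qp_len <- max(2L, round(0.030 / dt))
    beat_i <- pmin(pmax(round(beat_t / dt) + 1L, 2L), n - qp_len)
    last <- 1L
    for (b in beat_i) {
      seg <- last:b
      eye[seg] <- eye[last] + drift * (seg - last) * dt
      j <- b + qp_len - 1L
      prof <- (1 - cos(pi * seq_len(qp_len) / qp_len)) / 2
      eye[b:j] <- eye[b] - eye[b] * prof  # full reset to centre
      last <- j
    }
    if (last < n) eye[last:n] <- eye[last] + drift * ((last:n) - last) * dt
    eye <- eye + rnorm(n, 0, preset$noise_sd_deg)
  })
  tr <- new_trace(t, numeric(n), eye, "spontaneous", NULL, seed)
  tr$n_beats <- length(beat_i)
  tr$drift_side <- preset$drift_side
  tr
}

#' Simulate an off-vertical axis rotation (OVAR) trial
#'
#' Constant-velocity rotation about an axis tilted 17 deg from vertical;
#' the horizontal eye slow-phase velocity is the steady otolithic bias plus
#' a sinusoidal modulation at the rotation period, with resetting quick
#' phases and position noise. Lesioned presets carry a bias scaled toward
#' zero.
#'
#' @param preset an `oculo_preset`.
#' @param rot_vel rotation velocity, deg/s (period `360 / rot_vel` s).
#' @param duration trial length, s.
#' @param seed integer seed.
#' @return an `oculo_trace`.
#' @export
simulate_ovar <- function(preset, rot_vel = 50, duration = 45, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  fs <- 1000; dt <- 1 / fs
  t <- seq(0, duration, by = dt)
  w <- 2 * pi * rot_vel / 360
  sp_vel <- preset$bias_dps + preset$mor_modulation_dps * sin(w * t)
  res <- integrate_with_quick_phases(sp_vel, dt,
                                     amp = preset$quick_phase_amp_deg)
  eye <- res$eye
  with_seed(seed, {
    eye <- eye + rnorm(length(eye), 0, preset$noise_sd_deg)
  })
  tr <- new_trace(t, rot_vel * t, eye, "ovar",
                  list(rot_vel_dps = rot_vel, tilt_deg = 17,
                       toward_intact_side = TRUE), seed)
  tr$qp_onsets_s <- t[res$qp_onsets]
  tr
}

#' Write / read a trace as CSV plus JSON stimulus sidecar
#' @param trace an `oculo_trace`.
#' @param path CSV path (`<path>.json` holds kind/stimulus metadata).
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time, head_pos_deg = trace$head_pos,
                       eye_pos_deg = trace$eye_pos),
            path, row.names = FALSE)
  jsonlite::write_json(list(kind = trace$kind, stimulus = trace$stimulus,
                            fs_hz = trace$fs, seed = trace$seed),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- read.csv(path)
  tr <- new_trace(df$time_s, df$head_pos_deg, df$eye_pos_deg,
                  meta$kind, meta$stimulus, meta$seed)
  tr$fs <- meta$fs_hz
  tr
}
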