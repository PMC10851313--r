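#' Noise configuration for the EEG synthesizer
#'
#' Background activity is a sum of 1/f ("pink", power-spectral slope
#' `slope`) and white noise, generated independently per channel and scaled
#' so the combined RMS equals `rms_total` microvolts. `pink_fraction` is the
#' share of the total power carried by the 1/f component.
#'
#' @param rms_total Combined noise RMS in microvolts (0 disables noise).
#' @param slope Power-spectral slope of the coloured component.
#' @param pink_fraction Fraction of noise power assigned to the 1/f part.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(rms_total = 10, slope = -1, pink_fraction = 0.8) {
  stopifnot(rms_total >= 0, pink_fraction >= 0, pink_fraction <= 1)
  structure(list(rms_total = rms_total, slope = slope,
                 pink_fraction = pink_fraction), class = "noise_config")
}

default_kernel_windows <- function() {
  list(reward = c(-4, 0.2), anim_start = c(0, 0.8), anim_end = c(0, 0.8))
}

gauss_bump <- function(x, centre, width) exp(-((x - centre) / width)^2)

#' Ground truth for forward EEG synthesis
#'
#' Defines the response kernels, scalp topographies and per-condition gains
#' injected by [synthesize_eeg()], kept so that recovery can be scored
#' against them. Defaults: a smooth negative-going reward kernel ramping up
#' towards the time of maximum possible reward (a stimulus-preceding-
#' negativity-like shape, peak `-reward_amp_uv` at lag 0) with a
#' centro-parietal topography peaking at CP2; biphasic transients, maximal
#' at the vertex, for the start and end of the bar animation. Condition
#' gains scale the reward kernel by outcome predictability; the default
#' `(high = 0.5, medium = 1, low = 1.2)` makes the response smallest for the
#' most predictable outcomes.
#'
#' @param condition_gains Named multipliers for the reward kernel by
#'   predictability level.
#' @param reward_amp_uv Peak amplitude (microvolts, applied negatively) of
#'   the reward kernel.
#' @param srate Sample rate (Hz) of the kernels.
#' @param noise A [noise_config()] stored with the truth.
#' @param seed Seed used when synthesizing noise from this truth.
#' @param montage Scalp montage data frame (see [standard_montage()]).
#' @return List of class `ground_truth` with `kernels`, `lags`,
#'   `topographies`, `condition_gains`, `noise`, `seed`, `srate`, `montage`.
#' @export
make_ground_truth <- function(condition_gains = c(high = 0.5, medium = 1, low = 1.2),
                              reward_amp_uv = 5,
                              srate = 250,
                              noise = noise_config(),
                              seed = 1L,
                              montage = standard_montage()) {
  stopifnot(all(c("high", "medium", "low") %in% names(condition_gains)))
  win <- default_kernel_windows()
  lags <- lapply(win, function(w) seq(w[1], w[2], by = 1 / srate))
  kernels <- list(
    # slow ramp peaking at the moment of maximum possible reward
    reward = -reward_amp_uv * gauss_bump(lags$reward, 0, 1.6),
    # biphasic visual/motor transients at animation onset and offset
    anim_start = -4 * gauss_bump(lags$anim_start, 0.09, 0.03) +
                  7 * gauss_bump(lags$anim_start, 0.22, 0.06) -
                  2 * gauss_bump(lags$anim_start, 0.45, 0.10),
    anim_end   = -3 * gauss_bump(lags$anim_end, 0.10, 0.03) +
                  8 * gauss_bump(lags$anim_end, 0.30, 0.08)
  )
  topo <- function(cx, cy, width) {
    w <- gauss_bump(sqrt((montage$x - cx)^2 + (montage$y - cy)^2), 0, width)
    w <- w / max(w)
    names(w) <- montage$label
    w
  }
  cp2 <- montage[montage$label == "CP2", ]
  topographies <- list(
    reward = topo(cp2$x, cp2$y, 0.6),
    anim_start = topo(0, 0, 0.7),
    anim_end = topo(0, -0.1, 0.7)
  )
  structure(list(kernels = kernels, lags = lags, topographies = topographies,
                 condition_gains = condition_gains, noise = noise,
                 seed = as.integer(seed), srate = srate, montage = montage),
            class = "ground_truth")
}

mastoid_labels <- function() c("M1", "M2")

# animation sample indices and reward-aligned lags (samples); shared by the
# synthesizer and the design-matrix builder so truth and model agree on the
# "modeled times"
animation_samples <- function(trial, srate, n_samples) {
  i0 <- ceiling(trial$t_anim_start * srate) + 1
  i1 <- min(floor(trial$t_anim_end * srate) + 1, n_samples)
  if (i1 < i0 || i0 > n_samples) return(NULL)
  idx <- i0:i1
  align <- round(trial$t_max_reward * srate) + 1
  list(idx = idx, lag = idx - align)
}

#' Forward-generate a continuous EEG recording
#'
#' Superimposes, per trial, the ground-truth kernels at their event times --
#' the reward kernel aligned to the time of maximum possible reward, scaled
#' by that trial's predictability gain, and contributing only at samples
#' inside the bar-animation interval -- each multiplied by its scalp
#' topography, then adds 1/f plus white noise. The two mastoid channels
#' carry noise only.
#'
#' @param session A [simulate_session()] result.
#' @param truth A [make_ground_truth()] object at the same sample rate.
#' @param noise Optional [noise_config()] overriding the one in `truth`.
#' @param seed Optional seed overriding `truth$seed`.
#' @return An `eeg_recording`: `data` (channels x samples, microvolts),
#'   `srate`, `labels`, `events` data frame, logical `mask` (all `FALSE`),
#'   and the originating `session`/`truth` references.
#' @export
synthesize_eeg <- function(session, truth = make_ground_truth(),
                           noise = NULL, seed = NULL) {
  stopifnot(inherits(session, "gnomes_session"),
            inherits(truth, "ground_truth"))
  srate <- truth$srate
  if (is.null(noise)) noise <- truth$noise
  if (is.null(seed)) seed <- truth$seed
  n <- ceiling((session$duration + 2) * srate)
  labels <- c(truth$montage$label, mastoid_labels())
  n_scalp <- nrow(truth$montage)
  data <- matrix(0, length(labels), n, dimnames = list(labels, NULL))

  v <- list(reward = numeric(n), anim_start = numeric(n), anim_end = numeric(n))
  k <- truth$kernels
  n_start <- length(k$anim_start)
  n_end <- length(k$anim_end)
  lag0_reward <- round(truth$lags$reward[1] * srate)  # first lag, samples
  for (j in seq_len(nrow(session$trials))) {
    tr <- session$trials[j, ]
    s0 <- round(tr$t_anim_start * srate) + 1
    take <- seq_len(min(n_start, n - s0 + 1))
    v$anim_start[s0 + take - 1] <- v$anim_start[s0 + take - 1] + k$anim_start[take]
    e0 <- round(tr$t_anim_end * srate) + 1
    take <- seq_len(min(n_end, n - e0 + 1))
    v$anim_end[e0 + take - 1] <- v$anim_end[e0 + take - 1] + k$anim_end[take]

    an <- animation_samples(tr, srate, n)
    if (!is.null(an)) {
      pos <- an$lag - lag0_reward + 1
      ok <- pos >= 1 & pos <= length(k$reward)
      gain <- truth$condition_gains[[tr$predictability]]
      v$reward[an$idx[ok]] <- v$reward[an$idx[ok]] + gain * k$reward[pos[ok]]
    }
  }
  for (type in names(v)) {
    data[seq_len(n_scalp), ] <- data[seq_len(n_scalp), ] +
      outer(truth$topographies[[type]], v[[type]])
  }

  if (noise$rms_total > 0) {
    set.seed(seed)
    data <- data + t(noise_matrix(n, length(labels), noise))
  }

  events <- data.frame(
    trial = session$trials$trial,
    t_anim_start = session$trials$t_anim_start,
    t_anim_end = session$trials$t_anim_end,
    t_max_reward = session$trials$t_max_reward,
    predictability = session$trials$predictability,
    stringsAsFactors = FALSE)
  new_recording(data, srate, labels, events = events,
                meta = list(participant_id = session$config$participant_id,
                            truth_seed = seed))
}

new_recording <- function(data, srate, labels, events = NULL, mask = NULL,
                          meta = list()) {
  stopifnot(nrow(data) == length(labels))
  if (is.null(mask)) mask <- rep(FALSE, ncol(data))
  stopifnot(length(mask) == ncol(data))
  rownames(data) <- labels
  structure(list(data = data, srate = srate, labels = labels,
                 events = events, mask = mask, units = "uV", meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  cat(sprintf("  artifact mask: %.2f%% of samples flagged\n",
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
plot.eeg_recording <- function(x, channels = 1:6, t_range = NULL, ...) {
  if (is.null(t_range)) t_range <- c(0, min(10, ncol(x$data) / x$srate))
  idx <- seq(floor(t_range[1] * x$srate) + 1, floor(t_range[2] * x$srate))
  tt <- (idx - 1) / x$srate
  sel <- if (is.character(channels)) match(channels, x$labels) else channels
  offs <- (seq_along(sel) - 1) * 4 * stats::sd(x$data[sel, idx])
  graphics::matplot(tt, t(x$data[sel, idx, drop = FALSE]) +
                      rep(offs, each = length(idx)),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "amplitude (uV, offset)", ...)
  graphics::legend("topright", legend = x$labels[sel], lty = 1,
                   col = seq_along(sel), cex = 0.7, bty = "n")
  invisible(x)
}

#' Inject high-amplitude square-pulse artifacts
#'
#' Adds `n_events` square pulses (peak-to-peak `amplitude_uv`, one randomly
#' chosen channel each) at random positions, to exercise the sliding-window
#' artifact detector. Injected spans are recorded in the returned object's
#' `meta$artifact_spans`.
#'
#' @param recording An `eeg_recording`.
#' @param n_events Number of pulses (0 returns the recording unchanged).
#' @param amplitude_uv Peak-to-peak pulse amplitude in microvolts.
#' @param duration_s Pulse duration in seconds.
#' @param seed Seed for pulse placement.
#' @return The modified `eeg_recording`.
#' @export
inject_artifacts <- function(recording, n_events = 5, amplitude_uv = 200,
                             duration_s = 0.2, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (n_events == 0) return(recording)
  set.seed(seed)
  n <- ncol(recording$data)
  w <- max(2, round(duration_s * recording$srate))
  half <- w %/% 2
  starts <- sort(sample.int(n - w, n_events))
  chans <- sample.int(nrow(recording$data), n_events, replace = TRUE)
  for (i in seq_len(n_events)) {
    s <- starts[i]
    pulse <- c(rep(amplitude_uv / 2, half), rep(-amplitude_uv / 2, w - half))
    recording$data[chans[i], s:(s + w - 1)] <-
      recording$data[chans[i], s:(s + w - 1)] + pulse
  }
  spans <- data.frame(start = starts, end = starts + w - 1, channel = chans)
  recording$meta$artifact_spans <-
    rbind(recording$meta$artifact_spans, spans)
  recording
}
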