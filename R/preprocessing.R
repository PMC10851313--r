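#' Resample a recording (anti-aliased)
#'
#' Downsamples every channel to `target` Hz. Integer decimation uses an
#' anti-aliasing FIR low-pass ([signal::decimate]); rational ratios fall back
#' to polyphase resampling ([signal::resample]). Upsampling is rejected.
#' Event times are stored in seconds and therefore carry over unchanged; the
#' artifact mask is collapsed block-wise (a low-rate sample is flagged if any
#' of its high-rate constituents was).
#'
#' @param recording An `eeg_recording`.
#' @param target Target sample rate in Hz.
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(recording, target = 250) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (target > recording$srate) stop("upsampling is not supported")
  if (target == recording$srate) return(recording)
  ratio <- recording$srate / target
  n_new <- if (ratio == round(ratio)) ceiling(ncol(recording$data) / ratio) else
    ceiling(ncol(recording$data) * target / recording$srate)
  out <- matrix(0, nrow(recording$data), n_new)
  for (ch in seq_len(nrow(recording$data))) {
    x <- recording$data[ch, ]
    y <- if (ratio == round(ratio)) {
      signal::decimate(x, q = as.integer(ratio), ftype = "fir")
    } else {
      signal::resample(x, p = target, q = recording$srate)
    }
    out[ch, ] <- y[seq_len(n_new)]
  }
  mask <- recording$mask
  if (any(mask)) {
    grp <- floor((seq_along(mask) - 1) / ratio) + 1
    mask <- as.logical(tapply(mask, grp, any))[seq_len(n_new)]
  } else {
    mask <- rep(FALSE, n_new)
  }
  new_recording(out, target, recording$labels, events = recording$events,
                mask = mask, meta = recording$meta)
}

notch_coefficients <- function(f0, srate, q = 35) {
  w0 <- 2 * pi * f0 / srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase filtering per channel: a Butterworth band-pass (default
#' 0.1--30 Hz, 4th-order edges) combined with a narrow notch biquad
#' (default 50 Hz). The squared-magnitude response of the cascade -- the
#' response a forward-backward (filtfilt) application realizes -- is applied
#' in the frequency domain over a zero-padded FFT grid, which gives the
#' zero-phase result for all channels without recursive edge transients.
#' The channel mean is removed first; DC lies outside the passband.
#'
#' @param recording An `eeg_recording`.
#' @param band Passband edges in Hz (`c(low, high)`); low must be positive
#'   and high below Nyquist.
#' @param notch Notch frequency in Hz, or `NULL` to skip.
#' @param order Butterworth order of each band edge.
#' @param notch_q Quality factor of the notch biquad.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_and_notch <- function(recording, band = c(0.1, 30), notch = 50,
                               order = 4, notch_q = 35) {
  stopifnot(inherits(recording, "eeg_recording"),
            band[1] > 0, band[1] < band[2], band[2] < recording$srate / 2)
  srate <- recording$srate
  nyq <- srate / 2
  n <- ncol(recording$data)
  # pad beyond the ~ (1 / low edge) tail of the zero-phase impulse response
  pad <- ceiling(4 / band[1] * srate)
  m <- stats::nextn(n + 2 * pad, factors = c(2, 3, 5))
  w <- 2 * pi * (seq_len(m) - 1) / m          # digital frequency grid
  z <- exp(-1i * w)
  resp_sq <- function(b, a) {
    H <- (outer(z, 0:(length(b) - 1), `^`) %*% b) /
      (outer(z, 0:(length(a) - 1), `^`) %*% a)
    Mod(drop(H))^2
  }
  bp <- signal::butter(order, band / nyq, type = "pass")
  G <- resp_sq(bp$b, bp$a)
  if (!is.null(notch)) {
    nf <- notch_coefficients(notch, srate, notch_q)
    G <- G * resp_sq(nf$b, nf$a)
  }
  X <- matrix(0, m, nrow(recording$data))
  X[pad + seq_len(n), ] <- t(recording$data) -
    rep(rowMeans(recording$data), each = n)
  Y <- Re(stats::mvfft(stats::mvfft(X) * G, inverse = TRUE)) / m
  recording$data[] <- t(Y[pad + seq_len(n), , drop = FALSE])
  recording
}

#' Re-reference scalp channels to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every scalp channel
#' and drops the mastoids from the recording (they are identically zero
#' after referencing to their own mean up to a channel-independent term).
#'
#' @param recording An `eeg_recording` containing channels `M1` and `M2`.
#' @return The re-referenced, scalp-only `eeg_recording`.
#' @export
rereference_mastoids <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  m <- match(mastoid_labels(), recording$labels)
  if (any(is.na(m))) stop("mastoid channels M1/M2 not found")
  ref <- colMeans(recording$data[m, , drop = FALSE])
  keep <- setdiff(seq_along(recording$labels), m)
  data <- recording$data[keep, , drop = FALSE] -
    matrix(ref, length(keep), ncol(recording$data), byrow = TRUE)
  new_recording(data, recording$srate, recording$labels[keep],
                events = recording$events, mask = recording$mask,
                meta = recording$meta)
}

#' Sliding-window peak-to-peak artifact detection
#'
#' Slides a window (default 2000 ms, step 100 ms) along every channel; if
#' the peak-to-peak difference within a window exceeds `thresh_uv`
#' (microvolts), every sample of that window is flagged. The mask is the
#' union over channels and window positions; windows truncated at the
#' recording tail are still evaluated.
#'
#' @param recording An `eeg_recording`.
#' @param window_ms,step_ms Window length and step in milliseconds
#'   (window must be a multiple of step).
#' @param thresh_uv Peak-to-peak threshold in microvolts.
#' @return Logical vector, one element per sample (`TRUE` = flagged).
#' @export
detect_artifacts <- function(recording, window_ms = 2000, step_ms = 100,
                             thresh_uv = 150) {
  stopifnot(inherits(recording, "eeg_recording"), window_ms >= step_ms)
  n <- ncol(recording$data)
  st <- max(1L, round(step_ms / 1000 * recording$srate))
  w <- max(st, round(window_ms / 1000 * recording$srate))
  if (w %% st != 0) {
    return(detect_artifacts_slow(recording$data, w, st, thresh_uv))
  }
  k <- w %/% st
  n_chunk <- ceiling(n / st)
  pad <- n_chunk * st - n
  flagged_pos <- logical(n_chunk)
  for (ch in seq_len(nrow(recording$data))) {
    x <- c(recording$data[ch, ], rep(NA_real_, pad))
    m <- matrix(x, nrow = st)
    cmax <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
    cmin <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
    # rolling extrema over k chunks starting at each chunk position
    wmax <- cmax; wmin <- cmin
    if (k > 1) for (j in seq_len(k - 1)) {
      idx <- seq_len(n_chunk - j)
      wmax[idx] <- pmax(wmax[idx], cmax[idx + j])
      wmin[idx] <- pmin(wmin[idx], cmin[idx + j])
    }
    flagged_pos <- flagged_pos | (wmax - wmin > thresh_uv)
  }
  mask <- logical(n)
  for (p in which(flagged_pos)) {
    s <- (p - 1) * st + 1
    mask[s:min(s + w - 1, n)] <- TRUE
  }
  mask
}

# direct per-window evaluation; reference path when window %% step != 0
detect_artifacts_slow <- function(data, w, st, thresh) {
  n <- ncol(data)
  mask <- logical(n)
  starts <- seq(1, n, by = st)
  for (s in starts) {
    e <- min(s + w - 1, n)
    seg <- data[, s:e, drop = FALSE]
    if (any(apply(seg, 1, function(x) max(x) - min(x)) > thresh)) {
      mask[s:e] <- TRUE
    }
  }
  mask
}

#' Mask as run-length spans
#'
#' @param mask Logical artifact mask.
#' @return Data frame with `onset_sample`, `offset_sample` (1-based,
#'   inclusive) for each flagged run.
#' @export
mask_spans <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(onset_sample = starts[r$values], offset_sample = ends[r$values])
}

#' Standard preprocessing chain
#'
#' Resample to 250 Hz, band-pass (0.1--30 Hz) + 50 Hz notch, re-reference to
#' the mastoid average, then flag artifacts with the sliding-window
#' peak-to-peak detector. Returns the scalp-only recording with its `mask`
#' field set.
#'
#' @param recording An `eeg_recording` including mastoid channels.
#' @param target_srate Analysis sample rate (Hz).
#' @param band,notch,order Filter settings, see [bandpass_and_notch()].
#' @param window_ms,step_ms,thresh_uv Artifact-detector settings, see
#'   [detect_artifacts()].
#' @return The preprocessed `eeg_recording`.
#' @export
preprocess <- function(recording, target_srate = 250, band = c(0.1, 30),
                       notch = 50, order = 4, window_ms = 2000,
                       step_ms = 100, thresh_uv = 150) {
  rec <- resample_recording(recording, target_srate)
  rec <- bandpass_and_notch(rec, band = band, notch = notch, order = order)
  rec <- rereference_mastoids(rec)
  rec$mask <- rec$mask | detect_artifacts(rec, window_ms = window_ms,
                                          step_ms = step_ms,
                                          thresh_uv = thresh_uv)
  rec
}
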