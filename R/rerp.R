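#' Fit an overlap-corrected regression ERP
#'
#' The central model fit: the continuous preprocessed EEG of one participant
#' is modelled as a linear superposition of finite-impulse-response kernels
#' for the start of the bar animation, the reward-aligned continuous-reward
#' response, and the end of the animation (see [rerp_design()]). The
#' penalized least-squares problem with a first-difference Tikhonov penalty
#' is solved per electrode; the penalty weight is chosen by 10-fold
#' cross-validation over the lambda grid unless supplied. Samples flagged in
#' the recording's artifact mask are excluded from the regression rows.
#'
#' @param recording A preprocessed, scalp-only `eeg_recording`.
#' @param session The `gnomes_session` the recording was generated from (or
#'   a compatible trial table).
#' @param spec An [rerp_design()]; its sample rate must match the recording.
#' @param lambda Penalty weight; `NULL` (default) selects it by
#'   cross-validation.
#' @param lambda_grid,n_folds Cross-validation settings, see
#'   [crossval_lambda()].
#' @param baseline Optional lag window (s) passed to [baseline_correct()],
#'   e.g. `c(-4, -1)`; `NULL` for no baseline correction.
#' @return An object of class `rerp`: per-block electrode x lag coefficient
#'   matrices (microvolts per unit regressor) plus fit metadata.
#' @export
fit_rerp <- function(recording, session, spec = rerp_design(),
                     lambda = NULL,
                     lambda_grid = c(100, 1000, 1e4, 1e5, 1e6),
                     n_folds = 10, baseline = NULL) {
  stopifnot(inherits(recording, "eeg_recording"),
            spec$srate == recording$srate)
  n <- ncol(recording$data)
  dm <- build_design_matrix(session, spec, n)
  keep <- !recording$mask
  if (!any(keep)) stop("all samples are masked")
  X <- dm$X[keep, , drop = FALSE]
  Y <- t(recording$data[, keep, drop = FALSE])
  sizes <- as.integer(table(factor(dm$colmap$block,
                                   levels = unique(dm$colmap$block))))
  D <- first_difference_penalty(sizes)
  cv <- NULL
  if (is.null(lambda)) {
    cv <- crossval_lambda(X, Y, D, lambda_grid = lambda_grid,
                          n_folds = n_folds)
    lambda <- cv$lambda
  }
  B <- tikhonov_solve(X, Y, lambda, D)
  betas <- list()
  lags <- list()
  for (bl in unique(dm$colmap$block)) {
    rows <- dm$colmap$block == bl
    m <- t(B[dm$colmap$col[rows], , drop = FALSE])
    rownames(m) <- recording$labels
    colnames(m) <- dm$colmap$lag_s[rows]
    betas[[bl]] <- m
    lags[[bl]] <- dm$colmap$lag_s[rows]
  }
  events <- stats::setNames(
    dm$colmap$event[!duplicated(dm$colmap$block)],
    dm$colmap$block[!duplicated(dm$colmap$block)])
  obj <- structure(list(
    betas = betas, lags = lags, block_events = events,
    lambda = lambda, cv = cv, variant = spec$variant, spec = spec,
    srate = recording$srate, labels = recording$labels,
    participant_id = recording$meta$participant_id,
    n_samples_used = sum(keep), baseline = NULL), class = "rerp")
  if (!is.null(baseline)) obj <- baseline_correct(obj, baseline)
  obj
}

#' Baseline-correct the reward-aligned coefficients
#'
#' Subtracts, per electrode, the mean coefficient over the given lag window
#' (default -4.0 to -1.0 s) from every reward-aligned block. Idempotent.
#'
#' @param rerp An `rerp` object.
#' @param window Lag window in seconds; must lie within the reward lag axis.
#' @return The corrected `rerp`.
#' @export
baseline_correct <- function(rerp, window = c(-4, -1)) {
  stopifnot(inherits(rerp, "rerp"))
  reward_blocks <- names(rerp$block_events)[rerp$block_events == "reward"]
  for (bl in reward_blocks) {
    lag <- rerp$lags[[bl]]
    if (window[1] < min(lag) - 1e-9 || window[2] > max(lag) + 1e-9) {
      stop("baseline window outside the reward lag axis")
    }
    sel <- lag >= window[1] & lag <= window[2]
    rerp$betas[[bl]] <- rerp$betas[[bl]] - rowMeans(rerp$betas[[bl]][, sel,
                                                                    drop = FALSE])
  }
  rerp$baseline <- window
  rerp
}

#' @export
print.rerp <- function(x, ...) {
  cat("Regression ERP (", x$variant, " model)\n", sep = "")
  if (!is.null(x$participant_id)) cat("  participant:", x$participant_id, "\n")
  cat("  blocks:", paste(names(x$betas), collapse = ", "), "\n")
  cat(sprintf("  %d electrodes, lambda = %g%s, %d samples in fit\n",
              length(x$labels), x$lambda,
              if (is.null(x$cv)) " (fixed)" else " (10-fold CV)",
              x$n_samples_used))
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline corrected over [%g, %g] s\n",
                x$baseline[1], x$baseline[2]))
  }
  invisible(x)
}

#' @export
summary.rerp <- function(object, ...) {
  peaks <- t(vapply(names(object$betas), function(bl) {
    m <- object$betas[[bl]]
    i <- which(abs(m) == max(abs(m)), arr.ind = TRUE)[1, ]
    c(peak_uv = m[i[1], i[2]], lag_s = object$lags[[bl]][i[2]])
  }, numeric(2)))
  out <- data.frame(block = names(object$betas),
                    peak_uv = peaks[, 1], peak_lag_s = peaks[, 2],
                    peak_electrode = vapply(names(object$betas), function(bl) {
                      m <- object$betas[[bl]]
                      i <- which(abs(m) == max(abs(m)), arr.ind = TRUE)[1, 1]
                      object$labels[i]
                    }, character(1)), row.names = NULL)
  cat("Peak coefficients per block:\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Extract rERP coefficients
#'
#' @param object An `rerp` object.
#' @param block Block name (default the first reward-aligned block).
#' @param ... Unused.
#' @return Electrode x lag matrix of coefficients (microvolts).
#' @export
coef.rerp <- function(object, block = NULL, ...) {
  if (is.null(block)) {
    rb <- names(object$block_events)[object$block_events == "reward"]
    block <- if (length(rb)) rb[1] else names(object$betas)[1]
  }
  object$betas[[block]]
}

#' @export
plot.rerp <- function(x, block = NULL, electrodes = c("CP2", "CPz", "Pz"),
                      ...) {
  if (is.null(block)) {
    rb <- names(x$block_events)[x$block_events == "reward"]
    block <- if (length(rb)) rb[1] else names(x$betas)[1]
  }
  m <- x$betas[[block]]
  sel <- intersect(electrodes, rownames(m))
  if (!length(sel)) sel <- rownames(m)[1]
  graphics::matplot(x$lags[[block]], t(m[sel, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "lag (s)", ylab = "beta (uV)",
                    main = paste("rERP:", block), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::legend("bottomleft", legend = sel, lty = 1,
                   col = seq_along(sel), bty = "n", cex = 0.8)
  invisible(x)
}

#' Grand-average rERP coefficients across participants
#'
#' @param rerps List of `rerp` objects sharing labels and lag axes.
#' @param block Block to average (default first reward block).
#' @return Electrode x lag matrix of mean coefficients.
#' @export
grand_average <- function(rerps, block = NULL) {
  stopifnot(length(rerps) >= 1)
  if (is.null(block)) {
    rb <- names(rerps[[1]]$block_events)[rerps[[1]]$block_events == "reward"]
    block <- if (length(rb)) rb[1] else names(rerps[[1]]$betas)[1]
  }
  Reduce(`+`, lapply(rerps, function(r) r$betas[[block]])) / length(rerps)
}

#' Classical (naive) reward-aligned epoch average
#'
#' Averages the raw EEG in reward-aligned epochs without any overlap
#' correction -- the comparison baseline for the deconvolution approach.
#' Epoch samples outside the trial's animation interval, or flagged by the
#' artifact mask, are dropped from the average (matching the support of the
#' reward regressor).
#'
#' @param recording A preprocessed `eeg_recording`.
#' @param session The matching `gnomes_session`.
#' @param window Lag window in seconds around the maximum-reward time.
#' @return Electrode x lag matrix with the lag axis as column names.
#' @export
naive_reward_average <- function(recording, session, window = c(-4, 0.2)) {
  trials <- session$trials
  srate <- recording$srate
  lags <- seq(round(window[1] * srate), round(window[2] * srate))
  n <- ncol(recording$data)
  acc <- matrix(0, nrow(recording$data), length(lags))
  cnt <- matrix(0, 1, length(lags))
  for (k in seq_len(nrow(trials))) {
    an <- animation_samples(trials[k, ], srate, n)
    if (is.null(an)) next
    keep <- an$lag >= lags[1] & an$lag <= lags[length(lags)] &
      !recording$mask[an$idx]
    if (!any(keep)) next
    pos <- an$lag[keep] - lags[1] + 1
    acc[, pos] <- acc[, pos] + recording$data[, an$idx[keep], drop = FALSE]
    cnt[pos] <- cnt[pos] + 1
  }
  out <- sweep(acc, 2, pmax(cnt, 1), "/")
  out[, cnt == 0] <- NA_real_
  rownames(out) <- recording$labels
  colnames(out) <- lags / srate
  out
}
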