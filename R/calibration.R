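#' Type-I error calibration of the cluster permutation test
#'
#' Monte-Carlo calibration of the full analysis chain under the null
#' hypothesis: EEG is synthesized with the reward kernel silenced (start/end
#' transients and 1/f-plus-white noise remain), the reward-aligned rERP
#' model is fit per participant, and the sign-flip cluster-mass permutation
#' test is run. The reported rate is the fraction of simulated datasets with
#' at least one significant cluster, which should match `alpha`.
#'
#' Each participant's session (trial geometry) and design-matrix
#' factorization are held fixed across datasets and only the noise is
#' redrawn -- a conditional-on-design calibration that keeps hundreds of
#' replicates tractable. The scale is deliberately reduced relative to a
#' full analysis (short sessions, a shortened reward window, fixed penalty);
#' the permutation test itself is identical to [permutation_test()].
#'
#' @param n_datasets Number of simulated null datasets.
#' @param n_participants Participants per dataset.
#' @param encounters_per_cue Encounters of each cue per session.
#' @param window_reward Reward-aligned lag window (s) for model and test.
#' @param lambda Fixed penalty weight for the fits.
#' @param n_perm Permutations per dataset.
#' @param alpha Cluster significance level being calibrated.
#' @param seed Base seed.
#' @param noise A [noise_config()] for the background activity.
#' @return List of class `type1_calibration`: `rate`, `hits` (logical per
#'   dataset), `ci` (binomial 95% CI around `alpha` for `n_datasets`),
#'   and the settings.
#' @export
null_calibration <- function(n_datasets = 500, n_participants = 8,
                             encounters_per_cue = 1,
                             window_reward = c(-1.2, 0.2),
                             lambda = 1e4, n_perm = 200, alpha = 0.05,
                             seed = 1L, noise = noise_config()) {
  truth0 <- make_ground_truth(condition_gains = c(high = 0, medium = 0,
                                                  low = 0),
                              noise = noise_config(rms_total = 0))
  spec <- rerp_design(window_reward = window_reward)
  montage <- truth0$montage
  labels <- montage$label
  adjacency <- montage_adjacency(montage)
  A <- adjacency_matrix(adjacency, labels)

  # fixed per-participant geometry: design factorization and the
  # deterministic (transient-evoked) part of the signal
  subjects <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    cfg <- session_config(seed = derive_seed(seed, i, 4L),
                          participant_id = sprintf("null-%02d", i),
                          encounters_per_cue = encounters_per_cue)
    session <- simulate_session(cfg)
    sig <- synthesize_eeg(session, truth0)
    scalp <- sig$data[labels, , drop = FALSE]
    n <- ncol(scalp)
    dm <- build_design_matrix(session, spec, n)
    sizes <- as.integer(table(factor(dm$colmap$block,
                                     levels = unique(dm$colmap$block))))
    D <- first_difference_penalty(sizes)
    Amat <- as.matrix(Matrix::crossprod(dm$X)) +
      lambda * as.matrix(Matrix::crossprod(D))
    subjects[[i]] <- list(
      X = dm$X, R = chol(Amat), signal = t(scalp), n = n,
      reward_cols = dm$colmap$col[dm$colmap$block == "reward"])
  }
  lag_axis <- subjects[[1]]$reward_cols
  lags <- (seq(round(window_reward[1] * spec$srate),
               round(window_reward[2] * spec$srate))) / spec$srate
  thresh <- stats::qt(1 - 0.05 / 2, df = n_participants - 1)

  hits <- logical(n_datasets)
  set.seed(derive_seed(seed, 0L, 5L))
  for (d in seq_len(n_datasets)) {
    mats <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      s <- subjects[[i]]
      Y <- s$signal + noise_matrix(s$n, length(labels), noise)
      XtY <- as.matrix(Matrix::crossprod(s$X, Y))
      B <- backsolve(s$R, backsolve(s$R, XtY, transpose = TRUE))
      m <- t(B[s$reward_cols, , drop = FALSE])
      dimnames(m) <- list(labels, lags)
      mats[[i]] <- m
    }
    ct <- cluster_perm_core(mats, adjacency, n_perm = n_perm,
                            seed = sample.int(2^30, 1),
                            alpha = alpha, window = window_reward)
    hits[d] <- any(ct$clusters$significant)
  }
  rate <- mean(hits)
  ci <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_datasets)
  structure(list(rate = rate, hits = hits, ci = ci, alpha = alpha,
                 n_datasets = n_datasets, n_participants = n_participants,
                 n_perm = n_perm, lambda = lambda,
                 window_reward = window_reward, seed = seed),
            class = "type1_calibration")
}

#' @export
print.type1_calibration <- function(x, ...) {
  cat(sprintf(
    "Type-I calibration: %.3f significant-cluster rate over %d null datasets\n",
    x$rate, x$n_datasets))
  cat(sprintf("  nominal alpha %.2f, binomial 95%% band [%.3f, %.3f]\n",
              x$alpha, x$ci[1], x$ci[2]))
  invisible(x)
}

# samples x channels noise matrix, synthesized directly in the frequency
# domain: one Hermitian complex-Gaussian spectrum per channel whose power
# profile mixes the 1/f^|slope| and flat (white) components in the
# configured proportion, inverse-FFT'd and rescaled to the requested RMS.
noise_matrix <- function(n, n_ch, noise) {
  if (noise$rms_total == 0) return(matrix(0, n, n_ch))
  m <- stats::nextn(n, factors = c(2, 3, 5))
  if (m %% 2 == 1) m <- stats::nextn(m + 1, factors = c(2, 3, 5))
  f <- c(0, seq_len(m - 1))
  f <- pmin(f, m - f)
  p <- c(0, f[-1]^noise$slope)
  p <- p / mean(p[-1])                       # unit mean power off DC
  G <- sqrt(noise$pink_fraction * p + (1 - noise$pink_fraction))
  G[1] <- 0                                  # zero-mean series
  half <- m %/% 2
  C <- matrix(0i, m, n_ch)
  C[2:half, ] <- matrix(complex(real = stats::rnorm((half - 1) * n_ch),
                                imaginary = stats::rnorm((half - 1) * n_ch)),
                        half - 1, n_ch) * G[2:half]
  C[seq(m, half + 2), ] <- Conj(C[2:half, , drop = FALSE])
  C[half + 1, ] <- stats::rnorm(n_ch) * G[half + 1]
  x <- Re(stats::mvfft(C, inverse = TRUE))[seq_len(n), , drop = FALSE]
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  noise$rms_total * sweep(x, 2, sds, "/")
}
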