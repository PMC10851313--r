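#' Session configuration for the bar-betting task
#'
#' One session of the task: on each trial a pre-trial cue (one of six) signals
#' how predictable the outcome is, the participant bets on the final height of
#' a rising bar, then watches the bar grow at a constant rate and is awarded
#' points according to how close the guess was. Defaults reproduce the study
#' conditions: 6 cues x 25 encounters = 150 trials, fixation 400-600 ms,
#' cue 1500 ms, post-response delay 400-600 ms, a 3-degree bar rising at
#' 1 degree/s, and a 1000 ms outcome display.
#'
#' @param seed Integer seed; the session is a deterministic function of the
#'   configuration.
#' @param participant_id Identifier stored in the trial table.
#' @param n_cues Number of pre-trial cues (6).
#' @param encounters_per_cue Encounters of each cue (25; total trials is
#'   `n_cues * encounters_per_cue`).
#' @param fixation_range,delay_range Uniform bounds (s) for the fixation and
#'   post-response delays.
#' @param cue_duration Cue presentation time (s).
#' @param outcome_duration Time (s) the final outcome stays on screen.
#' @param bar_height_deg Bar height in degrees of visual angle.
#' @param rise_rate_deg_s Bar growth rate (degrees per second).
#' @param sigma_g SD of the Gaussian response noise added to the simulated
#'   guess (proportion of bar height).
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters (s); only
#'   inter-event spacing depends on these.
#' @return A list of class `session_config`.
#' @export
session_config <- function(seed = 1L, participant_id = "sub-01",
                           n_cues = 6L, encounters_per_cue = 25L,
                           fixation_range = c(0.4, 0.6),
                           delay_range = c(0.4, 0.6),
                           cue_duration = 1.5,
                           outcome_duration = 1.0,
                           bar_height_deg = 3,
                           rise_rate_deg_s = 1,
                           sigma_g = 0.05,
                           rt_meanlog = log(1.5), rt_sdlog = 0.3) {
  stopifnot(n_cues >= 1, encounters_per_cue >= 1,
            fixation_range[1] <= fixation_range[2],
            delay_range[1] <= delay_range[2],
            bar_height_deg > 0, rise_rate_deg_s > 0, sigma_g >= 0)
  structure(list(
    seed = as.integer(seed), participant_id = participant_id,
    n_cues = as.integer(n_cues),
    encounters_per_cue = as.integer(encounters_per_cue),
    fixation_range = fixation_range, delay_range = delay_range,
    cue_duration = cue_duration, outcome_duration = outcome_duration,
    bar_height_deg = bar_height_deg, rise_rate_deg_s = rise_rate_deg_s,
    sigma_g = sigma_g, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog
  ), class = "session_config")
}

cue_kinds <- function() {
  c("gaussian_low", "gaussian_high", "mix_80_20", "mix_20_80",
    "mix_50_50", "uniform")
}

kind_predictability <- function(kind) {
  switch(kind,
    gaussian_low = , gaussian_high = "high",
    mix_80_20 = , mix_20_80 = "medium",
    mix_50_50 = , uniform = "low",
    stop("unknown distribution kind: ", kind))
}

#' Build the six pre-trial cue specifications
#'
#' One cue per outcome-distribution kind: two tight Gaussians (SD 0.01,
#' means 1/3 and 2/3 of bar height; high predictability), two 80/20 mixtures
#' of those Gaussians (medium), a 50/50 mixture and a uniform on
#' \[0.2, 0.8\] (low). Which cue id carries which distribution is a random
#' permutation governed by `seed`, as in the task itself.
#'
#' @param seed Integer seed for the cue-to-distribution assignment.
#' @return List of class `cue_set`; each element has `cue_id`, `dist_kind`,
#'   `params` and `predictability`.
#' @export
make_cue_set <- function(seed = 1L) {
  kinds <- cue_kinds()
  perm <- sample_with_seed(length(kinds), seed = as.integer(seed))
  specs <- lapply(seq_along(kinds), function(i) {
    kind <- kinds[perm[i]]
    params <- switch(kind,
      gaussian_low  = list(mean = 1 / 3, sd = 0.01),
      gaussian_high = list(mean = 2 / 3, sd = 0.01),
      mix_80_20 = list(means = c(1 / 3, 2 / 3), sd = 0.01, weights = c(0.8, 0.2)),
      mix_20_80 = list(means = c(1 / 3, 2 / 3), sd = 0.01, weights = c(0.2, 0.8)),
      mix_50_50 = list(means = c(1 / 3, 2 / 3), sd = 0.01, weights = c(0.5, 0.5)),
      uniform   = list(min = 0.2, max = 0.8))
    list(cue_id = i, dist_kind = kind, params = params,
         predictability = kind_predictability(kind))
  })
  structure(specs, class = "cue_set")
}

# draw a permutation/sample under a local RNG state (callers' streams untouched)
sample_with_seed <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Draw one outcome from a cue's distribution
#'
#' Outcomes are proportions of the bar height. Gaussian and mixture draws
#' falling outside \[0, 1\] are clipped (with SD 0.01 this is astronomically
#' rare and bias-free in practice).
#'
#' @param cue One element of [make_cue_set()].
#' @param n Number of draws.
#' @return Numeric vector of outcomes in \[0, 1\].
#' @export
sample_outcome <- function(cue, n = 1L) {
  p <- cue$params
  o <- switch(cue$dist_kind,
    gaussian_low  = , gaussian_high = stats::rnorm(n, p$mean, p$sd),
    uniform = stats::runif(n, p$min, p$max),
    { # two-component Gaussian mixture
      comp <- sample(c(1L, 2L), n, replace = TRUE, prob = p$weights)
      stats::rnorm(n, p$means[comp], p$sd)
    })
  pmin(pmax(o, 0), 1)
}

#' Points awarded for a guess/outcome pair
#'
#' `100 * (1 - p)` where `p = |guess - outcome|` is the proportion-distance
#' between the bet and the final bar height.
#'
#' @param g,o Guess and outcome, proportions in \[0, 1\] (vectorized).
#' @return Points in \[0, 100\].
#' @export
compute_points <- function(g, o) {
  if (any(g < 0 | g > 1 | o < 0 | o > 1, na.rm = TRUE)) {
    stop("guesses and outcomes must lie in [0, 1]")
  }
  100 * (1 - abs(g - o))
}

#' Bonus payment implied by a points total
#'
#' @param points Total points earned.
#' @param rate Conversion rate in GBP per point.
#' @return Bonus in GBP.
#' @export
points_to_bonus <- function(points, rate = 0.0002) {
  points * rate
}

#' Simulated guess policy
#'
#' The stand-in for a human bettor: guess the running mean of the cue's
#' previously observed outcomes, plus Gaussian response noise, clipped to
#' \[0, 1\]. With no history the guess centres on the bar midpoint (0.5).
#'
#' @param cue_history Numeric vector of the cue's previous outcomes (possibly
#'   empty).
#' @param sigma_g Response-noise SD; 0 gives the deterministic tracker.
#' @return A guess in \[0, 1\].
#' @export
simulate_guess <- function(cue_history, sigma_g = 0.05) {
  centre <- if (length(cue_history) == 0) 0.5 else mean(cue_history)
  g <- centre + stats::rnorm(1, 0, sigma_g)
  min(max(g, 0), 1)
}

#' Simulate one session of the task
#'
#' Generates the full behavioural session: a randomized cue order (25 of each
#' of the 6 cues), outcomes, guesses under the running-mean policy, points,
#' and a strictly increasing event timeline (fixation, cue, response,
#' post-response delay, bar animation, outcome display). The time of maximum
#' possible reward on each trial is when the rising bar matches -- or would
#' have matched -- the guess.
#'
#' @param config A [session_config()].
#' @param cues Optionally a pre-built [make_cue_set()]; by default one is
#'   derived from the session seed.
#' @return An object of class `gnomes_session` with elements `trials` (data
#'   frame, one row per trial), `cues`, `config` and `duration` (s).
#' @export
simulate_session <- function(config = session_config(), cues = NULL) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  if (is.null(cues)) cues <- make_cue_set(seed = config$seed)
  n_trials <- config$n_cues * config$encounters_per_cue
  order_cues <- sample(rep(seq_len(config$n_cues), config$encounters_per_cue))

  prop_rate <- config$rise_rate_deg_s / config$bar_height_deg  # proportion/s
  hist_out <- vector("list", config$n_cues)   # outcomes seen per cue
  hist_pts <- vector("list", config$n_cues)   # points earned per cue

  rows <- vector("list", n_trials)
  t <- 0
  for (k in seq_len(n_trials)) {
    cue_id <- order_cues[k]
    cue <- cues[[cue_id]]
    fix <- stats::runif(1, config$fixation_range[1], config$fixation_range[2])
    rt <- stats::rlnorm(1, config$rt_meanlog, config$rt_sdlog)
    delay <- stats::runif(1, config$delay_range[1], config$delay_range[2])

    g <- simulate_guess(hist_out[[cue_id]], sigma_g = config$sigma_g)
    o <- sample_outcome(cue)
    pts <- compute_points(g, o)
    expectancy <- if (length(hist_pts[[cue_id]]) == 0) NA_real_ else
      mean(hist_pts[[cue_id]]) / 100

    t_fix <- t
    t_cue <- t_fix + fix
    t_resp <- t_cue + config$cue_duration + rt
    t_anim_start <- t_resp + delay
    t_anim_end <- t_anim_start + o / prop_rate
    t_max_reward <- t_anim_start + g / prop_rate
    t <- t_anim_end + config$outcome_duration

    hist_out[[cue_id]] <- c(hist_out[[cue_id]], o)
    hist_pts[[cue_id]] <- c(hist_pts[[cue_id]], pts)

    rows[[k]] <- data.frame(
      participant_id = config$participant_id, trial = k, cue_id = cue_id,
      dist_kind = cue$dist_kind, predictability = cue$predictability,
      guess = g, outcome = o, p_err = abs(g - o), points = pts,
      expectancy = expectancy,
      t_fix = t_fix, t_cue = t_cue, t_response = t_resp,
      t_anim_start = t_anim_start, t_anim_end = t_anim_end,
      t_max_reward = t_max_reward,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, cues = cues, config = config,
                 duration = t), class = "gnomes_session")
}

#' @export
print.gnomes_session <- function(x, ...) {
  cat("Simulated betting session:", x$config$participant_id, "\n")
  cat(sprintf("  %d trials (%d cues x %d encounters), %.1f s\n",
              nrow(x$trials), x$config$n_cues, x$config$encounters_per_cue,
              x$duration))
  cat(sprintf("  mean points/trial %.1f, total points %.0f\n",
              mean(x$trials$points), sum(x$trials$points)))
  invisible(x)
}

#' Continuous predicted-reward signal
#'
#' The instantaneous predicted reward while the bar is rising: the points
#' formula applied moment to moment, `1 - |g - h(t)|`, with `h(t)` the bar
#' height as a proportion of its full extent. The signal is exactly zero
#' outside the bar-animation intervals and peaks (at 1 for reachable guesses)
#' at the time of maximum possible reward.
#'
#' @param session A [simulate_session()] result.
#' @param srate Sample rate in Hz (250, matching the downsampled EEG).
#' @param n_samples Optional total length; defaults to the session duration
#'   plus 2 s padding.
#' @return List of class `reward_signal` with `values`, `srate`, `times`.
#' @export
continuous_reward_signal <- function(session, srate = 250, n_samples = NULL) {
  stopifnot(inherits(session, "gnomes_session"))
  if (is.null(n_samples)) n_samples <- ceiling((session$duration + 2) * srate)
  times <- (seq_len(n_samples) - 1) / srate
  values <- numeric(n_samples)
  cfg <- session$config
  prop_rate <- cfg$rise_rate_deg_s / cfg$bar_height_deg
  for (k in seq_len(nrow(session$trials))) {
    tr <- session$trials[k, ]
    i0 <- ceiling(tr$t_anim_start * srate) + 1
    i1 <- floor(tr$t_anim_end * srate) + 1
    if (i1 < i0 || i0 > n_samples) next
    i1 <- min(i1, n_samples)
    idx <- i0:i1
    h <- (times[idx] - tr$t_anim_start) * prop_rate
    values[idx] <- 1 - abs(tr$guess - h)
  }
  structure(list(values = values, srate = srate, times = times),
            class = "reward_signal")
}

#' Trial-by-trial reward expectancy
#'
#' For each trial, the mean reward (points rescaled to \[0, 1\]) obtained on
#' that cue's strictly earlier trials; the first encounter of a cue has no
#' history and is flagged `NA`. This running mean is the parametric
#' "expectancy" regressor of the deconvolution model.
#'
#' @param session A `gnomes_session` (or its `trials` data frame in
#'   chronological order).
#' @return Numeric vector, one value per trial (`NA` on first encounters).
#' @export
compute_expectancy <- function(session) {
  trials <- if (inherits(session, "gnomes_session")) session$trials else session
  out <- rep(NA_real_, nrow(trials))
  for (cue in unique(trials$cue_id)) {
    idx <- which(trials$cue_id == cue)
    pts <- trials$points[idx]
    if (length(idx) > 1) {
      out[idx[-1]] <- cumsum(pts)[-length(pts)] / seq_len(length(pts) - 1) / 100
    }
  }
  out
}
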