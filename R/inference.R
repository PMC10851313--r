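#' Zero-lag correlation between EEG and the continuous reward signal
#'
#' Pearson correlation per electrode between the preprocessed continuous EEG
#' and the continuous predicted-reward signal, after dropping artifact-
#' flagged samples. `scope = "modeled_only"` restricts the correlation to
#' samples where the reward signal is nonzero (inside bar animations);
#' the default uses the whole recording.
#'
#' @param recording A preprocessed `eeg_recording`.
#' @param reward_signal A [continuous_reward_signal()] result (or numeric
#'   vector at the recording's sample rate).
#' @param scope `"all_samples"` or `"modeled_only"`.
#' @return Named numeric vector of correlations, one per electrode.
#' @export
zero_lag_correlation <- function(recording, reward_signal,
                                 scope = c("all_samples", "modeled_only")) {
  scope <- match.arg(scope)
  v <- if (inherits(reward_signal, "reward_signal")) reward_signal$values else
    reward_signal
  n <- min(ncol(recording$data), length(v))
  keep <- !recording$mask[seq_len(n)]
  if (scope == "modeled_only") keep <- keep & v[seq_len(n)] != 0
  if (sum(keep) < 3) stop("fewer than 3 usable samples")
  r <- as.vector(stats::cor(t(recording$data[, which(keep), drop = FALSE]),
                            v[which(keep)]))
  stats::setNames(r, recording$labels)
}

#' Group-level one-sample t test per electrode
#'
#' One-sample t statistics (df = n - 1) of a participants x electrodes value
#' matrix against zero, with Bonferroni correction over electrodes
#' (alpha / 30 for the standard montage).
#'
#' @param values Participants x electrodes numeric matrix.
#' @param alpha Familywise alpha before correction.
#' @return Data frame with `electrode`, `mean`, `sd`, `t`, `df`, `p`,
#'   `significant` (at `alpha/n_electrodes`), `cohens_d` (mean/sd) and
#'   `zero_variance` flag.
#' @export
group_ttest_map <- function(values, alpha = 0.05) {
  stopifnot(is.matrix(values), nrow(values) >= 2)
  n <- nrow(values)
  m <- colMeans(values)
  s <- apply(values, 2, stats::sd)
  zero_var <- s == 0
  t <- ifelse(zero_var, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  crit <- alpha / ncol(values)
  data.frame(
    electrode = colnames(values) %||% as.character(seq_len(ncol(values))),
    mean = m, sd = s, t = t, df = n - 1, p = p,
    significant = p < crit, cohens_d = ifelse(zero_var, NA_real_, m / s),
    zero_variance = zero_var, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sample t map over electrodes and lags
#'
#' Stacks the chosen coefficient block of each participant's [fit_rerp()]
#' estimate and computes a one-sample t statistic against zero at every
#' (electrode, lag) cell.
#'
#' @param rerps List of `rerp` objects (or electrode x lag matrices) with a
#'   common lag axis.
#' @param block Coefficient block to test (default first reward block).
#' @return List of class `tmap`: `t` (electrode x lag), `n`, `df`, `lags`,
#'   `labels`, `zero_variance` (logical matrix).
#' @export
t_map <- function(rerps, block = NULL) {
  mats <- rerp_block_matrices(rerps, block)
  n <- length(mats)
  stopifnot(n >= 2)
  arr <- simplify2array(mats)
  if (any(!is.finite(arr))) stop("non-finite coefficients in input")
  m <- rowMeans(arr, dims = 2)
  ss <- rowSums(arr^2, dims = 2)
  s <- sqrt(pmax(ss - n * m^2, 0) / (n - 1))
  zero_var <- s == 0
  t <- ifelse(zero_var, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  lags <- as.numeric(colnames(mats[[1]]))
  structure(list(t = t, n = n, df = n - 1, lags = lags,
                 labels = rownames(mats[[1]]), zero_variance = zero_var),
            class = "tmap")
}

rerp_block_matrices <- function(rerps, block = NULL) {
  if (is.matrix(rerps[[1]])) return(rerps)
  if (is.null(block)) {
    rb <- names(rerps[[1]]$block_events)[rerps[[1]]$block_events == "reward"]
    block <- if (length(rb)) rb[1] else names(rerps[[1]]$betas)[1]
  }
  lapply(rerps, function(r) r$betas[[block]])
}

#' Candidate spatio-temporal clusters of a t map
#'
#' Finds all maximal clusters: connected electrode sets (under the montage
#' adjacency) and temporal runs over which every member electrode is
#' simultaneously supra-threshold with a common sign. The cluster-forming
#' threshold is the two-tailed critical t value at `alpha` with the map's
#' degrees of freedom. Cluster mass is the sum of |t| over the cluster's
#' electrodes and samples.
#'
#' @param tmap A [t_map()] result.
#' @param adjacency Neighbour list from [montage_adjacency()].
#' @param alpha Two-tailed cluster-forming alpha.
#' @param window Lag window (s) to which the cluster search is restricted.
#' @return Data frame with one row per cluster: `electrodes` (list column of
#'   labels), `lag_start`, `lag_end` (s), `sign`, `mass`.
#' @export
find_clusters <- function(tmap, adjacency, alpha = 0.05,
                          window = c(-4, 0.2)) {
  stopifnot(inherits(tmap, "tmap"))
  thresh <- stats::qt(1 - alpha / 2, df = tmap$df)
  sel <- which(tmap$lags >= window[1] - 1e-9 & tmap$lags <= window[2] + 1e-9)
  tm <- tmap$t[, sel, drop = FALSE]
  if (any(!is.finite(tm))) stop("non-finite t values (zero variance cells?)")
  A <- adjacency_matrix(adjacency, tmap$labels)
  res <- cpp_find_clusters(tm, A, thresh)
  k <- length(res$mass)
  out <- data.frame(
    lag_start = tmap$lags[sel][res$start],
    lag_end = tmap$lags[sel][res$end],
    sign = res$sign, mass = res$mass)[seq_len(k), , drop = FALSE]
  out$electrodes <- lapply(res$members, function(i) tmap$labels[i])
  out[order(-out$mass), , drop = FALSE]
}

cluster_perm_core <- function(mats, adjacency, n_perm = 1000, seed = 1L,
                              alpha = 0.05, cluster_alpha = 0.05,
                              window = c(-4, 0.2), p_plus_one = FALSE) {
  n <- length(mats)
  lags <- as.numeric(colnames(mats[[1]]))
  labels <- rownames(mats[[1]])
  tm <- t_map(mats)
  observed <- find_clusters(tm, adjacency, alpha = cluster_alpha,
                            window = window)
  sel <- which(lags >= window[1] - 1e-9 & lags <= window[2] + 1e-9)
  beta_cells <- vapply(mats, function(m) as.vector(m[, sel, drop = FALSE]),
                       numeric(length(labels) * length(sel)))
  A <- adjacency_matrix(adjacency, labels)
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  set.seed(seed)
  signs <- matrix(sample(c(-1L, 1L), n * n_perm, replace = TRUE), n, n_perm)
  null_max <- cpp_cluster_null(beta_cells, signs, A, thresh, length(labels))
  if (nrow(observed)) {
    observed$p <- vapply(observed$mass, function(m) {
      if (p_plus_one) (sum(null_max >= m) + 1) / (n_perm + 1) else
        mean(null_max >= m)
    }, numeric(1))
    observed$significant <- observed$p < alpha
  } else {
    observed$p <- numeric(0)
    observed$significant <- logical(0)
  }
  structure(list(clusters = observed, null_max = null_max, n_perm = n_perm,
                 n = n, threshold = thresh, window = window, seed = seed),
            class = "cluster_test")
}

#' Cluster-mass permutation test of group-level rERPs
#'
#' Tests whether the group rERP differs from zero anywhere in the search
#' window using the cluster-mass statistic. The null distribution is built
#' by randomly flipping each participant's entire coefficient map (all
#' electrodes together) in sign and recording the maximum cluster mass of
#' each permuted map (0 if none). A cluster's p value is the proportion of
#' permuted maxima at least as large as its mass; it is labelled significant
#' when its mass exceeds 95% of the permuted maxima.
#'
#' @param rerps List of `rerp` objects (or electrode x lag matrices).
#' @param adjacency Neighbour list from [montage_adjacency()].
#' @param block Coefficient block to test.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Seed for the permutation draws.
#' @param alpha Significance level for cluster p values.
#' @param cluster_alpha Cluster-forming (two-tailed) alpha.
#' @param window Lag search window in seconds.
#' @param p_plus_one Use the (k+1)/(n+1) small-sample p correction.
#' @return A `cluster_test`: `clusters` data frame (with `p`,
#'   `significant`), the permutation `null_max` distribution and settings.
#' @export
permutation_test <- function(rerps, adjacency, block = NULL, n_perm = 1000,
                             seed = 1L, alpha = 0.05, cluster_alpha = 0.05,
                             window = c(-4, 0.2), p_plus_one = FALSE) {
  mats <- rerp_block_matrices(rerps, block)
  cluster_perm_core(mats, adjacency, n_perm = n_perm, seed = seed,
                    alpha = alpha, cluster_alpha = cluster_alpha,
                    window = window, p_plus_one = p_plus_one)
}

#' Paired condition contrast via cluster permutation
#'
#' Forms per-participant difference maps (condition A minus condition B,
#' paired by list position) and submits them to the sign-flip cluster-mass
#' permutation test; flipping a difference map is equivalent to exchanging
#' the condition labels within a participant.
#'
#' @param rerps_a,rerps_b Paired lists of `rerp` objects (or matrices).
#' @param adjacency Neighbour list.
#' @param block_a,block_b Blocks to contrast (for condition-split fits,
#'   e.g. `"reward.high"` vs `"reward.low"`).
#' @param ... Passed to [permutation_test()].
#' @return A `cluster_test` for the difference.
#' @export
condition_contrast <- function(rerps_a, rerps_b, adjacency,
                               block_a = NULL, block_b = NULL, ...) {
  if (length(rerps_a) != length(rerps_b)) stop("inputs must be paired")
  ma <- rerp_block_matrices(rerps_a, block_a)
  mb <- rerp_block_matrices(rerps_b, block_b)
  diffs <- Map(function(a, b) a - b, ma, mb)
  cluster_perm_core(diffs, adjacency, ...)
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster-mass permutation test (%d permutations, n = %d)\n",
              x$n_perm, x$n))
  cat(sprintf("  cluster-forming |t| > %.3f, window [%g, %g] s\n",
              x$threshold, x$window[1], x$window[2]))
  if (!nrow(x$clusters)) {
    cat("  no candidate clusters\n")
    return(invisible(x))
  }
  show <- utils::head(x$clusters, 5)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %s cluster [%s], %g to %g s, mass %.1f, p %s%s\n",
                if (show$sign[i] > 0) "positive" else "negative",
                paste(show$electrodes[[i]], collapse = " "),
                show$lag_start[i], show$lag_end[i], show$mass[i],
                format.pval(show$p[i], eps = 1 / x$n_perm),
                if (show$significant[i]) " *" else ""))
  }
  if (nrow(x$clusters) > 5) {
    cat("  ...", nrow(x$clusters) - 5, "more\n")
  }
  invisible(x)
}

#' Cohen's d of a cluster
#'
#' Averages each participant's coefficients over the cluster's electrodes
#' and lag extent; d is the mean of those per-participant values divided by
#' their standard deviation.
#'
#' @param rerps List of `rerp` objects (or matrices), as passed to the test.
#' @param cluster One row of a `cluster_test`'s `clusters` data frame.
#' @param block Coefficient block.
#' @return Cohen's d (signed); `NA` with a warning if the SD is zero.
#' @export
cohens_d_cluster <- function(rerps, cluster, block = NULL) {
  mats <- rerp_block_matrices(rerps, block)
  lags <- as.numeric(colnames(mats[[1]]))
  sel <- lags >= cluster$lag_start - 1e-9 & lags <= cluster$lag_end + 1e-9
  els <- cluster$electrodes[[1]]
  vals <- vapply(mats, function(m) mean(m[els, sel, drop = FALSE]),
                 numeric(1))
  s <- stats::sd(vals)
  if (s == 0) {
    warning("zero standard deviation of cluster means")
    return(NA_real_)
  }
  mean(vals) / s
}

#' One-way repeated-measures ANOVA on predictability
#'
#' Tests the effect of outcome predictability (high, medium, low) on the
#' mean guess--outcome distance with a one-way repeated-measures ANOVA,
#' computed from the sum-of-squares decomposition. Effect sizes:
#' partial eta squared `SS_P / (SS_P + SS_sP)` and generalized eta squared
#' `SS_P / (SS_P + SS_S + SS_sP)`, where `SS_P` is the predictability
#' effect, `SS_sP` its error term and `SS_S` the between-subject sum of
#' squares.
#'
#' @param distances Participants x conditions numeric matrix (columns
#'   high, medium, low).
#' @return List of class `rm_anova`: `F`, `df`, `p`, `ss`, `eta_p2`,
#'   `eta_g2`, condition `means`.
#' @export
rm_anova_predictability <- function(distances) {
  stopifnot(is.matrix(distances), ncol(distances) >= 2)
  if (nrow(distances) < 2) stop("need at least 2 participants")
  if (any(is.na(distances))) stop("complete cases required")
  n <- nrow(distances)
  k <- ncol(distances)
  gm <- mean(distances)
  m_cond <- colMeans(distances)
  m_subj <- rowMeans(distances)
  ss_p <- n * sum((m_cond - gm)^2)
  ss_s <- k * sum((m_subj - gm)^2)
  ss_tot <- sum((distances - gm)^2)
  ss_sp <- ss_tot - ss_p - ss_s
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  # no effect variance at all (identical condition means) -> F is 0, not 0/0
  Fval <- if (ss_p <= 1e-300) 0 else (ss_p / df1) / (ss_sp / df2)
  structure(list(
    F = Fval, df = c(df1, df2), p = stats::pf(Fval, df1, df2,
                                              lower.tail = FALSE),
    ss = c(SS_P = ss_p, SS_sP = ss_sp, SS_S = ss_s),
    eta_p2 = ss_p / (ss_p + ss_sp),
    eta_g2 = ss_p / (ss_p + ss_s + ss_sp),
    means = m_cond), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.2f, p = %s\n",
              x$df[1], x$df[2], x$F, format.pval(x$p, digits = 3)))
  cat(sprintf("  partial eta^2 = %.2f, generalized eta^2 = %.2f\n",
              x$eta_p2, x$eta_g2))
  cat("  condition means:",
      paste(sprintf("%s = %.3f", names(x$means), x$means), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-participant guess--outcome distances by predictability
#'
#' @param sessions List of `gnomes_session` objects.
#' @return Participants x 3 matrix (columns high, medium, low) of mean
#'   absolute guess--outcome distances.
#' @export
behavioral_distances <- function(sessions) {
  rows <- t(vapply(sessions, function(s) {
    vapply(c("high", "medium", "low"), function(cond) {
      mean(s$trials$p_err[s$trials$predictability == cond])
    }, numeric(1))
  }, numeric(3)))
  rownames(rows) <- vapply(sessions,
                           function(s) s$config$participant_id, character(1))
  rows
}
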