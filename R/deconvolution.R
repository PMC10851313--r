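#' Design specification for the reward-aligned rERP model
#'
#' Defines the finite-impulse-response blocks of the deconvolution design
#' matrix. The three modelled events are the start of the bar animation
#' (0 to +0.8 s), the continuous reward signal aligned to the time of
#' maximum possible reward (-4.0 to +0.2 s; nonzero only at samples inside
#' the bar animation, the "modeled times"), and the end of the animation
#' (0 to +0.8 s). Variants: `"pooled"` collapses across cues; `"condition_split"`
#' duplicates every block per predictability level; `"parametric_expectancy"`
#' adds a reward-aligned block modulated by the mean-centred trial-by-trial
#' expectancy (first encounters, with undefined expectancy, contribute 0).
#'
#' @param variant One of `"pooled"`, `"condition_split"`,
#'   `"parametric_expectancy"`.
#' @param window_reward Reward-aligned lag window in seconds.
#' @param window_transient Lag window for the start/end transients.
#' @param srate Sample rate (Hz).
#' @param events Events to model (default all three).
#' @param split_transients For `condition_split`: also split the start/end
#'   blocks by predictability (default `TRUE`, modelling all three events
#'   separately per condition).
#' @return List of class `rerp_design`.
#' @export
rerp_design <- function(variant = c("pooled", "condition_split",
                                    "parametric_expectancy"),
                        window_reward = c(-4, 0.2),
                        window_transient = c(0, 0.8),
                        srate = 250,
                        events = c("anim_start", "reward", "anim_end"),
                        split_transients = TRUE) {
  variant <- match.arg(variant)
  stopifnot(window_reward[1] < window_reward[2],
            window_transient[1] < window_transient[2])
  structure(list(variant = variant, window_reward = window_reward,
                 window_transient = window_transient, srate = srate,
                 events = events, split_transients = split_transients),
            class = "rerp_design")
}

design_blocks <- function(spec, trials) {
  lag_r <- seq(round(spec$window_reward[1] * spec$srate),
               round(spec$window_reward[2] * spec$srate))
  lag_t <- seq(round(spec$window_transient[1] * spec$srate),
               round(spec$window_transient[2] * spec$srate))
  n_tr <- nrow(trials)
  ind <- rep(1, n_tr)
  blocks <- list()
  add <- function(blocks, name, event, lags, modulator) {
    blocks[[name]] <- list(name = name, event = event, lags = lags,
                           modulator = modulator)
    blocks
  }
  if (spec$variant == "condition_split") {
    for (cond in c("high", "medium", "low")) {
      sel <- as.numeric(trials$predictability == cond)
      if (spec$split_transients) {
        if ("anim_start" %in% spec$events)
          blocks <- add(blocks, paste0("anim_start.", cond), "anim_start",
                        lag_t, sel)
        if ("anim_end" %in% spec$events)
          blocks <- add(blocks, paste0("anim_end.", cond), "anim_end",
                        lag_t, sel)
      }
      if ("reward" %in% spec$events)
        blocks <- add(blocks, paste0("reward.", cond), "reward", lag_r, sel)
    }
    if (!spec$split_transients) {
      if ("anim_start" %in% spec$events)
        blocks <- add(blocks, "anim_start", "anim_start", lag_t, ind)
      if ("anim_end" %in% spec$events)
        blocks <- add(blocks, "anim_end", "anim_end", lag_t, ind)
    }
  } else {
    if ("anim_start" %in% spec$events)
      blocks <- add(blocks, "anim_start", "anim_start", lag_t, ind)
    if ("reward" %in% spec$events)
      blocks <- add(blocks, "reward", "reward", lag_r, ind)
    if (spec$variant == "parametric_expectancy") {
      ex <- trials$expectancy
      ex_c <- ex - mean(ex, na.rm = TRUE)
      ex_c[is.na(ex_c)] <- 0
      blocks <- add(blocks, "reward.expectancy", "reward", lag_r, ex_c)
    }
    if ("anim_end" %in% spec$events)
      blocks <- add(blocks, "anim_end", "anim_end", lag_t, ind)
  }
  blocks
}

#' Build the sparse FIR design matrix
#'
#' One column per (block, lag). Start/end blocks are stick expansions at the
#' event sample; reward-aligned columns receive the trial's modulator value
#' at sample `s` and lag `l` iff `s - l` equals the trial's
#' maximum-possible-reward sample and `s` lies inside that trial's animation
#' interval. Overlapping contributions from neighbouring trials sum.
#'
#' @param session A `gnomes_session` (its `trials` table supplies event
#'   times, predictability and expectancy).
#' @param spec An [rerp_design()].
#' @param n_samples Number of rows (samples of the recording).
#' @return List with sparse `X` (dgCMatrix), `colmap` data frame
#'   (`col`, `block`, `event`, `lag_s`) and `blocks`.
#' @export
build_design_matrix <- function(session, spec, n_samples) {
  trials <- if (inherits(session, "gnomes_session")) session$trials else session
  stopifnot(inherits(spec, "rerp_design"))
  if (max(trials$t_anim_end) * spec$srate > n_samples) {
    stop("event times extend beyond the recording")
  }
  if (any(is.na(trials$t_max_reward))) stop("t_max_reward missing")
  blocks <- design_blocks(spec, trials)
  srate <- spec$srate
  ii <- list(); jj <- list(); xx <- list()
  offset <- 0L
  colmap <- list()
  for (b in blocks) {
    L <- length(b$lags)
    if (b$event == "reward") {
      for (k in seq_len(nrow(trials))) {
        mod <- b$modulator[k]
        if (mod == 0) next
        an <- animation_samples(trials[k, ], srate, n_samples)
        if (is.null(an)) next
        keep <- an$lag >= b$lags[1] & an$lag <= b$lags[L]
        if (!any(keep)) next
        ii[[length(ii) + 1L]] <- an$idx[keep]
        jj[[length(jj) + 1L]] <- offset + (an$lag[keep] - b$lags[1] + 1L)
        xx[[length(xx) + 1L]] <- rep(mod, sum(keep))
      }
    } else {
      t_ev <- if (b$event == "anim_start") trials$t_anim_start else
        trials$t_anim_end
      s_ev <- round(t_ev * srate) + 1L
      for (k in seq_len(nrow(trials))) {
        mod <- b$modulator[k]
        if (mod == 0) next
        rows <- s_ev[k] + b$lags
        keep <- rows >= 1 & rows <= n_samples
        ii[[length(ii) + 1L]] <- rows[keep]
        jj[[length(jj) + 1L]] <- offset + which(keep)
        xx[[length(xx) + 1L]] <- rep(mod, sum(keep))
      }
    }
    colmap[[length(colmap) + 1L]] <- data.frame(
      col = offset + seq_len(L), block = b$name, event = b$event,
      lag_s = b$lags / srate, stringsAsFactors = FALSE)
    offset <- offset + L
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_samples, offset))
  list(X = X, colmap = do.call(rbind, colmap), blocks = blocks)
}

#' First-difference (Tikhonov) penalty operator
#'
#' Block-diagonal first-difference matrix: within each block, rows
#' `(-1, +1)` on adjacent lags; differences never span block boundaries, so
#' the penalty enforces smoothness of each response kernel separately.
#'
#' @param n_lags_per_block Integer vector of block sizes (each at least 2).
#' @return Sparse matrix `D` with `sum(n) - length(n)` rows.
#' @export
first_difference_penalty <- function(n_lags_per_block) {
  if (any(n_lags_per_block < 2)) stop("blocks must have at least 2 lags")
  offs <- cumsum(c(0, n_lags_per_block[-length(n_lags_per_block)]))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  r0 <- 0L
  for (i in seq_along(n_lags_per_block)) {
    L <- n_lags_per_block[i]
    r <- r0 + seq_len(L - 1)
    rows <- c(rows, r, r)
    cols <- c(cols, offs[i] + seq_len(L - 1), offs[i] + seq_len(L - 1) + 1)
    vals <- c(vals, rep(-1, L - 1), rep(1, L - 1))
    r0 <- r0 + L - 1L
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(sum(n_lags_per_block - 1),
                                sum(n_lags_per_block)))
}

#' Penalized least-squares solve
#'
#' Solves `argmin ||Y - X b||^2 + lambda ||D b||^2` for every column of `Y`
#' (electrode) via the normal equations `(X'X + lambda D'D) b = X'Y`,
#' factored once with a Cholesky decomposition.
#'
#' @param X Sparse or dense design matrix (rows already restricted to the
#'   samples entering the fit).
#' @param Y Numeric vector or samples x electrodes matrix.
#' @param lambda Penalty weight (>= 0).
#' @param D Penalty operator from [first_difference_penalty()].
#' @return Coefficient matrix (columns x electrodes), or vector if `Y` was.
#' @export
tikhonov_solve <- function(X, Y, lambda, D) {
  stopifnot(lambda >= 0)
  yvec <- is.null(dim(Y))
  Y <- as.matrix(Y)
  A <- as.matrix(Matrix::crossprod(X))
  if (lambda > 0) A <- A + lambda * as.matrix(Matrix::crossprod(D))
  XtY <- as.matrix(Matrix::crossprod(X, Y))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) <= max(diag(R)) * 1e-7) {
    stop("normal equations are singular (rank-deficient design with ",
         "lambda = ", lambda, ")")
  }
  B <- backsolve(R, backsolve(R, XtY, transpose = TRUE))
  if (yvec) drop(B) else B
}

#' Cross-validated choice of the regularization parameter
#'
#' Ten-fold cross-validation over contiguous blocks of sample rows (avoiding
#' autocorrelation leakage between train and test). For each fold and each
#' candidate lambda the model is fit on the remaining folds and scored by
#' mean squared prediction error averaged across all electrodes; the chosen
#' lambda minimizes the mean fold error, with ties broken towards the larger
#' (smoother) lambda.
#'
#' @param X,Y,D As in [tikhonov_solve()].
#' @param lambda_grid Candidate penalties (default `10^(2:6)`).
#' @param n_folds Number of folds.
#' @return List with `lambda` (chosen), `mean_error` (per lambda) and
#'   `fold_errors` (folds x lambdas matrix).
#' @export
crossval_lambda <- function(X, Y, D,
                            lambda_grid = c(100, 1000, 1e4, 1e5, 1e6),
                            n_folds = 10) {
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10 * n_folds) stop("too few samples for ", n_folds, "-fold CV")
  lambda_grid <- sort(lambda_grid)
  fold <- cut(seq_len(n), n_folds, labels = FALSE)
  XtX <- as.matrix(Matrix::crossprod(X))
  XtY <- as.matrix(Matrix::crossprod(X, Y))
  DtD <- as.matrix(Matrix::crossprod(D))
  errs <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    rows <- fold == f
    if (!any(rows)) stop("empty cross-validation fold")
    Xf <- X[rows, , drop = FALSE]
    Yf <- Y[rows, , drop = FALSE]
    XtXf <- as.matrix(Matrix::crossprod(Xf))
    XtYf <- as.matrix(Matrix::crossprod(Xf, Yf))
    for (l in seq_along(lambda_grid)) {
      A <- XtX - XtXf + lambda_grid[l] * DtD
      R <- chol(A)
      B <- backsolve(R, backsolve(R, XtY - XtYf, transpose = TRUE))
      resid <- Yf - as.matrix(Xf %*% B)
      errs[f, l] <- mean(resid^2)
    }
  }
  m <- colMeans(errs)
  best <- max(which(m <= min(m) + 1e-12 * abs(min(m))))
  list(lambda = lambda_grid[best], mean_error = stats::setNames(m, lambda_grid),
       fold_errors = errs)
}
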