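test_that("first-difference penalty has the stated block structure", {
  D <- as.matrix(first_difference_penalty(3))
  expect_equal(D, rbind(c(-1, 1, 0), c(0, -1, 1)), ignore_attr = TRUE)
  D2 <- first_difference_penalty(c(3, 4, 2))
  expect_equal(dim(D2), c(9 - 3, 9))
  # derivative of a block-constant vector is zero; no row spans blocks
  b <- c(rep(2, 3), rep(-1, 4), rep(5, 2))
  expect_true(all(as.vector(D2 %*% b) == 0))
  expect_error(first_difference_penalty(c(3, 1)), "at least 2")
})

test_that("tikhonov solve matches hand-computed and OLS references", {
  # 2x2 identity design, lambda = 1: [[2,-1],[-1,2]] b = (0,2)
  X <- diag(2)
  D <- matrix(c(-1, 1), 1, 2)
  b <- tikhonov_solve(X, c(0, 2), 1, D)
  expect_equal(b, c(2 / 3, 4 / 3))
  # lambda = 0 equals OLS on a full-rank random design
  set.seed(1)
  X <- matrix(rnorm(200), 40, 5)
  Y <- matrix(rnorm(80), 40, 2)
  D5 <- first_difference_penalty(5)
  expect_equal(tikhonov_solve(X, Y, 0, D5),
               qr.solve(X, Y), tolerance = 1e-10, ignore_attr = TRUE)
  # rank-deficient design at lambda = 0 is singular
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(tikhonov_solve(Xs, Y[, 1], 0, first_difference_penalty(3)),
               "singular")
})

test_that("solver agrees with a dense brute-force solve on random instances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(60:120, 1)
    p <- sample(5:50, 1)
    X <- Matrix::rsparsematrix(n, p, density = 0.3)
    y <- rnorm(n)
    blocks <- if (p >= 4 && runif(1) < 0.5) c(p %/% 2, p - p %/% 2) else p
    D <- first_difference_penalty(blocks)
    lam <- 10^runif(1, -1, 4)
    got <- tikhonov_solve(X, y, lam, D)
    A <- as.matrix(Matrix::t(X) %*% X) + lam * as.matrix(Matrix::t(D) %*% D)
    ref <- solve(A, as.vector(Matrix::t(X) %*% y))
    expect_lt(sqrt(sum((got - ref)^2)) / sqrt(sum(ref^2)), 1e-8)
  }
})

test_that("increasing lambda smooths monotonically towards block constants", {
  set.seed(3)
  X <- matrix(rnorm(400), 80, 5)
  y <- rnorm(80)
  D <- first_difference_penalty(5)
  lams <- c(0, 1, 10, 100, 1e4, 1e8)
  roughness <- vapply(lams, function(l) {
    sqrt(sum((D %*% tikhonov_solve(X, y, l, D))^2))
  }, numeric(1))
  expect_true(all(diff(roughness) <= 1e-10))
  b_inf <- tikhonov_solve(X, y, 1e10, D)
  expect_lt(max(abs(b_inf - mean(b_inf))), 1e-4)
})

test_that("design matrix geometry: reward columns live inside animations", {
  s <- forge_session(guess = c(0.5, 0.7), outcome = c(0.8, 0.4), gap = 12)
  spec <- rerp_design()
  n <- ceiling(s$duration * 250)
  dm <- build_design_matrix(s, spec, n)
  expect_equal(ncol(dm$X), 1051 + 201 + 201)
  expect_setequal(unique(dm$colmap$block),
                  c("anim_start", "reward", "anim_end"))
  # every nonzero reward entry is inside an animation interval
  rew_cols <- dm$colmap$col[dm$colmap$block == "reward"]
  sub <- dm$X[, rew_cols]
  rows <- unique(Matrix::summary(sub)$i)
  tt <- (rows - 1) / 250
  in_anim <- sapply(tt, function(t)
    any(t >= s$trials$t_anim_start - 1e-9 & t <= s$trials$t_anim_end + 1e-9))
  expect_true(all(in_anim))
  # start block: exactly one stick column per lag per trial
  st_cols <- dm$colmap$col[dm$colmap$block == "anim_start"]
  expect_equal(sum(dm$X[, st_cols] != 0), 2 * 201)
  expect_error(build_design_matrix(s, spec, 100), "beyond the recording")
})

test_that("with non-overlapping identical trials, OLS betas equal the epoch average", {
  # guesses/outcomes identical: every reward lag in [-1.2, 0.2] is supported
  s <- forge_session(guess = rep(0.4, 5), outcome = rep(0.6, 5), gap = 12)
  truth <- forge_truth(transients = FALSE, rms = 0)
  rec <- rereference_mastoids(synthesize_eeg(s, truth))
  spec <- rerp_design(window_reward = c(-1.2, 0.2), events = "reward")
  fit <- fit_rerp(rec, s, spec = spec, lambda = 0)
  avg <- naive_reward_average(rec, s, window = c(-1.2, 0.2))
  expect_equal(coef(fit), avg, tolerance = 1e-8)
})

test_that("deconvolution separates overlapping responses that bias naive averages", {
  # short gaps: start/end transients overlap the reward window
  set.seed(5)
  g <- runif(24, 0.35, 0.65)
  o <- runif(24, 0.5, 0.9)
  s <- forge_session(guess = g, outcome = o, gap = 5)
  truth <- forge_truth(rms = 0)
  rec <- rereference_mastoids(synthesize_eeg(s, truth))
  fit <- fit_rerp(rec, s, lambda = 1)
  true_cp2 <- truth$kernels$reward * truth$topographies$reward[["CP2"]]
  est <- coef(fit)["CP2", ]
  naive <- naive_reward_average(rec, s)["CP2", ]
  sup <- as.numeric(colnames(coef(fit))) >= -1.2  # lags with dense support
  rmse <- function(x) sqrt(mean((x[sup] - true_cp2[sup])^2))
  expect_gt(cor(est[sup], true_cp2[sup]), 0.99)
  expect_lt(rmse(est), rmse(naive) / 2)
})

test_that("scaling a block's regressor rescales its OLS betas inversely", {
  set.seed(6)
  X <- cbind(matrix(rnorm(300), 100, 3), matrix(rnorm(200), 100, 2))
  y <- rnorm(100)
  D <- first_difference_penalty(c(3, 2))
  b1 <- tikhonov_solve(X, y, 0, D)
  X2 <- X
  X2[, 4:5] <- 2 * X2[, 4:5]
  b2 <- tikhonov_solve(X2, y, 0, D)
  expect_equal(b2[1:3], b1[1:3], tolerance = 1e-8)
  expect_equal(b2[4:5], b1[4:5] / 2, tolerance = 1e-8)
})

test_that("condition-split and parametric designs carry the right modulators", {
  s <- forge_session(guess = rep(0.5, 6), outcome = rep(0.6, 6), gap = 10,
                     predictability = rep(c("high", "low"), 3))
  s$trials$expectancy <- c(NA, 0.6, 0.7, 0.8, 0.5, 0.4)
  n <- ceiling(s$duration * 250)
  dm_split <- build_design_matrix(s, rerp_design("condition_split"), n)
  expect_setequal(unique(dm_split$colmap$block),
                  c(paste0(c("anim_start.", "anim_end.", "reward."), "high"),
                    paste0(c("anim_start.", "anim_end.", "reward."), "medium"),
                    paste0(c("anim_start.", "anim_end.", "reward."), "low")))
  # medium blocks are empty (no medium trials here)
  med_cols <- dm_split$colmap$col[grepl("medium", dm_split$colmap$block)]
  expect_equal(sum(dm_split$X[, med_cols] != 0), 0)
  dm_par <- build_design_matrix(s, rerp_design("parametric_expectancy"), n)
  expect_true("reward.expectancy" %in% dm_par$colmap$block)
  # parametric entries: mean-centred expectancy; NA encounters contribute 0
  ex_cols <- dm_par$colmap$col[dm_par$colmap$block == "reward.expectancy"]
  vals <- unique(round(Matrix::summary(dm_par$X[, ex_cols])$x, 10))
  centred <- round(s$trials$expectancy - mean(s$trials$expectancy,
                                              na.rm = TRUE), 10)
  expect_setequal(vals, setdiff(centred[!is.na(centred)], 0))
})

test_that("cross-validation prefers heavy smoothing for pure white noise", {
  set.seed(9)
  s <- forge_session(guess = runif(30, 0.3, 0.7), outcome = runif(30, 0.3, 0.9),
                     gap = 5)
  n <- ceiling(s$duration * 250)
  dm <- build_design_matrix(s, rerp_design(window_reward = c(-1, 0.2)), n)
  D <- first_difference_penalty(as.integer(
    table(factor(dm$colmap$block, levels = unique(dm$colmap$block)))))
  Y <- matrix(rnorm(n * 2), n, 2)
  cv <- crossval_lambda(dm$X, Y, D, lambda_grid = c(100, 1e4, 1e6))
  expect_equal(cv$lambda, 1e6)
  # deterministic: same inputs, same choice and error table
  cv2 <- crossval_lambda(dm$X, Y, D, lambda_grid = c(100, 1e4, 1e6))
  expect_identical(cv, cv2)
})

test_that("cross-validation recovers smooth kernels from clean synthetic data", {
  s <- forge_session(guess = runif(20, 0.35, 0.6),
                     outcome = runif(20, 0.45, 0.85), gap = 6)
  truth <- forge_truth(rms = 1)
  rec <- rereference_mastoids(synthesize_eeg(s, truth, seed = 12))
  fit <- fit_rerp(rec, s, lambda_grid = c(1, 100, 1e4, 1e6))
  sup <- as.numeric(colnames(coef(fit))) >= -1.2
  true_cp2 <- truth$kernels$reward * truth$topographies$reward[["CP2"]]
  expect_gt(cor(coef(fit)["CP2", sup], true_cp2[sup]), 0.95)
})

test_that("condition-split and parametric variants fit end to end", {
  set.seed(31)
  s <- forge_session(guess = runif(18, 0.35, 0.65),
                     outcome = runif(18, 0.4, 0.9), gap = 6,
                     predictability = rep(c("high", "medium", "low"), 6))
  s$trials$expectancy <- c(NA, runif(17, 0.5, 0.9))
  truth <- forge_truth(rms = 3,
                       gains = c(high = 0.5, medium = 1, low = 1.2))
  rec <- rereference_mastoids(synthesize_eeg(s, truth, seed = 8))
  fs <- fit_rerp(rec, s, spec = rerp_design("condition_split",
                                            window_reward = c(-1.5, 0.2)),
                 lambda = 1e3)
  expect_setequal(names(fs$betas),
                  as.vector(outer(c("anim_start.", "anim_end.", "reward."),
                                  c("high", "medium", "low"), paste0)))
  # injected gains differ: recovered per-condition kernels differ too
  expect_gt(mean(abs(fs$betas$reward.low - fs$betas$reward.high)), 0.1)
  fp <- fit_rerp(rec, s, spec = rerp_design("parametric_expectancy",
                                            window_reward = c(-1.5, 0.2)),
                 lambda = 1e3)
  expect_true(all(c("anim_start", "reward", "reward.expectancy",
                    "anim_end") %in% names(fp$betas)))
  expect_equal(dim(fp$betas$reward.expectancy), dim(fp$betas$reward))
})

test_that("masking a few percent of modeled samples barely moves the kernel", {
  s <- simulate_session(session_config(seed = 77, encounters_per_cue = 8))
  truth <- forge_truth(rms = 10)
  rec <- rereference_mastoids(synthesize_eeg(s, truth, seed = 78))
  fit0 <- fit_rerp(rec, s, lambda = 1e4)
  # flag ~2.5% of modeled (animation) samples
  rw <- continuous_reward_signal(s, srate = rec$srate,
                                 n_samples = ncol(rec$data))
  modeled <- which(rw$values != 0)
  set.seed(79)
  start <- sample(modeled, 1)
  rec$mask[start:(start + round(0.025 * length(modeled)))] <- TRUE
  fit1 <- fit_rerp(rec, s, lambda = 1e4)
  r0 <- cor(coef(fit0)["CP2", ], truth$kernels$reward)
  r1 <- cor(coef(fit1)["CP2", ], truth$kernels$reward)
  expect_lt(abs(r0 - r1), 0.02)
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  s <- forge_session(guess = rep(0.5, 4), outcome = rep(0.7, 4), gap = 10)
  truth <- forge_truth(rms = 2)
  rec <- rereference_mastoids(synthesize_eeg(s, truth, seed = 2))
  fit <- fit_rerp(rec, s, lambda = 100)
  bc <- baseline_correct(fit, c(-4, -1))
  lag <- fit$lags$reward
  sel <- lag >= -4 & lag <= -1
  expect_equal(max(abs(rowMeans(bc$betas$reward[, sel]))), 0,
               tolerance = 1e-10)
  bc2 <- baseline_correct(bc, c(-4, -1))
  expect_equal(bc2$betas$reward, bc$betas$reward, tolerance = 1e-12)
  # constant series maps to zero
  fit0 <- fit
  fit0$betas$reward[] <- 3
  expect_true(all(abs(baseline_correct(fit0)$betas$reward) < 1e-12))
  expect_error(baseline_correct(fit, c(-5, -1)), "outside")
  # masked fits refuse to run on fully flagged data
  rec$mask[] <- TRUE
  expect_error(fit_rerp(rec, s, lambda = 1), "masked")
})
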