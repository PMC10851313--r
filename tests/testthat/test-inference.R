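toy_tmap <- function(E, T, labels = paste0("e", seq_len(E))) {
  m <- matrix(0, E, T, dimnames = list(labels, NULL))
  m
}

chain_adjacency <- function(labels) {
  adj <- lapply(seq_along(labels), function(i) {
    labels[setdiff(c(i - 1, i + 1), c(0, length(labels) + 1))]
  })
  names(adj) <- labels
  adj
}

as_tmap <- function(m, df = 10, lags = NULL) {
  if (is.null(lags)) lags <- (seq_len(ncol(m)) - 1) / 250
  structure(list(t = m, n = df + 1, df = df, lags = lags,
                 labels = rownames(m),
                 zero_variance = matrix(FALSE, nrow(m), ncol(m))),
            class = "tmap")
}

test_that("zero-lag correlation hits +/-1 on perfectly (anti)correlated channels", {
  set.seed(1)
  v <- pmax(sin(seq(0, 20, length.out = 2000)), 0)
  data <- rbind(v, -v, rnorm(2000))
  rec <- contrerp:::new_recording(data, 250, c("same", "opp", "noise"))
  r <- zero_lag_correlation(rec, v)
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["opp"]), -1)
  expect_lt(abs(r["noise"]), 0.1)
  # masked samples are dropped; scope restriction to modeled samples works
  rec$mask[1:500] <- TRUE
  r2 <- zero_lag_correlation(rec, v)
  expect_equal(unname(r2["same"]), 1)
  r3 <- zero_lag_correlation(rec, v, scope = "modeled_only")
  expect_equal(unname(r3["same"]), 1)
  rec$mask[] <- TRUE
  expect_error(zero_lag_correlation(rec, v), "3 usable")
})

test_that("group t map matches the closed form and flags degenerate input", {
  vals <- cbind(a = c(0.4, 0.6, 0.3, 0.7), b = c(-0.1, 0.1, -0.2, 0.2))
  res <- group_ttest_map(vals)
  expect_equal(res$t[1], mean(vals[, 1]) / (sd(vals[, 1]) / 2))
  expect_equal(res$t[2], 0)
  expect_false(res$significant[2])
  # n = 20, mean 0.5, SD 0.5 -> t = 4.472
  x <- qnorm(ppoints(20))
  x <- (x - mean(x)) / sd(x) * 0.5 + 0.5
  res20 <- group_ttest_map(cbind(v = x))
  expect_equal(res20$t[1], 4.472136, tolerance = 1e-6)
  expect_equal(res20$df[1], 19)
  const <- cbind(k = rep(0.3, 5))
  expect_true(group_ttest_map(const)$zero_variance[1])
})

test_that("t map equals the direct formula and is antisymmetric in sign", {
  m1 <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c(0, 0.004)))
  m2 <- m1 + 1
  m3 <- m1 - 0.5
  tm <- t_map(list(m1, m2, m3))
  arr <- simplify2array(list(m1, m2, m3))
  expect_equal(tm$t,
               apply(arr, c(1, 2), mean) /
                 (apply(arr, c(1, 2), sd) / sqrt(3)))
  expect_equal(tm$df, 2)
  flipped <- t_map(list(-m1, -m2, -m3))
  expect_equal(flipped$t, -tm$t)
  expect_error(t_map(list(m1, m2 * NA)), "non-finite")
})

test_that("cluster finding matches the brute-force enumeration oracle", {
  labels <- c("e1", "e2", "e3", "e4")
  adj <- chain_adjacency(labels)
  A <- contrerp:::adjacency_matrix(adj, labels)
  set.seed(11)
  for (rep in 1:12) {
    E <- 4; T <- sample(8:30, 1)
    m <- matrix(rnorm(E * T, sd = 2.2), E, T, dimnames = list(labels, NULL))
    tm <- as_tmap(m, df = 9)
    thresh <- qt(0.975, 9)
    got <- find_clusters(tm, adj, window = range(tm$lags))
    want <- oracle_clusters(m, A, thresh)
    got_keys <- sort(vapply(seq_len(nrow(got)), function(i) {
      paste(cluster_key(sort(match(got$electrodes[[i]], labels)),
                        round(got$lag_start[i] * 250) + 1,
                        round(got$lag_end[i] * 250) + 1, got$sign[i]),
            sprintf("%.6f", got$mass[i]))
    }, character(1)))
    want_keys <- sort(vapply(want, function(w)
      paste(cluster_key(w$members, w$a, w$b, w$sign),
            sprintf("%.6f", w$mass)), character(1)))
    expect_identical(got_keys, want_keys)
  }
})

test_that("cluster membership requires simultaneous same-sign exceedance", {
  labels <- c("e1", "e2", "e3")
  adj <- chain_adjacency(labels)
  m <- toy_tmap(3, 10, labels)
  expect_equal(nrow(find_clusters(as_tmap(m, 9), adj,
                                  window = c(0, 1))), 0)
  # single supra-threshold electrode, neighbours silent -> singleton cluster
  m["e2", 3:7] <- 5
  got <- find_clusters(as_tmap(m, 9), adj, window = c(0, 1))
  expect_equal(nrow(got), 1)
  expect_equal(got$electrodes[[1]], "e2")
  expect_equal(got$mass[1], 25)
  expect_equal(round(got$lag_start[1] * 250) + 1, 3)
  # adjacent electrodes with opposite signs never form one cluster
  m["e3", 3:7] <- -5
  got2 <- find_clusters(as_tmap(m, 9), adj, window = c(0, 1))
  expect_equal(nrow(got2), 2)
  expect_true(all(lengths(got2$electrodes) == 1))
})

test_that("permutation test is deterministic, calibrated on its own null draw", {
  labels <- paste0("e", 1:4)
  adj <- chain_adjacency(labels)
  set.seed(3)
  mats <- lapply(1:8, function(i) {
    matrix(rnorm(4 * 20, sd = 1), 4, 20,
           dimnames = list(labels, seq(0, 19) / 250))
  })
  r1 <- permutation_test(mats, adj, n_perm = 200, seed = 5,
                         window = c(0, 0.1))
  r2 <- permutation_test(mats, adj, n_perm = 200, seed = 5,
                         window = c(0, 0.1))
  expect_identical(r1$clusters$p, r2$clusters$p)
  expect_identical(r1$null_max, r2$null_max)
  expect_length(r1$null_max, 200)
  # strong common signal: a significant cluster with tiny p
  sig <- lapply(1:8, function(i) {
    m <- matrix(rnorm(4 * 20, sd = 0.2), 4, 20,
                dimnames = list(labels, seq(0, 19) / 250))
    m[2:3, 6:15] <- m[2:3, 6:15] - 3
    m
  })
  rs <- permutation_test(sig, adj, n_perm = 200, seed = 5, window = c(0, 0.1))
  expect_true(any(rs$clusters$significant))
  top <- rs$clusters[1, ]
  expect_equal(top$sign, -1)
  expect_true(all(c("e2", "e3") %in% top$electrodes[[1]]))
  # p-value options: strict proportion vs (k+1)/(n+1)
  rp <- permutation_test(sig, adj, n_perm = 200, seed = 5,
                         window = c(0, 0.1), p_plus_one = TRUE)
  expect_equal(rp$clusters$p[1], (sum(rs$null_max >= rp$clusters$mass[1]) + 1)
               / 201)
})

test_that("condition contrasts are antisymmetric and null under no difference", {
  labels <- paste0("e", 1:4)
  adj <- chain_adjacency(labels)
  set.seed(6)
  a <- lapply(1:6, function(i) {
    m <- matrix(rnorm(80, sd = 0.3), 4, 20,
                dimnames = list(labels, seq(0, 19) / 250))
    m[2, 5:12] <- m[2, 5:12] + 2
    m
  })
  b <- lapply(1:6, function(i) matrix(rnorm(80, sd = 0.3), 4, 20,
                                      dimnames = list(labels, seq(0, 19) / 250)))
  ab <- condition_contrast(a, b, adj, n_perm = 100, seed = 2,
                           window = c(0, 0.1))
  ba <- condition_contrast(b, a, adj, n_perm = 100, seed = 2,
                           window = c(0, 0.1))
  expect_equal(ab$clusters$mass, ba$clusters$mass)
  expect_equal(ab$clusters$sign, -ba$clusters$sign)
  expect_error(condition_contrast(a, b[1:3], adj), "paired")
  aa <- condition_contrast(a, a, adj, n_perm = 50, seed = 2,
                           window = c(0, 0.1))
  expect_equal(nrow(aa$clusters), 0)
})

test_that("cluster Cohen's d is the mean/SD of per-participant cluster means", {
  labels <- c("x", "y")
  mats <- lapply(c(-2, -1, -3), function(v) {
    matrix(v, 2, 4, dimnames = list(labels, c(0, 0.004, 0.008, 0.012)))
  })
  cl <- data.frame(lag_start = 0, lag_end = 0.012, sign = -1, mass = 10)
  cl$electrodes <- list(c("x", "y"))
  expect_equal(cohens_d_cluster(mats, cl[1, ]), -2)
  same <- lapply(c(1, 1, 1), function(v)
    matrix(v, 2, 4, dimnames = list(labels, c(0, 0.004, 0.008, 0.012))))
  expect_warning(d0 <- cohens_d_cluster(same, cl[1, ]), "zero standard")
  expect_true(is.na(d0))
})

test_that("repeated-measures ANOVA matches aov and the printed formulas", {
  d <- matrix(c(0.05, 0.11, 0.16,
                0.07, 0.10, 0.18,
                0.04, 0.13, 0.15,
                0.06, 0.09, 0.20), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("high", "medium", "low")))
  res <- rm_anova_predictability(d)
  long <- data.frame(y = as.vector(d),
                     cond = factor(rep(colnames(d), each = 4)),
                     subj = factor(rep(1:4, 3)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = long))
  tab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(res$F, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(unname(res$ss["SS_P"]), tab["cond", "Sum Sq"])
  expect_equal(unname(res$ss["SS_sP"]), tab["Residuals", "Sum Sq"])
  expect_equal(res$df, c(2, 6))
  # eta formulas
  expect_equal(res$eta_p2,
               res$ss[["SS_P"]] / (res$ss[["SS_P"]] + res$ss[["SS_sP"]]))
  expect_equal(res$eta_g2, res$ss[["SS_P"]] /
                 (res$ss[["SS_P"]] + res$ss[["SS_S"]] + res$ss[["SS_sP"]]))
  expect_true(res$eta_g2 <= res$eta_p2)
  expect_true(res$eta_p2 <= 1 && res$eta_g2 >= 0)
  # identical condition means per participant -> F = 0
  d0 <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), 3), 4, 3,
               dimnames = list(NULL, colnames(d)))
  expect_equal(rm_anova_predictability(d0)$F, 0)
  # direct formula check: SS_P = 4, SS_sP = 6 -> partial eta^2 = 0.4
  expect_equal(4 / (4 + 6), 0.4)
  expect_error(rm_anova_predictability(d[1, , drop = FALSE]), "2 participants")
  dna <- d; dna[2, 2] <- NA
  expect_error(rm_anova_predictability(dna), "complete")
})

test_that("permutation p values ignore channel order and all-zero participants", {
  labels <- paste0("e", 1:4)
  adj <- chain_adjacency(labels)
  set.seed(13)
  mats <- lapply(1:7, function(i) {
    m <- matrix(rnorm(80, sd = 0.5), 4, 20,
                dimnames = list(labels, seq(0, 19) / 250))
    m[1:2, 4:10] <- m[1:2, 4:10] + 1.5
    m
  })
  r <- permutation_test(mats, adj, n_perm = 150, seed = 4, window = c(0, 0.1))
  perm <- c(3, 1, 4, 2)
  mats_p <- lapply(mats, function(m) m[perm, ])
  r_p <- permutation_test(mats_p, adj, n_perm = 150, seed = 4,
                          window = c(0, 0.1))
  expect_equal(sort(r$clusters$mass), sort(r_p$clusters$mass))
  expect_equal(sort(r$clusters$p), sort(r_p$clusters$p))
})
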