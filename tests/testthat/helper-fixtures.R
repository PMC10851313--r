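# Shared fixture builders. Everything is generated in code at test time.

# A hand-built session with fully controlled guesses/outcomes and event
# times; bypasses the behavioural policy so tests can pin the geometry.
forge_session <- function(guess, outcome, gap = 4, first_start = 2,
                          predictability = NULL, participant_id = "sub-fx") {
  n <- length(guess)
  stopifnot(length(outcome) == n)
  if (is.null(predictability)) predictability <- rep("medium", n)
  starts <- first_start + (seq_len(n) - 1) * gap
  trials <- data.frame(
    participant_id = participant_id, trial = seq_len(n),
    cue_id = rep_len(1:6, n), dist_kind = "forged",
    predictability = predictability,
    guess = guess, outcome = outcome, p_err = abs(guess - outcome),
    points = 100 * (1 - abs(guess - outcome)),
    expectancy = NA_real_,
    t_fix = starts - 1.5, t_cue = starts - 1.2, t_response = starts - 0.6,
    t_anim_start = starts,
    t_anim_end = starts + 3 * outcome,
    t_max_reward = starts + 3 * guess,
    stringsAsFactors = FALSE)
  structure(list(trials = trials, cues = make_cue_set(1),
                 config = session_config(participant_id = participant_id),
                 duration = max(trials$t_anim_end) + 2),
            class = "gnomes_session")
}

# Ground truth with selected components silenced (zero amplitude)
forge_truth <- function(reward = TRUE, transients = TRUE,
                        gains = c(high = 1, medium = 1, low = 1),
                        rms = 0) {
  tr <- make_ground_truth(condition_gains = gains,
                          noise = noise_config(rms_total = rms))
  if (!reward) tr$kernels$reward[] <- 0
  if (!transients) {
    tr$kernels$anim_start[] <- 0
    tr$kernels$anim_end[] <- 0
  }
  tr
}

flat_recording <- function(n_ch = 4, n = 1000, srate = 250,
                           labels = paste0("ch", seq_len(n_ch))) {
  contrerp:::new_recording(matrix(0, n_ch, n), srate, labels)
}

# independent brute-force spatio-temporal cluster enumeration:
# all connected electrode subsets x all temporal runs, maximality enforced
# directly from the definition
oracle_clusters <- function(tmap, adj_mat, thresh) {
  E <- nrow(tmap); T <- ncol(tmap)
  labels <- rownames(tmap)
  subsets <- list()
  for (k in seq_len(E)) {
    for (comb in utils::combn(E, k, simplify = FALSE)) {
      if (k == 1) { subsets[[length(subsets) + 1]] <- comb; next }
      # connectivity check by flood fill
      reach <- comb[1]
      repeat {
        grow <- unique(unlist(lapply(reach, function(e)
          intersect(which(adj_mat[e, ]), comb))))
        new_reach <- union(reach, grow)
        if (length(new_reach) == length(reach)) break
        reach <- new_reach
      }
      if (length(reach) == k) subsets[[length(subsets) + 1]] <- comb
    }
  }
  out <- list()
  for (S in subsets) {
    for (sgn in c(1, -1)) {
      ok <- apply(tmap[S, , drop = FALSE] * sgn > thresh, 2, all)
      r <- rle(ok)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (i in which(r$values)) {
        a <- starts[i]; b <- ends[i]
        # electrode-maximality: no adjacent electrode supra throughout [a,b]
        nb <- setdiff(which(apply(adj_mat[S, , drop = FALSE], 2, any)), S)
        addable <- any(vapply(nb, function(e)
          all(tmap[e, a:b] * sgn > thresh), logical(1)))
        if (addable) next
        out[[length(out) + 1]] <- list(
          members = sort(S), a = a, b = b, sign = sgn,
          mass = sum(abs(tmap[S, a:b])))
      }
    }
  }
  out
}

cluster_key <- function(members, a, b, sign) {
  paste(paste(members, collapse = ","), a, b, sign, sep = "|")
}
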