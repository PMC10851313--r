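#' Configuration of an end-to-end simulation run
#'
#' Everything needed to reproduce a run: participant count, seeds, noise
#' settings, model variant, regularization, permutation count, and output
#' options. A run is a deterministic function of its configuration.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Base seed; per-participant and permutation seeds derive from
#'   it deterministically.
#' @param condition_gains Reward-kernel gains by predictability for the
#'   synthesizer.
#' @param noise A [noise_config()].
#' @param encounters_per_cue Encounters of each of the 6 cues.
#' @param variant Model variant passed to [rerp_design()].
#' @param lambda Fixed penalty, or `NULL` for per-participant 10-fold CV.
#' @param lambda_grid CV grid.
#' @param baseline Baseline window for [baseline_correct()] or `NULL`.
#' @param n_perm Permutations for the cluster test.
#' @param n_artifacts Square-pulse artifacts injected per participant.
#' @param exclude_flagged_frac Exclude participants whose fraction of
#'   flagged modeled samples exceeds this value.
#' @param output_dir Output directory, or `NULL` to skip writing files.
#' @param write_recordings Also export each preprocessed recording as a
#'   BrainVision triplet (large files; off by default).
#' @return List of class `run_config`.
#' @export
run_config <- function(n_participants = 20, seed = 1L,
                       condition_gains = c(high = 0.5, medium = 1, low = 1.2),
                       noise = noise_config(),
                       encounters_per_cue = 25L,
                       variant = "pooled",
                       lambda = NULL,
                       lambda_grid = c(100, 1000, 1e4, 1e5, 1e6),
                       baseline = NULL,
                       n_perm = 1000,
                       n_artifacts = 0,
                       exclude_flagged_frac = 0.175,
                       output_dir = NULL,
                       write_recordings = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-participant seed stream (kept well below 2^31)
derive_seed <- function(seed, i, stream = 0L) {
  (as.integer(seed) %% 100000L) * 10000L + stream * 1000L + i
}

config_hash <- function(config) {
  # 31-bit polynomial rolling hash of the JSON serialization; a content
  # fingerprint for sidecar files (stays exact in double arithmetic).
  # Output options are not part of the scientific configuration.
  config <- config[setdiff(names(config), c("output_dir", "write_recordings"))]
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, null = "null", force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror the arguments of [run_config()]; omitted fields keep their
#' defaults. `condition_gains` and `noise` may be given as named maps.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(vals$condition_gains)) {
    vals$condition_gains <- unlist(vals$condition_gains)
  }
  if (!is.null(vals$noise)) vals$noise <- do.call(noise_config, vals$noise)
  do.call(run_config, vals)
}

#' Run the full simulate-preprocess-fit-stats pipeline
#'
#' For each simulated participant: generate a behavioural session, forward-
#' synthesize EEG from the ground truth, preprocess (resample, filter,
#' re-reference, artifact mask), fit the rERP model, and compute the
#' zero-lag reward correlation. Then compute group statistics: the
#' Bonferroni-corrected correlation t map, the cluster-mass permutation test
#' of the reward rERP, and the behavioural repeated-measures ANOVA. If
#' `config$output_dir` is set, per-participant events and rERP tables plus
#' group-level JSON/TSV results (each stamped with the configuration hash)
#' are written there.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `rerps`, `sessions`, `correlations`,
#'   `corr_test`, `cluster_test`, `anova`, `excluded`, `truth`, `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  truth <- make_ground_truth(condition_gains = config$condition_gains,
                             noise = config$noise)
  adjacency <- montage_adjacency()
  spec <- rerp_design(variant = config$variant)
  rerps <- list(); sessions <- list(); correlations <- list()
  excluded <- character(0)
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("sub-%02d", i)
    cfg <- session_config(seed = derive_seed(config$seed, i, 0L),
                          participant_id = pid,
                          encounters_per_cue = config$encounters_per_cue)
    session <- simulate_session(cfg)
    rec <- synthesize_eeg(session, truth,
                          seed = derive_seed(config$seed, i, 1L))
    if (config$n_artifacts > 0) {
      rec <- inject_artifacts(rec, n_events = config$n_artifacts,
                              seed = derive_seed(config$seed, i, 2L))
    }
    rec <- preprocess(rec)
    reward <- continuous_reward_signal(session, srate = rec$srate,
                                       n_samples = ncol(rec$data))
    modeled <- reward$values != 0
    flagged_frac <- if (any(modeled)) mean(rec$mask[modeled]) else 0
    if (flagged_frac > config$exclude_flagged_frac) {
      excluded <- c(excluded, pid)
      next
    }
    fit <- fit_rerp(rec, session, spec = spec, lambda = config$lambda,
                    lambda_grid = config$lambda_grid,
                    baseline = config$baseline)
    rerps[[pid]] <- fit
    sessions[[pid]] <- session
    correlations[[pid]] <- zero_lag_correlation(rec, reward)
    if (!is.null(out_dir)) {
      write_events_tsv(session, file.path(out_dir,
                                          paste0(pid, "_events.tsv")))
      write_rerp_tsv(fit, file.path(out_dir, paste0(pid, "_rerp.tsv")))
      utils::write.table(mask_spans(rec$mask),
                         file.path(out_dir, paste0(pid, "_artifacts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (config$write_recordings) {
        write_brainvision(rec, file.path(out_dir, paste0(pid, "_eeg")))
      }
    }
  }
  if (length(rerps) < 2) stop("fewer than 2 participants survived exclusion")
  corr_mat <- do.call(rbind, correlations)
  corr_test <- group_ttest_map(corr_mat)
  ct <- permutation_test(unname(rerps), adjacency, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 0L, 3L))
  anova <- rm_anova_predictability(behavioral_distances(unname(sessions)))
  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(participant = rownames(corr_mat), corr_mat),
      file.path(out_dir, "correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- ct$clusters
    cl$electrodes <- vapply(cl$electrodes, paste, character(1),
                            collapse = " ")
    jsonlite::write_json(
      list(config_hash = hash, clusters = cl),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config_hash = hash, F = anova$F, df = anova$df, p = anova$p,
           eta_p2 = anova$eta_p2, eta_g2 = anova$eta_g2,
           means = as.list(anova$means)),
      file.path(out_dir, "behavior_anova.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           n_participants = config$n_participants,
           excluded = excluded,
           chosen_lambda = vapply(rerps, function(r) r$lambda, numeric(1))),
      file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(rerps = rerps, sessions = sessions,
                 correlations = corr_mat, corr_test = corr_test,
                 cluster_test = ct, anova = anova, excluded = excluded,
                 truth = truth, config = config, config_hash = hash))
}

#' Import a directory of BrainVision recordings with event tables
#'
#' Bridge for externally recorded data: pairs every `*.vhdr` in `dir` with a
#' sibling `*_events.tsv` (matching file stem up to a `_eeg` suffix). Trials
#' whose `t_max_reward` cannot be derived are skipped with a warning.
#'
#' @param dir Directory containing BrainVision triplets and events TSVs.
#' @return List with one element per recording: `recording` and `trials`.
#' @export
import_bids_like <- function(dir) {
  vhdrs <- list.files(dir, pattern = "\\.vhdr$", full.names = TRUE)
  if (!length(vhdrs)) stop("no .vhdr files found in ", dir)
  lapply(vhdrs, function(vh) {
    rec <- read_brainvision(vh)
    stem <- sub("_eeg$", "", sub("\\.vhdr$", "", vh))
    ev_path <- paste0(stem, "_events.tsv")
    trials <- NULL
    if (file.exists(ev_path)) {
      trials <- read_events_tsv(ev_path)
      bad <- is.na(trials$t_max_reward)
      if (any(bad)) {
        warning(sum(bad), " trial(s) without derivable t_max_reward skipped")
        trials <- trials[!bad, , drop = FALSE]
      }
    }
    list(recording = rec, trials = trials)
  })
}
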