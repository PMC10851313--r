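#' Write a session's trial events as a tab-separated table
#'
#' BIDS-events dialect: `onset` (s, animation start), `duration` (s), and
#' `trial_type`, followed by the behavioural columns the analysis needs
#' (`cue_id`, `guess`, `outcome`, `points`, `expectancy`, `t_max_reward`,
#' `predictability`).
#'
#' @param session A `gnomes_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(session, path) {
  tr <- session$trials
  tab <- data.frame(
    onset = tr$t_anim_start,
    duration = tr$t_anim_end - tr$t_anim_start,
    trial_type = "bar_animation",
    trial = tr$trial, cue_id = tr$cue_id,
    predictability = tr$predictability,
    guess = tr$guess, outcome = tr$outcome, points = tr$points,
    expectancy = ifelse(is.na(tr$expectancy), "n/a", tr$expectancy),
    t_max_reward = tr$t_max_reward,
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial-events table written by [write_events_tsv()]
#'
#' @param path File path.
#' @return Data frame of trials (with `t_anim_start`/`t_anim_end` columns
#'   reconstructed from onset/duration; `expectancy` `NA` where undefined).
#' @export
read_events_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = c("NA", "n/a"),
                           stringsAsFactors = FALSE)
  tab$t_anim_start <- tab$onset
  tab$t_anim_end <- tab$onset + tab$duration
  if (is.null(tab$t_max_reward)) {
    stop("events table lacks t_max_reward; trials cannot be reward-aligned")
  }
  tab
}

#' Write rERP coefficients as a long-format TSV plus JSON metadata
#'
#' @param rerp An `rerp` object.
#' @param path Output TSV path; a `.json` sidecar with lambda, variant and
#'   baseline settings is written next to it.
#' @return `path`, invisibly.
#' @export
write_rerp_tsv <- function(rerp, path) {
  rows <- do.call(rbind, lapply(names(rerp$betas), function(bl) {
    m <- rerp$betas[[bl]]
    data.frame(block = bl,
               electrode = rep(rownames(m), times = ncol(m)),
               lag_s = rep(as.numeric(colnames(m)), each = nrow(m)),
               beta_uv = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(lambda = rerp$lambda, variant = rerp$variant,
               baseline = rerp$baseline,
               participant_id = rerp$participant_id,
               srate = rerp$srate, n_samples_used = rerp$n_samples_used)
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Export a recording as a BrainVision triplet
#'
#' Minimal BrainVision writer: `.vhdr` header (INI dialect), `.vmrk` marker
#' file with one marker per bar-animation onset, and multiplexed IEEE
#' float32 binary `.eeg` data in microvolts.
#'
#' @param recording An `eeg_recording`.
#' @param basename Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(recording, basename) {
  stem <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nch <- nrow(recording$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$srate)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$labels))
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", stem, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(recording$events) && nrow(recording$events)) {
    pos <- round(recording$events$t_anim_start * recording$srate) + 1
    mk <- c(mk, sprintf("Mk%d=Stimulus,S %d,%d,1,0",
                        seq_along(pos) + 1, recording$events$trial, pos))
  }
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_vhdr <- function(lines) {
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("malformed BrainVision header: missing ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  fmt <- get1("BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stop("unsupported BinaryFormat: ", fmt)
  orient <- get1("DataOrientation")
  if (orient != "MULTIPLEXED") stop("unsupported DataOrientation: ", orient)
  nch <- as.integer(get1("NumberOfChannels"))
  srate <- 1e6 / as.numeric(get1("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  if (length(labels) != nch) stop("channel count mismatch in header")
  list(datafile = get1("DataFile"), markerfile = get1("MarkerFile"),
       nch = nch, srate = srate, labels = labels)
}

#' Import a BrainVision triplet
#'
#' Reads the `.vhdr`/`.vmrk`/`.eeg` files written by [write_brainvision()]
#' (multiplexed IEEE float32). Stimulus markers are returned as an event
#' table of onset samples.
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @return An `eeg_recording` (events hold marker onsets in seconds).
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  h <- parse_vhdr(lines)
  dir <- dirname(vhdr_path)
  vmrk <- file.path(dir, h$markerfile)
  eeg <- file.path(dir, h$datafile)
  if (!file.exists(vmrk)) stop("marker file not found: ", vmrk)
  if (!file.exists(eeg)) stop("data file not found: ", eeg)
  sz <- file.info(eeg)$size
  vals <- readBin(eeg, "numeric", n = sz / 4, size = 4, endian = "little")
  n <- length(vals) %/% h$nch
  data <- matrix(vals[seq_len(n * h$nch)], nrow = h$nch)
  mlines <- grep("^Mk[0-9]+=Stimulus", readLines(vmrk, warn = FALSE),
                 value = TRUE)
  events <- NULL
  if (length(mlines)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
    events <- data.frame(
      trial = as.integer(sub("^S\\s*", "", vapply(parts, `[`, character(1), 2))),
      t_anim_start = (as.numeric(vapply(parts, `[`, character(1), 3)) - 1) /
        h$srate,
      stringsAsFactors = FALSE)
  }
  new_recording(data, h$srate, h$labels, events = events)
}
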