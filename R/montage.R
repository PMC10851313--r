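#' Standard 30-channel scalp montage
#'
#' Returns the fixed 10-20 layout used throughout the package: 30 scalp
#' electrodes (the classic 32-channel cap minus the two mastoids) with
#' schematic top-view coordinates on a unit head (vertex at the origin,
#' radius 1 at the lowest electrode ring, roughly 9 cm on an adult head).
#' The two mastoid channels (`M1`, `M2`) are carried separately by
#' [synthesize_eeg()] and consumed by [rereference_mastoids()].
#'
#' @return A data frame with columns `label`, `x`, `y`.
#' @export
standard_montage <- function() {
  tab <- c(
    "Fp1", -0.31,  0.95,   "Fp2",  0.31,  0.95,
    "F7",  -0.81,  0.59,   "F3",  -0.40,  0.62,
    "Fz",   0.00,  0.64,   "F4",   0.40,  0.62,
    "F8",   0.81,  0.59,
    "FT9", -0.98,  0.33,   "FC5", -0.59,  0.31,
    "FC1", -0.22,  0.33,   "FC2",  0.22,  0.33,
    "FC6",  0.59,  0.31,   "FT10", 0.98,  0.33,
    "T7",  -1.00,  0.00,   "C3",  -0.50,  0.00,
    "Cz",   0.00,  0.00,   "C4",   0.50,  0.00,
    "T8",   1.00,  0.00,
    "CP5", -0.59, -0.31,   "CP1", -0.22, -0.33,
    "CPz",  0.00, -0.33,   "CP2",  0.22, -0.33,
    "CP6",  0.59, -0.31,
    "P7",  -0.81, -0.59,   "P3",  -0.40, -0.62,
    "Pz",   0.00, -0.64,   "P4",   0.40, -0.62,
    "P8",   0.81, -0.59,
    "O1",  -0.31, -0.95,   "O2",   0.31, -0.95
  )
  m <- matrix(tab, ncol = 3, byrow = TRUE)
  data.frame(
    label = m[, 1],
    x = as.numeric(m[, 2]),
    y = as.numeric(m[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Electrode adjacency graph for cluster formation
#'
#' Builds the neighbour lists used to define spatial clusters: two
#' electrodes are neighbours when their schematic distance is below
#' `max_dist` (default 0.55 head units, about 5 cm). The graph is
#' symmetric with no self-loops and is the package's stand-in for a
#' template neighbourhood file; supply your own list to the inference
#' functions to use a different template.
#'
#' @param montage Data frame from [standard_montage()] (or same format).
#' @param max_dist Neighbour distance threshold in head units.
#' @return Named list; element `i` holds the labels adjacent to electrode `i`.
#' @export
montage_adjacency <- function(montage = standard_montage(), max_dist = 0.55) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- lapply(seq_len(nrow(montage)), function(i) {
    montage$label[d[i, ] > 0 & d[i, ] <= max_dist]
  })
  names(adj) <- montage$label
  adj
}

# adjacency list -> logical matrix in a given label order
adjacency_matrix <- function(adjacency, labels) {
  A <- matrix(FALSE, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (lab in intersect(names(adjacency), labels)) {
    nb <- intersect(adjacency[[lab]], labels)
    A[lab, nb] <- TRUE
    A[nb, lab] <- TRUE
  }
  diag(A) <- FALSE
  A
}
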