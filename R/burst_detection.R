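# ISI-based burst/non-burst classification of spike trains.

#' Burst detection criteria
#'
#' The classical ISI criteria for midbrain dopamine neurons: an ISI of
#' `onset_isi_max` (80 ms) or less opens a burst, and the burst ends at the
#' first ISI exceeding `offset_isi_min` (160 ms). Intermediate ISIs
#' (80 < ISI <= 160 ms) extend an ongoing burst but cannot start one.
#'
#' @param onset_isi_max Burst-onset ISI threshold, ms.
#' @param offset_isi_min Burst-end ISI threshold, ms.
#' @return List of class `"burst_criteria"`.
#' @export
burst_criteria <- function(onset_isi_max = 80, offset_isi_min = 160) {
  if (!(onset_isi_max > 0 && onset_isi_max <= offset_isi_min))
    stop("require 0 < onset_isi_max <= offset_isi_min")
  structure(list(onset_isi_max = onset_isi_max,
                 offset_isi_min = offset_isi_min),
            class = "burst_criteria")
}

#' Label every spike of one trial as burst or non-burst
#'
#' State machine over the ISI sequence: outside a burst, an ISI at or below
#' the onset threshold starts a burst containing both spikes of the pair;
#' inside a burst, an ISI at or below the offset threshold extends it to
#' the next spike; a larger ISI closes it. Labeling never crosses trial
#' boundaries.
#'
#' @param times Strictly increasing spike times of one trial, ms.
#' @param criteria A [burst_criteria()].
#' @return List of class `"burst_labeling"`: `label` (character,
#'   `"burst"`/`"non_burst"` per spike) and `episodes` (`data.frame` with
#'   `first`, `last` spike indices, `start_ms`, `end_ms`, `n_spikes`).
#' @export
label_bursts <- function(times, criteria = burst_criteria()) {
  n <- length(times)
  if (n > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing within a trial")
  label <- rep("non_burst", n)
  eps <- list()
  if (n >= 2) {
    isi <- diff(times)
    in_burst <- FALSE
    first <- NA_integer_
    for (i in seq_len(n - 1)) {
      if (!in_burst) {
        if (isi[i] <= criteria$onset_isi_max) {
          in_burst <- TRUE
          first <- i
          label[c(i, i + 1)] <- "burst"
        }
      } else {
        if (isi[i] <= criteria$offset_isi_min) {
          label[i + 1] <- "burst"
        } else {
          eps[[length(eps) + 1]] <- c(first, i)
          in_burst <- FALSE
        }
      }
    }
    if (in_burst) eps[[length(eps) + 1]] <- c(first, n)
  }
  episodes <- if (length(eps)) {
    m <- do.call(rbind, eps)
    data.frame(first = m[, 1], last = m[, 2],
               start_ms = times[m[, 1]], end_ms = times[m[, 2]],
               n_spikes = m[, 2] - m[, 1] + 1L)
  } else {
    data.frame(first = integer(0), last = integer(0),
               start_ms = numeric(0), end_ms = numeric(0),
               n_spikes = integer(0))
  }
  structure(list(label = label, episodes = episodes),
            class = "burst_labeling")
}

#' Split one neuron's spike table by firing mode
#'
#' Applies [label_bursts()] per trial and partitions the spike table into a
#' burst-only and a non-burst-only table; both keep the input schema so any
#' downstream rate/SDF operation accepts them unchanged.
#'
#' @param session A [session_data()].
#' @param neuron_id Neuron.
#' @param criteria A [burst_criteria()].
#' @return List with elements `burst`, `non_burst` (spike tables) and
#'   `labeled` (the full table with a `mode` column).
#' @export
split_by_mode <- function(session, neuron_id, criteria = burst_criteria()) {
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  sp <- sp[order(sp$trial_id, sp$spike_time_ms), ]
  mode <- unlist(lapply(split(sp$spike_time_ms, sp$trial_id),
                        function(tt) label_bursts(tt, criteria)$label),
                 use.names = FALSE)
  sp$mode <- if (nrow(sp)) mode else character(0)
  rownames(sp) <- NULL
  list(burst = sp[sp$mode == "burst", setdiff(names(sp), "mode")],
       non_burst = sp[sp$mode == "non_burst", setdiff(names(sp), "mode")],
       labeled = sp)
}
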