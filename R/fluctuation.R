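# Detection of localization fluctuations ("localization-resets") in N/C
# traces: maximal continuously-increasing or -decreasing runs, with run
# continuity broken by stagnation, and cohort-level statistics.

# For one gap-free numeric segment, return all maximal qualifying runs.
# A run [s, e] qualifies when (i) every non-zero step inside it has the
# same sign and (ii) every complete sliding window of `w` frames changes
# by at least `delta` in absolute value.  Both conditions are hereditary,
# so maximal runs are found with a monotone two-pointer scan.
scan_runs <- function(x, delta, w, tol) {
  n <- length(x)
  if (n < 2L) return(NULL)
  es <- integer(n)
  dirs <- integer(n)
  for (s in seq_len(n - 1L)) {
    dir <- 0L; e <- s
    while (e < n) {
      st <- x[e + 1L] - x[e]
      sgn <- sign(st)
      if (sgn != 0L && dir != 0L && sgn != dir) break
      ws <- e + 2L - w  # start of the newest complete window
      if (ws >= s && abs(x[e + 1L] - x[ws]) < delta - tol) break
      e <- e + 1L
      if (sgn != 0L && dir == 0L) dir <- sgn
    }
    es[s] <- e
    dirs[s] <- dir
  }
  keep <- which(vapply(seq_len(n - 1L), function(s)
    es[s] > s && (s == 1L || es[s] > es[s - 1L]), logical(1)))
  if (!length(keep)) return(NULL)
  data.frame(start = keep, end = es[keep], dir = dirs[keep])
}

#' Detect localization fluctuations in an N/C trace
#'
#' Scans for maximal runs in which the signal continuously increases or
#' decreases, breaking continuity wherever the net change over a sliding
#' \code{stag_window}-frame window falls below \code{stag_delta}
#' (stagnation).  Runs whose net amplitude reaches \code{amp_min} are
#' reported as fluctuation events with their direction.  Missing frames
#' (NA) split the trace into independently scanned segments.  Threshold
#' comparisons carry a 1e-12 absolute slack so that traces constructed to
#' sit exactly on a boundary are classified by their intended value
#' despite binary floating-point representation.
#'
#' @param trace numeric N/C values, one per frame; NAs allowed.
#' @param frames optional frame numbers (default \code{seq_along(trace)}).
#' @param amp_min minimum net amplitude of an event, N/C units.
#' @param stag_delta minimum change per stagnation window, N/C units.
#' @param stag_window stagnation window length, frames.
#' @return \code{data.frame}: \code{start_frame}, \code{end_frame},
#'   \code{direction} (\code{"increase"}/\code{"decrease"}),
#'   \code{amplitude} (net |change|).
#' @export
detect_fluctuations <- function(trace, frames = NULL, amp_min = 0.12,
                                stag_delta = 0.005, stag_window = 3) {
  tol <- 1e-12
  frames <- frames %||% seq_along(trace)
  stop_if(length(frames) != length(trace), "frames/trace length mismatch")
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      direction = character(), amplitude = numeric())
  ok <- !is.na(trace)
  if (!any(ok)) return(empty)
  # segment boundaries: NA gaps and non-consecutive frame numbers
  idx <- which(ok)
  segs <- split(idx, cumsum(c(1, diff(idx) != 1 | diff(frames[idx]) != 1)))
  out <- list()
  for (seg in segs) {
    if (length(seg) < stag_window) next
    runs <- scan_runs(trace[seg], stag_delta, stag_window, tol)
    if (is.null(runs)) next
    amp <- trace[seg][runs$end] - trace[seg][runs$start]
    keep <- abs(amp) >= amp_min - tol & runs$dir != 0L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start_frame = frames[seg][runs$start[keep]],
      end_frame = frames[seg][runs$end[keep]],
      direction = ifelse(runs$dir[keep] > 0, "increase", "decrease"),
      amplitude = abs(amp[keep]))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start_frame), , drop = FALSE]
}

#' Cohort statistics of localization fluctuations
#'
#' @param events \code{data.frame} with at least \code{track_id} and
#'   \code{amplitude} (one row per detected event).
#' @param track_ids ids of all observed tracks (the denominator).
#' @param observation_span observed duration per track (time units, e.g.
#'   hours), recycled over tracks.
#' @param roi optional named vector mapping track id to a grouping
#'   (region of interest); statistics are then also reported per group.
#' @return list: \code{fraction_fluctuating}, \code{frequency}
#'   (per-track events per unit time), \code{amplitude_summary}
#'   (quartiles of event amplitudes), and \code{per_roi} when groups are
#'   given.
#' @export
fluctuation_cohort_stats <- function(events, track_ids, observation_span,
                                     roi = NULL) {
  stop_if(length(track_ids) == 0L, "cohort has zero tracks")
  stop_if(nrow(events) > 0 && !all(events$track_id %in% track_ids),
          "event refers to an unknown track")
  span <- rep_len(observation_span, length(track_ids))
  counts <- vapply(track_ids, function(id)
    sum(events$track_id == id), numeric(1))
  frac <- mean(counts >= 1)
  freq <- counts / span
  amp_sum <- if (nrow(events)) quantile(events$amplitude,
                                        c(0.25, 0.5, 0.75)) else
    setNames(rep(NA_real_, 3), c("25%", "50%", "75%"))
  out <- list(fraction_fluctuating = frac,
              frequency = setNames(freq, track_ids),
              amplitude_summary = amp_sum)
  if (!is.null(roi)) {
    grp <- roi[as.character(track_ids)]
    out$per_roi <- do.call(rbind, lapply(split(seq_along(track_ids), grp),
      function(i) data.frame(fraction = mean(counts[i] >= 1),
                             mean_frequency = mean(freq[i]),
                             n_tracks = length(i))))
  }
  out
}
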