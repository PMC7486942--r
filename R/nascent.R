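# Nascent-transcription spot calling inside segmented nuclei, pulse
# tracking, activity time courses, and mitosis-aligned statistics.

#' Integer pixel offsets of the spot-scoring disk and shell
#'
#' The inner disk holds pixels strictly closer than \code{r_inner} to the
#' centroid; the shell holds pixels with \code{r_inner <= r < r_outer}.
#' With the default 7-px inner and 9-px outer diameters the disk has 37
#' pixels and the shell 32.
#'
#' @param r_inner,r_outer disk and shell radii, pixels.
#' @return list of two integer matrices (\code{dy}, \code{dx} columns):
#'   \code{inner} and \code{shell}.
#' @export
spot_shell_offsets <- function(r_inner = 3.5, r_outer = 4.5) {
  r <- ceiling(r_outer)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  rr <- sqrt(g$dy^2 + g$dx^2)
  list(inner = as.matrix(g[rr < r_inner, ]),
       shell = as.matrix(g[rr >= r_inner & rr < r_outer, ]))
}

log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- expand.grid(y = -r:r, x = -r:r)
  s2 <- sigma^2
  k <- (g$y^2 + g$x^2 - 2 * s2) / (s2^2) *
    exp(-(g$y^2 + g$x^2) / (2 * s2))
  k <- k - mean(k)
  matrix(-k, 2 * r + 1, 2 * r + 1)  # negated: bright blobs -> maxima
}

#' Detect candidate nascent-transcription spots
#'
#' Two-step candidate detection per nucleus: a Laplacian-of-Gaussian
#' filter localizes blob-like maxima, and a rank-based local threshold
#' keeps pixels whose raw intensity exceeds the given percentile of all
#' pixels within that nucleus.  One candidate is emitted per LoG local
#' maximum falling in the thresholded set; thresholds are per-nucleus, so
#' nuclei of different brightness are treated alike and affine rescaling
#' of a nucleus leaves its candidates unchanged.
#'
#' @param image spot-channel frame, 2D \code{[Y, X]} or 3D
#'   \code{[Y, X, Z]}.
#' @param labels matching nucleus label array.
#' @param percentile per-nucleus intensity percentile (percent).
#' @param log_sigma LoG scale, pixels.
#' @return \code{data.frame}: \code{label}, \code{z}, \code{y}, \code{x}
#'   (0-based pixel coordinates; z = 0 for 2D), \code{peak_intensity}.
#' @export
detect_spot_candidates <- function(image, labels, percentile = 99.97,
                                   log_sigma = 1.5) {
  nd <- length(dim(image))
  img3 <- if (nd == 2L) array(image, c(dim(image), 1L)) else image
  lab3 <- if (nd == 2L) array(labels, c(dim(labels), 1L)) else labels
  kern <- log_kernel(log_sigma)
  resp <- img3
  for (z in seq_len(dim(img3)[3]))
    resp[, , z] <- EBImage::filter2(img3[, , z], kern)
  labs <- sort(unique(lab3[lab3 > 0]))
  out <- list()
  if (length(labs)) {
    mx <- local_maxima(resp, -Inf)
    is_max <- array(FALSE, dim(resp)); is_max[mx] <- TRUE
    for (lb in labs) {
      in_n <- lab3 == lb
      thr <- as.numeric(quantile(img3[in_n], percentile / 100,
                                 names = FALSE))
      sel <- in_n & (img3 > thr)
      if (!any(sel)) next
      cand <- which(sel & is_max)
      if (!length(cand)) {
        # degenerate flat peak: fall back to the brightest pixel
        cand <- which(sel)[which.max(img3[sel])]
      }
      ai <- arrayInd(cand, dim(img3))
      out[[length(out) + 1L]] <- data.frame(
        label = lb, z = ai[, 3] - 1L, y = ai[, 1] - 1L, x = ai[, 2] - 1L,
        peak_intensity = img3[cand])
    }
  }
  if (!length(out))
    return(data.frame(label = integer(), z = integer(), y = integer(),
                      x = integer(), peak_intensity = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score spot candidates with a shell-background integrated intensity
#'
#' For each candidate, the integrated intensity is the sum of pixel
#' values over the inner disk (radius < 3.5 px in the candidate's plane)
#' minus the disk pixel count times the mean of the surrounding shell
#' (3.5 <= r < 4.5 px).  Candidates whose disk is clipped by the image
#' border are flagged and excluded.
#'
#' @param candidates a \code{\link{detect_spot_candidates}} result.
#' @param image the spot-channel frame the candidates came from.
#' @param threshold minimum background-corrected integrated intensity;
#'   see \code{\link{calibrate_spot_threshold}}.
#' @param r_inner,r_outer disk and shell radii, pixels.
#' @return \code{data.frame}: candidate columns plus
#'   \code{integrated_intensity}, \code{shell_mean}, \code{clipped},
#'   \code{passed}.
#' @export
filter_spots <- function(candidates, image, threshold,
                         r_inner = 3.5, r_outer = 4.5) {
  nd <- length(dim(image))
  img3 <- if (nd == 2L) array(image, c(dim(image), 1L)) else image
  off <- spot_shell_offsets(r_inner, r_outer)
  n <- nrow(candidates)
  integ <- shellm <- rep(NA_real_, n)
  clipped <- rep(FALSE, n)
  dims <- dim(img3)
  for (i in seq_len(n)) {
    cy <- candidates$y[i] + 1L; cx <- candidates$x[i] + 1L
    cz <- candidates$z[i] + 1L
    iy <- cy + off$inner[, "dy"]; ix <- cx + off$inner[, "dx"]
    sy <- cy + off$shell[, "dy"]; sx <- cx + off$shell[, "dx"]
    if (any(c(iy, sy) < 1L) || any(c(iy, sy) > dims[1]) ||
        any(c(ix, sx) < 1L) || any(c(ix, sx) > dims[2])) {
      clipped[i] <- TRUE
      next
    }
    inner_vals <- img3[cbind(iy, ix, cz)]
    shell_vals <- img3[cbind(sy, sx, cz)]
    shellm[i] <- mean(shell_vals)
    integ[i] <- sum(inner_vals) - length(inner_vals) * shellm[i]
  }
  out <- candidates
  out$integrated_intensity <- integ
  out$shell_mean <- shellm
  out$clipped <- clipped
  out$passed <- !clipped & !is.na(integ) & integ >= threshold
  out
}

#' Calibrate the integrated-intensity spot threshold
#'
#' Samples random intranuclear positions in nuclei assumed spot-free,
#' scores them with the shell mask, and returns \code{n_sigma} times the
#' standard deviation of the background-corrected integrated intensity.
#'
#' @param image spot-channel frame.
#' @param labels nucleus label array.
#' @param n_sigma threshold in units of the background sd.
#' @param n_samples number of sampled positions.
#' @param seed RNG seed for the sampling.
#' @return numeric threshold.
#' @export
calibrate_spot_threshold <- function(image, labels, n_sigma = 5,
                                     n_samples = 200, seed = 1L) {
  set.seed(seed)
  nd <- length(dim(image))
  lab3 <- if (nd == 2L) array(labels, c(dim(labels), 1L)) else labels
  idx <- which(lab3 > 0)
  stop_if(!length(idx), "no nuclear pixels to calibrate on")
  pick <- sample(idx, min(n_samples, length(idx)))
  ai <- arrayInd(pick, dim(lab3))
  fake <- data.frame(label = lab3[pick], z = ai[, 3] - 1L,
                     y = ai[, 1] - 1L, x = ai[, 2] - 1L,
                     peak_intensity = NA_real_)
  sc <- filter_spots(fake, image, threshold = Inf)
  v <- sc$integrated_intensity[!sc$clipped]
  stop_if(length(v) < 10, "too few unclipped calibration samples")
  n_sigma * sd(v)
}

#' Merge per-frame spot detections into transcription pulses
#'
#' Spots are assigned to cells through the (frame, nucleus label) pairs
#' of the track table; per cell, detections in consecutive frames (up to
#' a gap tolerance) merge into pulses.  When a nucleus holds several
#' simultaneous spots they are ranked by integrated intensity and
#' threaded by rank, so two alleles yield two concurrent pulse threads.
#'
#' @param spots a \code{\link{filter_spots}} result with a \code{frame}
#'   column; only \code{passed} spots are used.
#' @param tracks a \code{\link{link_tracks}} table (\code{track_id},
#'   \code{frame}, \code{label}).
#' @param gap_tolerance largest number of missed frames bridged within a
#'   pulse.
#' @return \code{data.frame}: \code{track_id}, \code{thread},
#'   \code{start_frame}, \code{end_frame}, \code{duration} (frames),
#'   \code{mean_intensity}, \code{max_intensity}.
#' @export
track_pulses <- function(spots, tracks, gap_tolerance = 1) {
  sp <- spots[spots$passed & !is.na(spots$frame), , drop = FALSE]
  key <- paste(tracks$frame, tracks$label)
  sp$track_id <- tracks$track_id[match(paste(sp$frame, sp$label), key)]
  sp <- sp[!is.na(sp$track_id), , drop = FALSE]
  out <- list()
  for (id in unique(sp$track_id)) {
    si <- sp[sp$track_id == id, , drop = FALSE]
    si <- si[order(si$frame, -si$integrated_intensity), , drop = FALSE]
    si$thread <- stats::ave(si$frame, si$frame, FUN = seq_along)
    for (th in unique(si$thread)) {
      st <- si[si$thread == th, , drop = FALSE]
      fr <- st$frame
      pulse_id <- cumsum(c(1, diff(fr) > gap_tolerance + 1))
      for (p in unique(pulse_id)) {
        pp <- st[pulse_id == p, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          track_id = id, thread = th,
          start_frame = min(pp$frame), end_frame = max(pp$frame),
          duration = max(pp$frame) - min(pp$frame) + 1L,
          mean_intensity = mean(pp$integrated_intensity),
          max_intensity = max(pp$integrated_intensity))
      }
    }
  }
  if (!length(out))
    return(data.frame(track_id = integer(), thread = integer(),
                      start_frame = integer(), end_frame = integer(),
                      duration = integer(), mean_intensity = numeric(),
                      max_intensity = numeric()))
  res <- do.call(rbind, out)
  res[order(res$track_id, res$start_frame), , drop = FALSE]
}

#' Transcription activity time course
#'
#' Per frame, the fraction of tracked cells carrying at least one
#' passing nascent spot ("fraction of cells with a detectable
#' transcribing locus"), optionally normalized so the mean over a
#' pretreatment window equals 1.
#'
#' @param spots a \code{\link{filter_spots}} result with \code{frame}.
#' @param tracks a \code{\link{link_tracks}} table.
#' @param window optional integer frames of the pretreatment window for
#'   normalization.
#' @return \code{data.frame}: \code{frame}, \code{n_cells},
#'   \code{n_transcribing}, \code{activity}, and \code{normalized} when
#'   a window is given.
#' @export
activity_timecourse <- function(spots, tracks, window = NULL) {
  stop_if(nrow(tracks) == 0L, "empty cohort")
  sp <- spots[spots$passed, , drop = FALSE]
  key <- paste(tracks$frame, tracks$label)
  sp$track_id <- tracks$track_id[match(paste(sp$frame, sp$label), key)]
  frames <- sort(unique(tracks$frame))
  act <- vapply(frames, function(f) {
    cells <- unique(tracks$track_id[tracks$frame == f])
    on <- unique(sp$track_id[sp$frame == f & !is.na(sp$track_id)])
    c(length(cells), sum(cells %in% on))
  }, numeric(2))
  out <- data.frame(frame = frames, n_cells = act[1, ],
                    n_transcribing = act[2, ],
                    activity = act[2, ] / pmax(act[1, ], 1))
  if (!is.null(window)) {
    stop_if(!all(window %in% frames), "window outside observation")
    m <- mean(out$activity[out$frame %in% window])
    stop_if(!is.finite(m) || m <= 0, "window mean activity must be > 0")
    out$normalized <- out$activity / m
  }
  out
}

#' Align transcription and N/C traces around mitosis
#'
#' Recentres time at cytokinesis (relative frame 0 = the annotated
#' cytokinesis frame).  Before division a cell counts as transcribing if
#' its parent track carries a passing spot; after division, if either
#' daughter does (the premitosis nucleus is diploid, so the OR over the
#' two daughters monitors the same number of reporter cassettes).  The
#' aligned activity is normalized so the premitosis mean is 1.  The
#' aligned N/C trace is the parent trace concatenated with the per-frame
#' mean of the daughters.
#'
#' @param annotations \code{data.frame}: \code{parent_id},
#'   \code{daughter1_id}, \code{daughter2_id}, \code{cytokinesis_frame}.
#' @param transcribing \code{data.frame}: \code{track_id}, \code{frame},
#'   \code{on} (logical) -- per-cell transcription state per frame.
#' @param nc_traces optional \code{data.frame}: \code{track_id},
#'   \code{frame}, \code{nc}.
#' @return list: \code{activity} (\code{rel_frame},
#'   \code{frac_transcribing}, \code{normalized}, \code{n_divisions}),
#'   \code{nc} (\code{rel_frame}, \code{nc_mean}, \code{n}) or NULL,
#'   \code{skipped} (divisions lacking daughter tracks).
#' @export
align_mitosis <- function(annotations, transcribing, nc_traces = NULL) {
  stop_if(nrow(annotations) == 0L, "no annotated divisions")
  per_div <- list(); per_div_nc <- list(); skipped <- integer()
  state_of <- function(id, f) {
    v <- transcribing$on[transcribing$track_id == id &
                           transcribing$frame == f]
    if (length(v)) any(v) else NA
  }
  for (i in seq_len(nrow(annotations))) {
    an <- annotations[i, ]
    ids <- c(an$daughter1_id, an$daughter2_id)
    have <- vapply(ids, function(id)
      any(transcribing$track_id == id) ||
        (!is.null(nc_traces) && any(nc_traces$track_id == id)),
      logical(1))
    if (!all(have)) { skipped <- c(skipped, i); next }
    fr_all <- sort(unique(transcribing$frame))
    rel <- fr_all - an$cytokinesis_frame
    on <- vapply(seq_along(fr_all), function(j) {
      f <- fr_all[j]
      if (rel[j] < 0) state_of(an$parent_id, f)
      else {
        d <- c(state_of(ids[1], f), state_of(ids[2], f))
        if (all(is.na(d))) NA else any(d, na.rm = TRUE)
      }
    }, logical(1))
    per_div[[length(per_div) + 1L]] <-
      data.frame(division = i, rel_frame = rel, on = on)
    if (!is.null(nc_traces)) {
      nc_of <- function(id, f) {
        v <- nc_traces$nc[nc_traces$track_id == id & nc_traces$frame == f]
        if (length(v)) mean(v) else NA_real_
      }
      fr_nc <- sort(unique(nc_traces$frame))
      rel_nc <- fr_nc - an$cytokinesis_frame
      val <- vapply(seq_along(fr_nc), function(j) {
        f <- fr_nc[j]
        if (rel_nc[j] < 0) nc_of(an$parent_id, f)
        else mean(c(nc_of(ids[1], f), nc_of(ids[2], f)), na.rm = TRUE)
      }, numeric(1))
      per_div_nc[[length(per_div_nc) + 1L]] <-
        data.frame(division = i, rel_frame = rel_nc, nc = val)
    }
  }
  stop_if(!length(per_div), "all divisions skipped")
  all_on <- do.call(rbind, per_div)
  rels <- sort(unique(all_on$rel_frame))
  frac <- vapply(rels, function(r) {
    v <- all_on$on[all_on$rel_frame == r]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  pre <- mean(frac[rels < 0], na.rm = TRUE)
  activity <- data.frame(rel_frame = rels, frac_transcribing = frac,
                         normalized = if (is.finite(pre) && pre > 0)
                           frac / pre else NA_real_,
                         n_divisions = vapply(rels, function(r)
                           sum(!is.na(all_on$on[all_on$rel_frame == r])),
                           numeric(1)))
  nc_out <- NULL
  if (length(per_div_nc)) {
    all_nc <- do.call(rbind, per_div_nc)
    rels_nc <- sort(unique(all_nc$rel_frame))
    nc_out <- data.frame(
      rel_frame = rels_nc,
      nc_mean = vapply(rels_nc, function(r)
        mean(all_nc$nc[all_nc$rel_frame == r], na.rm = TRUE), numeric(1)),
      n = vapply(rels_nc, function(r)
        sum(!is.na(all_nc$nc[all_nc$rel_frame == r])), numeric(1)))
  }
  list(activity = activity, nc = nc_out, skipped = skipped)
}
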