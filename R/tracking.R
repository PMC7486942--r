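# Frame-to-frame nucleus tracking by distance-minimizing assignment.

#' Solve the linear sum assignment problem (Hungarian algorithm)
#'
#' Minimizes \code{sum(cost[i, assign[i]])} over one-to-one assignments of
#' rows to columns.  Rectangular matrices are padded internally; padded
#' matches are reported as \code{NA}.  O(n^3) shortest-augmenting-path
#' (Jonker-Volgenant style) implementation.
#'
#' @param cost numeric cost matrix; \code{Inf} forbids a pairing.
#' @return integer vector of length \code{nrow(cost)}: the column
#'   assigned to each row, \code{NA} if unassigned/forbidden.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  k <- max(n, m)
  big <- sum(cost[is.finite(cost)]) + 1
  if (!is.finite(big)) big <- 1
  C <- matrix(big, k, k)
  C[seq_len(n), seq_len(m)] <- pmin(cost, big)
  # shortest augmenting path with potentials (1-based ports cleanly)
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1)     # p[j]: row matched to column j (0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(k) + 1L) {
        if (used[j]) next
        cur <- C[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(k + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta
                       v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(k) + 1L) if (p[j] >= 1 && p[j] <= n)
    assign[p[j]] <- j - 1L
  out <- rep(NA_integer_, n)
  ok <- assign >= 1 & assign <= m
  out[ok] <- assign[ok]
  # forbidden or padded pairings are not real matches
  out[!is.na(out) & !is.finite(cost[cbind(seq_len(n), out)])] <- NA_integer_
  out
}

# Greedy nearest-neighbour fallback (mutual nearest within gate).
greedy_assignment <- function(cost) {
  out <- rep(NA_integer_, nrow(cost))
  if (!length(cost)) return(out)
  work <- cost
  repeat {
    if (!any(is.finite(work))) break
    ij <- arrayInd(which.min(work), dim(work))
    out[ij[1]] <- ij[2]
    work[ij[1], ] <- Inf
    work[, ij[2]] <- Inf
  }
  out
}

#' Link per-frame label maps into cell tracks
#'
#' For each consecutive frame pair, labels are matched by minimizing the
#' total centroid displacement (optimal one-to-one assignment), with
#' links beyond \code{gate} forbidden.  Unmatched labels terminate or
#' start tracks.
#'
#' @param label_maps list of integer label arrays, one per frame (2D
#'   \code{[Y, X]} or 3D \code{[Y, X, Z]}).
#' @param gate maximum allowed centroid displacement, pixels.
#' @param intensity optional list of intensity arrays matching
#'   \code{label_maps} (adds \code{mean_intensity}).
#' @param method \code{"optimal"} (Hungarian) or \code{"greedy"}.
#' @return \code{data.frame}: \code{track_id}, \code{frame} (1-based),
#'   \code{label}, centroid columns (0-based pixel coordinates),
#'   \code{area}, \code{mean_intensity}, \code{flagged} (always FALSE;
#'   reserved for manual curation).
#' @export
link_tracks <- function(label_maps, gate = 15,
                        intensity = NULL, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stop_if(length(label_maps) < 1L, "need at least one frame")
  props <- lapply(seq_along(label_maps), function(t)
    label_stats(label_maps[[t]],
                if (!is.null(intensity)) intensity[[t]] else NULL))
  coords <- function(df) {
    cols <- intersect(c("z", "y", "x"), names(df))
    as.matrix(df[, cols, drop = FALSE])
  }
  next_id <- 0L
  rows <- list()
  prev_ids <- integer()
  for (t in seq_along(props)) {
    cur <- props[[t]]
    n_cur <- nrow(cur)
    ids <- rep(NA_integer_, n_cur)
    if (t > 1L && n_cur > 0L && nrow(props[[t - 1L]]) > 0L) {
      prev <- props[[t - 1L]]
      d <- as.matrix(stats::dist(rbind(coords(prev), coords(cur))))
      d <- d[seq_len(nrow(prev)), nrow(prev) + seq_len(n_cur),
             drop = FALSE]
      d[d > gate] <- Inf
      a <- if (method == "optimal") solve_assignment(d) else
        greedy_assignment(d)
      for (i in seq_along(a)) if (!is.na(a[i])) ids[a[i]] <- prev_ids[i]
    }
    new <- is.na(ids)
    if (any(new)) {
      ids[new] <- next_id + seq_len(sum(new))
      next_id <- next_id + sum(new)
    }
    if (n_cur > 0L)
      rows[[t]] <- cbind(data.frame(track_id = ids, frame = t), cur)
    prev_ids <- ids
  }
  if (!length(rows)) {
    return(data.frame(track_id = integer(), frame = integer(),
                      label = integer(), area = integer(), y = numeric(),
                      x = numeric(), mean_intensity = numeric(),
                      flagged = logical()))
  }
  out <- do.call(rbind, rows)
  out$flagged <- FALSE
  rownames(out) <- NULL
  out[order(out$track_id, out$frame), ]
}
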