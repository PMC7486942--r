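# Nucleus segmentation: edge-preserving enhancement, global-threshold 2D
# segmentation with seeded-watershed splitting, and percentile-derivative
# (dI/dP) local thresholding for 3D stacks of unequally bright nuclei.

# One explicit Perona-Malik step with 2*nd neighbours (nd = 2 or 3).
pm_step <- function(img, kappa, lambda) {
  nd <- length(dim(img))
  out <- img
  for (d in seq_len(nd)) {
    fwd <- shift_arr(img, d, -1L) - img   # forward difference
    bwd <- shift_arr(img, d, +1L) - img   # backward difference
    cf <- exp(-(fwd / kappa)^2)
    cb <- exp(-(bwd / kappa)^2)
    out <- out + lambda * (cf * fwd + cb * bwd)
  }
  out
}

# Shift array along dim d by s with replicated (Neumann) edges.
shift_arr <- function(x, d, s) {
  dm <- dim(x)
  idx <- lapply(dm, seq_len)
  i <- idx[[d]] + s
  i <- pmin(pmax(i, 1L), dm[d])
  idx[[d]] <- i
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  dim(out) <- dm
  out
}

#' Edge-preserving enhancement of a nuclear-stain image
#'
#' Applies Perona-Malik anisotropic diffusion followed by addition of the
#' L1 sum of absolute first spatial derivatives (central differences) of
#' the smoothed image.  The derivative term sharpens nucleus boundaries
#' before thresholding; a constant image is a fixed point.
#'
#' @param image 2D \code{[Y, X]} or 3D \code{[Y, X, Z]} numeric array.
#' @param iterations number of diffusion steps.
#' @param kappa conduction coefficient (intensity units); gradients well
#'   above \code{kappa} are preserved as edges.
#' @param lambda stability factor of the explicit scheme, in
#'   \code{(0, 1/(2*ndim)]}.
#' @param derivative_weight weight of the gradient-magnitude term.
#' @return enhanced array, same shape as the input.
#' @export
enhance_image <- function(image, iterations = 10, kappa = 30,
                          lambda = 0.2, derivative_weight = 1) {
  assert_finite(image)
  x <- image
  was_matrix <- is.matrix(x)
  if (is.null(dim(x))) stop("image must be 2D or 3D", call. = FALSE)
  nd <- length(dim(x))
  stop_if(nd < 2 || nd > 3, "image must be 2D or 3D")
  lam <- min(lambda, 1 / (2 * nd))
  for (i in seq_len(iterations)) x <- pm_step(x, kappa, lam)
  grad <- 0
  for (d in seq_len(nd))
    grad <- grad + abs(shift_arr(x, d, -1L) - shift_arr(x, d, +1L)) / 2
  out <- x + derivative_weight * grad
  if (was_matrix) dim(out) <- dim(image)
  out
}

#' Otsu threshold of a numeric array
#'
#' @param x numeric array.
#' @param levels number of histogram bins.
#' @return threshold value separating background and foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * levels) + 1L,
                     levels), levels)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(levels) - 0.5) / levels * diff(r)
  w0 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[levels]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Split a binary mask into single nuclei with a watershed of the
# (smoothed) Euclidean distance transform; h = seed depth (EBImage
# watershed tolerance).
split_touching <- function(mask, seed_h = 1, smooth_sigma = 1) {
  if (!any(mask > 0)) return(array(0L, dim(mask)))
  dm <- EBImage::distmap(mask)
  if (smooth_sigma > 0) {
    if (length(dim(mask)) == 2L) {
      dm <- EBImage::gblur(dm, sigma = smooth_sigma)
    } else {
      for (z in seq_len(dim(dm)[3]))
        dm[, , z] <- EBImage::gblur(dm[, , z], sigma = smooth_sigma)
    }
    dm[mask == 0] <- 0
  }
  ws <- EBImage::watershed(dm, tolerance = seed_h)
  arr <- array(as.integer(EBImage::imageData(ws)), dim(mask))
  arr
}

drop_small <- function(labels, min_area) {
  if (min_area <= 1 || !any(labels > 0)) return(relabel(labels))
  tab <- table(labels[labels > 0])
  keep <- as.integer(names(tab)[tab >= min_area])
  labels[!(labels %in% keep)] <- 0L
  relabel(labels)
}

relabel <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) return(array(0L, dim(labels)))
  out <- array(0L, dim(labels))
  out[labels > 0] <- match(labels[labels > 0], labs)
  out
}

#' Segment nuclei in a 2D image with a global threshold
#'
#' Foreground is taken above a global threshold of the enhanced image
#' (Otsu by default, or a fixed value), touching nuclei are split by a
#' watershed seeded at smoothed distance-transform maxima, and regions
#' below a minimum area are discarded.
#'
#' @param image 2D numeric array (raw; enhancement applied internally
#'   unless \code{enhance = FALSE}).
#' @param threshold \code{"otsu"} or a fixed numeric threshold.
#' @param min_area minimum region area, pixels.
#' @param seed_h watershed seed depth (h-maxima of the distance map).
#' @param enhance whether to run \code{\link{enhance_image}} first.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei_2d <- function(image, threshold = "otsu", min_area = 40,
                              seed_h = 1, enhance = TRUE) {
  img <- if (enhance) enhance_image(image) else image
  thr <- if (identical(threshold, "otsu")) otsu_threshold(img) else
    as.numeric(threshold)
  mask <- array(as.integer(img > thr), dim(img))
  if (!any(mask > 0)) return(array(0L, dim(img)))
  mask <- EBImage::fillHull(mask)
  labels <- split_touching(mask, seed_h = seed_h)
  drop_small(labels, min_area)
}

#' Intensity-percentile curve and its derivative for one region
#'
#' Tabulates intensity at percentile I(P) on a regular percentile grid
#' and the forward-difference derivative dI/dP after moving-average
#' smoothing.  A peak in dI/dP marks the background-to-foreground
#' boundary of a region that mixes both.
#'
#' @param values pixel intensities of the region.
#' @param grid_step percentile grid spacing (percent).
#' @param smooth_window moving-average window (grid points) applied to
#'   dI/dP.
#' @return list with \code{P}, \code{I}, \code{dIdP}.
#' @export
percentile_curve <- function(values, grid_step = 0.5, smooth_window = 5) {
  P <- seq(grid_step, 100, by = grid_step)
  I <- as.numeric(quantile(values, P / 100, names = FALSE))
  d <- c(diff(I) / grid_step, 0)
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    pad <- floor(smooth_window / 2)
    dpad <- c(rep(d[1], pad), d, rep(d[length(d)], pad))
    d <- stats::filter(dpad, k, sides = 2)[(pad + 1):(pad + length(P))]
  }
  list(P = P, I = I, dIdP = as.numeric(d))
}

# Detect a significant interior peak of dI/dP; returns the percentile or
# NA when no peak has prominence above prominence_factor * median(dIdP).
# Multiple significant peaks can arise (e.g. a second jump at the
# nucleolus boundary); the background-to-foreground boundary is the one
# at the lowest percentile, so the first significant peak is returned.
didp_peak <- function(pc, prominence_factor = 5) {
  d <- pc$dIdP; n <- length(d)
  if (n < 5) return(NA_real_)
  interior <- 3:(n - 2)
  is_peak <- vapply(interior, function(i)
    d[i] >= d[i - 1] && d[i] >= d[i + 1], logical(1))
  cand <- interior[is_peak]
  if (!length(cand)) return(NA_real_)
  med <- median(d)
  sig <- cand[d[cand] > prominence_factor * max(med, .Machine$double.eps)]
  if (!length(sig)) return(NA_real_)
  pc$P[sig[1]]
}

# Local maxima of a 2D/3D array above a threshold (26/8-connected).
local_maxima <- function(img, lower_bound) {
  nd <- length(dim(img))
  mx <- img
  shifts <- if (nd == 2L) expand.grid(dy = -1:1, dx = -1:1) else
    expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  for (r in seq_len(nrow(shifts))) {
    s <- as.integer(shifts[r, ])
    if (all(s == 0L)) next
    sh <- img
    for (d in seq_len(nd)) if (s[d] != 0L) sh <- shift_arr(sh, d, s[d])
    mx <- pmax(mx, sh)
  }
  which(img >= mx & img > lower_bound)
}

#' Segment nuclei in 3D with per-region dI/dP local thresholds
#'
#' Implements a five-step local-threshold segmentation for stacks in
#' which nuclei differ in absolute brightness (e.g. variable expression
#' of a diffuse nuclear marker): (1) edge-preserving enhancement; (2)
#' local-maxima detection; (3) a permissive lower-bound threshold keeps
#' candidate regions containing at least one maximum; (4) each region is
#' re-thresholded at the percentile of the peak of its own dI/dP curve
#' (regions with no significant peak are kept as segmented); (5) a seeded
#' watershed separates touching nuclei.  Because thresholds are
#' percentile-based they are invariant to affine rescaling of a region's
#' intensities.
#'
#' @param stack 3D \code{[Y, X, Z]} numeric array (or a 2D matrix).
#' @param lower_bound lower-bound threshold on the enhanced image;
#'   \code{"otsu"} for automatic (Otsu of the enhanced stack scaled by
#'   \code{lower_bound_factor}).
#' @param lower_bound_factor multiplier applied when the lower bound is
#'   derived by Otsu (< 1 keeps dim nuclei).
#' @param min_area minimum region size, pixels.
#' @param seed_h watershed seed depth.
#' @param min_region_px regions smaller than this skip dI/dP refinement
#'   and are flagged.
#' @param prominence_factor significance factor for the dI/dP peak.
#' @return list: \code{labels} (integer array), \code{thresholds}
#'   (per-region data.frame with the applied percentile, NA = none),
#'   \code{flagged} (labels too small for percentile support).
#' @export
segment_nuclei_3d <- function(stack, lower_bound = "otsu",
                              lower_bound_factor = 0.6, min_area = 60,
                              seed_h = 1, min_region_px = 50,
                              prominence_factor = 5) {
  assert_finite(stack, "stack")
  empty_out <- list(labels = array(0L, dim(stack)),
                    thresholds = data.frame(region = integer(),
                                            percentile = numeric()),
                    flagged = integer())
  if (diff(range(stack)) == 0) return(empty_out)
  img <- enhance_image(stack)
  lb <- if (identical(lower_bound, "otsu"))
    otsu_threshold(img) * lower_bound_factor else as.numeric(lower_bound)
  maxima <- local_maxima(img, lb)
  mask <- array(as.integer(img > lb), dim(img))
  if (!any(mask > 0) || all(mask > 0) || !length(maxima))
    return(empty_out)
  regions <- EBImage::bwlabel(mask)
  regions <- array(as.integer(EBImage::imageData(regions)), dim(mask))
  keep <- unique(regions[maxima])
  keep <- keep[keep > 0]
  regions[!(regions %in% keep)] <- 0L
  # step 4: per-region local threshold from the dI/dP peak (on raw
  # intensities, rank-based so brightness-scale free)
  refined <- array(0L, dim(stack))
  thresholds <- data.frame(region = integer(), percentile = numeric())
  flagged <- integer()
  for (r in sort(keep)) {
    in_r <- regions == r
    vals <- stack[in_r]
    if (sum(in_r) < min_region_px) {
      refined[in_r] <- r
      flagged <- c(flagged, r)
      thresholds <- rbind(thresholds,
                          data.frame(region = r, percentile = NA_real_))
      next
    }
    pc <- percentile_curve(vals)
    pk <- didp_peak(pc, prominence_factor)
    if (!is.na(pk)) {
      cut <- as.numeric(quantile(vals, pk / 100, names = FALSE))
      sel <- in_r & (stack > cut)
      refined[sel] <- r
    } else {
      refined[in_r] <- r
    }
    thresholds <- rbind(thresholds,
                        data.frame(region = r, percentile = pk))
  }
  mask2 <- array(as.integer(refined > 0), dim(refined))
  # nuclei are solid: re-close interior holes (e.g. dim nucleoli) cut by
  # the local threshold
  if (length(dim(mask2)) == 3L) {
    for (z in seq_len(dim(mask2)[3]))
      mask2[, , z] <- EBImage::fillHull(mask2[, , z])
  } else {
    mask2 <- EBImage::fillHull(mask2)
  }
  final <- split_touching(mask2, seed_h = seed_h)
  final <- drop_small(final, min_area)
  list(labels = final, thresholds = thresholds, flagged = flagged)
}
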