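# Preprocessing of raw spatiotemporal line-FRAP acquisitions into
# normalized, folded recovery carpets.

#' Preprocess raw line-FRAP scans into a recovery carpet
#'
#' Steps: (1) each position is normalized by its prescan mean and the
#' whole series is corrected for acquisition bleaching with a
#' monoexponential fitted to the far-field (unbleached) positions;
#' (2) the two rows of the 2-pixel-wide line are averaged; (3) the
#' bleach centre is located by fitting an inverted Gaussian to the first
#' postbleach profile, and the profile is folded about the centre onto a
#' radial grid.
#'
#' @param scans array \code{[frame, position, row]} of raw intensities
#'   (a matrix is treated as a single row).
#' @param times acquisition time (s) of every frame.
#' @param n_prescan number of prescan frames (before the bleach).
#' @param pixel_size_um pixel size along the line, um.
#' @param far_field_frac fraction of positions at each end of the line
#'   treated as unbleached for the bleaching correction.
#' @param r_step_um radial grid step of the folded carpet.
#' @return carpet list: \code{times} (s, 0 = first postbleach frame),
#'   \code{r_um}, \code{surface} \code{[time, radius]},
#'   \code{center_px} (0-based), \code{bleach_tau} (s, Inf when no
#'   acquisition bleaching was detected).
#' @export
preprocess_carpet <- function(scans, times, n_prescan, pixel_size_um,
                              far_field_frac = 0.15, r_step_um = NULL) {
  if (length(dim(scans)) == 2L) scans <- array(scans, c(dim(scans), 1L))
  nt <- dim(scans)[1]; np <- dim(scans)[2]
  stop_if(length(times) != nt, "times/scans mismatch")
  stop_if(n_prescan < 1, "prescan frames required for normalization")
  # (1a) per-position prescan normalization (rows pooled)
  pre <- apply(scans[seq_len(n_prescan), , , drop = FALSE], 2, mean)
  stop_if(any(pre <= 0), "non-positive prescan mean")
  norm <- sweep(scans, 2, pre, `/`)
  # (1b) acquisition-bleaching correction from far-field positions
  nf <- max(2L, round(far_field_frac * np))
  far_cols <- c(seq_len(nf), np - nf + seq_len(nf))
  post_idx <- (n_prescan + 1L):nt
  far_tr <- apply(norm[, far_cols, , drop = FALSE], 1, mean)
  tt <- times - times[post_idx[1]]
  df <- data.frame(y = far_tr[post_idx], t = tt[post_idx])
  bleach_tau <- Inf
  if (stats::var(df$y) > 1e-12) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = df,
                        start = list(a = df$y[1],
                                     tau = max(df$t[length(df$t)], 1)),
                        lower = c(0.1, 1e-3)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      bleach_tau <- cf[["tau"]]
      corr <- cf[["a"]] * exp(-pmax(tt, 0) / bleach_tau)
      norm <- sweep(norm, 1, corr, `/`)
    }
  }
  # (2) average across the line rows
  prof <- apply(norm, c(1, 2), mean)
  # (3) bleach centre from the first postbleach profile
  p0 <- prof[post_idx[1], ]
  x <- seq_len(np) - 1
  ctr <- fit_bleach_center(x, p0)
  # fold about the centre onto a radial grid
  r_px <- abs(x - ctr)
  r_step <- (r_step_um %||% pixel_size_um) / pixel_size_um
  r_grid <- seq(0, max(r_px), by = r_step)
  post <- prof[post_idx, , drop = FALSE]
  left <- x <= ctr; right <- x >= ctr
  fold <- vapply(seq_len(nrow(post)), function(i) {
    gl <- if (sum(left) >= 2)
      stats::approx(r_px[left], post[i, left], xout = r_grid,
                    rule = 2)$y else rep(NA_real_, length(r_grid))
    gr <- if (sum(right) >= 2)
      stats::approx(r_px[right], post[i, right], xout = r_grid,
                    rule = 2)$y else rep(NA_real_, length(r_grid))
    colMeans(rbind(gl, gr), na.rm = TRUE)
  }, numeric(length(r_grid)))
  list(times = tt[post_idx], r_um = r_grid * pixel_size_um,
       surface = t(fold), center_px = ctr, bleach_tau = bleach_tau,
       prebleach_level = 1)
}

# Inverted-Gaussian fit of the bleach centre; errors if no fit converges.
fit_bleach_center <- function(x, profile) {
  c0 <- x[which.min(profile)]
  depth0 <- max(0.05, 1 - min(profile))
  fit <- tryCatch(
    minpack.lm::nlsLM(profile ~ a - b * exp(-(x - c)^2 / (2 * s^2)),
                      start = list(a = 1, b = depth0, c = c0,
                                   s = diff(range(x)) / 8),
                      data = data.frame(x = x, profile = profile)),
    error = function(e) NULL)
  stop_if(is.null(fit),
          "bleach-centre Gaussian fit failed to converge; ",
          "check the first postbleach profile")
  coef(fit)[["c"]]
}

#' Average recovery carpets from multiple experiments
#'
#' @param carpets list of carpets on a common time and radius grid.
#' @return single carpet with the element-wise mean surface.
#' @export
average_carpets <- function(carpets) {
  stop_if(!length(carpets), "no carpets")
  base <- carpets[[1]]
  base$surface <- Reduce(`+`, lapply(carpets, `[[`, "surface")) /
    length(carpets)
  base
}
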