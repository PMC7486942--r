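# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
assert_finite <- function(x, what = "image") {
  stop_if(!all(is.finite(x)), what, " contains non-finite values")
}

# Region properties of an integer label array (2D y,x or 3D z,y,x).
# Returns one row per label: label, area, centroid coordinates (0-based,
# pixel-centered), mean intensity (if an intensity array is supplied).
label_stats <- function(labels, intensity = NULL) {
  labs <- sort(unique(as.integer(labels[labels > 0])))
  nd <- length(dim(labels))
  if (length(labs) == 0L) {
    out <- data.frame(label = integer(), area = integer(),
                      y = numeric(), x = numeric(), mean_intensity = numeric())
    if (nd == 3L) out$z <- numeric()
    return(out)
  }
  idx <- which(labels > 0)
  lab <- as.integer(labels[idx])
  ai <- arrayInd(idx, dim(labels))
  area <- as.integer(table(factor(lab, levels = labs)))
  cent <- vapply(seq_len(nd), function(d) {
    as.numeric(tapply(ai[, d] - 1, lab, mean))
  }, numeric(length(labs)))
  if (length(labs) == 1L) cent <- matrix(cent, nrow = 1L)
  mi <- if (is.null(intensity)) rep(NA_real_, length(labs)) else
    as.numeric(tapply(as.numeric(intensity[idx]), lab, mean))
  if (nd == 2L) {
    # array dims are (y, x)
    data.frame(label = labs, area = area,
               y = cent[, 1], x = cent[, 2], mean_intensity = mi)
  } else {
    # array dims are (y, x, z); report z, y, x
    data.frame(label = labs, area = area,
               z = cent[, 3], y = cent[, 1], x = cent[, 2],
               mean_intensity = mi)
  }
}

# Mode of an integer-valued sample (used for camera-offset background).
int_mode <- function(x) {
  x <- round(as.numeric(x))
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
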