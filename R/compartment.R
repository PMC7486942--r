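# Per-cell compartment measurements: nuclear/cytoplasmic masks with
# nucleolar exclusion, N/C ratio, local density, ring intensity,
# pretreatment normalization, and qPCR fold change.

#' Build nuclear and cytoplasmic-ring masks for one cell
#'
#' The nuclear mask is the cell's label restricted to a 3-plane volume
#' centred on the plane of maximum nuclear-stain intensity (or the single
#' plane of a 2D image).  Nucleolar regions -- where the reporter is
#' physically excluded -- are removed as the strictly lowest
#' \code{nucleolus_pct} percent of reporter intensities within the
#' nuclear mask (ties at the percentile value are kept).  The cytoplasmic
#' ring extends \code{ring_um} outward from the nucleus boundary
#' (Euclidean distance, rounded to the nearest whole pixel radius) and
#' excludes every nuclear label.
#'
#' @param labels integer label array \code{[Y, X, Z]} (or 2D matrix).
#' @param label the cell's label.
#' @param stain nuclear-stain array, same shape (picks the centre plane).
#' @param reporter reporter-channel array, same shape (nucleolar
#'   exclusion uses its intensities).
#' @param pixel_size_um pixel size in micrometres.
#' @param ring_um ring width in micrometres.
#' @param nucleolus_pct percentile of reporter intensities removed as
#'   nucleolar.
#' @return list of class \code{compartment_masks}: linear index vectors
#'   \code{nuclear}, \code{nuclear_excl} (nucleolus-excluded),
#'   \code{ring}; \code{center_plane} (1-based, NA for 2D);
#'   \code{ring_radius_px}; \code{missing} (TRUE when the ring is empty).
#' @export
build_compartment_masks <- function(labels, label, stain, reporter,
                                    pixel_size_um, ring_um = 0.5,
                                    nucleolus_pct = 35) {
  nd <- length(dim(labels))
  stop_if(!any(labels == label), "label not present in the label map")
  if (nd == 2L) {
    planes <- NULL
    lab3 <- array(labels, c(dim(labels), 1L))
    st3 <- array(stain, c(dim(stain), 1L))
    rp3 <- array(reporter, c(dim(reporter), 1L))
    center <- NA_integer_
  } else {
    lab3 <- labels; st3 <- stain; rp3 <- reporter
    Z <- dim(lab3)[3]
    per_plane <- vapply(seq_len(Z), function(z)
      sum(st3[, , z][lab3[, , z] == label]), numeric(1))
    center <- which.max(per_plane)
    planes <- max(1L, center - 1L):min(Z, center + 1L)
    keep <- array(FALSE, dim(lab3)); keep[, , planes] <- TRUE
    lab3 <- ifelse(keep, lab3, 0L)
    dim(lab3) <- dim(labels)
  }
  nuclear <- which(lab3 == label)
  stop_if(!length(nuclear), "empty nuclear mask")
  # nucleolar exclusion on reporter intensities: strictly-below pixels out
  vals <- rp3[nuclear]
  cut <- as.numeric(quantile(vals, nucleolus_pct / 100, names = FALSE))
  nuclear_excl <- nuclear[vals >= cut]
  # ring: per-plane Euclidean distance from this nucleus, minus all nuclei
  r_px <- round(ring_um / pixel_size_um)
  dims <- dim(lab3)
  ring <- integer()
  zs <- if (nd == 2L) 1L else planes
  for (z in zs) {
    pl <- lab3[, , z]
    this <- pl == label
    if (!any(this)) next
    # distance from outside pixels to the nucleus = distmap of complement
    dm <- EBImage::distmap(matrix(as.integer(!this), dims[1], dims[2]))
    sel <- which(!this & dm <= r_px & pl == 0)
    ring <- c(ring, sel + (z - 1L) * dims[1] * dims[2])
  }
  structure(list(nuclear = nuclear, nuclear_excl = nuclear_excl,
                 ring = ring, center_plane = center,
                 ring_radius_px = r_px, dims = dims,
                 missing = length(ring) == 0L),
            class = "compartment_masks")
}

#' Estimate the fluorescence background of an image
#'
#' Default policy: the mode of the rounded intensity histogram outside
#' all (dilated) nuclei, i.e. the camera offset plus ambient level.
#'
#' @param image numeric array.
#' @param labels matching label array (0 = background); \code{NULL} uses
#'   the whole image.
#' @param dilate_px exclusion margin around nuclei, pixels.
#' @return scalar background estimate.
#' @export
estimate_background <- function(image, labels = NULL, dilate_px = 3) {
  if (is.null(labels)) return(int_mode(image))
  mask <- labels > 0
  nd <- length(dim(mask))
  if (dilate_px > 0) {
    if (nd == 2L) {
      dm <- EBImage::distmap(matrix(as.integer(!mask),
                                    dim(mask)[1], dim(mask)[2]))
      mask <- mask | (dm <= dilate_px)
    } else {
      for (z in seq_len(dim(mask)[3])) {
        dm <- EBImage::distmap(matrix(as.integer(!mask[, , z]),
                                      dim(mask)[1], dim(mask)[2]))
        mask[, , z] <- mask[, , z] | (dm <= dilate_px)
      }
    }
  }
  out <- image[!mask]
  if (!length(out)) return(int_mode(image))
  int_mode(out)
}

#' Nuclear-to-cytoplasmic ratio of a reporter channel
#'
#' \code{N/C = (mean(nucleolus-excluded nuclear) - b) /
#' (mean(cytoplasmic ring) - b)}.
#'
#' @param reporter reporter array matching the masks' geometry.
#' @param masks a \code{\link{build_compartment_masks}} result.
#' @param background scalar background \code{b}.
#' @return the N/C ratio, or \code{NA} when the ring is missing or the
#'   denominator is non-positive after background subtraction.
#' @export
nc_ratio <- function(reporter, masks, background = 0) {
  if (isTRUE(masks$missing)) return(NA_real_)
  num <- mean(reporter[masks$nuclear_excl]) - background
  den <- mean(reporter[masks$ring]) - background
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' Mean intensity over the cytoplasmic ring
#'
#' Used for cytoplasm-localized sensors (e.g. a calcium indicator
#' excluded from the nucleus): the mean of the channel over the 0.5-um
#' contour extending from the nuclear boundary into the cytoplasm.
#'
#' @param channel intensity array matching the masks' geometry.
#' @param masks a \code{\link{build_compartment_masks}} result.
#' @return mean intensity, or \code{NA} when the ring is empty.
#' @export
ring_intensity <- function(channel, masks) {
  if (isTRUE(masks$missing) || !length(masks$ring)) return(NA_real_)
  mean(channel[masks$ring])
}

#' Local cell density from centroid positions
#'
#' Counts, for each cell, the centroids within a search radius
#' (Euclidean, pixels).  The cell's own centroid is included, so an
#' isolated cell has density 1.
#'
#' @param centroids numeric matrix or data.frame with columns
#'   \code{y, x} (one frame).
#' @param radius_px search radius, pixels.
#' @return integer vector of neighbour counts (self included).
#' @export
local_density <- function(centroids, radius_px = 250) {
  stop_if(radius_px <= 0, "radius must be positive")
  xy <- as.matrix(as.data.frame(centroids)[, c("y", "x")])
  n <- nrow(xy)
  if (n == 0L) return(integer())
  d <- as.matrix(stats::dist(xy))
  as.integer(rowSums(d <= radius_px))
}

#' Normalize a per-cell trace to its pretreatment window
#'
#' Divides the trace by its mean over the window, so the normalized
#' signal averages 1 there.
#'
#' @param trace numeric vector (NAs allowed outside the window).
#' @param window integer indices of the pretreatment window.
#' @return normalized trace.
#' @export
normalize_trace <- function(trace, window) {
  stop_if(!length(window), "window must be non-empty")
  stop_if(any(window < 1 | window > length(trace)),
          "window outside the trace")
  m <- mean(trace[window], na.rm = TRUE)
  stop_if(!is.finite(m) || m <= 0, "window mean must be positive")
  trace / m
}

#' RT-qPCR fold change relative to a reference gene
#'
#' Replicate Ct values are averaged per gene and condition; the fold
#' change of gene g between conditions is \code{2^(delta Ct)} with
#' \code{delta Ct = Ct(control) - Ct(treated)}, and is then divided by
#' the reference gene's fold change.
#'
#' @param ct \code{data.frame} with columns \code{gene},
#'   \code{condition}, \code{ct} (one row per replicate).
#' @param reference reference (housekeeping) gene name.
#' @param control name of the control condition.
#' @return \code{data.frame}: \code{gene}, \code{condition},
#'   \code{fold} (raw \code{2^dCt}), \code{fold_norm} (reference-
#'   normalized).
#' @export
qpcr_fold_change <- function(ct, reference = "HPRT1",
                             control = NULL) {
  stop_if(!all(c("gene", "condition", "ct") %in% names(ct)),
          "ct table needs gene, condition, ct columns")
  stop_if(!all(is.finite(ct$ct)), "Ct values must be finite")
  stop_if(!(reference %in% ct$gene), "reference gene missing from table")
  agg <- stats::aggregate(ct ~ gene + condition, data = ct, FUN = mean)
  conds <- unique(agg$condition)
  control <- control %||% conds[1]
  stop_if(!(control %in% conds), "control condition not present")
  ref_ok <- all(conds %in% agg$condition[agg$gene == reference])
  stop_if(!ref_ok, "reference gene not measured in every condition")
  out <- list()
  for (cond in conds) {
    genes <- agg$gene[agg$condition == cond]
    stopifnot(all(genes %in% agg$gene[agg$condition == control]))
    ct_c <- setNames(agg$ct[agg$condition == control],
                     agg$gene[agg$condition == control])
    ct_t <- setNames(agg$ct[agg$condition == cond], genes)
    fold <- 2^(ct_c[genes] - ct_t[genes])
    fold_ref <- 2^(ct_c[reference] - ct_t[reference])
    out[[cond]] <- data.frame(gene = genes, condition = cond,
                              fold = as.numeric(fold),
                              fold_norm = as.numeric(fold / fold_ref))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
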