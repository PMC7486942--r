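# Image and table I/O: multi-page TIFF movies, 16-bit label maps, and
# the CSV track/event/spot schemas shared by the pipeline stages.

#' Write a movie to multi-page TIFF files
#'
#' One 32-bit float TIFF per channel, pages ordered plane-fastest
#' (z within t), plus a JSON sidecar recording shape, pixel size and
#' frame interval.  Intensities are stored divided by \code{scale}.
#'
#' @param movie a movie list as produced by
#'   \code{\link{generate_monolayer_movie}}.
#' @param dir output directory (created if needed).
#' @param scale intensity scale divisor for storage.
#' @return invisibly, the sidecar path.
#' @export
write_movie_tiff <- function(movie, dir, scale = 65535) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(channels = names(movie$channels),
               pixel_size_um = movie$pixel_size_um,
               frame_interval = movie$frame_interval, scale = scale)
  for (ch in names(movie$channels)) {
    a <- movie$channels[[ch]]
    meta$shape <- dim(a)  # Y X Z T
    pages <- lapply(seq_len(dim(a)[4]), function(t)
      lapply(seq_len(dim(a)[3]), function(z) a[, , z, t] / scale))
    pages <- do.call(c, pages)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  side <- file.path(dir, "movie.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a movie written by \code{\link{write_movie_tiff}}
#'
#' @param dir directory holding the channel TIFFs and sidecar.
#' @return a movie list (channels, pixel size, frame interval).
#' @export
read_movie_tiff <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")),
                            all = TRUE)
    a <- array(0, shape)
    i <- 1L
    for (t in seq_len(shape[4])) for (z in seq_len(shape[3])) {
      a[, , z, t] <- pages[[i]] * meta$scale
      i <- i + 1L
    }
    a
  })
  names(channels) <- meta$channels
  structure(list(channels = channels,
                 pixel_size_um = meta$pixel_size_um,
                 frame_interval = meta$frame_interval),
            class = "lr_movie")
}

#' Write label maps as 16-bit TIFF
#'
#' @param labels integer array \code{[Y, X, Z, T]} (or fewer trailing
#'   dimensions).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_labels_tiff <- function(labels, path) {
  dm <- dim(labels)
  if (length(dm) == 2L) dim(labels) <- c(dm, 1L, 1L)
  if (length(dim(labels)) == 3L) dim(labels) <- c(dim(labels), 1L)
  stop_if(max(labels) > 65535, "more labels than 16-bit range")
  pages <- list()
  for (t in seq_len(dim(labels)[4])) for (z in seq_len(dim(labels)[3]))
    pages[[length(pages) + 1L]] <- labels[, , z, t] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read 16-bit label TIFF written by \code{\link{write_labels_tiff}}
#'
#' @param path label TIFF path.
#' @param shape original \code{[Y, X, Z, T]} shape (pages are
#'   plane-fastest).
#' @return integer label array.
#' @export
read_labels_tiff <- function(path, shape) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0L, shape)
  i <- 1L
  for (t in seq_len(shape[4])) for (z in seq_len(shape[3])) {
    a[, , z, t] <- as.integer(round(pages[[i]] * 65535))
    i <- i + 1L
  }
  a
}
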