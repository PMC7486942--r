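# Pipeline configuration and the end-to-end driver tying the stages
# together: simulate/load -> segment -> track -> quantify ->
# fluctuations -> spots -> pulses, with a manifest for auditability.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    input = list(simulate = TRUE, movie_dir = ""),
    scene = list(n_cells = 8L, n_frames = 12L, size_px = 160L,
                 n_planes = 3L, pixel_size_um = 0.276,
                 frame_interval = 15, noise_sd = 2, background = 100,
                 spots = FALSE),
    segment = list(threshold = "otsu", min_area = 40, seed_h = 1),
    track = list(gate = 15, method = "optimal"),
    quantify = list(ring_um = 0.5, nucleolus_pct = 35,
                    density_radius_px = 250),
    fluctuations = list(amp_min = 0.12, stag_delta = 0.005,
                        stag_window = 3),
    spots = list(percentile = 99.97, log_sigma = 1.5, n_sigma = 5,
                 gap_tolerance = 1)
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and merges overrides; unknown keys
#' are rejected by name so configuration typos fail loudly.
#'
#' @param ... named overrides, nested as in the defaults (e.g.
#'   \code{segment = list(min_area = 60)}).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  merge1 <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!(k %in% names(base)))
        stop("unknown configuration key: ", path, k, call. = FALSE)
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge1(base[[k]], over[[k]], paste0(path, k, ".")) else over[[k]]
    }
    base
  }
  cfg <- merge1(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file representation round-trips losslessly through
#' \code{\link{pipeline_config}} validation.
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config} (read) or invisibly the path
#'   (write).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes versioned CSV outputs plus
#' a JSON manifest (configuration echo, per-stage counts).  With a fixed
#' seed the outputs are byte-identical across reruns.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory.
#' @param stages character subset of
#'   \code{c("segment", "track", "quantify", "fluctuations", "spots")}.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("segment", "track", "quantify",
                                    "fluctuations", "spots")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(),
                   package_version =
                     as.character(utils::packageVersion("locreset")))
  log_stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    message("[", name, "] ",
            paste(names(counts), counts, sep = "=", collapse = " "))
  }
  fail <- function(stage, e) {
    manifest$failed_stage <<- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  # --- input ---------------------------------------------------------
  sc <- config$scene
  if (isTRUE(config$input$simulate)) {
    cfg <- scene_config(shape = c(T = sc$n_frames, Z = sc$n_planes,
                                  Y = sc$size_px, X = sc$size_px),
                        pixel_size_um = sc$pixel_size_um,
                        frame_interval = sc$frame_interval,
                        n_cells = sc$n_cells, noise_sd = sc$noise_sd,
                        background = sc$background, seed = config$seed)
    scene <- if (isTRUE(sc$spots))
      generate_spot_movie(cfg, burst_program(sc$n_cells)) else
        generate_monolayer_movie(cfg)
    movie <- scene$movie
  } else {
    stop_if(!nzchar(config$input$movie_dir %||% ""),
            "movie_dir required")
    movie <- read_movie_tiff(config$input$movie_dir)
  }
  Tn <- dim(movie$channels[[1]])[4]
  # --- segment + track ----------------------------------------------
  tracks <- NULL; label_maps <- NULL
  if ("segment" %in% stages) {
    label_maps <- tryCatch(lapply(seq_len(Tn), function(t) {
      st <- movie$channels$stain[, , , t]
      if (dim(movie$channels$stain)[3] == 1L) {
        segment_nuclei_2d(movie$channels$stain[, , 1, t],
                          threshold = config$segment$threshold,
                          min_area = config$segment$min_area,
                          seed_h = config$segment$seed_h)
      } else {
        segment_nuclei_3d(st, min_area = config$segment$min_area,
                          seed_h = config$segment$seed_h)$labels
      }
    }), error = function(e) fail("segment", e))
    log_stage("segment",
              c(frames = Tn,
                nuclei = sum(vapply(label_maps, max, numeric(1)))))
  }
  if ("track" %in% stages && !is.null(label_maps)) {
    tracks <- tryCatch(
      link_tracks(label_maps, gate = config$track$gate,
                  method = config$track$method),
      error = function(e) fail("track", e))
    write.csv(tracks, file.path(out_dir, "tracks.csv"),
              row.names = FALSE)
    log_stage("track", c(tracks = length(unique(tracks$track_id))))
  }
  # --- quantify ------------------------------------------------------
  nc_tab <- NULL
  if ("quantify" %in% stages && !is.null(tracks)) {
    nc_tab <- tryCatch({
      rows <- list()
      for (t in seq_len(Tn)) {
        lab <- label_maps[[t]]
        lab3 <- if (length(dim(lab)) == 2L)
          array(lab, c(dim(lab), 1L)) else lab
        st <- movie$channels$stain[, , , t, drop = FALSE]
        dim(st) <- dim(st)[1:3]
        rp <- movie$channels$reporter[, , , t, drop = FALSE]
        dim(rp) <- dim(rp)[1:3]
        bg <- estimate_background(rp, lab3)
        trt <- tracks[tracks$frame == t, ]
        dens <- if (nrow(trt))
          local_density(trt, config$quantify$density_radius_px) else
            integer()
        for (i in seq_len(nrow(trt))) {
          m <- build_compartment_masks(
            lab3, trt$label[i], st, rp,
            pixel_size_um = movie$pixel_size_um,
            ring_um = config$quantify$ring_um,
            nucleolus_pct = config$quantify$nucleolus_pct)
          rows[[length(rows) + 1L]] <- data.frame(
            track_id = trt$track_id[i], frame = t,
            nc_ratio = nc_ratio(rp, m, bg),
            nuc_mean = mean(rp[m$nuclear_excl]),
            cyto_mean = if (m$missing) NA_real_ else mean(rp[m$ring]),
            background = bg, density = dens[i],
            nuclear_area_um2 = trt$area[i] *
              movie$pixel_size_um^2 /
              max(1L, length(unique(which(lab3 == trt$label[i],
                                          arr.ind = TRUE)[, 3]))))
        }
      }
      do.call(rbind, rows)
    }, error = function(e) fail("quantify", e))
    write.csv(nc_tab, file.path(out_dir, "nc_traces.csv"),
              row.names = FALSE)
    log_stage("quantify", c(measurements = nrow(nc_tab)))
  }
  # --- fluctuations --------------------------------------------------
  if ("fluctuations" %in% stages && !is.null(nc_tab)) {
    ev <- tryCatch({
      out <- list()
      for (id in unique(nc_tab$track_id)) {
        tr <- nc_tab[nc_tab$track_id == id, ]
        e <- detect_fluctuations(tr$nc_ratio, frames = tr$frame,
                                 amp_min = config$fluctuations$amp_min,
                                 stag_delta =
                                   config$fluctuations$stag_delta,
                                 stag_window =
                                   config$fluctuations$stag_window)
        if (nrow(e)) out[[length(out) + 1L]] <-
            cbind(data.frame(track_id = id), e)
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(track_id = integer(), start_frame = integer(),
                   end_frame = integer(), direction = character(),
                   amplitude = numeric())
    }, error = function(e) fail("fluctuations", e))
    write.csv(ev, file.path(out_dir, "fluctuations.csv"),
              row.names = FALSE)
    log_stage("fluctuations", c(events = nrow(ev)))
  }
  # --- spots ---------------------------------------------------------
  if ("spots" %in% stages && !is.null(tracks) &&
      "spot" %in% names(movie$channels)) {
    sp <- tryCatch({
      all_sp <- list()
      for (t in seq_len(Tn)) {
        lab <- label_maps[[t]]
        img <- movie$channels$spot[, , , t, drop = FALSE]
        dim(img) <- dim(img)[1:3]
        lab3 <- if (length(dim(lab)) == 2L)
          array(lab, c(dim(lab), 1L)) else lab
        cand <- detect_spot_candidates(
          img, lab3, percentile = config$spots$percentile,
          log_sigma = config$spots$log_sigma)
        thr <- calibrate_spot_threshold(img, lab3,
                                        n_sigma = config$spots$n_sigma,
                                        seed = config$seed)
        sc <- filter_spots(cand, img, thr)
        if (nrow(sc)) { sc$frame <- t
          all_sp[[length(all_sp) + 1L]] <- sc }
      }
      if (length(all_sp)) do.call(rbind, all_sp) else NULL
    }, error = function(e) fail("spots", e))
    if (!is.null(sp)) {
      write.csv(sp, file.path(out_dir, "spots.csv"), row.names = FALSE)
      pulses <- track_pulses(sp, tracks,
                             gap_tolerance = config$spots$gap_tolerance)
      write.csv(pulses, file.path(out_dir, "pulses.csv"),
                row.names = FALSE)
      log_stage("spots", c(spots = sum(sp$passed),
                           pulses = nrow(pulses)))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
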