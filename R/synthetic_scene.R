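# Synthetic microscopy scenes with exported ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: textured elliptical nuclei with nucleoli moving in a monolayer,
# a reporter channel realizing a programmed N/C ratio per cell, a spot
# channel with telegraph-model nascent-transcription foci, and
# two-compartment exchange traces for import/export estimation.

#' Scene configuration for the synthetic-microscopy generator
#'
#' @param shape integer vector \code{c(T, Z, Y, X)}: frames, planes, image
#'   height and width in pixels. \code{Z = 1} produces 2D frames.
#' @param pixel_size_um pixel size, micrometres per pixel.
#' @param frame_interval time between frames (any unit; carried through to
#'   outputs).
#' @param n_cells number of nuclei to place.
#' @param nucleus_axes_px range (min, max) of nucleus semi-axes, pixels.
#' @param motion_sd_px per-frame standard deviation of the reflected
#'   Gaussian random walk of nucleus centres, pixels.
#' @param nucleolus_fraction fraction of nuclear pixels occupied by the
#'   nucleolus, in \code{[0, 1)}.
#' @param nucleolus_dim multiplicative dimming of reporter signal inside
#'   the nucleolus (1 = none).
#' @param background out-of-cell fluorescence level, intensity units.
#' @param camera_offset constant camera offset added to every pixel.
#' @param poisson_gain gain of the Poisson shot-noise model (0 disables
#'   shot noise; photons = intensity / gain).
#' @param noise_sd additive Gaussian read-noise standard deviation.
#' @param cyto_extent_px how far (pixels) the cytoplasmic territory
#'   extends beyond the nucleus boundary.
#' @param min_separation_px minimum centre-to-centre separation enforced
#'   at placement; overlap tolerance of the random walk.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(shape = c(T = 20L, Z = 5L, Y = 192L, X = 192L),
                         pixel_size_um = 0.276,
                         frame_interval = 15,
                         n_cells = 8L,
                         nucleus_axes_px = c(9, 13),
                         motion_sd_px = 0.6,
                         nucleolus_fraction = 0.25,
                         nucleolus_dim = 0.3,
                         background = 100,
                         camera_offset = 0,
                         poisson_gain = 0,
                         noise_sd = 0,
                         cyto_extent_px = 8,
                         min_separation_px = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  names(shape) <- c("T", "Z", "Y", "X")
  stop_if(any(shape < 1L), "all scene dimensions must be positive")
  stop_if(nucleolus_fraction < 0 || nucleolus_fraction >= 1,
          "nucleolus_fraction must be in [0, 1)")
  stop_if(n_cells < 1L, "n_cells must be positive")
  cfg <- list(shape = shape, pixel_size_um = pixel_size_um,
              frame_interval = frame_interval, n_cells = as.integer(n_cells),
              nucleus_axes_px = nucleus_axes_px, motion_sd_px = motion_sd_px,
              nucleolus_fraction = nucleolus_fraction,
              nucleolus_dim = nucleolus_dim,
              background = background, camera_offset = camera_offset,
              poisson_gain = poisson_gain, noise_sd = noise_sd,
              cyto_extent_px = cyto_extent_px,
              min_separation_px = min_separation_px %||%
                (2 * max(nucleus_axes_px) + 4),
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Programmed N/C trajectories for a synthetic cohort
#'
#' Each cell carries a baseline N/C ratio and a list of non-overlapping
#' events.  A \code{"reset"} is a single cycle of nuclear exodus followed
#' by re-entry (triangular excursion of the given amplitude and duration);
#' a \code{"ramp"} is a sustained linear shift by the signed amplitude; a
#' \code{"stagnation"} freezes the trace.
#'
#' @param n_cells number of cells.
#' @param baseline baseline N/C ratio, recycled over cells.
#' @param events \code{data.frame} with columns \code{cell}, \code{onset}
#'   (frame, 1-based), \code{type} (\code{reset}/\code{ramp}/
#'   \code{stagnation}), \code{amplitude} (N/C units, signed for ramps),
#'   \code{duration} (frames); or \code{NULL} for none.
#' @return object of class \code{nc_program}.
#' @export
nc_program <- function(n_cells, baseline = 1.5, events = NULL) {
  baseline <- rep_len(baseline, n_cells)
  if (is.null(events))
    events <- data.frame(cell = integer(), onset = integer(),
                         type = character(), amplitude = numeric(),
                         duration = integer())
  stop_if(!all(events$type %in% c("reset", "ramp", "stagnation")),
          "unknown event type")
  # check per-cell overlap
  if (nrow(events) > 1) {
    for (cl in unique(events$cell)) {
      ev <- events[events$cell == cl, , drop = FALSE]
      ev <- ev[order(ev$onset), , drop = FALSE]
      if (nrow(ev) > 1 &&
          any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)]))
        stop("events overlap for cell ", cl, call. = FALSE)
    }
  }
  structure(list(n_cells = as.integer(n_cells), baseline = baseline,
                 events = events), class = "nc_program")
}

# Realize the programmed N/C(t) matrix (frames x cells).
realize_nc <- function(program, n_frames) {
  nc <- matrix(rep(program$baseline, each = n_frames),
               nrow = n_frames, ncol = program$n_cells)
  ev <- program$events
  for (i in seq_len(nrow(ev))) {
    cl <- ev$cell[i]; t0 <- ev$onset[i]; d <- ev$duration[i]
    tt <- t0:min(t0 + d - 1L, n_frames)
    phase <- (tt - t0) / max(d - 1L, 1L)
    if (ev$type[i] == "reset") {
      # exodus then re-entry: triangular dip of the given amplitude
      nc[tt, cl] <- nc[tt, cl] - ev$amplitude[i] * (1 - abs(2 * phase - 1))
    } else if (ev$type[i] == "ramp") {
      nc[tt, cl] <- nc[tt, cl] + ev$amplitude[i] * phase
      if (t0 + d <= n_frames)
        nc[(t0 + d):n_frames, cl] <- nc[(t0 + d):n_frames, cl] +
          ev$amplitude[i]
    } # stagnation: trace already flat between events
  }
  stop_if(any(nc <= 0), "programmed N/C must remain positive")
  nc
}

# Place n_cells centres with minimum separation; bounded retries.
place_centres <- function(cfg) {
  Y <- unname(cfg$shape["Y"]); X <- unname(cfg$shape["X"])
  margin <- max(cfg$nucleus_axes_px) + 2
  centres <- matrix(NA_real_, cfg$n_cells, 2)
  for (i in seq_len(cfg$n_cells)) {
    ok <- FALSE
    for (try in 1:2000) {
      p <- c(runif(1, margin, Y - margin), runif(1, margin, X - margin))
      if (i == 1L ||
          all(sqrt(rowSums((centres[seq_len(i - 1), , drop = FALSE] -
                            matrix(p, i - 1, 2, byrow = TRUE))^2)) >=
              cfg$min_separation_px)) {
        centres[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", cfg$n_cells,
                  " nuclei without overlap; reduce n_cells or separation",
                  call. = FALSE)
  }
  centres
}

# Smooth boundary jitter: low-order Fourier perturbation of the radius.
jitter_coefs <- function(n_cells, amp = 0.06) {
  lapply(seq_len(n_cells), function(i)
    list(a = rnorm(3, 0, amp / sqrt(3)), phi = runif(3, 0, 2 * pi)))
}

# Per-cell geometry for one frame: nucleus/nucleolus/cyto masks as pixel
# index lists into a (Y, X) plane.
cell_geometry <- function(centre, axes, angle, jit, cfg) {
  Y <- unname(cfg$shape["Y"]); X <- unname(cfg$shape["X"])
  ext <- max(axes) * 1.4 + cfg$cyto_extent_px + 2
  ys <- max(1, floor(centre[1] - ext)):min(Y, ceiling(centre[1] + ext))
  xs <- max(1, floor(centre[2] - ext)):min(X, ceiling(centre[2] + ext))
  dy <- rep(ys - centre[1], times = length(xs))
  dx <- rep(xs - centre[2], each = length(ys))
  ca <- cos(angle); sa <- sin(angle)
  u <- (dx * ca + dy * sa) / axes[2]
  v <- (-dx * sa + dy * ca) / axes[1]
  r <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  bnd <- 1 + jit$a[1] * cos(th + jit$phi[1]) +
    jit$a[2] * cos(2 * th + jit$phi[2]) + jit$a[3] * cos(3 * th + jit$phi[3])
  nuc <- r <= bnd
  # cytoplasmic territory: same shape scaled outward by cyto_extent
  scale_c <- 1 + cfg$cyto_extent_px / mean(axes)
  cyto <- (r <= bnd * scale_c) & !nuc
  # nucleolus: concentric scaled copy occupying ~nucleolus_fraction of area
  nlo <- if (cfg$nucleolus_fraction > 0)
    r <= bnd * sqrt(cfg$nucleolus_fraction) else rep(FALSE, length(r))
  idx_of <- function(m) {
    ij <- which(m)
    iy <- ys[(ij - 1L) %% length(ys) + 1L]
    ix <- xs[(ij - 1L) %/% length(ys) + 1L]
    cbind(iy, ix)
  }
  list(nucleus = idx_of(nuc), cyto = idx_of(cyto), nucleolus = idx_of(nlo))
}

apply_noise <- function(img, cfg) {
  if (cfg$poisson_gain > 0) {
    img <- rpois(length(img), pmax(img, 0) / cfg$poisson_gain) *
      cfg$poisson_gain
  }
  if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img
}

# z-profile of the nucleus stain across planes (ellipsoid cross-section).
z_weights <- function(Z) {
  if (Z == 1L) return(1)
  zc <- (Z + 1) / 2
  # gentle axial profile: the centre plane is brightest (so the 3-plane
  # mask centres correctly) but edge planes stay well above threshold
  0.75 + 0.25 * sqrt(pmax(0, 1 - ((seq_len(Z) - zc) / zc)^2))
}

#' Generate a two-channel synthetic monolayer movie
#'
#' Renders moving textured nuclei (channel \code{stain}) and a reporter
#' channel whose per-cell nuclear and cytoplasmic mean intensities realize
#' a programmed N/C ratio.  The total reporter signal per cell is held
#' constant over time, so programmed localization-resets redistribute
#' signal between compartments without creating or destroying it.
#'
#' @param config a \code{\link{scene_config}}.
#' @param program an \code{\link{nc_program}} with at most
#'   \code{config$n_cells} cells.
#' @return a list with elements \code{movie} (named list of
#'   \code{[Y, X, Z, T]} arrays \code{stain} and \code{reporter}, plus
#'   \code{pixel_size_um} and \code{frame_interval}) and \code{truth}
#'   (label maps \code{[Y, X, Z, T]}, a tracks \code{data.frame}, the
#'   realized N/C matrix, per-cell protein totals, and the config).
#' @export
generate_monolayer_movie <- function(config, program = NULL) {
  cfg <- config
  if (is.null(program)) program <- nc_program(cfg$n_cells)
  stop_if(program$n_cells > cfg$n_cells,
          "program has more cells than the scene")
  set.seed(cfg$seed)
  Tn <- unname(cfg$shape["T"]); Z <- unname(cfg$shape["Z"])
  Y <- unname(cfg$shape["Y"]); X <- unname(cfg$shape["X"])
  centres <- place_centres(cfg)
  axes <- cbind(runif(cfg$n_cells, cfg$nucleus_axes_px[1],
                      cfg$nucleus_axes_px[2]),
                runif(cfg$n_cells, cfg$nucleus_axes_px[1],
                      cfg$nucleus_axes_px[2]))
  angles <- runif(cfg$n_cells, 0, pi)
  jits <- jitter_coefs(cfg$n_cells)
  nc <- realize_nc(program, Tn)
  if (program$n_cells < cfg$n_cells) {
    extra <- matrix(rep(1.5, Tn * (cfg$n_cells - program$n_cells)),
                    nrow = Tn)
    nc <- cbind(nc, extra)
  }
  # per-cell protein total, set so the baseline cytoplasmic
  # concentration is ~80-120 intensity units; compartment
  # concentrations then follow from conservation as N/C changes.
  conc0 <- runif(cfg$n_cells, 80, 120)
  geom0 <- lapply(seq_len(cfg$n_cells), function(i)
    cell_geometry(centres[i, ], axes[i, ], angles[i], jits[[i]], cfg))
  eff_nuc_area <- function(g) {
    # nucleolar pixels hold only dim * the nuclear concentration, so
    # they contribute a reduced effective volume (keeps per-cell totals
    # exactly conserved as N/C changes)
    nrow(g$nucleus) - nrow(g$nucleolus) * (1 - cfg$nucleolus_dim)
  }
  protein <- vapply(seq_len(cfg$n_cells), function(i) {
    conc0[i] * (nrow(geom0[[i]]$cyto) + eff_nuc_area(geom0[[i]]) *
                  nc[1, i])
  }, numeric(1))
  zw <- z_weights(Z)
  stain <- array(0, c(Y, X, Z, Tn))
  reporter <- array(0, c(Y, X, Z, Tn))
  labels <- array(0L, c(Y, X, Z, Tn))
  tracks <- vector("list", Tn)
  pos <- centres
  margin <- max(cfg$nucleus_axes_px) + 2
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      step <- matrix(rnorm(cfg$n_cells * 2, 0, cfg$motion_sd_px),
                     ncol = 2)
      cand <- pos + step
      # reflect at borders
      cand[, 1] <- pmin(pmax(cand[, 1], margin), Y - margin)
      cand[, 2] <- pmin(pmax(cand[, 2], margin), X - margin)
      # reject moves that violate the separation tolerance
      for (i in seq_len(cfg$n_cells)) {
        others <- cand[-i, , drop = FALSE]
        if (all(sqrt(rowSums((others - matrix(cand[i, ], nrow(others), 2,
                                              byrow = TRUE))^2)) >=
                0.9 * cfg$min_separation_px)) pos[i, ] <- cand[i, ]
      }
    }
    st_pl <- matrix(cfg$background, Y, X)
    rp_pl <- matrix(cfg$background, Y, X)
    lab_pl <- matrix(0L, Y, X)
    geoms <- lapply(seq_len(cfg$n_cells), function(i)
      cell_geometry(pos[i, ], axes[i, ], angles[i], jits[[i]], cfg))
    for (i in seq_len(cfg$n_cells)) {
      g <- geoms[[i]]
      a_c <- nrow(g$cyto)
      conc_c <- protein[i] / (a_c + eff_nuc_area(g) * nc[t, i])
      conc_n <- conc_c * nc[t, i]
      rp_pl[g$cyto] <- cfg$background + conc_c
      rp_pl[g$nucleus] <- cfg$background + conc_n
      if (nrow(g$nucleolus))
        rp_pl[g$nucleolus] <- cfg$background + conc_n * cfg$nucleolus_dim
      st_pl[g$nucleus] <- cfg$background + 160
      if (nrow(g$nucleolus)) st_pl[g$nucleolus] <- cfg$background + 160 * 0.6
      lab_pl[g$nucleus] <- i
    }
    for (z in seq_len(Z)) {
      sz <- matrix(cfg$background, Y, X)
      in_n <- lab_pl > 0
      sz[in_n] <- cfg$background + (st_pl[in_n] - cfg$background) * zw[z]
      rz <- rp_pl  # reporter roughly uniform across the thin volume
      stain[, , z, t] <- apply_noise(sz + cfg$camera_offset, cfg)
      reporter[, , z, t] <- apply_noise(rz + cfg$camera_offset, cfg)
      labels[, , z, t] <- lab_pl
    }
    tracks[[t]] <- data.frame(track_id = seq_len(cfg$n_cells), frame = t,
                              y = pos[, 1] - 1, x = pos[, 2] - 1)
  }
  movie <- list(channels = list(stain = stain, reporter = reporter),
                pixel_size_um = cfg$pixel_size_um,
                frame_interval = cfg$frame_interval)
  class(movie) <- "lr_movie"
  truth <- list(labels = labels, tracks = do.call(rbind, tracks),
                nc = nc, protein = protein, config = cfg,
                events = program$events)
  list(movie = movie, truth = truth)
}

#' Telegraph burst program for nascent-transcription spots
#'
#' @param n_cells number of cells.
#' @param k_on,k_off per-frame on/off switching probabilities of the
#'   telegraph model.
#' @param intensity spot photon count (integrated Gaussian amplitude).
#' @param psf_sigma_px point-spread sigma, pixels (must be >= 0.5).
#' @return object of class \code{burst_program}.
#' @export
burst_program <- function(n_cells, k_on = 0.2, k_off = 0.2,
                          intensity = 2000, psf_sigma_px = 1.5) {
  stop_if(k_on < 0 || k_off < 0, "telegraph rates must be >= 0")
  stop_if(psf_sigma_px < 0.5, "PSF sigma must be >= 0.5 px")
  structure(list(n_cells = as.integer(n_cells), k_on = k_on, k_off = k_off,
                 intensity = intensity, psf_sigma_px = psf_sigma_px),
            class = "burst_program")
}

#' Generate a synthetic movie with nascent-transcription spots
#'
#' Adds a spot channel to a monolayer scene: each cell carries one
#' transcription locus at a fixed intranuclear position whose on/off state
#' follows a two-state telegraph chain; in "on" frames a Gaussian focus of
#' the programmed intensity is rendered over a diffuse nuclear background
#' (free MCP signal).
#'
#' @param config a \code{\link{scene_config}}.
#' @param bursts a \code{\link{burst_program}}.
#' @return as \code{\link{generate_monolayer_movie}}, with an extra
#'   channel \code{spot} and ground-truth elements \code{on_state}
#'   (frames x cells logical matrix) and \code{spot_positions}.
#' @export
generate_spot_movie <- function(config, bursts) {
  base <- generate_monolayer_movie(config,
                                   nc_program(config$n_cells, baseline = 1.5))
  cfg <- config
  Tn <- unname(cfg$shape["T"]); Z <- unname(cfg$shape["Z"])
  Y <- unname(cfg$shape["Y"]); X <- unname(cfg$shape["X"])
  # RNG continues from the generator state (still fully seed-determined)
  p_on <- if (bursts$k_on + bursts$k_off > 0)
    bursts$k_on / (bursts$k_on + bursts$k_off) else 0
  state <- matrix(FALSE, Tn, cfg$n_cells)
  state[1, ] <- runif(cfg$n_cells) < p_on
  if (Tn > 1) for (t in 2:Tn) {
    sw_on <- runif(cfg$n_cells) < bursts$k_on
    sw_off <- runif(cfg$n_cells) < bursts$k_off
    state[t, ] <- ifelse(state[t - 1, ], !sw_off, sw_on)
  }
  # fixed intranuclear positions: offset from centroid in truth tracks,
  # kept at 40% of the minor axis so spots stay inside through motion.
  tr <- base$truth$tracks
  offs <- matrix(rnorm(cfg$n_cells * 2), ncol = 2)
  offs <- offs / sqrt(rowSums(offs^2)) *
    runif(cfg$n_cells, 0, 0.4 * cfg$nucleus_axes_px[1])
  zc <- (Z + 1) %/% 2
  spot <- array(0, c(Y, X, Z, Tn))
  amp <- bursts$intensity / (2 * pi * bursts$psf_sigma_px^2)
  halo <- ceiling(4 * bursts$psf_sigma_px)
  positions <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    pl <- matrix(cfg$background, Y, X)
    lab_pl <- base$truth$labels[, , 1, t]
    pl[lab_pl > 0] <- cfg$background + 60  # diffuse nuclear MCP
    trt <- tr[tr$frame == t, ]
    py <- unname(trt$y[order(trt$track_id)] + 1 + offs[, 1])
    px <- unname(trt$x[order(trt$track_id)] + 1 + offs[, 2])
    for (i in seq_len(cfg$n_cells)) {
      if (!state[t, i]) next
      ys <- max(1, round(py[i]) - halo):min(Y, round(py[i]) + halo)
      xs <- max(1, round(px[i]) - halo):min(X, round(px[i]) + halo)
      dy <- outer(ys - py[i], rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - px[i])
      g <- amp * exp(-(dy^2 + dx^2) / (2 * bursts$psf_sigma_px^2))
      pl[ys, xs] <- pl[ys, xs] + g
    }
    for (z in seq_len(Z)) {
      w <- if (Z == 1L) 1 else exp(-((z - zc) / 1.2)^2 / 2)
      pz <- matrix(cfg$background, Y, X)
      pz <- pz + (pl - cfg$background) * w
      spot[, , z, t] <- apply_noise(pz + cfg$camera_offset, cfg)
    }
    positions[[t]] <- data.frame(track_id = seq_len(cfg$n_cells),
                                 frame = t, y = as.numeric(py) - 1,
                                 x = as.numeric(px) - 1,
                                 z = zc - 1, on = state[t, ])
  }
  base$movie$channels$spot <- spot
  base$truth$on_state <- state
  base$truth$spot_positions <- do.call(rbind, positions)
  base$truth$bursts <- bursts
  base
}

#' Simulate a two-compartment photobleach recovery trace
#'
#' Integrates the two-pool exchange model
#' \deqn{dN/dt = k_{import} C - k_{export} N,\qquad
#'       dC/dt = -k_{import} C + k_{export} N}
#' for the fluorescent species from the postbleach initial condition
#' (the bleached pool reduced to \code{residual_fraction} of its
#' prebleach equilibrium value).  The solution is the exact
#' one-exponential relaxation of the 2x2 linear system.
#'
#' @param k_import,k_export first-order exchange rates (1/time unit of
#'   \code{times}); must be >= 0.
#' @param bleach_target \code{"nucleus"} or \code{"cytoplasm"}.
#' @param times strictly increasing sampling times, first = postbleach.
#' @param residual_fraction fraction of the bleached pool surviving.
#' @return a list: \code{trace} \code{data.frame(time, nuclear, cyto)},
#'   \code{postbleach_nucleus}, \code{postbleach_cytoplasm}.
#' @export
simulate_compartment_bleach <- function(k_import, k_export,
                                        bleach_target = c("nucleus",
                                                          "cytoplasm"),
                                        times,
                                        residual_fraction = 0) {
  stop_if(k_import < 0 || k_export < 0, "rates must be >= 0")
  stop_if(any(diff(times) <= 0), "sampling times must be strictly increasing")
  bleach_target <- match.arg(bleach_target)
  k <- k_import + k_export
  # prebleach equilibrium of the fluorescent pool (total = 1)
  if (k > 0) {
    N_eq <- k_import / k; C_eq <- k_export / k
  } else {
    N_eq <- 0.5; C_eq <- 0.5
  }
  N0 <- if (bleach_target == "nucleus") N_eq * residual_fraction else N_eq
  C0 <- if (bleach_target == "cytoplasm") C_eq * residual_fraction else C_eq
  S <- N0 + C0
  tt <- times - times[1]
  if (k > 0) {
    N_inf <- k_import * S / k
    N <- N_inf + (N0 - N_inf) * exp(-k * tt)
  } else {
    N <- rep(N0, length(tt))
  }
  C <- S - N
  list(trace = data.frame(time = times, nuclear = N, cyto = C),
       postbleach_nucleus = N0, postbleach_cytoplasm = C0)
}
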