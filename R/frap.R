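# Spatiotemporal FRAP analysis: radially symmetric pure-diffusion and
# reaction-diffusion (single pseudo-first-order binding mode) forward
# models, nonlinear least-squares fitting, bootstrap uncertainty, model
# selection, and first-order import/export rate estimation from
# compartment-bleach traces.

#' Radial geometry and discretization for the FRAP forward model
#'
#' Builds the finite-volume radial Laplacian (zero-flux at the centre and
#' at the outer boundary) on a uniform grid and caches its symmetrized
#' eigendecomposition, which the pure-diffusion model reuses across
#' diffusivity values.
#'
#' @param r_obs_um radial observation positions of the carpet, um.
#' @param bleach_depth fractional depth of the Gaussian bleach profile at
#'   the centre (0-1).
#' @param bleach_sigma_um Gaussian sigma of the bleach profile, um.
#' @param domain_radius_um closed-domain radius; defaults to three times
#'   the farthest observation (far field effectively unbleached).
#' @param n_grid number of radial grid cells.
#' @return object of class \code{frap_geometry}.
#' @export
frap_geometry <- function(r_obs_um, bleach_depth = 0.7,
                          bleach_sigma_um = 1.0,
                          domain_radius_um = NULL, n_grid = 80L) {
  R <- domain_radius_um %||% max(12, 3 * max(r_obs_um))
  n <- as.integer(n_grid)
  dr <- R / n
  r <- (seq_len(n) - 0.5) * dr           # cell centres
  rf <- seq_len(n - 1) * dr              # interior faces
  # finite-volume radial Laplacian, zero flux at r = 0 and r = R
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) L[i, i - 1] <- rf[i - 1] / (r[i] * dr^2)
    if (i < n) L[i, i + 1] <- rf[i] / (r[i] * dr^2)
    L[i, i] <- -(ifelse(i > 1, rf[i - 1], 0) + ifelse(i < n, rf[i], 0)) /
      (r[i] * dr^2)
  }
  w <- sqrt(r)
  # S = W L W^-1 with W = diag(sqrt(r)) is symmetric
  S <- sweep(sweep(L, 1, w, `*`), 2, w, `/`)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  profile <- 1 - bleach_depth * exp(-r^2 / (2 * bleach_sigma_um^2))
  structure(list(r = r, dr = dr, n = n, R = R, L = L, w = w,
                 eig_values = es$values, eig_vectors = es$vectors,
                 r_obs = r_obs_um, bleach_depth = bleach_depth,
                 bleach_sigma = bleach_sigma_um, profile = profile),
            class = "frap_geometry")
}

# Interpolate grid columns at the observation radii.
obs_interp <- function(geom, U) {
  # U: n_grid x n_times
  t(apply(U, 2, function(col)
    stats::approx(geom$r, col, xout = geom$r_obs, rule = 2)$y))
}

#' Forward FRAP model surface
#'
#' Pure diffusion: the free pool obeys the radial diffusion equation with
#' diffusivity \code{D}, starting from the Gaussian bleach profile.
#' Reaction-diffusion: a free pool f and an immobile bound pool c couple
#' through pseudo-first-order binding,
#' \deqn{\partial f/\partial t = D_f \nabla^2 f - k^*_{on} f + k_{off} c,
#'  \qquad \partial c/\partial t = k^*_{on} f - k_{off} c,}
#' with prebleach equilibrium \code{f/c = k_off/k_on*}; the observed
#' signal is \code{f + c}.  The semi-discrete system is linear, so it is
#' propagated exactly by the eigendecomposition of the (symmetrized)
#' operator.
#'
#' @param model \code{"pure_diffusion"} or \code{"reaction_diffusion"}.
#' @param params named vector: \code{D} for pure diffusion;
#'   \code{D_f, k_on, k_off} for reaction-diffusion (rates 1/s, D um2/s).
#' @param geometry a \code{\link{frap_geometry}}.
#' @param times observation times (s) after the bleach (first may be 0).
#' @return matrix \code{[length(times), length(geometry$r_obs)]} of
#'   normalized fluorescence.
#' @export
frap_forward_model <- function(model = c("pure_diffusion",
                                         "reaction_diffusion"),
                               params, geometry, times) {
  model <- match.arg(model)
  g <- geometry
  u0 <- g$profile - 1  # deviation from prebleach level
  if (model == "pure_diffusion" ||
      (model == "reaction_diffusion" && params[["k_on"]] <= 0)) {
    D <- if (model == "pure_diffusion") params[["D"]] else
      params[["D_f"]]
    stop_if(D <= 0, "D must be positive")
    V <- g$eig_vectors
    a0 <- crossprod(V, g$w * u0)
    E <- exp(outer(g$eig_values * D, times))   # n x n_t
    U <- (V %*% (E * as.vector(a0))) / g$w
    return(obs_interp(g, U) + 1)
  }
  D <- params[["D_f"]]; kon <- params[["k_on"]]; koff <- params[["k_off"]]
  stop_if(D <= 0 || kon < 0 || koff <= 0,
          "need D_f > 0, k_on >= 0, k_off > 0")
  n <- g$n
  Feq <- koff / (kon + koff); Ceq <- kon / (kon + koff)
  f0 <- Feq * u0; c0 <- Ceq * u0
  # symmetrized block operator: T M T^-1 with T = diag(W, sqrt(koff/kon) W)
  S_d <- sweep(sweep(g$L, 1, g$w, `*`), 2, g$w, `/`)
  S_d <- (S_d + t(S_d)) / 2
  cross <- sqrt(kon * koff)
  M <- matrix(0, 2 * n, 2 * n)
  M[1:n, 1:n] <- D * S_d - diag(kon, n)
  M[1:n, (n + 1):(2 * n)] <- diag(cross, n)
  M[(n + 1):(2 * n), 1:n] <- diag(cross, n)
  M[(n + 1):(2 * n), (n + 1):(2 * n)] <- -diag(koff, n)
  es <- eigen(M, symmetric = TRUE)
  cc <- sqrt(koff / kon)
  y0 <- c(g$w * f0, cc * g$w * c0)
  a0 <- crossprod(es$vectors, y0)
  E <- exp(outer(es$values, times))
  Yt <- es$vectors %*% (E * as.vector(a0))
  Ft <- Yt[1:n, , drop = FALSE] / g$w
  Ct <- Yt[(n + 1):(2 * n), , drop = FALSE] / (cc * g$w)
  obs_interp(g, Ft + Ct) + 1
}

#' Fit a FRAP carpet to a recovery model
#'
#' Nonlinear least squares (Levenberg-Marquardt on log-parameters) of the
#' forward model against the carpet surface.
#'
#' @param carpet list with \code{times} (s), \code{r_um} (radial
#'   positions) and \code{surface} (\code{[time, position]} normalized
#'   fluorescence), e.g. from \code{\link{preprocess_carpet}} or
#'   \code{\link{simulate_frap_carpet}}.
#' @param model \code{"pure_diffusion"} or \code{"reaction_diffusion"}.
#' @param init named initial guess (\code{D}; or \code{D_f, k_on,
#'   k_off}).
#' @param geometry optional \code{\link{frap_geometry}}.  When omitted,
#'   the initial condition is the measured first postbleach profile
#'   (inverted-Gaussian fit) and times are taken relative to that frame;
#'   when supplied, the geometry's own bleach profile is evolved from
#'   time zero and the carpet times are used as-is.
#' @return object of class \code{frap_fit_result}: \code{model},
#'   \code{params}, \code{Keq}, \code{bound_fraction}, \code{ssd},
#'   \code{converged}, \code{fitted} surface.
#' @export
frap_fit <- function(carpet, model = c("pure_diffusion",
                                       "reaction_diffusion"),
                     init = NULL, geometry = NULL) {
  model <- match.arg(model)
  tt <- if (is.null(geometry)) carpet$times - carpet$times[1] else
    carpet$times
  g <- geometry %||% carpet_geometry(carpet)
  init <- init %||% (if (model == "pure_diffusion") c(D = 10) else
    c(D_f = 10, k_on = 0.1, k_off = 0.1))
  obs <- carpet$surface
  resid_fn <- function(logp) {
    p <- exp(logp)
    names(p) <- names(init)
    pred <- tryCatch(frap_forward_model(model, p, g, tt),
                     error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, length(obs)))
    as.vector(pred - obs)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                     ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid_fn,
                            control = ctrl)
  p <- exp(fit$par); names(p) <- names(init)
  pred <- frap_forward_model(model, p, g, tt)
  ssd <- sum((pred - obs)^2)
  keq <- if (model == "reaction_diffusion")
    p[["k_on"]] / p[["k_off"]] else NA_real_
  structure(list(model = model, params = p, Keq = keq,
                 bound_fraction = if (is.na(keq)) NA_real_ else
                   keq / (1 + keq),
                 ssd = ssd, converged = fit$info %in% 1:4,
                 info = fit$message, geometry = g, fitted = pred),
            class = "frap_fit_result")
}

# Geometry inferred from a carpet: inverted-Gaussian fit of the first
# postbleach radial profile.
carpet_geometry <- function(carpet) {
  prof <- carpet$surface[1, ]
  r <- carpet$r_um
  depth0 <- max(0.05, 1 - min(prof))
  sig0 <- max(r[which(prof < 1 - depth0 / 2)], 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(prof ~ 1 - K * exp(-r^2 / (2 * s^2)),
                      start = list(K = depth0, s = sig0),
                      lower = c(1e-3, 0.1), upper = c(1, max(r)),
                      data = data.frame(prof = prof, r = r)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    frap_geometry(r, bleach_depth = cf[["K"]], bleach_sigma_um = cf[["s"]])
  } else {
    frap_geometry(r, bleach_depth = depth0, bleach_sigma_um = sig0)
  }
}

#' Simulate a synthetic FRAP carpet
#'
#' Generates a carpet from the forward model, optionally with Gaussian
#' noise, as ground truth for fitting validation.
#'
#' @inheritParams frap_forward_model
#' @param r_obs_um observation radii, um.
#' @param noise_sd additive Gaussian noise sd (fraction of prebleach).
#' @param seed RNG seed used when noise is added.
#' @return carpet list: \code{times}, \code{r_um}, \code{surface},
#'   \code{params}, \code{model}.
#' @export
simulate_frap_carpet <- function(model, params, times,
                                 r_obs_um = seq(0, 6, by = 0.25),
                                 bleach_depth = 0.7,
                                 bleach_sigma_um = 1.0,
                                 noise_sd = 0, seed = 1L) {
  g <- frap_geometry(r_obs_um, bleach_depth = bleach_depth,
                     bleach_sigma_um = bleach_sigma_um)
  surf <- frap_forward_model(model, params, g, times)
  if (noise_sd > 0) {
    set.seed(seed)
    surf <- surf + rnorm(length(surf), 0, noise_sd)
  }
  list(times = times, r_um = r_obs_um, surface = surf,
       params = params, model = model, geometry = g)
}

#' Bootstrap FRAP fits over experiments
#'
#' Samples \code{per_boot} experiments with replacement, averages their
#' carpets, fits the model, and reports the mean and standard deviation
#' of each parameter over \code{n_boot} bootstraps.
#'
#' @param carpets list of carpets on a common grid.
#' @param model,init,geometry as in \code{\link{frap_fit}}.
#' @param n_boot number of bootstrap draws.
#' @param per_boot experiments per draw.
#' @param seed RNG seed.
#' @return list: \code{mean}, \code{sd} (named per parameter),
#'   \code{fits} (per-bootstrap parameter matrix), \code{n_failed}.
#' @export
bootstrap_frap <- function(carpets, model, init = NULL, geometry = NULL,
                           n_boot = 30, per_boot = 5, seed = 1L) {
  stop_if(length(carpets) < per_boot,
          "need at least per_boot experiments")
  set.seed(seed)
  res <- list(); n_failed <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample(length(carpets), per_boot, replace = TRUE)
    avg <- carpets[[pick[1]]]
    avg$surface <- Reduce(`+`, lapply(carpets[pick], `[[`, "surface")) /
      per_boot
    fit <- tryCatch(frap_fit(avg, model, init = init,
                             geometry = geometry),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    res[[length(res) + 1L]] <- fit$params
  }
  stop_if(!length(res), "all bootstrap fits failed")
  m <- do.call(rbind, res)
  list(mean = colMeans(m), sd = apply(m, 2, sd), fits = m,
       n_failed = n_failed)
}

#' Choose between pure-diffusion and reaction-diffusion FRAP fits
#'
#' The reaction-diffusion fit is preferred only when (a) it lowers the
#' sum of squared residuals by more than a relative margin and (b) its
#' free diffusivity is physically plausible; otherwise the pure-diffusion
#' fit is returned.  The default plausibility band reflects that a
#' ~100 kDa protein diffuses at roughly 21 um2/s, so effective
#' diffusivities far above that indicate an overparameterized fit.
#'
#' @param fit_pd,fit_rd \code{frap_fit_result}s for the two models.
#' @param ssd_margin minimum relative SSD improvement (0.1 = 10 percent).
#' @param d_bounds plausible free-diffusivity interval, um2/s.
#' @return the chosen \code{frap_fit_result} with a \code{decision}
#'   attribute describing the rule outcome.
#' @export
select_frap_model <- function(fit_pd, fit_rd, ssd_margin = 0.1,
                              d_bounds = c(1, 30)) {
  improve <- (fit_pd$ssd - fit_rd$ssd) / fit_pd$ssd
  d_ok <- fit_rd$params[["D_f"]] >= d_bounds[1] &&
    fit_rd$params[["D_f"]] <= d_bounds[2]
  choose_rd <- improve > ssd_margin && d_ok
  out <- if (choose_rd) fit_rd else fit_pd
  attr(out, "decision") <- list(chosen = out$model,
                                ssd_improvement = improve,
                                d_plausible = d_ok,
                                ssd_margin = ssd_margin,
                                d_bounds = d_bounds)
  out
}

#' Estimate a specific first-order transport rate from a bleach trace
#'
#' The nuclear signal change from the first postbleach frame is divided
#' by the postbleach intensity of the source compartment (cytoplasm for
#' import, nucleus for export); the specific rate is the slope of an
#' ordinary least-squares line over the first four postbleach frames
#' (30 s at a 10-s frame interval).  Export traces decay, so the export
#' rate is the negated slope.
#'
#' @param nuclear numeric nuclear-intensity trace, first value =
#'   first postbleach frame.
#' @param direction \code{"import"} (nucleus was bleached) or
#'   \code{"export"} (cytoplasm was bleached).
#' @param postbleach_nucleus,postbleach_cytoplasm compartment intensities
#'   right after the bleach.
#' @param frame_interval seconds between frames.
#' @param fit_frames 1-based frames of the linear-fit window.
#' @return list: \code{rate} (1/s), \code{slope}, \code{direction},
#'   \code{normalizer}, \code{fit_frames}.
#' @export
estimate_transport_rate <- function(nuclear,
                                    direction = c("import", "export"),
                                    postbleach_nucleus,
                                    postbleach_cytoplasm,
                                    frame_interval = 10,
                                    fit_frames = 1:4) {
  direction <- match.arg(direction)
  stop_if(length(nuclear) < max(fit_frames),
          "trace shorter than the fit window")
  normalizer <- if (direction == "import") postbleach_cytoplasm else
    postbleach_nucleus
  stop_if(!is.finite(normalizer) || normalizer <= 0,
          "postbleach normalizer must be positive")
  y <- (nuclear[fit_frames] - nuclear[fit_frames[1]]) / normalizer
  t_s <- (fit_frames - fit_frames[1]) * frame_interval
  slope <- coef(lm(y ~ t_s))[["t_s"]]
  list(rate = if (direction == "export") -slope else slope,
       slope = slope, direction = direction, normalizer = normalizer,
       fit_frames = fit_frames)
}
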