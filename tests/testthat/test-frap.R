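# FRAP forward models, fitting, bootstrap, model selection, and
# line-scan preprocessing.

test_that("the forward model matches the closed-form Gaussian solution", {
  r_obs <- seq(0, 6, by = 0.25)
  g <- frap_geometry(r_obs, bleach_depth = 0.7, bleach_sigma_um = 1,
                     domain_radius_um = 24, n_grid = 800L)
  times <- c(0, 0.01, 0.05, 0.1, 0.3)
  surf <- frap_forward_model("pure_diffusion", c(D = 21), g, times)
  want <- t(vapply(times, function(t)
    oracle_gaussian_diffusion(r_obs, t, 21, 0.7, 1),
    numeric(length(r_obs))))
  expect_lt(max(abs(surf - want)), 1e-4)
})

test_that("reaction-diffusion with k_on = 0 nests pure diffusion", {
  r_obs <- seq(0, 5, by = 0.5)
  g <- frap_geometry(r_obs)
  times <- c(0, 0.05, 0.5, 2)
  pd <- frap_forward_model("pure_diffusion", c(D = 15), g, times)
  rd <- frap_forward_model("reaction_diffusion",
                           c(D_f = 15, k_on = 0, k_off = 0.1), g, times)
  expect_lt(max(abs(pd - rd)), 1e-6)
})

test_that("both models recover fully at long times", {
  r_obs <- seq(0, 5, by = 0.5)
  g <- frap_geometry(r_obs, domain_radius_um = 40, n_grid = 120L)
  pd <- frap_forward_model("pure_diffusion", c(D = 15), g, 1e5)
  rd <- frap_forward_model("reaction_diffusion",
                           c(D_f = 15, k_on = 0.1, k_off = 0.1), g, 1e5)
  # closed domain: recovery to the conserved mean (~1 for a large field)
  expect_true(all(abs(pd - 1) < 2e-3))
  expect_true(all(abs(rd - 1) < 2e-3))
})

test_that("the semi-discrete scheme conserves total signal", {
  g <- frap_geometry(seq(0, 5, 0.5), n_grid = 100L)
  u0 <- g$profile - 1
  mass0 <- sum(g$r * u0) * g$dr
  for (t in c(0.01, 1, 100, 1e4)) {
    V <- g$eig_vectors
    a0 <- crossprod(V, g$w * u0)
    u <- as.vector((V %*% (exp(g$eig_values * 10 * t) *
                             as.vector(a0))) / g$w)
    expect_lt(abs(sum(g$r * u) * g$dr - mass0), 1e-6 * abs(mass0))
  }
})

test_that("fitting a self-generated surface recovers parameters exactly", {
  times <- c(0, exp(seq(log(0.005), log(2), length.out = 30)))
  carp <- simulate_frap_carpet("pure_diffusion", c(D = 12),
                               times = times)
  fit <- frap_fit(carp, "pure_diffusion", init = c(D = 4),
                  geometry = carp$geometry)
  expect_lt(fit$ssd, 1e-10)
  expect_lt(abs(fit$params[["D"]] - 12) / 12, 0.001)
})

test_that("a 21 um2/s pure-diffusion recovery is refit within 5%", {
  times <- c(0, exp(seq(log(0.002), log(2), length.out = 40)))
  carp <- simulate_frap_carpet("pure_diffusion", c(D = 21),
                               times = times)
  fit <- frap_fit(carp, "pure_diffusion", init = c(D = 5))
  expect_lt(abs(fit$params[["D"]] - 21) / 21, 0.05)
})

test_that("Keq = 1 fits give a bound fraction of 0.5", {
  times <- c(0, exp(seq(log(0.005), log(120), length.out = 50)))
  carp <- simulate_frap_carpet("reaction_diffusion",
                               c(D_f = 15, k_on = 0.1, k_off = 0.1),
                               times = times)
  fit <- frap_fit(carp, "reaction_diffusion",
                  init = c(D_f = 8, k_on = 0.05, k_off = 0.2))
  expect_equal(fit$bound_fraction, 0.5, tolerance = 0.02)
  expect_equal(fit$Keq, 1, tolerance = 0.05)
})

test_that("noiseless fits recover a parameter grid within 5%", {
  times <- c(0, exp(seq(log(0.005), log(150), length.out = 45)))
  for (D_f in c(5, 15, 25)) {
    for (Keq in c(0.25, 1, 4)) {
      for (k_off in c(0.05, 0.5)) {
        k_on <- Keq * k_off
        carp <- simulate_frap_carpet(
          "reaction_diffusion",
          c(D_f = D_f, k_on = k_on, k_off = k_off), times = times)
        fit <- frap_fit(carp, "reaction_diffusion",
                        init = c(D_f = 10, k_on = 0.1, k_off = 0.1),
                        geometry = carp$geometry)
        rel <- abs(fit$params - c(D_f, k_on, k_off)) /
          c(D_f, k_on, k_off)
        expect_true(all(rel < 0.05),
                    label = sprintf("D=%g Keq=%g koff=%g: %s", D_f,
                                    Keq, k_off,
                                    paste(signif(rel, 2),
                                          collapse = ", ")))
      }
    }
  }
})

test_that("1% measurement noise keeps recovery within 20%", {
  times <- c(0, exp(seq(log(0.005), log(120), length.out = 45)))
  carp <- simulate_frap_carpet("reaction_diffusion",
                               c(D_f = 15, k_on = 0.2, k_off = 0.2),
                               times = times, noise_sd = 0.01,
                               seed = 5L)
  fit <- frap_fit(carp, "reaction_diffusion",
                  init = c(D_f = 10, k_on = 0.1, k_off = 0.1),
                  geometry = carp$geometry)
  rel <- abs(fit$params - c(15, 0.2, 0.2)) / c(15, 0.2, 0.2)
  expect_true(all(rel < 0.20))
})

test_that("model selection chooses the generating model", {
  times <- c(0, exp(seq(log(0.005), log(60), length.out = 40)))
  # pure-diffusion data
  cpd <- simulate_frap_carpet("pure_diffusion", c(D = 18),
                              times = times)
  f_pd <- frap_fit(cpd, "pure_diffusion", geometry = cpd$geometry)
  f_rd <- frap_fit(cpd, "reaction_diffusion",
                   init = c(D_f = 18, k_on = 0.05, k_off = 0.1),
                   geometry = cpd$geometry)
  sel <- select_frap_model(f_pd, f_rd)
  expect_equal(sel$model, "pure_diffusion")
  # reaction-diffusion data, Keq = 1 at k_off = 0.1
  crd <- simulate_frap_carpet("reaction_diffusion",
                              c(D_f = 15, k_on = 0.1, k_off = 0.1),
                              times = times)
  g_pd <- frap_fit(crd, "pure_diffusion", geometry = crd$geometry)
  g_rd <- frap_fit(crd, "reaction_diffusion",
                   init = c(D_f = 10, k_on = 0.05, k_off = 0.2),
                   geometry = crd$geometry)
  sel2 <- select_frap_model(g_pd, g_rd)
  expect_equal(sel2$model, "reaction_diffusion")
  expect_equal(sel2$bound_fraction, 0.5, tolerance = 0.02)
  # implausibly fast free diffusion forces pure diffusion
  g_rd_bad <- g_rd
  g_rd_bad$params[["D_f"]] <- 42
  sel3 <- select_frap_model(g_pd, g_rd_bad)
  expect_equal(sel3$model, "pure_diffusion")
  expect_false(attr(sel3, "decision")$d_plausible)
})

test_that("bootstrap statistics behave on identical and jittered data", {
  times <- c(0, exp(seq(log(0.01), log(2), length.out = 25)))
  base <- simulate_frap_carpet("pure_diffusion", c(D = 15),
                               times = times)
  same <- replicate(6, base, simplify = FALSE)
  bs <- bootstrap_frap(same, "pure_diffusion", init = c(D = 10),
                       geometry = base$geometry, n_boot = 8,
                       per_boot = 5, seed = 2L)
  expect_equal(unname(bs$sd), 0, tolerance = 1e-8)
  expect_equal(unname(bs$mean[["D"]]), 15, tolerance = 1e-3)
  # determinism under a fixed seed
  bs2 <- bootstrap_frap(same, "pure_diffusion", init = c(D = 10),
                        geometry = base$geometry, n_boot = 8,
                        per_boot = 5, seed = 2L)
  expect_identical(bs$fits, bs2$fits)
  # between-experiment jitter: bootstrap sd within 2x the analytic sd
  # of the mean of per_boot draws
  set.seed(11)
  Ds <- rnorm(12, 15, 1.5)
  carps <- lapply(Ds, function(D)
    simulate_frap_carpet("pure_diffusion", c(D = D), times = times))
  bj <- bootstrap_frap(carps, "pure_diffusion", init = c(D = 10),
                       geometry = base$geometry, n_boot = 20,
                       per_boot = 5, seed = 3L)
  analytic <- sd(Ds) / sqrt(5)
  expect_lt(bj$sd[["D"]], 2 * analytic)
  expect_gt(bj$sd[["D"]], analytic / 3)
})

test_that("bound fraction is monotone in Keq with the right anchors", {
  keq <- seq(0, 10, by = 0.25)
  bf <- keq / (1 + keq)
  expect_true(all(diff(bf) > 0))
  expect_equal(bf[keq == 0], 0)
  expect_equal(bf[keq == 1], 0.5)
})

test_that("flat line scans preprocess to a unit carpet", {
  nt <- 40; np <- 61
  scans <- array(500, c(nt, np, 2))
  # bleach something minimal so the centre fit has a target
  x <- seq_len(np) - 1
  dip <- 0.3 * exp(-(x - 30)^2 / (2 * 9))
  for (t in 6:nt) scans[t, , ] <- 500 * (1 - dip * exp(-(t - 6) / 8))
  carp <- preprocess_carpet(scans, times = (0:(nt - 1)) * 0.1,
                            n_prescan = 5, pixel_size_um = 0.1)
  expect_equal(carp$surface[1, 1],
               min(carp$surface[1, ]), tolerance = 1e-6)
  # prescan-normalized far field stays at 1
  expect_lt(abs(mean(carp$surface[, ncol(carp$surface)]) - 1), 0.02)
  # truly flat scans: carpet identically 1 (no centre fit possible on a
  # constant profile is an error, so add an infinitesimal dip)
  flat <- array(500, c(10, np, 2))
  expect_error(preprocess_carpet(flat, (0:9) * 0.1, 3, 0.1), "Gaussian")
})

test_that("the bleach centre is recovered within 0.2 px", {
  np <- 81; nt <- 30
  x <- seq_len(np) - 1
  centre_true <- 42.3
  scans <- array(0, c(nt, np, 2))
  for (t in 1:nt) {
    prof <- if (t <= 5) rep(1, np) else
      1 - 0.6 * exp(-(x - centre_true)^2 / (2 * 16)) *
        exp(-(t - 6) * 0.05)
    scans[t, , 1] <- 800 * prof
    scans[t, , 2] <- 800 * prof
  }
  carp <- preprocess_carpet(scans, times = (0:(nt - 1)) * 0.2,
                            n_prescan = 5, pixel_size_um = 0.09)
  expect_lt(abs(carp$center_px - centre_true), 0.2)
})

test_that("far-field acquisition bleaching is corrected to flat", {
  np <- 81; nt <- 50
  x <- seq_len(np) - 1
  tau <- 20
  scans <- array(0, c(nt, np, 2))
  tt <- (0:(nt - 1)) * 0.2
  for (t in 1:nt) {
    decay <- if (t <= 5) 1 else exp(-(tt[t] - tt[6]) / tau)
    prof <- if (t <= 5) rep(1, np) else
      (1 - 0.5 * exp(-(x - 40)^2 / (2 * 9))) * decay
    scans[t, , ] <- 700 * prof
  }
  carp <- preprocess_carpet(scans, times = tt, n_prescan = 5,
                            pixel_size_um = 0.09)
  far <- carp$surface[, ncol(carp$surface)]
  expect_true(all(abs(far - 1) < 1e-3))
  expect_equal(carp$bleach_tau, tau, tolerance = 0.05)
})
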