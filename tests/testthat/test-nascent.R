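# Nascent-transcription spot calling, pulse tracking, activity traces,
# and mitosis alignment.

test_that("disk and shell pixel counts match brute-force enumeration", {
  off <- spot_shell_offsets()
  # independent enumeration over a wide integer grid
  g <- expand.grid(dy = -10:10, dx = -10:10)
  r <- sqrt(g$dy^2 + g$dx^2)
  expect_equal(nrow(off$inner), sum(r < 3.5))
  expect_equal(nrow(off$shell), sum(r >= 3.5 & r < 4.5))
  expect_equal(nrow(off$inner), 37)
  expect_equal(nrow(off$shell), 32)
})

test_that("the rank threshold keeps at most 3 of 10,000 distinct pixels", {
  lab <- matrix(0L, 100, 100)
  lab[1:10000] <- 1L
  img <- matrix(0, 100, 100)
  set.seed(1)
  img[1:10000] <- sample(seq_len(10000))
  thr <- quantile(img[lab == 1], 0.9997)
  expect_equal(sum(img[lab == 1] > thr), 3)
  cand <- detect_spot_candidates(img, lab)
  expect_lte(nrow(cand), 3)
})

test_that("candidates are invariant to affine rescaling of a nucleus", {
  set.seed(8)
  img <- matrix(100 + rnorm(80 * 80, 0, 3), 80, 80)
  lab <- matrix(0L, 80, 80); lab[20:60, 20:60] <- 1L
  img[40, 40] <- 220
  a <- detect_spot_candidates(img, lab)
  b <- detect_spot_candidates(img * 2.5 + 40, lab)
  expect_equal(a[, c("label", "z", "y", "x")],
               b[, c("label", "z", "y", "x")])
})

test_that("a single Gaussian spot is found at its centre", {
  set.seed(4)
  sigma_n <- 2
  img <- matrix(100 + rnorm(80 * 80, 0, sigma_n), 80, 80)
  lab <- matrix(0L, 80, 80); lab[15:65, 15:65] <- 1L
  g <- expand.grid(y = 1:80, x = 1:80)
  amp <- 10 * sigma_n
  img <- img + amp * exp(-((g$y - 37)^2 + (g$x - 44)^2) / (2 * 1.5^2))
  cand <- detect_spot_candidates(img, lab)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$y - 36), 1)   # 0-based centre
  expect_lte(abs(cand$x - 43), 1)
  # empty frame: no nuclei -> no candidates
  expect_equal(nrow(detect_spot_candidates(img, lab * 0L)), 0)
})

test_that("integrated intensity recovers the programmed photon count", {
  img <- matrix(100, 90, 90)
  g <- expand.grid(y = 1:90, x = 1:90)
  F_ph <- 3000; s <- 1.5
  img <- img + F_ph / (2 * pi * s^2) *
    exp(-((g$y - 45)^2 + (g$x - 45)^2) / (2 * s^2))
  cand <- data.frame(label = 1L, z = 0L, y = 44L, x = 44L,
                     peak_intensity = max(img))
  sc <- filter_spots(cand, img, threshold = 0)
  # analytic Gaussian mass inside r < 3.5 px minus the shell-mean
  # correction (the shell still holds faint tails)
  mass_in <- function(r) 1 - exp(-r^2 / (2 * s^2))
  inner <- F_ph * mass_in(3.5)
  shell_mass <- F_ph * (mass_in(4.5) - mass_in(3.5))
  expected <- inner - 37 * shell_mass / 32
  expect_equal(sc$integrated_intensity, expected, tolerance = 0.02)
  # uniform nucleus: background-corrected intensity ~ 0 -> rejected
  flat <- matrix(100, 90, 90)
  sc0 <- filter_spots(cand, flat, threshold = 50)
  expect_equal(sc0$integrated_intensity, 0)
  expect_false(sc0$passed)
})

test_that("border-clipped disks are flagged and excluded", {
  img <- matrix(100, 30, 30)
  cand <- data.frame(label = 1L, z = 0L, y = 1L, x = 15L,
                     peak_intensity = 100)
  sc <- filter_spots(cand, img, threshold = 0)
  expect_true(sc$clipped)
  expect_false(sc$passed)
})

test_that("spot precision and recall reach 0.95 at SNR 8", {
  # one locus per nucleus; spot amplitude / noise sd = 8
  psf <- 1.5
  intensity <- 3000
  amp <- intensity / (2 * pi * psf^2)
  noise <- amp / 8
  cfg <- scene_config(shape = c(T = 6L, Z = 1L, Y = 200L, X = 200L),
                      n_cells = 8L, noise_sd = noise, seed = 19L)
  sp <- generate_spot_movie(cfg, burst_program(8, k_on = 0.5,
                                               k_off = 0.5,
                                               intensity = intensity,
                                               psf_sigma_px = psf))
  tp <- 0; fp <- 0; fn <- 0
  for (t in 1:6) {
    img <- sp$movie$channels$spot[, , 1, t]
    lab <- sp$truth$labels[, , 1, t]
    cand <- detect_spot_candidates(img, lab)
    thr <- 5 * sd(replicate(50, {
      v <- rnorm(37, 0, noise); s <- rnorm(32, 0, noise)
      sum(v) - 37 * mean(s)
    }))
    sc <- filter_spots(cand, img, thr)
    sc <- sc[sc$passed, ]
    truth <- sp$truth$spot_positions
    truth <- truth[truth$frame == t & truth$on, ]
    matched <- rep(FALSE, nrow(truth))
    for (i in seq_len(nrow(sc))) {
      d <- sqrt((truth$y - sc$y[i])^2 + (truth$x - sc$x[i])^2)
      j <- which.min(d)
      if (length(j) && d[j] <= 2 && !matched[j]) matched[j] <- TRUE
      else fp <- fp + 1
    }
    tp <- tp + sum(matched); fn <- fn + sum(!matched)
  }
  expect_gte(tp / (tp + fp), 0.95)  # precision
  expect_gte(tp / (tp + fn), 0.95)  # recall
})

test_that("pulse merging respects duration and the gap tolerance", {
  tracks <- data.frame(track_id = 1L, frame = 1:10, label = 1L)
  mk <- function(frames) data.frame(
    label = 1L, z = 0L, y = 10L, x = 10L, peak_intensity = 1,
    integrated_intensity = 100, shell_mean = 0, clipped = FALSE,
    passed = TRUE, frame = frames)
  # single-frame detection -> pulse of duration 1
  p1 <- track_pulses(mk(4L), tracks)
  expect_equal(p1$duration, 1L)
  # one missed frame inside a pulse is bridged (gap tolerance 1)
  p2 <- track_pulses(mk(c(2L, 3L, 5L, 6L)), tracks)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$duration, 5L)
  # a 2-frame hole splits the pulse
  p3 <- track_pulses(mk(c(2L, 6L)), tracks, gap_tolerance = 1)
  expect_equal(nrow(p3), 2)
})

test_that("two simultaneous spots form two concurrent pulse threads", {
  tracks <- data.frame(track_id = 1L, frame = 1:3, label = 1L)
  sp <- rbind(
    data.frame(label = 1L, z = 0L, y = 10L, x = 10L, peak_intensity = 1,
               integrated_intensity = 200, shell_mean = 0,
               clipped = FALSE, passed = TRUE, frame = c(1L, 2L)),
    data.frame(label = 1L, z = 0L, y = 20L, x = 20L, peak_intensity = 1,
               integrated_intensity = 150, shell_mean = 0,
               clipped = FALSE, passed = TRUE, frame = c(1L, 2L)))
  p <- track_pulses(sp, tracks)
  expect_equal(sort(unique(p$thread)), c(1, 2))
  expect_equal(nrow(p), 2)
  expect_true(all(p$duration == 2))
})

test_that("telegraph pulse durations are recovered within 15%", {
  # geometric on-times with mean 5 frames
  set.seed(41)
  k_off <- 0.2
  n_cells <- 40; n_frames <- 120
  tracks <- do.call(rbind, lapply(seq_len(n_cells), function(i)
    data.frame(track_id = i, frame = 1:n_frames, label = i)))
  spots <- list()
  true_durs <- c()
  for (i in seq_len(n_cells)) {
    t <- 1
    while (t <= n_frames) {
      if (runif(1) < 0.25) {        # enter a burst
        dur <- rgeom(1, k_off) + 1
        fr <- t:min(t + dur - 1, n_frames)
        true_durs <- c(true_durs, length(fr))
        spots[[length(spots) + 1]] <- data.frame(
          label = i, z = 0L, y = 10L, x = 10L, peak_intensity = 1,
          integrated_intensity = 100, shell_mean = 0, clipped = FALSE,
          passed = TRUE, frame = fr)
        t <- t + dur + 2
      } else t <- t + 1
    }
  }
  sp <- do.call(rbind, spots)
  p <- track_pulses(sp, tracks, gap_tolerance = 0)
  expect_lt(abs(mean(p$duration) - mean(true_durs)) / mean(true_durs),
            0.15)
})

test_that("activity time courses report transcribing fractions", {
  tracks <- do.call(rbind, lapply(1:10, function(i)
    data.frame(track_id = i, frame = 1:6, label = i)))
  mk_sp <- function(ids, frames) do.call(rbind, lapply(frames,
    function(f) data.frame(label = ids, z = 0L, y = 1L, x = 1L,
                           peak_intensity = 1,
                           integrated_intensity = 10, shell_mean = 0,
                           clipped = FALSE, passed = TRUE, frame = f)))
  # everyone transcribing always -> flat 1
  a1 <- activity_timecourse(mk_sp(1:10, 1:6), tracks)
  expect_true(all(a1$activity == 1))
  # step 0.2 -> 0.5 normalized to the window
  sp2 <- rbind(mk_sp(1:2, 1:3), mk_sp(1:5, 4:6))
  a2 <- activity_timecourse(sp2, tracks, window = 1:3)
  expect_equal(a2$normalized, c(1, 1, 1, 2.5, 2.5, 2.5))
  expect_error(activity_timecourse(sp2, tracks[0, ]), "empty")
})

test_that("mitosis alignment applies the daughter OR rule", {
  ann <- data.frame(parent_id = 1L, daughter1_id = 2L,
                    daughter2_id = 3L, cytokinesis_frame = 5L)
  tr <- rbind(
    data.frame(track_id = 1L, frame = 1:4, on = TRUE),
    data.frame(track_id = 2L, frame = 5:8, on = c(TRUE, FALSE, TRUE,
                                                  FALSE)),
    data.frame(track_id = 3L, frame = 5:8, on = c(FALSE, FALSE, TRUE,
                                                  TRUE)))
  nc <- rbind(
    data.frame(track_id = 1L, frame = 1:4, nc = 2.0),
    data.frame(track_id = 2L, frame = 5:8, nc = 1.0),
    data.frame(track_id = 3L, frame = 5:8, nc = 3.0))
  out <- align_mitosis(ann, tr, nc)
  post <- out$activity[out$activity$rel_frame >= 0, ]
  expect_equal(post$frac_transcribing, c(1, 0, 1, 1))  # OR of daughters
  expect_equal(out$activity$normalized[out$activity$rel_frame < 0],
               rep(1, 4))
  # aligned N/C after cytokinesis is the daughters' mean
  expect_true(all(out$nc$nc_mean[out$nc$rel_frame >= 0] == 2.0))
  expect_true(all(out$nc$nc_mean[out$nc$rel_frame < 0] == 2.0))
  # OR-rule implication: aligned activity >= either daughter alone
  for (d in 2:3) {
    own <- tr$on[tr$track_id == d]
    expect_true(all(post$frac_transcribing >= own))
  }
})

test_that("activity constant through division aligns to exactly one", {
  ann <- data.frame(parent_id = 1L, daughter1_id = 2L,
                    daughter2_id = 3L, cytokinesis_frame = 4L)
  tr <- rbind(data.frame(track_id = 1L, frame = 1:3, on = TRUE),
              data.frame(track_id = 2L, frame = 4:6, on = TRUE),
              data.frame(track_id = 3L, frame = 4:6, on = TRUE))
  out <- align_mitosis(ann, tr)
  expect_true(all(out$activity$normalized == 1))
})

test_that("divisions lacking daughter tracks are skipped", {
  ann <- data.frame(parent_id = c(1L, 4L), daughter1_id = c(2L, 8L),
                    daughter2_id = c(3L, 9L),
                    cytokinesis_frame = c(4L, 4L))
  tr <- rbind(data.frame(track_id = 1L, frame = 1:3, on = TRUE),
              data.frame(track_id = 2L, frame = 4:6, on = TRUE),
              data.frame(track_id = 3L, frame = 4:6, on = FALSE),
              data.frame(track_id = 4L, frame = 1:3, on = TRUE))
  out <- align_mitosis(ann, tr)
  expect_equal(out$skipped, 2L)
})

test_that("a programmed post-division burst appears in aligned traces", {
  # activity 0.2 premitosis, 0.6 for the post window: normalized ~3
  set.seed(6)
  n_div <- 30
  anns <- data.frame(parent_id = seq_len(n_div),
                     daughter1_id = n_div + seq_len(n_div),
                     daughter2_id = 2 * n_div + seq_len(n_div),
                     cytokinesis_frame = 9L)
  tr <- list()
  for (i in seq_len(n_div)) {
    tr[[length(tr) + 1]] <- data.frame(track_id = i, frame = 1:8,
                                       on = runif(8) < 0.2)
    for (d in c(n_div + i, 2 * n_div + i)) {
      # per-daughter on-fraction ~0.37 so the OR gives ~0.6
      tr[[length(tr) + 1]] <- data.frame(track_id = d, frame = 9:16,
                                         on = runif(8) < 0.37)
    }
  }
  out <- align_mitosis(anns, do.call(rbind, tr))
  pre <- mean(out$activity$frac_transcribing[out$activity$rel_frame < 0])
  post <- mean(out$activity$frac_transcribing[out$activity$rel_frame >=
                                                0])
  expect_gt(post / pre, 2)
  expect_lt(post / pre, 4.5)
})
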