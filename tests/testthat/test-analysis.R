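test_that("stationary detections link into full-length tracks", {
  det <- data.frame(time = rep(0:4 * 300, each = 2),
                    x = rep(c(10, 50), 5), y = rep(c(20, 20), 5))
  tr <- link_tracks(det, max_link_distance = 10)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 5))
})

test_that("the link gate prevents false links for large jumps", {
  ## both cells jump far beyond the gate in one step: no links allowed
  det <- data.frame(time = c(0, 0, 300, 300),
                    x = c(0, 100, 200, 300), y = c(0, 0, 0, 0))
  tr <- link_tracks(det, max_link_distance = 10)
  expect_equal(length(unique(tr$track_id)), 4)
})

test_that("tracking recovers simulated identities when motion is small", {
  set.seed(31)
  n <- 60
  x <- runif(n, 0, 400); y <- runif(n, 0, 400)
  frames <- lapply(0:9, function(k) {
    data.frame(time = k * 300, x = x + k * 1.5 + rnorm(n, 0, 0.3),
               y = y + rnorm(n, 0, 0.3), true_id = 1:n)
  })
  det <- do.call(rbind, frames)
  tr <- link_tracks(det, max_link_distance = 10)
  ## every track should contain exactly one true identity
  purity <- tapply(tr$true_id, tr$track_id, function(z) length(unique(z)))
  expect_gte(mean(purity == 1), 0.99)
})

test_that("velocities are exact finite differences in um/h", {
  tr <- data.frame(track_id = 1, time = 0:4 * 300,
                   x = rep(5, 5), y = seq(0, 40, 10))
  v <- frame_velocities(tr)
  expect_equal(v$vy, rep(120, 5))   # +10 um per 5 min
  expect_equal(v$vx, rep(0, 5))
  still <- frame_velocities(data.frame(track_id = 2, time = 0:3 * 60,
                                       x = 3, y = 9))
  expect_true(all(still$vx == 0 & still$vy == 0))
})

test_that("recovered drift matches an imposed drift field within 5%", {
  set.seed(32)
  n <- 50
  x0 <- runif(n, 0, 300); y0 <- runif(n, 0, 300)
  det <- do.call(rbind, lapply(0:11, function(k)
    data.frame(time = k * 300, x = x0 + 4 * k * 300 / 3600 + rnorm(n, 0, 0.1),
               y = y0 - 7 * k * 300 / 3600 + rnorm(n, 0, 0.1))))
  v <- frame_velocities(link_tracks(det, max_link_distance = 10))
  expect_lt(abs(mean(v$vx) - 4) / 4, 0.05)
  expect_lt(abs(mean(v$vy) + 7) / 7, 0.05)
})

test_that("phase binning reproduces hand-computed means and conserves counts", {
  p <- bar_wave_params(period_um = 100, speed_um_per_h = 0, duty = 0.5, offset_um = 0)
  ## with v=0 and y0=0, the bar centre is at y=25: phase = (y-25)/100
  s <- data.frame(time = 0, y = c(20, 30, 70, 80, 24, 26),
                  x = 0, vx = 0, vy = c(1, 3, -2, -4, 5, 7))
  vb <- velocity_vs_phase(s, p, n_bins = 4, min_count = 1)
  expect_equal(sum(vb$n), 6)
  ## bins of width 0.25: y in (0,25)->bin 2 ; (25,50)->bin 3 ; 70,80 -> bins 4,1
  expect_equal(vb$mean_v[2], mean(c(1, 5)))
  expect_equal(vb$mean_v[3], mean(c(3, 7)))
  expect_equal(vb$mean_v[4], -2)
  expect_equal(vb$mean_v[1], -4)

  uni <- data.frame(time = 0, y = runif(400, 0, 100), x = 0, vx = 0, vy = 2)
  vbu <- velocity_vs_phase(uni, p, n_bins = 5, min_count = 1)
  expect_true(all(abs(vbu$mean_v - 2) < 1e-12))

  ## sparse bins are flagged missing but still counted
  vbs <- velocity_vs_phase(s, p, n_bins = 4, min_count = 2)
  expect_true(is.na(vbs$mean_v[4]))
  expect_equal(sum(vbs$n), 6)
})

test_that("phase-aligned traces anchor at the zero crossing", {
  p <- bar_wave_params(period_um = 100, speed_um_per_h = 10, duty = 0.5,
                       offset_um = 0)
  ## a stationary track at y=25: phase 0 at t=0 (bar centre starts at 25)
  tr <- data.frame(track_id = 1, time = -2:2 * 360 + 720, x = 0, y = 25)
  tr$time <- 0:4 * 360
  ## centre passes y=25 at t=0; track phases go positive after 0
  res <- phase_aligned_traces(tr, p)
  expect_equal(res$n_excluded, 0)
  expect_equal(res$traces$disp, rep(0, 5))
  ## a track that never crosses zero phase is excluded and counted
  far <- data.frame(track_id = 2, time = 0:2 * 60, x = 0, y = 60)
  res2 <- phase_aligned_traces(far, p)
  expect_equal(res2$n_excluded, 1)
})

test_that("polar decomposition separates rotation from expansion exactly", {
  set.seed(33)
  th <- runif(200, 0, 2 * pi); r <- runif(200, 1, 50)
  x <- 100 + r * cos(th); y <- 100 + r * sin(th)
  ## rigid ccw rotation in display coordinates (y down): v = omega*(ry,-rx)
  omega <- 0.3
  rot <- data.frame(x = x, y = y, vx = omega * (y - 100), vy = -omega * (x - 100))
  pr <- polar_decompose(rot, c(100, 100))
  expect_true(all(abs(pr$v_radial) < 1e-9))
  expect_equal(pr$v_tangential, omega * r, tolerance = 1e-9)

  exp_ <- data.frame(x = x, y = y, vx = 2 * (x - 100), vy = 2 * (y - 100))
  pe <- polar_decompose(exp_, c(100, 100))
  expect_true(all(abs(pe$v_tangential) < 1e-9))
  expect_true(all(pe$v_radial > 0))

  ## energy identity on random fields
  rnd <- data.frame(x = x, y = y, vx = rnorm(200), vy = rnorm(200))
  pn <- polar_decompose(rnd, c(100, 100))
  expect_equal(pn$v_radial^2 + pn$v_tangential^2, rnd$vx^2 + rnd$vy^2,
               tolerance = 1e-12)
})

test_that("radial profiles recover rigid-body kinematics", {
  set.seed(34)
  th <- runif(600, 0, 2 * pi); r <- sqrt(runif(600)) * 60
  x <- r * cos(th); y <- r * sin(th)
  omega <- 0.5
  s <- polar_decompose(data.frame(x = x, y = y, vx = omega * y,
                                  vy = -omega * x), c(0, 0))
  prof <- radial_profile(s, n_rings = 4, max_radius = 60)
  expect_equal(prof$mean_omega[!prof$empty], rep(omega, sum(!prof$empty)),
               tolerance = 1e-9)
  expect_true(all(diff(prof$mean_v_tangential[!prof$empty]) > 0))
  ## hand-computed ring means
  ring <- findInterval(s$r, seq(0, 60, 15), rightmost.closed = TRUE,
                       all.inside = TRUE)
  expect_equal(prof$mean_v_tangential[2], mean(s$v_tangential[ring == 2]))
})

test_that("CV time courses are exact, scale-invariant and flag zero means", {
  cells <- data.frame(time_s = rep(c(0, 60), each = 2),
                      mean_intensity = c(1, 3, 2, 6))
  cv <- intensity_cv_timecourse(cells, background_subtract = FALSE)
  expect_equal(cv$cv, rep(0.5, 2))   # {1,3}: population SD 1, mean 2
  expect_equal(cv$fold_reduction[2], 1)          # scaling preserves CV
  scaled <- cells; scaled$mean_intensity <- scaled$mean_intensity * 37
  expect_equal(intensity_cv_timecourse(scaled, background_subtract = FALSE)$cv,
               cv$cv)
  equal <- data.frame(time_s = 0, mean_intensity = rep(5, 4))
  expect_equal(intensity_cv_timecourse(equal, background_subtract = FALSE)$cv, 0)
  zero <- data.frame(time_s = 0, mean_intensity = c(-1, 1))
  expect_true(is.na(intensity_cv_timecourse(zero, background_subtract = FALSE)$cv))

  h <- intensity_histograms(cells, times = 0, breaks = c(0, 2, 4),
                            background_subtract = FALSE)
  expect_equal(h$count, c(1, 1))
})
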