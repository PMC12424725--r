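## Brute-force oracles live in helper-oracles.R.

test_that("bar patterns match the per-row brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    p <- bar_wave_params(period_um = runif(1, 10, 300),
                         speed_um_per_h = runif(1, -60, 60),
                         duty = runif(1, 0.05, 1),
                         offset_um = runif(1, -200, 200))
    t <- runif(1, 0, 57600)
    psz <- sample(c(0.5, 1, 2), 1)
    rows <- sample(20:80, 1)
    pat <- bar_wave_pattern(p, t, psz, c(rows, 5))
    y <- (seq_len(rows) - 0.5) * psz
    expect_equal(pat$intensity[, 1], oracle_bar_row(y, t, p))
    expect_true(all(pat$intensity %in% c(0, 1)))
  }
})

test_that("duty is conserved to one row over whole-period windows", {
  ## the illuminated fraction equals the duty to within one row of
  ## discretization when the field spans an integer number of periods
  set.seed(102)
  for (i in 1:100) {
    P <- sample(20:120, 1)
    p <- bar_wave_params(period_um = P, speed_um_per_h = runif(1, -60, 60),
                         duty = runif(1, 0.05, 1),
                         offset_um = runif(1, -200, 200))
    rows <- P * sample(1:3, 1)
    pat <- bar_wave_pattern(p, runif(1, 0, 57600), 1, c(rows, 2))
    expect_lt(abs(mean(pat$intensity) - p$duty), 1 / P + 1e-9)
  }
})

test_that("full-duty bars illuminate everything at every time", {
  p <- bar_wave_params(period_um = 50, speed_um_per_h = 20, duty = 1)
  for (t in c(0, 123, 7200)) {
    expect_true(all(bar_wave_pattern(p, t, 1, c(40, 8))$intensity == 1))
  }
})

test_that("wave phase matches the enumerated-bar-centre oracle", {
  set.seed(202)
  for (i in 1:1000) {
    p <- bar_wave_params(period_um = runif(1, 5, 400),
                         speed_um_per_h = runif(1, -80, 80),
                         duty = runif(1, 0.05, 1),
                         offset_um = runif(1, -500, 500))
    y <- runif(1, -1000, 1000); t <- runif(1, 0, 1e5)
    ph <- wave_phase(y, t, p)
    expect_gte(ph, -0.5); expect_lt(ph, 0.5)
    expect_equal(ph, oracle_phase(y, t, p), tolerance = 1e-9)
  }
  ## zero at a bar centre; wrap boundary just below +0.5
  p <- bar_wave_params(100, 10, 0.4, 7)
  centre <- 7 + 10 * 3600 / 3600 + 0.4 * 100 / 2
  expect_equal(wave_phase(centre, 3600, p), 0)
  eps <- 1e-6
  expect_equal(wave_phase(centre + 50 - eps, 3600, p), 0.5 - eps / 100)
})

test_that("a pixel is illuminated exactly when its phase is in [-d/2, d/2)", {
  set.seed(303)
  for (i in 1:40) {
    p <- bar_wave_params(period_um = runif(1, 20, 200),
                         speed_um_per_h = runif(1, -50, 50),
                         duty = runif(1, 0.1, 0.95))
    t <- runif(1, 0, 57600)
    pat <- bar_wave_pattern(p, t, 1, c(128, 2))
    ph <- wave_phase((1:128) - 0.5, t, p)
    expect_equal(pat$intensity[, 1] == 1, ph >= -p$duty / 2 & ph < p$duty / 2)
  }
})

test_that("voronoi assignment equals the brute-force nearest-centroid scan", {
  set.seed(404)
  for (i in 1:50) {
    rows <- sample(16:128, 1); cols <- sample(16:128, 1)
    n <- sample(1:64, 1)
    cent <- data.frame(label = sample(1:500, n),
                       x = round(runif(n, 0, cols - 1), 2),
                       y = round(runif(n, 0, rows - 1), 2))
    vm <- voronoi_assign(cent, c(rows, cols))
    ## independent oracle with explicit smallest-label tie handling
    want <- matrix(0L, rows, cols)
    for (r in 1:rows) for (cc in 1:cols) {
      d <- (cent$x - (cc - 1))^2 + (cent$y - (r - 1))^2
      want[r, cc] <- min(cent$label[d == min(d)])
    }
    expect_equal(vm$labels, want)
  }
  ## explicit tie on the midline between two seeds
  cent <- data.frame(label = c(4, 9), x = c(0, 10), y = c(2, 2))
  vm <- voronoi_assign(cent, c(5, 12))
  expect_true(all(vm$labels[, 6] == 4))   # x = 5 equidistant -> smaller label
  expect_true(all(vm$labels[, 7] == 9))
  ## single centroid owns the field; empty input errors
  one <- voronoi_assign(data.frame(label = 3, x = 1, y = 1), c(6, 6))
  expect_true(all(one$labels == 3))
  expect_error(voronoi_assign(data.frame(label = integer(0), x = numeric(0),
                                         y = numeric(0)), c(6, 6)))
})

test_that("vortex gradients ramp along the tangent and mirror with chirality", {
  cent <- data.frame(label = 1, x = 30, y = 10)
  regions <- voronoi_assign(cent, c(21, 41))
  p <- vortex_params(center = c(10, 10), max_intensity = 0.8)
  pat <- vortex_gradient_pattern(cent, regions, p)
  ## radius vector points +x, so the ccw tangent (y down) is -y: intensity
  ## must increase upward (decreasing row) and be constant along x
  expect_true(all(diff(pat$intensity[, 5]) < 0))
  expect_equal(pat$intensity[3, 1], pat$intensity[3, 41])
  expect_equal(max(pat$intensity), 0.8)
  expect_equal(min(pat$intensity), 0)

  cw <- vortex_gradient_pattern(cent, regions,
                                vortex_params(center = c(10, 10),
                                              max_intensity = 0.8,
                                              chirality = "cw"))
  expect_equal(cw$intensity, 0.8 - pat$intensity)

  ## centred cell: uniform half intensity
  centre_cell <- data.frame(label = 1, x = 10, y = 10)
  reg2 <- voronoi_assign(centre_cell, c(21, 21))
  mid <- vortex_gradient_pattern(centre_cell, reg2, p)
  expect_true(all(mid$intensity == 0.4))
})

test_that("bang-bang patterns implement the thermostat rule exactly", {
  lbl <- matrix(0L, 10, 10); lbl[2:4, 2:4] <- 1L; lbl[7:9, 7:9] <- 2L
  mask <- label_mask(lbl, frame_time = 10)
  obs <- data.frame(label = c(1, 2), x = c(2, 7), y = c(2, 7), area = 9,
                    mean_intensity = c(10, 30))
  p <- bang_bang_params(setpoint = 20)
  pat <- bang_bang_pattern(obs, mask, p)
  expect_true(all(pat$intensity[lbl == 1] == 1))   # below set point: lit
  expect_true(all(pat$intensity[lbl == 2] == 0))   # above: dark
  expect_true(all(pat$intensity[lbl == 0] == 0))   # background dark
  expect_true(all(pat$intensity %in% c(0, 1)))

  ## all above set point -> all dark
  hi <- obs; hi$mean_intensity <- c(50, 60)
  expect_true(all(bang_bang_pattern(hi, mask, p)$intensity == 0))

  ## idempotence at fixed measurements
  expect_equal(bang_bang_pattern(obs, mask, p), bang_bang_pattern(obs, mask, p))

  ## hysteresis shifts the threshold down
  ph <- bang_bang_params(setpoint = 20, hysteresis_band = 15)
  expect_true(all(bang_bang_pattern(obs, mask, ph)$intensity == 0))

  ## image-valued set point, sampled as the mask-region mean
  spimg <- matrix(5, 10, 10); spimg[, 6:10] <- 100
  pi_ <- bang_bang_params(setpoint = spimg)
  pat2 <- bang_bang_pattern(obs, mask, pi_)
  expect_true(all(pat2$intensity[lbl == 1] == 0))  # 10 >= 5
  expect_true(all(pat2$intensity[lbl == 2] == 1))  # 30 < 100
  expect_error(bang_bang_pattern(obs, mask, bang_bang_params(matrix(5, 3, 3))),
               "shape")
})

test_that("constant patterns fill the requested region only", {
  full <- constant_pattern(c(8, 8), 1)
  expect_true(all(full$intensity == 1))
  empty <- constant_pattern(c(8, 8), 1, region = c(5, 5, 4, 4))
  expect_true(all(empty$intensity == 0))
  sq <- constant_pattern(c(8, 8), 0.5, region = c(2, 1, 4, 3))
  expect_equal(sum(sq$intensity), 0.5 * 9)
  expect_equal(sq$intensity[2, 3], 0.5)
  expect_equal(sq$intensity[1, 3], 0)
})

test_that("the pattern manager serves the latest valid pattern, dark before any", {
  pm <- pattern_manager(c(4, 4))
  dark <- pattern_manager_current(pm, 100)
  expect_true(all(dark$intensity == 0))
  a <- stimulus_pattern(matrix(1, 4, 4), valid_from = 0)
  b <- stimulus_pattern(matrix(0.5, 4, 4), valid_from = 300)
  pattern_manager_submit(pm, a)
  pattern_manager_submit(pm, b)
  expect_equal(pattern_manager_current(pm, 200)$intensity, a$intensity)
  expect_equal(pattern_manager_current(pm, 300)$intensity, b$intensity)

  ## time-parametric manager evaluates the module at query time
  p <- bar_wave_params(32, 12, 0.75)
  pmt <- pattern_manager(c(40, 4), evaluator = function(t)
    bar_wave_pattern(p, t, 1, c(40, 4)))
  for (t in c(60, 120, 3600)) {
    expect_equal(pattern_manager_current(pmt, t)$intensity,
                 bar_wave_pattern(p, t, 1, c(40, 4))$intensity)
  }
})

test_that("stimulus patterns reject out-of-range intensities", {
  expect_error(stimulus_pattern(matrix(1.5, 2, 2)))
  expect_error(stimulus_pattern(matrix(-0.1, 2, 2)))
})
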