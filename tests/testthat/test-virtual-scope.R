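test_that("population initialization reproduces the requested heterogeneity", {
  pop <- init_population(1000, c(512, 512), heterogeneity_cv = 0.45, seed = 1)
  cv <- sd(pop$baseline) / mean(pop$baseline)
  expect_lt(abs(cv - 0.45), 0.05)
  expect_true(all(pop$x >= 0 & pop$x <= 512))
  expect_equal(pop$fluor, pop$baseline)

  expect_equal(init_population(40, c(100, 100), 0.3, seed = 7),
               init_population(40, c(100, 100), 0.3, seed = 7))
  expect_equal(nrow(init_population(0, c(100, 100))), 0)
  expect_error(init_population(10, c(100, 100), heterogeneity_cv = -0.1))
})

test_that("photochromic kinetics have the right fixed points and closed form", {
  p <- photochromic_params(fold_change = 4.5, tau_on = 30, tau_off = 120)
  ## dark at baseline is a fixed point
  expect_equal(photochromic_update(100, 100, FALSE, 1e6, p), 100)
  ## sustained light saturates at the configured fold change
  expect_equal(photochromic_update(100, 100, TRUE, 1e6, p), 450)
  ## one tau_on of light from baseline: b * (k - (k - 1)/e)
  expect_equal(photochromic_update(100, 100, TRUE, 30, p),
               100 * (4.5 - 3.5 / exp(1)))
  expect_error(photochromic_update(100, 100, TRUE, -1, p))
})

test_that("closed-form relaxation matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- photochromic_params(4.5, 30, 120)
  rhs <- function(t, y, parms) {
    target <- if (parms$lit) parms$k * parms$b else parms$b
    tau <- if (parms$lit) parms$tau_on else parms$tau_off
    list((target - y) / tau)
  }
  set.seed(5)
  for (i in 1:20) {
    b <- runif(1, 50, 2000)
    f0 <- runif(1, b, 4.5 * b)
    dt <- runif(1, 1, 600)
    lit <- i %% 2 == 0
    num <- as.numeric(deSolve::lsoda(f0, c(0, dt), rhs,
                          list(lit = lit, k = 4.5, b = b, tau_on = 30,
                               tau_off = 120),
                          rtol = 1e-10, atol = 1e-10)[2, 2])
    expect_equal(photochromic_update(f0, b, lit, dt, p), num,
                 tolerance = 1e-6)
  }
})

test_that("fluorescence stays within [baseline, k*baseline] for any light sequence", {
  p <- photochromic_params(4.5, 30, 120)
  set.seed(6)
  for (i in 1:30) {
    b <- runif(1, 10, 1000)
    f <- b
    for (s in 1:50) {
      f <- photochromic_update(f, b, runif(1) < 0.5, runif(1, 0, 300), p)
      expect_gte(f, b - 1e-9)
      expect_lte(f, 4.5 * b + 1e-9)
    }
  }
})

test_that("brightening reverses to within 1% of baseline after 5 tau_off dark", {
  p <- photochromic_params(4.5, 30, 120)
  f <- photochromic_update(200, 200, TRUE, 600, p)     # near saturation
  f <- photochromic_update(f, 200, FALSE, 5 * 120, p)
  ## 99%+ of the light-induced change relaxes away
  expect_lt((f - 200) / (4.5 * 200 - 200), 0.01)
})

test_that("cells decay to rest under uniform light and climb gradients", {
  mot <- motility_params(noise_sigma = 0)
  pop <- init_population(20, c(64, 64), 0, seed = 2)
  pop$px <- 0.5; pop$py <- -0.3
  uni <- prepare_sense_field(matrix(1, 64, 64), 1)
  p0 <- pop
  for (i in 1:80) p0 <- step_dynamics(p0, uni, 60, mot, pixel_size = 1)
  expect_lt(max(abs(p0$px)), 1e-3)      # polarity decays under zero gradient
  expect_lt(max(abs(p0$py)), 1e-3)

  ## half-bright field: a cell at the boundary is pulled toward the light
  half <- matrix(0, 64, 64); half[, 33:64] <- 1   # bright at large x
  sh <- prepare_sense_field(half, 1)
  edge <- init_population(1, c(64, 64), 0, seed = 3)
  edge$x <- 32; edge$y <- 32
  x0 <- edge$x
  for (i in 1:20) edge <- step_dynamics(edge, sh, 60, mot, pixel_size = 1)
  expect_gt(edge$x, x0)
  expect_equal(edge$y, 32, tolerance = 0.3)

  ## positions stay inside the field under reflection
  drift <- init_population(50, c(64, 64), 0, seed = 4)
  drift$px <- 1
  for (i in 1:30) drift <- step_dynamics(drift, uni, 600,
                                         motility_params(v0 = 50, noise_sigma = 5),
                                         pixel_size = 1)
  expect_true(all(drift$x >= 0 & drift$x <= 64))
  expect_true(all(drift$y >= 0 & drift$y <= 64))
})

test_that("rendering places mass correctly and preserves totals", {
  cam <- camera_model(pixel_size = 1, fov_shape = c(65, 65), background = 0,
                      read_noise_sigma = 0, psf_sigma = 1)
  one <- init_population(1, c(65, 65), 0, seed = 1)
  one$x <- 32.5; one$y <- 32.5         # centre of pixel (33, 33)
  fr <- render_image(one, "nuclear", cam)
  expect_equal(which(fr$pixels == max(fr$pixels)), (33 - 1) * 65 + 33)

  many <- init_population(12, c(65, 65), 0.4, seed = 9)
  frn <- render_image(many, "fluor", cam)
  expect_equal(sum(frn$pixels), sum(many$fluor), tolerance = 1e-6)

  cam_bg <- camera_model(pixel_size = 1, fov_shape = c(65, 65), background = 7,
                         read_noise_sigma = 0, psf_sigma = 1)
  frb <- render_image(many, "fluor", cam_bg)
  expect_equal(sum(frb$pixels), sum(many$fluor) + 7 * 65 * 65, tolerance = 1e-6)

  ## two well-separated cells at fluorescence ratio 4.5 show peak ratio 4.5
  two <- init_population(2, c(129, 129), 0, seed = 1)
  two$x <- c(32.5, 96.5); two$y <- c(64.5, 64.5)
  two$fluor <- c(1000, 4500)
  f2 <- render_image(two, "fluor", cam_bg <- camera_model(
    pixel_size = 1, fov_shape = c(129, 129), background = 0,
    read_noise_sigma = 0, psf_sigma = 1))
  peak1 <- max(f2$pixels[, 1:64]); peak2 <- max(f2$pixels[, 65:129])
  expect_equal(peak2 / peak1, 4.5, tolerance = 0.01)
})

test_that("the simulated scope honors the interface contract", {
  pop <- init_population(30, c(96, 96), 0.3, seed = 11)
  cam <- camera_model(pixel_size = 1, fov_shape = c(96, 96))
  sc <- simulated_scope(pop, cam, motility_params(v0 = 0),
                        photochromic_params(4.5, 30, 120), seed = 12)
  expect_error(sc$project(matrix(1, 10, 10)), "shape")

  ## dark: fluorescence stays put
  sc$project(matrix(0, 96, 96))
  sc$advance_to(300)
  expect_equal(sc$population$fluor, pop$fluor)

  ## sustained full-field light: population mean rises toward 4.5x
  sc$project(matrix(1, 96, 96))
  sc$advance_to(300 + 600)
  expect_gt(mean(sc$population$fluor) / mean(pop$baseline), 4)
  expect_true(all(sc$dose_s > 0))

  expect_error(sc$advance_to(10), "backwards")

  ## determinism: same seed, same trajectory
  sc2 <- simulated_scope(init_population(30, c(96, 96), 0.3, seed = 11), cam,
                         motility_params(v0 = 0),
                         photochromic_params(4.5, 30, 120), seed = 12)
  sc2$project(matrix(0, 96, 96)); sc2$advance_to(300)
  sc2$project(matrix(1, 96, 96)); sc2$advance_to(900)
  expect_equal(sc2$population, sc$population)
})

test_that("projected bar schedules reproduce direct dynamics calls", {
  p <- bar_wave_params(32, 12, 0.75)
  pop <- init_population(25, c(128, 128), 0, seed = 21)
  cam <- camera_model(pixel_size = 1, fov_shape = c(128, 128))
  mot <- motility_params(noise_sigma = 0)
  sc <- simulated_scope(pop, cam, mot, seed = 22, boundary = "wrap")
  direct <- pop
  for (k in 0:9) {
    pat <- bar_wave_pattern(p, k * 60, 1, c(128, 128))
    sc$project(pat); sc$advance_to((k + 1) * 60)
    sense <- prepare_sense_field(pat$intensity, 1, boundary = "wrap")
    direct <- step_dynamics(direct, sense, 60, mot, pixel_size = 1,
                            boundary = "wrap")
  }
  expect_equal(sc$population$x, direct$x, tolerance = 1e-12)
  expect_equal(sc$population$y, direct$y, tolerance = 1e-12)
})
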