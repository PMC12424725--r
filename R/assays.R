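## Canonical simulated assays. These wrappers pin down the study
## conditions (field size, cell numbers, cadences, module parameters)
## used throughout the package's tests, vignette and reproduction script,
## so every consumer runs the same experiment definitions.

wave_position_toml <- function(name, speed, period = 32, duty = 0.75,
                               n_cells = 240, fov = 480) {
  paste(c(
    "[position]",
    sprintf('name = "%s"', name),
    "pixel_size_um = 1.0",
    sprintf("fov = [%d, %d]", fov, fov),
    "[segmentation]",
    'module = "threshold"',
    "smooth_sigma = 2",
    "min_area = 9",
    "[pattern]",
    'module = "bars"',
    sprintf("period_um = %g", period),
    sprintf("speed_um_per_h = %g", speed),
    sprintf("duty = %g", duty),
    "[simulate]",
    sprintf("n_cells = %d", n_cells),
    "cv = 0.2",
    'boundary = "wrap"',
    "[[channels]]",
    'name = "nuclear"',
    "exposure_ms = 50"
  ), collapse = "\n")
}

#' Simulate the traveling-wave migration assay
#'
#' One stage position per wave speed, all in a single multipoint run:
#' 480 x 480 um fields of 240 cells, horizontal bars (period 32 um, duty
#' 0.75) swept at the requested speeds, stimulation every minute and
#' nuclear imaging every 5 minutes. Cell positions are read back from the
#' recorded segmentations, linked into tracks, differentiated, and binned
#' by wave phase; the analysis window drops the first hour
#' (equilibration).
#'
#' @param speeds Wave speeds to sweep (um/h).
#' @param seed Master seed.
#' @param length_h Experiment length (h).
#' @param n_cells Cells per field.
#' @param window_start_s Analysis window start (s).
#' @return List per speed: `mean_v` (um/h along the wave), `phase_bins`
#'   ([velocity_vs_phase()] table), `n_tracks`; plus `record`.
#' @export
simulate_wave_assay <- function(speeds = c(8, 12, 25, 50), seed = 1,
                                length_h = 16, n_cells = 240,
                                window_start_s = 3600) {
  sched <- parse_schedule(sprintf(paste(
    "[schedule]", 'length = "%gh"', 'imaging_interval = "5min"',
    'stimulation_interval = "1min"', "seed = %d", sep = "\n"),
    length_h, seed))
  names_ <- sprintf("wave%02d", speeds)
  pos <- data.frame(name = names_, x = seq_along(speeds) * 1000, y = 0, z = NA)
  cfgs <- lapply(seq_along(speeds), function(i)
    parse_position_config(wave_position_toml(names_[i], speeds[i],
                                             n_cells = n_cells)))
  plan <- build_experiment_plan(sched, pos, cfgs)
  record <- run_loop(plan)
  out <- list()
  for (i in seq_along(speeds)) {
    cells <- record$cells[record$cells$position == names_[i], ]
    det <- data.frame(time = cells$time_s, x = cells$x_px + 0.5,
                      y = cells$y_px + 0.5)  # 1 um/px
    tracks <- link_tracks(det, max_link_distance = 10)
    vel <- frame_velocities(tracks)
    vel <- vel[vel$time >= window_start_s, ]
    bp <- plan$configs[[i]]$pattern$params
    p <- bar_wave_params(period_um = bp$period_um, speed_um_per_h = bp$speed_um_per_h,
                         duty = bp$duty)
    out[[names_[i]]] <- list(
      speed = speeds[i],
      mean_v = mean(vel$vy) * sign(speeds[i]),
      phase_bins = velocity_vs_phase(vel, p),
      n_tracks = length(unique(tracks$track_id)))
  }
  out$record <- record
  out
}

feedback_position_toml <- function(name, setpoint, n_cells = 1000, fov = 512,
                                   hysteresis = 0) {
  paste(c(
    "[position]",
    sprintf('name = "%s"', name),
    "pixel_size_um = 1.0",
    sprintf("fov = [%d, %d]", fov, fov),
    "[segmentation]",
    'module = "threshold"',
    "smooth_sigma = 2",
    "min_area = 9",
    "[pattern]",
    'module = "bangbang"',
    sprintf("setpoint = %g", setpoint),
    sprintf("hysteresis = %g", hysteresis),
    'channel = "fluor"',
    "[simulate]",
    sprintf("n_cells = %d", n_cells),
    "cv = 0.45",
    'arrangement = "grid"',
    "v0 = 0",          # H2B reporter line: no light-driven migration
    "k_fold = 4.5",
    "tau_on_s = 30",
    "tau_off_s = 120",
    "[[channels]]",
    'name = "nuclear"',
    "exposure_ms = 50",
    "[[channels]]",
    'name = "fluor"',
    "exposure_ms = 100"
  ), collapse = "\n")
}

#' Simulate the bang-bang fluorescence feedback assay
#'
#' A field of non-migrating nuclei with lognormal baseline fluorescence
#' (CV 0.45) and reversible 4.5-fold photochromic brightening is imaged
#' and controlled at a fixed cadence: each round, every nucleus whose
#' measured mean fluorescence falls below the set point has its mask
#' region illuminated until the next round. The scalar set point defaults
#' to `setpoint_factor` times the population-mean baseline, expressed in
#' measured (image) units from a probe render; alternatively a set-point
#' image assigns spatially varying targets.
#'
#' @param n_cells Number of cells.
#' @param seed Master seed.
#' @param n_steps Number of control steps.
#' @param interval_s Imaging + control interval (s).
#' @param setpoint_factor Scalar set point as a multiple of the mean
#'   measured baseline (ignored when `setpoint_image_levels` is given).
#' @param setpoint_image_levels Optional `c(lo, hi)` multiples of the
#'   mean measured baseline: the left half of the field is targeted at
#'   `lo`, the right half at `hi` (a two-level grayscale set-point image).
#' @param fov Field size (px, 1 um/px).
#' @return List: `record`, `cv_table`, `cv_fold`, `spearman_dose_baseline`,
#'   `within_10pct`, `setpoint` (scalar or image), `background`.
#' @export
simulate_feedback_assay <- function(n_cells = 1000, seed = 1, n_steps = 40,
                                    interval_s = 30, setpoint_factor = 2.5,
                                    setpoint_image_levels = NULL, fov = 512) {
  ## probe render: express the set point in measured image units
  probe_seed <- derive_seed(seed, "feedback")
  pop <- init_population(n_cells, c(fov, fov), heterogeneity_cv = 0.45,
                         seed = probe_seed, arrangement = "grid")
  cam <- camera_model(pixel_size = 1, fov_shape = c(fov, fov))
  probe_stream <- rng_stream(derive_seed(probe_seed, "probe"))
  nuc <- with_stream(probe_stream, render_image(pop, "nuclear", cam))
  flu <- with_stream(probe_stream, render_image(pop, "fluor", cam))
  mask0 <- segment_nuclei_threshold(nuc, smooth_sigma = 2, min_area = 9)
  obs0 <- measure_cells(list(nuclear = nuc, fluor = flu), mask0)
  bg <- obs0$background_fluor[1]
  mean_meas0 <- mean(obs0$mean_fluor - bg)

  sched <- parse_schedule(sprintf(paste(
    "[schedule]", 'length = "%ds"', 'imaging_interval = "%ds"',
    'stimulation_interval = "%ds"', "seed = %d", sep = "\n"),
    n_steps * interval_s, interval_s, interval_s, seed))
  setpoint <- bg + setpoint_factor * mean_meas0
  toml <- feedback_position_toml("ctrl", setpoint, n_cells, fov)
  cfg <- parse_position_config(toml)
  sp_img <- NULL
  if (!is.null(setpoint_image_levels)) {
    sp_img <- matrix(bg + setpoint_image_levels[2] * mean_meas0, fov, fov)
    sp_img[, seq_len(fov %/% 2)] <- bg + setpoint_image_levels[1] * mean_meas0
    cfg$pattern$params$setpoint <- NULL
    cfg$pattern$params$setpoint_image <- sp_img
  }
  pos <- data.frame(name = "ctrl", x = 0, y = 0, z = NA)
  plan <- build_experiment_plan(sched, pos, list(cfg))
  ## the population must match the probe: rebuild scopes with that seed
  plan$schedule$seed <- seed
  record <- run_loop(plan, scopes = list(
    ctrl = simulated_scope(pop, cam,
                           motility_params(v0 = 0),
                           photochromic_params(4.5, 30, 120),
                           seed = derive_seed(probe_seed, "scope"),
                           position_name = "ctrl")),
    keep_masks = TRUE)

  cells <- record$cells
  cvt <- intensity_cv_timecourse(cells)
  cv0 <- cvt$cv[cvt$time_s == min(cvt$time_s)]
  cvf <- cvt$cv[cvt$time_s == max(cvt$time_s)]
  tr <- record$truth$ctrl
  rho <- suppressWarnings(cor(tr$dose_s, tr$population$baseline,
                              method = "spearman"))
  ## fraction of cells within 10% of their (local) set point at the end
  last_t <- max(cells$time_s)
  fin <- cells[cells$time_s == last_t, ]
  masks <- record$masks$ctrl
  last_mask <- masks[[length(masks)]]
  target <- if (is.null(sp_img)) rep(setpoint, nrow(fin)) else
    vapply(fin$label, function(l) mean(sp_img[last_mask$labels == l]), 0)
  within <- abs((fin$mean_intensity - fin$background) - (target - bg)) <=
    0.1 * (target - bg)
  list(record = record, cv_table = cvt, cv_fold = cv0 / cvf,
       spearman_dose_baseline = rho, within_10pct = mean(within),
       setpoint = if (is.null(sp_img)) setpoint else sp_img, background = bg)
}

vortex_position_toml <- function(name, n_cells = 80, fov = 256,
                                 chirality = "ccw") {
  paste(c(
    "[position]",
    sprintf('name = "%s"', name),
    "pixel_size_um = 1.0",
    sprintf("fov = [%d, %d]", fov, fov),
    "[segmentation]",
    'module = "threshold"',
    "smooth_sigma = 2",
    "min_area = 9",
    "[pattern]",
    'module = "vortex"',
    sprintf('chirality = "%s"', chirality),
    "max_intensity = 1.0",
    "[simulate]",
    sprintf("n_cells = %d", n_cells),
    "cv = 0.2",
    "[[channels]]",
    'name = "nuclear"',
    "exposure_ms = 50"
  ), collapse = "\n")
}

#' Simulate the closed-loop vortex (rotational flow) assay
#'
#' Every cell's Voronoi territory receives a light gradient tangential to
#' its position about the field centre; the segmentation -> pattern loop
#' re-targets the gradients as cells move. Velocities are decomposed into
#' radial and tangential components about the centre.
#'
#' @param seed Master seed.
#' @param length_h Experiment length (h).
#' @param n_cells Number of cells.
#' @param fov Field size (px, 1 um/px).
#' @param chirality `"ccw"` or `"cw"`.
#' @return List: `record`, `samples` (polar-decomposed velocities),
#'   `mean_v_tangential`, `mean_v_radial`, `profile` (radial profile).
#' @export
simulate_vortex_assay <- function(seed = 1, length_h = 3, n_cells = 80,
                                  fov = 256, chirality = "ccw") {
  sched <- parse_schedule(sprintf(paste(
    "[schedule]", 'length = "%gh"', 'imaging_interval = "5min"',
    'stimulation_interval = "1min"', "seed = %d", sep = "\n"),
    length_h, seed))
  cfg <- parse_position_config(vortex_position_toml("vortex", n_cells, fov,
                                                    chirality))
  pos <- data.frame(name = "vortex", x = 0, y = 0, z = NA)
  plan <- build_experiment_plan(sched, pos, list(cfg))
  record <- run_loop(plan)
  cells <- record$cells
  det <- data.frame(time = cells$time_s, x = cells$x_px + 0.5,
                    y = cells$y_px + 0.5)
  vel <- frame_velocities(link_tracks(det, max_link_distance = 10))
  vel <- vel[vel$time >= 1800, ]
  samples <- polar_decompose(vel, center = c(fov / 2, fov / 2))
  list(record = record, samples = samples,
       mean_v_tangential = mean(samples$v_tangential),
       mean_v_radial = mean(samples$v_radial),
       profile = radial_profile(samples, n_rings = 5, max_radius = fov / 2))
}

#' Generate a synthetic nuclei fixture with ground truth
#'
#' Well-separated nuclei (minimum pairwise distance enforced by rejection
#' sampling) rendered through the camera model, with the true positions
#' and fluorescences returned for validating segmentation and
#' measurement.
#'
#' @param n Number of nuclei.
#' @param fov Field size (px, 1 um/px).
#' @param seed Seed.
#' @param min_sep Minimum pairwise separation (um).
#' @param cv Baseline fluorescence CV.
#' @param snr Approximate peak signal-to-noise ratio of the render.
#' @return List: `nuclear`, `fluor` (frames), `truth` (data.frame
#'   `id, x, y, fluor` in um / a.u.).
#' @export
make_nuclei_fixture <- function(n = 50, fov = 256, seed = 1, min_sep = 20,
                                cv = 0.45, snr = 50) {
  stream <- rng_stream(seed)
  with_stream(stream, {
    pts <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (nrow(pts) < n && guard < 20000) {
      cand <- runif(2, min_sep / 2, fov - min_sep / 2)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
        pts <- rbind(pts, cand)
      guard <- guard + 1
    }
    if (nrow(pts) < n) stop("could not place nuclei at the requested separation")
    sdlog <- sqrt(log(1 + cv^2))
    base <- rlnorm(n, log(1000) - sdlog^2 / 2, sdlog)
    pop <- structure(data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2],
                                px = 0, py = 0, baseline = base, fluor = base,
                                radius = 3),
                     class = c("cell_population", "data.frame"))
    peak <- 1000 / (2 * pi * 10)   # integrated 1000, sigma_eff ~ sqrt(10)
    cam <- camera_model(pixel_size = 1, fov_shape = c(fov, fov),
                        background = 50, read_noise_sigma = peak / snr,
                        psf_sigma = 1)
    list(nuclear = render_image(pop, "nuclear", cam),
         fluor = render_image(pop, "fluor", cam),
         truth = data.frame(id = pop$id, x = pop$x, y = pop$y, fluor = pop$fluor))
  })
}
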