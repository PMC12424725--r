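## The simulated microscope: agent cells that polarize and migrate along
## illumination gradients (a surrogate for light-activated receptor
## signalling), a reversible photochromic fluorophore, and a renderer that
## produces nuclear-dye-like images. This is the backend that makes the
## whole closed loop runnable without hardware.

#' Motility parameters
#'
#' Cells carry a polarity vector `p` that relaxes toward `alpha * grad(L)`
#' (the local gradient of the illumination field, sensed after smoothing
#' at the cell scale and clamped to unit magnitude) with time constant
#' `tau_p`, and translocate with velocity `v0 * p` plus Brownian noise.
#'
#' @param v0 Maximum migration speed (um/h).
#' @param alpha Gradient sensitivity (um): polarity target is
#'   `alpha * grad(L)` with the gradient in 1/um.
#' @param tau_p_min Polarity relaxation time (minutes).
#' @param noise_sigma Positional noise (um per sqrt(hour)).
#' @param sense_sigma_um Spatial scale (um) over which a cell senses the
#'   illumination field (Gaussian smoothing before the gradient).
#' @return A `motility_params` list.
#' @export
motility_params <- function(v0 = 20, alpha = 47, tau_p_min = 10,
                            noise_sigma = 0.2, sense_sigma_um = 8) {
  stopifnot(v0 >= 0, tau_p_min > 0, noise_sigma >= 0, sense_sigma_um > 0)
  structure(list(v0 = v0, alpha = alpha, tau_p_min = tau_p_min,
                 noise_sigma = noise_sigma, sense_sigma_um = sense_sigma_um),
            class = "motility_params")
}

#' Photochromic fluorophore parameters
#'
#' Two-state first-order kinetics: under blue light the fluorescence
#' relaxes toward `fold_change * baseline` with time constant `tau_on`;
#' in the dark it relaxes back toward `baseline` with `tau_off`. The
#' steady-state brightening is the configured fold change (default 4.5).
#'
#' @param fold_change Steady-state fold brightening, >= 1.
#' @param tau_on,tau_off Time constants (s) under light / in the dark.
#' @return A `photochromic_params` list.
#' @export
photochromic_params <- function(fold_change = 4.5, tau_on = 30, tau_off = 120) {
  stopifnot(fold_change >= 1, tau_on > 0, tau_off > 0)
  structure(list(fold_change = fold_change, tau_on = tau_on, tau_off = tau_off),
            class = "photochromic_params")
}

#' Camera / optics model
#'
#' @param pixel_size um per pixel.
#' @param fov_shape `(rows, cols)` pixels.
#' @param background Additive background level (a.u.).
#' @param read_noise_sigma Gaussian read noise sd (a.u.).
#' @param psf_sigma Point-spread sigma (um).
#' @return A `camera_model` list.
#' @export
camera_model <- function(pixel_size = 1, fov_shape = c(512, 512),
                         background = 50, read_noise_sigma = 2, psf_sigma = 1) {
  stopifnot(pixel_size > 0, psf_sigma > 0)
  structure(list(pixel_size = pixel_size, fov_shape = as.integer(fov_shape),
                 background = background, read_noise_sigma = read_noise_sigma,
                 psf_sigma = psf_sigma), class = "camera_model")
}

#' Initialize a simulated cell population
#'
#' Positions are uniform in the FOV (or a jittered grid); baseline
#' fluorescences are lognormal with the requested coefficient of
#' variation. Deterministic given the seed.
#'
#' @param n Number of cells.
#' @param fov_um `(width, height)` of the field (um).
#' @param heterogeneity_cv CV of the lognormal baseline distribution, >= 0.
#' @param seed Integer seed.
#' @param arrangement `"uniform"` or `"grid"` (jittered grid, which avoids
#'   the chance overlaps of uniform placement in dense fields).
#' @param baseline_mean Mean baseline fluorescence (a.u.).
#' @param radius Nuclear radius (um).
#' @param jitter_sd Grid jitter sd (um), for `arrangement = "grid"`.
#' @return A `cell_population` data.frame: `id, x, y, px, py, baseline,
#'   fluor, radius`.
#' @export
init_population <- function(n, fov_um, heterogeneity_cv = 0.45, seed = 1,
                            arrangement = c("uniform", "grid"),
                            baseline_mean = 1000, radius = 3, jitter_sd = 2) {
  arrangement <- match.arg(arrangement)
  if (heterogeneity_cv < 0) stop("heterogeneity_cv must be >= 0")
  if (n < 0) stop("n must be >= 0")
  if (n == 0)
    return(structure(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                                px = numeric(0), py = numeric(0),
                                baseline = numeric(0), fluor = numeric(0),
                                radius = numeric(0)),
                     class = c("cell_population", "data.frame")))
  stream <- rng_stream(seed)
  with_stream(stream, {
    if (arrangement == "uniform") {
      x <- runif(n, 0, fov_um[1]); y <- runif(n, 0, fov_um[2])
    } else {
      k <- ceiling(sqrt(n))
      gx <- (rep(seq_len(k), times = k)[seq_len(n)] - 0.5) * fov_um[1] / k
      gy <- (rep(seq_len(k), each = k)[seq_len(n)] - 0.5) * fov_um[2] / k
      x <- clamp(gx + rnorm(n, 0, jitter_sd), 0, fov_um[1])
      y <- clamp(gy + rnorm(n, 0, jitter_sd), 0, fov_um[2])
    }
    if (heterogeneity_cv > 0) {
      sdlog <- sqrt(log(1 + heterogeneity_cv^2))
      base <- rlnorm(n, log(baseline_mean) - sdlog^2 / 2, sdlog)
    } else base <- rep(baseline_mean, n)
    structure(data.frame(id = seq_len(n), x = x, y = y, px = 0, py = 0,
                         baseline = base, fluor = base, radius = radius),
              class = c("cell_population", "data.frame"))
  })
}

#' Photochromic fluorescence update (closed form)
#'
#' Exponential relaxation toward `fold_change * baseline` (illuminated,
#' time constant `tau_on`) or toward `baseline` (dark, `tau_off`); those
#' two levels are the only fixed points, so fluorescence never leaves
#' `[baseline, fold_change * baseline]`.
#'
#' @param fluor Current fluorescence(s), a.u.
#' @param baseline Baseline fluorescence(s), a.u.
#' @param illuminated Logical (vectorized).
#' @param dt Time step (s), >= 0.
#' @param p [photochromic_params()].
#' @return Updated fluorescence(s).
#' @export
photochromic_update <- function(fluor, baseline, illuminated, dt,
                                p = photochromic_params()) {
  if (any(dt < 0)) stop("dt must be >= 0")
  target <- ifelse(illuminated, p$fold_change * baseline, baseline)
  tau <- ifelse(illuminated, p$tau_on, p$tau_off)
  target + (fluor - target) * exp(-dt / tau)
}

#' Precompute the sensed illumination field
#'
#' Smooths the pattern at the cell sensing scale and takes its spatial
#' gradient; reused across sub-steps while the projected pattern is
#' unchanged.
#'
#' @param field Intensity matrix in `[0, 1]` (or a `stimulus_pattern`).
#' @param pixel_size um/px.
#' @param sense_sigma_um Sensing scale (um).
#' @param boundary `"reflect"` or `"wrap"`.
#' @return List `raw`, `gx`, `gy` (gradients in 1/um).
#' @export
prepare_sense_field <- function(field, pixel_size, sense_sigma_um = 8,
                                boundary = "reflect") {
  raw <- if (inherits(field, "stimulus_pattern")) field$intensity else field
  sigma_px <- sense_sigma_um / pixel_size
  nr <- nrow(raw); nc <- ncol(raw)
  ## fast path for patterns constant along x (e.g. bar waves): smooth and
  ## differentiate the 1-D row profile only
  if (nc > 1 && all(raw == raw[, 1])) {
    prof <- raw[, 1]
    r <- ceiling(3 * sigma_px)
    k <- dnorm(seq(-r, r), sd = sigma_px); k <- k / sum(k)
    idx <- outer(seq_len(nr), seq(-r, r), function(i, j) ((i + j - 1) %% nr) + 1)
    sm <- as.numeric(matrix(prof[idx], nr) %*% k)
    gyp <- (sm[c(2:nr, 1)] - sm[c(nr, 1:(nr - 1))]) / (2 * pixel_size)
    return(list(raw = raw, gx = matrix(0, nr, nc),
                gy = matrix(gyp, nr, nc)))
  }
  sm <- EBImage::gblur(raw, sigma = sigma_px)
  g <- field_gradient(sm, pixel_size, boundary)
  list(raw = raw, gx = g$gx, gy = g$gy)
}

#' Advance cell dynamics one step
#'
#' Polarity relaxes toward the clamped gradient target; positions advance
#' with `v0 * polarity * dt` plus Gaussian noise; fluorescence follows the
#' photochromic kinetics with `illuminated = (local raw intensity > 0)`.
#' Positions are reflected (default) or wrapped at the FOV boundary.
#' Uses the caller's RNG state for the noise.
#'
#' @param cells A `cell_population`.
#' @param sense Output of [prepare_sense_field()] for the active pattern.
#' @param dt Time step (s), > 0.
#' @param motility [motility_params()].
#' @param photo [photochromic_params()].
#' @param pixel_size um/px.
#' @param fov_um `(width, height)` (um).
#' @param boundary `"reflect"` or `"wrap"`.
#' @return Updated `cell_population`.
#' @export
step_dynamics <- function(cells, sense, dt, motility = motility_params(),
                          photo = photochromic_params(), pixel_size = 1,
                          fov_um = NULL, boundary = "reflect") {
  stopifnot(dt > 0)
  n <- nrow(cells)
  if (n == 0L) return(cells)
  if (is.null(fov_um))
    fov_um <- c(ncol(sense$raw), nrow(sense$raw)) * pixel_size
  gx <- sample_field(sense$gx, cells$x, cells$y, pixel_size, boundary)
  gy <- sample_field(sense$gy, cells$x, cells$y, pixel_size, boundary)
  tx <- motility$alpha * gx; ty <- motility$alpha * gy
  nrm <- sqrt(tx^2 + ty^2)
  scale <- ifelse(nrm > 1, 1 / nrm, 1)
  tx <- tx * scale; ty <- ty * scale
  decay <- exp(-dt / (motility$tau_p_min * 60))
  cells$px <- tx + (cells$px - tx) * decay
  cells$py <- ty + (cells$py - ty) * decay
  dth <- dt / 3600
  sdn <- motility$noise_sigma * sqrt(dth)
  cells$x <- cells$x + motility$v0 * cells$px * dth + if (sdn > 0) rnorm(n, 0, sdn) else 0
  cells$y <- cells$y + motility$v0 * cells$py * dth + if (sdn > 0) rnorm(n, 0, sdn) else 0
  if (boundary == "wrap") {
    cells$x <- cells$x %% fov_um[1]
    cells$y <- cells$y %% fov_um[2]
  } else {
    refl <- function(z, L) { z <- z %% (2 * L); ifelse(z > L, 2 * L - z, z) }
    cells$x <- refl(cells$x, fov_um[1])
    cells$y <- refl(cells$y, fov_um[2])
  }
  lit <- sample_field(sense$raw, cells$x, cells$y, pixel_size, boundary) > 0
  cells$fluor <- photochromic_update(cells$fluor, cells$baseline, lit, dt, photo)
  attr(cells, "lit") <- lit
  cells
}

#' Render a synthetic fluorescence image
#'
#' Each cell contributes an isotropic Gaussian spot (sigma =
#' `sqrt(psf_sigma^2 + radius^2)`) whose integrated intensity is a
#' constant nuclear-dye amplitude (`channel = "nuclear"`) or the cell's
#' current fluorescence (`channel = "fluor"`); additive background and
#' Gaussian read noise follow, and intensities are clipped at zero. Uses
#' the caller's RNG state for the noise.
#'
#' @param cells A `cell_population`.
#' @param channel `"nuclear"` or `"fluor"`.
#' @param cam [camera_model()].
#' @param time,frame_index Metadata stamped on the frame.
#' @param position_name Metadata stamped on the frame.
#' @param nuclear_amplitude Integrated intensity of a nucleus in the
#'   nuclear channel (a.u.).
#' @return A `frame` (list with `pixels`, `position_name`, `channel`,
#'   `time`, `frame_index`).
#' @export
render_image <- function(cells, channel = c("nuclear", "fluor"),
                         cam = camera_model(), time = 0, frame_index = 0L,
                         position_name = "", nuclear_amplitude = 1000) {
  channel <- match.arg(channel)
  rows <- cam$fov_shape[1]; cols <- cam$fov_shape[2]
  img <- matrix(0, rows, cols)
  if (nrow(cells)) {
    amp <- if (channel == "nuclear") rep(nuclear_amplitude, nrow(cells)) else cells$fluor
    ## bilinear deposition of each cell's integrated intensity
    cc <- clamp(cells$x / cam$pixel_size - 0.5, 0, cols - 1)
    rr <- clamp(cells$y / cam$pixel_size - 0.5, 0, rows - 1)
    c0 <- floor(cc); r0 <- floor(rr)
    fc <- cc - c0; fr <- rr - r0
    for (dr in 0:1) for (dc in 0:1) {
      w <- (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc)
      ri <- pmin(r0 + dr, rows - 1) + 1; ci <- pmin(c0 + dc, cols - 1) + 1
      delta <- amp * w
      keep <- delta > 0
      if (any(keep)) {
        lin <- (ci[keep] - 1) * rows + ri[keep]
        add <- rowsum(delta[keep], lin)
        img[as.integer(rownames(add))] <- img[as.integer(rownames(add))] + add[, 1]
      }
    }
    ## populations share one nuclear radius, so a single blur suffices
    sigma_px <- sqrt(cam$psf_sigma^2 + cells$radius[1]^2) / cam$pixel_size
    img <- EBImage::gblur(img, sigma = sigma_px)
    ## peak of a unit-integral Gaussian is 1/(2 pi sigma^2)
  }
  img <- img + cam$background
  if (cam$read_noise_sigma > 0)
    img <- img + matrix(rnorm(rows * cols, 0, cam$read_noise_sigma), rows, cols)
  img[img < 0] <- 0
  structure(list(pixels = img, position_name = position_name, channel = channel,
                 time = time, frame_index = as.integer(frame_index)),
            class = "frame")
}

#' Create a simulated microscope for one stage position
#'
#' Implements the microscope interface contract (`move_to`, `snap`,
#' `project`) plus `advance_to(t)`, which advances the agent dynamics on
#' the simulated clock under the currently projected pattern. A projected
#' pattern stays active until the next projection. The scope keeps a
#' ground-truth ledger: per-cell cumulative illumination time (`dose_s`)
#' and the true population state, for validation against measured data.
#'
#' @param population A `cell_population`.
#' @param cam [camera_model()].
#' @param motility [motility_params()].
#' @param photo [photochromic_params()].
#' @param seed Integer seed for this scope's private random stream.
#' @param boundary `"reflect"` or `"wrap"`.
#' @param dt_max Largest internal integration step (s).
#' @param position_name Name stamped on produced frames.
#' @return A `simulated_scope` environment with functions `move_to(pos)`,
#'   `snap(channel, exposure_ms)`, `project(pattern, duration_ms)`,
#'   `advance_to(t)`, and fields `population`, `dose_s`, `time`.
#' @export
simulated_scope <- function(population, cam = camera_model(),
                            motility = motility_params(),
                            photo = photochromic_params(),
                            seed = 1, boundary = "reflect", dt_max = 60,
                            position_name = "") {
  self <- new.env(parent = emptyenv())
  self$population <- population
  self$cam <- cam
  self$motility <- motility
  self$photo <- photo
  self$boundary <- boundary
  self$dt_max <- dt_max
  self$position_name <- position_name
  self$time <- 0
  self$frame_count <- 0L
  self$dose_s <- setNames(rep(0, nrow(population)), population$id)
  self$field <- matrix(0, cam$fov_shape[1], cam$fov_shape[2])
  self$sense <- prepare_sense_field(self$field, cam$pixel_size,
                                    motility$sense_sigma_um, boundary)
  self$stream <- rng_stream(seed)
  self$fov_um <- c(cam$fov_shape[2], cam$fov_shape[1]) * cam$pixel_size

  self$advance_to <- function(t) {
    if (t < self$time) stop("simulated clock cannot run backwards")
    while (self$time < t - 1e-9) {
      dt <- min(self$dt_max, t - self$time)
      with_stream(self$stream, {
        self$population <- step_dynamics(self$population, self$sense, dt,
                                         self$motility, self$photo,
                                         self$cam$pixel_size, self$fov_um,
                                         self$boundary)
      })
      lit <- attr(self$population, "lit")
      if (!is.null(lit)) self$dose_s <- self$dose_s + lit * dt
      self$time <- self$time + dt
    }
    invisible(self$time)
  }
  self$move_to <- function(pos) invisible(NULL)
  self$snap <- function(channel, exposure_ms = 50) {
    self$frame_count <- self$frame_count + 1L
    with_stream(self$stream,
      render_image(self$population, channel, self$cam, time = self$time,
                   frame_index = self$frame_count,
                   position_name = self$position_name))
  }
  self$project <- function(pattern, duration_ms = NULL) {
    intensity <- if (inherits(pattern, "stimulus_pattern")) pattern$intensity else pattern
    if (!all(dim(intensity) == self$cam$fov_shape))
      stop("pattern shape does not match the FOV")
    self$field <- intensity
    self$sense <- prepare_sense_field(intensity, self$cam$pixel_size,
                                      self$motility$sense_sigma_um, self$boundary)
    invisible(NULL)
  }
  class(self) <- "simulated_scope"
  self
}
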