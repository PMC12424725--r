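## Stimulus pattern generation: traveling bar waves and their phase,
## Voronoi cell territories, per-cell tangential ("vortex") gradients,
## bang-bang feedback patterns, constant regions, and the pattern manager
## that serves the currently valid pattern to the microscope side.

#' Construct a stimulus pattern object
#'
#' A stimulus pattern is a 2-D illumination intensity map in `[0, 1]`
#' stamped with the time from which it is valid.
#'
#' @param intensity Matrix in `[0, 1]`, `[row, col] = [y, x]`.
#' @param valid_from Experiment-clock time (s) from which the pattern applies.
#' @param position_name Stage position the pattern belongs to.
#' @param provenance Free-form list (module name, source frame time).
#' @return A `stimulus_pattern`.
#' @export
stimulus_pattern <- function(intensity, valid_from = 0, position_name = "",
                             provenance = list()) {
  if (any(intensity < 0) || any(intensity > 1)) stop("pattern intensities must lie in [0, 1]")
  structure(list(intensity = intensity, valid_from = valid_from,
                 position_name = position_name, provenance = provenance),
            class = "stimulus_pattern")
}

#' Bar-wave parameters
#'
#' @param period_um Spatial period between successive bars (um), > 0.
#' @param speed_um_per_h Signed wave speed (um/h); positive waves travel
#'   toward increasing y (downward in display orientation).
#' @param duty Illuminated fraction of each period, in (0, 1].
#' @param offset_um Phase offset y0 (um): at t = 0 the illuminated band of
#'   the reference bar starts at y = y0.
#' @return A `bar_wave_params` list.
#' @export
bar_wave_params <- function(period_um = 32, speed_um_per_h = 12, duty = 0.75,
                            offset_um = 0) {
  stopifnot(period_um > 0, duty > 0, duty <= 1)
  structure(list(period_um = period_um, speed_um_per_h = speed_um_per_h,
                 duty = duty, offset_um = offset_um), class = "bar_wave_params")
}

#' Traveling horizontal bar pattern
#'
#' Rows whose physical coordinate y (um) satisfies
#' `wrap(y - y0 - v t, P) < d P` are fully illuminated; the pattern is
#' constant along x and binary.
#'
#' @param p [bar_wave_params()].
#' @param t Time (s), >= 0.
#' @param pixel_size Pixel size (um/px).
#' @param fov_shape `(rows, cols)` in pixels.
#' @return A `stimulus_pattern`.
#' @export
bar_wave_pattern <- function(p, t, pixel_size, fov_shape) {
  rows <- fov_shape[1]; cols <- fov_shape[2]
  y <- (seq_len(rows) - 0.5) * pixel_size
  a <- (y - p$offset_um - p$speed_um_per_h * t / 3600) %% p$period_um
  lit <- as.numeric(a < p$duty * p$period_um)
  stimulus_pattern(matrix(lit, nrow = rows, ncol = cols),
                   valid_from = t,
                   provenance = list(module = "bars", t = t))
}

#' Wave phase at a position
#'
#' The signed fractional offset of position y from the nearest bar centre,
#' in cycles, in `[-0.5, 0.5)`. Phase 0 means the light bar is centred on
#' the position; positive phase means the position lies ahead of the bar
#' centre along +y (the direction of travel for positive speeds). A pixel
#' is illuminated exactly when its phase lies in `[-duty/2, duty/2)`.
#'
#' @param y Position(s) (um).
#' @param t Time (s).
#' @param p [bar_wave_params()].
#' @return Phase(s) in cycles, `[-0.5, 0.5)`.
#' @export
wave_phase <- function(y, t, p) {
  centre <- p$offset_um + p$speed_um_per_h * t / 3600 + p$duty * p$period_um / 2
  ((y - centre) / p$period_um + 0.5) %% 1 - 0.5
}

#' Voronoi assignment of the field of view to cell centroids
#'
#' Every pixel is assigned the label of the nearest centroid (Euclidean
#' distance between pixel centres and centroids); ties go to the smaller
#' label. The partition covers the full field of view.
#'
#' @param centroids Data.frame with columns `label`, `x`, `y`
#'   (0-based pixel-centre coordinates).
#' @param fov_shape `(rows, cols)`.
#' @return A `label_mask` whose labels partition the FOV.
#' @export
voronoi_assign <- function(centroids, fov_shape) {
  if (is.null(centroids) || nrow(centroids) == 0L)
    stop("voronoi_assign needs at least one centroid")
  if (anyDuplicated(centroids$label)) stop("centroid labels must be unique")
  ord <- order(centroids$label)
  cx <- centroids$x[ord]; cy <- centroids$y[ord]; lab <- centroids$label[ord]
  rows <- fov_shape[1]; cols <- fov_shape[2]
  px <- rep(seq_len(cols) - 1, each = rows)   # x, 0-based, column-major
  py <- rep(seq_len(rows) - 1, times = cols)  # y
  ## squared distance to each centroid; seeds in ascending label order so
  ## that max.col(ties = "first") implements the smaller-label tie rule
  d2 <- outer(px, cx, function(a, b) (a - b)^2) + outer(py, cy, function(a, b) (a - b)^2)
  win <- max.col(-d2, ties.method = "first")
  label_mask(matrix(lab[win], nrow = rows, ncol = cols))
}

#' Vortex parameters
#'
#' @param center `(x, y)` in 0-based pixels, or NULL for the FOV centre.
#' @param max_intensity Peak intensity of each per-cell ramp, <= 1.
#' @param chirality `"ccw"` or `"cw"`, in display orientation.
#' @return A `vortex_params` list.
#' @export
vortex_params <- function(center = NULL, max_intensity = 1, chirality = "ccw") {
  stopifnot(max_intensity > 0, max_intensity <= 1, chirality %in% c("ccw", "cw"))
  structure(list(center = center, max_intensity = max_intensity,
                 chirality = chirality), class = "vortex_params")
}

#' Per-cell tangential gradient ("vortex") pattern
#'
#' Within each cell's Voronoi territory, intensity ramps linearly along the
#' tangential direction of that cell's centroid about the pattern centre,
#' so the brightest edge of every territory faces the direction of
#' intended motion. With y pointing down, the ccw tangent of radius vector
#' r is `(r_y, -r_x)/|r|`. A cell exactly at the centre receives a uniform
#' half-intensity field; a degenerate (single-pixel or zero-extent) region
#' receives uniform `max_intensity`.
#'
#' @param centroids Data.frame `label`, `x`, `y` (0-based px).
#' @param regions `label_mask` from [voronoi_assign()] over the same centroids.
#' @param p [vortex_params()].
#' @return A `stimulus_pattern`.
#' @export
vortex_gradient_pattern <- function(centroids, regions, p = vortex_params()) {
  lbl <- regions$labels
  rows <- nrow(lbl); cols <- ncol(lbl)
  ctr <- p$center %||% c((cols - 1) / 2, (rows - 1) / 2)
  out <- matrix(0, rows, cols)
  px <- rep(seq_len(cols) - 1, each = rows)
  py <- rep(seq_len(rows) - 1, times = cols)
  sgn <- if (p$chirality == "ccw") 1 else -1
  for (i in seq_len(nrow(centroids))) {
    sel <- lbl == centroids$label[i]
    if (!any(sel)) next
    rvec <- c(centroids$x[i] - ctr[1], centroids$y[i] - ctr[2])
    rn <- sqrt(sum(rvec^2))
    if (rn == 0) { out[sel] <- p$max_intensity / 2; next }
    that <- sgn * c(rvec[2], -rvec[1]) / rn
    proj <- px[sel] * that[1] + py[sel] * that[2]
    rng <- range(proj)
    out[sel] <- if (diff(rng) == 0) p$max_intensity else
      p$max_intensity * (proj - rng[1]) / diff(rng)
  }
  stimulus_pattern(out, provenance = list(module = "vortex"))
}

#' Bang-bang parameters
#'
#' @param setpoint Scalar set point (a.u.) or a 2-D set-point image the
#'   same shape as the FOV; per-cell set points are the image mean over
#'   the cell's mask pixels.
#' @param hysteresis_band Light is applied when a cell's mean intensity
#'   falls below `setpoint - hysteresis_band` (default 0: plain threshold).
#' @param channel Measurement channel name.
#' @return A `bang_bang_params` list.
#' @export
bang_bang_params <- function(setpoint, hysteresis_band = 0, channel = "fluor") {
  if (any(setpoint <= 0)) stop("set point must be > 0 everywhere")
  structure(list(setpoint = setpoint, hysteresis_band = hysteresis_band,
                 channel = channel), class = "bang_bang_params")
}

#' Bang-bang feedback pattern
#'
#' Thermostat rule per cell: if the cell's measured mean intensity is
#' below its set point (minus the hysteresis band), its entire mask region
#' is illuminated at full intensity; otherwise it is dark. Background
#' pixels are always dark, and the output is binary.
#'
#' @param observations [measure_cells()] output for `p$channel`.
#' @param mask The `label_mask` the observations were measured on.
#' @param p [bang_bang_params()].
#' @return A `stimulus_pattern`.
#' @export
bang_bang_pattern <- function(observations, mask, p) {
  lbl <- mask$labels
  out <- matrix(0, nrow(lbl), ncol(lbl))
  if (is.matrix(p$setpoint) &&
      !all(dim(p$setpoint) == dim(lbl))) stop("set-point image shape mismatch")
  if (nrow(observations) > 0L) {
    sp <- if (is.matrix(p$setpoint)) {
      vapply(observations$label, function(l) mean(p$setpoint[lbl == l]), 0)
    } else rep(p$setpoint, nrow(observations))
    lit <- observations$mean_intensity < sp - p$hysteresis_band
    lit_labels <- observations$label[lit]
    if (length(lit_labels)) out[lbl %in% lit_labels] <- 1
  }
  stimulus_pattern(out, provenance = list(module = "bangbang",
                                          frame_time = mask$frame_time))
}

#' Constant illumination pattern
#'
#' @param fov_shape `(rows, cols)`.
#' @param intensity Intensity in `[0, 1]`.
#' @param region `NULL` for the full FOV, or `c(x0, y0, x1, y1)` (0-based
#'   pixel corners, inclusive).
#' @return A `stimulus_pattern`.
#' @export
constant_pattern <- function(fov_shape, intensity = 1, region = NULL) {
  out <- matrix(0, fov_shape[1], fov_shape[2])
  if (is.null(region)) {
    out[] <- intensity
  } else if (length(region) == 4L && region[3] >= region[1] && region[4] >= region[2]) {
    r0 <- clamp(region[2] + 1, 1, fov_shape[1]); r1 <- clamp(region[4] + 1, 1, fov_shape[1])
    c0 <- clamp(region[1] + 1, 1, fov_shape[2]); c1 <- clamp(region[3] + 1, 1, fov_shape[2])
    out[r0:r1, c0:c1] <- intensity
  }
  stimulus_pattern(out, provenance = list(module = "constant"))
}

## ---------------------------------------------------------------------
## Pattern manager: stores submitted patterns per position and serves the
## one with the greatest valid_from <= t. Time-parametric modules (bars,
## constant) are evaluated at query time instead of replaying a stored
## frame. Before any pattern exists, an all-dark fallback is served.

#' Create a pattern manager
#'
#' @param fov_shape `(rows, cols)`, used for the all-dark fallback.
#' @param evaluator Optional function `(t) -> stimulus_pattern` for
#'   time-parametric modules; when set, [pattern_manager_current()]
#'   evaluates it instead of replaying stored patterns.
#' @return A `pattern_manager` environment.
#' @export
pattern_manager <- function(fov_shape, evaluator = NULL) {
  env <- new.env(parent = emptyenv())
  env$fov_shape <- fov_shape
  env$evaluator <- evaluator
  env$store <- list()
  class(env) <- "pattern_manager"
  env
}

#' Submit a pattern to the manager
#' @param pm A [pattern_manager()].
#' @param pattern A `stimulus_pattern`.
#' @export
pattern_manager_submit <- function(pm, pattern) {
  pm$store[[length(pm$store) + 1L]] <- pattern
  invisible(pm)
}

#' Retrieve the pattern currently valid at time t
#'
#' Returns the submitted pattern with the greatest `valid_from <= t`
#' (evaluating the module directly for time-parametric managers); all-dark
#' if nothing is available yet.
#'
#' @param pm A [pattern_manager()].
#' @param t Query time (s).
#' @return A `stimulus_pattern`.
#' @export
pattern_manager_current <- function(pm, t) {
  if (!is.null(pm$evaluator)) return(pm$evaluator(t))
  if (length(pm$store)) {
    vf <- vapply(pm$store, function(p) p$valid_from, 0)
    ok <- which(vf <= t)
    if (length(ok)) return(pm$store[[ok[which.max(vf[ok])]]])
  }
  stimulus_pattern(matrix(0, pm$fov_shape[1], pm$fov_shape[2]), valid_from = -Inf,
                   provenance = list(module = "fallback_dark"))
}
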