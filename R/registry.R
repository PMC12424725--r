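## The module registry maps pattern / segmentation module names (as they
## appear in position TOMLs) to factories. Registering additional modules
## never invalidates an existing plan (the registry only grows).

#' Create the default module registry
#'
#' Pattern modules: `bars` (traveling bar wave), `constant` (static
#' region), `vortex` (per-cell Voronoi tangential gradients; needs
#' segmentation) and `bangbang` (per-cell feedback control; needs
#' segmentation). Segmentation modules: `threshold` and
#' `cellpose_adapter`.
#'
#' @return A `module_registry` list with `pattern` and `segmentation`
#'   entries.
#' @export
module_registry <- function() {
  reg <- list(pattern = list(), segmentation = list())

  reg$pattern$bars <- list(
    needs_segmentation = FALSE,
    make = function(params, geom) {
      bp <- bar_wave_params(period_um = params$period_um %||% 32,
                            speed_um_per_h = params$speed_um_per_h %||% 12,
                            duty = params$duty %||% 0.75,
                            offset_um = params$offset_um %||% 0)
      list(evaluator = function(t) {
        pat <- bar_wave_pattern(bp, t, geom$pixel_size, geom$fov_shape)
        pat$position_name <- geom$position_name
        pat
      }, compute = NULL, params = bp)
    })

  reg$pattern$constant <- list(
    needs_segmentation = FALSE,
    make = function(params, geom) {
      pat <- constant_pattern(geom$fov_shape,
                              intensity = params$intensity %||% 1,
                              region = params$region)
      pat$position_name <- geom$position_name
      list(evaluator = function(t) { pat$valid_from <- t; pat },
           compute = NULL)
    })

  reg$pattern$vortex <- list(
    needs_segmentation = TRUE,
    make = function(params, geom) {
      vp <- vortex_params(center = params$center,
                          max_intensity = params$max_intensity %||% 1,
                          chirality = params$chirality %||% "ccw")
      list(evaluator = NULL, compute = function(ctx) {
        obs <- ctx$observations
        if (is.null(obs) || nrow(obs) == 0L) return(NULL)
        cent <- data.frame(label = obs$label, x = obs$x, y = obs$y)
        regions <- voronoi_assign(cent, geom$fov_shape)
        pat <- vortex_gradient_pattern(cent, regions, vp)
        pat$valid_from <- ctx$t
        pat$position_name <- geom$position_name
        pat$provenance$frame_time <- ctx$mask$frame_time
        pat
      })
    })

  reg$pattern$bangbang <- list(
    needs_segmentation = TRUE,
    make = function(params, geom) {
      sp <- params$setpoint
      if (!is.null(params$setpoint_image)) {
        sp <- if (is.matrix(params$setpoint_image)) params$setpoint_image
              else read_image_file(params$setpoint_image)
      }
      if (is.null(sp)) stop("bangbang needs 'setpoint' or 'setpoint_image'")
      bp <- bang_bang_params(sp, hysteresis_band = params$hysteresis %||% 0,
                             channel = params$channel %||% "fluor")
      list(evaluator = NULL, compute = function(ctx) {
        obs <- ctx$observations
        if (is.null(obs) || is.null(ctx$mask)) return(NULL)
        meas <- obs
        mcol <- paste0("mean_", bp$channel)
        if (mcol %in% names(meas)) meas$mean_intensity <- meas[[mcol]]
        pat <- bang_bang_pattern(meas, ctx$mask, bp)
        pat$valid_from <- ctx$t
        pat$position_name <- geom$position_name
        pat
      })
    })

  reg$segmentation$threshold <- list(adapter = external_segmenter_adapter)
  reg$segmentation$cellpose_adapter <- list(adapter = external_segmenter_adapter)
  structure(reg, class = "module_registry")
}

#' Register an additional pattern module
#'
#' @param registry A `module_registry`.
#' @param name Module name as used in position TOMLs.
#' @param needs_segmentation Does the module require masks?
#' @param make Factory `(params, geom) -> list(evaluator, compute)` where
#'   `geom` has `fov_shape`, `pixel_size`, `position_name`; `evaluator(t)`
#'   serves time-parametric patterns, `compute(ctx)` closed-loop ones.
#' @return The extended registry.
#' @export
register_pattern_module <- function(registry, name, make, needs_segmentation = FALSE) {
  registry$pattern[[name]] <- list(needs_segmentation = needs_segmentation, make = make)
  registry
}

## Read a grayscale set-point image from TIFF or PNG.
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
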