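## Nuclear segmentation and per-cell measurement. The built-in segmenter
## (Gaussian smoothing -> Otsu threshold -> 8-connected labelling -> area
## filter) is deterministic and weight-free; an adapter slot matches the
## signature for external learned segmenters.

#' Construct a label mask
#'
#' @param labels Integer matrix; 0 = background, 1..n = cells.
#' @param frame_time Acquisition time (s) of the source frame.
#' @param position_name Stage position.
#' @return A `label_mask`.
#' @export
label_mask <- function(labels, frame_time = NA_real_, position_name = "") {
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  structure(list(labels = labels, frame_time = frame_time,
                 position_name = position_name), class = "label_mask")
}

## 8-connected labelling: EBImage's bwlabel is 4-connected, so components
## that touch only diagonally are merged afterwards with a union-find pass
## over the (small) label adjacency set. Labels are renumbered 1..n in
## raster order (row-major) of each component's first pixel.
label_components8 <- function(binary) {
  lb <- EBImage::bwlabel(binary)
  lb <- matrix(as.integer(round(lb)), nrow(binary), ncol(binary))
  n <- max(lb)
  if (n > 1L) {
    nr <- nrow(lb); nc <- ncol(lb)
    a <- lb[-nr, -nc]; b <- lb[-1, -1]    # diagonal down-right
    c1 <- lb[-nr, -1]; d <- lb[-1, -nc]   # diagonal down-left
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(c1), as.vector(d)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), find, 0L)
      lb[lb > 0] <- roots[lb[lb > 0]]
    }
  }
  renumber_raster(lb)
}

## Renumber positive labels 1..n by row-major order of first occurrence.
renumber_raster <- function(lb) {
  pos <- which(t(lb) > 0)               # row-major scan
  if (!length(pos)) return(lb)
  vals <- t(lb)[pos]
  first <- vals[!duplicated(vals)]
  map <- integer(max(lb))
  map[first] <- seq_along(first)
  lb[lb > 0] <- map[lb[lb > 0]]
  lb
}

#' Threshold-based nuclear segmentation
#'
#' Pipeline: Gaussian smoothing, Otsu global threshold, 8-connected
#' component labelling, removal of components outside `[min_area,
#' max_area]`, and renumbering 1..n in raster order. A constant or empty
#' frame yields an empty mask rather than an error.
#'
#' @param frame A `frame` (see [render_image()]) or a plain matrix.
#' @param smooth_sigma Smoothing sigma in pixels.
#' @param min_area,max_area Component area bounds (px).
#' @return A `label_mask`.
#' @export
segment_nuclei_threshold <- function(frame, smooth_sigma = 2,
                                     min_area = 9, max_area = Inf) {
  px <- if (inherits(frame, "frame")) frame$pixels else frame
  ft <- if (inherits(frame, "frame")) frame$time else NA_real_
  pn <- if (inherits(frame, "frame")) frame$position_name else ""
  sm <- if (smooth_sigma > 0) EBImage::gblur(px, sigma = smooth_sigma) else px
  rng <- range(sm)
  if (diff(rng) == 0)
    return(label_mask(matrix(0L, nrow(px), ncol(px)), ft, pn))
  norm <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lb <- label_components8(norm > th)
  if (max(lb) > 0L) {
    areas <- tabulate(lb[lb > 0], nbins = max(lb))
    bad <- which(areas < min_area | areas > max_area)
    if (length(bad)) lb[lb %in% bad] <- 0L
    lb <- renumber_raster(lb)
  }
  label_mask(lb, ft, pn)
}

#' Measure per-cell geometry and intensity
#'
#' For each label: pixel area, intensity-unweighted centroid in 0-based
#' `(x, y) = (col, row)` pixel units, and the mean pixel intensity in each
#' supplied channel frame. Also reports the median intensity of background
#' pixels per channel (`background_<channel>`), the standard estimate used
#' for background subtraction.
#'
#' @param frames A single `frame`/matrix or a named list of them
#'   (names = channels).
#' @param mask A `label_mask` of the same shape.
#' @return Data.frame sorted by label: `label`, `x`, `y`, `area`,
#'   `mean_<channel>` and `background_<channel>` columns, plus
#'   `mean_intensity` duplicating the first channel for convenience.
#' @export
measure_cells <- function(frames, mask) {
  if (inherits(frames, "frame") || is.matrix(frames)) frames <- list(intensity = frames)
  lbl <- mask$labels
  mats <- lapply(frames, function(f) if (inherits(f, "frame")) f$pixels else f)
  for (m in mats) if (!all(dim(m) == dim(lbl))) stop("frame/mask shape mismatch")
  n <- max(lbl)
  if (n == 0L) {
    out <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0))
    for (ch in names(mats)) { out[[paste0("mean_", ch)]] <- numeric(0) }
    out$mean_intensity <- numeric(0)
    return(out)
  }
  idx <- which(lbl > 0)
  l <- lbl[idx]
  rows <- ((idx - 1) %% nrow(lbl)) + 1
  cols <- ((idx - 1) %/% nrow(lbl)) + 1
  area <- tabulate(l, nbins = n)
  sx <- tapply(cols - 1, l, sum); sy <- tapply(rows - 1, l, sum)
  keep <- which(area > 0)
  out <- data.frame(label = keep,
                    x = as.numeric(sx[as.character(keep)]) / area[keep],
                    y = as.numeric(sy[as.character(keep)]) / area[keep],
                    area = area[keep])
  for (ch in names(mats)) {
    s <- tapply(mats[[ch]][idx], l, sum)
    out[[paste0("mean_", ch)]] <- as.numeric(s[as.character(keep)]) / area[keep]
    bgpx <- mats[[ch]][lbl == 0L]
    out[[paste0("background_", ch)]] <- if (length(bgpx)) median(bgpx) else 0
  }
  out$mean_intensity <- out[[paste0("mean_", names(mats)[1])]]
  out[order(out$label), , drop = FALSE]
}

#' Resolve a segmentation module specification to a segmenter function
#'
#' `"threshold"` returns the built-in segmenter with the spec's parameters
#' bound. `"cellpose_adapter"` checks at plan-build time that an external
#' backend is available and fails with a capability error otherwise (no
#' model weights ship with this package). `"none"` returns NULL.
#'
#' @param spec List with `module` and `params` (see
#'   [parse_position_config()]).
#' @return A function `(frame) -> label_mask`, or NULL for `"none"`.
#' @export
external_segmenter_adapter <- function(spec) {
  mod <- spec$module %||% "threshold"
  pars <- spec$params %||% list()
  if (mod == "none") return(NULL)
  if (mod == "threshold") {
    return(function(frame) segment_nuclei_threshold(
      frame,
      smooth_sigma = pars$smooth_sigma %||% 2,
      min_area = pars$min_area %||% 9,
      max_area = pars$max_area %||% Inf))
  }
  if (mod == "cellpose_adapter") {
    backend <- pars$backend %||% "cellpose"
    runner <- getOption("loopscope.cellpose_backend", NULL)
    if (is.null(runner))
      stop(sprintf(paste0("segmentation backend '%s' is not available: install it and ",
                          "register a runner via options(loopscope.cellpose_backend=...)"),
                   backend), call. = FALSE)
    return(function(frame) {
      px <- if (inherits(frame, "frame")) frame$pixels else frame
      lb <- runner(px, pars)   # parameter table passed through verbatim
      label_mask(lb, if (inherits(frame, "frame")) frame$time else NA_real_,
                 if (inherits(frame, "frame")) frame$position_name else "")
    })
  }
  stop(sprintf("unknown segmentation module '%s'", mod), call. = FALSE)
}
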