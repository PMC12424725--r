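## Post-hoc quantification: greedy mutual-nearest-neighbour track linking,
## finite-difference velocities, wave-phase binning, phase-aligned traces,
## polar decomposition with radial profiles, and coefficient-of-variation
## time courses.

#' Link per-frame detections into tracks
#'
#' Consecutive frames are linked by mutual nearest neighbours within
#' `max_link_distance` (matches taken in ascending distance order); every
#' unmatched detection starts a new track, and no detection is used
#' twice. Cells are not tracked during the live loop, so this runs on the
#' recorded centroid tables.
#'
#' @param detections Data.frame with columns `time`, `x`, `y` (um) and
#'   any extra columns to carry along (e.g. `mean_intensity`).
#' @param max_link_distance Gate distance (um) per frame step.
#' @return The detections with a `track_id` column, ordered by track and
#'   time.
#' @export
link_tracks <- function(detections, max_link_distance = 10) {
  d <- detections[order(detections$time), , drop = FALSE]
  times <- sort(unique(d$time))
  d$track_id <- NA_integer_
  next_id <- 1L
  prev_idx <- which(d$time == times[1])
  d$track_id[prev_idx] <- seq_len(length(prev_idx))
  next_id <- length(prev_idx) + 1L
  if (length(times) > 1) for (k in 2:length(times)) {
    cur_idx <- which(d$time == times[k])
    if (!length(cur_idx)) next
    if (length(prev_idx)) {
      dx <- outer(d$x[prev_idx], d$x[cur_idx], "-")
      dy <- outer(d$y[prev_idx], d$y[cur_idx], "-")
      dist <- sqrt(dx^2 + dy^2)
      nn_fwd <- apply(dist, 1, which.min)
      nn_bwd <- apply(dist, 2, which.min)
      cand <- which(nn_bwd[nn_fwd[seq_along(prev_idx)]] == seq_along(prev_idx))
      cand_d <- dist[cbind(cand, nn_fwd[cand])]
      ok <- cand[cand_d <= max_link_distance]
      ok <- ok[order(dist[cbind(ok, nn_fwd[ok])])]
      for (i in ok) d$track_id[cur_idx[nn_fwd[i]]] <- d$track_id[prev_idx[i]]
    }
    new <- cur_idx[is.na(d$track_id[cur_idx])]
    if (length(new)) {
      d$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  d[order(d$track_id, d$time), , drop = FALSE]
}

#' Finite-difference velocities along tracks
#'
#' Central differences at interior samples, forward/backward at track
#' ends, converted to um/h; optional boxcar smoothing of the velocity
#' series.
#'
#' @param tracks Output of [link_tracks()] (needs `track_id`, `time`,
#'   `x`, `y`).
#' @param smoothing_window Odd boxcar width in samples (1 = none).
#' @return Data.frame `track_id`, `time`, `x`, `y`, `vx`, `vy` (um/h);
#'   tracks of a single sample are dropped.
#' @export
frame_velocities <- function(tracks, smoothing_window = 1) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    tr <- tr[order(tr$time), ]
    diffv <- function(z) {
      dz <- numeric(n)
      if (n == 2) {
        dz[] <- (z[2] - z[1]) / (tr$time[2] - tr$time[1])
      } else {
        dz[1] <- (z[2] - z[1]) / (tr$time[2] - tr$time[1])
        dz[n] <- (z[n] - z[n - 1]) / (tr$time[n] - tr$time[n - 1])
        dz[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (tr$time[3:n] - tr$time[1:(n - 2)])
      }
      dz * 3600
    }
    vx <- diffv(tr$x); vy <- diffv(tr$y)
    if (smoothing_window > 1) {
      k <- rep(1 / smoothing_window, smoothing_window)
      pad <- function(v) as.numeric(stats::filter(v, k, sides = 2))
      sx <- pad(vx); sy <- pad(vy)
      vx <- ifelse(is.na(sx), vx, sx); vy <- ifelse(is.na(sy), vy, sy)
    }
    data.frame(track_id = tr$track_id, time = tr$time, x = tr$x, y = tr$y,
               vx = vx, vy = vy)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Velocity binned by traveling-wave phase
#'
#' Annotates each velocity sample with the wave phase at its (y, t) and
#' averages the velocity component along the wave axis (signed along the
#' direction of wave travel) in phase bins partitioning `[-0.5, 0.5)`.
#' With a `replicate` column, bin means are computed per replicate and
#' the spread reported is the SD across replicate means. Bins with fewer
#' than `min_count` samples are reported as missing (`NA` mean) — their
#' counts are still returned.
#'
#' @param samples [frame_velocities()] output (plus optional `replicate`).
#' @param p [bar_wave_params()] of the stimulus.
#' @param n_bins Number of phase bins.
#' @param min_count Minimum samples for a bin estimate.
#' @return Data.frame `bin`, `phase_mid`, `mean_v`, `sd_v`, `n`.
#' @export
velocity_vs_phase <- function(samples, p, n_bins = 20, min_count = 20) {
  sgn <- if (p$speed_um_per_h < 0) -1 else 1
  ph <- wave_phase(samples$y, samples$time, p)
  v <- samples$vy * sgn
  edges <- seq(-0.5, 0.5, length.out = n_bins + 1)
  bin <- findInterval(ph, edges, rightmost.closed = FALSE, all.inside = TRUE)
  n <- tabulate(bin, nbins = n_bins)
  if (!is.null(samples$replicate)) {
    rep_means <- tapply(v, list(bin = factor(bin, levels = 1:n_bins),
                                rep = samples$replicate), mean)
    mean_v <- rowMeans(rep_means, na.rm = TRUE)
    sd_v <- apply(rep_means, 1, sd, na.rm = TRUE)
  } else {
    mean_v <- as.numeric(tapply(v, factor(bin, levels = 1:n_bins), mean))
    sd_v <- as.numeric(tapply(v, factor(bin, levels = 1:n_bins), sd))
  }
  mean_v[n < min_count] <- NA
  sd_v[n < min_count] <- NA
  data.frame(bin = 1:n_bins, phase_mid = (edges[-1] + edges[-length(edges)]) / 2,
             mean_v = mean_v, sd_v = sd_v, n = n)
}

#' Phase-aligned single-cell displacement traces
#'
#' For each track, t0 is the first time its wave phase crosses zero
#' (linear interpolation between frames); displacement along the wave
#' axis is measured relative to the track's position at t0. Tracks that
#' never cross zero phase are excluded and counted.
#'
#' @param tracks [link_tracks()] output.
#' @param p [bar_wave_params()].
#' @return List: `traces` (`track_id`, `t_rel`, `disp`), `mean_trace`
#'   (`t_rel`, `disp`, `n` on the common frame grid), `n_excluded`.
#' @export
phase_aligned_traces <- function(tracks, p) {
  sgn <- if (p$speed_um_per_h < 0) -1 else 1
  excluded <- 0L
  traces <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$time), ]
    if (nrow(tr) < 2) { excluded <<- excluded + 1L; return(NULL) }
    ph <- wave_phase(tr$y, tr$time, p)
    k <- which(ph[-length(ph)] <= 0 & ph[-1] > 0 &
                 (ph[-1] - ph[-length(ph)]) < 0.5)
    if (!length(k)) {
      k0 <- which(ph == 0)
      if (!length(k0)) { excluded <<- excluded + 1L; return(NULL) }
      t0 <- tr$time[k0[1]]
      y0 <- tr$y[k0[1]]
    } else {
      i <- k[1]
      f <- -ph[i] / (ph[i + 1] - ph[i])
      t0 <- tr$time[i] + f * (tr$time[i + 1] - tr$time[i])
      y0 <- tr$y[i] + f * (tr$y[i + 1] - tr$y[i])
    }
    data.frame(track_id = tr$track_id[1], t_rel = tr$time - t0,
               disp = (tr$y - y0) * sgn)
  })
  traces <- do.call(rbind, traces)
  mean_trace <- NULL
  if (!is.null(traces)) {
    rounded <- round(traces$t_rel)
    mean_trace <- aggregate(traces["disp"], list(t_rel = rounded), mean)
    mean_trace$n <- as.numeric(table(rounded))
  }
  list(traces = traces, mean_trace = mean_trace, n_excluded = excluded)
}

#' Decompose velocities into radial and tangential components
#'
#' `v_radial` is positive outward from the centre; `v_tangential` is
#' positive along the counter-clockwise tangent (display orientation,
#' same chirality convention as the vortex pattern). Speed is preserved:
#' `v_radial^2 + v_tangential^2 = vx^2 + vy^2`. Samples exactly at the
#' centre get zero components by convention.
#'
#' @param samples [frame_velocities()] output.
#' @param center `(x, y)` centre (um).
#' @return `samples` with `r`, `v_radial`, `v_tangential` columns added.
#' @export
polar_decompose <- function(samples, center) {
  rx <- samples$x - center[1]; ry <- samples$y - center[2]
  r <- sqrt(rx^2 + ry^2)
  safe <- ifelse(r > 0, r, 1)
  ux <- rx / safe; uy <- ry / safe
  samples$r <- r
  samples$v_radial <- ifelse(r > 0, samples$vx * ux + samples$vy * uy, 0)
  ## ccw tangent in row-down coordinates: (r_y, -r_x)/|r|
  samples$v_tangential <- ifelse(r > 0, samples$vx * uy - samples$vy * ux, 0)
  samples
}

#' Radial profile of tangential motion
#'
#' Equal-width rings from the centre out to `max_radius`; per-ring mean
#' tangential velocity and angular velocity `omega = v_tangential / r`.
#'
#' @param samples [polar_decompose()] output.
#' @param n_rings Number of rings.
#' @param max_radius Outer radius (um); default: the largest sample radius.
#' @return Data.frame `ring`, `r_mid`, `mean_v_tangential`, `mean_omega`,
#'   `n`, `empty`.
#' @export
radial_profile <- function(samples, n_rings = 8, max_radius = NULL) {
  if (is.null(max_radius)) max_radius <- max(samples$r)
  edges <- seq(0, max_radius, length.out = n_rings + 1)
  ring <- findInterval(samples$r, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n <- tabulate(ring, nbins = n_rings)
  f <- factor(ring, levels = 1:n_rings)
  vt <- as.numeric(tapply(samples$v_tangential, f, mean))
  om <- as.numeric(tapply(ifelse(samples$r > 0, samples$v_tangential / samples$r, NA),
                          f, mean, na.rm = TRUE))
  data.frame(ring = 1:n_rings, r_mid = (edges[-1] + edges[-(n_rings + 1)]) / 2,
             mean_v_tangential = vt, mean_omega = om, n = n, empty = n == 0)
}

#' Coefficient-of-variation time course
#'
#' CV(t) = SD/mean of the per-cell mean intensities at each frame time,
#' per condition, with the per-frame background estimate subtracted when
#' available. Reports the fold reduction CV(first)/CV(t). A zero mean is
#' flagged undefined.
#'
#' @param cells A per-cell table (`time_s`, `mean_intensity`, optional
#'   `background` and `condition` columns).
#' @param background_subtract Subtract the `background` column first.
#' @return Data.frame `condition`, `time_s`, `n`, `mean`, `sd`, `cv`,
#'   `fold_reduction`.
#' @export
intensity_cv_timecourse <- function(cells, background_subtract = TRUE) {
  v <- cells$mean_intensity
  if (background_subtract && !is.null(cells$background)) v <- v - cells$background
  cond <- cells$condition %||% rep("all", nrow(cells))
  out <- do.call(rbind, lapply(split(seq_along(v), list(cond, cells$time_s), drop = TRUE),
    function(ix) {
      m <- mean(v[ix])
      ## population (n-divisor) SD: the CV of the cells actually present
      s <- sqrt(mean((v[ix] - m)^2))
      data.frame(condition = cond[ix[1]], time_s = cells$time_s[ix[1]],
                 n = length(ix), mean = m, sd = s,
                 cv = if (abs(m) > .Machine$double.eps) s / m else NA_real_)
    }))
  out <- out[order(out$condition, out$time_s), ]
  out$fold_reduction <- stats::ave(out$cv, out$condition,
                                   FUN = function(z) z[1] / z)
  rownames(out) <- NULL
  out
}

#' Histograms of per-cell intensities at selected times
#'
#' @param cells Per-cell table as in [intensity_cv_timecourse()].
#' @param times Frame times (s) to tabulate.
#' @param breaks Bin edges (a.u.).
#' @param background_subtract Subtract the `background` column first.
#' @return Data.frame `time_s`, `bin_lo`, `bin_hi`, `count`.
#' @export
intensity_histograms <- function(cells, times, breaks, background_subtract = TRUE) {
  v <- cells$mean_intensity
  if (background_subtract && !is.null(cells$background)) v <- v - cells$background
  out <- lapply(times, function(tt) {
    vv <- v[cells$time_s == tt]
    h <- hist(vv, breaks = breaks, plot = FALSE)
    data.frame(time_s = tt, bin_lo = head(breaks, -1), bin_hi = breaks[-1],
               count = h$counts)
  })
  do.call(rbind, out)
}
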