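## The master scheduler: builds the event timeline for a plan, runs the
## closed loop over a (simulated) microscope, persists artifacts through
## the outbox, and replays records to verify the closed-loop ordering
## contract.

KIND_PRIORITY <- c(stimulate = 1, image = 2, segment = 3, compute_pattern = 4)

#' Generate the event timeline for an experiment plan
#'
#' For every position: `image` events at each multiple of the imaging
#' interval and `stimulate` events at each multiple of the stimulation
#' interval, from t = 0 through the experiment length inclusive. Each
#' image event is followed (same timestamp) by a `segment` event when the
#' position configures segmentation and a `compute_pattern` event when
#' its pattern module is closed-loop. Events are sorted by time, ties
#' broken by kind priority (stimulate < image < segment <
#' compute_pattern) then position order — except at t = 0, where
#' positions with closed-loop patterns image (and segment) before the
#' first stimulate so the first feedback pattern can derive from a mask.
#'
#' @param plan An `experiment_plan`.
#' @return Data.frame `time`, `position_name`, `kind`, `sequence_index`.
#' @export
generate_event_timeline <- function(plan) {
  sch <- plan$schedule
  out <- list()
  for (i in seq_len(nrow(plan$positions))) {
    pos <- plan$positions$name[i]
    cf <- plan$configs[[i]]
    closed_loop <- is_closed_loop(plan$registry, cf)
    tim <- seq(0, sch$experiment_length_s, by = sch$imaging_interval_s)
    tst <- seq(0, sch$experiment_length_s, by = sch$stimulation_interval_s)
    ev <- data.frame(time = tst, position_name = pos, kind = "stimulate")
    ev <- rbind(ev, data.frame(time = tim, position_name = pos, kind = "image"))
    if (cf$segmentation$module != "none")
      ev <- rbind(ev, data.frame(time = tim, position_name = pos, kind = "segment"))
    if (closed_loop)
      ev <- rbind(ev, data.frame(time = tim, position_name = pos, kind = "compute_pattern"))
    ev$pos_index <- i
    ev$closed_loop <- closed_loop
    out[[i]] <- ev
  }
  ev <- do.call(rbind, out)
  prio <- KIND_PRIORITY[ev$kind]
  ## closed-loop t=0: image/segment/compute precede the first stimulate
  prio[ev$time == 0 & ev$kind == "stimulate" & ev$closed_loop] <- 5
  ev <- ev[order(ev$time, prio, ev$pos_index), , drop = FALSE]
  ev$sequence_index <- stats::ave(seq_len(nrow(ev)),
                                  ev$position_name, ev$kind,
                                  FUN = seq_along)
  rownames(ev) <- NULL
  ev[, c("time", "position_name", "kind", "sequence_index")]
}

is_closed_loop <- function(registry, cf) {
  entry <- registry$pattern[[cf$pattern$module]]
  isTRUE(entry$needs_segmentation)
}

#' Deterministic outbox path for an artifact
#'
#' `<position>/images/<channel>/t<seconds, 6 digits>.tif` for frames,
#' `<position>/masks/t......tif` for masks,
#' `<position>/patterns/t......png` for patterns, and
#' `<position>/cells.csv` for the per-cell table.
#'
#' @param kind `"image"`, `"mask"`, `"pattern"` or `"cells"`.
#' @param position Position name.
#' @param time Experiment-clock time (s).
#' @param channel Channel (images only).
#' @return Relative path string.
#' @export
outbox_path <- function(kind, position, time = 0, channel = NULL) {
  switch(kind,
    image = sprintf("%s/images/%s/t%06d.tif", position, channel, round(time)),
    mask = sprintf("%s/masks/t%06d.tif", position, round(time)),
    pattern = sprintf("%s/patterns/t%06d.png", position, round(time)),
    cells = sprintf("%s/cells.csv", position),
    stop(sprintf("unknown artifact kind '%s'", kind)))
}

#' Persist one artifact through the outbox
#'
#' Images and masks are written as 16-bit TIFF, patterns as 8-bit PNG,
#' tables appended to CSV. Returns the artifact path.
#'
#' @param out_dir Output root (created if needed); NULL skips writing and
#'   just returns the path the artifact would get.
#' @param kind,position,time,channel As in [outbox_path()].
#' @param payload Matrix (image/mask/pattern) or data.frame (cells).
#' @return The relative artifact path.
#' @export
outbox_store <- function(out_dir, kind, position, payload, time = 0, channel = NULL) {
  rel <- outbox_path(kind, position, time, channel)
  if (is.null(out_dir)) return(rel)
  path <- file.path(out_dir, rel)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (kind %in% c("image", "mask")) {
    m <- pmin(pmax(payload / 65535, 0), 1)
    ok <- try(tiff::writeTIFF(t(m), path, bits.per.sample = 16L), silent = TRUE)
    if (inherits(ok, "try-error")) stop(sprintf("storage error writing %s", path))
  } else if (kind == "pattern") {
    png::writePNG(t(pmin(pmax(payload, 0), 1)), path)
  } else if (kind == "cells") {
    write.csv(payload, path, row.names = FALSE)
  }
  rel
}

#' Build simulated scopes for every position of a plan
#'
#' Simulator parameters come from each position TOML's `[simulate]` table
#' (`n_cells`, `cv`, `v0`, `alpha`, `tau_p_min`, `noise`, `sense_sigma_um`,
#' `k_fold`, `tau_on_s`, `tau_off_s`, `psf_sigma_um`, `background`,
#' `read_noise`, `radius_um`, `baseline_mean`, `arrangement`, `boundary`);
#' anything omitted uses the package defaults. Each scope draws from its
#' own random stream derived from the schedule seed and the position name.
#'
#' @param plan An `experiment_plan`.
#' @return Named list of [simulated_scope()] objects.
#' @export
build_simulated_scopes <- function(plan) {
  scopes <- list()
  for (i in seq_len(nrow(plan$positions))) {
    cf <- plan$configs[[i]]
    sim <- cf$simulate
    cam <- camera_model(pixel_size = cf$pixel_size_um, fov_shape = cf$fov_shape,
                        background = sim$background %||% 50,
                        read_noise_sigma = sim$read_noise %||% 2,
                        psf_sigma = sim$psf_sigma_um %||% 1)
    mot <- motility_params(v0 = sim$v0 %||% 20, alpha = sim$alpha %||% 47,
                           tau_p_min = sim$tau_p_min %||% 10,
                           noise_sigma = sim$noise %||% 0.2,
                           sense_sigma_um = sim$sense_sigma_um %||% 8)
    pho <- photochromic_params(fold_change = sim$k_fold %||% 4.5,
                               tau_on = sim$tau_on_s %||% 30,
                               tau_off = sim$tau_off_s %||% 120)
    seed <- derive_seed(plan$schedule$seed, plan$positions$name[i])
    fov_um <- c(cf$fov_shape[2], cf$fov_shape[1]) * cf$pixel_size_um
    pop <- init_population(n = sim$n_cells %||% 100, fov_um = fov_um,
                           heterogeneity_cv = sim$cv %||% 0.45, seed = seed,
                           arrangement = sim$arrangement %||% "uniform",
                           baseline_mean = sim$baseline_mean %||% 1000,
                           radius = sim$radius_um %||% 3)
    scopes[[plan$positions$name[i]]] <-
      simulated_scope(pop, cam, mot, pho, seed = derive_seed(seed, "scope"),
                      boundary = sim$boundary %||% "reflect",
                      position_name = plan$positions$name[i])
  }
  scopes
}

#' Run the closed loop
#'
#' Executes the plan's event timeline in order on the experiment clock.
#' Closed-loop ordering contract: the pattern projected at any stimulate
#' event at time t derives from the most recent completed segmentation
#' whose source frame time is <= t; stimulation cadence is never broken —
#' before the first computed pattern (or after a module failure) the
#' all-dark fallback or the most recent completed pattern is projected.
#' Any event failure is logged and the loop continues: one position's
#' failures never affect another position.
#'
#' @param plan An `experiment_plan`.
#' @param scopes Named list of microscope objects (one per position);
#'   NULL builds simulated scopes from the plan.
#' @param out_dir Output directory for artifacts, or NULL for in-memory
#'   only.
#' @param keep_masks Keep label masks in the returned record (memory!).
#' @return An `experiment_record`: `$events` log, `$cells` per-cell
#'   table, `$truth` per-position simulator ground truth (baselines,
#'   cumulative light dose), `$n_pattern_errors`, `$scopes`.
#' @export
run_loop <- function(plan, scopes = NULL, out_dir = NULL, keep_masks = FALSE) {
  if (is.null(scopes)) scopes <- build_simulated_scopes(plan)
  timeline <- generate_event_timeline(plan)
  npos <- nrow(plan$positions)
  state <- list()
  for (i in seq_len(npos)) {
    cf <- plan$configs[[i]]
    geom <- list(fov_shape = cf$fov_shape, pixel_size = cf$pixel_size_um,
                 position_name = cf$position_name)
    entry <- plan$registry$pattern[[cf$pattern$module]]
    inst <- entry$make(cf$pattern$params, geom)
    segfun <- external_segmenter_adapter(cf$segmentation)
    state[[cf$position_name]] <- list(
      cf = cf, geom = geom, inst = inst, segfun = segfun,
      pm = pattern_manager(cf$fov_shape, evaluator = inst$evaluator),
      frames = NULL, mask = NULL, obs = NULL, last_pattern = NULL,
      cells = list(), masks = list(), n_frames = 0L, n_patterns = 0L,
      n_errors = 0L)
  }
  ev_log <- vector("list", nrow(timeline))

  for (k in seq_len(nrow(timeline))) {
    ev <- timeline[k, ]
    pn <- ev$position_name
    st <- state[[pn]]
    scope <- scopes[[pn]]
    status <- "ok"; artifact <- ""; note <- ""
    src_time <- NA_real_
    res <- tryCatch({
      if (!is.null(scope$advance_to)) scope$advance_to(ev$time)
      scope$move_to(plan$positions[plan$positions$name == pn, ])
      if (ev$kind == "image") {
        frames <- list()
        for (ch in st$cf$channels) {
          fr <- scope$snap(ch$name, ch$exposure_ms %||% 50)
          fr$time <- ev$time
          frames[[ch$name]] <- fr
          artifact <- outbox_store(out_dir, "image", pn, fr$pixels,
                                   time = ev$time, channel = ch$name)
        }
        st$frames <- frames
        st$n_frames <- st$n_frames + 1L
      } else if (ev$kind == "segment") {
        if (!is.null(st$frames)) {
          seg_channel <- st$cf$segmentation$params$channel %||% "nuclear"
          frame <- st$frames[[seg_channel]] %||% st$frames[[1]]
          mask <- st$segfun(frame)
          obs <- measure_cells(st$frames, mask)
          st$mask <- mask
          st$obs <- obs
          src_time <- mask$frame_time
          if (keep_masks) st$masks[[length(st$masks) + 1L]] <- mask
          artifact <- outbox_store(out_dir, "mask", pn, mask$labels, time = ev$time)
          if (nrow(obs)) {
            stim_flag <- if (!is.null(st$last_pattern)) {
              as.integer(st$last_pattern$intensity[cbind(
                clamp(round(obs$y) + 1, 1, st$geom$fov_shape[1]),
                clamp(round(obs$x) + 1, 1, st$geom$fov_shape[2]))] > 0)
            } else 0L
            ## the logged intensity is the measurement channel: the
            ## pattern module's channel when it declares one, else the
            ## first configured channel
            mch <- st$cf$pattern$params$channel %||% st$cf$channels[[1]]$name
            mcol <- paste0("mean_", mch)
            bcol <- paste0("background_", mch)
            if (!mcol %in% names(obs)) {
              mcol <- "mean_intensity"
              bcol <- grep("^background_", names(obs), value = TRUE)[1]
            }
            st$cells[[length(st$cells) + 1L]] <- data.frame(
              time_s = ev$time, label = obs$label, x_px = obs$x, y_px = obs$y,
              area_px = obs$area, mean_intensity = obs[[mcol]],
              stimulated = stim_flag,
              background = if (!is.na(bcol) && bcol %in% names(obs)) obs[[bcol]] else 0,
              position = pn)
          }
        }
      } else if (ev$kind == "compute_pattern") {
        if (!is.null(st$inst$compute)) {
          pat <- st$inst$compute(list(observations = st$obs, mask = st$mask,
                                      t = ev$time, geom = st$geom))
          if (!is.null(pat)) {
            pattern_manager_submit(st$pm, pat)
            st$n_patterns <- st$n_patterns + 1L
            src_time <- pat$provenance$frame_time %||% NA_real_
            artifact <- outbox_store(out_dir, "pattern", pn, pat$intensity,
                                     time = ev$time)
          } else {
            status <- "no_input"
          }
        }
      } else if (ev$kind == "stimulate") {
        pat <- pattern_manager_current(st$pm, ev$time)
        scope$project(pat, duration_ms = plan$schedule$stimulation_interval_s * 1000)
        st$last_pattern <- pat
        src_time <- pat$provenance$frame_time %||% NA_real_
        note <- pat$provenance$module %||% ""
      }
      TRUE
    }, error = function(e) {
      status <<- "failed"; note <<- conditionMessage(e)
      st$n_errors <<- st$n_errors + 1L
      if (ev$kind %in% c("compute_pattern", "stimulate")) {
        ## fault isolation: stimulation cadence continues with the
        ## fallback (most recent completed pattern, else all-dark)
        if (ev$kind == "stimulate") {
          fb <- tryCatch(pattern_manager_current(st$pm, ev$time), error = function(e2) NULL)
          if (!is.null(fb)) try(scope$project(fb), silent = TRUE)
        }
      }
      FALSE
    })
    state[[pn]] <- st
    ev_log[[k]] <- data.frame(time_s = ev$time, position = pn, kind = ev$kind,
                              status = status, artifact = artifact,
                              source_frame_time = src_time, note = note)
  }

  events <- do.call(rbind, ev_log)
  cells <- do.call(rbind, unlist(lapply(state, function(s) s$cells),
                                 recursive = FALSE))
  truth <- lapply(state, function(s) {
    sc <- scopes[[s$cf$position_name]]
    if (inherits(sc, "simulated_scope"))
      list(population = sc$population, dose_s = sc$dose_s)
    else NULL
  })
  if (!is.null(out_dir)) {
    if (!is.null(cells)) {
      for (pn in names(state)) {
        pc <- cells[cells$position == pn, , drop = FALSE]
        if (nrow(pc)) outbox_store(out_dir, "cells", pn, pc)
      }
    }
    write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  }
  structure(list(
    events = events,
    cells = if (is.null(cells)) data.frame() else cells,
    truth = truth,
    n_frames = vapply(state, function(s) s$n_frames, 0L),
    n_patterns = vapply(state, function(s) s$n_patterns, 0L),
    n_errors = vapply(state, function(s) s$n_errors, 0L),
    masks = lapply(state, function(s) s$masks),
    plan = plan, scopes = scopes
  ), class = "experiment_record")
}

#' Replay-validate the closed-loop ordering contract
#'
#' Independently checks an [run_loop()] record: (1) every stimulate
#' event's pattern derives from a segmentation of a frame acquired at or
#' before the event time; (2) the stimulation cadence is unbroken — every
#' scheduled stimulate event executed (fallbacks count, failures do not
#' break later events); (3) event times are non-decreasing and
#' sequence indices strictly increase within (position, kind).
#'
#' @param record An `experiment_record`.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
validate_record <- function(record) {
  ev <- record$events
  problems <- character(0)
  stim <- ev[ev$kind == "stimulate", ]
  bad <- !is.na(stim$source_frame_time) & stim$source_frame_time > stim$time_s + 1e-9
  if (any(bad))
    problems <- c(problems, sprintf("%d stimulate event(s) use a pattern from the future", sum(bad)))
  sch <- record$plan$schedule
  expected <- length(seq(0, sch$experiment_length_s, by = sch$stimulation_interval_s))
  for (pn in unique(ev$position)) {
    ns <- sum(stim$position == pn)
    if (ns != expected)
      problems <- c(problems, sprintf("position %s: %d stimulate events, expected %d", pn, ns, expected))
  }
  for (pn in unique(ev$position)) for (kd in unique(ev$kind)) {
    tt <- ev$time_s[ev$position == pn & ev$kind == kd]
    if (is.unsorted(tt, strictly = TRUE))
      problems <- c(problems, sprintf("position %s kind %s: times not strictly increasing", pn, kd))
  }
  list(ok = length(problems) == 0L, problems = problems)
}
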