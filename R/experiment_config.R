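## Experiment configuration surface: a master schedule TOML, a multipoint
## stage-position list (XML or CSV), and one TOML per position describing
## the modules to run there. Everything is validated up front so that a
## plan that builds is a plan that runs.

cfg_error <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Parse a master schedule configuration
#'
#' The schedule TOML sets the overall experiment: total length, imaging
#' cadence and stimulation cadence (the two cadences are independent),
#' plus an output directory and a master seed.
#'
#' ```
#' [schedule]
#' length = "16h"
#' imaging_interval = "5min"
#' stimulation_interval = "1min"
#' output_dir = "results"
#' seed = 0
#' ```
#'
#' @param toml_text Schedule TOML text.
#' @return A `schedule_config` list with fields `experiment_length_s`,
#'   `imaging_interval_s`, `stimulation_interval_s`, `output_dir`, `seed`.
#' @export
parse_schedule <- function(toml_text) {
  cfg <- parse_toml(toml_text)
  sch <- cfg$schedule
  if (is.null(sch)) cfg_error("schedule TOML must contain a [schedule] table")
  known <- c("length", "imaging_interval", "stimulation_interval", "output_dir", "seed")
  extra <- setdiff(names(sch), known)
  if (length(extra)) warning(sprintf("unknown schedule keys ignored: %s", paste(extra, collapse = ", ")))
  need <- c("length", "imaging_interval", "stimulation_interval")
  for (k in need) if (is.null(sch[[k]])) cfg_error("schedule is missing required key '%s'", k)
  len <- parse_duration(sch$length)
  img <- parse_duration(sch$imaging_interval)
  stim <- parse_duration(sch$stimulation_interval)
  if (len < 0) cfg_error("'length' must be >= 0")
  if (img <= 0) cfg_error("'imaging_interval' must be > 0")
  if (stim <= 0) cfg_error("'stimulation_interval' must be > 0")
  structure(list(
    experiment_length_s = len,
    imaging_interval_s = img,
    stimulation_interval_s = stim,
    output_dir = sch$output_dir %||% "loopscope-out",
    seed = as.integer(sch$seed %||% 0)
  ), class = "schedule_config")
}

#' Serialize a schedule back to TOML text
#'
#' Inverse of [parse_schedule()]; `parse_schedule(serialize_schedule(x))`
#' reproduces `x`.
#'
#' @param sch A `schedule_config`.
#' @return TOML text (single string).
#' @export
serialize_schedule <- function(sch) {
  paste(toml_table("schedule", list(
    length = sch$experiment_length_s,
    imaging_interval = sch$imaging_interval_s,
    stimulation_interval = sch$stimulation_interval_s,
    output_dir = sch$output_dir,
    seed = sch$seed
  )), collapse = "\n")
}

#' Parse a multipoint stage-position list
#'
#' Accepts the XML dialect
#' `<positions><position name="A1" x="0" y="0" z="0"/></positions>`
#' (`z` optional) or, as a fallback, CSV text with a `name,x,y[,z]` header.
#' Coordinates are stage micrometres. Position order is preserved and
#' names must be unique.
#'
#' @param text XML or CSV text.
#' @return A data.frame with columns `name`, `x`, `y`, `z` (`z` may be NA).
#' @export
parse_multipoints <- function(text) {
  text_flat <- paste(text, collapse = "\n")
  if (grepl("^\\s*<", text_flat)) {
    doc <- xml2::read_xml(text_flat)
    nodes <- xml2::xml_find_all(doc, ".//position")
    pos <- data.frame(
      name = vapply(nodes, function(n) xml2::xml_attr(n, "name"), ""),
      x = vapply(nodes, function(n) xml2::xml_attr(n, "x"), ""),
      y = vapply(nodes, function(n) xml2::xml_attr(n, "y"), ""),
      z = vapply(nodes, function(n) xml2::xml_attr(n, "z") %||% NA_character_, ""),
      stringsAsFactors = FALSE
    )
  } else {
    pos <- read.csv(text = text_flat, stringsAsFactors = FALSE)
    if (!all(c("name", "x", "y") %in% names(pos)))
      cfg_error("multipoint CSV must have columns name,x,y[,z]")
    if (is.null(pos$z)) pos$z <- NA
    pos <- pos[, c("name", "x", "y", "z")]
    pos$name <- as.character(pos$name)
  }
  if (nrow(pos) == 0L)
    return(data.frame(name = character(0), x = numeric(0), y = numeric(0), z = numeric(0)))
  if (anyNA(pos$name) || any(pos$name == "")) cfg_error("every position needs a name")
  for (cc in c("x", "y", "z")) {
    raw <- pos[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    if (cc != "z" && anyNA(num)) cfg_error("non-numeric %s coordinate for position '%s'",
                                           cc, pos$name[which(is.na(num))[1]])
    pos[[cc]] <- num
  }
  dup <- pos$name[duplicated(pos$name)]
  if (length(dup)) cfg_error("duplicate position name(s): %s", paste(unique(dup), collapse = ", "))
  rownames(pos) <- NULL
  pos
}

#' Parse a per-position experiment configuration
#'
#' Each stage position carries its own TOML describing what happens there:
#'
#' ```
#' [position]
#' name = "A1"
#' pixel_size_um = 1.0
#' fov = [480, 480]
#' [segmentation]
#' module = "threshold"
#' [pattern]
#' module = "bars"
#' period_um = 32
#' [[channels]]
#' name = "nuclear"
#' exposure_ms = 50
#' ```
#'
#' `[segmentation]` may be omitted (or `module = "none"`) for open-loop
#' patterns. Unknown keys inside module parameter tables are passed
#' through to the module untouched.
#'
#' @param toml_text Per-position TOML text.
#' @return A `position_config` list.
#' @export
parse_position_config <- function(toml_text) {
  cfg <- parse_toml(toml_text)
  p <- cfg$position
  if (is.null(p) || is.null(p$name)) cfg_error("position TOML needs [position] with a 'name'")
  if (is.null(p$pixel_size_um) || p$pixel_size_um <= 0)
    cfg_error("position '%s': pixel_size_um must be > 0", p$name)
  fov <- p$fov %||% c(512, 512)
  if (length(fov) != 2L || any(fov < 1)) cfg_error("position '%s': fov must be [rows, cols]", p$name)
  pat <- cfg$pattern
  if (is.null(pat) || is.null(pat$module)) cfg_error("position '%s': [pattern] with 'module' required", p$name)
  seg <- cfg$segmentation
  seg_module <- if (is.null(seg) || is.null(seg$module)) "none" else seg$module
  channels <- cfg$channels %||% list(list(name = "nuclear", exposure_ms = 50))
  for (ch in channels) if (is.null(ch$name)) cfg_error("position '%s': channel without a name", p$name)
  structure(list(
    position_name = p$name,
    pixel_size_um = p$pixel_size_um,
    fov_shape = as.integer(round(fov)),
    pattern = list(module = pat$module, params = pat[setdiff(names(pat), "module")]),
    segmentation = list(module = seg_module,
                        params = if (is.null(seg)) list() else seg[setdiff(names(seg), "module")]),
    channels = channels,
    simulate = cfg$simulate %||% list()
  ), class = "position_config")
}

#' Assemble and validate a complete experiment plan
#'
#' Establishes the one-to-one link between stage positions and position
#' configurations, and resolves every pattern / segmentation module name
#' against the module registry. A pattern module that declares it needs
#' segmentation masks is rejected unless the position configures a
#' segmenter.
#'
#' @param schedule A `schedule_config` from [parse_schedule()].
#' @param positions Stage positions from [parse_multipoints()].
#' @param configs List of `position_config`s (order irrelevant).
#' @param registry A module registry, see [module_registry()].
#' @return An `experiment_plan`.
#' @export
build_experiment_plan <- function(schedule, positions, configs,
                                  registry = module_registry()) {
  if (!inherits(schedule, "schedule_config")) cfg_error("schedule must come from parse_schedule()")
  if (nrow(positions) == 0L) cfg_error("a plan needs at least one stage position")
  cfg_names <- vapply(configs, function(cf) cf$position_name, "")
  if (anyDuplicated(cfg_names)) cfg_error("more than one config for position '%s'",
                                          cfg_names[duplicated(cfg_names)][1])
  orphan <- setdiff(cfg_names, positions$name)
  if (length(orphan)) cfg_error("config references unknown position '%s'", orphan[1])
  missing_cfg <- setdiff(positions$name, cfg_names)
  if (length(missing_cfg)) cfg_error("no config for position(s): %s", paste(missing_cfg, collapse = ", "))
  configs <- configs[match(positions$name, cfg_names)]
  for (cf in configs) {
    pm <- registry$pattern[[cf$pattern$module]]
    if (is.null(pm)) cfg_error("position '%s': unknown pattern module '%s'",
                               cf$position_name, cf$pattern$module)
    if (cf$segmentation$module != "none" &&
        is.null(registry$segmentation[[cf$segmentation$module]]))
      cfg_error("position '%s': unknown segmentation module '%s'",
                cf$position_name, cf$segmentation$module)
    if (isTRUE(pm$needs_segmentation) && cf$segmentation$module == "none")
      cfg_error("position '%s': pattern module '%s' requires a segmentation module",
                cf$position_name, cf$pattern$module)
  }
  structure(list(schedule = schedule, positions = positions,
                 configs = configs, registry = registry),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("experiment_plan: %d position(s), length %.0f s (imaging %.0f s, stimulation %.0f s)\n",
              nrow(x$positions), x$schedule$experiment_length_s,
              x$schedule$imaging_interval_s, x$schedule$stimulation_interval_s))
  for (i in seq_len(nrow(x$positions))) {
    cf <- x$configs[[i]]
    cat(sprintf("  %-8s pattern=%s segmentation=%s fov=%dx%d @%.2f um/px\n",
                x$positions$name[i], cf$pattern$module, cf$segmentation$module,
                cf$fov_shape[1], cf$fov_shape[2], cf$pixel_size_um))
  }
  invisible(x)
}
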