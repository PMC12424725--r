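## Shared fixtures: the expensive simulated assays are run once per test
## session and cached for every test that needs them.

.assay_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.assay_cache[[key]])) .assay_cache[[key]] <- force(expr)
  .assay_cache[[key]]
}

get_wave_assay <- function() {
  cached("wave", simulate_wave_assay(speeds = c(8, 12, 25, 50), seed = 1))
}

get_feedback_assay <- function() {
  cached("feedback", simulate_feedback_assay(n_cells = 1000, seed = 1,
                                             n_steps = 40))
}

get_setpoint_image_assay <- function() {
  cached("setpoint", simulate_feedback_assay(n_cells = 1000, seed = 1,
                                             n_steps = 40,
                                             setpoint_image_levels = c(1.8, 2.6)))
}

## A tiny valid plan used by configuration and orchestrator tests.
tiny_plan <- function(n_pos = 1, length = "10min", imaging = "5min",
                      stimulation = "1min", pattern = "bars", fov = 64,
                      n_cells = 15, seed = 3, segmentation = TRUE) {
  sched <- parse_schedule(sprintf(
    "[schedule]\nlength = \"%s\"\nimaging_interval = \"%s\"\nstimulation_interval = \"%s\"\nseed = %d",
    length, imaging, stimulation, seed))
  names_ <- sprintf("P%02d", seq_len(n_pos))
  pos <- data.frame(name = names_, x = seq_len(n_pos) * 500, y = 0, z = NA)
  cfgs <- lapply(names_, function(nm)
    parse_position_config(position_toml(nm, pattern, fov, n_cells,
                                        segmentation)))
  build_experiment_plan(sched, pos, cfgs)
}

position_toml <- function(name, pattern = "bars", fov = 64, n_cells = 15,
                          segmentation = TRUE) {
  seg <- if (segmentation)
    "[segmentation]\nmodule = \"threshold\"\nmin_area = 9" else ""
  pat <- switch(pattern,
    bars = "[pattern]\nmodule = \"bars\"\nperiod_um = 32\nspeed_um_per_h = 12\nduty = 0.75",
    constant = "[pattern]\nmodule = \"constant\"\nintensity = 1.0",
    vortex = "[pattern]\nmodule = \"vortex\"",
    bangbang = "[pattern]\nmodule = \"bangbang\"\nsetpoint = 60",
    explode = "[pattern]\nmodule = \"explode\"")
  sprintf(paste(
    "[position]", "name = \"%s\"", "pixel_size_um = 1.0", "fov = [%d, %d]",
    "%s", "%s",
    "[simulate]", "n_cells = %d", "cv = 0.3",
    "[[channels]]", "name = \"nuclear\"", "exposure_ms = 50",
    "[[channels]]", "name = \"fluor\"", "exposure_ms = 100",
    sep = "\n"), name, fov, fov, seg, pat, n_cells)
}

## A registry with a deliberately failing closed-loop pattern module, for
## fault-isolation tests.
registry_with_bomb <- function() {
  register_pattern_module(module_registry(), "explode",
    make = function(params, geom)
      list(evaluator = NULL, compute = function(ctx) stop("injected failure")),
    needs_segmentation = TRUE)
}
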