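#' Run configuration
#'
#' Collects every tunable of the pipeline in one validated list: imaging
#' calibration, segmentation parameters, the focal-adhesion stability
#' tolerance, the volatility sampling interval, cortex-metric geometry and
#' AFM probe constants. Defaults mirror the published analysis settings
#' (10-px median window, 3-px opening kernel, 10% stability tolerance,
#' hourly volatility sampling, 15-um edge profile, 0.06 N/m cantilever,
#' 18-degree half-angle, Poisson ratio 0.5, 1.5 nN trigger).
#'
#' @param pixel_size_um Pixel size, um/px.
#' @param frame_interval_s Frame interval, s.
#' @param median_window Median-filter window, px (square).
#' @param opening_kernel Binary-opening kernel, px (square).
#' @param min_area Minimum adhesion segment area, px^2.
#' @param stability_tolerance Maximum relative change (area and intensity)
#'   for a stable adhesion; in (0, 1).
#' @param iou_threshold Minimum intersection-over-union to link adhesion
#'   segments across consecutive frames.
#' @param sampling_interval_h Volatility sampling interval, h.
#' @param band_width_um Edge band width for the edge-positive fraction, um.
#' @param max_distance_um Maximum edge distance of the intensity profile, um.
#' @param bin_width_um Profile bin width, um.
#' @param spring_constant AFM cantilever spring constant, N/m.
#' @param half_angle_deg AFM tip half-angle, degrees.
#' @param poisson_ratio Sample Poisson ratio.
#' @param trigger_nN AFM trigger force, nN.
#' @param seed Integer random seed recorded in output metadata.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 0.65, frame_interval_s = 1800,
                       median_window = 10, opening_kernel = 3, min_area = 4,
                       stability_tolerance = 0.10, iou_threshold = 0.3,
                       sampling_interval_h = 1, band_width_um = 1,
                       max_distance_um = 15, bin_width_um = 1,
                       spring_constant = 0.06, half_angle_deg = 18,
                       poisson_ratio = 0.5, trigger_nN = 1.5, seed = 1L) {
  cfg <- list(pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              median_window = median_window,
              opening_kernel = opening_kernel, min_area = min_area,
              stability_tolerance = stability_tolerance,
              iou_threshold = iou_threshold,
              sampling_interval_h = sampling_interval_h,
              band_width_um = band_width_um,
              max_distance_um = max_distance_um,
              bin_width_um = bin_width_um,
              spring_constant = spring_constant,
              half_angle_deg = half_angle_deg,
              poisson_ratio = poisson_ratio, trigger_nN = trigger_nN,
              seed = as.integer(seed))
  pos <- c("pixel_size_um", "frame_interval_s", "median_window",
           "opening_kernel", "min_area", "sampling_interval_h",
           "band_width_um", "max_distance_um", "bin_width_um",
           "spring_constant", "half_angle_deg", "trigger_nN")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (cfg$stability_tolerance <= 0 || cfg$stability_tolerance >= 1)
    stop("`stability_tolerance` must lie in (0, 1)")
  if (cfg$poisson_ratio < 0 || cfg$poisson_ratio > 0.5)
    stop("`poisson_ratio` must lie in [0, 0.5]")
  if (is.na(cfg$seed)) stop("`seed` must be an integer")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' YAML is the native format; JSON files parse as well (JSON is a subset of
#' YAML). Keys found in the file override [run_config()] defaults; `overrides`
#' (e.g. parsed command-line flags) override the file in turn.
#'
#' @param path Path to a YAML/JSON configuration file, or `NULL` for
#'   defaults only.
#' @param overrides Named list applied on top of the file values.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must contain a mapping")
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), known)])
}
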