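#' Default simulation configuration
#'
#' The study conditions as a plain list, in the shape accepted by
#' [read_sim_config()]: fluid constants for air/water at 30 degrees C,
#' the measured spray size distribution (lognormal mean 54.0 um, SD
#' 52.3 um, truncated at 7 um), launch speed 3 m/s with +/- 10 degrees
#' spread, 100 000 droplets, nozzle-to-screen distance 19 cm, and no
#' barriers. Geometry lengths are in cm, as in the bench description;
#' [read_sim_config()] converts to SI.
#'
#' @param seed Base RNG seed recorded in the config.
#' @return A nested list with blocks `fluid`, `emission`, `geometry`,
#'   `barriers`, `seed`.
#' @export
default_sim_config <- function(seed = 1L) {
  list(
    fluid = list(air_viscosity = 18.73e-6, liquid_density = 995.7,
                 gravity = 9.81),
    emission = list(speed = 3, angle_low_deg = -10, angle_high_deg = 10,
                    mean_diameter_um = 54.0, sd_diameter_um = 52.3,
                    min_diameter_um = 7, count = 100000L),
    geometry = list(screen_distance_cm = 19, nozzle_height_cm = 10,
                    screen_extent_cm = c(0, 30), roi_half_height_cm = 2),
    barriers = list(),
    seed = as.integer(seed)
  )
}

need_field <- function(block, field, where) {
  if (is.null(block[[field]]))
    stop(sprintf("config is missing field '%s' in block '%s'", field, where))
  block[[field]]
}

#' Read and validate a simulation configuration
#'
#' Parses a JSON configuration (or an equivalent already-parsed list) with
#' blocks `fluid`, `emission`, `geometry`, `barriers` and `seed` into the
#' package's typed objects. Geometry and barrier distances are given in cm
#' and converted to SI here, at the boundary; angular limits are in
#' degrees. Any missing field is reported by name. Absent blocks fall back
#' to the defaults of [default_sim_config()].
#'
#' @param config Path to a JSON file, or a nested list.
#' @return A list with elements `env` ([fluid_environment()]), `model`
#'   ([emission_model()]), `geometry` ([experiment_geometry()]),
#'   `barriers` (list of [barrier()], possibly empty), `seed`.
#' @export
read_sim_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stop("config must be a JSON path or a list")
  dflt <- default_sim_config()
  fl <- utils::modifyList(dflt$fluid, config$fluid %||% list())
  em <- utils::modifyList(dflt$emission, config$emission %||% list())
  ge <- utils::modifyList(dflt$geometry, config$geometry %||% list())
  seed <- as.integer(config$seed %||% dflt$seed)

  env <- fluid_environment(
    air_viscosity = need_field(fl, "air_viscosity", "fluid"),
    liquid_density = need_field(fl, "liquid_density", "fluid"),
    gravity = need_field(fl, "gravity", "fluid"))
  model <- emission_model(
    speed = need_field(em, "speed", "emission"),
    angle_low = need_field(em, "angle_low_deg", "emission") * pi / 180,
    angle_high = need_field(em, "angle_high_deg", "emission") * pi / 180,
    diameters = em$diameters_um,
    mean_diameter = need_field(em, "mean_diameter_um", "emission"),
    sd_diameter = need_field(em, "sd_diameter_um", "emission"),
    min_diameter = need_field(em, "min_diameter_um", "emission"),
    count = need_field(em, "count", "emission"),
    seed = seed)
  geometry <- experiment_geometry(
    screen_distance = need_field(ge, "screen_distance_cm", "geometry") / 100,
    nozzle_height = need_field(ge, "nozzle_height_cm", "geometry") / 100,
    screen_extent = need_field(ge, "screen_extent_cm", "geometry") / 100,
    roi_half_height = need_field(ge, "roi_half_height_cm", "geometry") / 100)

  barriers <- lapply(seq_along(config$barriers %||% list()), function(i) {
    b <- config$barriers[[i]]
    barrier(
      distance_from_nozzle =
        need_field(b, "distance_from_nozzle_cm",
                   sprintf("barriers[%d]", i)) / 100,
      p = need_field(b, "p", sprintf("barriers[%d]", i)),
      f = need_field(b, "f", sprintf("barriers[%d]", i)))
  })
  list(env = env, model = model, geometry = geometry, barriers = barriers,
       seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evenly spaced barrier positions between the end configurations
#'
#' The cloth positions studied between the source-side and receiver-side
#' placements: the first sits `margin` from the nozzle, the last `margin`
#' from the screen (both 1.5 cm by default, mirroring the bench layout),
#' and the rest are evenly spaced between.
#'
#' @param geometry An [experiment_geometry()].
#' @param n Number of positions (default 4).
#' @param margin Distance of the end positions from nozzle and screen, m.
#' @return Numeric vector of distances from the nozzle, m.
#' @export
default_barrier_positions <- function(geometry = experiment_geometry(),
                                      n = 4L, margin = 0.015) {
  if (2 * margin >= geometry$screen_distance)
    stop("margins leave no room between nozzle and screen")
  seq(margin, geometry$screen_distance - margin, length.out = n)
}
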