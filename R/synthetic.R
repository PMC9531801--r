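#' Scanner-render settings
#'
#' Controls how simulated impacts are rasterized into scanner-like stain
#' images. The default 4800 dpi gives a pixel pitch of ~5.3 um, below the
#' 7 um stain detectability floor, so the smallest physical stains remain
#' representable. The rendered window is a `width_cm x height_cm` patch of
#' the screen centered vertically on the nozzle height. The spread factor
#' `beta` scales stain diameter relative to the droplet diameter (stains
#' are wider than the droplets that caused them; the default 1.0 keeps the
#' stain-as-proxy convention of the measurements).
#'
#' @param dpi Render resolution, dots per inch.
#' @param width_cm,height_cm Physical size of the rendered window, cm.
#' @param beta Stain spread factor (>= 1).
#' @param noise_rate Salt-and-pepper pixel flip rate, in [0, 0.01].
#' @param blur_sigma Gaussian blur radius in pixels (0 = none).
#' @param stains_dark Render stains darker than the background?
#' @param seed RNG seed for transverse placement and noise.
#' @return An object of class `render_settings`.
#' @export
render_settings <- function(dpi = 4800, width_cm = 1, height_cm = 1,
                            beta = 1.0, noise_rate = 2e-4, blur_sigma = 0,
                            stains_dark = TRUE, seed = 1L) {
  if (dpi <= 0) stop("dpi must be > 0")
  if (width_cm <= 0 || height_cm <= 0) stop("image size must be > 0")
  if (beta < 1) stop("spread factor beta must be >= 1")
  if (noise_rate < 0 || noise_rate > 0.01)
    stop("noise_rate must be in [0, 0.01]")
  structure(list(dpi = dpi, width_cm = width_cm, height_cm = height_cm,
                 beta = beta, noise_rate = noise_rate,
                 blur_sigma = blur_sigma, stains_dark = stains_dark,
                 seed = as.integer(seed)),
            class = "render_settings")
}

# intensity levels of the rendered "scan"
.render_bg <- 0.92
.render_fg <- 0.10

#' Render simulated impacts as a scanner-like stain image
#'
#' Turns the screen impacts of a simulated experiment into a grayscale
#' stain image with known ground truth. Each impact that lands inside the
#' rendered window becomes a filled disk of diameter `beta x (2 r)` at its
#' physical height; the transverse (horizontal-on-screen) coordinate is
#' drawn uniformly across the window width, a visualization convention for
#' the dimension the planar flight model does not resolve. Impacts outside
#' the vertical extent are dropped and counted. Salt-and-pepper noise and
#' optional Gaussian blur are applied after rasterization. Deterministic
#' given `settings$seed`.
#'
#' @param impacts Impact records from [simulate_experiment()]; only fates
#'   `hit_roi` and `hit_screen` are rendered.
#' @param settings A [render_settings()].
#' @param geometry The [experiment_geometry()] the impacts came from (fixes
#'   the vertical mapping).
#' @return A list: `image` (a [scan_image()]), `disks` (data frame
#'   `x_px`, `y_px`, `diameter_um` of every rendered disk), `n_dropped`
#'   (impacts outside the window), `stain_area_um2` (total nominal disk
#'   area, the area-based ground truth).
#' @export
render_scan <- function(impacts, settings = render_settings(),
                        geometry = experiment_geometry()) {
  stopifnot(inherits(settings, "render_settings"))
  px_m <- 0.0254 / settings$dpi
  nc <- max(1L, round(settings$width_cm / 100 / px_m))
  nr <- max(1L, round(settings$height_cm / 100 / px_m))
  h <- geometry$nozzle_height
  y_max <- h + settings$height_cm / 200
  y_min <- h - settings$height_cm / 200

  hits <- impacts[impacts$fate %in% c("hit_roi", "hit_screen"), ,
                  drop = FALSE]
  inside <- hits$y_m >= y_min & hits$y_m <= y_max
  n_dropped <- sum(!inside)
  hits <- hits[inside, , drop = FALSE]

  set.seed(settings$seed)
  mask <- matrix(FALSE, nr, nc)
  n <- nrow(hits)
  disks <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      diameter_um = numeric(0))
  if (n > 0L) {
    cx <- stats::runif(n, 0.5, nc + 0.5)
    cy <- (y_max - hits$y_m) / px_m + 0.5
    r_px <- settings$beta * hits$radius_m / px_m
    for (i in seq_len(n)) {
      x0 <- max(1L, ceiling(cx[i] - r_px[i]))
      x1 <- min(nc, floor(cx[i] + r_px[i]))
      y0 <- max(1L, ceiling(cy[i] - r_px[i]))
      y1 <- min(nr, floor(cy[i] + r_px[i]))
      if (x1 < x0 || y1 < y0) next # disk smaller than a pixel pitch
      xs <- x0:x1
      ys <- y0:y1
      dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+") <= r_px[i]^2
      mask[ys, xs] <- mask[ys, xs] | dd
    }
    disks <- data.frame(x_px = cx, y_px = cy,
                        diameter_um = settings$beta * 2 * hits$radius_m * 1e6)
  }

  if (settings$noise_rate > 0) {
    n_noise <- stats::rbinom(1L, nr * nc, settings$noise_rate)
    if (n_noise > 0L) {
      at <- sample.int(nr * nc, n_noise)
      mask[at] <- stats::runif(n_noise) < 0.5
    }
  }

  fg <- .render_fg; bg <- .render_bg
  if (!settings$stains_dark) { fg <- .render_bg; bg <- .render_fg }
  px <- matrix(bg, nr, nc)
  px[mask] <- fg
  if (settings$blur_sigma > 0)
    px <- as.matrix(EBImage::gblur(EBImage::Image(px),
                                   sigma = settings$blur_sigma))
  list(image = scan_image(px, settings$dpi),
       disks = disks,
       n_dropped = n_dropped,
       stain_area_um2 = sum(pi * (disks$diameter_um / 2)^2))
}

#' Generate a full synthetic experiment set with ground truth
#'
#' Runs the transport simulation for a free (no barrier) configuration and
#' every supplied barrier configuration, each with `replicates` independent
#' derived seeds, renders each run into a stain scan, writes the images as
#' PNG plus a manifest CSV (directly consumable by [read_manifest()]), and
#' writes a ground-truth manifest JSON recording the rendered disks, the
#' realized area-based blocking fraction, and the volume-based simulated
#' blocking statistic for every configuration.
#'
#' @param configurations Named list; each element is `NULL` (free
#'   configuration), a [barrier()], or a list of barriers. Must contain at
#'   least one `NULL` entry, used as the reference group.
#' @param model An [emission_model()]; its seed is the base seed from which
#'   each configuration/replicate seed is derived.
#' @param geometry An [experiment_geometry()].
#' @param settings A [render_settings()].
#' @param replicates Replicates per configuration (default 3).
#' @param out_dir Output directory (created if needed).
#' @param env A [fluid_environment()].
#' @return The ground-truth manifest, invisibly (also written as
#'   `manifest.json` in `out_dir`).
#' @export
generate_experiment_set <- function(configurations, model,
                                    geometry = experiment_geometry(),
                                    settings = render_settings(),
                                    replicates = 3L,
                                    out_dir,
                                    env = fluid_environment()) {
  if (is.null(names(configurations)) || any(names(configurations) == ""))
    stop("configurations must be a fully named list")
  is_free <- vapply(configurations, is.null, logical(1))
  if (!any(is_free))
    stop("configurations must include a free (NULL) reference entry")
  if (replicates < 1L) stop("replicates must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); truth <- list()
  for (ic in seq_along(configurations)) {
    cname <- names(configurations)[ic]
    barr <- configurations[[ic]]
    per_rep <- list()
    for (j in seq_len(replicates)) {
      m_j <- model
      m_j$seed <- model$seed + 997L * ic + j
      rec <- simulate_experiment(m_j, geometry, barr, env,
                                 barrier_mode = "bernoulli")
      s_j <- settings
      s_j$seed <- settings$seed + 131L * ic + j
      rnd <- render_scan(rec, s_j, geometry)
      fname <- sprintf("%s_rep%d.png", cname, j)
      write_scan(rnd$image, file.path(out_dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        path = fname, configuration = cname, replicate = j,
        dpi = settings$dpi)
      per_rep[[j]] <- list(
        file = fname, seed = m_j$seed, render_seed = s_j$seed,
        n_disks = nrow(rnd$disks), n_dropped = rnd$n_dropped,
        stain_area_um2 = rnd$stain_area_um2,
        roi_volume_m3 = sum(rec$volume_m3[rec$fate == "hit_roi"]))
    }
    truth[[cname]] <- list(
      barrier = if (is.null(barr)) NULL else {
        bl <- if (inherits(barr, "barrier")) list(barr) else barr
        lapply(bl, function(b) list(
          distance_from_nozzle_m = b$distance_from_nozzle, p = b$p,
          f = b$f))
      },
      replicates = per_rep,
      mean_stain_area_um2 =
        mean(vapply(per_rep, `[[`, numeric(1), "stain_area_um2")),
      mean_roi_volume_m3 =
        mean(vapply(per_rep, `[[`, numeric(1), "roi_volume_m3")))
  }

  free_name <- names(configurations)[which(is_free)[1]]
  a_free <- truth[[free_name]]$mean_stain_area_um2
  v_free <- truth[[free_name]]$mean_roi_volume_m3
  for (cname in names(truth)) {
    truth[[cname]]$area_blocking_percent <-
      if (a_free > 0) (1 - truth[[cname]]$mean_stain_area_um2 / a_free) * 100
      else NA_real_
    truth[[cname]]$volume_blocking_percent <-
      if (v_free > 0) (1 - truth[[cname]]$mean_roi_volume_m3 / v_free) * 100
      else NA_real_
  }

  manifest_csv <- do.call(rbind, rows)
  utils::write.csv(manifest_csv, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest <- list(
    base_seed = model$seed,
    render_base_seed = settings$seed,
    reference_configuration = free_name,
    emission = list(speed = model$speed,
                    mean_diameter_um = model$mean_diameter,
                    sd_diameter_um = model$sd_diameter,
                    min_diameter_um = model$min_diameter,
                    count = model$count),
    render = list(dpi = settings$dpi, width_cm = settings$width_cm,
                  height_cm = settings$height_cm, beta = settings$beta,
                  noise_rate = settings$noise_rate,
                  blur_sigma = settings$blur_sigma),
    configurations = truth)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
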