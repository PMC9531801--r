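#' Droplet emission model
#'
#' Describes the spray at the nozzle: launch speed, angular spread, droplet
#' size law, and how many droplets a simulation emits. Sizes are expressed
#' as diameters in micrometers (the convention of stain measurements);
#' either an empirical list of diameters or a lognormal matched by moments
#' to a (mean, SD) pair and truncated below at `min_diameter`. The moment
#' match is done before truncation.
#'
#' Defaults are the experimental characterization of the spray: mean stain
#' diameter 54.0 um, SD 52.3 um, minimum detectable 7 um, launch speed
#' 3 m/s, angles uniform in [-10, 10] degrees, 100 000 droplets.
#'
#' @param speed Launch speed, m/s.
#' @param angle_low,angle_high Angular range, radians from horizontal.
#' @param diameters Optional empirical droplet diameters, um. When given,
#'   sampling resamples this list with replacement and the lognormal
#'   parameters are ignored.
#' @param mean_diameter,sd_diameter Lognormal moments (before truncation), um.
#' @param min_diameter Truncation floor, um.
#' @param count Number of droplets per simulation.
#' @param seed RNG seed for emission sampling.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(speed = 3,
                           angle_low = -10 * pi / 180,
                           angle_high = 10 * pi / 180,
                           diameters = NULL,
                           mean_diameter = 54.0,
                           sd_diameter = 52.3,
                           min_diameter = 7,
                           count = 100000L,
                           seed = 1L) {
  if (angle_low > angle_high) stop("angle_low must be <= angle_high")
  if (min_diameter <= 0) stop("min_diameter must be > 0")
  if (!is.null(diameters)) {
    if (length(diameters) == 0L) stop("empirical diameter list is empty")
    if (any(diameters < min_diameter))
      stop("all empirical diameters must be >= min_diameter")
  } else {
    if (mean_diameter <= 0 || sd_diameter <= 0)
      stop("mean_diameter and sd_diameter must be > 0")
  }
  if (count < 0) stop("count must be >= 0")
  structure(list(speed = speed, angle_low = angle_low,
                 angle_high = angle_high, diameters = diameters,
                 mean_diameter = mean_diameter, sd_diameter = sd_diameter,
                 min_diameter = min_diameter, count = as.integer(count),
                 seed = as.integer(seed)),
            class = "emission_model")
}

# Lognormal parameters matched to arithmetic mean/SD (pre-truncation).
lognormal_params <- function(mean, sd) {
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Sample droplets from an emission model
#'
#' Draws `model$count` droplets: diameters from the empirical list
#' (resampled with replacement) or from the truncated lognormal (inverse-CDF
#' conditional sampling, so truncation costs no rejection loop), and launch
#' angles uniform on the angular range. Deterministic given `model$seed`;
#' diameters are drawn before angles.
#'
#' @param model An [emission_model()].
#' @param origin Nozzle position `c(x, y)` in m.
#' @return A [droplet()] data frame with `model$count` rows.
#' @export
sample_droplets <- function(model, origin = c(0, 0)) {
  stopifnot(inherits(model, "emission_model"))
  n <- model$count
  if (n == 0L) return(droplet(numeric(0), numeric(0), numeric(0),
                              numeric(0), numeric(0)))
  set.seed(model$seed)
  if (!is.null(model$diameters)) {
    d_um <- sample(model$diameters, n, replace = TRUE)
  } else {
    lp <- lognormal_params(model$mean_diameter, model$sd_diameter)
    p0 <- stats::plnorm(model$min_diameter, lp$meanlog, lp$sdlog)
    d_um <- stats::qlnorm(stats::runif(n, p0, 1), lp$meanlog, lp$sdlog)
  }
  angle <- stats::runif(n, model$angle_low, model$angle_high)
  droplet(radius = d_um * 1e-6 / 2, x = origin[1], y = origin[2],
          speed = model$speed, angle = angle)
}

#' Porous barrier (cloth) model
#'
#' A flat porous cloth at a fixed distance from the nozzle, characterized
#' by two dimensionless parameters: the tunneling probability `p` (chance a
#' droplet passes through) and the deceleration factor `f` (ratio of exit to
#' entry speed for droplets that pass). Neither depends on droplet radius or
#' incidence angle.
#'
#' @param distance_from_nozzle Barrier plane position, m from the nozzle.
#' @param p Tunneling probability in [0, 1].
#' @param f Deceleration factor in [0, 1].
#' @return An object of class `barrier`.
#' @export
barrier <- function(distance_from_nozzle, p, f) {
  if (p < 0 || p > 1) stop("tunneling probability p must be in [0, 1]")
  if (f < 0 || f > 1) stop("deceleration factor f must be in [0, 1]")
  if (distance_from_nozzle <= 0)
    stop("barrier distance_from_nozzle must be > 0")
  structure(list(distance_from_nozzle = distance_from_nozzle, p = p, f = f),
            class = "barrier")
}

#' Experiment geometry
#'
#' Nozzle, screen and region-of-interest layout. The nozzle sits at height
#' `nozzle_height` above the bucket floor (y = 0) and sprays horizontally
#' toward a screen at distance `screen_distance`. The "center of the
#' screen" used by the simulated blocking statistic is the horizontal band
#' within `roi_half_height` of the nozzle height.
#'
#' @param screen_distance Nozzle-to-screen distance L, m (default 0.19).
#' @param nozzle_height Nozzle height above the floor, m (default 0.10).
#' @param screen_extent Vertical extent `c(y_min, y_max)` of the screen, m.
#' @param roi_half_height Half-height of the central screen band, m
#'   (default 0.02).
#' @return An object of class `experiment_geometry`.
#' @export
experiment_geometry <- function(screen_distance = 0.19,
                                nozzle_height = 0.10,
                                screen_extent = c(0, 0.30),
                                roi_half_height = 0.02) {
  if (screen_distance <= 0) stop("screen_distance must be > 0")
  if (nozzle_height <= screen_extent[1] || nozzle_height >= screen_extent[2])
    stop("nozzle_height must lie inside the screen's vertical extent")
  if (nozzle_height - roi_half_height < screen_extent[1] ||
      nozzle_height + roi_half_height > screen_extent[2])
    stop("ROI band must be contained in the screen extent")
  structure(list(screen_distance = screen_distance,
                 nozzle_height = nozzle_height,
                 screen_extent = screen_extent,
                 roi_half_height = roi_half_height),
            class = "experiment_geometry")
}

#' Droplet-cloth interaction
#'
#' Applies the two-parameter cloth model to droplets at the barrier plane:
#' each droplet passes with probability `p` (its speed multiplied by `f`,
#' direction unchanged) and is otherwise blocked. One uniform variate per
#' droplet decides the outcome; supplying `u` explicitly enables
#' common-random-number comparisons across parameter values (the pass set
#' `u < p` grows monotonically with p).
#'
#' @param droplets A [droplet()] data frame at the barrier plane.
#' @param barrier A [barrier()].
#' @param u Uniform(0,1) variates, one per droplet; drawn internally when
#'   omitted.
#' @return `droplets` with a logical column `passed`; rows with
#'   `passed == TRUE` have their speed multiplied by `barrier$f`.
#' @export
barrier_interaction <- function(droplets, barrier, u = NULL) {
  stopifnot(inherits(barrier, "barrier"))
  n <- nrow(droplets)
  if (is.null(u)) u <- stats::runif(n)
  if (length(u) != n) stop("length(u) must equal nrow(droplets)")
  passed <- u < barrier$p
  droplets$speed[passed] <- droplets$speed[passed] * barrier$f
  droplets$passed <- passed
  droplets
}

fate_levels <- c("hit_roi", "hit_screen", "blocked", "stalled", "fell")

#' Simulate a spray experiment
#'
#' Monte-Carlo transport of an emitted droplet population from the nozzle to
#' the screen, through zero or more porous barriers. Each droplet flies
#' ballistically (closed-form gravity + Stokes drag) to the first barrier
#' plane; droplets whose asymptotic range falls short stall, droplets
#' crossing the floor fall. At a barrier the two-parameter cloth model is
#' applied, then flight resumes toward the next plane. Impacts on the screen
#' are classified `hit_roi` when they land within the central band
#' (`|y - nozzle_height| <= roi_half_height`), else `hit_screen`.
#'
#' Two tunneling treatments are available. `"bernoulli"` (default) flips one
#' coin per droplet per barrier, matching the physical picture: fates are
#' mutually exclusive and counts add up to the emitted count.
#' `"weighted"` replaces the coin by its conditional expectation: every
#' droplet reaching a barrier continues with its carried volume multiplied
#' by `p` (speed still multiplied by `f`), and the blocked mass
#' `(1 - p) x volume` is recorded separately. Both conserve total volume
#' exactly; the weighted estimator has no tunneling variance, which makes
#' the simulated blocking statistic exactly affine in `p` under common
#' random numbers and is what the model calibration uses.
#'
#' Emission sampling uses `model$seed`; barrier coins use an independent
#' stream derived from it, so the same seed reproduces the run byte for
#' byte.
#'
#' @param model An [emission_model()].
#' @param geometry An [experiment_geometry()].
#' @param barriers A [barrier()], a list of barriers (applied in order of
#'   distance), or `NULL` for the free configuration.
#' @param env A [fluid_environment()].
#' @param barrier_mode `"bernoulli"` or `"weighted"` (see Details).
#' @return A data frame of impact records with columns `radius_m`, `y_m`,
#'   `speed_m_s`, `volume_m3`, `fate` (factor) and attributes `seed`,
#'   `barrier_mode`. `y_m`/`speed_m_s` are `NA` for droplets that never
#'   reach the screen.
#' @export
simulate_experiment <- function(model, geometry = experiment_geometry(),
                                barriers = NULL,
                                env = fluid_environment(),
                                barrier_mode = c("bernoulli", "weighted")) {
  barrier_mode <- match.arg(barrier_mode)
  stopifnot(inherits(model, "emission_model"),
            inherits(geometry, "experiment_geometry"))
  if (inherits(barriers, "barrier")) barriers <- list(barriers)
  if (!is.null(barriers)) {
    ok <- vapply(barriers, inherits, logical(1), "barrier")
    if (!all(ok)) stop("barriers must be barrier objects")
    d <- vapply(barriers, `[[`, numeric(1), "distance_from_nozzle")
    if (any(d >= geometry$screen_distance))
      stop("barrier planes must lie strictly between nozzle and screen")
    barriers <- barriers[order(d)]
  }
  drops <- sample_droplets(model,
                           origin = c(0, geometry$nozzle_height))
  n <- nrow(drops)
  nb <- length(barriers)
  if (nb > 0L && barrier_mode == "bernoulli") {
    # independent coin stream so emission and tunneling don't interleave
    set.seed(model$seed + 1L)
    U <- matrix(stats::runif(n * nb), nrow = n, ncol = nb)
  }

  rad <- drops$radius
  vol <- droplet_volume(rad)
  xs <- drops$x; ys <- drops$y; v <- drops$speed; th <- drops$angle
  fate <- rep(NA_character_, n)
  w <- rep(1, n)            # carried volume fraction (weighted mode)
  extra <- list()           # blocked-mass records in weighted mode

  planes <- c(if (nb) vapply(barriers, `[[`, numeric(1),
                             "distance_from_nozzle"),
              geometry$screen_distance)
  for (k in seq_along(planes)) {
    at_barrier <- k <= nb
    idx <- which(is.na(fate))
    if (!length(idx)) break
    fl <- flight_to_plane(rad[idx], xs[idx], ys[idx], v[idx], th[idx],
                          planes[k], env)
    stalled <- !fl$reached
    fell <- fl$reached & fl$y < 0
    fate[idx[stalled]] <- "stalled"
    fate[idx[fell]] <- "fell"
    go <- which(fl$reached & !fell)
    j <- idx[go]
    xs[j] <- planes[k]; ys[j] <- fl$y[go]
    v[j] <- fl$speed[go]; th[j] <- fl$angle[go]
    if (at_barrier) {
      b <- barriers[[k]]
      if (barrier_mode == "bernoulli") {
        pass <- U[j, k] < b$p
        fate[j[!pass]] <- "blocked"
        v[j[pass]] <- v[j[pass]] * b$f
      } else {
        if (length(j)) {
          extra[[length(extra) + 1L]] <- data.frame(
            radius_m = rad[j], y_m = NA_real_, speed_m_s = NA_real_,
            volume_m3 = (1 - b$p) * w[j] * vol[j],
            fate = "blocked")
        }
        w[j] <- w[j] * b$p
        v[j] <- v[j] * b$f
      }
    } else {
      roi <- abs(ys[j] - geometry$nozzle_height) <= geometry$roi_half_height
      fate[j] <- ifelse(roi, "hit_roi", "hit_screen")
    }
  }

  terminal <- fate %in% c("hit_roi", "hit_screen")
  rec <- data.frame(radius_m = rad,
                    y_m = ifelse(terminal, ys, NA_real_),
                    speed_m_s = ifelse(terminal, v, NA_real_),
                    volume_m3 = w * vol,
                    fate = fate)
  if (length(extra)) rec <- rbind(rec, do.call(rbind, extra))
  rec$fate <- factor(rec$fate, levels = fate_levels)
  attr(rec, "seed") <- model$seed
  attr(rec, "barrier_mode") <- barrier_mode
  rec
}

#' Simulated Ballistic Blocking Capacity (SBBC)
#'
#' The simulated analogue of the blocking statistic: from two simulated
#' experiments (with and without the obstacle),
#' `SBBC = (1 - V_o / V_no) x 100`, where each V is the total droplet
#' volume reaching the central band of the screen (fate `hit_roi`).
#'
#' @param with_barrier,without_barrier Impact-record data frames from
#'   [simulate_experiment()].
#' @return SBBC in percent.
#' @export
sbbc <- function(with_barrier, without_barrier) {
  v_no <- sum(without_barrier$volume_m3[without_barrier$fate == "hit_roi"])
  if (!is.finite(v_no) || v_no <= 0)
    stop("no droplet volume reaches the screen center without the barrier")
  v_o <- sum(with_barrier$volume_m3[with_barrier$fate == "hit_roi"])
  (1 - v_o / v_no) * 100
}
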