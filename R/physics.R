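#' Fluid environment constants
#'
#' Bundle of the physical constants that parameterize every droplet
#' trajectory: the dynamic viscosity of the surrounding air, the density of
#' the sprayed liquid, and gravitational acceleration. Defaults are air at
#' 30 degrees C and water at 30 degrees C.
#'
#' @param air_viscosity Dynamic viscosity of air, Pa s. Must be > 0.
#' @param liquid_density Density of the droplet liquid, kg/m^3. Must be > 0.
#' @param gravity Gravitational acceleration, m/s^2. Must be > 0.
#' @return An object of class `fluid_environment`.
#' @examples
#' env <- fluid_environment()
#' relaxation_time(100e-6, env)
#' @export
fluid_environment <- function(air_viscosity = 18.73e-6,
                              liquid_density = 995.7,
                              gravity = 9.81) {
  stopifnot(is.numeric(air_viscosity), length(air_viscosity) == 1L,
            is.numeric(liquid_density), length(liquid_density) == 1L,
            is.numeric(gravity), length(gravity) == 1L)
  if (air_viscosity <= 0 || liquid_density <= 0 || gravity <= 0)
    stop("all fluid_environment constants must be strictly positive")
  structure(list(air_viscosity = air_viscosity,
                 liquid_density = liquid_density,
                 gravity = gravity),
            class = "fluid_environment")
}

#' @export
print.fluid_environment <- function(x, ...) {
  cat("Fluid environment:\n",
      sprintf("  air viscosity  : %.4g Pa s\n", x$air_viscosity),
      sprintf("  liquid density : %.4g kg/m^3\n", x$liquid_density),
      sprintf("  gravity        : %.4g m/s^2\n", x$gravity), sep = "")
  invisible(x)
}

#' Droplet state
#'
#' A set of droplets in flight, each described by its radius and kinematic
#' state (position in the vertical plane, speed, elevation angle). All
#' physics operations are vectorized over the rows of this data frame.
#'
#' @param radius Droplet radius, m. Must be > 0.
#' @param x,y Position, m. `x` is horizontal distance toward the screen,
#'   `y` is height above the bucket floor.
#' @param speed Speed magnitude, m/s. Must be >= 0.
#' @param angle Elevation angle from the horizontal, radians.
#' @return A data frame with class `droplet` and columns
#'   `radius`, `x`, `y`, `speed`, `angle`.
#' @export
droplet <- function(radius, x = 0, y = 0, speed = 3, angle = 0) {
  if (any(radius <= 0)) stop("droplet radius must be > 0")
  if (any(speed < 0)) stop("droplet speed must be >= 0")
  d <- data.frame(radius = radius, x = x, y = y, speed = speed, angle = angle)
  class(d) <- c("droplet", "data.frame")
  d
}

#' Droplet volume
#'
#' Sphere volume (4/3) pi r^3, derived from the radius so that volume and
#' radius can never disagree.
#'
#' @param radius Droplet radius, m (vectorized).
#' @return Volume, m^3.
#' @export
droplet_volume <- function(radius) {
  if (any(radius <= 0)) stop("droplet radius must be > 0")
  (4 / 3) * pi * radius^3
}

#' Stokes relaxation time
#'
#' The time scale tau = 2 rho r^2 / (9 eta) on which a droplet of radius r
#' relaxes to its terminal velocity under Stokes drag. Scales quadratically
#' with radius.
#'
#' @param radius Droplet radius, m (vectorized).
#' @param env A [fluid_environment()].
#' @return Relaxation time, s.
#' @export
relaxation_time <- function(radius, env = fluid_environment()) {
  if (any(radius <= 0)) stop("radius must be > 0")
  2 * env$liquid_density * radius^2 / (9 * env$air_viscosity)
}

#' Stokes terminal velocity
#'
#' Settling speed v_T = tau g of a droplet under gravity and Stokes drag.
#'
#' @inheritParams relaxation_time
#' @return Terminal velocity, m/s.
#' @export
terminal_velocity <- function(radius, env = fluid_environment()) {
  relaxation_time(radius, env) * env$gravity
}

#' Maximum horizontal range under Stokes drag
#'
#' The supremum tau v0 cos(theta0) of the horizontal displacement of a
#' droplet launched with speed v0 at angle theta0: under pure Stokes drag
#' the horizontal coordinate approaches this value asymptotically and never
#' exceeds it. Droplets whose range falls short of a target plane stall
#' (physically: they decelerate and fall) before reaching it.
#'
#' @param droplet A [droplet()] data frame.
#' @param env A [fluid_environment()].
#' @return Horizontal range, m (one value per droplet row).
#' @export
max_horizontal_range <- function(droplet, env = fluid_environment()) {
  if (any(cos(droplet$angle) <= 0))
    stop("max_horizontal_range requires |angle| < pi/2")
  relaxation_time(droplet$radius, env) * droplet$speed * cos(droplet$angle)
}

# Stalled-flight condition: raised when a droplet cannot ballistically reach
# the requested plane. Distinct class so callers can distinguish it from
# argument errors.
stalled_error <- function(msg) {
  stop(structure(class = c("bbcsim_stalled_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Vectorized closed-form flight under gravity + Stokes drag, from each
# droplet's current state to horizontal coordinate x_target. Returns a list
# of vectors; entries where reached == FALSE carry NA kinematics. Internal
# workhorse shared by trajectory_height(), flight_state_at() and the
# simulator (no data-frame overhead in the Monte-Carlo loop).
flight_to_plane <- function(radius, x0, y0, speed, angle, x_target, env) {
  tau <- 2 * env$liquid_density * radius^2 / (9 * env$air_viscosity)
  g <- env$gravity
  vx0 <- speed * cos(angle)
  vy0 <- speed * sin(angle)
  dx <- x_target - x0
  rng <- tau * vx0
  # u = fraction of the asymptotic range consumed; domain is [0, 1)
  u <- dx / rng
  reached <- dx >= 0 & u < 1 & vx0 > 0
  reached[dx == 0] <- TRUE
  u <- ifelse(reached, u, NA_real_)
  # y(x) = y0 + (tan(th) + tau*g/(v0 cos th)) dx + tau^2 g log(1 - u)
  y <- y0 + (vy0 / vx0 + tau * g / vx0) * dx + tau^2 * g * log1p(-u)
  # velocity components from the same drag solution:
  # vx = vx0 (1 - u); vy = (vy0 + tau g)(1 - u) - tau g
  vx <- vx0 * (1 - u)
  vy <- (vy0 + tau * g) * (1 - u) - tau * g
  list(reached = reached,
       y = ifelse(reached, y, NA_real_),
       speed = ifelse(reached, sqrt(vx^2 + vy^2), NA_real_),
       angle = ifelse(reached, atan2(vy, vx), NA_real_))
}

#' Trajectory height at a horizontal coordinate
#'
#' Closed-form vertical position of a droplet moving under gravity and
#' Stokes drag when its horizontal coordinate reaches `x`:
#' \deqn{y(x) = y_0 + \left(\tan\theta_0 +
#'   \frac{\tau g}{v_0\cos\theta_0}\right)(x - x_0) +
#'   \tau^2 g \,\ln\!\left(1 - \frac{x - x_0}{\tau v_0 \cos\theta_0}\right)}
#' with relaxation time \eqn{\tau = 2\rho r^2/(9\eta)}. The formula is only
#' defined while the log argument stays positive, i.e. for horizontal
#' displacements below [max_horizontal_range()]; beyond that the droplet has
#' stalled and a dedicated error condition is raised.
#'
#' @param x Horizontal coordinate, m (scalar, or one per droplet row).
#' @param droplet A [droplet()] data frame.
#' @param env A [fluid_environment()].
#' @return Height y, m (one value per droplet row).
#' @export
trajectory_height <- function(x, droplet, env = fluid_environment()) {
  if (any(droplet$speed <= 0)) stop("trajectory requires speed > 0")
  if (any(cos(droplet$angle) <= 0)) stop("trajectory requires |angle| < pi/2")
  if (any(x < droplet$x)) stop("x must be >= the droplet's current x")
  fl <- flight_to_plane(droplet$radius, droplet$x, droplet$y,
                        droplet$speed, droplet$angle, x, env)
  if (any(!fl$reached))
    stalled_error(sprintf(
      "droplet stalled before reaching x = %g m (max range %g m)",
      x[which(!fl$reached)[1]],
      max_horizontal_range(droplet, env)[which(!fl$reached)[1]]))
  fl$y
}

#' Droplet state after flying to a horizontal coordinate
#'
#' Propagates position and velocity to the plane at horizontal coordinate
#' `x`, using the same closed-form drag solution as [trajectory_height()].
#' Flights compose: flying x0 -> x1 -> x2 in two steps equals one direct
#' flight x0 -> x2 up to floating-point error.
#'
#' @inheritParams trajectory_height
#' @return A [droplet()] data frame at the new state.
#' @export
flight_state_at <- function(x, droplet, env = fluid_environment()) {
  if (any(droplet$speed <= 0)) stop("flight requires speed > 0")
  if (any(cos(droplet$angle) <= 0)) stop("flight requires |angle| < pi/2")
  if (any(x < droplet$x)) stop("x must be >= the droplet's current x")
  fl <- flight_to_plane(droplet$radius, droplet$x, droplet$y,
                        droplet$speed, droplet$angle, x, env)
  if (any(!fl$reached))
    stalled_error(sprintf("droplet stalled before reaching x = %g m",
                          x[which(!fl$reached)[1]]))
  droplet(radius = droplet$radius, x = rep_len(x, nrow(droplet)),
          y = fl$y, speed = fl$speed, angle = fl$angle)
}
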