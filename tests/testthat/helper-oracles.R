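# Independent oracles used across the suite. None of these call into the
# closed-form flight solution they are checking.

# Brute-force RK4 integration of the equations of motion under gravity and
# Stokes drag: state (x, y, vx, vy), dv/dt = -g e_y - v / tau. Integrates
# until the horizontal coordinate crosses x_target, then bisects the final
# step size to land on the plane.
rk4_flight <- function(radius, x0, y0, speed, angle, x_target,
                       env = fluid_environment(), steps_per_tau = 400) {
  tau <- 2 * env$liquid_density * radius^2 / (9 * env$air_viscosity)
  g <- env$gravity
  deriv <- function(s) c(s[3], s[4], -s[3] / tau, -g - s[4] / tau)
  step <- function(s, h) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(x0, y0, speed * cos(angle), speed * sin(angle))
  h <- tau / steps_per_tau
  max_steps <- 100 * steps_per_tau # ~100 tau: far beyond any test flight
  for (i in seq_len(max_steps)) {
    s_new <- step(s, h)
    if (s_new[1] >= x_target) break
    s <- s_new
  }
  if (s_new[1] < x_target) stop("rk4 oracle: droplet never reached x_target")
  lo <- 0; hi <- h
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (step(s, mid)[1] < x_target) lo <- mid else hi <- mid
  }
  s <- step(s, (lo + hi) / 2)
  list(x = s[1], y = s[2], vx = s[3], vy = s[4],
       speed = sqrt(s[3]^2 + s[4]^2), angle = atan2(s[4], s[3]))
}

# Mean of a lognormal truncated below at `lo`, by numerical quadrature.
truncated_lognormal_mean <- function(mean, sd, lo) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  z <- 1 - stats::plnorm(lo, meanlog, sdlog)
  num <- stats::integrate(function(x) x * stats::dlnorm(x, meanlog, sdlog),
                          lo, Inf, rel.tol = 1e-10)$value
  num / z
}

# Brute-force one-tailed Mann-Whitney p-value: enumerate every assignment
# of the pooled observations to the two groups and count assignments whose
# U statistic is at least the observed one.
brute_force_mw <- function(a, b) {
  u_of <- function(a, b) sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  n <- length(pooled)
  picks <- utils::combn(n, length(b))
  u_obs <- u_of(a, b)
  hits <- 0L
  for (k in seq_len(ncol(picks))) {
    j <- picks[, k]
    if (u_of(pooled[-j], pooled[j]) >= u_obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(picks)
}

# Rasterize disks of known diameters (um) onto a binary grid: the
# ground-truth generator for imaging tests, independent of render_scan.
raster_disks <- function(centers_px, diameters_um, dpi, nrow_px, ncol_px) {
  px_um <- 25400 / dpi
  m <- matrix(0L, nrow_px, ncol_px)
  for (i in seq_len(nrow(centers_px))) {
    r_px <- diameters_um[i] / 2 / px_um
    cy <- centers_px[i, 1]; cx <- centers_px[i, 2]
    ys <- max(1, ceiling(cy - r_px)):min(nrow_px, floor(cy + r_px))
    xs <- max(1, ceiling(cx - r_px)):min(ncol_px, floor(cx + r_px))
    hit <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r_px^2
    m[ys, xs][hit] <- 1L
  }
  m
}

# Grayscale image from a binary stain mask (dark stains on light paper).
as_gray <- function(mask, fg = 0.1, bg = 0.9) {
  px <- matrix(bg, nrow(mask), ncol(mask))
  px[mask > 0] <- fg
  px
}
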