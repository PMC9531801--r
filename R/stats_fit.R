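#' Read blocking observations from CSV
#'
#' Observations are one row per barrier position with columns
#' `distance_cm` (barrier distance from the nozzle), `bbc_percent` and
#' `sigma_percent`. Distances are converted to meters at this boundary;
#' everything downstream is SI.
#'
#' @param path CSV path.
#' @return A data frame with columns `distance_m`, `bbc`, `sigma`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("distance_cm", "bbc_percent", "sigma_percent")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("observations CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  data.frame(distance_m = d$distance_cm / 100, bbc = d$bbc_percent,
             sigma = d$sigma_percent)
}

# Cached-flight SBBC engine. Samples the emission once, pre-flies every
# droplet to each barrier position, and exposes the ROI volume that would
# arrive at the screen center for a given deceleration factor f. Under the
# conditional-expectation (weighted) tunneling treatment,
# SBBC_i(p, f) = 100 (1 - p V_i(f) / V_free), exactly affine in p, so the
# p-dependence of the fit objective costs nothing to evaluate.
sbbc_engine <- function(model, geometry, positions, env) {
  drops <- sample_droplets(model, origin = c(0, geometry$nozzle_height))
  rad <- drops$radius
  vol <- droplet_volume(rad)
  L <- geometry$screen_distance
  h <- geometry$nozzle_height
  half <- geometry$roi_half_height
  roi_vol <- function(fl) {
    ok <- fl$reached & fl$y >= 0 & abs(fl$y - h) <= half
    ok
  }
  free <- flight_to_plane(rad, drops$x, drops$y, drops$speed, drops$angle,
                          L, env)
  v_free <- sum(vol[roi_vol(free)])
  if (v_free <= 0)
    stop("no droplet volume reaches the screen center in the free run")
  at_barrier <- lapply(positions, function(d) {
    fl <- flight_to_plane(rad, drops$x, drops$y, drops$speed, drops$angle,
                          d, env)
    ok <- fl$reached & fl$y >= 0
    list(rad = rad[ok], vol = vol[ok], y = fl$y[ok], v = fl$speed[ok],
         th = fl$angle[ok], d = d)
  })
  list(
    v_free = v_free,
    # V_i(f): ROI volume given passage through barrier i with factor f
    pass_volume = function(i, f) {
      st <- at_barrier[[i]]
      if (!length(st$rad)) return(0)
      fl <- flight_to_plane(st$rad, st$d, st$y, st$v * f, st$th, L, env)
      sum(st$vol[fl$reached & fl$y >= 0 & abs(fl$y - h) <= half])
    }
  )
}

#' Calibrate the cloth parameters (p, f) against blocking observations
#'
#' Fits the tunneling probability p and deceleration factor f of the cloth
#' model by minimizing the weighted sum of squares
#' `sum_i w_i (SBBC_i(p, f) - BBC_i)^2` with weights `w_i = 1/sigma_i^2`,
#' where SBBC_i is the simulated blocking at the i-th barrier position.
#' The simulator uses one fixed emission sample (common random numbers) and
#' the conditional-expectation tunneling treatment, so the objective is a
#' smooth, exactly quadratic function of p at fixed f. The optimum is found
#' by a grid search over `[0, 1]^2` followed by one local grid refinement;
#' exact ties break to the smallest p, then the smallest f. Deterministic
#' given `model$seed`.
#'
#' @param observations Data frame with columns `distance_m`, `bbc`,
#'   `sigma` (see [read_observations()]); all sigmas must be > 0.
#' @param model An [emission_model()] (its seed fixes the common random
#'   numbers).
#' @param geometry An [experiment_geometry()].
#' @param env A [fluid_environment()].
#' @param p_grid,f_grid Coarse search grids over [0, 1] (default 101
#'   points each).
#' @param refine Run one local refinement (21 x 21 over +/- one coarse
#'   step)?
#' @param keep_surface Return the coarse objective surface as a data
#'   frame?
#' @return An object of class `fit_result`: `p_hat`, `f_hat`, `objective`,
#'   per-position `sbbc` and `residuals`, the experimental and simulated
#'   linear-fit slopes vs. position with their relative difference in
#'   percent, an `over_range` flag marking fitted-line values above 100%,
#'   and optionally `surface`.
#' @export
fit_pf <- function(observations, model, geometry = experiment_geometry(),
                   env = fluid_environment(),
                   p_grid = seq(0, 1, length.out = 101),
                   f_grid = seq(0, 1, length.out = 101),
                   refine = TRUE, keep_surface = FALSE) {
  obs <- observations
  need <- c("distance_m", "bbc", "sigma")
  if (!all(need %in% names(obs)))
    stop("observations must have columns distance_m, bbc, sigma")
  if (nrow(obs) < 2L) stop("need at least 2 observations")
  if (any(obs$sigma <= 0)) stop("all observation sigmas must be > 0")
  if (any(obs$distance_m <= 0 | obs$distance_m >= geometry$screen_distance))
    stop("barrier positions must lie strictly between nozzle and screen")

  eng <- sbbc_engine(model, geometry, obs$distance_m, env)
  w <- 1 / obs$sigma^2
  a <- 100 - obs$bbc # deficit the model must explain: p * 100 * R_i(f)

  eval_grid <- function(pg, fg) {
    R <- vapply(fg, function(f)
      vapply(seq_len(nrow(obs)), function(i) eng$pass_volume(i, f),
             numeric(1)) / eng$v_free,
      numeric(nrow(obs)))
    R <- matrix(R, nrow = nrow(obs)) # positions x f
    # obj(p, f) = sum_i w_i (a_i - 100 p R_if)^2, quadratic in p
    A <- sum(w * a^2)
    Bf <- colSums(w * a * 100 * R)        # per f
    Cf <- colSums(w * (100 * R)^2)
    obj <- outer(pg^2, Cf) - 2 * outer(pg, Bf) + A
    obj[obj < 0] <- 0 # guard tiny negative round-off
    list(obj = obj, R = R)
  }

  pick <- function(obj, pg, fg) {
    m <- min(obj)
    cand <- which(obj <= m + 1e-12 * max(1, abs(m)), arr.ind = TRUE)
    cand <- cand[order(pg[cand[, 1]], fg[cand[, 2]]), , drop = FALSE]
    c(pi = as.integer(cand[1, 1]), fi = as.integer(cand[1, 2]))
  }

  g <- eval_grid(p_grid, f_grid)
  best <- pick(g$obj, p_grid, f_grid)
  p_hat <- p_grid[best["pi"]]; f_hat <- f_grid[best["fi"]]
  R_best <- g$R[, best["fi"]]

  if (refine) {
    dp <- if (length(p_grid) > 1) diff(p_grid)[1] else 0.01
    df_ <- if (length(f_grid) > 1) diff(f_grid)[1] else 0.01
    pg2 <- seq(max(0, p_hat - dp), min(1, p_hat + dp), length.out = 21)
    fg2 <- seq(max(0, f_hat - df_), min(1, f_hat + df_), length.out = 21)
    g2 <- eval_grid(pg2, fg2)
    best2 <- pick(g2$obj, pg2, fg2)
    if (min(g2$obj) <= min(g$obj)) {
      p_hat <- pg2[best2["pi"]]; f_hat <- fg2[best2["fi"]]
      R_best <- g2$R[, best2["fi"]]
    }
  }

  sbbc_hat <- 100 * (1 - p_hat * R_best)
  resid <- sbbc_hat - obs$bbc
  objective <- sum(w * resid^2)

  fit_exp <- linear_fit(obs$distance_m, obs$bbc)
  fit_sim <- linear_fit(obs$distance_m, sbbc_hat)
  over <- any(c(fit_exp$fitted, fit_sim$fitted) > 100)

  out <- list(p_hat = p_hat, f_hat = f_hat, objective = objective,
              sbbc = sbbc_hat, residuals = resid,
              observations = obs,
              slope_experimental = fit_exp$slope,
              slope_simulated = fit_sim$slope,
              slope_rel_diff_percent = if (fit_exp$slope == 0) NA_real_
                else slope_relative_difference(fit_exp$slope, fit_sim$slope),
              over_range = over)
  if (keep_surface)
    out$surface <- data.frame(p = rep(p_grid, length(f_grid)),
                              f = rep(f_grid, each = length(p_grid)),
                              objective = as.vector(g$obj))
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Cloth model fit: p = %.4g, f = %.4g (objective %.4g)\n",
              x$p_hat, x$f_hat, x$objective))
  cat(sprintf("  slopes vs position: experimental %.4g, simulated %.4g %%/m",
              x$slope_experimental, x$slope_simulated),
      sprintf("(rel. diff %.2f%%)\n", x$slope_rel_diff_percent))
  if (x$over_range)
    cat("  note: fitted line exceeds 100% inside the data range\n")
  invisible(x)
}

#' Ordinary least-squares line
#'
#' OLS fit of blocking percentage against barrier position; exact on
#' collinear input.
#'
#' @param xs,ys Numeric vectors of equal length (>= 2 distinct x).
#' @return List with `slope`, `intercept`, `residuals`, `fitted`,
#'   `slope_se`.
#' @export
linear_fit <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(unique(xs)) < 2L) stop("need at least 2 distinct x values")
  fit <- stats::lm(ys ~ xs)
  co <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["xs", "Std. Error"]),
    error = function(e) NA_real_)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)), slope_se = unname(se))
}

#' Relative difference between two slopes
#'
#' `|slope_b - slope_a| / |slope_a| x 100`, with `slope_a` the reference
#' (experimental) slope.
#'
#' @param slope_a Reference slope (must be nonzero).
#' @param slope_b Comparison slope.
#' @return Relative difference in percent.
#' @export
slope_relative_difference <- function(slope_a, slope_b) {
  if (slope_a == 0) stop("reference slope is zero")
  abs(slope_b - slope_a) / abs(slope_a) * 100
}

#' One-tailed Mann-Whitney U test (exact for small samples)
#'
#' Tests H1: `sample_b` is stochastically larger than `sample_a`, using the
#' U statistic `#{(i,j): b_j > a_i} + 0.5 #{b_j = a_i}`. For combined
#' sample sizes up to 12 the p-value is exact, by enumeration of all
#' assignments of the pooled values to the two groups (ties handled by the
#' enumeration itself); beyond that the normal approximation with tie
#' correction and continuity correction is used. Designed for the tiny
#' replicate counts of stain experiments (3 per group).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return One-tailed p-value, `P(U >= U_obs)` under the null.
#' @export
mann_whitney_one_tailed <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  na <- length(sample_a); nb <- length(sample_b)
  ustat <- function(a, b) {
    cmp <- outer(a, b, "<")
    eq <- outer(a, b, "==")
    sum(cmp) + 0.5 * sum(eq)
  }
  u_obs <- ustat(sample_a, sample_b)
  pooled <- c(sample_a, sample_b)
  n <- na + nb
  if (n <= 12L) {
    idx <- utils::combn(n, nb)
    u_all <- apply(idx, 2L, function(j) ustat(pooled[-j], pooled[j]))
    mean(u_all >= u_obs - 1e-9)
  } else {
    mu <- na * nb / 2
    tie_counts <- table(pooled)
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    stats::pnorm((u_obs - mu - 0.5) / sigma, lower.tail = FALSE)
  }
}
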