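test_that("linear fits are exact on collinear input and sane on noise", {
  two <- linear_fit(c(1, 3), c(5, 9))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 3)
  tri <- linear_fit(c(0, 1, 2), c(100, 90, 80))
  expect_equal(tri$slope, -10)
  expect_equal(max(abs(tri$residuals)), 0, tolerance = 1e-12)
  expect_error(linear_fit(c(2, 2, 2), c(1, 2, 3)), "distinct")

  set.seed(17)
  xs <- seq(0, 1, length.out = 30)
  ys <- 50 - 20 * xs + rnorm(30, sd = 2)
  f <- linear_fit(xs, ys)
  expect_lt(abs(f$slope - (-20)), 4 * f$slope_se)
})

test_that("slope comparison is a relative difference in percent", {
  expect_equal(slope_relative_difference(-10, -10), 0)
  expect_equal(slope_relative_difference(-10, -9), 10)
  expect_equal(slope_relative_difference(-8.4, -8.03),
               abs(-8.03 + 8.4) / 8.4 * 100)
  expect_error(slope_relative_difference(0, 1), "zero")
})

test_that("exact one-tailed Mann-Whitney matches enumeration and wilcox", {
  expect_equal(mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6)), 1 / 20)
  # symmetry: identical samples cannot show b larger
  expect_gte(mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3)), 0.5)

  set.seed(23)
  for (rep in 1:20) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    vals <- sample(100, na + nb) # tie-free
    a <- vals[seq_len(na)]; b <- vals[na + seq_len(nb)]
    p_pkg <- mann_whitney_one_tailed(a, b)
    expect_equal(p_pkg, brute_force_mw(a, b))
    # independent implementation: exact wilcox, H1 "b greater"
    expect_equal(p_pkg,
                 stats::wilcox.test(b, a, alternative = "greater",
                                    exact = TRUE)$p.value)
    # tail reversal for tie-free data
    expect_gte(p_pkg + mann_whitney_one_tailed(b, a), 1)
  }
})

test_that("the normal approximation engages smoothly for larger samples", {
  set.seed(29)
  a <- rnorm(8); b <- rnorm(8) + 1.5
  p_apx <- mann_whitney_one_tailed(a, b)
  p_ref <- stats::wilcox.test(b, a, alternative = "greater",
                              exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_apx, p_ref, tolerance = 1e-6)
})

small_model <- function(seed = 1) emission_model(count = 20000, seed = seed)

test_that("degenerate all-100% observations pin p to zero", {
  obs <- data.frame(distance_m = default_barrier_positions(),
                    bbc = 100, sigma = 1)
  fit <- fit_pf(obs, small_model(),
                p_grid = seq(0, 1, length.out = 21),
                f_grid = seq(0, 1, length.out = 21), refine = FALSE)
  expect_equal(fit$p_hat, 0)
  expect_equal(fit$f_hat, 0) # tie broken to the smallest f
  expect_equal(fit$objective, 0)
})

test_that("fitting observations the simulator itself produced is exact", {
  m <- small_model(seed = 6)
  geo <- experiment_geometry()
  pos <- default_barrier_positions(geo)
  free <- simulate_experiment(m, geo)
  truth <- vapply(pos, function(d)
    sbbc(simulate_experiment(m, geo, barrier(d, 0.3, 0.5),
                             barrier_mode = "weighted"), free),
    numeric(1))
  obs <- data.frame(distance_m = pos, bbc = truth, sigma = 1)
  fit <- fit_pf(obs, m, geo)
  expect_equal(fit$objective, 0, tolerance = 1e-10)
  # recovery to grid resolution (ties on objective plateaus break low)
  expect_lt(abs(fit$p_hat - 0.3), 0.01)
  expect_lt(abs(fit$f_hat - 0.5), 0.01)
  # the fitted SBBC reproduces the observations exactly
  expect_equal(fit$sbbc, truth, tolerance = 1e-9)
})

test_that("the objective is exactly quadratic in p at fixed f (CRN)", {
  m <- small_model(seed = 10)
  obs <- data.frame(distance_m = c(0.05, 0.1, 0.15),
                    bbc = c(99, 97, 95), sigma = 1)
  fit <- fit_pf(obs, m, p_grid = seq(0, 1, length.out = 5),
                f_grid = c(0.4, 0.6), refine = FALSE, keep_surface = TRUE)
  for (fv in c(0.4, 0.6)) {
    s <- fit$surface[fit$surface$f == fv, ]
    s <- s[order(s$p), ]
    # quadratic through 3 points predicts the remaining two
    qf <- lm(objective ~ poly(p, 2, raw = TRUE), data = s[1:3, ])
    pred <- predict(qf, newdata = s[4:5, ])
    expect_equal(unname(pred), s$objective[4:5], tolerance = 1e-8)
  }
})

test_that("fit input contracts are enforced", {
  obs <- data.frame(distance_m = c(0.05, 0.1), bbc = c(99, 97), sigma = 1)
  expect_error(fit_pf(obs[1, ], small_model()), "at least 2")
  obs_bad <- transform(obs, sigma = 0)
  expect_error(fit_pf(obs_bad, small_model()), "sigma")
  obs_out <- transform(obs, distance_m = c(0.05, 0.25))
  expect_error(fit_pf(obs_out, small_model()), "between nozzle and screen")
  expect_error(read_observations(tempfile()), "not found")
})

test_that("observation CSVs convert cm to m and name missing columns", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "obs.csv")
  utils::write.csv(data.frame(distance_cm = c(1.5, 17.5),
                              bbc_percent = c(99.9, 96),
                              sigma_percent = c(0.1, 1)),
                   f, row.names = FALSE)
  obs <- read_observations(f)
  expect_equal(obs$distance_m, c(0.015, 0.175))
  f2 <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(distance_cm = 1), f2, row.names = FALSE)
  expect_error(read_observations(f2), "bbc_percent")
})
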