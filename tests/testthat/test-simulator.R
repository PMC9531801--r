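test_that("emission sampling is deterministic and honors the size law", {
  m0 <- emission_model(count = 0)
  expect_equal(nrow(sample_droplets(m0)), 0L)

  m <- emission_model(count = 5000, seed = 42)
  a <- sample_droplets(m)
  b <- sample_droplets(m)
  expect_identical(a, b)
  expect_true(all(a$radius * 2e6 >= m$min_diameter))
  expect_true(all(a$angle >= m$angle_low & a$angle <= m$angle_high))
  expect_true(all(a$speed == m$speed))

  # sample mean diameter vs. quadrature mean of the truncated lognormal
  big <- sample_droplets(emission_model(count = 100000, seed = 1))
  d_um <- big$radius * 2e6
  mu <- truncated_lognormal_mean(54.0, 52.3, 7)
  se <- sd(d_um) / sqrt(length(d_um))
  expect_lt(abs(mean(d_um) - mu), 3 * se)
})

test_that("empirical diameter lists are resampled with replacement", {
  m <- emission_model(diameters = c(20, 40, 80), count = 1000, seed = 3)
  d <- sample_droplets(m)
  expect_true(all(round(d$radius * 2e6, 9) %in% c(20, 40, 80)))
  expect_error(emission_model(diameters = numeric(0)), "empty")
})

test_that("barrier interaction applies the two-parameter cloth model", {
  d <- droplet(rep(1e-4, 1000), speed = 2, angle = 0)
  all_blocked <- barrier_interaction(d, barrier(0.1, p = 0, f = 0.5),
                                     u = runif(1000))
  expect_false(any(all_blocked$passed))
  transparent <- barrier_interaction(d, barrier(0.1, p = 1, f = 1),
                                     u = runif(1000))
  expect_true(all(transparent$passed))
  expect_equal(transparent$speed, d$speed)

  half <- barrier_interaction(d, barrier(0.1, p = 0.5, f = 0.25),
                              u = runif(1000))
  expect_equal(half$speed[half$passed], rep(0.5, sum(half$passed)))
  expect_equal(half$speed[!half$passed], rep(2, sum(!half$passed)))

  # pass fraction within 3 binomial SE of p at n = 1e5
  set.seed(11)
  n <- 100000
  big <- barrier_interaction(droplet(rep(1e-4, n), speed = 1),
                             barrier(0.1, p = 0.5, f = 1), u = runif(n))
  expect_lt(abs(mean(big$passed) - 0.5), 3 * sqrt(0.25 / n))
  expect_error(barrier(0.1, p = 1.2, f = 0.5), "p")
  expect_error(barrier(0.1, p = 0.5, f = -0.1), "f")
})

test_that("simulation fates are exhaustive and conserve volume", {
  m <- emission_model(count = 20000, seed = 5)
  for (mode in c("bernoulli", "weighted")) {
    rec <- simulate_experiment(m, barriers = barrier(0.1, 0.3, 0.7),
                               barrier_mode = mode)
    expect_false(any(is.na(rec$fate)))
    if (mode == "bernoulli") expect_equal(nrow(rec), 20000L)
    emitted <- sum(droplet_volume(sample_droplets(m)$radius))
    expect_equal(sum(rec$volume_m3), emitted, tolerance = 1e-12)
  }
})

test_that("an opaque barrier stops everything; a transparent one is a no-op", {
  m <- emission_model(count = 20000, seed = 9)
  opaque <- simulate_experiment(m, barriers = barrier(0.1, p = 0, f = 0.5))
  expect_equal(sum(opaque$fate %in% c("hit_roi", "hit_screen")), 0L)

  free <- simulate_experiment(m)
  thru <- simulate_experiment(m, barriers = barrier(0.1, p = 1, f = 1))
  keep <- c("radius_m", "y_m", "speed_m_s", "fate")
  expect_equal(thru[keep], free[keep], tolerance = 1e-9)
})

test_that("free-flight stalling agrees with the closed-form range per droplet", {
  m <- emission_model(count = 20000, seed = 13)
  geo <- experiment_geometry()
  rec <- simulate_experiment(m, geo)
  drops <- sample_droplets(m, origin = c(0, geo$nozzle_height))
  rng <- max_horizontal_range(drops, fluid_environment())
  expect_identical(rec$fate == "stalled", rng < geo$screen_distance)
})

test_that("simulations are reproducible byte for byte", {
  m <- emission_model(count = 5000, seed = 21)
  b <- barrier(0.05, 0.4, 0.6)
  expect_identical(simulate_experiment(m, barriers = b),
                   simulate_experiment(m, barriers = b))
  expect_identical(
    simulate_experiment(m, barriers = b, barrier_mode = "weighted"),
    simulate_experiment(m, barriers = b, barrier_mode = "weighted"))
})

test_that("SBBC boundary identities hold", {
  m <- emission_model(count = 20000, seed = 2)
  free <- simulate_experiment(m)
  expect_equal(sbbc(free, free), 0)
  opaque <- simulate_experiment(m, barriers = barrier(0.1, p = 0, f = 0.5))
  expect_equal(sbbc(opaque, free), 100)
  none <- simulate_experiment(emission_model(count = 10, seed = 2,
                                             diameters = 10)) # all stall
  expect_error(sbbc(free, none), "volume")
})

test_that("SBBC falls as the barrier moves from nozzle to screen (CRN)", {
  m <- emission_model(count = 50000, seed = 4)
  free <- simulate_experiment(m)
  vals <- vapply(default_barrier_positions(), function(d)
    sbbc(simulate_experiment(m, barriers = barrier(d, 0.2, 0.5),
                             barrier_mode = "weighted"), free),
    numeric(1))
  expect_true(all(diff(vals) <= 0))
  # source-side placement blocks at least as much as receiver-side
  expect_gte(vals[1], vals[length(vals)])
})

test_that("two stacked barriers block at least as much as either alone", {
  m <- emission_model(count = 30000, seed = 8)
  free <- simulate_experiment(m)
  b1 <- barrier(0.175, 0.3, 0.6)
  b4 <- barrier(0.015, 0.3, 0.6)
  s1 <- sbbc(simulate_experiment(m, barriers = b1,
                                 barrier_mode = "weighted"), free)
  s14 <- sbbc(simulate_experiment(m, barriers = list(b1, b4),
                                  barrier_mode = "weighted"), free)
  expect_gte(s14, s1)
  expect_lte(s14, 100)
})
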