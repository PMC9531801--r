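test_that("binarization maps stains to 1 under either polarity", {
  # constructed half-stain image: exactly half the pixels dark
  px <- matrix(0.9, 40, 40)
  px[1:20, ] <- 0.1
  bin <- binarize(scan_image(px, 600))
  expect_equal(mean(bin), 0.5)
  # inverted polarity: bright stains
  bin2 <- binarize(scan_image(1 - px, 600), stains_dark = FALSE)
  expect_equal(bin2, bin)
  # fixed threshold policy
  bin3 <- binarize(px, policy = "fixed", threshold = 0.5)
  expect_equal(bin3, bin)
  # uniform image: no threshold exists, fall back to "no stains"
  expect_warning(b0 <- binarize(scan_image(matrix(0.7, 10, 10), 600)),
                 "uniform")
  expect_equal(sum(b0), 0)
})

test_that("a rendered disk binarizes to its ground-truth area", {
  mask <- raster_disks(cbind(60, 60), diameters_um = 2 * 20 * 25400 / 600,
                       dpi = 600, 120, 120) # 20 px radius disk
  bin <- binarize(scan_image(as_gray(mask), 600))
  expect_lt(abs(sum(bin) - pi * 20^2) / (pi * 20^2), 0.05)
})

test_that("mean pixel fraction is the plain average, ROI-restricted", {
  expect_equal(mean_pixel_fraction(matrix(0L, 5, 5)), 0)
  expect_equal(mean_pixel_fraction(matrix(1L, 5, 5)), 1)
  checker <- matrix(c(0L, 1L), 6, 6)
  expect_equal(mean_pixel_fraction(checker), 0.5)
  roi <- matrix(FALSE, 6, 6); roi[1:3, ] <- TRUE
  expect_equal(mean_pixel_fraction(checker, roi), mean(checker[1:3, ]))
  expect_error(mean_pixel_fraction(checker, matrix(FALSE, 6, 6)), "ROI")
  expect_error(mean_pixel_fraction(matrix(0.5, 2, 2)), "binary")
})

test_that("stain detection finds 8-connected components above min_area", {
  expect_equal(nrow(detect_stains(matrix(0L, 10, 10), 600)), 0L)

  # two disjoint disks: exact count, diameters within one pixel-equivalent
  px_um <- 25400 / 600
  d1 <- 30 * px_um; d2 <- 16 * px_um
  mask <- raster_disks(rbind(c(40, 40), c(40, 110)), c(d1, d2), 600, 80, 150)
  st <- detect_stains(mask, 600)
  expect_equal(nrow(st), 2L)
  got <- sort(st$eq_diameter_um)
  expect_lt(abs(got[1] - d2), px_um)
  expect_lt(abs(got[2] - d1), px_um)
  # centroids at the rendered centers (within a pixel)
  expect_equal(sort(st$centroid_x_px), c(40, 110), tolerance = 0.05)

  # a diagonal pair is one stain under 8-connectivity
  diag2 <- matrix(0L, 5, 5); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(nrow(detect_stains(diag2, 600, min_area = 1)), 1L)

  # below the area filter, nothing is reported
  tiny <- matrix(0L, 10, 10); tiny[5, 5] <- 1L; tiny[5, 6] <- 1L
  expect_equal(nrow(detect_stains(tiny, 600, min_area = 3)), 0L)
  expect_equal(nrow(detect_stains(tiny, 600, min_area = 2)), 1L)
})

test_that("stain statistics summarize equivalent diameters", {
  fake <- function(d_um) {
    p <- data.frame(centroid_x_px = seq_along(d_um),
                    centroid_y_px = seq_along(d_um),
                    area_px2 = rep(1, length(d_um)), eq_diameter_um = d_um)
    class(p) <- c("stain_pattern", "data.frame")
    p
  }
  one <- stain_statistics(fake(12))
  expect_equal(one$sd_um, 0)
  s <- stain_statistics(fake(c(10, 20, 30)))
  expect_equal(s$mean_um, 20)
  expect_equal(s$min_um, 10)
  expect_equal(s$max_um, 30)
  expect_equal(s$count, 3L)
  # population vs sample divisor
  expect_equal(s$sd_um, sd(c(10, 20, 30)) * sqrt(2 / 3))
  expect_equal(stain_statistics(fake(c(10, 20, 30)), "n-1")$sd_um,
               sd(c(10, 20, 30)))
  empty <- stain_statistics(fake(numeric(0)))
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$mean_um))
})

test_that("detected size statistics recover a known diameter sample", {
  set.seed(31)
  n <- 200
  d_um <- exp(rnorm(n, log(300), 0.25)) # well above pixel pitch at 1200 dpi
  px_um <- 25400 / 1200
  # non-overlapping grid placement
  step <- ceiling(max(d_um) / px_um) + 4
  rows <- ((seq_len(n) - 1) %% 14) * step + step / 2
  cols <- ((seq_len(n) - 1) %/% 14) * step + step / 2
  side_r <- 14 * step; side_c <- (ceiling(n / 14)) * step
  mask <- raster_disks(cbind(rows, cols), d_um, 1200, side_r, side_c)
  st <- detect_stains(mask, 1200)
  expect_equal(nrow(st), n)
  se <- sd(d_um) / sqrt(n)
  # 3 SE plus a one-pixel quantization allowance
  expect_lt(abs(mean(st$eq_diameter_um) - mean(d_um)), 3 * se + px_um)
})

test_that("BBC reproduces the boundary identities and simple arithmetic", {
  px_um <- 25400 / 600
  mk <- function(k) {
    mask <- raster_disks(cbind(30 + 10 * k, 40), 24 * px_um, 600, 100, 100)
    scan_image(as_gray(mask), 600)
  }
  ref <- lapply(1:3, mk)
  blank <- lapply(1:3, function(i) scan_image(matrix(0.9, 100, 100), 600))

  r100 <- suppressWarnings(compute_bbc(blank, ref))
  expect_equal(r100$bbc, 100)
  r0 <- compute_bbc(ref, ref)
  expect_equal(r0$bbc, 0)

  # constructed fractions 0.1 vs 0.2 => 50%
  f01 <- matrix(0, 100, 100); f01[1:10, ] <- 1
  f02 <- matrix(0, 100, 100); f02[1:20, ] <- 1
  r50 <- compute_bbc(scan_image(1 - f01 * 0.8, 600),
                     scan_image(1 - f02 * 0.8, 600))
  expect_equal(r50$bbc, 50)
  expect_equal(r50$mean_pixel_obstacle, 0.1)

  expect_error(suppressWarnings(compute_bbc(ref, blank)), "reference")
})

test_that("BBC is invariant under intensity changes that keep the split", {
  px_um <- 25400 / 600
  mask_a <- raster_disks(cbind(50, 50), 30 * px_um, 600, 100, 100)
  mask_b <- raster_disks(rbind(c(30, 30), c(70, 70)), c(30, 22) * px_um,
                         600, 100, 100)
  bbc1 <- compute_bbc(scan_image(as_gray(mask_a, 0.1, 0.9), 600),
                      scan_image(as_gray(mask_b, 0.1, 0.9), 600))$bbc
  bbc2 <- compute_bbc(scan_image(as_gray(mask_a, 0.3, 0.7), 600),
                      scan_image(as_gray(mask_b, 0.3, 0.7), 600))$bbc
  expect_equal(bbc1, bbc2)
})

test_that("replicate uncertainty propagation matches hand arithmetic", {
  expect_equal(propagate_bbc_uncertainty(c(0.1, 0.1), c(0.2, 0.2)), 0)
  expect_equal(propagate_bbc_uncertainty(c(0, 0), c(0.2, 0.3)), 0)
  expect_true(is.na(propagate_bbc_uncertainty(0.1, c(0.2, 0.2))))
  # hand-computed: 100 * 0.55 * (0.02/sqrt(2)) / (0.11 * sqrt(2)) = 5.0
  expect_equal(propagate_bbc_uncertainty(c(0.10, 0.12), c(0.20, 0.20)), 5.0)
})

test_that("scan IO round-trips through PNG and manifests resolve paths", {
  dir <- withr::local_tempdir()
  px <- matrix(runif(400), 20, 20)
  img <- scan_image(px, 600, "free", 1L)
  write_scan(img, file.path(dir, "a.png"))
  back <- read_scan(file.path(dir, "a.png"), 600, "free", 1L)
  expect_equal(back$pixels, px, tolerance = 0.01)

  utils::write.csv(data.frame(path = "a.png", configuration = "free",
                              replicate = 1, dpi = 600),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_true(file.exists(m$path[1]))
  grp <- load_scan_group(m, "free")
  expect_length(grp, 1L)
  expect_error(load_scan_group(m, "nope"), "no scans")
  utils::write.csv(data.frame(path = "a.png"), file.path(dir, "bad.csv"),
                   row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad.csv")), "configuration")
})
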