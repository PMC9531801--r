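#' Scanned stain image
#'
#' A grayscale scan of the stain pattern on the screen: a matrix of
#' intensities in [0, 1], its scanner resolution, and provenance labels.
#'
#' @param pixels Numeric matrix of grayscale intensities in [0, 1].
#' @param dpi Scanner resolution, dots per inch. Must be > 0.
#' @param configuration,replicate Optional provenance labels.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, dpi, configuration = NA_character_,
                       replicate = NA_integer_) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  if (dpi <= 0) stop("dpi must be > 0")
  structure(list(pixels = pixels, dpi = dpi,
                 configuration = configuration, replicate = replicate),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("scan_image: %d x %d px at %g dpi (%s, replicate %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$dpi,
              x$configuration, x$replicate))
  invisible(x)
}

#' Read a scan from PNG or TIFF
#'
#' Reads a grayscale scan; RGB(A) input is collapsed to luminance by
#' channel averaging.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param dpi Scanner resolution (PNG and most TIFFs do not carry it).
#' @inheritParams scan_image
#' @return A [scan_image()].
#' @export
read_scan <- function(path, dpi, configuration = NA_character_,
                      replicate = NA_integer_) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported scan format: .", ext))
  if (length(dim(px)) == 3L) px <- rowMeans(px[, , 1:min(3, dim(px)[3]),
                                               drop = FALSE], dims = 2)
  scan_image(px, dpi, configuration, replicate)
}

#' Write a scan to PNG
#'
#' @param image A [scan_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_scan <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Binarize a scan
#'
#' Maps stain pixels to 1 and background to 0. The threshold is picked by
#' Otsu's method by default, or fixed. Scans can come with either ink
#' polarity (stains darker than paper, or a binarized scan where hit areas
#' are light); the `stains_dark` flag selects which side of the threshold
#' is the stain. A perfectly uniform image has no Otsu threshold and is
#' returned as all background with a warning.
#'
#' @param image A [scan_image()] or a plain intensity matrix in [0, 1].
#' @param policy `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `policy = "fixed"`.
#' @param stains_dark `TRUE` when stains are darker than the background.
#' @return An integer 0/1 matrix of the same dimension (1 = stain).
#' @export
binarize <- function(image, policy = c("otsu", "fixed"), threshold = 0.5,
                     stains_dark = TRUE) {
  policy <- match.arg(policy)
  px <- if (inherits(image, "scan_image")) image$pixels else image
  if (!is.matrix(px)) stop("binarize expects a scan_image or a matrix")
  if (policy == "otsu") {
    if (diff(range(px)) == 0) {
      warning("uniform image: no Otsu threshold, returning all background")
      return(matrix(0L, nrow(px), ncol(px)))
    }
    threshold <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  }
  bin <- if (stains_dark) px < threshold else px > threshold
  matrix(as.integer(bin), nrow(px), ncol(px))
}

#' Mean pixel fraction of a binary image
#'
#' The arithmetic mean of the 0/1 pixel values, i.e. the fraction of the
#' (ROI of the) image covered by stains — the quantity averaged over
#' replicates in the blocking statistic.
#'
#' @param binary A 0/1 matrix from [binarize()].
#' @param roi Optional logical mask of the same dimension restricting the
#'   average.
#' @return A fraction in [0, 1].
#' @export
mean_pixel_fraction <- function(binary, roi = NULL) {
  if (!all(binary %in% c(0L, 1L))) stop("input must be binary (0/1)")
  if (is.null(roi)) return(mean(binary))
  if (!identical(dim(roi), dim(binary)))
    stop("roi mask must match the image dimensions")
  if (!any(roi)) stop("empty ROI")
  mean(binary[roi])
}

#' Detect stains as connected components
#'
#' Labels 8-connected foreground components, discards those below
#' `min_area` pixels (scanner noise), and reports each stain's centroid,
#' pixel area and equivalent-disk diameter: stains are treated as disks of
#' the same area, so `d = 2 sqrt(A / pi)` with A converted to physical
#' units through the dpi scale.
#'
#' @param binary A 0/1 matrix from [binarize()].
#' @param dpi Scanner resolution, dots per inch.
#' @param min_area Minimum component area in pixels (default 3).
#' @return A data frame of class `stain_pattern` with columns
#'   `centroid_x_px`, `centroid_y_px`, `area_px2`, `eq_diameter_um`, and
#'   attributes `dpi`, `min_area`.
#' @export
detect_stains <- function(binary, dpi, min_area = 3) {
  if (!all(binary %in% c(0L, 1L))) stop("input must be binary (0/1)")
  if (dpi <= 0) stop("dpi must be > 0")
  lab <- .label8(binary > 0)
  px_um <- 25400 / dpi
  out <- data.frame(centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                    area_px2 = numeric(0), eq_diameter_um = numeric(0))
  if (max(lab) > 0L) {
    fg <- which(lab > 0L)
    l <- lab[fg]
    area <- tabulate(l)
    # row = y (scan line), col = x
    rr <- (fg - 1L) %% nrow(lab) + 1L
    cc <- (fg - 1L) %/% nrow(lab) + 1L
    cx <- rowsum(as.numeric(cc), l)[, 1] / area
    cy <- rowsum(as.numeric(rr), l)[, 1] / area
    keep <- area >= min_area
    out <- data.frame(centroid_x_px = cx[keep], centroid_y_px = cy[keep],
                      area_px2 = area[keep],
                      eq_diameter_um = 2 * sqrt(area[keep] * px_um^2 / pi))
    rownames(out) <- NULL
  }
  class(out) <- c("stain_pattern", "data.frame")
  attr(out, "dpi") <- dpi
  attr(out, "min_area") <- min_area
  out
}

#' Stain size statistics
#'
#' Mean, SD, minimum and maximum of the equivalent-disk diameters of a
#' detected stain pattern. The SD uses the population divisor n by default
#' (switchable to the sample divisor n - 1).
#'
#' @param pattern A `stain_pattern` from [detect_stains()].
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return A list with `count`, `mean_um`, `sd_um`, `min_um`, `max_um`
#'   (all `NA` except `count` when the pattern is empty).
#' @export
stain_statistics <- function(pattern, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  d <- pattern$eq_diameter_um
  n <- length(d)
  if (n == 0L)
    return(list(count = 0L, mean_um = NA_real_, sd_um = NA_real_,
                min_um = NA_real_, max_um = NA_real_))
  s <- if (n == 1L) 0 else stats::sd(d)
  if (sd_divisor == "n" && n > 1L) s <- s * sqrt((n - 1) / n)
  list(count = n, mean_um = mean(d), sd_um = s, min_um = min(d),
       max_um = max(d))
}

#' Replicate-propagated uncertainty of the blocking statistic
#'
#' First-order propagation of replicate scatter through the ratio in the
#' blocking formula:
#' `sigma = 100 (po/pno) sqrt((s_o/(po sqrt(n_o)))^2 +
#' (s_no/(pno sqrt(n_no)))^2)` with `s` the sample SD of the per-replicate
#' mean pixel fractions. Undefined (NA) with fewer than 2 replicates in
#' either group; 0 when the obstacle group mean is 0.
#'
#' @param obstacle_fractions,reference_fractions Per-replicate mean pixel
#'   fractions.
#' @return Uncertainty in percentage points, or `NA` when undefined.
#' @export
propagate_bbc_uncertainty <- function(obstacle_fractions,
                                      reference_fractions) {
  n_o <- length(obstacle_fractions); n_no <- length(reference_fractions)
  if (n_o < 2L || n_no < 2L) return(NA_real_)
  po <- mean(obstacle_fractions); pno <- mean(reference_fractions)
  if (pno <= 0) stop("reference group mean pixel fraction must be > 0")
  if (po == 0) return(0)
  s_o <- stats::sd(obstacle_fractions)
  s_no <- stats::sd(reference_fractions)
  100 * (po / pno) * sqrt((s_o / po / sqrt(n_o))^2 +
                          (s_no / pno / sqrt(n_no))^2)
}

#' Ballistic Blocking Capacity from scan groups
#'
#' The blocking statistic computed from stain scans: each image is
#' binarized, its mean pixel fraction taken, fractions averaged within the
#' obstacle and reference (no obstacle) groups, and
#' `BBC = (1 - <po>/<pno>) x 100`. BBC is 100% when the obstacle stopped
#' every droplet (blank obstacle scans) and 0% when the obstacle group
#' matches the reference; it can go negative if the obstacle scans are
#' denser. The uncertainty is the replicate-propagated rule of
#' [propagate_bbc_uncertainty()].
#'
#' @param obstacle_images,reference_images A [scan_image()] or list of them
#'   (replicates of the same configuration).
#' @param policy,threshold,stains_dark Binarization settings, see
#'   [binarize()].
#' @return An object of class `bbc_result`: list with `bbc`, `sigma`
#'   (percent), `mean_pixel_obstacle`, `mean_pixel_no_obstacle`,
#'   per-replicate fractions and replicate counts.
#' @export
compute_bbc <- function(obstacle_images, reference_images,
                        policy = c("otsu", "fixed"), threshold = 0.5,
                        stains_dark = TRUE) {
  policy <- match.arg(policy)
  as_group <- function(x) if (inherits(x, "scan_image")) list(x) else x
  obstacle_images <- as_group(obstacle_images)
  reference_images <- as_group(reference_images)
  if (!length(obstacle_images) || !length(reference_images))
    stop("each group needs at least one image")
  frac <- function(img)
    mean_pixel_fraction(binarize(img, policy, threshold, stains_dark))
  f_o <- vapply(obstacle_images, frac, numeric(1))
  f_no <- vapply(reference_images, frac, numeric(1))
  po <- mean(f_o); pno <- mean(f_no)
  if (pno <= 0)
    stop("no droplets detected in the free configuration (reference mean 0)")
  structure(list(bbc = (1 - po / pno) * 100,
                 sigma = propagate_bbc_uncertainty(f_o, f_no),
                 mean_pixel_obstacle = po,
                 mean_pixel_no_obstacle = pno,
                 obstacle_fractions = f_o,
                 reference_fractions = f_no,
                 n_obstacle = length(f_o),
                 n_reference = length(f_no)),
            class = "bbc_result")
}

#' @export
print.bbc_result <- function(x, ...) {
  cat(sprintf("BBC = %.2f%%%s  (<po> = %.4g over %d, <pno> = %.4g over %d)\n",
              x$bbc,
              if (is.na(x$sigma)) "" else sprintf(" +/- %.2f", x$sigma),
              x$mean_pixel_obstacle, x$n_obstacle,
              x$mean_pixel_no_obstacle, x$n_reference))
  invisible(x)
}

#' Read a scan manifest
#'
#' A manifest CSV lists one scan per row with columns `path`,
#' `configuration`, `replicate`, `dpi`. Paths are resolved relative to the
#' manifest location.
#'
#' @param path Manifest CSV path.
#' @return A data frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "configuration", "replicate", "dpi")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load the scans of one configuration from a manifest
#'
#' @param manifest Data frame from [read_manifest()].
#' @param configuration Configuration id to load.
#' @return A list of [scan_image()]s.
#' @export
load_scan_group <- function(manifest, configuration) {
  rows <- manifest[manifest$configuration == configuration, , drop = FALSE]
  if (!nrow(rows)) stop("no scans for configuration: ", configuration)
  lapply(seq_len(nrow(rows)), function(i)
    read_scan(rows$path[i], rows$dpi[i], rows$configuration[i],
              rows$replicate[i]))
}
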