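#' Simulate an Oil-Red-O-stained wood section image
#'
#' Builds a synthetic RGB micrograph of an ORO-stained section: red lipid
#' droplets (non-overlapping disks with radii drawn from the given range) on
#' a pale wood-tissue background. Disks are added until the realized pixel
#' coverage is within 0.02 percentage points of the target; near the target
#' the droplet radius is shrunk toward the minimum so the deficit can be
#' closed. The realized coverage (by exact pixel count) is recorded as the
#' ground truth.
#'
#' @param true_coverage_pct Target areal droplet coverage, percent (0-50).
#' @param droplet_radius_um Length-2 range of droplet radii, um; the minimum
#'   must map to at least 1 px at the given scale.
#' @param um_per_px Physical scale, um per pixel.
#' @param size_px Image size `c(width, height)`, px.
#' @param seed Integer seed (same seed, identical image).
#' @param max_attempts Consecutive rejected placements tolerated before the
#'   target is declared unreachable (packing limit).
#' @return A list of class `oro_image`: `pixels` (H x W x 3 array in
#'   \[0, 1\]), `um_per_px`, `true_coverage_pct` (realized, percent).
#' @examples
#' img <- simulate_oro_image(1, c(20, 60), um_per_px = 10,
#'                           size_px = c(600, 300), seed = 1)
#' img$true_coverage_pct
#' @export
simulate_oro_image <- function(true_coverage_pct, droplet_radius_um = c(20, 60),
                               um_per_px = 10, size_px = c(3000, 600),
                               seed = 1L, max_attempts = 5000L) {
  stopifnot(true_coverage_pct >= 0, true_coverage_pct <= 50,
            length(droplet_radius_um) == 2,
            droplet_radius_um[1] <= droplet_radius_um[2],
            um_per_px > 0, length(size_px) == 2, all(size_px >= 8))
  r_min <- droplet_radius_um[1] / um_per_px
  r_max <- droplet_radius_um[2] / um_per_px
  if (r_min < 1) stop("minimum droplet radius below 1 px", call. = FALSE)

  w <- as.integer(size_px[1]); h <- as.integer(size_px[2])
  n_px <- as.numeric(w) * h
  mask <- matrix(FALSE, nrow = h, ncol = w)

  withr::with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 3) # cx, cy, r
    covered <- 0
    rejects <- 0L
    while ((true_coverage_pct - covered / n_px * 100) > 0.02) {
      deficit_px <- (true_coverage_pct / 100) * n_px - covered
      r_cap <- max(r_min, min(r_max, sqrt(deficit_px / pi)))
      r <- runif(1, r_min, r_cap)
      cx <- runif(1, r + 1, w - r)
      cy <- runif(1, r + 1, h - r)
      if (nrow(centers) > 0 &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
              (centers[, 3] + r)^2)) {
        rejects <- rejects + 1L
        if (rejects >= max_attempts)
          stop("target coverage unreachable (disk packing limit)", call. = FALSE)
        next
      }
      rejects <- 0L
      centers <- rbind(centers, c(cx, cy, r))
      xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
      ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
      disk <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
      added <- disk & !mask[ys, xs, drop = FALSE]
      covered <- covered + sum(added)
      mask[ys, xs] <- mask[ys, xs] | disk
    }
  })

  bg <- c(0.96, 0.93, 0.88)
  fg <- c(0.80, 0.10, 0.10)
  pixels <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) pixels[, , ch] <- ifelse(mask, fg[ch], bg[ch])

  structure(
    list(pixels = pixels, um_per_px = um_per_px,
         true_coverage_pct = covered / n_px * 100),
    class = "oro_image"
  )
}

#' Threshold an ORO image into a lipid mask
#'
#' A pixel is classified as lipid-stained when its red channel dominates:
#' `R - max(G, B) > threshold` on the 8-bit channel scale. The ORO stain is
#' strongly red against the pale wood background, so a simple red-dominance
#' rule separates droplets cleanly; the threshold is exposed because real
#' captures vary in illumination.
#'
#' @param image An `oro_image` or an H x W x 3 RGB array in \[0, 1\].
#' @param red_threshold Red-dominance threshold on 0-255 channels.
#' @return Logical H x W matrix (TRUE = lipid).
#' @examples
#' img <- simulate_oro_image(1, c(20, 60), 10, c(400, 200), seed = 1)
#' mean(stain_mask(img)) * 100 # ~1 percent
#' @export
stain_mask <- function(image, red_threshold = 50) {
  px <- if (inherits(image, "oro_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] < 3)
    stop("RGB image required (grayscale input?)", call. = FALSE)
  r <- px[, , 1] * 255
  gb <- pmax(px[, , 2], px[, , 3]) * 255
  (r - gb) > red_threshold
}

#' ROI sampling specification
#'
#' The field protocol samples 50 random regions of interest of 0.25 mm^2 in
#' each of ten contiguous 3-mm sections from bark to pith (500 ROIs over
#' 3 cm of wood).
#'
#' @param roi_area_mm2 ROI area, mm^2 (square ROIs, side `sqrt(area)`).
#' @param n_per_section ROIs per section.
#' @param section_width_mm Section width along the bark-to-pith axis, mm.
#' @param n_sections Number of sections.
#' @param seed Integer seed for ROI placement.
#' @return A validated list of class `roi_spec`.
#' @export
roi_spec <- function(roi_area_mm2 = 0.25, n_per_section = 50,
                     section_width_mm = 3, n_sections = 10, seed = 1L) {
  stopifnot(roi_area_mm2 > 0, n_per_section >= 1, section_width_mm > 0,
            n_sections >= 1)
  if (sqrt(roi_area_mm2) > section_width_mm)
    stop("ROI side exceeds the section width", call. = FALSE)
  structure(
    list(roi_area_mm2 = roi_area_mm2, n_per_section = as.integer(n_per_section),
         section_width_mm = section_width_mm, n_sections = as.integer(n_sections),
         seed = as.integer(seed)),
    class = "roi_spec"
  )
}

#' Areal lipid coverage by random-ROI sampling
#'
#' Reproduces the field estimator: the bark-to-pith axis (image columns) is
#' partitioned into `n_sections` contiguous sections of `section_width_mm`;
#' in each section `n_per_section` square ROIs are placed uniformly at
#' random (fully inside the section; independent placement, overlaps
#' allowed); per-ROI coverage is the lipid-pixel fraction; the section
#' estimate is the mean over its ROIs and the overall estimate the mean over
#' all ROIs. ROI sums use a summed-area table, so the cost is independent of
#' ROI size.
#'
#' @param mask Logical matrix from [stain_mask()].
#' @param um_per_px Physical scale, um per pixel.
#' @param spec A [roi_spec()].
#' @return A list of class `coverage_result`: `mean_coverage_pct`, `sd_pct`
#'   (SD over ROIs), `se_pct` (standard error of the mean), `per_section`
#'   tibble, `n_rois`, and `roi_pct` (all per-ROI values).
#' @export
roi_coverage <- function(mask, um_per_px, spec = roi_spec()) {
  stopifnot(is.matrix(mask), is.logical(mask), um_per_px > 0)
  h <- nrow(mask); w <- ncol(mask)
  side_px <- max(1L, round(sqrt(spec$roi_area_mm2) * 1000 / um_per_px))
  sec_px <- round(spec$section_width_mm * 1000 / um_per_px)
  if (side_px > sec_px) stop("ROI larger than a section", call. = FALSE)
  if (w < spec$n_sections * sec_px)
    stop("mask too narrow for the requested sections", call. = FALSE)
  if (side_px > h) stop("ROI taller than the image", call. = FALSE)

  # summed-area table with zero padding
  sat <- matrix(0, h + 1L, w + 1L)
  sat[-1L, -1L] <- apply(apply(mask, 2L, cumsum), 1L, cumsum) |> t()

  roi_sum <- function(y0, x0) { # top-left corners, 1-based
    sat[y0 + side_px, x0 + side_px] - sat[y0, x0 + side_px] -
      sat[y0 + side_px, x0] + sat[y0, x0]
  }

  withr::with_seed(spec$seed, {
    section <- rep(seq_len(spec$n_sections), each = spec$n_per_section)
    x_lo <- (section - 1L) * sec_px + 1L
    x0 <- x_lo + floor(runif(length(section)) * (sec_px - side_px + 1L))
    y0 <- 1L + floor(runif(length(section)) * (h - side_px + 1L))
    vals <- vapply(seq_along(section),
                   function(i) roi_sum(y0[i], x0[i]), numeric(1))
  })
  roi_pct <- vals / side_px^2 * 100

  sec_means <- as.numeric(tapply(roi_pct,
                                 factor(section, seq_len(spec$n_sections)),
                                 mean))
  per_section <- tibble(section = seq_len(spec$n_sections),
                        mean_coverage_pct = sec_means)
  structure(
    list(mean_coverage_pct = mean(roi_pct),
         sd_pct = sd(roi_pct),
         se_pct = sd(roi_pct) / sqrt(length(roi_pct)),
         per_section = per_section,
         n_rois = length(roi_pct),
         roi_pct = roi_pct),
    class = "coverage_result"
  )
}

#' Write / read an ORO image as PNG with a scale sidecar
#'
#' @param image An `oro_image`.
#' @param path PNG path; the sidecar CSV (`<path>.csv`) records the scale
#'   and ground-truth coverage.
#' @return `write_oro_image` returns `path` invisibly; `read_oro_image`
#'   returns an `oro_image`.
#' @export
write_oro_image <- function(image, path) {
  stopifnot(inherits(image, "oro_image"))
  png::writePNG(image$pixels, target = path)
  readr::write_csv(tibble(um_per_px = image$um_per_px,
                          true_coverage_pct = image$true_coverage_pct),
                   paste0(path, ".csv"))
  invisible(path)
}

#' @rdname write_oro_image
#' @export
read_oro_image <- function(path) {
  px <- png::readPNG(path)
  meta <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  structure(list(pixels = px, um_per_px = meta$um_per_px[1],
                 true_coverage_pct = meta$true_coverage_pct[1]),
            class = "oro_image")
}
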