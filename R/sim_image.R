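#' Configuration for synthetic microscopy images
#'
#' Cells are ellipses with a co-centred elliptical nucleus; a low-order
#' harmonic radial perturbation of amplitude `boundary_roughness` distorts
#' the boundaries (lowering circularity) and Gaussian noise is added to the
#' intensities.
#'
#' @param image_size_px Square image side, pixels.
#' @param pixel_size_um Physical pixel size, µm.
#' @param n_cells Number of cells to place without overlap.
#' @param nucleus_axes_px Nucleus semi-axes `c(major, minor)`, px.
#' @param cell_axes_px Cell semi-axes; defaults to 2.2x the nucleus axes.
#' @param boundary_roughness Relative amplitude of the radial perturbation
#'   (0 = smooth ellipse).
#' @param cell_intensity,nuclear_intensity,background_intensity Mean gray
#'   levels of cytoplasm, nucleus and background (all >= 0).
#' @param noise_sd Gaussian intensity noise s.d.
#' @param max_tries Placement retries per cell before a generation error.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size_px = 256,
                             pixel_size_um = 0.5,
                             n_cells = 5,
                             nucleus_axes_px = c(18, 12),
                             cell_axes_px = NULL,
                             boundary_roughness = 0,
                             cell_intensity = 50,
                             nuclear_intensity = 100,
                             background_intensity = 10,
                             noise_sd = 0,
                             max_tries = 200,
                             seed = NULL) {
  if (is.null(cell_axes_px)) cell_axes_px <- 2.2 * nucleus_axes_px
  cfg <- as.list(environment())
  if (any(c(cell_intensity, nuclear_intensity, background_intensity) < 0))
    stop("configuration error: intensities must be >= 0")
  if (n_cells < 0) stop("configuration error: n_cells must be >= 0")
  if (any(nucleus_axes_px <= 0) || any(cell_axes_px <= 0))
    stop("configuration error: axes must be > 0")
  if (any(nucleus_axes_px >= cell_axes_px))
    stop("configuration error: nucleus must fit inside the cell")
  if (boundary_roughness < 0 || boundary_roughness >= 1)
    stop("configuration error: boundary_roughness must be in [0, 1)")
  structure(cfg, class = "image_sim_config")
}

# pixel mask of a (possibly perturbed) ellipse on an n x n grid
ellipse_mask <- function(n, cx, cy, a, b, angle, roughness, phases) {
  x <- matrix(seq_len(n), n, n) - cx
  y <- matrix(seq_len(n), n, n, byrow = TRUE) - cy
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  if (roughness > 0) {
    phi <- atan2(yr / b, xr / a)
    bound <- 1 + roughness * (0.6 * sin(3 * phi + phases[1]) +
                              0.4 * sin(7 * phi + phases[2]))
  } else bound <- 1
  r <= bound
}

#' Simulate a labeled microscopy image with ground truth
#'
#' @param config An [image_sim_config()].
#' @return A `labeled_image`: list with `channels` (named list of intensity
#'   matrices; one channel `"intensity"`), `masks` (integer label matrices
#'   `cell`, `nucleus` and binary `background`; 0 = unlabeled),
#'   `pixel_size_um` and `truth` (per-object areas and expected integrated
#'   densities).
#' @export
simulate_image <- function(config = image_sim_config()) {
  stopifnot(inherits(config, "image_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$image_size_px
  cell_lab <- matrix(0L, n, n)
  nuc_lab <- matrix(0L, n, n)
  a_c <- config$cell_axes_px[1]; b_c <- config$cell_axes_px[2]
  a_n <- config$nucleus_axes_px[1]; b_n <- config$nucleus_axes_px[2]
  margin <- ceiling(a_c * (1 + config$boundary_roughness)) + 2
  if (config$n_cells > 0 && 2 * margin >= n)
    stop("generation error: cells do not fit in the image")
  for (i in seq_len(config$n_cells)) {
    placed <- FALSE
    for (try in seq_len(config$max_tries)) {
      cx <- stats::runif(1, margin, n - margin)
      cy <- stats::runif(1, margin, n - margin)
      ang <- stats::runif(1, 0, pi)
      ph <- stats::runif(4, 0, 2 * pi)
      cm <- ellipse_mask(n, cx, cy, a_c, b_c, ang, config$boundary_roughness,
                         ph[1:2])
      if (any(cell_lab[cm] != 0L)) next
      nm <- ellipse_mask(n, cx, cy, a_n, b_n, ang, config$boundary_roughness,
                         ph[3:4]) & cm   # nuclei stay inside their cells
      cell_lab[cm] <- i
      nuc_lab[nm] <- i
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generation error: could not place cell ", i,
           " without overlap after ", config$max_tries, " tries")
  }
  mean_img <- matrix(config$background_intensity, n, n)
  mean_img[cell_lab > 0L] <- config$cell_intensity
  mean_img[nuc_lab > 0L] <- config$nuclear_intensity
  img <- mean_img
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  ids <- seq_len(config$n_cells)
  truth <- data.frame(
    object_id = ids,
    cell_area_px = vapply(ids, function(i) sum(cell_lab == i), 0L),
    nucleus_area_px = vapply(ids, function(i) sum(nuc_lab == i), 0L),
    expected_integrated_density = vapply(ids, function(i)
      sum(mean_img[cell_lab == i]), 0))
  structure(list(channels = list(intensity = img),
                 masks = list(cell = cell_lab, nucleus = nuc_lab,
                              background = (cell_lab == 0L) * 1L),
                 pixel_size_um = config$pixel_size_um,
                 truth = truth),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("labeled_image: %d x %d px (%.3g um/px), %d cells\n",
              d[1], d[2], x$pixel_size_um, max(x$masks$cell)))
  invisible(x)
}

#' Write / read an image channel or label mask as TIFF
#'
#' Values are stored as 16-bit grayscale scaled by `max_value`, so integer
#' matrices (label masks, integer gray levels) with values in
#' `[0, max_value]` round-trip exactly; continuous intensities are quantized
#' to `max_value / 65535` steps.
#'
#' @param mat Numeric or integer matrix with values in `[0, max_value]`.
#' @param file Path.
#' @param max_value Full-scale value (default 65535, i.e. one unit per
#'   16-bit level).
#' @return `write_image_tiff` returns `file` invisibly; `read_image_tiff` a
#'   numeric matrix.
#' @export
write_image_tiff <- function(mat, file, max_value = 65535) {
  if (any(mat < 0 | mat > max_value))
    stop("I/O error: values outside [0, max_value]")
  tiff::writeTIFF(mat / max_value, file, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(file)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(file, max_value = 65535) {
  m <- tiff::readTIFF(file, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m * (max_value / 65535)
}
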