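#' Corrected total cell fluorescence
#'
#' For each labeled cell,
#' `CTCF = integrated density - area(cell) x mean(background intensity)`,
#' the standard background-corrected fluorescence measure. Adding a constant
#' to the whole image leaves CTCF unchanged, and scaling the image scales
#' CTCF proportionally.
#'
#' @param channel Numeric intensity matrix.
#' @param cell_mask Integer label matrix (0 = not a cell).
#' @param background_mask Matrix, non-zero over manually chosen background
#'   regions; must be non-empty and disjoint from `cell_mask`.
#' @return data.frame with columns `object_id`, `area_px`,
#'   `integrated_density`, `ctcf`.
#' @export
ctcf <- function(channel, cell_mask, background_mask) {
  stopifnot(all(dim(channel) == dim(cell_mask)),
            all(dim(channel) == dim(background_mask)))
  if (!any(background_mask > 0))
    stop("measurement error: empty background mask")
  if (!any(cell_mask > 0))
    stop("measurement error: empty cell mask")
  if (any(cell_mask > 0 & background_mask > 0))
    stop("measurement error: cell and background masks overlap")
  bg_mean <- mean(channel[background_mask > 0])
  ids <- sort(unique(cell_mask[cell_mask > 0]))
  area <- vapply(ids, function(i) sum(cell_mask == i), 0L)
  int_den <- vapply(ids, function(i) sum(channel[cell_mask == i]), 0)
  data.frame(object_id = ids, area_px = area, integrated_density = int_den,
             ctcf = int_den - area * bg_mean)
}

# closed polygon perimeter
polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Ramer-Douglas-Peucker polyline simplification (keeps endpoints)
rdp_simplify <- function(x, y, eps) {
  n <- length(x)
  if (n < 3 || eps <= 0) return(cbind(x, y))
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rg[1]; j <- rg[2]
    if (j - i < 2L) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    idx <- (i + 1L):(j - 1L)
    d <- if (len == 0)
      sqrt((x[idx] - x[i])^2 + (y[idx] - y[i])^2)
    else
      abs(dy * (x[idx] - x[i]) - dx * (y[idx] - y[i])) / len
    kmax <- idx[which.max(d)]
    if (max(d) > eps) {
      keep[kmax] <- TRUE
      stack <- c(stack, list(c(i, kmax)), list(c(kmax, j)))
    }
  }
  cbind(x[keep], y[keep])
}

#' Shape circularity of a labeled object
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, lower for elongated or
#' distorted shapes. The perimeter is measured on the object's traced
#' contour polygon (marching squares at the 0.5 level), simplified with a
#' Douglas-Peucker tolerance of `simplify_tol` pixels to suppress the
#' digitization staircase that would otherwise bias the perimeter upwards.
#' The result is clipped to `[0, 1.05]` (unit circularity plus digitization
#' slack).
#'
#' @param mask Integer label matrix, or logical/binary matrix.
#' @param object_id Label to measure; `NULL` measures all non-zero pixels as
#'   one object.
#' @param simplify_tol Contour simplification tolerance in pixels
#'   (default 0.8).
#' @return Circularity value. Single-pixel objects are reported as 1 with
#'   attribute `degenerate = TRUE`.
#' @export
circularity <- function(mask, object_id = NULL, simplify_tol = 0.8) {
  obj <- if (is.null(object_id)) mask > 0 else mask == object_id
  area <- sum(obj)
  if (area == 0) stop("measurement error: object has no pixels")
  if (area == 1) return(structure(1, degenerate = TRUE))
  # pad so contours close even when the object touches the image border
  padded <- matrix(0, nrow(obj) + 2L, ncol(obj) + 2L)
  padded[2:(nrow(obj) + 1L), 2:(ncol(obj) + 1L)] <- obj
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  per <- sum(vapply(cl, function(p) {
    sxy <- rdp_simplify(p$x, p$y, simplify_tol)
    polygon_perimeter(sxy[, 1], sxy[, 2])
  }, 0))
  min(max(4 * pi * area / per^2, 0), 1.05)
}

#' Nuclear vs cytoplasmic mean intensity
#'
#' Mean intensity over the nuclear mask (intersected with the cell-coverage
#' mask) and over the remaining covered pixels, the per-image quantities
#' used to compare nuclear and cytoplasmic protein levels when a DAPI mask
#' is subtracted from thresholded cell coverage.
#'
#' @param channel Numeric intensity matrix.
#' @param coverage_mask Matrix, non-zero where cells cover the field.
#' @param nuclear_mask Matrix, non-zero over nuclei.
#' @return list with `nuclear_mean`, `cytoplasmic_mean`, `n_nuclear_px`,
#'   `n_cytoplasmic_px`.
#' @export
nuclear_cytoplasmic_split <- function(channel, coverage_mask, nuclear_mask) {
  stopifnot(all(dim(channel) == dim(coverage_mask)),
            all(dim(channel) == dim(nuclear_mask)))
  nuc <- coverage_mask > 0 & nuclear_mask > 0
  cyt <- coverage_mask > 0 & !nuc
  if (!any(nuc)) stop("measurement error: empty nuclear region")
  if (!any(cyt))
    stop("measurement error: empty cytoplasmic region after nuclear subtraction")
  list(nuclear_mean = mean(channel[nuc]),
       cytoplasmic_mean = mean(channel[cyt]),
       n_nuclear_px = sum(nuc),
       n_cytoplasmic_px = sum(cyt))
}

#' Mean intensity within each labeled mask region
#'
#' @param channel Numeric intensity matrix.
#' @param mask Integer label matrix (0 = unlabeled).
#' @return data.frame with columns `object_id`, `mean_intensity`, `n_px`.
#' @export
masked_mean_intensity <- function(channel, mask) {
  stopifnot(all(dim(channel) == dim(mask)))
  if (!any(mask > 0)) stop("measurement error: empty mask")
  ids <- sort(unique(mask[mask > 0]))
  data.frame(object_id = ids,
             mean_intensity = vapply(ids, function(i)
               mean(channel[mask == i]), 0),
             n_px = vapply(ids, function(i) sum(mask == i), 0L))
}

#' 8-connected component labeling of a binary mask
#'
#' Iterative minimum-label propagation over the 8-neighborhood; compact for
#' the image sizes this package works with.
#'
#' @param bin Logical or 0/1 matrix.
#' @return Integer label matrix with consecutive labels from 1; 0 =
#'   background.
#' @export
label_components <- function(bin) {
  fg <- bin > 0
  n <- nrow(fg); m <- ncol(fg)
  lab <- matrix(Inf, n + 2L, m + 2L)
  core <- cbind(rep(2:(n + 1L), m), rep(2:(m + 1L), each = n))
  fg_idx <- core[as.vector(fg), , drop = FALSE]
  lab[fg_idx] <- which(as.vector(fg))
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  repeat {
    old <- lab
    for (k in seq_len(nrow(shifts))) {
      di <- shifts$di[k]; dj <- shifts$dj[k]
      nb <- lab[(2:(n + 1L)) + di, (2:(m + 1L)) + dj, drop = FALSE]
      cur <- lab[2:(n + 1L), 2:(m + 1L), drop = FALSE]
      upd <- pmin(cur, nb)
      upd[!fg] <- cur[!fg]
      lab[2:(n + 1L), 2:(m + 1L)] <- upd
    }
    if (identical(old, lab)) break
  }
  out <- lab[2:(n + 1L), 2:(m + 1L), drop = FALSE]
  out[!fg] <- 0
  ids <- sort(unique(out[out > 0]))
  out[] <- match(out, c(0, ids)) - 1L
  storage.mode(out) <- "integer"
  out
}

#' Count objects above an intensity threshold
#'
#' Binarizes the channel at `threshold` (strictly greater), labels
#' 8-connected components and discards components smaller than `min_area`
#' pixels. The label image is returned for audit.
#'
#' @param channel Numeric intensity matrix.
#' @param threshold Intensity threshold.
#' @param min_area Minimum component area in pixels (default 1).
#' @return list with `count` and `labels` (relabeled 1..count).
#' @export
count_objects <- function(channel, threshold, min_area = 1) {
  lab <- label_components(channel > threshold)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area)
    lab[] <- match(lab, c(0L, keep), nomatch = 1L) - 1L
    storage.mode(lab) <- "integer"
  }
  list(count = max(lab), labels = lab)
}
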