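#' Hertz-fit parameters
#'
#' @param poisson_ratio Poisson ratio; 0.5 (incompressible) by default.
#' @param edge_angle_deg Pyramidal tip half-angle, degrees (default 25).
#' @param angle_convention `"face"` (face-to-axis, default) or `"edge"`; the
#'   instrument's definition of "edge angle" is not universal, so both are
#'   selectable.
#' @param cantilever_tilt_deg Cantilever mounting angle, degrees (default 10).
#' @param tilt_correction Apply the multiplicative force correction
#'   `1/cos^2(tilt)`? Off by default.
#' @param max_indentation_fraction Fit only indentations up to this fraction
#'   of the maximum post-contact indentation (default 1 = use all).
#' @param min_contact_points Minimum post-contact points for a fit to count
#'   as converged (default 10).
#' @param baseline_fraction Fraction of the approach (from the far end) used
#'   for the initial baseline estimate (default 0.6).
#' @return list of class `fit_params`.
#' @export
fit_params <- function(poisson_ratio = 0.5,
                       edge_angle_deg = 25,
                       angle_convention = c("face", "edge"),
                       cantilever_tilt_deg = 10,
                       tilt_correction = FALSE,
                       max_indentation_fraction = 1,
                       min_contact_points = 10,
                       baseline_fraction = 0.6) {
  angle_convention <- match.arg(angle_convention)
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("parameter error: poisson_ratio must be in [0, 0.5]")
  if (edge_angle_deg <= 0 || edge_angle_deg >= 90)
    stop("parameter error: edge_angle_deg must be in (0, 90)")
  if (max_indentation_fraction <= 0 || max_indentation_fraction > 1)
    stop("parameter error: max_indentation_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "fit_params")
}

#' Calibrate deflection sensitivity on a rigid substrate
#'
#' On an effectively infinitely stiff substrate (bare Petri dish) the
#' cantilever deflects by the full piezo travel past contact, so the contact
#' region of the raw volts-vs-height ramp is a straight line whose inverse
#' slope is the deflection sensitivity. The contact region is selected as the
#' steep terminal segment between 25% and 90% of the signal range and
#' validated by its linearity.
#'
#' @param rigid_curve A raw-mode `force_curve` recorded on a rigid substrate.
#' @param r2_tol Minimum R-squared of the linear contact fit (default 0.95).
#' @param min_points Minimum points in the contact window (default 8).
#' @return Sensitivity in nm/V, with the fitted slope (V/µm) and the z-window
#'   used attached as attributes `slope_V_per_um` and `window_um`.
#' @export
calibrate_sensitivity <- function(rigid_curve, r2_tol = 0.95, min_points = 8) {
  stopifnot(inherits(rigid_curve, "force_curve"))
  if (!identical(rigid_curve$mode, "raw"))
    stop("calibration error: sensitivity calibration needs a raw (volts) curve")
  z <- rigid_curve$z_um
  v <- rigid_curve$signal
  span <- diff(range(v))
  # signal span must clearly exceed the noise of the far (non-contact) half
  far <- v[z >= stats::median(z)]
  noise <- stats::sd(far)
  if (span < .Machine$double.eps^0.5 || (is.finite(noise) && span < 10 * noise))
    stop("calibration error: no contact region detectable (flat curve)")
  lo <- min(v)
  in_win <- v > lo + 0.25 * span & v < lo + 0.90 * span
  if (sum(in_win) < min_points)
    stop("calibration error: contact window too short")
  fit <- stats::lm(v[in_win] ~ z[in_win])
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2) || r2 < r2_tol)
    stop(sprintf("calibration error: contact region not linear (R^2 = %.3f)", r2))
  slope <- unname(stats::coef(fit)[2])              # V per um of z travel
  structure(1000 / abs(slope),                      # nm per V
            slope_V_per_um = slope,
            window_um = range(z[in_win]))
}

#' Baseline-correct a force ramp and convert to force vs separation
#'
#' Estimates the linear pre-contact baseline (offset and slope) on the
#' non-contact region — initially the far `baseline_fraction` of the
#' approach, refined once after a first contact-point estimate — and
#' subtracts it. Raw photodiode signals are converted to force via the
#' deflection sensitivity and spring constant, and the tip-sample separation
#' is corrected for the cantilever deflection (with the piezo height
#' decreasing during the approach, the deflection adds back into the
#' separation; where deflection is zero the separation equals `z`).
#' Force-mode curves are taken to have the deflection correction already
#' applied, so their `z` axis is used as the separation directly.
#'
#' @param curve A `force_curve` (approach segment).
#' @param params [fit_params()].
#' @param sensitivity_nm_per_V Deflection sensitivity; required in raw mode
#'   (e.g. from [calibrate_sensitivity()]), ignored otherwise.
#' @param min_noncontact_fraction Minimum fraction of points that must lie in
#'   the non-contact region (default 0.1).
#' @return data.frame of class `force_separation` with columns
#'   `separation_um`, `force_nN`; baseline coefficients, the contact
#'   estimate and the baseline residual s.d. are attached as attributes.
#' @export
preprocess_curve <- function(curve, params = fit_params(),
                             sensitivity_nm_per_V = NULL,
                             min_noncontact_fraction = 0.1) {
  stopifnot(inherits(curve, "force_curve"))
  if (!identical(curve$segment, "approach"))
    stop("preprocessing error: approach segment required")
  z <- curve$z_um
  sig <- curve$signal
  ord <- order(z, decreasing = TRUE)   # approach: far to near
  z <- z[ord]; sig <- sig[ord]
  k <- curve$spring_constant_N_per_m
  if (identical(curve$mode, "raw")) {
    sens <- sensitivity_nm_per_V %||% curve$sensitivity_nm_per_V
    if (is.null(sens) || is.null(k))
      stop("preprocessing error: raw mode needs sensitivity and spring constant")
    force <- sig * sens * k            # V * nm/V * N/m = nN
  } else {
    force <- sig
  }
  n <- length(force)
  margin <- 0.02 * diff(range(z))
  idx <- seq_len(max(5L, floor(params$baseline_fraction * n)))
  contact_i <- n
  # refine baseline window after each contact estimate until it stabilizes
  for (iter in 1:5) {
    bl <- stats::lm(force[idx] ~ z[idx])
    b <- stats::coef(bl)
    corr <- force - (b[1] + b[2] * z)
    res_sd <- max(stats::sd(stats::residuals(bl)), 1e-12 / 5)
    thr <- 5 * res_sd
    # first index (approaching) where corrected force stays above threshold,
    # then walk back to where the signal last sat at baseline level
    above <- corr > thr
    sustained <- which(above & c(above[-1], FALSE) &
                         c(above[-(1:2)], FALSE, FALSE))
    contact_i <- if (length(sustained)) sustained[1] else n
    while (contact_i > 1 && corr[contact_i - 1] > res_sd)
      contact_i <- contact_i - 1L
    new_idx <- which(z > z[contact_i] + margin)
    if (length(new_idx) < max(5, min_noncontact_fraction * n))
      stop("preprocessing error: non-contact region too short")
    if (identical(new_idx, idx)) break
    idx <- new_idx
  }
  # raw curves carry a real cantilever deflection; with z decreasing during
  # the approach the deflection adds back into the tip-sample separation
  defl_um <- if (identical(curve$mode, "raw")) corr / k / 1000 else 0
  out <- data.frame(separation_um = z + defl_um, force_nN = corr)
  attr(out, "baseline_offset_nN") <- unname(b[1])
  attr(out, "baseline_slope_nN_per_um") <- unname(b[2])
  attr(out, "contact_z_estimate_um") <- z[contact_i]
  attr(out, "baseline_resid_sd_nN") <- stats::sd(stats::residuals(bl))
  class(out) <- c("force_separation", class(out))
  out
}

#' Fit the pyramidal Hertz model to a force-separation curve
#'
#' Least-squares fit of \eqn{F(\delta) = (\tan\theta/\sqrt2)\,
#' E/(1-\nu^2)\,\delta^2}, \eqn{\delta = z_c - s} for separations `s` below
#' the contact point `z_c`, with `z_c` a free parameter fitted jointly with
#' E. A residual linear baseline (offset and slope) is fitted jointly with
#' the Hertz term: for a candidate contact point all three coefficients are
#' linear in the data and solved in closed form, and the contact point is
#' found by a coarse grid over the separation range followed by
#' golden-section refinement. Pre-contact points enter the residual with
#' predicted force equal to the baseline alone, which anchors the contact
#' point.
#'
#' @param fsc A `force_separation` curve from [preprocess_curve()].
#' @param params [fit_params()].
#' @return list of class `hertz_fit`: `E_eff_kPa`, `contact_z_um`,
#'   `baseline_offset_nN`, `baseline_slope_nN_per_um`, `rss`,
#'   `n_points_fit`, `converged`.
#' @export
fit_hertz_pyramid <- function(fsc, params = fit_params()) {
  stopifnot(inherits(fsc, "force_separation"))
  s <- fsc$separation_um
  f <- fsc$force_nN
  geom <- pyramid_geometry_factor(params$edge_angle_deg,
                                  params$angle_convention)
  tilt <- if (params$tilt_correction)
    1 / cos(params$cantilever_tilt_deg * pi / 180)^2 else 1
  frac <- params$max_indentation_fraction

  # given a candidate contact point, the model F = a + b s + C delta^2 is
  # linear in (a, b, C): the residual baseline left by preprocessing is
  # absorbed here rather than biasing the modulus
  rss_of <- function(cz) {
    delta <- pmax(cz - s, 0)
    if (frac < 1) {
      dmax <- max(delta)
      use <- delta <= frac * dmax | delta == 0
    } else use <- rep(TRUE, length(delta))
    d2 <- delta[use]^2
    fv <- f[use]
    X <- cbind(1, s[use], d2)
    cf <- tryCatch(qr.coef(qr(X), fv), error = function(e) c(0, 0, 0))
    cf[is.na(cf)] <- 0
    if (cf[3] < 0) {  # non-physical modulus: refit baseline alone
      cf <- c(qr.coef(qr(X[, 1:2, drop = FALSE]), fv), 0)
      cf[is.na(cf)] <- 0
    }
    list(rss = sum((fv - X %*% cf)^2), chat = cf[3],
         offset = cf[1], slope = cf[2], n_contact = sum(delta[use] > 0))
  }

  grid <- seq(min(s), max(s), length.out = 101)
  rss_grid <- vapply(grid, function(cz) rss_of(cz)$rss, 0)
  i0 <- which.min(rss_grid)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(function(cz) rss_of(cz)$rss, c(lo, hi), tol = 1e-12)
  best <- rss_of(opt$minimum)
  E <- best$chat * (1 - params$poisson_ratio^2) / (geom * tilt)
  converged <- is.finite(E) && E > 0 &&
    best$n_contact >= params$min_contact_points
  structure(list(E_eff_kPa = E,
                 contact_z_um = opt$minimum,
                 baseline_offset_nN = best$offset,
                 baseline_slope_nN_per_um = best$slope,
                 rss = best$rss,
                 n_points_fit = length(s),
                 n_contact_points = best$n_contact,
                 converged = converged),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("hertz_fit: E_eff = %.4g kPa, contact at %.3f um, rss = %.3g%s\n",
              x$E_eff_kPa, x$contact_z_um, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Simulate, preprocess and fit a force curve in one call
#'
#' @param config [curve_sim_config()].
#' @param params [fit_params()].
#' @return A `hertz_fit`.
#' @export
fit_simulated_curve <- function(config, params = fit_params()) {
  fit_hertz_pyramid(preprocess_curve(simulate_force_curve(config), params),
                    params)
}

#' Aggregate Hertz fits into per-region stiffness statistics
#'
#' Means and standard errors of the effective Young's modulus over converged
#' fits, grouped by tissue region, plus the fold difference between two
#' regions. Non-converged fits are counted as rejected, never silently
#' dropped.
#'
#' @param fits data.frame with columns `E_eff_kPa`, `converged` and `region`
#'   (e.g. built from a list of `hertz_fit` objects), optionally `position`
#'   and `ramp` for provenance.
#' @param fold Character vector of two region names: the fold is
#'   `mean(fold[1]) / mean(fold[2])`. Defaults to the two regions in order of
#'   appearance; must be omitted or length 2.
#' @return list of class `region_stats`: `stats` (data.frame with `region`,
#'   `n`, `mean_E_kPa`, `sem_E_kPa`, `rejected`), `fold`, `fold_regions`.
#' @export
aggregate_region <- function(fits, fold = NULL) {
  fits <- as.data.frame(fits)
  stopifnot(all(c("E_eff_kPa", "converged", "region") %in% names(fits)))
  regions <- unique(fits$region)
  rows <- lapply(regions, function(r) {
    e <- fits$E_eff_kPa[fits$region == r & fits$converged]
    rej <- sum(fits$region == r & !fits$converged)
    if (!length(e))
      stop("aggregation error: region '", r, "' has no converged fits")
    data.frame(region = r, n = length(e), mean_E_kPa = mean(e),
               sem_E_kPa = if (length(e) >= 2)
                 stats::sd(e) / sqrt(length(e)) else NA_real_,
               rejected = rej)
  })
  stats_df <- do.call(rbind, rows)
  if (is.null(fold)) fold <- as.character(regions[seq_len(min(2, length(regions)))])
  if (length(fold) == 1) fold <- rep(fold, 2)
  if (!all(fold %in% stats_df$region))
    stop("aggregation error: fold regions not present")
  fnum <- stats_df$mean_E_kPa[match(fold[1], stats_df$region)]
  fden <- stats_df$mean_E_kPa[match(fold[2], stats_df$region)]
  structure(list(stats = stats_df, fold = fnum / fden, fold_regions = fold),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  print(x$stats, row.names = FALSE)
  cat(sprintf("fold (%s / %s): %.3g\n", x$fold_regions[1], x$fold_regions[2],
              x$fold))
  invisible(x)
}

#' Bind a list of Hertz fits into a fits table
#'
#' @param fit_list list of `hertz_fit` objects.
#' @param region Region label(s), recycled over fits.
#' @return data.frame suitable for [aggregate_region()].
#' @export
hertz_fit_table <- function(fit_list, region) {
  data.frame(E_eff_kPa = vapply(fit_list, `[[`, 0, "E_eff_kPa"),
             converged = vapply(fit_list, `[[`, TRUE, "converged"),
             rss = vapply(fit_list, `[[`, 0, "rss"),
             region = rep_len(region, length(fit_list)))
}
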