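#' Hertz contact force for a four-sided pyramidal indenter
#'
#' \deqn{F = \frac{\tan\theta}{\sqrt 2}\,\frac{E}{1-\nu^2}\,\delta^2}
#' with \eqn{\theta} the face-to-axis half-angle. With E in kPa and
#' \eqn{\delta} in micrometres the force comes out in nN (1 kPa µm² = 1 nN).
#'
#' @param delta_um Indentation depth(s), µm (values <= 0 give zero force).
#' @param E_kPa Effective Young's modulus, kPa.
#' @param poisson_ratio Poisson ratio (0.5 for incompressible soft tissue).
#' @param edge_angle_deg Tip half-angle, degrees.
#' @param angle_convention `"face"` (face-to-axis, default) or `"edge"`
#'   (edge-to-axis; related by \eqn{\tan\theta_{face} = \tan\theta_{edge}/\sqrt2}).
#' @return Force(s) in nN.
#' @export
hertz_force <- function(delta_um, E_kPa, poisson_ratio = 0.5,
                        edge_angle_deg = 25,
                        angle_convention = c("face", "edge")) {
  angle_convention <- match.arg(angle_convention)
  geom <- pyramid_geometry_factor(edge_angle_deg, angle_convention)
  geom * E_kPa / (1 - poisson_ratio^2) * pmax(delta_um, 0)^2
}

pyramid_geometry_factor <- function(edge_angle_deg, angle_convention = "face") {
  th <- edge_angle_deg * pi / 180
  switch(angle_convention,
         face = tan(th) / sqrt(2),
         edge = tan(th) / 2,
         stop("unknown angle convention: ", angle_convention))
}

#' Configuration for synthetic AFM force ramps
#'
#' Defaults follow common soft-tissue force-spectroscopy settings: a 5 nN
#' force setpoint, scan range within the 1-14 µm envelope, ν = 0.5 and a 25°
#' pyramidal tip.
#'
#' @param true_modulus_kPa Ground-truth effective Young's modulus (kPa).
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`.
#' @param edge_angle_deg Tip face-to-axis half-angle, degrees, in (0, 90).
#' @param contact_z_um Piezo height at which the tip touches the sample.
#' @param baseline_offset_nN,baseline_slope_nN_per_um Linear pre-contact
#'   baseline (photodiode offset and drift).
#' @param noise_sd_nN Gaussian force noise s.d.
#' @param z_range_um Scan range, µm.
#' @param n_points Samples per ramp.
#' @param setpoint_nN Force at which the approach stops (default 5).
#' @param pre_contact_fraction Fraction of the scan range above the contact
#'   point.
#' @param mode `"force"`: the deflection-to-force conversion is assumed
#'   already applied; `"raw"`: the signal is photodiode volts, for testing
#'   sensitivity calibration.
#' @param spring_constant_N_per_m,sensitivity_nm_per_V Cantilever constants
#'   used in raw mode.
#' @param rigid `TRUE` simulates contact with an infinitely stiff substrate
#'   (bare Petri dish): deflection equals piezo travel past contact.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `curve_sim_config`.
#' @export
curve_sim_config <- function(true_modulus_kPa = 1,
                             poisson_ratio = 0.5,
                             edge_angle_deg = 25,
                             contact_z_um = 0,
                             baseline_offset_nN = 0,
                             baseline_slope_nN_per_um = 0,
                             noise_sd_nN = 0,
                             z_range_um = 6,
                             n_points = 600,
                             setpoint_nN = 5,
                             pre_contact_fraction = 0.5,
                             mode = c("force", "raw"),
                             spring_constant_N_per_m = 0.06,
                             sensitivity_nm_per_V = 50,
                             rigid = FALSE,
                             seed = NULL) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  if (true_modulus_kPa <= 0) stop("configuration error: modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("configuration error: poisson_ratio must be in [0, 0.5]")
  if (edge_angle_deg <= 0 || edge_angle_deg >= 90)
    stop("configuration error: edge_angle_deg must be in (0, 90)")
  if (z_range_um <= 0 || n_points < 10)
    stop("configuration error: need positive z range and >= 10 points")
  if (pre_contact_fraction <= 0 || pre_contact_fraction >= 1)
    stop("configuration error: pre_contact_fraction must be in (0, 1)")
  if (setpoint_nN <= 0) stop("configuration error: setpoint must be > 0")
  structure(cfg, class = "curve_sim_config")
}

#' Simulate an AFM approach force ramp
#'
#' The piezo height `z` decreases from above the sample; past the contact
#' point the indentation is \eqn{\delta = z_{contact} - z} and the force
#' follows the pyramidal Hertz model on top of a linear baseline. The ramp is
#' truncated once the contact force reaches the setpoint. In raw mode the
#' signal is converted to photodiode volts through the spring constant and
#' deflection sensitivity.
#'
#' @param config A [curve_sim_config()].
#' @return A `force_curve`: list with `z_um`, `signal` (nN in force mode,
#'   V in raw mode), `mode`, `segment = "approach"`, cantilever metadata and
#'   the generating truth (`true_modulus_kPa`, `contact_z_um`).
#' @export
simulate_force_curve <- function(config = curve_sim_config()) {
  stopifnot(inherits(config, "curve_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  z_hi <- config$contact_z_um + config$pre_contact_fraction * config$z_range_um
  z_lo <- z_hi - config$z_range_um
  z <- seq(z_hi, z_lo, length.out = config$n_points)
  travel <- pmax(config$contact_z_um - z, 0)
  f_contact <- if (config$rigid) {
    # rigid substrate: cantilever deflects by the full piezo travel
    travel * config$spring_constant_N_per_m * 1000  # um * 1000 * N/m = nN
  } else if (config$mode == "raw") {
    # piezo travel past contact splits into indentation and deflection:
    # K delta^2 = 1000 k (travel - delta), solved for delta
    K <- pyramid_geometry_factor(config$edge_angle_deg) *
      config$true_modulus_kPa / (1 - config$poisson_ratio^2)
    kc <- 1000 * config$spring_constant_N_per_m
    delta <- (-kc + sqrt(kc^2 + 4 * K * kc * travel)) / (2 * K)
    K * delta^2
  } else {
    # force mode: z already plays the role of the tip-sample separation
    hertz_force(travel, config$true_modulus_kPa, config$poisson_ratio,
                config$edge_angle_deg)
  }
  cut <- which(f_contact >= config$setpoint_nN)[1]
  if (!is.na(cut)) {
    z <- z[seq_len(cut)]
    f_contact <- f_contact[seq_len(cut)]
  }
  force <- config$baseline_offset_nN + config$baseline_slope_nN_per_um * z +
    f_contact
  if (config$noise_sd_nN > 0)
    force <- force + stats::rnorm(length(force), 0, config$noise_sd_nN)
  signal <- force
  if (config$mode == "raw") {
    defl_nm <- force / config$spring_constant_N_per_m    # nN / (N/m) = nm
    signal <- defl_nm / config$sensitivity_nm_per_V      # V
  }
  structure(list(z_um = z, signal = signal, mode = config$mode,
                 segment = "approach",
                 spring_constant_N_per_m = config$spring_constant_N_per_m,
                 sensitivity_nm_per_V = if (config$mode == "raw")
                   NULL else config$sensitivity_nm_per_V,
                 true_modulus_kPa = config$true_modulus_kPa,
                 contact_z_um = config$contact_z_um),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve (%s, %s): %d points, z in [%.2f, %.2f] um\n",
              x$segment, x$mode, length(x$z_um), min(x$z_um), max(x$z_um)))
  invisible(x)
}

#' Write / read force curves as annotated two-column TSV
#'
#' Metadata (mode, segment, spring constant, sensitivity) is stored in
#' `# key: value` header lines followed by a `z_um <tab> signal` table.
#'
#' @param curve A `force_curve`.
#' @param file Path.
#' @return `write_force_curve` returns `file` invisibly; `read_force_curve`
#'   a `force_curve`.
#' @export
write_force_curve <- function(curve, file) {
  meta <- c(mode = curve$mode, segment = curve$segment,
            spring_constant_N_per_m = curve$spring_constant_N_per_m,
            sensitivity_nm_per_V = curve$sensitivity_nm_per_V)
  meta <- meta[!vapply(meta, is.null, TRUE)]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  writeLines("z_um\tsignal", con)
  utils::write.table(data.frame(curve$z_um, curve$signal), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  structure(list(z_um = tab[[1]], signal = tab[[2]],
                 mode = meta$mode %||% "force",
                 segment = meta$segment %||% "approach",
                 spring_constant_N_per_m =
                   as_num_or_null(meta$spring_constant_N_per_m),
                 sensitivity_nm_per_V =
                   as_num_or_null(meta$sensitivity_nm_per_V)),
            class = "force_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
as_num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
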