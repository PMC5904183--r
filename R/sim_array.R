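#' Configuration for the synthetic exon-array generator
#'
#' Describes a probe-level log2 expression simulation with planted,
#' direction-specific stiffness effects and optional knockdown dependence.
#' Defaults mirror the study design the package analyses: 6 biological
#' replicates per control condition (stiff vs soft matrix), 2 per siRNA
#' condition, a log2 expression floor near 5 separating expressed from
#' unexpressed probes, and planted per-probe effects of about one log2 unit.
#'
#' @param n_genes Number of simulated genes.
#' @param probes_per_gene Integer vector `c(min, max)`: each gene receives a
#'   uniformly drawn number of exon probe sets in this range.
#' @param frac_up,frac_down Fractions of genes planted as up- or
#'   down-regulated in the soft (or OSS) arm. Their sum must be <= 1.
#' @param frac_gata2_dependent Fraction of planted genes whose effect is
#'   abolished (or attenuated, see `dependence_attenuation`) under GATA2
#'   knockdown. Default 0.25 reflects that roughly a quarter of
#'   stiffness-regulated transcripts lose their regulation without GATA2.
#' @param effect_log2fc Mean planted per-probe effect (log2 units).
#' @param effect_sd Probe-to-probe spread of the planted effect.
#' @param noise_sd Replicate noise s.d. on the log2 scale.
#' @param baseline_mean,baseline_sd Log2 baseline intensity distribution of
#'   expressed probes.
#' @param frac_unexpressed Fraction of probes drawn from the low-intensity
#'   (unexpressed) component so the expression floor has real work to do.
#' @param unexpressed_mean,unexpressed_sd Intensity distribution of the
#'   unexpressed component (well below the floor of 5 by default).
#' @param dependence_attenuation Multiplier removed from the planted effect
#'   in the knockdown arm for dependent genes: 1 = complete abolition
#'   (default), values in (0, 1) model partial dependence.
#' @param n_reps_ctrl Replicates per control condition (and per arm of the
#'   two-arm shear design).
#' @param n_reps_kd Replicates per knockdown condition.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_genes = 500,
                             probes_per_gene = c(4, 8),
                             frac_up = 0.07,
                             frac_down = 0.06,
                             frac_gata2_dependent = 0.25,
                             effect_log2fc = 1.0,
                             effect_sd = 0.2,
                             noise_sd = 0.1,
                             baseline_mean = 7,
                             baseline_sd = 1,
                             frac_unexpressed = 0.1,
                             unexpressed_mean = 3,
                             unexpressed_sd = 0.7,
                             dependence_attenuation = 1,
                             n_reps_ctrl = 6,
                             n_reps_kd = 2,
                             seed = NULL) {
  cfg <- as.list(environment())
  fr <- c(frac_up, frac_down, frac_gata2_dependent, frac_unexpressed)
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must be in [0, 1]")
  if (frac_up + frac_down > 1)
    stop("configuration error: frac_up + frac_down must be <= 1")
  if (n_genes < 1) stop("configuration error: n_genes must be >= 1")
  if (length(probes_per_gene) != 2L || any(probes_per_gene < 1) ||
      probes_per_gene[1] > probes_per_gene[2])
    stop("configuration error: probes_per_gene must be c(min, max) with min <= max, min >= 1")
  if (n_reps_ctrl < 1) stop("configuration error: n_reps_ctrl must be >= 1")
  if (n_reps_kd < 1) stop("configuration error: n_reps_kd must be >= 1")
  if (noise_sd < 0 || effect_sd < 0) stop("configuration error: s.d. must be >= 0")
  if (dependence_attenuation < 0 || dependence_attenuation > 1)
    stop("configuration error: dependence_attenuation must be in [0, 1]")
  structure(cfg, class = "array_sim_config")
}

#' Simulate a probe-level expression matrix with planted ground truth
#'
#' Generates log2-scale probe intensities with gene-wise multi-probe
#' structure. Planted genes shift their expressed probes by the configured
#' effect in the soft-matrix (or oscillatory-shear) arm; GATA2-dependent
#' genes lose that shift in the knockdown arm. Noise is additive Gaussian on
#' the log2 scale, matching the arithmetic of RMA-normalized arrays.
#'
#' Two layouts are supported: `"stiffness_4arm"` produces conditions
#' `ctrl-stiff`, `ctrl-soft` (`n_reps_ctrl` replicates each) and `kd-stiff`,
#' `kd-soft` (`n_reps_kd` each); `"oss_2arm"` produces `static` and `OSS`
#' (`n_reps_ctrl` each), with planted effects in the OSS arm and the
#' knockdown flag unused.
#'
#' Every regulated gene is guaranteed at least one expressed probe carrying
#' its effect, so the recorded truth is always recoverable in principle.
#'
#' @param config An [array_sim_config()].
#' @param design `"stiffness_4arm"` or `"oss_2arm"`.
#' @return A list with elements `matrix` (a [probe_matrix()]) and `truth`
#'   (class `planted_truth`: `$genes` with per-gene direction and dependence
#'   flag, `$probes` with per-probe expressed flag and planted effect).
#' @export
simulate_probe_matrix <- function(config = array_sim_config(),
                                  design = c("stiffness_4arm", "oss_2arm")) {
  stopifnot(inherits(config, "array_sim_config"))
  design <- match.arg(design)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  npr <- if (config$probes_per_gene[1] == config$probes_per_gene[2])
    rep(config$probes_per_gene[1], n)
  else
    sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]), n,
           replace = TRUE)

  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  direction <- rep("none", n)
  reg_idx <- sample.int(n, n_up + n_down)
  direction[reg_idx] <- rep(c("up", "down"), c(n_up, n_down))
  dependent <- rep(FALSE, n)
  dependent[reg_idx] <- stats::runif(length(reg_idx)) < config$frac_gata2_dependent

  g_of_probe <- rep(seq_len(n), npr)
  probe_id <- sprintf("%s_p%d", gene_id[g_of_probe],
                      sequence(npr))
  n_probes <- length(probe_id)
  expressed <- stats::runif(n_probes) >= config$frac_unexpressed
  # truth consistency: a regulated gene must keep >= 1 expressed probe
  first_probe <- match(seq_len(n), g_of_probe)
  needs_fix <- direction != "none" &
    !as.logical(tapply(expressed, g_of_probe, any))
  expressed[first_probe[needs_fix]] <- TRUE

  baseline <- ifelse(expressed,
                     stats::rnorm(n_probes, config$baseline_mean, config$baseline_sd),
                     stats::rnorm(n_probes, config$unexpressed_mean, config$unexpressed_sd))
  sign_g <- c(up = 1, down = -1, none = 0)[direction]
  effect <- ifelse(expressed & sign_g[g_of_probe] != 0,
                   sign_g[g_of_probe] *
                     stats::rnorm(n_probes, config$effect_log2fc, config$effect_sd),
                   0)

  if (design == "stiffness_4arm") {
    cond <- rep(c("ctrl-stiff", "ctrl-soft", "kd-stiff", "kd-soft"),
                c(config$n_reps_ctrl, config$n_reps_ctrl,
                  config$n_reps_kd, config$n_reps_kd))
  } else {
    cond <- rep(c("static", "OSS"), c(config$n_reps_ctrl, config$n_reps_ctrl))
  }
  sample_id <- paste(cond, stats::ave(seq_along(cond), cond, FUN = seq_along),
                     sep = "_")
  # per-sample multiplier on the planted effect
  kd_mult <- 1 - config$dependence_attenuation
  eff_scale <- vapply(seq_along(cond), function(j) {
    switch(cond[j],
           "ctrl-soft" = rep(1, n_probes),
           "OSS" = rep(1, n_probes),
           "kd-soft" = ifelse(dependent[g_of_probe], kd_mult, 1),
           rep(0, n_probes))
  }, numeric(n_probes))
  expr <- baseline + effect * eff_scale +
    matrix(stats::rnorm(n_probes * length(cond), 0, config$noise_sd),
           n_probes, length(cond))
  dimnames(expr) <- list(probe_id, sample_id)

  pm <- probe_matrix(expr,
                     data.frame(probe_id = probe_id,
                                gene_id = gene_id[g_of_probe]),
                     data.frame(sample_id = sample_id, condition = cond))
  truth <- structure(list(
    genes = data.frame(gene_id = gene_id, direction = direction,
                       gata2_dependent = dependent),
    probes = data.frame(probe_id = probe_id, gene_id = gene_id[g_of_probe],
                        expressed = expressed, planted_effect = effect)),
    class = "planted_truth")
  list(matrix = pm, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  tb <- table(x$genes$direction)
  cat("planted_truth:", nrow(x$genes), "genes (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ");",
      sum(x$genes$gata2_dependent), "knockdown-dependent\n")
  invisible(x)
}
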