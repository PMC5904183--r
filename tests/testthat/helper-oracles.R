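# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# brute-force gene calling: enumerate probes per gene with explicit loops
oracle_call_genes <- function(probe_fcs, threshold, min_probes) {
  genes <- unique(probe_fcs$gene_id)
  out <- list()
  for (g in genes) {
    fcs <- probe_fcs$log2fc[probe_fcs$gene_id == g]
    n_up <- 0L
    n_down <- 0L
    up_sum <- 0
    down_sum <- 0
    for (fc in fcs) {
      if (fc > threshold) { n_up <- n_up + 1L; up_sum <- up_sum + fc }
      if (fc < -threshold) { n_down <- n_down + 1L; down_sum <- down_sum + fc }
    }
    status <- "unregulated"
    avg <- NA_real_
    if (n_up >= min_probes && n_down >= min_probes) {
      status <- "bidirectional"
    } else if (n_up >= min_probes) {
      status <- "up"; avg <- up_sum / n_up
    } else if (n_down >= min_probes) {
      status <- "down"; avg <- down_sum / n_down
    }
    out[[g]] <- data.frame(gene_id = g, status = status,
                           avg_log2fc_regulated = avg)
  }
  do.call(rbind, out)
}

# random small probe-fc fixture
random_probe_fcs <- function(n_genes, seed) {
  set.seed(seed)
  npr <- sample(1:6, n_genes, replace = TRUE)
  gene <- rep(sprintf("g%02d", seq_len(n_genes)), npr)
  data.frame(probe_id = sprintf("%s_p%d", gene, sequence(npr)),
             gene_id = gene,
             log2fc = round(stats::rnorm(length(gene), 0, 0.8), 3))
}

# minimal probe_matrix from an expression matrix, one probe per row
toy_matrix <- function(values, conditions, gene_ids = NULL) {
  expr <- as.matrix(values)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("p%d", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- sprintf("s%d", seq_len(ncol(expr)))
  if (is.null(gene_ids)) gene_ids <- rownames(expr)
  probe_matrix(expr,
               data.frame(probe_id = rownames(expr), gene_id = gene_ids),
               data.frame(sample_id = colnames(expr), condition = conditions))
}

# 2-D grid search over (modulus prefactor, contact point), the independent
# check for the profiled Hertz fit
oracle_grid_hertz <- function(fsc, poisson_ratio = 0.5, edge_angle_deg = 25,
                              n_grid = 241) {
  s <- fsc$separation_um
  f <- fsc$force_nN
  geom <- tan(edge_angle_deg * pi / 180) / sqrt(2)
  c_grid <- seq(min(s), max(s), length.out = n_grid)
  best <- list(rss = Inf)
  for (cz in c_grid) {
    delta <- ifelse(s < cz, cz - s, 0)
    pred_unit <- delta^2
    # inner grid over E around the closed-form optimum
    e0 <- sum(f * pred_unit) / sum(pred_unit^2)
    if (!is.finite(e0) || e0 <= 0) e0 <- 1e-6
    for (E in e0 * seq(0.9, 1.1, length.out = 41)) {
      rss <- sum((f - E * pred_unit)^2)
      if (rss < best$rss)
        best <- list(rss = rss, C = E, contact = cz)
    }
  }
  best$E <- best$C * (1 - poisson_ratio^2) / geom
  best
}

# analytic ellipse perimeter by numerical quadrature (high-resolution oracle)
oracle_ellipse_circularity <- function(a, b) {
  per <- stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                          0, 2 * pi, rel.tol = 1e-10)$value
  4 * pi * (pi * a * b) / per^2
}

# rasterized shapes for image tests
raster_disc <- function(r, n = ceiling(2.2 * r)) {
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - n / 2)^2 + (j - n / 2)^2 <= r^2) * 1L)
}

raster_ellipse <- function(a, b, n = ceiling(2.2 * max(a, b))) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (((i - n / 2) / a)^2 + ((j - n / 2) / b)^2 <= 1) * 1L)
}
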