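#' Remove probes below the expression floor
#'
#' Probe sets whose mean log2 expression over the samples of the contrast
#' being analysed is below the floor are considered not significantly
#' expressed and excluded. Removal is strict (`mean < floor`), so a probe
#' averaging exactly the floor is retained.
#'
#' @param pm A [probe_matrix()].
#' @param floor Log2 expression floor (default 5).
#' @param conditions Optional character vector of condition labels: the mean
#'   is computed over the samples of those conditions only. `NULL` uses all
#'   samples.
#' @return The filtered [probe_matrix()] (all samples retained; only probes
#'   dropped).
#' @export
filter_expressed <- function(pm, floor = 5, conditions = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  cols <- if (is.null(conditions)) colnames(pm$expr)
          else samples_for(pm, conditions)
  keep <- rowMeans(pm$expr[, cols, drop = FALSE]) >= floor
  if (!any(keep)) stop("input error: no probe passes the expression floor")
  subset_probes(pm, keep)
}

#' Per-probe log2 fold changes between two conditions
#'
#' Values are already log2, so the fold change is a difference of
#' per-condition replicate means: `mean(cond_b) - mean(cond_a)`.
#'
#' @param pm A [probe_matrix()] (typically after [filter_expressed()]).
#' @param cond_a Reference condition (e.g. `"ctrl-stiff"`).
#' @param cond_b Test condition (e.g. `"ctrl-soft"`).
#' @return data.frame with columns `probe_id`, `gene_id`, `log2fc`.
#' @export
probe_log2fc <- function(pm, cond_a, cond_b) {
  stopifnot(inherits(pm, "probe_matrix"))
  a <- samples_for(pm, cond_a)
  b <- samples_for(pm, cond_b)
  data.frame(probe_id = pm$probes$probe_id,
             gene_id = pm$probes$gene_id,
             log2fc = rowMeans(pm$expr[, b, drop = FALSE]) -
                      rowMeans(pm$expr[, a, drop = FALSE]),
             row.names = NULL)
}

#' Call regulated genes from probe-level fold changes
#'
#' A probe is regulated up if `log2fc > threshold` and down if
#' `log2fc < -threshold` (strict in both cases; the default 0.5 corresponds
#' to a 1.4-fold change). A gene is called up (or down) when at least
#' `min_probes` of its probes are regulated in that direction; genes
#' qualifying in both directions are flagged `bidirectional` — a signature of
#' differential splice-variant expression — and excluded from the final
#' up/down lists. For up/down genes the average log2 fold change over only
#' the regulated probes is reported.
#'
#' @param probe_fcs data.frame from [probe_log2fc()].
#' @param threshold Per-probe log2 fold-change threshold (default 0.5).
#' @param min_probes Minimum number of regulated probes per direction
#'   (default 3).
#' @return data.frame of class `gene_calls` with columns `gene_id`,
#'   `n_probes_total`, `n_probes_up`, `n_probes_down`, `status`
#'   (`up`/`down`/`bidirectional`/`unregulated`), `avg_log2fc_regulated` and
#'   list-column `regulated_probe_ids`. The fraction of regulated genes that
#'   are bidirectional is attached as attribute `bidirectional_fraction`.
#' @export
call_genes <- function(probe_fcs, threshold = 0.5, min_probes = 3) {
  if (min_probes < 1) stop("parameter error: min_probes must be >= 1")
  if (threshold < 0) stop("parameter error: threshold must be >= 0")
  stopifnot(all(c("probe_id", "gene_id", "log2fc") %in% names(probe_fcs)))
  sp <- split(probe_fcs[c("probe_id", "log2fc")], probe_fcs$gene_id)
  rows <- lapply(names(sp), function(g) {
    fc <- sp[[g]]$log2fc
    up <- fc > threshold
    dn <- fc < -threshold
    qual_up <- sum(up) >= min_probes
    qual_dn <- sum(dn) >= min_probes
    status <- if (qual_up && qual_dn) "bidirectional"
              else if (qual_up) "up"
              else if (qual_dn) "down"
              else "unregulated"
    reg <- switch(status,
                  up = sp[[g]]$probe_id[up],
                  down = sp[[g]]$probe_id[dn],
                  bidirectional = sp[[g]]$probe_id[up | dn],
                  character(0))
    avg <- switch(status,
                  up = mean(fc[up]),
                  down = mean(fc[dn]),
                  NA_real_)
    list(gene_id = g, n_probes_total = length(fc),
         n_probes_up = sum(up), n_probes_down = sum(dn),
         status = status, avg_log2fc_regulated = avg,
         regulated_probe_ids = list(reg))
  })
  out <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    n_probes_total = vapply(rows, `[[`, 0L, "n_probes_total"),
    n_probes_up = vapply(rows, `[[`, 0L, "n_probes_up"),
    n_probes_down = vapply(rows, `[[`, 0L, "n_probes_down"),
    status = vapply(rows, `[[`, "", "status"),
    avg_log2fc_regulated = vapply(rows, `[[`, 0, "avg_log2fc_regulated"))
  out$regulated_probe_ids <- lapply(rows, function(r) r$regulated_probe_ids[[1L]])
  n_reg <- sum(out$status %in% c("up", "down", "bidirectional"))
  attr(out, "bidirectional_fraction") <-
    if (n_reg == 0) NA_real_ else sum(out$status == "bidirectional") / n_reg
  class(out) <- c("gene_calls", class(out))
  out
}

#' Extract the final up/down gene sets from gene calls
#'
#' Bidirectional genes are excluded, mirroring their exclusion from the
#' final regulated lists.
#'
#' @param calls A `gene_calls` data.frame from [call_genes()].
#' @return list with character vectors `up` and `down`.
#' @export
regulated_sets <- function(calls) {
  list(up = calls$gene_id[calls$status == "up"],
       down = calls$gene_id[calls$status == "down"])
}

#' Assess knockdown dependence of stiffness-regulated genes
#'
#' For each gene called up or down in the stiffness contrast, the previously
#' identified regulated probe IDs are re-extracted in the knockdown contrast
#' and their log2 fold changes averaged. A gene is dependent when the
#' absolute average exceeds `threshold` in either direction;
#' `concordant_reversal` records whether the knockdown shift opposes the
#' gene's stiffness-regulation direction (the stricter reading of
#' dependence). Genes whose probes are absent from the knockdown contrast
#' are kept with `assessable = FALSE` rather than dropped.
#'
#' @param calls `gene_calls` from [call_genes()] on the stiffness contrast.
#' @param kd_probe_fcs data.frame from [probe_log2fc()] on the knockdown
#'   contrast (e.g. control-siRNA soft vs GATA2-siRNA soft).
#' @param threshold Log2 fold-change threshold for dependence (default 0.5).
#' @return data.frame with columns `gene_id`, `stiffness_status`,
#'   `avg_log2fc_kd`, `dependent`, `concordant_reversal`, `assessable`.
#' @export
assess_gata2_dependence <- function(calls, kd_probe_fcs, threshold = 0.5) {
  reg <- calls[calls$status %in% c("up", "down"), , drop = FALSE]
  fc_of <- stats::setNames(kd_probe_fcs$log2fc, kd_probe_fcs$probe_id)
  avg <- vapply(reg$regulated_probe_ids, function(ids) {
    v <- fc_of[ids]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, 0)
  assessable <- !is.na(avg)
  dir_sign <- ifelse(reg$status == "up", 1, -1)
  data.frame(gene_id = reg$gene_id,
             stiffness_status = reg$status,
             avg_log2fc_kd = avg,
             dependent = ifelse(assessable, abs(avg) > threshold, NA),
             concordant_reversal = ifelse(assessable,
                                          sign(avg) == -dir_sign, NA),
             assessable = assessable,
             row.names = NULL)
}

#' Convenience wrapper: full stepwise gene calling on a probe matrix
#'
#' Applies the expression floor over the contrast samples, computes
#' per-probe log2 fold changes, and calls genes. Genes present in the input
#' whose probes were all removed by the floor are appended with status
#' `not_expressed`.
#'
#' @inheritParams probe_log2fc
#' @inheritParams filter_expressed
#' @inheritParams call_genes
#' @return A `gene_calls` data.frame covering every gene of the input matrix.
#' @export
call_stiffness_genes <- function(pm, cond_a, cond_b, floor = 5,
                                 threshold = 0.5, min_probes = 3) {
  kept <- filter_expressed(pm, floor = floor, conditions = c(cond_a, cond_b))
  calls <- call_genes(probe_log2fc(kept, cond_a, cond_b),
                      threshold = threshold, min_probes = min_probes)
  gone <- setdiff(unique(pm$probes$gene_id), calls$gene_id)
  if (length(gone)) {
    extra <- data.frame(gene_id = gone, n_probes_total = 0L,
                        n_probes_up = 0L, n_probes_down = 0L,
                        status = "not_expressed",
                        avg_log2fc_regulated = NA_real_)
    extra$regulated_probe_ids <- rep(list(character(0)), length(gone))
    bf <- attr(calls, "bidirectional_fraction")
    calls <- rbind(as.data.frame(calls), extra)
    attr(calls, "bidirectional_fraction") <- bf
    class(calls) <- c("gene_calls", class(calls))
  }
  calls
}

#' Gene-level flat fold-change filter
#'
#' The simpler path used for gene-level matrices (e.g. the oscillatory shear
#' stress comparison): expression floor over the contrast samples, then
#' per-row mean log2 fold change; a gene is up if `log2fc > threshold`, down
#' if `log2fc < -threshold` (strict). No minimum-probe rule is applied.
#'
#' @inheritParams probe_log2fc
#' @inheritParams filter_expressed
#' @param threshold Log2 fold-change threshold (default 0.5).
#' @return list with character vectors `up`, `down` (unique gene IDs) and
#'   `n_tested`, the number of rows passing the floor.
#' @export
apply_flat_filter <- function(pm, cond_a, cond_b, floor = 5, threshold = 0.5) {
  kept <- filter_expressed(pm, floor = floor, conditions = c(cond_a, cond_b))
  fc <- probe_log2fc(kept, cond_a, cond_b)
  list(up = unique(fc$gene_id[fc$log2fc > threshold]),
       down = unique(fc$gene_id[fc$log2fc < -threshold]),
       n_tested = nrow(fc))
}

#' Overlap between two stimulus-response gene sets
#'
#' Exact set intersections by gene identifier between two call sets (e.g.
#' soft-matrix vs oscillatory-shear responses), as summarized by
#' area-proportional Venn analyses: shared-up, shared-down and
#' opposite-direction counts, plus fractions relative to each set.
#'
#' @param a,b Lists with character vectors `up` and `down` (see
#'   [regulated_sets()] / [apply_flat_filter()]).
#' @param id_map Optional data.frame with columns `from`, `to` translating
#'   `b`'s gene identifiers onto `a`'s platform. Identifier matching is
#'   case-sensitive and exact.
#' @return list of class `overlap_result` with set sizes, `shared_up`,
#'   `shared_down`, `discordant` and fraction entries.
#' @export
cross_stimulus_overlap <- function(a, b, id_map = NULL) {
  if (!is.null(id_map)) {
    translate <- function(x) {
      hit <- id_map$to[match(x, id_map$from)]
      unique(ifelse(is.na(hit), x, hit))
    }
    b <- list(up = translate(b$up), down = translate(b$down))
  }
  shared_up <- length(intersect(a$up, b$up))
  shared_down <- length(intersect(a$down, b$down))
  discordant <- length(intersect(a$up, b$down)) +
    length(intersect(a$down, b$up))
  frac <- function(k, n) if (n == 0) NA_real_ else k / n
  structure(list(
    n_a_up = length(a$up), n_a_down = length(a$down),
    n_b_up = length(b$up), n_b_down = length(b$down),
    shared_up = shared_up, shared_down = shared_down,
    discordant = discordant,
    frac_a_up_shared = frac(shared_up, length(a$up)),
    frac_a_down_shared = frac(shared_down, length(a$down)),
    frac_b_up_shared = frac(shared_up, length(b$up)),
    frac_b_down_shared = frac(shared_down, length(b$down))),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: up %d/%d vs %d shared; down %d/%d vs %d shared; %d discordant\n",
              x$shared_up, x$n_a_up, x$n_b_up,
              x$shared_down, x$n_a_down, x$n_b_down, x$discordant))
  invisible(x)
}

#' Count regulated transcription factors
#'
#' Intersects the regulated genes (up and down, bidirectional excluded) with
#' a user-supplied transcription-factor list; no TF database is bundled
#' because such lists are version-dependent.
#'
#' @param calls `gene_calls` from [call_genes()], or a list with `up`/`down`
#'   vectors.
#' @param tf_list Character vector of transcription-factor gene identifiers.
#' @return Integer count of regulated genes present in `tf_list`.
#' @export
count_regulated_tfs <- function(calls, tf_list) {
  sets <- if (inherits(calls, "gene_calls")) regulated_sets(calls) else calls
  if (!length(tf_list)) {
    warning("empty transcription-factor list; count is 0")
    return(0L)
  }
  length(intersect(union(sets$up, sets$down), tf_list))
}

#' Write gene calls as TSV
#'
#' The `regulated_probe_ids` list-column is serialized as a comma-separated
#' field.
#'
#' @param calls `gene_calls` data.frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gene_calls <- function(calls, file) {
  out <- as.data.frame(calls)
  out$regulated_probe_ids <- vapply(out$regulated_probe_ids,
                                    paste, "", collapse = ",")
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
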