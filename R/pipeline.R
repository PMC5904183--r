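#' Run an end-to-end analysis pipeline from a single configuration
#'
#' Executes a list of stages in order, passing intermediate results through a
#' shared state, and returns a run report summarizing each stage. The
#' configuration can be an R list or the path of a YAML/JSON file with the
#' same structure:
#'
#' ```yaml
#' seed: 1
#' stages:
#'   - name: simulate_array
#'     params: {design: stiffness_4arm, n_genes: 300}
#'   - name: call_genes
#'     params: {cond_a: ctrl-stiff, cond_b: ctrl-soft,
#'              floor: 5, threshold: 0.5, min_probes: 3}
#'   - name: dependence
#'     params: {cond_a: ctrl-soft, cond_b: kd-soft, threshold: 0.5}
#'   - name: afm_regions
#'     params:
#'       regions: {CV: {true_modulus_kPa: 3.6, n_curves: 10},
#'                 outside: {true_modulus_kPa: 0.27, n_curves: 10}}
#'   - name: image_quant
#'     params: {n_cells: 4, measures: [ctcf, circularity, nuccyt]}
#' ```
#'
#' Supported stages:
#' \describe{
#'   \item{`simulate_array`}{[simulate_probe_matrix()]; params are
#'     [array_sim_config()] fields plus `design`.}
#'   \item{`call_genes`}{[call_stiffness_genes()] on the simulated (or
#'     loaded) matrix; params `cond_a`, `cond_b`, `floor`, `threshold`,
#'     `min_probes`.}
#'   \item{`dependence`}{[assess_gata2_dependence()] on the knockdown
#'     contrast given by `cond_a`/`cond_b`.}
#'   \item{`flat_filter`}{[apply_flat_filter()]; params `cond_a`, `cond_b`,
#'     `floor`, `threshold`.}
#'   \item{`overlap`}{[cross_stimulus_overlap()] between the current call
#'     set and `params$b` (a list with `up`/`down`).}
#'   \item{`load_matrix`}{[read_probe_matrix()]; params `file`,
#'     `design_file`.}
#'   \item{`afm_regions`}{Simulates `n_curves` noisy ramps per region at the
#'     stated true moduli, fits each and aggregates via
#'     [aggregate_region()].}
#'   \item{`image_quant`}{Simulates an image ([image_sim_config()] fields)
#'     and applies the measures in `params$measures` (subset of `ctcf`,
#'     `circularity`, `nuccyt`, `count`).}
#' }
#'
#' @param config List or path to a YAML/JSON configuration.
#' @param seed Optional integer overriding `config$seed`; seeds all stage
#'   randomness.
#' @param out_dir Optional directory: the JSON report (and a `FAILED` marker
#'   on error) is written there.
#' @return A `run_report`: list with `seed`, `stages` (named per-stage
#'   summaries), `totals` and `timestamp`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: configuration must be a list or path")
  stages <- config$stages %||% list()
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  state <- new.env(parent = emptyenv())
  report <- list(seed = seed, stages = list())
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (st in stages) {
    name <- st$name %||% stop("config error: stage without a name")
    params <- st$params %||% list()
    summary <- tryCatch(
      run_stage(name, params, state),
      error = function(e) {
        if (!is.null(out_dir)) {
          report$stages[[name]] <- list(status = "FAILED",
                                        message = conditionMessage(e))
          write_report(report, file.path(out_dir, "report.json"))
          writeLines(name, file.path(out_dir, "FAILED"))
        }
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    report$stages[[name]] <- summary
  }
  report$totals <- report_totals(report$stages)
  report$timestamp <- format(Sys.time(), tz = "UTC")
  class(report) <- "run_report"
  if (!is.null(out_dir))
    write_report(report, file.path(out_dir, "report.json"))
  report
}

run_stage <- function(name, params, state) {
  switch(name,
    simulate_array = {
      design <- params$design %||% "stiffness_4arm"
      cfg_args <- params[setdiff(names(params), "design")]
      cfg <- do.call(array_sim_config, cfg_args)
      sim <- simulate_probe_matrix(cfg, design = design)
      state$matrix <- sim$matrix
      state$truth <- sim$truth
      tb <- table(sim$truth$genes$direction)
      list(status = "ok", n_genes = nrow(sim$truth$genes),
           n_probes = nrow(sim$matrix$expr),
           n_samples = ncol(sim$matrix$expr),
           planted_up = unname(tb["up"]) %|NA|% 0L,
           planted_down = unname(tb["down"]) %|NA|% 0L)
    },
    load_matrix = {
      state$matrix <- read_probe_matrix(params$file, params$design_file)
      list(status = "ok", n_probes = nrow(state$matrix$expr),
           n_samples = ncol(state$matrix$expr))
    },
    call_genes = {
      if (is.null(state$matrix)) stop("no matrix in pipeline state")
      calls <- call_stiffness_genes(state$matrix,
        cond_a = params$cond_a %||% "ctrl-stiff",
        cond_b = params$cond_b %||% "ctrl-soft",
        floor = params$floor %||% 5,
        threshold = params$threshold %||% 0.5,
        min_probes = params$min_probes %||% 3)
      state$calls <- calls
      list(status = "ok",
           n_up = sum(calls$status == "up"),
           n_down = sum(calls$status == "down"),
           n_bidirectional = sum(calls$status == "bidirectional"),
           bidirectional_fraction =
             attr(calls, "bidirectional_fraction") %|NA|% NA_real_)
    },
    dependence = {
      if (is.null(state$matrix) || is.null(state$calls))
        stop("dependence needs a matrix and gene calls in the pipeline state")
      kd_pm <- filter_expressed(state$matrix,
        floor = params$floor %||% 5,
        conditions = c(params$cond_a %||% "ctrl-soft",
                       params$cond_b %||% "kd-soft"))
      kd_fcs <- probe_log2fc(kd_pm, params$cond_a %||% "ctrl-soft",
                             params$cond_b %||% "kd-soft")
      dep <- assess_gata2_dependence(state$calls, kd_fcs,
                                     threshold = params$threshold %||% 0.5)
      state$dependence <- dep
      list(status = "ok",
           n_assessed = sum(dep$assessable),
           n_dependent_up = sum(dep$dependent & dep$stiffness_status == "up",
                                na.rm = TRUE),
           n_dependent_down = sum(dep$dependent &
                                  dep$stiffness_status == "down",
                                  na.rm = TRUE),
           n_unassessable = sum(!dep$assessable))
    },
    flat_filter = {
      if (is.null(state$matrix)) stop("no matrix in pipeline state")
      sets <- apply_flat_filter(state$matrix,
        cond_a = params$cond_a %||% "static",
        cond_b = params$cond_b %||% "OSS",
        floor = params$floor %||% 5,
        threshold = params$threshold %||% 0.5)
      state$flat_sets <- sets
      list(status = "ok", n_up = length(sets$up),
           n_down = length(sets$down), n_tested = sets$n_tested)
    },
    overlap = {
      a <- if (!is.null(state$calls)) regulated_sets(state$calls)
           else state$flat_sets
      if (is.null(a)) stop("no call set in pipeline state")
      if (is.null(params$b)) stop("overlap needs params$b with up/down sets")
      ov <- cross_stimulus_overlap(a, params$b)
      state$overlap <- ov
      ov_plain <- unclass(ov)
      c(list(status = "ok"), ov_plain)
    },
    afm_regions = {
      if (is.null(params$regions)) stop("afm_regions needs params$regions")
      fitp <- do.call(fit_params, params$fit_params %||% list())
      tabs <- lapply(names(params$regions), function(r) {
        spec <- params$regions[[r]]
        ncur <- spec$n_curves %||% 10
        cfg_args <- spec[setdiff(names(spec), "n_curves")]
        fits <- lapply(seq_len(ncur), function(i) {
          cfg <- do.call(curve_sim_config, cfg_args)
          fit_simulated_curve(cfg, fitp)
        })
        hertz_fit_table(fits, r)
      })
      rs <- aggregate_region(do.call(rbind, tabs), fold = params$fold)
      state$region_stats <- rs
      list(status = "ok",
           regions = stats::setNames(as.list(rs$stats$mean_E_kPa),
                                     rs$stats$region),
           fold = rs$fold)
    },
    image_quant = {
      measures <- params$measures %||% c("ctcf", "circularity", "nuccyt")
      cfg_args <- params[setdiff(names(params), c("measures", "count_threshold",
                                                  "count_min_area"))]
      cfg <- do.call(image_sim_config, cfg_args)
      img <- simulate_image(cfg)
      state$image <- img
      out <- list(status = "ok", n_cells = max(img$masks$cell))
      ch <- img$channels$intensity
      if ("ctcf" %in% measures)
        out$mean_ctcf <- mean(ctcf(ch, img$masks$cell,
                                   img$masks$background)$ctcf)
      if ("circularity" %in% measures && max(img$masks$nucleus) > 0)
        out$mean_nuclear_circularity <- mean(vapply(
          seq_len(max(img$masks$nucleus)),
          function(i) circularity(img$masks$nucleus, i), 0))
      if ("nuccyt" %in% measures && max(img$masks$nucleus) > 0) {
        sp <- nuclear_cytoplasmic_split(ch, img$masks$cell, img$masks$nucleus)
        out$nuclear_mean <- sp$nuclear_mean
        out$cytoplasmic_mean <- sp$cytoplasmic_mean
      }
      if ("count" %in% measures)
        out$object_count <- count_objects(ch,
          params$count_threshold %||%
            mean(c(cfg$cell_intensity, cfg$background_intensity)),
          params$count_min_area %||% 10)$count
      out
    },
    stop("unknown stage: ", name)
  )
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

report_totals <- function(stages) {
  num <- function(field) {
    v <- unlist(lapply(stages, `[[`, field))
    if (is.null(v)) NULL else sum(v)
  }
  tot <- list(n_stages = length(stages),
              n_regulated_genes = {
                up <- num("n_up"); dn <- num("n_down")
                if (is.null(up) && is.null(dn)) NULL
                else (up %||% 0) + (dn %||% 0)
              },
              n_dependent_genes = {
                u <- num("n_dependent_up"); d <- num("n_dependent_down")
                if (is.null(u) && is.null(d)) NULL else (u %||% 0) + (d %||% 0)
              })
  tot[!vapply(tot, is.null, TRUE)]
}

#' Serialize a run report to JSON
#'
#' Serialization is deterministic: identical report contents produce
#' byte-identical files apart from the `timestamp` field.
#'
#' @param report A `run_report` (or any list with at least one stage
#'   summary).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.null(report) || is.null(report$stages))
    stop("report error: no stage results to write")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed:", x$seed %||% "none", ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    fields <- setdiff(names(st), "status")
    cat(sprintf("  %-16s %s\n", nm, paste(fields,
      vapply(st[fields], function(v) paste(format(v, digits = 4),
                                           collapse = ","), ""),
      sep = "=", collapse = "  ")))
  }
  if (length(x$totals))
    cat("  totals:", paste(names(x$totals), unlist(x$totals), sep = "=",
                           collapse = "  "), "\n")
  invisible(x)
}
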