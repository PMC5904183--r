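#' Construct a probe-level expression matrix
#'
#' Bundles normalized log2 probe intensities with their probe-to-gene mapping
#' and the sample design. This is the container consumed by the stepwise
#' stiffness-response filter: rows are exon probe set IDs (several per gene),
#' columns are arrays.
#'
#' @param expr Numeric matrix of normalized log2 expression values; rows are
#'   probe set IDs (rownames required), columns are samples (colnames
#'   required). All values must be finite.
#' @param probes data.frame with columns `probe_id` and `gene_id`, one row per
#'   row of `expr`, in the same order (or matched by `probe_id`).
#' @param design data.frame with columns `sample_id` and `condition`, one row
#'   per column of `expr`.
#' @return An object of class `probe_matrix`: a list with elements `expr`,
#'   `probes` and `design`.
#' @export
probe_matrix <- function(expr, probes, design) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix")
  if (nrow(expr) == 0L) stop("input error: empty expression matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate probe set IDs in `expr`")
  if (!all(is.finite(expr))) stop("`expr` contains non-finite values")
  probes <- as.data.frame(probes)
  if (!all(c("probe_id", "gene_id") %in% names(probes)))
    stop("`probes` needs columns probe_id and gene_id")
  if (!setequal(probes$probe_id, rownames(expr)))
    stop("`probes$probe_id` must match rownames(expr)")
  probes <- probes[match(rownames(expr), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  design <- as.data.frame(design)
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("`design` needs columns sample_id and condition")
  if (!setequal(design$sample_id, colnames(expr)))
    stop("design error: every sample must have a condition")
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(expr = expr, probes = probes, design = design),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$expr), "probe sets,",
      length(unique(x$probes$gene_id)), "genes,",
      ncol(x$expr), "samples\n")
  cat("conditions:", paste(sprintf("%s (n=%d)",
      names(table(x$design$condition)), table(x$design$condition)),
      collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$expr)

# samples belonging to one or more condition labels
samples_for <- function(pm, conditions) {
  missing <- setdiff(conditions, pm$design$condition)
  if (length(missing))
    stop("design error: condition(s) not present: ",
         paste(missing, collapse = ", "))
  pm$design$sample_id[pm$design$condition %in% conditions]
}

subset_probes <- function(pm, keep) {
  probe_matrix(pm$expr[keep, , drop = FALSE],
               pm$probes[keep, , drop = FALSE],
               pm$design)
}

#' Write / read a probe matrix as TSV
#'
#' The matrix file has columns `probe_id`, `gene_id` and one column per
#' sample; the design sidecar has columns `sample_id` and `condition`.
#'
#' @param pm A [probe_matrix()].
#' @param file,design_file Paths of the expression table and design sidecar.
#' @return `write_probe_matrix` returns `file` invisibly;
#'   `read_probe_matrix` returns a [probe_matrix()].
#' @export
write_probe_matrix <- function(pm, file, design_file) {
  tab <- data.frame(probe_id = pm$probes$probe_id,
                    gene_id = pm$probes$gene_id,
                    pm$expr, check.names = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pm$design, design_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(file, design_file) {
  tab <- utils::read.delim(file, check.names = FALSE)
  design <- utils::read.delim(design_file)
  expr <- as.matrix(tab[, setdiff(names(tab), c("probe_id", "gene_id")),
                        drop = FALSE])
  rownames(expr) <- tab$probe_id
  probe_matrix(expr, tab[, c("probe_id", "gene_id")], design)
}

#' Read a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format (metadata lines prefixed `!`,
#' expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`). Series matrices are gene- or transcript-level
#' tables, so each row is treated as its own single-probe gene unless a
#' `gene_map` is supplied.
#'
#' @param file Path to an uncompressed series-matrix file.
#' @param conditions Named character vector mapping sample IDs (the GSM
#'   accessions in the table header) to condition labels. Samples not named
#'   are dropped; `NULL` keeps all samples with condition `"unknown"`.
#' @param gene_map Optional data.frame with columns `probe_id`, `gene_id`
#'   used to attach gene identifiers to the table rows.
#' @return A [probe_matrix()]; the `!Sample_title` metadata (when present) is
#'   attached as attribute `sample_title`.
#' @export
read_series_matrix <- function(file, conditions = NULL, gene_map = NULL) {
  lines <- readLines(file)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("input error: no series-matrix table found in ", file)
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, quote = "\"")
  ids <- as.character(tab[[1L]])
  expr <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- ids
  if (!is.null(conditions)) {
    keep <- intersect(colnames(expr), names(conditions))
    if (!length(keep)) stop("design error: no samples match `conditions`")
    expr <- expr[, keep, drop = FALSE]
    design <- data.frame(sample_id = keep,
                         condition = unname(conditions[keep]))
  } else {
    design <- data.frame(sample_id = colnames(expr), condition = "unknown")
  }
  gene_id <- if (is.null(gene_map)) ids else {
    gm <- gene_map$gene_id[match(ids, gene_map$probe_id)]
    ifelse(is.na(gm), ids, gm)
  }
  keep_rows <- stats::complete.cases(expr)
  pm <- probe_matrix(expr[keep_rows, , drop = FALSE],
                     data.frame(probe_id = ids[keep_rows],
                                gene_id = gene_id[keep_rows]),
                     design)
  title_line <- grep("^!Sample_title", lines, value = TRUE)
  if (length(title_line))
    attr(pm, "sample_title") <- gsub("\"", "",
      strsplit(title_line[1L], "\t")[[1L]][-1L])
  pm
}
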