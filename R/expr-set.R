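#' Expression set: intensity matrix plus sample descriptors
#'
#' Lightweight container pairing a numeric probes/genes x samples matrix with
#' a sample sheet (one row per array). Mirrors the matrix-plus-targets idiom
#' of classic microarray analysis.
#'
#' @param values numeric matrix, rows = probes or genes (unique rownames),
#'   columns = samples in sample-sheet order.
#' @param samples data.frame with columns `sample_id`, `genotype`
#'   (`"control"`/`"ko"`), `timepoint` (one of [TIMEPOINTS]) and `replicate`
#'   (positive integer).
#' @param require_positive require all values strictly positive (raw
#'   intensities); normalized log-scale matrices set this to `FALSE`.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `samples`.
#' @export
expr_set <- function(values, samples, require_positive = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)))
    stop("`values` must have rownames (probe or gene ids)", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate row ids in expression matrix", call. = FALSE)
  samples <- validate_sample_sheet(samples)
  if (ncol(values) != nrow(samples))
    stop("column count (", ncol(values), ") != sample sheet rows (",
         nrow(samples), ")", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (require_positive && any(values <= 0))
    stop("raw intensities must be strictly positive", call. = FALSE)
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "rows x", ncol(x$values), "samples\n")
  cat("  genotypes: ", paste(sort(unique(x$samples$genotype)), collapse = ", "),
      "; timepoints: ",
      paste(intersect(TIMEPOINTS, unique(x$samples$timepoint)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Validate a sample sheet
#'
#' Checks the invariants of the sample descriptors: unique `sample_id`,
#' known genotype and timepoint labels, positive integer replicates, and a
#' unique (genotype, timepoint, replicate) combination per row.
#'
#' @param samples data.frame as in [expr_set()].
#' @return The validated data.frame, with `timepoint` as an ordered factor.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "genotype", "timepoint", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$genotype <- as.character(samples$genotype)
  tp <- as.character(samples$timepoint)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  bad_g <- setdiff(unique(samples$genotype), GENOTYPES)
  if (length(bad_g))
    stop("unknown genotype label(s): ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  bad_t <- setdiff(unique(tp), TIMEPOINTS)
  if (length(bad_t))
    stop("unknown timepoint label(s): ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  rep_num <- suppressWarnings(as.numeric(samples$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop("replicate must be a positive integer", call. = FALSE)
  samples$replicate <- as.integer(rep_num)
  key <- paste(samples$genotype, tp, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (genotype, timepoint, replicate) combination",
         call. = FALSE)
  samples$timepoint <- factor(tp, levels = TIMEPOINTS, ordered = TRUE)
  rownames(samples) <- NULL
  samples
}

#' Subset an expression set to a genotype
#' @param x an `expr_set`
#' @param genotype `"control"` or `"ko"`
#' @return an `expr_set` restricted to the matching samples
#' @export
subset_genotype <- function(x, genotype) {
  stopifnot(inherits(x, "expr_set"))
  keep <- x$samples$genotype == genotype
  if (!any(keep)) stop("no samples with genotype ", genotype, call. = FALSE)
  expr_set(x$values[, keep, drop = FALSE], x$samples[keep, , drop = FALSE])
}

# log2 medians per timepoint (one column per level present), rows preserved
timepoint_medians <- function(x, log2_scale = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  tps <- intersect(TIMEPOINTS, as.character(unique(x$samples$timepoint)))
  v <- if (log2_scale) log2(x$values) else x$values
  out <- vapply(tps, function(tp) {
    cols <- x$samples$timepoint == tp
    apply(v[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(v), tps))
  out
}
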