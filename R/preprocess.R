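#' Per-array background cutoff from negative-control values
#'
#' The detection cutoff of an array is the mean plus twice the sample
#' standard deviation (n-1 denominator) of its negative-control intensities.
#'
#' @param negative_values numeric vector of negative-control intensities
#'   (>= 2 values).
#' @return the cutoff (scalar).
#' @export
background_cutoff <- function(negative_values) {
  negative_values <- as.numeric(negative_values)
  if (length(negative_values) < 2L)
    stop("need at least 2 negative-control values", call. = FALSE)
  if (any(negative_values <= 0))
    stop("negative-control intensities must be positive", call. = FALSE)
  mean(negative_values) + 2 * stats::sd(negative_values)
}

#' Background cutoffs for every array of an expression set
#'
#' @param x raw probe-level [expr_set()].
#' @param annotation probe annotation covering all rows of `x`.
#' @return data.frame: `sample_id`, `mean`, `sd`, `cutoff` (one row per
#'   array; `cutoff == mean + 2 * sd` exactly).
#' @export
background_cutoffs <- function(x, annotation) {
  stopifnot(inherits(x, "expr_set"))
  annotation <- validate_probe_annotation(annotation)
  nc_ids <- annotation$probe_id[annotation$is_negative_control]
  nc_ids <- intersect(rownames(x$values), nc_ids)
  if (length(nc_ids) < 2L)
    stop("need at least 2 negative-control probes in the matrix",
         call. = FALSE)
  nc <- x$values[nc_ids, , drop = FALSE]
  data.frame(sample_id = colnames(nc),
             mean = colMeans(nc),
             sd = apply(nc, 2, stats::sd),
             cutoff = apply(nc, 2, background_cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter probes by quality, negative-control status and detection
#'
#' Applies, in order: (1) removal of probes with quality `bad` or
#' `no_match`; (2) removal of negative-control probes; (3) the detection
#' rule — a probe is retained only if at every timepoint present in `x` it
#' is detected (value >= that array's cutoff) in at least one replicate.
#' Below-cutoff values of retained probes keep their measured value:
#' filtering is probe-level, not value-level, so downstream quantile
#' normalization sees complete columns.
#'
#' @param x raw probe-level [expr_set()] (typically one genotype).
#' @param annotation probe annotation covering all rows of `x`.
#' @param cutoffs data.frame from [background_cutoffs()] covering all
#'   columns of `x`.
#' @return list with `expr` (filtered `expr_set`) and `report` (data.frame
#'   of per-stage removal counts; stages sum to input minus output rows).
#' @export
filter_probes <- function(x, annotation, cutoffs) {
  stopifnot(inherits(x, "expr_set"))
  annotation <- validate_probe_annotation(annotation)
  ids <- rownames(x$values)
  missing <- setdiff(ids, annotation$probe_id)
  if (length(missing))
    stop("annotation missing probes: ", paste(utils::head(missing, 3),
                                              collapse = ", "), call. = FALSE)
  ann <- annotation[match(ids, annotation$probe_id), ]
  cut <- cutoffs$cutoff[match(colnames(x$values), cutoffs$sample_id)]
  if (anyNA(cut))
    stop("cutoffs missing for some arrays", call. = FALSE)

  n_in <- length(ids)
  bad <- ann$quality %in% c("bad", "no_match")
  negctl <- !bad & ann$is_negative_control

  detected <- sweep(x$values, 2, cut, ">=")
  tps <- intersect(TIMEPOINTS, as.character(unique(x$samples$timepoint)))
  present_all_tp <- rep(TRUE, n_in)
  for (tp in tps) {
    cols <- x$samples$timepoint == tp
    present_all_tp <- present_all_tp &
      rowSums(detected[, cols, drop = FALSE]) >= 1L
  }
  undetected <- !bad & !negctl & !present_all_tp
  keep <- !(bad | negctl | undetected)

  report <- data.frame(
    stage = c("input", "quality_bad_or_no_match", "negative_control",
              "undetected_at_some_timepoint", "retained"),
    probes = c(n_in, sum(bad), sum(negctl), sum(undetected), sum(keep)),
    stringsAsFactors = FALSE)
  list(expr = expr_set(x$values[keep, , drop = FALSE], x$samples,
                       require_positive = TRUE),
       report = report)
}

#' Collapse probes to genes by brightest probe at P1
#'
#' When a gene is represented by multiple probes, the probe with the highest
#' median intensity across the P1 replicates of the control genotype is
#' retained; ties break to the lexicographically smallest probe id. Probes
#' without a gene symbol are dropped with a warning. Row ids become gene
#' symbols.
#'
#' @param x probe-level [expr_set()] (may contain both genotypes).
#' @param annotation probe annotation covering all rows of `x`.
#' @return gene-level `expr_set` with a `probe_chosen` attribute mapping
#'   gene -> retained probe.
#' @export
collapse_to_genes <- function(x, annotation) {
  stopifnot(inherits(x, "expr_set"))
  annotation <- validate_probe_annotation(annotation)
  ids <- rownames(x$values)
  ann <- annotation[match(ids, annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation missing probes present in the matrix", call. = FALSE)
  no_sym <- !nzchar(ann$gene_symbol)
  if (any(no_sym)) {
    warning(sum(no_sym), " probe(s) without gene symbol excluded",
            call. = FALSE)
    x <- expr_set(x$values[!no_sym, , drop = FALSE], x$samples)
    ann <- ann[!no_sym, ]
    ids <- ids[!no_sym]
  }
  p1_cols <- x$samples$genotype == "control" & x$samples$timepoint == "P1"
  if (!any(p1_cols)) {
    # single-genotype matrix (e.g. KO preprocessed independently): fall
    # back to its own P1 replicates
    p1_cols <- x$samples$timepoint == "P1"
  }
  if (!any(p1_cols)) stop("no P1 arrays to rank probes on", call. = FALSE)
  p1_median <- apply(x$values[, p1_cols, drop = FALSE], 1, stats::median)
  ord <- order(ann$gene_symbol, -p1_median, ids, method = "radix")
  first <- !duplicated(ann$gene_symbol[ord])
  chosen <- ids[ord][first]
  genes <- ann$gene_symbol[ord][first]
  out <- x$values[chosen, , drop = FALSE]
  rownames(out) <- genes
  res <- expr_set(out, x$samples)
  attr(res, "probe_chosen") <- stats::setNames(chosen, genes)
  res
}

#' Quantile normalization
#'
#' Forces every column to share the common distribution given by the mean of
#' per-rank sorted values. Ties within a column receive the mean of the
#' reference values their ranks span. Idempotent.
#'
#' @param x [expr_set()] or numeric matrix with no missing values.
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  vals <- if (inherits(x, "expr_set")) x$values else x
  stopifnot(is.matrix(vals))
  if (anyNA(vals)) stop("quantile normalization requires complete data",
                        call. = FALSE)
  n <- nrow(vals)
  ref <- rowMeans(apply(vals, 2, sort, method = "quick"))
  cref <- c(0, cumsum(ref))
  out <- apply(vals, 2, function(col) {
    r_min <- rank(col, ties.method = "min")
    k <- tabulate(r_min, nbins = n)[r_min]  # tie-group sizes
    (cref[r_min + k] - cref[r_min]) / k
  })
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "expr_set")) expr_set(out, x$samples) else out
}

#' Classical multidimensional scaling of arrays
#'
#' Torgerson MDS on Euclidean distances between sample columns, as a QC
#' projection of array similarity.
#'
#' @param x [expr_set()] or numeric matrix.
#' @param k number of dimensions (default 2; must be < number of samples).
#' @return matrix samples x k of centered coordinates.
#' @export
mds_coordinates <- function(x, k = 2) {
  vals <- if (inherits(x, "expr_set")) x$values else x
  if (k >= ncol(vals))
    stop("k must be smaller than the number of samples", call. = FALSE)
  coords <- stats::cmdscale(stats::dist(t(vals)), k = k)
  if (ncol(coords) < k) {
    # degenerate configurations (e.g. coincident points) span fewer
    # dimensions; pad with zeros so the contract holds
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
    rownames(coords) <- colnames(vals)
  }
  colnames(coords) <- paste0("Dim", seq_len(k))
  coords
}

#' Full preprocessing pipeline for a two-genotype dataset
#'
#' Runs, per genotype: background cutoffs, probe filtering with the
#' per-timepoint detection rule; then intersects the retained probes across
#' genotypes, recombines the arrays, collapses probes to genes (brightest
#' P1 probe of the control genotype), and quantile-normalizes the combined
#' matrix. Downstream analyses log2-transform as needed.
#'
#' @param control,ko raw probe-level [expr_set()]s.
#' @param annotation shared probe annotation.
#' @return list with `expr` (normalized gene-level `expr_set`, intensity
#'   scale), `report` (per-genotype filter reports plus final counts),
#'   `cutoffs` (per-genotype cutoff tables).
#' @export
preprocess_pipeline <- function(control, ko, annotation) {
  annotation <- validate_probe_annotation(annotation)
  cuts <- list(control = background_cutoffs(control, annotation),
               ko = background_cutoffs(ko, annotation))
  f_ctrl <- filter_probes(control, annotation, cuts$control)
  f_ko <- filter_probes(ko, annotation, cuts$ko)
  shared <- intersect(rownames(f_ctrl$expr$values),
                      rownames(f_ko$expr$values))
  if (!length(shared)) stop("no probes survive in both genotypes",
                            call. = FALSE)
  combined <- expr_set(
    cbind(f_ctrl$expr$values[shared, , drop = FALSE],
          f_ko$expr$values[shared, , drop = FALSE]),
    rbind(f_ctrl$expr$samples, f_ko$expr$samples),
    require_positive = TRUE)
  genes <- collapse_to_genes(combined, annotation)
  norm <- quantile_normalize(genes)
  attr(norm, "probe_chosen") <- attr(genes, "probe_chosen")
  list(expr = norm,
       report = list(control = f_ctrl$report, ko = f_ko$report,
                     shared_probes = length(shared),
                     genes = nrow(norm$values)),
       cutoffs = cuts)
}
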