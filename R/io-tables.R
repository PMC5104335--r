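#' Read and validate a tab-separated sample sheet
#'
#' Expected header: `sample_id`, `genotype`, `timepoint`, `replicate`.
#'
#' @param path path to the sheet.
#' @return validated sample data.frame (see [validate_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

#' Write a sample sheet
#' @param samples sample data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- samples
  out$timepoint <- as.character(out$timepoint)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a probe annotation table
#'
#' Tab-separated with header `probe_id`, `gene_symbol`, `quality`,
#' `is_negative_control`. Quality is one of `good`, `bad`, `no_match`;
#' negative-control probes must have an empty gene symbol. Gene symbols are
#' whitespace-trimmed and compared case-sensitively downstream.
#'
#' @param path path to the table.
#' @return validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_probe_annotation(df)
}

#' Validate a probe annotation data.frame
#' @param annotation data.frame with the columns described in
#'   [read_probe_annotation()].
#' @return validated data.frame with logical `is_negative_control`.
#' @export
validate_probe_annotation <- function(annotation) {
  need <- c("probe_id", "gene_symbol", "quality", "is_negative_control")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("probe annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  annotation$probe_id <- as.character(annotation$probe_id)
  annotation$gene_symbol <- trimws(as.character(annotation$gene_symbol))
  annotation$quality <- as.character(annotation$quality)
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe_id in annotation", call. = FALSE)
  bad_q <- setdiff(unique(annotation$quality), c("good", "bad", "no_match"))
  if (length(bad_q))
    stop("unknown probe quality: ", paste(bad_q, collapse = ", "),
         call. = FALSE)
  nc <- annotation$is_negative_control
  if (!is.logical(nc)) nc <- as.logical(toupper(as.character(nc)))
  if (anyNA(nc))
    stop("is_negative_control must be TRUE/FALSE", call. = FALSE)
  annotation$is_negative_control <- nc
  if (any(nc & nzchar(annotation$gene_symbol)))
    stop("negative-control probes must have empty gene_symbol", call. = FALSE)
  rownames(annotation) <- NULL
  annotation
}

#' Write a probe annotation table
#' @param annotation annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `term_id<TAB>description<TAB>member...`. Duplicate
#' members within a set are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   members with a `description` attribute. An empty file gives an empty
#'   collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1L], "' deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    if (!length(members))
      stop("GMT set '", f[1L], "' has no members", call. = FALSE)
    attr(members, "description") <- f[2L]
    sets[[f[1L]]] <- members
  }
  sets
}
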