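#' Read a GCT 1.2 expression file
#'
#' GCT 1.2: a `#1.2` version line, a `rows<TAB>cols` dimension line, then a
#' header row `Name  Description  <sample ids...>` followed by one data row
#' per probe/gene. The Description column is carried through but unused.
#'
#' @param path path to a GCT file.
#' @param samples optional sample sheet (data.frame); when supplied, sample
#'   ids must match the GCT columns in order and the return value is an
#'   [expr_set()], otherwise a bare matrix with a `description` attribute.
#' @return numeric matrix (rownames = Name column) or an `expr_set`.
#' @export
read_gct <- function(path, samples = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("malformed GCT: fewer than 3 lines", call. = FALSE)
  if (trimws(lines[1L]) != "#1.2")
    stop("malformed GCT: expected version line '#1.2', got '", lines[1L], "'",
         call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) != 2L || anyNA(dims) || any(dims < 0))
    stop("malformed GCT: bad dimension line", call. = FALSE)
  header <- strsplit(lines[3L], "\t")[[1L]]
  if (length(header) < 2L || header[1L] != "Name")
    stop("malformed GCT: header must start with 'Name\\tDescription'",
         call. = FALSE)
  n_samp <- length(header) - 2L
  if (n_samp != dims[2L])
    stop("GCT declares ", dims[2L], " samples but header has ", n_samp,
         call. = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1L])
    stop("GCT declares ", dims[1L], " rows but contains ", length(body),
         call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop("GCT data row with wrong field count (row ",
         which(nf != length(header))[1L], ")", call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate row ids in GCT", call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2L)
  vals <- matrix(NA_real_, length(ids), n_samp,
                 dimnames = list(ids, header[-(1:2)]))
  for (j in seq_len(n_samp)) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j + 2L)))
    if (anyNA(v)) stop("non-numeric value in GCT column ", header[j + 2L],
                       call. = FALSE)
    vals[, j] <- v
  }
  attr(vals, "description") <- stats::setNames(desc, ids)
  if (is.null(samples)) return(vals)
  samples <- validate_sample_sheet(samples)
  if (!identical(colnames(vals), samples$sample_id))
    stop("GCT sample columns do not match the sample sheet", call. = FALSE)
  expr_set(vals, samples)
}

#' Write a GCT 1.2 expression file
#'
#' @param x numeric matrix with rownames, or an [expr_set()].
#' @param path output path.
#' @param description optional per-row description vector (defaults to the
#'   row id).
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path, description = NULL) {
  vals <- if (inherits(x, "expr_set")) x$values else x
  stopifnot(is.matrix(vals), !is.null(rownames(vals)))
  if (is.null(description)) {
    description <- attr(vals, "description")
    if (is.null(description)) description <- rownames(vals)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(vals), ncol(vals), sep = "\t"),
               paste(c("Name", "Description", colnames(vals)),
                     collapse = "\t")), con)
  body <- cbind(rownames(vals), as.character(description),
                format(vals, trim = TRUE, digits = 17))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
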