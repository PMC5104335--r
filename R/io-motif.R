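#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text layout: a `>ID name` header followed by four rows
#' (A, C, G, T), each either `A  [ 10  0  5 ... ]` or bare whitespace-
#' separated counts. Counts are converted to column probabilities after
#' adding a total pseudocount of 1 distributed proportionally to the
#' background frequencies, which keeps log-odds finite for zero counts.
#'
#' @param path path to the PFM file.
#' @param background base frequencies for A, C, G, T (must be positive and
#'   sum to 1); also stored for later log-odds scoring.
#' @param pseudocount total pseudocount distributed over the 4 bases per
#'   column (default 1).
#' @return an object of class `pwm`: list with `motif_id`, `prob` (4 x L
#'   probability matrix, rows A/C/G/T), `counts`, and `background`.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4),
                            pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("JASPAR PFM must start with a '>ID name' header", call. = FALSE)
  motif_id <- strsplit(sub("^>\\s*", "", lines[1L]), "\\s+")[[1L]][1L]
  rows <- lines[-1L]
  if (length(rows) != 4L)
    stop("JASPAR PFM must have exactly 4 count rows, found ", length(rows),
         call. = FALSE)
  parse_row <- function(s) {
    s <- gsub("^[ACGTacgt]\\s*", "", trimws(s))
    s <- gsub("[][]", " ", s)
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1L]]))
    if (anyNA(v) || !length(v))
      stop("unparseable PFM count row: ", s, call. = FALSE)
    v
  }
  counts <- lapply(rows, parse_row)
  if (length(unique(lengths(counts))) != 1L)
    stop("PFM rows have unequal lengths", call. = FALSE)
  counts <- do.call(rbind, counts)
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("negative PFM counts", call. = FALSE)
  pwm(counts, background = background, pseudocount = pseudocount,
      motif_id = motif_id)
}

#' Construct a position weight matrix from counts or probabilities
#'
#' @param counts 4 x L nonnegative matrix (rows A, C, G, T). Columns are
#'   normalized to probabilities after adding `pseudocount` distributed
#'   proportionally to `background`.
#' @param background positive base frequencies summing to 1.
#' @param pseudocount total pseudocount per column.
#' @param motif_id identifier string.
#' @return a `pwm` object.
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 1,
                motif_id = "motif") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, ncol(counts) >= 1L)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 positive frequencies summing to 1",
         call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  aug <- counts + pseudocount * background
  prob <- sweep(aug, 2, colSums(aug), "/")
  stopifnot(all(abs(colSums(prob) - 1) < 1e-9))
  structure(list(motif_id = motif_id, prob = prob, counts = counts,
                 background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$motif_id, "': length ", ncol(x$prob), ", consensus ",
      paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Write a thresholded TOM as a tab-separated edge list
#'
#' Emits one `node_a<TAB>node_b<TAB>weight` row per unordered pair with
#' weight at or above `min_connectivity`; no self-edges. This is the export
#' used for core network modules (default threshold 0.05).
#'
#' @param tom symmetric matrix with values in `[0, 1]`.
#' @param row_ids node names (defaults to `rownames(tom)`).
#' @param path output path.
#' @param min_connectivity minimum edge weight retained.
#' @return data.frame of the written edges, invisibly.
#' @export
write_edge_list <- function(tom, path, row_ids = rownames(tom),
                            min_connectivity = 0.05) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8)))
    stop("edge-list export requires a symmetric matrix", call. = FALSE)
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(tom)))
  idx <- which(upper.tri(tom) & tom >= min_connectivity, arr.ind = TRUE)
  edges <- data.frame(node_a = row_ids[idx[, 1L]],
                      node_b = row_ids[idx[, 2L]],
                      weight = tom[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}
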