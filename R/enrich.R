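#' Hypergeometric gene-set overrepresentation
#'
#' Per set, the upper-tail hypergeometric probability `P(X >= k)` of
#' observing `k` query genes in the set, given the set size within the
#' universe and the query size. P-values are BH-adjusted across sets;
#' results with adjusted p at or below `p_max` are returned sorted by
#' ascending p.
#'
#' @param query character vector of query genes (must be within
#'   `universe`).
#' @param sets named list of gene sets (e.g. [read_gmt()] output); members
#'   are intersected with the universe.
#' @param universe character vector of all testable genes.
#' @param p_max maximum adjusted p reported (default 0.01); set to 1 to
#'   see everything.
#' @return data.frame: `term_id`, `term_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `p_adjust`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe, p_max = 0.01) {
  query <- unique(trimws(query))
  universe <- unique(trimws(universe))
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(trimws(sets[[id]])), universe)
    K <- length(members)
    if (!K) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = attr(sets[[id]], "description") %||% id,
               overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), term_name = character(),
                      overlap = integer(), set_size = integer(),
                      query_size = integer(), universe_size = integer(),
                      p = numeric(), p_adjust = numeric(),
                      stringsAsFactors = FALSE))
  out$p_adjust <- bh_adjust(out$p)
  out <- out[out$p_adjust <= p_max, , drop = FALSE]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer-encode a sequence; lowercase (soft-masked) and N -> NA
encode_seq <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unname(BASE_CODE[chars])
}

#' Best log-odds PWM score of a sequence
#'
#' Maximum over all ungapped windows on both strands of
#' `sum log2(P_motif(base) / P_background(base))`. Windows containing `N`
#' or lowercase (soft-masked) letters are skipped. Returns `NA` with a
#' warning when no valid window exists.
#'
#' @param sequence a promoter sequence (character scalar; case matters).
#' @param pwm a [pwm()] object.
#' @return best log2-odds score, or `NA_real_`.
#' @export
pwm_best_score <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "pwm"), is.character(sequence),
            length(sequence) == 1L)
  lo <- log2(pwm$prob / pwm$background)
  L <- ncol(lo)
  best <- -Inf
  for (code in list(encode_seq(sequence),
                    rev(5L - encode_seq(sequence)))) {
    n <- length(code)
    if (n < L) next
    n_win <- n - L + 1L
    scores <- numeric(n_win)
    valid <- rep(TRUE, n_win)
    for (j in seq_len(L)) {
      b <- code[j:(j + n_win - 1L)]
      ok <- !is.na(b)
      valid <- valid & ok
      scores[ok] <- scores[ok] + lo[cbind(b[ok], j)]
    }
    if (any(valid)) best <- max(best, scores[valid])
  }
  if (!is.finite(best)) {
    warning("no valid (unmasked) window of length ", L, call. = FALSE)
    return(NA_real_)
  }
  best
}

#' PWM motif enrichment between two promoter sets
#'
#' Scores every sequence with [pwm_best_score()], sets the hit threshold at
#' the `score_quantile` of the pooled foreground+background best scores,
#' calls a sequence a hit when its best score reaches the threshold, and
#' tests foreground enrichment with a one-sided Fisher exact test on the
#' 2x2 hit table. Sequences without a valid window are excluded with a
#' warning.
#'
#' @param fg,bg named character vectors of sequences (or paths to FASTA
#'   files); at least 5 sequences per group.
#' @param pwm a [pwm()] object.
#' @param score_quantile pooled-score quantile defining the hit threshold
#'   (default 0.95; use a lower quantile when hits are expected to be
#'   abundant).
#' @return list of class `motif_enrichment`: `motif_id`, `threshold`,
#'   `fg_hits`, `fg_total`, `bg_hits`, `bg_total`, `p` (one-sided Fisher),
#'   `scores` (list with fg/bg score vectors).
#' @export
motif_enrichment <- function(fg, bg, pwm, score_quantile = 0.95) {
  if (is.character(fg) && length(fg) == 1L && file.exists(fg))
    fg <- read_fasta(fg)
  if (is.character(bg) && length(bg) == 1L && file.exists(bg))
    bg <- read_fasta(bg)
  stopifnot(inherits(pwm, "pwm"), score_quantile > 0, score_quantile < 1)
  if (length(fg) < 5L || length(bg) < 5L)
    stop("need at least 5 sequences per group", call. = FALSE)
  sfg <- vapply(fg, pwm_best_score, numeric(1), pwm = pwm)
  sbg <- vapply(bg, pwm_best_score, numeric(1), pwm = pwm)
  sfg <- sfg[!is.na(sfg)]; sbg <- sbg[!is.na(sbg)]
  if (!length(sfg) || !length(sbg))
    stop("a group has no scorable sequences after masking", call. = FALSE)
  threshold <- stats::quantile(c(sfg, sbg), score_quantile, names = FALSE)
  fg_hits <- sum(sfg >= threshold)
  bg_hits <- sum(sbg >= threshold)
  tab <- matrix(c(fg_hits, length(sfg) - fg_hits,
                  bg_hits, length(sbg) - bg_hits), 2, 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(motif_id = pwm$motif_id, threshold = threshold,
                 fg_hits = fg_hits, fg_total = length(sfg),
                 bg_hits = bg_hits, bg_total = length(sbg), p = p,
                 scores = list(fg = sfg, bg = sbg)),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat("motif_enrichment '", x$motif_id, "': fg ", x$fg_hits, "/",
      x$fg_total, " vs bg ", x$bg_hits, "/", x$bg_total,
      " hits (threshold ", signif(x$threshold, 4), "), one-sided Fisher p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}
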