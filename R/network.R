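#' Network configuration
#'
#' Defaults follow the pipeline's published settings: soft power chosen
#' from 1..20 at a scale-free fit target of 0.80 (0.85 where applicable),
#' 100 bootstrap networks, hubs = top 5% of average connectivity ranks,
#' and a 0.05 minimum connectivity for the core-module edge export.
#'
#' @param power_candidates candidate soft-thresholding powers.
#' @param fit_target minimum signed scale-free fit index.
#' @param n_bootstrap number of bootstrap networks.
#' @param hub_quantile top fraction of mean ranks flagged as hubs.
#' @param min_connectivity_export TOM threshold for edge export.
#' @param seed integer seed for the bootstrap resampling.
#' @return a `network_config` list.
#' @export
network_config <- function(power_candidates = 1:20, fit_target = 0.80,
                           n_bootstrap = 100, hub_quantile = 0.05,
                           min_connectivity_export = 0.05, seed = 1L) {
  stopifnot(length(power_candidates) >= 1, all(power_candidates >= 1),
            n_bootstrap >= 1, hub_quantile > 0, hub_quantile < 1)
  structure(list(power_candidates = as.integer(power_candidates),
                 fit_target = fit_target,
                 n_bootstrap = as.integer(n_bootstrap),
                 hub_quantile = hub_quantile,
                 min_connectivity_export = min_connectivity_export,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Scale-free topology fit index
#'
#' Bins the connectivity values into `n_bins` equal-width bins, regresses
#' log10(frequency per bin) on log10(mean connectivity per bin), and
#' returns the regression R-squared, signed negative when the slope is
#' positive (a scale-free network has decreasing frequency in k).
#'
#' @param connectivities nonnegative connectivity values (at least
#'   `n_bins` positive ones).
#' @param n_bins number of bins (default 10).
#' @return signed R-squared in `[-1, 1]`.
#' @export
scale_free_fit <- function(connectivities, n_bins = 10) {
  k <- connectivities[connectivities > 0]
  if (length(k) < n_bins)
    stop("need at least ", n_bins, " positive connectivities", call. = FALSE)
  if (diff(range(k)) < .Machine$double.eps * max(k))
    stop("all connectivities equal; fit undefined", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE, labels = FALSE)
  mean_k <- tapply(k, bin, mean)
  freq <- tabulate(bin, nbins = n_bins)[as.integer(names(mean_k))] /
    length(k)
  ok <- freq > 0 & mean_k > 0
  if (sum(ok) < 3L)
    stop("fewer than 3 non-empty bins; fit undefined", call. = FALSE)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  # an exactly linear log-log table is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- stats::coef(fit)[2L]
  if (is.finite(slope) && slope > 0) -r2 else r2
}

#' Soft-thresholding adjacency matrix
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^beta`, Pearson
#' correlation across samples, diagonal set to 0 for connectivity purposes.
#'
#' @param expr genes x samples numeric matrix (>= 3 samples, no constant
#'   genes).
#' @param beta soft-thresholding power.
#' @return symmetric genes x genes matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, beta >= 1)
  s <- apply(expr, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene: ", rownames(expr)[which(s == 0)[1L]],
         call. = FALSE)
  a <- abs(stats::cor(t(expr)))^beta
  a[a > 1] <- 1
  diag(a) <- 0
  a
}

#' Pick the soft-thresholding power by the scale-free criterion
#'
#' Returns the smallest candidate power whose adjacency-based connectivity
#' distribution reaches the scale-free fit target; `NA` (with attribute
#' `fits`) when no candidate satisfies the criterion, in which case
#' downstream hub calling reports "not determined".
#'
#' @param expr genes x samples matrix.
#' @param config a [network_config()].
#' @return integer power, or `NA_integer_` if the criterion is not
#'   satisfiable; attribute `fits` holds the per-candidate fit indices. A
#'   `fit_target` of 0 (or below) disables the criterion and yields the
#'   smallest candidate.
#' @export
pick_soft_power <- function(expr, config = network_config()) {
  fits <- vapply(config$power_candidates, function(b) {
    a <- adjacency_matrix(expr, b)
    k <- rowSums(a)
    tryCatch(scale_free_fit(k), error = function(e) -Inf)
  }, numeric(1))
  names(fits) <- config$power_candidates
  ok <- if (config$fit_target <= 0) seq_along(fits)
        else which(fits >= config$fit_target)
  out <- if (length(ok)) config$power_candidates[ok[1L]] else NA_integer_
  attr(out, "fits") <- fits
  out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_u a_iu a_uj` and `k_i` is the row sum of the
#' adjacency; the diagonal is 1.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with zero diagonal.
#' @return symmetric TOM with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-10)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  k <- rowSums(adjacency)
  l <- adjacency %*% adjacency  # zero diagonal makes this sum_{u != i,j}
  min_k <- outer(k, k, pmin)
  tom <- (l + adjacency) / (min_k + 1 - adjacency)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' TOM-based connectivity
#' @param tom topological overlap matrix (unit diagonal).
#' @return per-gene connectivity `k_i = sum_{j != i} TOM_ij`.
#' @export
tom_connectivity <- function(tom) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  rowSums(tom) - diag(tom)
}

# descending connectivity ranks (1 = most connected, average ties);
# genes flagged constant get the worst rank n
connectivity_ranks <- function(k, constant = rep(FALSE, length(k))) {
  n <- length(k)
  r <- rep(NA_real_, n)
  if (any(!constant))
    r[!constant] <- rank(-k[!constant], ties.method = "average")
  r[constant] <- n
  r
}

#' Bootstrap-stabilized hub ranking
#'
#' For each of `n_bootstrap` replicates, samples (columns) are resampled
#' with replacement to the original size; adjacency (at the fixed power) ->
#' TOM -> connectivity -> descending ranks (1 = most connected, ties share
#' the mean rank; genes constant within a replicate get the worst rank).
#' Per-gene mean and s.d. of ranks are aggregated and the
#' `floor(hub_quantile * n)` genes (minimum 1) with the smallest mean rank
#' are flagged as hubs, ties at the cutoff broken by smaller rank s.d.,
#' then gene id. Replicates with fewer than 3 distinct samples are redrawn
#' (at most 10 retries each).
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param beta soft power, normally chosen on the full data with
#'   [pick_soft_power()]. If `NA`, the ranking is "not determined".
#' @param config a [network_config()].
#' @param resample_indices optional list of column-index vectors (test
#'   hook) overriding the random resampling; its length overrides
#'   `n_bootstrap`.
#' @return data.frame of class `hub_ranking`: `gene`, `mean_rank`,
#'   `sd_rank`, `hub`, sorted by mean rank; attributes `beta` and
#'   `n_bootstrap`.
#' @export
bootstrap_hub_ranking <- function(expr, beta, config = network_config(),
                                  resample_indices = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) >= 4)
  n <- nrow(expr)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  if (is.na(beta)) {
    out <- data.frame(gene = genes, mean_rank = NA_real_,
                      sd_rank = NA_real_, hub = NA, stringsAsFactors = FALSE)
    attr(out, "beta") <- NA_integer_
    attr(out, "determined") <- FALSE
    class(out) <- c("hub_ranking", "data.frame")
    return(out)
  }
  B <- if (!is.null(resample_indices)) length(resample_indices)
       else config$n_bootstrap
  set.seed(config$seed)
  ranks <- matrix(NA_real_, n, B)
  for (b in seq_len(B)) {
    if (!is.null(resample_indices)) {
      idx <- resample_indices[[b]]
    } else {
      for (try in seq_len(10L)) {
        idx <- sample.int(ncol(expr), ncol(expr), replace = TRUE)
        if (length(unique(idx)) >= 3L) break
        if (try == 10L)
          stop("could not draw a bootstrap replicate with >= 3 distinct ",
               "samples", call. = FALSE)
      }
    }
    xb <- expr[, idx, drop = FALSE]
    s <- apply(xb, 1, stats::sd)
    const <- s == 0 | !is.finite(s)
    ktom <- rep(0, n)
    if (sum(!const) >= 2L) {
      a <- abs(stats::cor(t(xb[!const, , drop = FALSE])))^beta
      a[a > 1] <- 1
      diag(a) <- 0
      ktom[!const] <- tom_connectivity(tom_similarity(a))
    }
    ranks[, b] <- connectivity_ranks(ktom, const)
  }
  mean_rank <- rowMeans(ranks)
  sd_rank <- apply(ranks, 1, stats::sd)
  n_hub <- max(1L, floor(config$hub_quantile * n))
  ord <- order(mean_rank, sd_rank, genes, method = "radix")
  hub <- rep(FALSE, n)
  hub[ord[seq_len(n_hub)]] <- TRUE
  out <- data.frame(gene = genes, mean_rank = mean_rank, sd_rank = sd_rank,
                    hub = hub, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  attr(out, "beta") <- beta
  attr(out, "determined") <- TRUE
  attr(out, "n_bootstrap") <- B
  class(out) <- c("hub_ranking", "data.frame")
  out
}

#' Per-cluster network analysis
#'
#' For every SOM cluster with enough genes: choose the soft power on the
#' full data, run the bootstrap hub ranking, and compute the full-data TOM
#' for edge export. Clusters where no power satisfies the scale-free
#' criterion are reported with `determined = FALSE` (hubs "not
#' determined").
#'
#' @param x normalized gene-level [expr_set()] (intensity scale; log2 is
#'   taken internally).
#' @param assignment named unit index per gene (from [som_cluster()]).
#' @param config a [network_config()].
#' @param genotype genotype whose arrays build the networks.
#' @param min_genes smallest cluster analyzed (default 10, the scale-free
#'   fit needs that many points).
#' @return named list per cluster: `genes`, `beta`, `determined`,
#'   `ranking` ([bootstrap_hub_ranking()] output), `tom`.
#' @export
cluster_networks <- function(x, assignment, config = network_config(),
                             genotype = "control", min_genes = 10) {
  stopifnot(inherits(x, "expr_set"))
  sub <- if (genotype %in% x$samples$genotype) subset_genotype(x, genotype)
         else x
  expr <- log2(sub$values)
  units <- sort(unique(assignment))
  out <- list()
  for (u in units) {
    genes <- intersect(names(assignment)[assignment == u], rownames(expr))
    if (length(genes) < min_genes) next
    xg <- expr[genes, , drop = FALSE]
    beta <- pick_soft_power(xg, config)
    ranking <- bootstrap_hub_ranking(xg, beta, config)
    tom <- if (!is.na(beta))
      tom_similarity(adjacency_matrix(xg, beta)) else NULL
    out[[paste0("U", u)]] <- list(genes = genes, beta = as.integer(beta),
                                  determined = !is.na(beta),
                                  ranking = ranking, tom = tom,
                                  fits = attr(beta, "fits"))
  }
  out
}
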