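#' Select dynamically varying genes by coefficient of variation
#'
#' CV is computed on unlogged per-timepoint median intensities of the
#' control genotype (sd/mean over the 5-point median profile); the genes
#' with the largest CV are retained, `floor(fraction * n)` of them, ties
#' broken by gene id. Genes with nonpositive mean are excluded with a
#' warning.
#'
#' @param x normalized gene-level [expr_set()] (intensity scale).
#' @param fraction fraction of genes retained (default 0.30).
#' @param genotype genotype whose medians drive the selection.
#' @return `expr_set` restricted to the selected genes, with attribute
#'   `cv` (named vector over the input genes).
#' @export
cv_select <- function(x, fraction = 0.30, genotype = "control") {
  stopifnot(inherits(x, "expr_set"), fraction > 0, fraction <= 1)
  sub <- if (genotype %in% x$samples$genotype) subset_genotype(x, genotype)
         else x
  med <- timepoint_medians(sub, log2_scale = FALSE)
  m <- rowMeans(med)
  bad <- m <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with nonpositive mean excluded from CV",
            call. = FALSE)
  }
  cv <- ifelse(bad, NA_real_, apply(med, 1, stats::sd) / m)
  n_keep <- floor(fraction * nrow(x$values))
  ord <- order(-cv, rownames(x$values), na.last = TRUE, method = "radix")
  keep <- sort(rownames(x$values)[ord][seq_len(n_keep)])
  keep <- rownames(x$values)[rownames(x$values) %in% keep]
  res <- expr_set(x$values[keep, , drop = FALSE], x$samples)
  attr(res, "cv") <- cv
  res
}

#' Median temporal profiles
#'
#' Per-gene log2 median across replicates at each timepoint, for one
#' genotype. These are the profiles fed to scaling, PCA and the SOM.
#'
#' @param x gene-level [expr_set()] (intensity scale).
#' @param genotype genotype to profile.
#' @return genes x timepoints matrix of log2 medians.
#' @export
median_profiles <- function(x, genotype = "control") {
  sub <- if (genotype %in% x$samples$genotype) subset_genotype(x, genotype)
         else x
  timepoint_medians(sub, log2_scale = TRUE)
}

#' Scale temporal profiles to per-gene z-scores
#'
#' Each row is centered and scaled to unit variance (n-1 denominator)
#' across the timepoints.
#'
#' @param profiles genes x timepoints numeric matrix.
#' @return matrix of the same shape; rows have mean 0 and sd 1.
#' @export
scale_profiles <- function(profiles) {
  stopifnot(is.matrix(profiles))
  s <- apply(profiles, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance profile cannot be scaled (gene ",
         rownames(profiles)[which(s == 0)[1L]], ")", call. = FALSE)
  t(scale(t(profiles)))[, , drop = FALSE]
}

#' PCA of scaled temporal profiles
#'
#' Genes are the observations, timepoints the variables. Components are
#' ordered by decreasing variance with a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param scaled genes x timepoints matrix (typically [scale_profiles()]
#'   output).
#' @return list with `scores` (genes x PCs), `loadings` (timepoints x PCs)
#'   and `variance_explained` (fractions summing to 1).
#' @export
profile_pca <- function(scaled) {
  stopifnot(is.matrix(scaled), nrow(scaled) >= 2, ncol(scaled) >= 2)
  p <- stats::prcomp(scaled, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop("degenerate (rank 0) input", call. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings, variance_explained = ve)
}

#' SOM configuration
#'
#' Defaults follow the pipeline's published settings: a 3 x 6 hexagonal
#' grid trained for 100 iterations while the learning rate decays linearly
#' from 0.009 to 0.006 and the neighborhood radius shrinks from the larger
#' grid dimension to 1.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param topology `"hexagonal"` or `"rectangular"`.
#' @param iterations number of passes over the data.
#' @param alpha_start,alpha_end learning-rate schedule
#'   (`alpha_start >= alpha_end > 0`).
#' @param seed integer seed (initialization and presentation order).
#' @return a `som_config` list.
#' @export
som_config <- function(grid_rows = 3, grid_cols = 6,
                       topology = c("hexagonal", "rectangular"),
                       iterations = 100, alpha_start = 0.009,
                       alpha_end = 0.006, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(grid_rows >= 1, grid_cols >= 1, iterations >= 1,
            alpha_start >= alpha_end, alpha_end > 0)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), topology = topology,
                 iterations = as.integer(iterations),
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 seed = as.integer(seed)),
            class = "som_config")
}

# planar coordinates of the grid units (hexagonal: odd rows offset by 0.5,
# rows sqrt(3)/2 apart)
som_grid_coords <- function(config) {
  g <- expand.grid(col = seq_len(config$grid_cols),
                   row = seq_len(config$grid_rows))
  if (config$topology == "hexagonal") {
    x <- g$col + ((g$row - 1) %% 2) * 0.5
    y <- (g$row - 1) * sqrt(3) / 2
  } else {
    x <- g$col
    y <- g$row - 1
  }
  cbind(x = x, y = y)
}

#' Train a self-organizing map on temporal profiles
#'
#' Online SOM: codebooks are initialized from a random sample of the data,
#' then for each of `iterations` passes every gene is presented in random
#' order; the best-matching unit and its grid neighborhood (Gaussian kernel,
#' radius decaying linearly from `max(grid_rows, grid_cols)` to 1) move
#' toward the presented profile with the decaying learning rate. The same
#' seed gives an identical result. Empty units are allowed.
#'
#' @param scaled genes x timepoints matrix of scaled profiles.
#' @param config a [som_config()].
#' @return list of class `som_fit`: `assignment` (named unit index per
#'   gene), `codebook` (units x timepoints), `grid` (unit planar
#'   coordinates), `config`.
#' @export
train_som <- function(scaled, config = som_config()) {
  stopifnot(is.matrix(scaled), all(is.finite(scaled)),
            inherits(config, "som_config"))
  n <- nrow(scaled)
  n_units <- config$grid_rows * config$grid_cols
  if (n_units > n)
    warning("more units (", n_units, ") than genes (", n,
            "); empty units expected", call. = FALSE)
  set.seed(config$seed)
  grid <- som_grid_coords(config)
  grid_d2 <- as.matrix(stats::dist(grid))^2
  init_idx <- sample.int(n, min(n, n_units))
  codebook <- scaled[init_idx, , drop = FALSE]
  if (n_units > n)
    codebook <- rbind(codebook,
                      matrix(stats::rnorm((n_units - n) * ncol(scaled),
                                          sd = 0.1),
                             ncol = ncol(scaled)))
  rownames(codebook) <- NULL

  total <- config$iterations * n
  step <- 0L
  r_start <- max(config$grid_rows, config$grid_cols)
  for (it in seq_len(config$iterations)) {
    for (g in sample.int(n)) {
      frac <- if (total > 1) step / (total - 1) else 0
      alpha <- config$alpha_start +
        (config$alpha_end - config$alpha_start) * frac
      radius <- r_start + (1 - r_start) * frac
      xg <- scaled[g, ]
      d2 <- rowSums((codebook - rep(xg, each = n_units))^2)
      bmu <- which.min(d2)
      h <- exp(-grid_d2[bmu, ] / (2 * radius^2))
      codebook <- codebook + (alpha * h) *
        (rep(xg, each = n_units) - codebook)
      step <- step + 1L
    }
  }
  d_all <- outer(rowSums(scaled^2), rowSums(codebook^2), "+") -
    2 * scaled %*% t(codebook)
  assignment <- stats::setNames(apply(d_all, 1, which.min), rownames(scaled))
  structure(list(assignment = assignment, codebook = codebook, grid = grid,
                 config = config), class = "som_fit")
}

#' Categorize SOM units into developmental stages
#'
#' A unit whose median scaled profile has amplitude (max - min) below
#' `amplitude_threshold` is `atypical`; otherwise the position of the
#' profile maximum decides: P1 is `neonatal`, P7/P14 `juvenile`,
#' P30/P60 `adult`. Empty units are skipped (`NA`).
#'
#' @param unit_profiles units x 5 matrix of median scaled profiles (rows
#'   may contain `NA` for empty units).
#' @param amplitude_threshold minimum amplitude for a stage-specific call
#'   (default 1.0, in z-score units).
#' @return character vector of categories per unit (`NA` for empty units).
#' @export
categorize_clusters <- function(unit_profiles, amplitude_threshold = 1.0) {
  stopifnot(is.matrix(unit_profiles), ncol(unit_profiles) == 5L)
  apply(unit_profiles, 1, function(p) {
    if (anyNA(p)) return(NA_character_)
    if (max(p) - min(p) < amplitude_threshold) return("atypical")
    switch(which.max(p), "neonatal", "juvenile", "juvenile", "adult",
           "adult")
  })
}

#' Cluster temporal profiles: CV selection, scaling, PCA, SOM, staging
#'
#' Convenience wrapper running the whole clustering stage on a normalized
#' gene-level expression set.
#'
#' @param x normalized gene-level [expr_set()] (intensity scale).
#' @param cv_fraction CV selection fraction.
#' @param config a [som_config()].
#' @param amplitude_threshold passed to [categorize_clusters()].
#' @param genotype genotype whose profiles are clustered.
#' @return list of class `som_result`: `assignment`, `codebook`,
#'   `unit_profiles` (median scaled profile per unit), `category` (per
#'   unit), `gene_category`, `pca` (scores/loadings/variance_explained),
#'   `scaled`, `selected` (gene ids).
#' @export
som_cluster <- function(x, cv_fraction = 0.30, config = som_config(),
                        amplitude_threshold = 1.0, genotype = "control") {
  sel <- cv_select(x, cv_fraction, genotype = genotype)
  prof <- median_profiles(sel, genotype = genotype)
  scaled <- scale_profiles(prof)
  fit <- train_som(scaled, config)
  n_units <- nrow(fit$codebook)
  unit_profiles <- matrix(NA_real_, n_units, ncol(scaled),
                          dimnames = list(NULL, colnames(scaled)))
  for (u in seq_len(n_units)) {
    members <- names(fit$assignment)[fit$assignment == u]
    if (length(members))
      unit_profiles[u, ] <- apply(scaled[members, , drop = FALSE], 2,
                                  stats::median)
  }
  category <- categorize_clusters(unit_profiles, amplitude_threshold)
  pca <- profile_pca(scaled)
  structure(list(assignment = fit$assignment, codebook = fit$codebook,
                 unit_profiles = unit_profiles, category = category,
                 gene_category = stats::setNames(category[fit$assignment],
                                                 names(fit$assignment)),
                 pca = pca, scaled = scaled,
                 selected = rownames(scaled), config = config),
            class = "som_result")
}

#' @export
print.som_result <- function(x, ...) {
  cat("som_result:", length(x$assignment), "genes on a",
      x$config$grid_rows, "x", x$config$grid_cols, x$config$topology,
      "grid\n")
  tab <- table(factor(x$category[x$assignment],
                      levels = c("neonatal", "juvenile", "adult",
                                 "atypical")))
  print(tab)
  invisible(x)
}
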