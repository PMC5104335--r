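# shared fixtures and small independent oracles used across test files

# minimal valid sample sheet: one genotype x all 5 ages x `reps` replicates
make_samples <- function(genotypes = c("control", "ko"), reps = 3) {
  g <- expand.grid(replicate = seq_len(reps), timepoint = TIMEPOINTS,
                   genotype = genotypes, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$genotype, g$timepoint, g$replicate,
                               sep = "_"),
             genotype = g$genotype, timepoint = g$timepoint,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

make_expr <- function(n_genes = 10, genotypes = c("control", "ko"),
                      reps = 3, seed = 1, ids = sprintf("g%03d", 1:n_genes)) {
  set.seed(seed)
  s <- make_samples(genotypes, reps)
  v <- matrix(2^rnorm(n_genes * nrow(s), 8, 1), n_genes, nrow(s),
              dimnames = list(ids, s$sample_id))
  expr_set(v, s)
}

# adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random symmetric adjacency in [0,1] with zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# brute-force TOM by its defining triple loop
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# sharp, informative 15-column PWM (synthetic stand-in for an HMG-box
# motif): one dominant base per column
sharp_pwm <- function(seed = 42, len = 15, motif_id = "sharp") {
  set.seed(seed)
  counts <- vapply(seq_len(len), function(i) {
    v <- rep(1, 4)
    v[sample(4, 1)] <- 17
    v
  }, numeric(4))
  pwm(counts, motif_id = motif_id)
}

reverse_complement <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}
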