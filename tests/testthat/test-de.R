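null_fit_data <- function(n_genes, seed, d0 = 4, s0_2 = 0.04) {
  set.seed(seed)
  sigma2 <- s0_2 * d0 / stats::rchisq(n_genes, d0)
  x <- t(vapply(sigma2, function(v) stats::rnorm(6, 8, sqrt(v)),
                numeric(6)))
  rownames(x) <- paste0("g", seq_len(n_genes))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        genotype = rep(c("control", "ko"), each = 3),
                        timepoint = "P7", replicate = rep(1:3, 2))
  list(x = x, samples = samples)
}

test_that("moderated t reduces to the pooled t when d0 = 0", {
  d <- null_fit_data(50, seed = 1)
  fit <- fit_moderated_t(d$x, d$samples, "P7", prior_df = 0)
  # ordinary pooled two-sample t, computed directly
  t_oracle <- apply(d$x, 1, function(v) {
    stats::t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic
  })
  expect_equal(fit$t, unname(t_oracle), tolerance = 1e-9)
  expect_equal(unique(fit$df), 4)
})

test_that("moderated t reduces to a fixed-variance statistic when d0 = Inf", {
  d <- null_fit_data(50, seed = 2)
  s0 <- 0.09
  fit <- fit_moderated_t(d$x, d$samples, "P7", prior_df = Inf,
                         prior_var = s0)
  m1 <- rowMeans(d$x[, 1:3]); m2 <- rowMeans(d$x[, 4:6])
  expect_equal(fit$t, unname((m2 - m1) / sqrt(s0 * (2 / 3))),
               tolerance = 1e-12)
  expect_equal(fit$s2_post, rep(s0, 50))
})

test_that("posterior variance interpolates prior and sample variance", {
  d <- null_fit_data(200, seed = 3)
  fit <- fit_moderated_t(d$x, d$samples, "P7")
  d0 <- attr(fit, "d0"); s0 <- attr(fit, "s0_2")
  expect_gt(d0, 0)
  expect_equal(fit$s2_post, (d0 * s0 + 4 * fit$s2) / (d0 + 4),
               tolerance = 1e-12)
  expect_true(all(fit$s2_post >= pmin(fit$s2, s0) - 1e-12))
  expect_true(all(fit$s2_post <= pmax(fit$s2, s0) + 1e-12))
})

test_that("prior estimation recovers inverse-gamma parameters", {
  d0s <- s0s <- numeric(20)
  for (s in 1:20) {
    d <- null_fit_data(200, seed = s)
    fit <- fit_moderated_t(d$x, d$samples, "P7")
    d0s[s] <- attr(fit, "d0"); s0s[s] <- attr(fit, "s0_2")
  }
  expect_lt(abs(median(d0s) - 4) / 4, 0.25)
  expect_lt(abs(median(s0s) - 0.04) / 0.04, 0.25)
})

test_that("moderated machinery agrees with the limma oracle", {
  skip_if_not_installed("limma")
  d <- null_fit_data(150, seed = 6)
  fit <- fit_moderated_t(d$x, d$samples, "P7")
  design <- cbind(Intercept = 1, ko = rep(c(0, 1), each = 3))
  lf <- limma::eBayes(limma::lmFit(d$x, design))
  expect_equal(attr(fit, "d0"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s0_2"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$t, unname(lf$t[, "ko"]), tolerance = 1e-9)
  expect_equal(fit$p, unname(lf$p.value[, "ko"]), tolerance = 1e-9)
})

test_that("null p-values are uniform", {
  ps <- unlist(lapply(1:10, function(s) {
    d <- null_fit_data(2000, seed = 100 + s)
    fit_moderated_t(d$x, d$samples, "P7")$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH step-up matches hand example, p.adjust, and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force oracle: q_i = smallest alpha at which the BH procedure
  # (largest k with p_(k) <= k alpha / m) rejects i
  bh_oracle <- function(p) {
    m <- length(p)
    alphas <- sort(unique(pmin(1, p * m / rank(p, ties.method = "first"))))
    vapply(seq_len(m), function(i) {
      for (a in alphas) {
        ps <- sort(p)
        k <- suppressWarnings(max(which(ps <= seq_len(m) * a / m)))
        if (is.finite(k) && p[i] <= ps[k]) return(a)
      }
      1
    }, numeric(1))
  }
  set.seed(17)
  for (rep in 1:5) {
    p <- round(runif(sample(3:12, 1)), 3)
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(q, bh_oracle(p), tolerance = 1e-9)
    # properties: q >= p, monotone in sorted p
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("DE calls apply FDR and two-sided fold-change thresholds", {
  fit <- data.frame(gene = paste0("g", 1:4),
                    p = c(1e-5, 1e-5, 1e-5, 0.9),
                    fold_change = c(2.0, 1.4, 0.5, 3.0),
                    log2_fc = log2(c(2.0, 1.4, 0.5, 3.0)))
  got <- call_de(fit, fdr_max = 0.01, fc_min = 1.5)
  expect_equal(got$call, c("up_in_ko", "ns", "down_in_ko", "ns"))
  expect_true(all(got$q >= got$p))
})

test_that("swapping genotype labels negates fold changes and calls", {
  sim <- generate_expression(sim_config(n_genes = 120, modules = list(),
                                        seed = 41))
  pre <- preprocess_pipeline(sim$control, sim$ko, sim$annotation)
  de <- de_timepoints(pre$expr)
  swapped <- pre$expr
  swapped$samples$genotype <- ifelse(swapped$samples$genotype == "ko",
                                     "control", "ko")
  de2 <- de_timepoints(swapped)
  expect_equal(de2$log2_fc, -de$log2_fc, tolerance = 1e-12)
  expect_equal(de2$call == "up_in_ko", de$call == "down_in_ko")
  expect_equal(de2$q, de$q, tolerance = 1e-12)
})

test_that("planted consistent DE genes are recovered", {
  for (s in 1:2) {
    sim <- generate_expression(sim_config(modules = list(), seed = 60 + s))
    pre <- preprocess_pipeline(sim$control, sim$ko, sim$annotation)
    de <- de_timepoints(pre$expr)
    cons <- consistent_de(de)
    expect_identical(cons$up, sort(sprintf("Gene%04d", 1:9)))
    expect_identical(cons$down, sort(sprintf("Gene%04d", 10:11)))
    # the single-age genes are called where planted but not consistently
    expect_true("up_in_ko" %in%
                  de$call[de$gene == "Gene0012" & de$timepoint == "P7"])
    expect_false("Gene0012" %in% cons$up)
  }
  # missing a timepoint errors
  de_sub <- de[de$timepoint != "P60", ]
  expect_error(consistent_de(de_sub), "all timepoints")
})

test_that("DE-hub intersection reports hub genes at significant ages", {
  # network side: a module whose hub is known
  x <- simulate_module_expr(20, 30, seed = 8)
  ranking <- bootstrap_hub_ranking(x, 3, network_config(n_bootstrap = 30,
                                                        seed = 8))
  networks <- list(U1 = list(ranking = ranking))

  # DE side: the hub gene is planted down 0.4-fold at P7
  genes <- rownames(x)
  s <- make_samples()
  set.seed(9)
  base <- matrix(2^rnorm(length(genes) * nrow(s), 8, 0.05),
                 length(genes), nrow(s),
                 dimnames = list(genes, s$sample_id))
  hit <- s$genotype == "ko" & s$timepoint == "P7"
  base["hub", hit] <- base["hub", hit] * 0.4
  de <- de_timepoints(expr_set(base, s))
  tab <- intersect_de_hubs(de, networks)
  expect_true("hub" %in% tab$gene)
  row <- tab[tab$gene == "hub" & tab$timepoint == "P7", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$fold_change, 0.4, tolerance = 0.1)
  expect_identical(row$call, "down_in_ko")
  # non-hub DE genes are excluded even if significant
  expect_true(all(tab$gene %in% ranking$gene[ranking$hub]))

  # no DE hubs -> empty table
  de_null <- de; de_null$call <- "ns"
  expect_equal(nrow(intersect_de_hubs(de_null, networks)), 0L)
})
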