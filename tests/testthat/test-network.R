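test_that("adjacency is powered absolute correlation with zero diagonal", {
  x <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(1, 2, 3, 4, 5),
             g3 = c(5, 4, 3, 2, 1))
  a1 <- adjacency_matrix(x, 1)
  expect_equal(a1["g1", "g2"], 1)         # identical genes
  expect_equal(a1["g1", "g3"], 1)         # unsigned network
  expect_equal(diag(a1), c(g1 = 0, g2 = 0, g3 = 0))
  # |cor| = 0.5 at beta 6 -> 0.015625
  set.seed(6)
  y <- matrix(rnorm(40), 2, 20)
  y[2, ] <- 0.5 * scale(y[1, ])[, 1] + sqrt(0.75) * scale(rnorm(20))[, 1]
  # force the sample correlation to exactly 0.5 via constructed residual
  r <- stats::cor(y[1, ], y[2, ])
  a <- adjacency_matrix(y, 6)
  expect_equal(a[1, 2], abs(r)^6, tolerance = 1e-12)
  expect_equal(abs(stats::cor(t(y)))[1, 2], adjacency_matrix(y, 1)[1, 2])
  expect_equal(0.5^6, 0.015625)
  expect_error(adjacency_matrix(rbind(c(1, 1, 1), c(1, 2, 3)), 6),
               "zero-variance")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # 2-gene network: TOM equals the adjacency entry
  a2 <- matrix(c(0, 0.37, 0.37, 0), 2, 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.37)
  # all-0.5 triangle: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  t3 <- tom_similarity(a3)
  expect_equal(t3[1, 2], 0.5)
  expect_equal(tom_connectivity(t3), rep(1, 3))

  for (seed in 1:5) {
    a <- random_adjacency(6, seed)
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-12)
  }

  asym <- random_adjacency(4, 1); asym[1, 2] <- 0.99
  expect_error(tom_similarity(asym), "symmetric")
})

test_that("TOM bounds and connectivity equivariance hold on random inputs", {
  for (seed in 1:10) {
    a <- random_adjacency(8, seed)
    tm <- tom_similarity(a)
    off <- tm[upper.tri(tm)]
    expect_true(all(off <= 1 + 1e-12))
    k <- rowSums(a)
    lower <- a / (outer(k, k, pmin) + 1)
    expect_true(all(tm[upper.tri(tm)] >= lower[upper.tri(lower)] - 1e-12))

    perm <- sample(8)
    expect_equal(tom_connectivity(tm[perm, perm]),
                 tom_connectivity(tm)[perm], tolerance = 1e-12)
  }
})

test_that("scale-free fit obeys the sign rule and edge conditions", {
  # frequency increasing in k -> positive slope -> negative fit
  k <- rep(1:10, times = 1:10)
  expect_lt(scale_free_fit(k), 0)
  # decreasing frequency -> positive fit
  k2 <- rep(1:10, times = 10:1)
  expect_gt(scale_free_fit(k2), 0)
  expect_error(scale_free_fit(rep(2, 50)), "equal")
  expect_error(scale_free_fit(1:5), "at least 10")
})

test_that("scale-free fit agrees with an independent binned regression", {
  set.seed(13)
  k <- exp(rnorm(200, 1, 0.8))
  got <- scale_free_fit(k, n_bins = 10)
  # oracle: equal-width bins, log-log regression
  breaks <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, breaks, include.lowest = TRUE, labels = FALSE)
  mk <- tapply(k, bin, mean)
  fr <- as.numeric(table(factor(bin, levels = 1:10)))[as.integer(names(mk))] /
    length(k)
  fit <- stats::lm(log10(fr) ~ log10(as.numeric(mk)))
  r2 <- summary(fit)$r.squared * ifelse(unname(coef(fit)[2]) > 0, -1, 1)
  expect_equal(got, unname(r2), tolerance = 1e-12)
})

test_that("soft power selection returns the smallest satisfying candidate", {
  set.seed(14)
  # heterogeneous factor coupling yields a satisfiable instance
  loads <- runif(40, 0.1, 0.95)
  z <- rnorm(30)
  x <- outer(loads, z) + matrix(rnorm(40 * 30), 40, 30) * sqrt(1 - loads^2)
  rownames(x) <- paste0("g", 1:40)
  cfg <- network_config(fit_target = 0.8)
  beta <- pick_soft_power(x, cfg)
  fits <- attr(beta, "fits")
  # oracle: smallest candidate whose fit reaches the target, where fits are
  # recomputed directly from |cor|^beta connectivities
  oracle_fit <- vapply(cfg$power_candidates, function(b) {
    a <- abs(stats::cor(t(x)))^b; diag(a) <- 0
    tryCatch(scale_free_fit(rowSums(a)), error = function(e) -Inf)
  }, numeric(1))
  expect_equal(unname(fits), oracle_fit, tolerance = 1e-10)
  satisfying <- which(oracle_fit >= 0.8)
  expect_false(is.na(beta))
  expect_equal(as.integer(beta), cfg$power_candidates[satisfying[1]])

  # vacuous criterion: target 0 picks the smallest candidate
  expect_equal(as.integer(pick_soft_power(x, network_config(fit_target = 0))),
               1L)

  # an unsatisfiable instance signals not-determined
  set.seed(15)
  flat <- matrix(rnorm(12 * 30), 12, 30,
                 dimnames = list(paste0("g", 1:12), NULL))
  flat_beta <- pick_soft_power(flat, network_config(fit_target = 0.999))
  expect_true(is.na(flat_beta))
  rk <- bootstrap_hub_ranking(flat, flat_beta)
  expect_false(attr(rk, "determined"))
  expect_true(all(is.na(rk$mean_rank)))
})

test_that("degenerate bootstrap equals the plain full-data ranking", {
  x <- simulate_module_expr(15, 12, seed = 20)
  r <- bootstrap_hub_ranking(x, 4, resample_indices = list(1:12))
  k <- tom_connectivity(tom_similarity(adjacency_matrix(x, 4)))
  want <- rank(-k, ties.method = "average")
  expect_equal(r$mean_rank[match(rownames(x), r$gene)], unname(want))
  expect_equal(r$sd_rank, rep(NA_real_, 15))  # single replicate: sd undefined
})

test_that("hub set size, ordering and input-order invariance", {
  x <- simulate_module_expr(100, 20, seed = 3)
  cfg <- network_config(n_bootstrap = 10, seed = 9)
  r <- bootstrap_hub_ranking(x, 3, cfg)
  expect_equal(sum(r$hub), 5L)                   # floor(0.05 * 100)
  expect_true(all(diff(r$mean_rank) >= 0))       # sorted by mean rank
  expect_true(all(r$mean_rank >= 1 & r$mean_rank <= 100))
  # hubs are exactly the head of the ordering
  expect_true(all(r$hub[1:5]) && !any(r$hub[-(1:5)]))
  # many ranks average to about (n+1)/2
  expect_equal(mean(r$mean_rank), (100 + 1) / 2, tolerance = 0.01)

  perm <- sample(100)
  r2 <- bootstrap_hub_ranking(x[perm, ], 3, cfg)
  expect_setequal(r2$gene[r2$hub], r$gene[r$hub])
})

test_that("planted hubs are recovered at adequate sample size", {
  # module invariant: recovery >= 0.9 at loading separation >= 0.4
  hits <- 0
  for (s in 1:10) {
    x <- simulate_module_expr(20, 30, hub_loading = 0.95,
                              member_loading = 0.5, seed = s)
    r <- bootstrap_hub_ranking(x, 3, network_config(n_bootstrap = 50,
                                                    seed = s))
    hits <- hits + ("hub" %in% r$gene[r$hub])
  }
  expect_gte(hits / 10, 0.9)
})

test_that("constant genes within a replicate get the worst rank", {
  x <- simulate_module_expr(10, 8, seed = 5)
  x[3, ] <- 7  # constant gene
  r <- bootstrap_hub_ranking(x, 2, resample_indices = list(1:8))
  expect_equal(r$mean_rank[r$gene == rownames(x)[3]], 10)
})
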