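test_that("background cutoff is mean plus two sample s.d.", {
  expect_equal(background_cutoff(c(100, 100, 100)), 100)
  expect_equal(background_cutoff(c(8, 10, 12)), 14)  # mean 10, sd 2
  expect_error(background_cutoff(numeric()), "at least 2")
  expect_error(background_cutoff(c(5)), "at least 2")
})

test_that("probe filtering applies the three rules like a direct scan", {
  sim <- generate_expression(sim_config(n_genes = 120, seed = 21))
  x <- sim$control
  ann <- sim$annotation
  cuts <- background_cutoffs(x, ann)
  expect_equal(cuts$cutoff, cuts$mean + 2 * cuts$sd, tolerance = 1e-12)

  res <- filter_probes(x, ann, cuts)
  rep <- res$report
  # report conservation: input = retained + removed
  expect_equal(rep$probes[rep$stage == "input"],
               sum(rep$probes[rep$stage != "input"]))
  expect_lte(nrow(res$expr$values), nrow(x$values))

  # rule-by-rule oracle
  a <- ann[match(rownames(x$values), ann$probe_id), ]
  bad <- a$quality %in% c("bad", "no_match")
  neg <- !bad & a$is_negative_control
  cut <- cuts$cutoff[match(colnames(x$values), cuts$sample_id)]
  det <- sweep(x$values, 2, cut, ">=")
  ok_tp <- rep(TRUE, nrow(x$values))
  for (tp in TIMEPOINTS) {
    cols <- x$samples$timepoint == tp
    ok_tp <- ok_tp & apply(det[, cols, drop = FALSE], 1, any)
  }
  keep_oracle <- rownames(x$values)[!bad & !neg & ok_tp]
  expect_setequal(rownames(res$expr$values), keep_oracle)

  # all negative controls gone; >= 99% of good signal probes survive
  expect_length(intersect(rownames(res$expr$values),
                          ann$probe_id[ann$is_negative_control]), 0)
  signal <- ann$probe_id[!ann$is_negative_control & ann$quality == "good"]
  expect_gte(length(intersect(rownames(res$expr$values), signal)) /
               length(intersect(rownames(x$values), signal)), 0.99)

  # annotation must cover the matrix
  expect_error(filter_probes(x, ann[-1, ], cuts), "missing")
})

test_that("identity filtering when everything is clean and detected", {
  x <- make_expr(6, "control", seed = 2)
  ann <- data.frame(probe_id = c(rownames(x$values), "n1", "n2"),
                    gene_symbol = c(rownames(x$values), "", ""),
                    quality = "good",
                    is_negative_control = c(rep(FALSE, 6), TRUE, TRUE))
  low <- matrix(1, 2, ncol(x$values),
                dimnames = list(c("n1", "n2"), colnames(x$values)))
  low["n2", ] <- 1.2
  full <- expr_set(rbind(x$values, low), x$samples)
  cuts <- background_cutoffs(full, ann)
  res <- filter_probes(full, ann, cuts)
  expect_setequal(rownames(res$expr$values), rownames(x$values))
  rep <- res$report
  expect_equal(rep$probes[rep$stage == "quality_bad_or_no_match"], 0)
  expect_equal(rep$probes[rep$stage == "undetected_at_some_timepoint"], 0)
})

test_that("probe collapse keeps the brightest P1 probe with id tie-break", {
  s <- make_samples("control", reps = 3)
  v <- matrix(100, 4, nrow(s), dimnames = list(
    c("p1", "p2", "q1", "q2"), s$sample_id))
  p1_cols <- s$timepoint == "P1"
  v["p1", p1_cols] <- 500
  v["p2", p1_cols] <- 700       # brighter at P1 -> retained for gene G
  v["q1", p1_cols] <- 300       # exact tie with q2 -> lexicographic
  v["q2", p1_cols] <- 300
  x <- expr_set(v, s)
  ann <- data.frame(probe_id = c("p1", "p2", "q1", "q2"),
                    gene_symbol = c("G", "G", "H", "H"),
                    quality = "good", is_negative_control = FALSE)
  out <- collapse_to_genes(x, ann)
  chosen <- attr(out, "probe_chosen")
  expect_identical(unname(chosen["G"]), "p2")
  expect_identical(unname(chosen["H"]), "q1")
  expect_setequal(rownames(out$values), c("G", "H"))

  # single-probe genes pass through; empty symbols warn and drop
  ann2 <- ann; ann2$gene_symbol[3:4] <- c("", "")
  expect_warning(out2 <- collapse_to_genes(x, ann2), "without gene symbol")
  expect_identical(rownames(out2$values), "G")
})

test_that("quantile normalization matches the hand example and limma", {
  v <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  got <- quantile_normalize(v)
  expect_equal(got[, "s1"], c(a = 1.5, b = 3.5, c = 5.5))
  expect_equal(got[, "s2"], c(a = 1.5, b = 3.5, c = 5.5))

  # idempotence and identical sorted columns on random input
  set.seed(8)
  m <- matrix(2^rnorm(200, 8, 1), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  n1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(n1), n1, tolerance = 1e-12)
  sorted <- apply(n1, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], tolerance = 1e-12,
               ignore_attr = TRUE)

  # equal columns unchanged
  eq <- matrix(rep(c(3, 1, 2), 3), 3, 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(quantile_normalize(eq), eq)

  # independent oracle: limma's implementation (tie-free input)
  skip_if_not_installed("limma")
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-9)
})

test_that("tied values receive the mean of the spanned quantiles", {
  v <- matrix(c(1, 1, 5, 2, 3, 4), 3, 2,
              dimnames = list(letters[1:3], c("s1", "s2")))
  ref <- rowMeans(apply(v, 2, sort))   # 1.5, 2, 4.5
  got <- quantile_normalize(v)
  expect_equal(got[, "s1"],
               c(a = mean(ref[1:2]), b = mean(ref[1:2]), c = unname(ref[3])))
})

test_that("classical MDS recovers Euclidean configurations", {
  # two samples at distance d -> 1-D coordinates +/- d/2
  v <- matrix(c(0, 0, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  got <- mds_coordinates(v, k = 1)
  expect_equal(unname(sort(abs(got[, 1]))), c(2.5, 2.5))

  # identical columns are coincident
  m <- matrix(c(1, 2, 1, 2, 1, 2), 2, 3,
              dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  got <- suppressWarnings(mds_coordinates(m, k = 1))
  expect_lt(max(dist(got)), 1e-9)

  # 4-point distance preservation
  set.seed(3)
  pts <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  got <- mds_coordinates(pts, k = 3)
  expect_equal(as.matrix(dist(got)), as.matrix(dist(t(pts))),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(mds_coordinates(pts, k = 4), "smaller")
})

test_that("full preprocessing keeps genotypes aligned and reports counts", {
  sim <- generate_expression(sim_config(n_genes = 150, seed = 31))
  pre <- preprocess_pipeline(sim$control, sim$ko, sim$annotation)
  expect_equal(ncol(pre$expr$values), 30L)
  expect_false(anyNA(pre$expr$values))
  expect_equal(nrow(pre$expr$values), pre$report$genes)
  # normalized columns share one distribution
  sorted <- apply(pre$expr$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
})
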