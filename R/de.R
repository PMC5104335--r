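#' Empirical-Bayes moderated t for a two-group contrast at one timepoint
#'
#' Per-gene two-sample linear model with pooled variance
#' (`d = n1 + n2 - 2` residual df). The prior degrees of freedom `d0` and
#' prior variance `s0^2` are estimated by moment matching on
#' `log(s^2)`: with `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`,
#' `var(e) - trigamma(d/2)` estimates `trigamma(d0/2)` (inverted by
#' bisection) and `mean(e)` pins `s0^2`. Posterior variances are
#' `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)` and the moderated t uses
#' `d0 + d` degrees of freedom.
#'
#' @param expr_log2 genes x samples matrix of log2 expression.
#' @param samples sample sheet matching the columns.
#' @param timepoint which age to test.
#' @param prior_df optional override of `d0` (test hook: `0` gives the
#'   ordinary pooled t, `Inf` full shrinkage to `prior_var`).
#' @param prior_var optional override of `s0^2`.
#' @return data.frame of class `moderated_fit`: `gene`, `log2_fc`
#'   (KO - control), `fold_change` (linear), `t`, `df`, `p`, `s2`,
#'   `s2_post`; attributes `d0`, `s0_2`, `d`.
#' @export
fit_moderated_t <- function(expr_log2, samples, timepoint,
                            prior_df = NULL, prior_var = NULL) {
  stopifnot(is.matrix(expr_log2))
  samples <- validate_sample_sheet(samples)
  stopifnot(ncol(expr_log2) == nrow(samples))
  sel <- as.character(samples$timepoint) == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint, call. = FALSE)
  g <- samples$genotype[sel]
  x <- expr_log2[, sel, drop = FALSE]
  n1 <- sum(g == "control"); n2 <- sum(g == "ko")
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 replicates per genotype at ", timepoint, call. = FALSE)
  d <- n1 + n2 - 2
  x1 <- x[, g == "control", drop = FALSE]
  x2 <- x[, g == "ko", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d

  if (is.null(prior_df)) {
    est <- estimate_variance_prior(s2, d)
    d0 <- est$d0; s0_2 <- est$s0_2
  } else {
    d0 <- prior_df
    s0_2 <- if (!is.null(prior_var)) prior_var
            else estimate_variance_prior(s2, d)$s0_2
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  tt <- delta / se
  df_total <- d0 + d
  p <- 2 * stats::pt(abs(tt), df = df_total, lower.tail = FALSE)
  out <- data.frame(gene = rownames(x), log2_fc = delta,
                    fold_change = 2^delta, t = tt, df = df_total, p = p,
                    s2 = s2, s2_post = s2_post, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "d") <- d
  class(out) <- c("moderated_fit", "data.frame")
  out
}

#' Moment estimation of the inverse-gamma variance prior
#'
#' @param s2 per-gene residual variances.
#' @param d residual degrees of freedom (scalar).
#' @return list with `d0` (possibly `Inf`) and `s0_2`.
#' @export
estimate_variance_prior <- function(s2, d) {
  stopifnot(d >= 1, length(s2) >= 2)
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0)
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  # trigamma is decreasing; solve trigamma(d0/2) = ev by bisection
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > ev) lo <- mid else hi <- mid
  }
  half_d0 <- sqrt(lo * hi)
  d0 <- 2 * half_d0
  # E[log sigma^2] = log(s0^2) + log(d0/2) - digamma(d0/2)
  s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_2 = s0_2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  if (!m) return(numeric())
  o <- order(pvalues)
  q_sorted <- pmin(1, cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

#' Call differential expression from a moderated fit
#'
#' `up_in_ko` requires `q <= fdr_max` and linear fold change `>= fc_min`;
#' `down_in_ko` requires `q <= fdr_max` and fold change `<= 1/fc_min`;
#' everything else is `ns`.
#'
#' @param fit a [fit_moderated_t()] result.
#' @param fdr_max maximum BH FDR (default 0.01).
#' @param fc_min minimum linear fold change (default 1.5), applied
#'   two-sidedly.
#' @return the fit data.frame with added `q` and `call` columns.
#' @export
call_de <- function(fit, fdr_max = 0.01, fc_min = 1.5) {
  stopifnot(is.data.frame(fit), all(c("p", "fold_change") %in% names(fit)))
  fit$q <- bh_adjust(fit$p)
  fit$call <- ifelse(fit$q <= fdr_max & fit$fold_change >= fc_min,
                     "up_in_ko",
              ifelse(fit$q <= fdr_max & fit$fold_change <= 1 / fc_min,
                     "down_in_ko", "ns"))
  fit
}

#' Differential expression at every timepoint
#'
#' Each age is tested as an independent KO vs control contrast with its own
#' BH family.
#'
#' @param x normalized gene-level [expr_set()] containing both genotypes
#'   (intensity scale; log2 is taken internally).
#' @param fdr_max,fc_min thresholds passed to [call_de()].
#' @param ... passed to [fit_moderated_t()] (test hooks).
#' @return data.frame of class `de_table` with one row per gene x
#'   timepoint: `gene`, `timepoint`, `log2_fc`, `fold_change`, `t`, `p`,
#'   `q`, `call`.
#' @export
de_timepoints <- function(x, fdr_max = 0.01, fc_min = 1.5, ...) {
  stopifnot(inherits(x, "expr_set"))
  expr <- log2(x$values)
  tps <- intersect(TIMEPOINTS, as.character(unique(x$samples$timepoint)))
  out <- do.call(rbind, lapply(tps, function(tp) {
    fit <- call_de(fit_moderated_t(expr, x$samples, tp, ...),
                   fdr_max = fdr_max, fc_min = fc_min)
    cbind(data.frame(timepoint = tp, stringsAsFactors = FALSE),
          fit[, c("gene", "log2_fc", "fold_change", "t", "p", "q", "call")])
  }))
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Intersect DE calls with hub genes
#'
#' Rows are hub genes with at least one significant call; fold changes are
#' reported per significant timepoint.
#'
#' @param de a [de_timepoints()] table.
#' @param networks a [cluster_networks()] result (or any named list whose
#'   elements carry a `ranking` hub table).
#' @return data.frame: `gene`, `cluster`, `timepoint`, `fold_change`,
#'   `call` — one row per significant (hub gene, timepoint).
#' @export
intersect_de_hubs <- function(de, networks) {
  stopifnot(inherits(de, "data.frame"))
  hubs <- do.call(rbind, lapply(names(networks), function(cl) {
    r <- networks[[cl]]$ranking
    if (is.null(r) || !isTRUE(attr(r, "determined"))) return(NULL)
    h <- r[r$hub, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    data.frame(gene = h$gene, cluster = cl, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(gene = character(), cluster = character(),
                      timepoint = character(), fold_change = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  if (is.null(hubs) || !nrow(hubs)) return(empty)
  sig <- de[de$call != "ns" & de$gene %in% hubs$gene, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  out <- merge(hubs, sig[, c("gene", "timepoint", "fold_change", "call")],
               by = "gene")
  out <- out[order(out$cluster, out$gene,
                   match(out$timepoint, TIMEPOINTS)), ]
  rownames(out) <- NULL
  out
}

#' Genes consistently differentially expressed at every age
#'
#' @param de a [de_timepoints()] table covering all five ages.
#' @return list with `up` and `down`: genes with the same non-`ns`
#'   direction at every timepoint.
#' @export
consistent_de <- function(de) {
  stopifnot(inherits(de, "data.frame"))
  tps <- unique(de$timepoint)
  if (!setequal(tps, TIMEPOINTS))
    stop("DE table must cover all timepoints: ",
         paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  calls <- tapply(de$call, de$gene, function(v) {
    if (length(v) == length(TIMEPOINTS) && all(v == "up_in_ko")) "up"
    else if (length(v) == length(TIMEPOINTS) && all(v == "down_in_ko"))
      "down"
    else "no"
  })
  list(up = sort(names(calls)[calls == "up"]),
       down = sort(names(calls)[calls == "down"]))
}
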