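#' Simulation configuration for the synthetic expression world
#'
#' The generator emulates the study design the pipeline assumes: 2 genotypes
#' (control, ko) x 5 postnatal ages x 3 replicates of strictly positive
#' intensities with log-normal noise, negative-control probes, multi-probe
#' genes, low-quality probes, four temporal archetypes, latent-factor
#' co-expression modules with a designated hub gene each, and genotype-
#' specific fold changes at chosen ages.
#'
#' @param n_genes number of genes.
#' @param n_negative_controls number of negative-control probes.
#' @param archetype_fractions nonnegative fractions (neonatal, juvenile,
#'   adult, flat) summing to 1.
#' @param modules list of co-expression modules; each element is a list with
#'   `size`, `hub_loading` in (0, 1], `member_loading` in (0, 1) and an
#'   optional `archetype` shared by all members (so the module survives CV
#'   selection and lands in one temporal cluster). The first gene of a
#'   module is its designated hub.
#' @param ko_effects data.frame with columns `gene`, `timepoint`,
#'   `fold_change` (> 0): KO samples at that age have their linear mean
#'   multiplied by `fold_change`.
#' @param noise_sd_log2 typical (median) s.d. of the additive log2-scale
#'   noise.
#' @param noise_sd_spread_log sigma of the lognormal per-gene spread around
#'   `noise_sd_log2` (0 = homoskedastic genes; a positive default gives
#'   the variance heterogeneity that empirical-Bayes variance shrinkage
#'   targets).
#' @param amplitude_range per-gene multiplier range for the archetype curve
#'   amplitude; heterogeneous coupling to the temporal program is what
#'   gives co-expression networks their heavy-tailed connectivity.
#' @param multi_probe_fraction fraction of genes carrying a second,
#'   strictly lower-intensity probe.
#' @param bad_probe_fraction fraction of probes flagged as low quality
#'   (split between `bad` and `no_match`); probes carrying planted KO
#'   effects or hub roles are never flagged so ground truth stays
#'   recoverable.
#' @param seed integer seed; one RNG stream drives the whole dataset.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1500,
                       n_negative_controls = 100,
                       archetype_fractions = c(neonatal = 0.25,
                                               juvenile = 0.25,
                                               adult = 0.25, flat = 0.25),
                       modules = default_modules(),
                       ko_effects = default_ko_effects(),
                       noise_sd_log2 = 0.1,
                       noise_sd_spread_log = 0.25,
                       amplitude_range = c(0.4, 1.6),
                       multi_probe_fraction = 0.2,
                       bad_probe_fraction = 0.05,
                       seed = 1L) {
  stopifnot(n_genes >= 10, n_negative_controls >= 2,
            length(archetype_fractions) == 4L,
            all(archetype_fractions >= 0),
            abs(sum(archetype_fractions) - 1) < 1e-9,
            noise_sd_log2 > 0, noise_sd_spread_log >= 0,
            length(amplitude_range) == 2L, all(amplitude_range > 0),
            amplitude_range[1] <= amplitude_range[2],
            multi_probe_fraction >= 0, multi_probe_fraction <= 1,
            bad_probe_fraction >= 0, bad_probe_fraction <= 1)
  names(archetype_fractions) <- c("neonatal", "juvenile", "adult", "flat")
  if (sum(vapply(modules, `[[`, 0, "size")) > n_genes)
    stop("module sizes exceed n_genes", call. = FALSE)
  for (m in modules)
    stopifnot(m$size >= 2, m$hub_loading > 0, m$hub_loading <= 1,
              m$member_loading > 0, m$member_loading < 1)
  ko_effects <- validate_ko_effects(ko_effects)
  structure(list(n_genes = as.integer(n_genes),
                 n_negative_controls = as.integer(n_negative_controls),
                 archetype_fractions = archetype_fractions,
                 modules = modules, ko_effects = ko_effects,
                 noise_sd_log2 = noise_sd_log2,
                 noise_sd_spread_log = noise_sd_spread_log,
                 amplitude_range = amplitude_range,
                 multi_probe_fraction = multi_probe_fraction,
                 bad_probe_fraction = bad_probe_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

validate_ko_effects <- function(ko_effects) {
  if (is.null(ko_effects) || (is.data.frame(ko_effects) && !nrow(ko_effects)))
    return(data.frame(gene = character(), timepoint = character(),
                      fold_change = numeric(), stringsAsFactors = FALSE))
  stopifnot(is.data.frame(ko_effects),
            all(c("gene", "timepoint", "fold_change") %in% names(ko_effects)))
  if (!all(ko_effects$timepoint %in% TIMEPOINTS))
    stop("ko_effects timepoint must be one of ",
         paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ko_effects$fold_change)) ||
      any(ko_effects$fold_change <= 0))
    stop("ko_effects fold_change must be finite and positive", call. = FALSE)
  ko_effects$gene <- as.character(ko_effects$gene)
  ko_effects$timepoint <- as.character(ko_effects$timepoint)
  ko_effects
}

#' Default co-expression modules: three 30-gene one-factor modules
#'
#' One module per developmental stage so each survives CV selection and
#' clusters together.
#' @return list of module descriptors.
#' @export
default_modules <- function() {
  mapply(function(a) list(size = 30L, hub_loading = 0.9,
                          member_loading = 0.5, archetype = a),
         c("neonatal", "juvenile", "adult"), SIMPLIFY = FALSE)
}

#' Default KO effects: consistent all-age effects plus two single-age ones
#'
#' Nine genes upregulated 2.5-fold and two downregulated to 0.35-fold at
#' every age (the consistently-DE gene counts the pipeline is meant to
#' recover, at fold-change magnitudes matching those reported for DE hub
#' genes), plus one gene up 1.9-fold only at P7 and one down to 0.4-fold
#' at P7/P14.
#' @return ko_effects data.frame.
#' @export
default_ko_effects <- function() {
  up9 <- sprintf("Gene%04d", 1:9)
  down2 <- sprintf("Gene%04d", 10:11)
  one_up <- "Gene0012"
  one_down <- "Gene0013"
  rbind(
    expand_effects(up9, TIMEPOINTS, 2.5),
    expand_effects(down2, TIMEPOINTS, 0.35),
    expand_effects(one_up, "P7", 1.9),
    expand_effects(one_down, c("P7", "P14"), 0.4)
  )
}

expand_effects <- function(genes, timepoints, fold) {
  g <- expand.grid(gene = genes, timepoint = timepoints,
                   stringsAsFactors = FALSE)
  g$fold_change <- fold
  g
}

#' Temporal archetype curves
#'
#' The log2-scale shapes (amplitude ~2 log2 units) the generator plants:
#' `neonatal` declines linearly from P1; `juvenile` peaks at P7
#' (variant 1) or P14 (variant 2) with roughly symmetric decay; `adult`
#' rises logistically, saturating at P30-P60; `flat` is constant. After
#' z-scoring, each non-flat shape satisfies the corresponding
#' [categorize_clusters()] rule.
#'
#' @param archetype one of `"neonatal"`, `"juvenile"`, `"adult"`, `"flat"`.
#' @param variant 1 or 2 (juvenile peak position).
#' @return numeric vector over [TIMEPOINTS].
#' @export
archetype_curve <- function(archetype, variant = 1L) {
  shape <- switch(archetype,
                  neonatal = c(1, 0.5, 0, -0.5, -1),
                  juvenile = if (variant %% 2L == 0L)
                    c(-1, 0.3, 1, -0.3, -1) else c(-1, 1, 0.3, -0.6, -1),
                  adult = c(-1, -0.95, -0.4, 0.75, 1),
                  flat = c(0, 0, 0, 0, 0),
                  stop("unknown archetype ", archetype, call. = FALSE))
  # common log2 s.d. (0.8) across shapes so no stage dominates CV ranking
  if (archetype != "flat") shape <- shape / stats::sd(shape) * 0.8
  shape
}

#' Generate a synthetic probe-level expression dataset with ground truth
#'
#' Gene g at age t has log2 mean `base + archetype curve + loading * z(sample)`
#' where `z` is a per-sample standard-normal module factor; KO samples at a
#' planted (gene, age) get `+ log2(fold_change)`; the observation is
#' `2^(mu + eps)` with `eps ~ N(0, noise_sd_log2)`. Negative-control probes
#' are drawn from a low-intensity log-normal background whose mean + 2 s.d.
#' sits below the 5th percentile of true-signal intensities. A fraction of
#' genes carries a second probe at strictly lower intensity, and a fraction
#' of probes is flagged `bad`/`no_match`.
#'
#' @param config a [sim_config()].
#' @return list with elements `control` and `ko` (raw probe-level
#'   [expr_set()]s), `annotation` (probe annotation data.frame) and `truth`
#'   (list: `archetype`, `modules`, `hubs`, `de`, `probe_map`).
#' @export
generate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("Gene%04d", seq_len(n))

  # archetype assignment: planted-effect genes come first, keep them out of
  # the module blocks below by assigning archetypes to a shuffled remainder
  counts <- floor(config$archetype_fractions * n)
  counts[4L] <- n - sum(counts[1:3])
  archetype <- rep(names(counts), counts)[seq_len(n)]
  archetype <- sample(archetype)
  names(archetype) <- genes
  juvenile_variant <- stats::setNames(sample(1:2, n, replace = TRUE), genes)

  # module membership: genes without planted KO effects; when a module
  # declares an archetype, its members are reassigned to it (one shared
  # curve variant) so CV selection and the SOM keep them together
  effect_genes <- unique(config$ko_effects$gene)
  pool <- setdiff(genes, effect_genes)
  modules <- list()
  used <- character()
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    members <- setdiff(pool, used)[seq_len(m$size)]
    if (anyNA(members)) stop("not enough genes for modules", call. = FALSE)
    if (!is.null(m$archetype)) {
      archetype[members] <- m$archetype
      juvenile_variant[members] <- 1L
    }
    modules[[paste0("M", i)]] <- list(members = members, hub = members[1L],
                                      hub_loading = m$hub_loading,
                                      member_loading = m$member_loading,
                                      archetype = m$archetype %||% NA)
    used <- c(used, members)
  }

  samples <- expand.grid(replicate = 1:3, timepoint = TIMEPOINTS,
                         genotype = GENOTYPES, stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste(genotype, timepoint, replicate,
                                           sep = "_"))
  samples <- validate_sample_sheet(
    samples[, c("sample_id", "genotype", "timepoint", "replicate")])
  ns <- nrow(samples)

  base <- stats::setNames(stats::runif(n, 6, 12), genes)
  # planted-effect genes sit in the mid-intensity range: rank-based
  # normalization compresses fold changes at the intensity extremes
  # (bright probes saturate in rank), which is a property of the
  # normalization, not of the DE machinery under test
  if (length(effect_genes))
    base[effect_genes] <- stats::runif(length(effect_genes), 7.5, 10)
  tp_idx <- match(as.character(samples$timepoint), TIMEPOINTS)

  amplitude <- stats::setNames(
    stats::runif(n, config$amplitude_range[1], config$amplitude_range[2]),
    genes)
  noise_sd <- stats::setNames(
    config$noise_sd_log2 * exp(stats::rnorm(n, 0,
                                            config$noise_sd_spread_log)),
    genes)
  mu <- matrix(0, n, ns, dimnames = list(genes, samples$sample_id))
  for (g in seq_len(n)) {
    curve <- archetype_curve(archetype[g], juvenile_variant[g])
    mu[g, ] <- base[g] + amplitude[g] * curve[tp_idx]
  }
  for (mod in modules) {
    z <- stats::rnorm(ns)
    loads <- stats::setNames(rep(mod$member_loading, length(mod$members)),
                             mod$members)
    loads[mod$hub] <- mod$hub_loading
    mu[mod$members, ] <- mu[mod$members, ] + outer(loads, z)
  }
  ko_cols <- samples$genotype == "ko"
  for (i in seq_len(nrow(config$ko_effects))) {
    eff <- config$ko_effects[i, ]
    if (!eff$gene %in% genes) stop("ko_effects gene not in gene set: ",
                                   eff$gene, call. = FALSE)
    cols <- ko_cols & as.character(samples$timepoint) == eff$timepoint
    mu[eff$gene, cols] <- mu[eff$gene, cols] + log2(eff$fold_change)
  }

  eps <- matrix(stats::rnorm(n * ns), n, ns) * noise_sd
  signal <- 2^(mu + eps)

  # secondary probes: scaled-down copies of the realized primary values so
  # the primary is strictly brighter at every sample
  n_multi <- round(config$multi_probe_fraction * n)
  multi_genes <- if (n_multi > 0) sample(genes, n_multi) else character()
  delta <- stats::setNames(stats::runif(n_multi, 0.5, 1.5), multi_genes)

  probe_of <- function(g, k) sprintf("PB_%s_%d", sub("^Gene", "", g), k)
  primary_ids <- probe_of(genes, 1L)
  rownames(signal) <- primary_ids
  if (n_multi > 0) {
    secondary <- signal[probe_of(multi_genes, 1L), , drop = FALSE] *
      rep(2^(-delta), ns)
    rownames(secondary) <- probe_of(multi_genes, 2L)
    signal <- rbind(signal, secondary)
  }

  # negative controls: low-intensity log-normal background
  q05 <- stats::quantile(signal, 0.05)
  nc_ids <- sprintf("NEG_%04d", seq_len(config$n_negative_controls))
  nc <- matrix(2^(stats::rnorm(config$n_negative_controls * ns,
                               mean = log2(q05) - 2.5, sd = 0.4)),
               config$n_negative_controls, ns,
               dimnames = list(nc_ids, samples$sample_id))
  values <- rbind(signal, nc)

  probe_map <- data.frame(
    probe_id = c(primary_ids, if (n_multi > 0) probe_of(multi_genes, 2L)),
    gene_symbol = c(genes, multi_genes),
    stringsAsFactors = FALSE)

  # quality flags: never on probes whose gene carries a planted role
  protected <- unique(c(effect_genes, unlist(lapply(modules, `[[`, "members"))))
  flaggable <- probe_map$probe_id[!probe_map$gene_symbol %in% protected]
  n_bad <- round(config$bad_probe_fraction * nrow(probe_map))
  bad_ids <- if (n_bad > 0) sample(flaggable, min(n_bad, length(flaggable)))
             else character()
  quality <- stats::setNames(rep("good", nrow(probe_map)), probe_map$probe_id)
  if (length(bad_ids))
    quality[bad_ids] <- rep_len(c("bad", "no_match"), length(bad_ids))

  annotation <- rbind(
    data.frame(probe_id = probe_map$probe_id,
               gene_symbol = probe_map$gene_symbol,
               quality = unname(quality),
               is_negative_control = FALSE, stringsAsFactors = FALSE),
    data.frame(probe_id = nc_ids, gene_symbol = "",
               quality = "good", is_negative_control = TRUE,
               stringsAsFactors = FALSE))
  annotation <- validate_probe_annotation(annotation)

  ctrl_cols <- samples$genotype == "control"
  truth <- list(archetype = archetype,
                amplitude = amplitude, noise_sd = noise_sd,
                modules = modules,
                hubs = vapply(modules, `[[`, "", "hub"),
                de = config$ko_effects,
                probe_map = probe_map,
                flagged_probes = bad_ids)
  list(control = expr_set(values[, ctrl_cols], samples[ctrl_cols, ],
                          require_positive = TRUE),
       ko = expr_set(values[, !ctrl_cols], samples[!ctrl_cols, ],
                     require_positive = TRUE),
       annotation = annotation, truth = truth, config = config)
}

#' Simulate a single one-factor co-expression module
#'
#' Small helper for network benchmarking: `x_g = loading_g * z + noise`,
#' with unit marginal variance, the first gene being the hub.
#'
#' @param n_genes module size (hub included).
#' @param n_samples number of samples.
#' @param hub_loading factor loading of the hub gene.
#' @param member_loading loading of the remaining genes.
#' @param seed integer seed.
#' @return numeric matrix genes x samples, first row `hub`.
#' @export
simulate_module_expr <- function(n_genes = 20, n_samples = 15,
                                 hub_loading = 0.95, member_loading = 0.5,
                                 seed = 1L) {
  stopifnot(n_genes >= 2, n_samples >= 4)
  set.seed(seed)
  loads <- c(hub_loading, rep(member_loading, n_genes - 1L))
  z <- stats::rnorm(n_samples)
  noise <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  x <- outer(loads, z) + noise * sqrt(1 - loads^2)
  rownames(x) <- c("hub", sprintf("member%02d", seq_len(n_genes - 1L)))
  x
}

#' Generate promoter FASTA files with planted motif occurrences
#'
#' Background sequences are i.i.d. draws from the PWM's background base
#' frequencies; a planted sequence additionally receives one motif instance
#' sampled from the PWM column probabilities, inserted at a uniform random
#' position on a uniform random strand.
#'
#' @param n_fg,n_bg number of foreground/background sequences.
#' @param length sequence length (>= motif length).
#' @param pwm a [pwm()] object.
#' @param planted_fraction_fg,planted_fraction_bg fraction of sequences in
#'   each group receiving a planted occurrence (in `[0, 1]`).
#' @param seed integer seed.
#' @param fg_path,bg_path optional paths; when given, sequences are written
#'   as FASTA.
#' @return list with `fg` and `bg` (named character vectors of sequences)
#'   and `truth` (data.frame: seq name, group, planted, position, strand).
#' @export
generate_promoters <- function(n_fg, n_bg, length, pwm,
                               planted_fraction_fg = 0.5,
                               planted_fraction_bg = 0.05,
                               seed = 1L, fg_path = NULL, bg_path = NULL) {
  stopifnot(inherits(pwm, "pwm"), length >= ncol(pwm$prob), n_fg >= 1,
            n_bg >= 1)
  if (planted_fraction_fg < 0 || planted_fraction_fg > 1 ||
      planted_fraction_bg < 0 || planted_fraction_bg > 1)
    stop("planted fractions must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm$prob)
  make_group <- function(n, frac, prefix) {
    planted <- seq_len(n) <= round(frac * n)
    truth <- data.frame(name = sprintf("%s_%03d", prefix, seq_len(n)),
                        planted = planted, position = NA_integer_,
                        strand = NA_character_, stringsAsFactors = FALSE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(bases, length, replace = TRUE, prob = pwm$background)
      if (planted[i]) {
        inst <- vapply(seq_len(L), function(j)
          sample(bases, 1L, prob = pwm$prob[, j]), "")
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") inst <- rev(chartr("ACGT", "TGCA", inst))
        pos <- sample.int(length - L + 1L, 1L)
        s[pos:(pos + L - 1L)] <- inst
        truth$position[i] <<- pos
        truth$strand[i] <<- strand
      }
      paste(s, collapse = "")
    }, "")
    names(seqs) <- truth$name
    list(seqs = seqs, truth = truth)
  }
  fg <- make_group(n_fg, planted_fraction_fg, "fg")
  bg <- make_group(n_bg, planted_fraction_bg, "bg")
  fg$truth$group <- "fg"; bg$truth$group <- "bg"
  if (!is.null(fg_path)) write_fasta(fg$seqs, fg_path)
  if (!is.null(bg_path)) write_fasta(bg$seqs, bg_path)
  list(fg = fg$seqs, bg = bg$seqs, truth = rbind(fg$truth, bg$truth))
}

#' Read promoter sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences (case preserved; soft-masked
#'   lowercase stretches are meaningful to the motif scanner).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
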