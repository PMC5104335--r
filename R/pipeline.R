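#' Run the full analysis pipeline
#'
#' simulate/load -> preprocess -> CV + SOM clustering -> per-cluster
#' bootstrap hub networks -> per-age differential expression -> DE-hub
#' intersection and cross-age consistency. Enrichment is left to the
#' caller because it needs external gene sets / promoter sequences.
#'
#' @param control,ko raw probe-level [expr_set()]s.
#' @param annotation probe annotation.
#' @param cv_fraction CV selection fraction.
#' @param som som configuration ([som_config()]).
#' @param network network configuration ([network_config()]).
#' @param fdr_max,fc_min DE thresholds.
#' @return list: `preprocess`, `clusters` (`som_result`), `networks`,
#'   `de` (`de_table`), `de_hubs`, `consistent`.
#' @export
run_pipeline <- function(control, ko, annotation, cv_fraction = 0.30,
                         som = som_config(), network = network_config(),
                         fdr_max = 0.01, fc_min = 1.5) {
  pre <- preprocess_pipeline(control, ko, annotation)
  clusters <- som_cluster(pre$expr, cv_fraction = cv_fraction,
                          config = som)
  networks <- cluster_networks(pre$expr, clusters$assignment,
                               config = network)
  de <- de_timepoints(pre$expr, fdr_max = fdr_max, fc_min = fc_min)
  list(preprocess = pre, clusters = clusters, networks = networks,
       de = de, de_hubs = intersect_de_hubs(de, networks),
       consistent = consistent_de(de))
}
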