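# End-to-end convenience wrapper: cohort -> filters -> windows -> DPG ->
# GNN embeddings -> DTW K-means subphenotypes.

#' Run the full subphenotyping pipeline
#'
#' Applies the cohort filters, vectorizes windows, builds the directed
#' patient graph, trains the encoder, extracts per-patient embedding
#' sequences and clusters them with DTW K-means.
#'
#' The default encoder configuration trains the MagNet encoder with a short
#' *representation budget* (25 epochs): the next-window prediction task is
#' auxiliary here — its purpose is a faithful longitudinal representation,
#' and training it to convergence progressively collapses within-class
#' patient heterogeneity onto the three outcome classes, which is exactly
#' the structure the clustering stage needs. When the classifier itself is
#' the product, train with [train_gnn()] and the full default budget
#' instead; see the package vignette for the measurements behind this
#' split.
#'
#' @param cohort an `ehr_cohort`
#' @param k similarity neighbors per node in the DPG
#' @param K number of subphenotypes
#' @param cfg an [encoder_config()]; NULL for the representation-budget
#'   default described above
#' @param maps code maps
#' @param window_days window width
#' @param n_init K-means restarts
#' @param seed seed controlling the encoder (when `cfg` is NULL) and the
#'   clustering stage
#' @return list with `filter`, `features`, `graph`, `fit`, `sequences`,
#'   `clusters` (a [ts_kmeans()] fit) and `assignments`
#' @export
run_subphenotyping <- function(cohort, k = 15L, K = 4L, cfg = NULL,
                               maps = default_code_maps(),
                               window_days = 90L, n_init = 5L, seed = 1L) {
  cfg <- cfg %||% encoder_config(variant = "magnet", embedding_dim = 64L,
                                 loss = "focal", q = 0.05, dropout = 0.5,
                                 epochs = 25L, seed = seed)
  flt <- cohort_filter(cohort)
  feats <- vectorize_cohort(cohort, patient_ids = flt$eligible, maps = maps,
                            window_days = window_days)
  graph <- build_dpg(feats, k = k)
  fit <- train_gnn(graph, cfg)
  seqs <- embedding_sequences(fit, graph)
  clus <- ts_kmeans(seqs, K = K, seed = seed, n_init = n_init)
  list(filter = flt, features = feats, graph = graph, fit = fit,
       sequences = seqs, clusters = clus, assignments = clus$cluster)
}
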