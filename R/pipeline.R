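# End-to-end synthetic study: generate -> partition -> delineate/extract ->
# train -> threshold -> test metrics -> SHAP importance, with every
# intermediate persisted as CSV so stages can be re-run.

#' Default pipeline configuration
#'
#' Flat key = value list; all training defaults match the classifier's
#' stated hyperparameters (Adam 0.001/0.9/0.999, dropout 0.3, max 400
#' epochs, patience 10, prevalence-derived class weights).
#'
#' @param ... Overrides of the defaults.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_records = 200, af_fraction = 0.08, duration_s = 20,
    lead_set = "twelve", hidden = c(16, 8), seed = 1L,
    fractions = c(0.7, 0.2, 0.1),
    background_size = 100, n_permutations = 500,
    out_dir = NULL
  )
  upd <- list(...)
  if (length(upd) == 1 && is.list(upd[[1]]) && is.null(names(upd))) upd <- upd[[1]]
  for (k in names(upd)) {
    if (!k %in% names(cfg)) stop("unknown pipeline config key: ", k)
    cfg[[k]] <- upd[[k]]
  }
  cfg$lead_set <- as.character(cfg$lead_set)
  lead_set_leads(cfg$lead_set)  # validates, with an error listing options
  cfg
}

#' Run the full synthetic AF-detection study
#'
#' Generates a labelled synthetic dataset, partitions it patient-wise,
#' extracts AV-synchronization features, fits the dense classifier with
#' validation-threshold selection, evaluates on the held-out test subset
#' and computes SHAP feature importance over the test records against a
#' seeded training background.
#'
#' @param config A [pipeline_config()] list (or overrides passed to it).
#' @return List with `manifest`, `features`, `model`, `metrics` (test
#'   confusion counts and Se/Sp/BAC/F1), and `importance` (a `shap_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!identical(sort(names(config)), sort(names(pipeline_config()))))
    config <- pipeline_config(config)
  set.seed(config$seed)

  ds <- generate_dataset(config$n_records, config$af_fraction,
                         seed = config$seed, duration_s = config$duration_s)
  manifest <- partition_dataset(ds$manifest, config$fractions,
                                seed = config$seed + 1L)

  fx <- extract_features_dataset(ds$records, lead_set = config$lead_set)
  feats <- fx$features
  manifest <- manifest[manifest$record_id %in% rownames(feats), ]
  feats <- feats[manifest$record_id, , drop = FALSE]

  sel <- function(sub) manifest$subset == sub
  model <- af_densenet(feats[sel("train"), ], manifest$label[sel("train")],
                       hidden = config$hidden,
                       x_val = feats[sel("validation"), ],
                       y_val = manifest$label[sel("validation")],
                       seed = config$seed)
  metrics <- evaluate_model(model, feats[sel("test"), ],
                            manifest$label[sel("test")])

  set.seed(config$seed + 2L)
  train_ids <- which(sel("train"))
  bg_idx <- sample(train_ids, min(config$background_size, length(train_ids)))
  importance <- explain_model(model, feats[sel("test"), , drop = FALSE],
                              feats[bg_idx, , drop = FALSE],
                              n_permutations = config$n_permutations,
                              seed = config$seed)

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(d, "manifest.csv"), row.names = FALSE)
    write.csv(cbind(record_id = rownames(feats), feats),
              file.path(d, "features.csv"), row.names = FALSE)
    write.csv(metrics, file.path(d, "metrics.csv"), row.names = FALSE)
    write.csv(importance$report$ranked, file.path(d, "shap_global.csv"),
              row.names = FALSE)
    save_model(model, file.path(d, "model.json"))
  }
  list(manifest = manifest, features = feats, model = model,
       metrics = metrics, importance = importance, rejected = fx$rejected)
}
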