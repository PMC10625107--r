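# End-to-end demo pipeline: sample -> label -> train -> predict -> score ->
# laws -> transfer. Every stage is deterministic given the configuration, so
# a rerun with the same config reproduces all outputs byte for byte.

#' Pipeline configuration
#'
#' @param out_dir artifact directory (created if missing).
#' @param length peptide length for the sampled space.
#' @param n_train,n_test sizes of the training pool (includes the validation
#'   quarter) and the held-out test set.
#' @param seed master seed for sampling, labelling and training.
#' @param epochs,batch_size,learning_rate training-protocol overrides for the
#'   desk-scale run.
#' @param dropout decoder dropout rate.
#' @param n_transfer_pairs pairs in the transferability stage.
#' @param surrogate [surrogate_params()] used as the label oracle.
#' @param hc [hc_params()] for the corrected scores.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, length = 5L, n_train = 2000L,
                            n_test = 500L, seed = 0L, epochs = 10L,
                            batch_size = 256L, learning_rate = 0.2,
                            dropout = 0, n_transfer_pairs = 200L,
                            surrogate = surrogate_params(),
                            hc = hc_params()) {
  stopifnot(is.character(out_dir), n_train >= 8L, n_test >= 2L)
  structure(list(out_dir = out_dir, length = as.integer(length),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 n_transfer_pairs = as.integer(n_transfer_pairs),
                 surrogate = surrogate, hc = hc),
            class = "pipeline_config")
}

#' Run the screening pipeline end to end
#'
#' Samples the sequence space, labels it with the surrogate oracle, trains the
#' scaled regression network, predicts the held-out set, assembles the score
#' table (AP', logP', AP_H, AP_HC), derives the range partition and residue
#' composition, and runs the transferability stage. Artifacts are written
#' under `config$out_dir`; deterministic outputs are identical across reruns
#' of the same config.
#'
#' @param config [pipeline_config()].
#' @param verbose log stage progress.
#' @return invisibly, a list with the stage results (`labels`, `fit`,
#'   `metrics`, `scores`, `composition`, `transfer`, `files`).
#' @export
pipeline_run <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[3]

  say("[sample] %d peptides of length %d (seed %d)",
      config$n_train + config$n_test, config$length, config$seed)
  pool <- suppressMessages(
    lhs_sample(config$length, config$n_train + config$n_test,
               seed = config$seed))

  say("[label] surrogate oracle, noise sd %.3f", config$surrogate$noise_sd)
  labelled <- label_dataset(pool, config$surrogate, seed = config$seed)
  f_labels <- file.path(config$out_dir, "labels.csv")
  write_scores(labelled, f_labels,
               annotations = list(seed = config$seed, source = "surrogate",
                                  noise_sd = config$surrogate$noise_sd))

  say("[train] scaled TRN, %d epochs", config$epochs)
  cfg <- trn_config("scaled", model_length = config$length,
                    dropout = config$dropout)
  tcfg <- trn_train_config(learning_rate = config$learning_rate,
                           epochs = config$epochs,
                           batch_size = config$batch_size, n_seeds = 1L)
  train_data <- labelled[seq_len(config$n_train), ]
  test_data <- labelled[config$n_train + seq_len(config$n_test), ]
  fit <- trn_train(train_data, cfg, tcfg, seed = config$seed)
  f_model <- file.path(config$out_dir, "model.rds")
  saveRDS(fit$model, f_model)

  say("[predict] %d held-out peptides", nrow(test_data))
  pred <- trn_predict(fit$model, test_data$system)
  metrics <- evaluate_predictions(pred, test_data$ap)
  f_pred <- file.path(config$out_dir, "predictions.csv")
  write_scores(data.frame(system = test_data$system, ap_sim = test_data$ap,
                          ap_prd = pred, stringsAsFactors = FALSE),
               f_pred, annotations = list(seed = config$seed))

  say("[score] AP', logP', AP_H, AP_HC")
  scores <- score_table(test_data$system, pred, params = config$hc)
  f_scores <- file.path(config$out_dir, "scores.csv")
  write_scores(scores, f_scores, annotations = list(seed = config$seed))

  say("[laws] range partition and composition")
  ranges <- partition_ranges(scores$ap_prime)
  comp <- composition_by_range(scores$sequence, ranges)
  f_comp <- file.path(config$out_dir, "composition.csv")
  utils::write.csv(as.data.frame(comp), f_comp)

  say("[transfer] %d pairs", config$n_transfer_pairs)
  records <- make_transfer_fixture(config$n_transfer_pairs, config$surrogate,
                                   seed = config$seed)
  transfer <- transfer_analysis(records)
  f_transfer <- file.path(config$out_dir, "transfer.csv")
  write_scores(records, f_transfer, annotations = list(seed = config$seed))

  summary <- list(seed = config$seed, n_train = config$n_train,
                  n_test = config$n_test, test_mae = metrics$mae,
                  test_r2 = metrics$r2,
                  frac_mix_positive = transfer$frac_mix_positive,
                  median_delta_mix = transfer$median_delta_mix,
                  range_counts = as.list(attr(ranges, "counts")))
  f_summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, f_summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("[done] %.1f s; test MAE %.4f, R2 %.3f", proc.time()[3] - t_start,
      metrics$mae, metrics$r2)

  invisible(list(labels = labelled, fit = fit, metrics = metrics,
                 scores = scores, composition = comp, transfer = transfer,
                 files = c(labels = f_labels, model = f_model,
                           predictions = f_pred, scores = f_scores,
                           composition = f_comp, transfer = f_transfer,
                           summary = f_summary)))
}
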