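#' Validation performance as a function of network depth
#'
#' Trains one model per requested depth (all hidden widths equal to the
#' first entry of `config$layer_sizes`, embedding taken halfway) and reports
#' the best validation loss and labeled-set accuracy, so the effect of depth
#' on this data can be inspected directly.
#'
#' @param features A `feature_matrix` (or aligned matrix).
#' @param network A `ppi_network`.
#' @param labels Named label vector as in [train_gcn()].
#' @param depths Integer vector of total layer counts to try.
#' @param config Base `model_config`; width and seed are taken from it.
#' @return Data frame with `depth`, `best_epoch`, `validation_loss`,
#'   `train_accuracy`.
#' @export
depth_profile <- function(features, network, labels, depths = 2:6,
                          config = model_config()) {
  width <- config$layer_sizes[[1L]]
  rows <- lapply(depths, function(d) {
    l1 <- max(1L, d %/% 2L)
    cfg <- model_config(layer_sizes = rep(width, d), l1 = l1, l2 = d - l1,
                        lambda_weight = config$lambda_weight,
                        learning_rate = config$learning_rate,
                        max_epochs = config$max_epochs,
                        patience = config$patience,
                        seed = derive_seed(config$seed, "depth", d))
    model <- train_gcn(features, network, labels, cfg)
    probs <- predict.gcn_model(model, features, network)
    pred <- model$classes[max.col(probs[names(labels), , drop = FALSE])]
    data.frame(depth = d, best_epoch = model$best_epoch,
               validation_loss = min(model$trace$validation),
               train_accuracy = mean(pred == as.character(labels)))
  })
  do.call(rbind, rows)
}

#' Write the per-epoch training log as TSV
#'
#' Columns: epoch, supervised, unsupervised, total, validation.
#'
#' @param model A `gcn_model` with a training trace.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(model, path) {
  stopifnot(inherits(model, "gcn_model"), !is.null(model$trace))
  utils::write.table(model$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
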