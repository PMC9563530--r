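#' Train the semi-supervised graph-convolutional classifier
#'
#' Alternating stochastic gradient descent: each epoch takes one gradient
#' step on the supervised loss over a batch of labeled nodes, then one step
#' on `lambda * L_u` over a batch of sampled context triples. A stratified
#' fraction of the labeled nodes is held out and its supervised loss
#' monitored; training stops once it has not decreased for `patience`
#' consecutive epochs, and the parameters from the best epoch are returned.
#' Fully deterministic given `config$seed`.
#'
#' @param features A `feature_matrix` (or a plain numeric matrix row-aligned
#'   with `network$gene_order`).
#' @param network A `ppi_network`.
#' @param labels Named vector (names = gene IDs) labeling a subset of nodes;
#'   at least one node per class.
#' @param config A `model_config`.
#' @return A `gcn_model`: list with `params` (best-epoch `model_params`),
#'   `trace` (per-epoch data frame: `epoch`, `supervised`, `unsupervised`,
#'   `total`, `validation`), `classes`, `config` and the number of clipped
#'   gradient steps in `attr(trace, "clipped_steps")`.
#' @export
train_gcn <- function(features, network, labels, config = model_config()) {
  stopifnot(inherits(network, "ppi_network"), inherits(config, "model_config"))
  X <- if (inherits(features, "feature_matrix")) features$values else features
  N <- length(network$gene_order)
  if (nrow(X) != N)
    stop_validation("feature rows (", nrow(X), ") do not match network size (",
                    N, ")")
  if (is.null(labels) || length(labels) == 0L)
    stop_validation("empty label set")
  lab_idx <- match(names(labels), network$gene_order)
  if (anyNA(lab_idx))
    stop_validation("labeled gene(s) absent from the network: ",
                    paste(head(names(labels)[is.na(lab_idx)], 3), collapse = ", "))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop_validation("labels must cover at least 2 classes")
  yidx <- match(as.character(labels), classes)

  A_tilde <- make_propagation_matrix(network, config)
  P0 <- propagate_input(A_tilde, X, config)

  # stratified validation split for early stopping
  split <- with_seed(derive_seed(config$seed, "valsplit"), {
    val <- integer(0)
    for (k in seq_along(classes)) {
      members <- which(yidx == k)
      n_val <- floor(length(members) * config$validation_fraction)
      if (length(members) - n_val < 1L) n_val <- length(members) - 1L
      if (n_val > 0L) val <- c(val, sample(members, n_val))
    }
    val
  })
  train_pos <- setdiff(seq_along(lab_idx), split)
  val_pos <- split
  train_labels <- labels[train_pos]

  params <- init_params(config, ncol(X), length(classes), N,
                        seed = derive_seed(config$seed, "init"))

  n_epochs <- config$max_epochs
  trace <- data.frame(epoch = integer(0), supervised = numeric(0),
                      unsupervised = numeric(0), total = numeric(0),
                      validation = numeric(0))
  clipped_steps <- 0L
  best <- list(params = params, val = Inf, epoch = 0L)
  stall <- 0L

  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(n_epochs)) {
      # supervised step
      bsz <- min(config$batch_labeled, length(train_pos))
      batch <- if (bsz == length(train_pos)) train_pos else
        sample(train_pos, bsz)
      cache <- forward_all(params, P0, A_tilde, config)
      g <- sup_grad_graph(params, P0, A_tilde, lab_idx[batch], yidx[batch],
                          config, cache)
      cl <- clip_grads(g, config$clip_norm)
      if (cl$clipped) clipped_steps <- clipped_steps + 1L
      params <- sgd_step(params, cl$grads, config$learning_rate)

      # context step
      triples <- NULL
      if (config$lambda_weight > 0) {
        triples <- sample_context(network, train_labels, config,
                                  config$batch_context)
        cache <- forward_all(params, P0, A_tilde, config)
        g <- ctx_grad_graph(params, P0, A_tilde, triples, config, cache)
        g$W <- lapply(g$W, `*`, config$lambda_weight)
        g$b <- lapply(g$b, `*`, config$lambda_weight)
        g$Wc <- g$Wc * config$lambda_weight
        cl <- clip_grads(g, config$clip_norm)
        if (cl$clipped) clipped_steps <- clipped_steps + 1L
        params <- sgd_step(params, cl$grads, config$learning_rate)
      }

      # epoch report
      cache <- forward_all(params, P0, A_tilde, config)
      probs <- probs_from_cache(params, cache, config)
      ls <- -mean(log(pmax(probs[cbind(lab_idx[train_pos], yidx[train_pos])],
                           1e-300)))
      lu <- if (is.null(triples)) 0 else
        context_loss(triples, cache$H[[config$l1]], params)
      val <- if (length(val_pos)) {
        -mean(log(pmax(probs[cbind(lab_idx[val_pos], yidx[val_pos])], 1e-300)))
      } else ls
      if (!is.finite(ls) || !is.finite(lu) || !is.finite(val))
        stop("training diverged at epoch ", epoch,
             " (non-finite loss); try a smaller learning rate")
      trace[epoch, ] <- list(epoch, ls, lu,
                              ls + config$lambda_weight * lu, val)

      if (val < best$val - 1e-12) {
        best <- list(params = params, val = val, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  attr(trace, "clipped_steps") <- clipped_steps
  structure(list(params = best$params, best_epoch = best$epoch,
                 trace = trace, classes = classes, config = config),
            class = "gcn_model")
}

make_propagation_matrix <- function(network, config) {
  At <- add_self_loops(network)
  if (config$normalize_adjacency) {
    d <- Matrix::rowSums(At)
    Dm <- Matrix::Diagonal(x = 1 / sqrt(d))
    At <- Dm %*% At %*% Dm
  }
  At
}

#' @export
print.gcn_model <- function(x, ...) {
  cat("gcn_model:", length(x$params$W), "layers,",
      nrow(x$trace), "epochs (best", x$best_epoch, "),",
      "classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Node class probabilities under a trained model
#'
#' Runs the full graph forward pass and returns the per-node class
#' distribution.
#'
#' @param object A `gcn_model`.
#' @param features Feature matrix used at training time (row-aligned with
#'   the network).
#' @param network The `ppi_network` the model was trained on.
#' @param ... Unused.
#' @return Numeric matrix, nodes x classes, rownames = gene IDs.
#' @export
predict.gcn_model <- function(object, features, network, ...) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  A_tilde <- make_propagation_matrix(network, object$config)
  P0 <- propagate_input(A_tilde, X, object$config)
  cache <- forward_all(object$params, P0, A_tilde, object$config)
  probs <- probs_from_cache(object$params, cache, object$config)
  dimnames(probs) <- list(network$gene_order, object$classes)
  probs
}

#' Write a model checkpoint as JSON
#'
#' Stores all weight arrays and the configuration in a single versioned
#' JSON file (text, portable; adequate at these model sizes).
#'
#' @param model A `gcn_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gcn_model"))
  obj <- list(format = "gcnprio-checkpoint", version = 1L,
              config = unclass(model$config), classes = model$classes,
              best_epoch = model$best_epoch,
              params = list(W = model$params$W, b = model$params$b,
                            Wy = model$params$Wy, Wc = model$params$Wc,
                            input_width = model$params$input_width,
                            n_classes = model$params$n_classes))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `gcn_model` (without a training trace).
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gcnprio-checkpoint"))
    stop_validation("not a gcnprio checkpoint: ", path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  params <- structure(list(W = lapply(obj$params$W, as.matrix),
                           b = lapply(obj$params$b, as.numeric),
                           Wy = as.matrix(obj$params$Wy),
                           Wc = as.matrix(obj$params$Wc),
                           input_width = as.integer(obj$params$input_width),
                           n_classes = as.integer(obj$params$n_classes)),
                      class = "model_params")
  structure(list(params = params, best_epoch = obj$best_epoch,
                 trace = NULL, classes = obj$classes, config = cfg),
            class = "gcn_model")
}
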