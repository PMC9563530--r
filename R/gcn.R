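#' Model configuration for the semi-supervised graph-convolutional classifier
#'
#' Collects the architecture and training hyperparameters. Defaults follow a
#' four-layer network of width 16 trained with plain SGD (learning rate 0.01,
#' at most 200 epochs, early stopping after 10 epochs without improvement of
#' the validation loss).
#'
#' @param layer_sizes Hidden widths of the `l1 + l2` layers.
#' @param l1 Layers applied before the embedding `e = h^l1(x)` used by the
#'   graph-context loss.
#' @param l2 Layers applied after the embedding.
#' @param lambda_weight Weight of the unsupervised context loss in the
#'   combined objective `L_s + lambda * L_u`.
#' @param learning_rate SGD step size.
#' @param max_epochs Maximum number of training epochs (one supervised and
#'   one context gradient step per epoch).
#' @param patience Early-stopping window: training stops after this many
#'   consecutive epochs without a decrease of the validation loss.
#' @param batch_labeled,batch_context Batch sizes for the supervised step and
#'   for the sampled context triples.
#' @param walk_length Random-walk length `q` for graph-context sampling.
#' @param window Co-occurrence window `d` within a walk.
#' @param negative_ratio Fraction of sampled triples with `gamma = -1`.
#' @param label_context_ratio Probability that a positive triple is
#'   label-based (shared class) rather than walk-based.
#' @param validation_fraction Fraction of labeled nodes held out (stratified)
#'   to monitor early stopping.
#' @param or_propagation_depth Number of leading layers whose propagation
#'   uses the boolean OR product; it applies only while the propagated
#'   matrix is binary, i.e. at layer 1 where `H^0 = X`. Must be 0 or 1.
#' @param normalize_adjacency If TRUE, use the symmetrically normalized
#'   `D^-1/2 (A+I) D^-1/2` instead of the raw `A + I` (default off: raw
#'   augmented adjacency, with the OR product at layer 1).
#' @param clip_norm Global gradient-norm clip guarding against divergence.
#' @param seed Integer seed; all randomness in training derives from it.
#' @return A `model_config` list.
#' @export
model_config <- function(layer_sizes = c(16, 16, 16, 16),
                         l1 = 2, l2 = 2,
                         lambda_weight = 1,
                         learning_rate = 0.01,
                         max_epochs = 200,
                         patience = 10,
                         batch_labeled = 64,
                         batch_context = 64,
                         walk_length = 10,
                         window = 3,
                         negative_ratio = 0.5,
                         label_context_ratio = 0.5,
                         validation_fraction = 0.2,
                         or_propagation_depth = 1,
                         normalize_adjacency = FALSE,
                         clip_norm = 5,
                         seed = 1) {
  if (l1 < 1 || l2 < 0) stop_validation("need l1 >= 1 and l2 >= 0")
  if (length(layer_sizes) != l1 + l2)
    stop_validation("length(layer_sizes) must equal l1 + l2")
  if (any(layer_sizes < 1)) stop_validation("zero-width layer")
  if (learning_rate <= 0) stop_validation("learning_rate must be positive")
  if (patience < 1) stop_validation("patience must be >= 1")
  if (lambda_weight < 0) stop_validation("lambda_weight must be >= 0")
  if (batch_labeled < 1 || batch_context < 1)
    stop_validation("batch sizes must be >= 1")
  if (!or_propagation_depth %in% c(0, 1))
    stop_validation("or_propagation_depth must be 0 or 1 (the OR product is ",
                    "defined only where the propagated matrix is binary)")
  if (negative_ratio < 0 || negative_ratio > 1 ||
      label_context_ratio < 0 || label_context_ratio > 1 ||
      validation_fraction < 0 || validation_fraction >= 1)
    stop_validation("ratios must lie in [0, 1]")
  structure(list(layer_sizes = as.integer(layer_sizes),
                 l1 = as.integer(l1), l2 = as.integer(l2),
                 lambda_weight = lambda_weight,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_labeled = as.integer(batch_labeled),
                 batch_context = as.integer(batch_context),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 negative_ratio = negative_ratio,
                 label_context_ratio = label_context_ratio,
                 validation_fraction = validation_fraction,
                 or_propagation_depth = as.integer(or_propagation_depth),
                 normalize_adjacency = isTRUE(normalize_adjacency),
                 clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' Layer weights are drawn uniformly within the Glorot bound
#' `sqrt(6 / (fan_in + fan_out))`; biases start at zero. Deterministic given
#' the seed.
#'
#' @param config A `model_config`.
#' @param input_width Feature width `m`.
#' @param n_classes Number of classes.
#' @param n_context Number of context units (one weight vector `w_c` per
#'   node of the graph).
#' @param seed Integer seed.
#' @return A `model_params` list with `W` (list of layer weights, shapes
#'   chaining from `input_width`), `b` (zero biases), `Wy` (class weights on
#'   the concatenated `[h^l1, h^l]` representation) and `Wc` (context
#'   weights).
#' @export
init_params <- function(config, input_width, n_classes, n_context,
                        seed = config$seed) {
  stopifnot(inherits(config, "model_config"))
  if (input_width < 1 || n_classes < 2 || n_context < 1)
    stop_validation("invalid widths for parameter initialization")
  widths <- c(input_width, config$layer_sizes)
  l <- length(config$layer_sizes)
  with_seed(seed, {
    W <- lapply(seq_len(l), function(k) glorot(widths[k], widths[k + 1]))
    b <- lapply(seq_len(l), function(k) numeric(widths[k + 1]))
    d1 <- config$layer_sizes[config$l1]
    dl <- config$layer_sizes[l]
    Wy <- glorot(d1 + dl, n_classes)
    Wc <- glorot(n_context, d1)
    structure(list(W = W, b = b, Wy = Wy, Wc = Wc,
                   input_width = as.integer(input_width),
                   n_classes = as.integer(n_classes)),
              class = "model_params")
  })
}

#' Feed-forward hidden representation of a single feature vector
#'
#' Applies `depth` dense layers `h^k(x) = ReLU(W^k h^{k-1}(x) + b^k)` with
#' `h^0(x) = x`; no graph propagation is involved (this is the per-sample
#' view of the network used when a gene has no node in the graph).
#'
#' @param x Numeric feature vector of the model's input width.
#' @param params A `model_params`.
#' @param depth Number of layers to apply (0 returns `x` unchanged).
#' @return Numeric vector.
#' @export
hidden_forward <- function(x, params, depth) {
  if (depth < 0 || depth > length(params$W))
    stop_validation("depth must lie in 0..", length(params$W))
  if (length(x) != params$input_width)
    stop_validation("feature vector has width ", length(x),
                    ", expected ", params$input_width)
  h <- as.numeric(x)
  for (k in seq_len(depth))
    h <- pmax(drop(h %*% params$W[[k]]) + params$b[[k]], 0)
  h
}

#' One graph-convolution layer
#'
#' Propagate-then-transform: the neighbourhood aggregation of `H` under
#' `A_tilde` (boolean OR for binary inputs, ordinary summation otherwise)
#' followed by the layer's linear map and a ReLU.
#'
#' @param A_tilde Self-loop-augmented adjacency.
#' @param H Input activations (binary if `binary_mode`).
#' @param W Layer weight matrix.
#' @param binary_mode Use the boolean OR product (requires binary `H`).
#' @return Dense activation matrix `ReLU(prop(A_tilde, H) %*% W)`.
#' @export
gcn_layer <- function(A_tilde, H, W, binary_mode = FALSE) {
  P <- if (binary_mode) {
    or_propagate(A_tilde, H)
  } else {
    A_tilde %*% H
  }
  pmax(as.matrix(P %*% W), 0)
}

# Precompute the layer-1 propagated input: OR product while X is binary
# (the default), ordinary product otherwise.
propagate_input <- function(A_tilde, X, config) {
  if (config$or_propagation_depth >= 1L &&
      is_binary_matrix(A_tilde) && is_binary_matrix(X)) {
    or_propagate(A_tilde, X)
  } else {
    A_tilde %*% X
  }
}

# Full forward pass over all N nodes. P0 is the precomputed layer-1
# propagated input; deeper layers propagate their (real-valued) activations
# with the ordinary sparse product. Returns per-layer pre-activations Z,
# activations H and propagated inputs M (needed by backprop).
forward_all <- function(params, P0, A_tilde, config) {
  l <- length(params$W)
  H <- Z <- M <- vector("list", l)
  for (k in seq_len(l)) {
    M[[k]] <- if (k == 1L) P0 else A_tilde %*% H[[k - 1L]]
    Zk <- as.matrix(M[[k]] %*% params$W[[k]])
    Zk <- Zk + matrix(params$b[[k]], nrow(Zk), ncol(Zk), byrow = TRUE)
    Z[[k]] <- Zk
    H[[k]] <- pmax(Zk, 0)
  }
  list(H = H, Z = Z, M = M)
}

softmax_rows <- function(logits) {
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  e / rowSums(e)
}

# Class probabilities for all nodes from a forward cache: softmax over the
# class weights applied to the concatenation [h^l1, h^l].
probs_from_cache <- function(params, cache, config) {
  l <- length(params$W)
  softmax_rows(cbind(cache$H[[config$l1]], cache$H[[l]]) %*% params$Wy)
}

#' Class distribution for a single feature vector
#'
#' Softmax over the class weights applied to the concatenated
#' representation `[h^l1(x), h^l(x)]` computed feed-forward.
#'
#' @param x Numeric feature vector.
#' @param params A `model_params`.
#' @param config A `model_config`.
#' @return Numeric probability vector summing to 1.
#' @export
predict_proba <- function(x, params, config) {
  h1 <- hidden_forward(x, params, config$l1)
  hl <- h1
  l <- length(params$W)
  for (k in seq.int(config$l1 + 1L, length.out = l - config$l1))
    hl <- pmax(drop(hl %*% params$W[[k]]) + params$b[[k]], 0)
  logits <- drop(c(h1, hl) %*% params$Wy)
  p <- exp(logits - max(logits))
  p / sum(p)
}

#' Mean negative log-likelihood of labeled samples (feed-forward view)
#'
#' @param x Matrix of feature rows (or a single vector).
#' @param y Integer class indices (1-based), one per row.
#' @param params,config Model parameters and configuration.
#' @return Nonnegative scalar loss.
#' @export
supervised_loss <- function(x, y, params, config) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) == 0L) stop_validation("empty labeled set")
  if (length(y) != nrow(x)) stop_validation("labels do not match rows")
  p <- vapply(seq_len(nrow(x)), function(i)
    predict_proba(x[i, ], params, config)[y[[i]]], 0)
  -mean(log(pmax(p, 1e-300)))
}

#' Graph-context (unsupervised) loss
#'
#' Mean over sampled triples `(i, c, gamma)` of
#' `-log sigmoid(gamma * w_c' e_i)`, with `e_i` the embedding of node `i`.
#'
#' @param triples Data frame with integer columns `i`, `c` and `gamma`
#'   (+1 or -1).
#' @param embeddings Matrix of node embeddings (rows indexed by `i`).
#' @param params A `model_params` (supplies the context weights `Wc`,
#'   rows indexed by `c`).
#' @return Nonnegative scalar loss.
#' @export
context_loss <- function(triples, embeddings, params) {
  if (NROW(triples) == 0L) stop_validation("empty context sample")
  if (!all(triples$gamma %in% c(-1, 1)))
    stop_validation("gamma must be +1 or -1")
  s <- rowSums(embeddings[triples$i, , drop = FALSE] *
                 params$Wc[triples$c, , drop = FALSE])
  v <- triples$gamma * s
  # -log sigmoid(v) = softplus(-v), computed stably
  mean(pmax(-v, 0) + log1p(exp(-abs(v))))
}

# ---- training-mode objectives (graph forward) and their gradients --------

sup_loss_graph <- function(params, P0, A_tilde, rows, yidx, config) {
  cache <- forward_all(params, P0, A_tilde, config)
  probs <- probs_from_cache(params, cache, config)
  -mean(log(pmax(probs[cbind(rows, yidx)], 1e-300)))
}

zero_grads <- function(params) {
  list(W = lapply(params$W, function(w) array(0, dim(w))),
       b = lapply(params$b, function(v) numeric(length(v))),
       Wy = array(0, dim(params$Wy)),
       Wc = array(0, dim(params$Wc)))
}

# Backpropagate dH arriving at layer `top` down to layer 1, accumulating
# layer gradients. `inject` optionally adds a second dH contribution at
# layer `at` (used for the concatenated classifier input when l2 > 0).
backprop_layers <- function(dH_top, top, inject = NULL, at = NULL,
                            params, cache, A_tilde, grads) {
  dH <- dH_top
  for (k in seq.int(top, 1L)) {
    if (!is.null(at) && k == at) dH <- dH + inject
    dZ <- dH * (cache$Z[[k]] > 0)
    grads$W[[k]] <- grads$W[[k]] + as.matrix(Matrix::crossprod(cache$M[[k]], dZ))
    grads$b[[k]] <- grads$b[[k]] + colSums(dZ)
    if (k > 1L)
      dH <- as.matrix(A_tilde %*% (dZ %*% t(params$W[[k]])))
  }
  grads
}

sup_grad_graph <- function(params, P0, A_tilde, rows, yidx, config,
                           cache = forward_all(params, P0, A_tilde, config)) {
  l <- length(params$W)
  l1 <- config$l1
  d1 <- ncol(cache$H[[l1]])
  n <- nrow(cache$H[[l]])
  B <- length(rows)
  concat <- cbind(cache$H[[l1]][rows, , drop = FALSE],
                  cache$H[[l]][rows, , drop = FALSE])
  probs <- softmax_rows(concat %*% params$Wy)
  dlog <- probs
  dlog[cbind(seq_len(B), yidx)] <- dlog[cbind(seq_len(B), yidx)] - 1
  dlog <- dlog / B
  grads <- zero_grads(params)
  grads$Wy <- crossprod(concat, dlog)
  dC <- dlog %*% t(params$Wy)
  scatter <- function(block) {
    m <- matrix(0, n, ncol(block))
    m[rows, ] <- block
    m
  }
  dHl1 <- scatter(dC[, seq_len(d1), drop = FALSE])
  dHl  <- scatter(dC[, d1 + seq_len(ncol(dC) - d1), drop = FALSE])
  if (l1 == l) {
    backprop_layers(dHl1 + dHl, l, params = params, cache = cache,
                    A_tilde = A_tilde, grads = grads)
  } else {
    backprop_layers(dHl, l, inject = dHl1, at = l1, params = params,
                    cache = cache, A_tilde = A_tilde, grads = grads)
  }
}

ctx_loss_graph <- function(params, P0, A_tilde, triples, config) {
  cache <- forward_all(params, P0, A_tilde, config)
  context_loss(triples, cache$H[[config$l1]], params)
}

ctx_grad_graph <- function(params, P0, A_tilde, triples, config,
                           cache = forward_all(params, P0, A_tilde, config)) {
  l1 <- config$l1
  E <- cache$H[[l1]]
  s <- rowSums(E[triples$i, , drop = FALSE] *
                 params$Wc[triples$c, , drop = FALSE])
  g <- triples$gamma
  n <- length(s)
  ds <- -g / (1 + exp(g * s)) / n       # d loss / d score, sigma(-g s) form
  grads <- zero_grads(params)
  tmp <- ds * E[triples$i, , drop = FALSE]
  agg <- rowsum(tmp, group = triples$c)
  grads$Wc[as.integer(rownames(agg)), ] <- agg
  dErows <- ds * params$Wc[triples$c, , drop = FALSE]
  aggE <- rowsum(dErows, group = triples$i)
  dE <- matrix(0, nrow(E), ncol(E))
  dE[as.integer(rownames(aggE)), ] <- aggE
  backprop_layers(dE, l1, params = params, cache = cache,
                  A_tilde = A_tilde, grads = grads)
}

# Global-norm gradient clipping; returns grads plus whether clipping fired.
clip_grads <- function(grads, max_norm) {
  flat <- c(unlist(grads$W), unlist(grads$b), grads$Wy, grads$Wc)
  nrm <- sqrt(sum(flat^2))
  clipped <- is.finite(nrm) && nrm > max_norm
  if (clipped) {
    sc <- max_norm / nrm
    grads$W <- lapply(grads$W, `*`, sc)
    grads$b <- lapply(grads$b, `*`, sc)
    grads$Wy <- grads$Wy * sc
    grads$Wc <- grads$Wc * sc
  }
  list(grads = grads, clipped = clipped)
}

sgd_step <- function(params, grads, lr) {
  for (k in seq_along(params$W)) {
    params$W[[k]] <- params$W[[k]] - lr * grads$W[[k]]
    params$b[[k]] <- params$b[[k]] - lr * grads$b[[k]]
  }
  params$Wy <- params$Wy - lr * grads$Wy
  params$Wc <- params$Wc - lr * grads$Wc
  params
}
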