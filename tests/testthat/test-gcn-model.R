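cfg_small <- model_config(layer_sizes = c(4, 3), l1 = 1, l2 = 1,
                          max_epochs = 5, seed = 9)

test_that("parameter initialization is Glorot-bounded, zero-biased, seeded", {
  p1 <- init_params(cfg_small, input_width = 6, n_classes = 2, n_context = 8,
                    seed = 123)
  p2 <- init_params(cfg_small, input_width = 6, n_classes = 2, n_context = 8,
                    seed = 123)
  expect_identical(p1, p2)
  lim <- sqrt(6 / (6 + 4))
  expect_true(all(abs(p1$W[[1]]) <= lim))
  expect_true(all(abs(p1$W[[2]]) <= sqrt(6 / (4 + 3))))
  expect_true(all(p1$b[[1]] == 0) && all(p1$b[[2]] == 0))
  expect_error(init_params(cfg_small, 0, 2, 3), class = "gcnprio_validation")
})

test_that("feed-forward hidden layers follow the ReLU recursion", {
  p <- init_params(cfg_small, 4, 2, 3, seed = 5)
  x <- c(0.3, 0, 1, 0.5)
  expect_identical(hidden_forward(x, p, 0), x)      # h^0(x) = x

  pneg <- p
  pneg$W[[1]] <- -diag(4)
  expect_equal(hidden_forward(x, pneg, 1), rep(0, 4))  # ReLU kills negatives

  # hand-rolled two-layer loop oracle
  h1 <- pmax(as.numeric(x %*% p$W[[1]]) + p$b[[1]], 0)
  h2 <- pmax(as.numeric(h1 %*% p$W[[2]]) + p$b[[2]], 0)
  expect_equal(hidden_forward(x, p, 2), h2)
  expect_error(hidden_forward(c(1, 2), p, 1), class = "gcnprio_validation")
})

test_that("a graph-convolution layer ORs neighbourhoods then transforms", {
  H <- diag(3)                                    # one-hot features
  expect_equal(gcn_layer(diag(3), H, diag(3), binary_mode = TRUE), H,
               ignore_attr = TRUE)
  # 3-node path graph with self-loops: rows = OR over closed neighbourhoods
  A <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  out <- gcn_layer(A, H, diag(3), binary_mode = TRUE)
  expect_equal(out, rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)),
               ignore_attr = TRUE)
  # additive propagation differs where a node has 2+ annotated neighbours
  H2 <- rbind(c(1, 0), c(1, 0), c(1, 0))
  or_out <- gcn_layer(A, H2, diag(2), binary_mode = TRUE)
  add_out <- gcn_layer(A, H2, diag(2), binary_mode = FALSE)
  expect_equal(or_out[, 1], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(add_out[, 1], c(2, 3, 2), ignore_attr = TRUE)
})

test_that("predicted class distributions form a simplex", {
  p <- init_params(cfg_small, 5, 3, 4, seed = 77)
  # symmetric class weights give the uniform distribution
  psym <- p
  psym$Wy <- matrix(0.37, nrow(p$Wy), ncol(p$Wy))
  expect_equal(predict_proba(runif(5), psym, cfg_small), rep(1 / 3, 3))

  # scalar softmax oracle on fixed small params
  set.seed(2)
  x <- runif(5)
  h1 <- hidden_forward(x, p, 1)
  h2 <- hidden_forward(x, p, 2)
  logits <- as.numeric(c(h1, h2) %*% p$Wy)
  expect_equal(predict_proba(x, p, cfg_small),
               exp(logits) / sum(exp(logits)))

  for (s in 1:5) {
    pr <- init_params(cfg_small, 5, 3, 4, seed = s)
    probs <- predict_proba(rnorm(5), pr, cfg_small)
    expect_true(all(probs >= 0))
    expect_equal(sum(probs), 1)
  }
})

test_that("supervised loss is the mean negative log-likelihood", {
  p <- init_params(cfg_small, 4, 2, 3, seed = 5)
  psym <- p
  psym$Wy <- matrix(0, nrow(p$Wy), 2)          # uniform 2-class model
  x <- matrix(runif(12), 3, 4)
  expect_equal(supervised_loss(x, c(1, 2, 1), psym, cfg_small), log(2))

  # per-sample loop oracle
  y <- c(2, 1, 2)
  oracle <- -mean(vapply(1:3, function(i)
    log(predict_proba(x[i, ], p, cfg_small)[y[i]]), 0))
  expect_equal(supervised_loss(x, y, p, cfg_small), oracle)
  expect_error(supervised_loss(matrix(0, 0, 4), integer(0), p, cfg_small),
               class = "gcnprio_validation")
})

test_that("context loss matches the scalar logistic form", {
  d <- 3
  E <- rbind(c(1, 0, 0), c(0, 2, 0))
  p <- list(Wc = rbind(c(0, 0, 0), c(1, 1, 1)))
  # zero dot product gives ln 2 for either sign
  t0 <- data.frame(i = 1L, c = 1L, gamma = 1L)
  expect_equal(context_loss(t0, E, p), log(2))
  t0$gamma <- -1L
  expect_equal(context_loss(t0, E, p), log(2))

  # mixed batch of four hand-set dot products
  tr <- data.frame(i = c(1L, 1L, 2L, 2L), c = c(2L, 2L, 2L, 1L),
                   gamma = c(1L, -1L, 1L, -1L))
  s <- c(1, 1, 2, 0)
  expected <- mean(-log(1 / (1 + exp(-tr$gamma * s))))
  expect_equal(context_loss(tr, E, p), expected)
  expect_error(context_loss(tr[0, ], E, p), class = "gcnprio_validation")
})

test_that("training traces satisfy the combined-loss identity and seeding", {
  tp <- tiny_problem(n = 8, m = 6, seed = 3)
  labels <- stats::setNames(c("disease", "disease", "other", "other"),
                            tp$genes[c(1, 2, 7, 8)])
  cfg <- model_config(layer_sizes = c(4, 4), l1 = 1, l2 = 1,
                      max_epochs = 12, patience = 12, batch_labeled = 4,
                      batch_context = 8, walk_length = 4, window = 2,
                      validation_fraction = 0, seed = 17)
  m1 <- train_gcn(tp$X, tp$network, labels, cfg)
  m2 <- train_gcn(tp$X, tp$network, labels, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$trace$total,
               m1$trace$supervised + cfg$lambda_weight * m1$trace$unsupervised)
  expect_true(all(is.finite(as.matrix(m1$trace))))
})

test_that("a small supervised gradient step does not increase batch loss", {
  tp <- tiny_problem(n = 6, m = 5, seed = 4)
  cfg <- model_config(layer_sizes = c(4, 3), l1 = 1, l2 = 1,
                      lambda_weight = 0, seed = 2)
  At <- add_self_loops(tp$network)
  P0 <- or_propagate(At, tp$X)
  params <- init_params(cfg, ncol(tp$X), 2, 6, seed = 2)
  rows <- c(1L, 6L); y <- c(1L, 2L)
  before <- gcnprio:::sup_loss_graph(params, P0, At, rows, y, cfg)
  g <- gcnprio:::sup_grad_graph(params, P0, At, rows, y, cfg)
  after <- gcnprio:::sup_loss_graph(gcnprio:::sgd_step(params, g, 0.01),
                                    P0, At, rows, y, cfg)
  expect_lte(after, before)
})

test_that("with lambda 0 and an edgeless graph the model is a plain MLP", {
  # independent minimal dense implementation, same seeding protocol
  n <- 10; m <- 7
  genes <- sprintf("n%02d", 1:n)
  net <- ppi_from_adjacency(matrix(0, n, n, dimnames = list(genes, genes)))
  set.seed(8)
  X <- Matrix::Matrix(matrix(as.numeric(runif(n * m) < 0.5), n, m,
                             dimnames = list(genes, NULL)), sparse = TRUE)
  labels <- stats::setNames(rep(c("disease", "other"), each = 3),
                            genes[c(1:3, 8:10)])
  cfg <- model_config(layer_sizes = c(5, 4), l1 = 1, l2 = 1,
                      lambda_weight = 0, max_epochs = 15, patience = 15,
                      batch_labeled = 6, validation_fraction = 0, seed = 33)
  model <- train_gcn(X, net, labels, cfg)

  # --- minimal reference: dense forward/backward, no graph ----------------
  glorot_ref <- function(fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(runif(fi * fo, -lim, lim), fi, fo)
  }
  params <- gcnprio:::with_seed(gcnprio:::derive_seed(33L, "init"), {
    W <- list(glorot_ref(m, 5), glorot_ref(5, 4))
    b <- list(numeric(5), numeric(4))
    Wy <- glorot_ref(5 + 4, 2)
    Wc <- glorot_ref(n, 5)
    list(W = W, b = b, Wy = Wy, Wc = Wc)
  })
  Xd <- as.matrix(X)
  lab_idx <- match(names(labels), genes)
  yidx <- ifelse(labels == "disease", 1L, 2L)
  fwd <- function(p) {
    H1 <- pmax(sweep(Xd %*% p$W[[1]], 2, p$b[[1]], "+"), 0)
    H2 <- pmax(sweep(H1 %*% p$W[[2]], 2, p$b[[2]], "+"), 0)
    C <- cbind(H1, H2)
    L <- C %*% p$Wy
    P <- exp(L - apply(L, 1, max)); P <- P / rowSums(P)
    list(H1 = H1, H2 = H2, C = C, P = P)
  }
  ref_trace <- numeric(0)
  for (epoch in 1:15) {
    f <- fwd(params)
    B <- length(lab_idx)
    dL <- f$P[lab_idx, ]
    dL[cbind(1:B, yidx)] <- dL[cbind(1:B, yidx)] - 1
    dL <- dL / B
    gWy <- crossprod(f$C[lab_idx, ], dL)
    dC <- dL %*% t(params$Wy)
    dH1 <- matrix(0, n, 5); dH2 <- matrix(0, n, 4)
    dH1[lab_idx, ] <- dC[, 1:5]; dH2[lab_idx, ] <- dC[, 6:9]
    dZ2 <- dH2 * (f$H2 > 0)
    gW2 <- crossprod(f$H1, dZ2); gb2 <- colSums(dZ2)
    dH1 <- dH1 + dZ2 %*% t(params$W[[2]])
    dZ1 <- dH1 * (f$H1 > 0)
    gW1 <- crossprod(Xd, dZ1); gb1 <- colSums(dZ1)
    nrm <- sqrt(sum(gW1^2) + sum(gW2^2) + sum(gb1^2) + sum(gb2^2) +
                  sum(gWy^2))
    sc <- if (nrm > 5) 5 / nrm else 1
    params$W[[1]] <- params$W[[1]] - 0.01 * sc * gW1
    params$W[[2]] <- params$W[[2]] - 0.01 * sc * gW2
    params$b[[1]] <- params$b[[1]] - 0.01 * sc * gb1
    params$b[[2]] <- params$b[[2]] - 0.01 * sc * gb2
    params$Wy <- params$Wy - 0.01 * sc * gWy
    f <- fwd(params)
    ref_trace[epoch] <- -mean(log(f$P[cbind(lab_idx, yidx)]))
  }
  expect_equal(model$trace$supervised, ref_trace, tolerance = 1e-10)
})
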