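# Transformer-based regression network (TRN) for AP prediction: token
# embedding + sinusoidal positional encoding, a stack of post-norm encoder
# blocks (multi-head self-attention and feed-forward sublayers, each with a
# residual connection and layer normalization), and an MLP decoder over the
# flattened encoder output with batch normalization, leaky-rectifier
# activations and dropout. Trained with plain SGD on mean squared error;
# model selection by validation MAE.

#' TRN architecture configuration
#'
#' The `"full"` preset is the production architecture (512-dim embedding, 6
#' encoder blocks, 8 heads with 64-dim K/Q/V, 2048-dim feed-forward, MLP
#' \[512, 256, 64, 32, 1\]); the `"scaled"` preset keeps the same topology at
#' desk scale (64-dim embedding, 2 blocks, 4 heads of 16, 256-dim
#' feed-forward, MLP \[64, 32, 16, 8, 1\]) and is the default for tests and
#' examples.
#'
#' @param preset `"scaled"` or `"full"`.
#' @param model_length fixed token length: 5 (pentapeptides), 10 (single
#'   peptides up to decapeptides, shorter ones padded), or 11 (mixed
#'   pentapeptides, `PEN1+PEN2`).
#' @param pooling `"flatten"` concatenates all position embeddings before the
#'   MLP; `"mean"` averages them.
#' @param dropout dropout rate in the MLP decoder.
#' @param lrelu_slope negative slope of the leaky-rectifier activation.
#' @param embed_dim,n_blocks,n_heads,head_dim,ffn_dim,mlp_dims overrides of
#'   the preset architecture.
#' @return list of class `trn_config`.
#' @export
trn_config <- function(preset = c("scaled", "full"), model_length = 5L,
                       pooling = c("flatten", "mean"), dropout = 0.1,
                       lrelu_slope = 0.01, embed_dim = NULL, n_blocks = NULL,
                       n_heads = NULL, head_dim = NULL, ffn_dim = NULL,
                       mlp_dims = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "full")
    list(embed_dim = 512L, n_blocks = 6L, n_heads = 8L, head_dim = 64L,
         ffn_dim = 2048L, mlp_dims = c(512L, 256L, 64L, 32L, 1L))
  else
    list(embed_dim = 64L, n_blocks = 2L, n_heads = 4L, head_dim = 16L,
         ffn_dim = 256L, mlp_dims = c(64L, 32L, 16L, 8L, 1L))
  cfg <- list(preset = preset,
              embed_dim = as.integer(embed_dim %||% def$embed_dim),
              n_blocks = as.integer(n_blocks %||% def$n_blocks),
              n_heads = as.integer(n_heads %||% def$n_heads),
              head_dim = as.integer(head_dim %||% def$head_dim),
              ffn_dim = as.integer(ffn_dim %||% def$ffn_dim),
              mlp_dims = as.integer(mlp_dims %||% def$mlp_dims),
              model_length = as.integer(model_length),
              pooling = match.arg(pooling),
              dropout = dropout, lrelu_slope = lrelu_slope,
              vocab_size = length(AA_VOCAB))
  if (cfg$n_heads * cfg$head_dim != cfg$embed_dim)
    stop("n_heads * head_dim must equal embed_dim", call. = FALSE)
  if (cfg$mlp_dims[length(cfg$mlp_dims)] != 1L)
    stop("mlp_dims must end at 1", call. = FALSE)
  class(cfg) <- "trn_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a TRN model
#'
#' Initializes all learnable parameters (Xavier-uniform linear maps, unit-gain
#' normalization layers, zero biases) under the given seed; identical seeds
#' give bitwise-identical initial parameters.
#'
#' @param config [trn_config()].
#' @param seed integer seed for parameter initialization.
#' @return list of class `trn_model` with elements `config`, `params`,
#'   `bn_state`, `posenc`.
#' @export
trn_build <- function(config, seed = 0L) {
  stopifnot(inherits(config, "trn_config"))
  set.seed(as.integer(seed))
  d <- config$embed_dim
  params <- list(embed = matrix(rnorm(config$vocab_size * d, 0, 0.1),
                                config$vocab_size, d))
  params$blocks <- lapply(seq_len(config$n_blocks), function(b) {
    list(Wq = init_linear(d, d), bq = numeric(d),
         Wk = init_linear(d, d), bk = numeric(d),
         Wv = init_linear(d, d), bv = numeric(d),
         Wo = init_linear(d, d), bo = numeric(d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         W1 = init_linear(d, config$ffn_dim), b1 = numeric(config$ffn_dim),
         W2 = init_linear(config$ffn_dim, d), b2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  })
  in_dim <- if (config$pooling == "flatten") config$model_length * d else d
  dims <- c(in_dim, config$mlp_dims)
  k <- length(config$mlp_dims)
  params$mlp <- lapply(seq_len(k), function(j) {
    layer <- list(W = init_linear(dims[j], dims[j + 1]),
                  b = numeric(dims[j + 1]))
    if (j < k) {
      layer$bn_g <- rep(1, dims[j + 1])
      layer$bn_b <- numeric(dims[j + 1])
    }
    layer
  })
  bn_state <- lapply(seq_len(k - 1), function(j)
    list(mean = numeric(dims[j + 1]), var = rep(1, dims[j + 1])))
  structure(list(config = config, params = params, bn_state = bn_state,
                 posenc = positional_encoding(config$model_length, d),
                 seed = as.integer(seed)),
            class = "trn_model")
}

#' @export
print.trn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("TRN model (%s preset): embed %d, %d blocks, %d heads x %d,",
                     " ffn %d, mlp [%s], length %d, %s pooling\n"),
              cfg$preset, cfg$embed_dim, cfg$n_blocks, cfg$n_heads,
              cfg$head_dim, cfg$ffn_dim, paste(cfg$mlp_dims, collapse = ", "),
              cfg$model_length, cfg$pooling))
  cat(sprintf("  %d parameters\n", trn_n_params(x)))
  invisible(x)
}

#' @rdname trn_build
#' @param model a `trn_model`.
#' @return `trn_n_params()` returns the total learnable parameter count.
#' @export
trn_n_params <- function(model) {
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1)))
                       else length(x)
  count(model$params)
}

# forward pass; returns predictions and (optionally) the caches needed for
# backprop. `training` switches batch-norm to batch statistics and enables
# dropout (masks drawn from the current RNG stream).
trn_forward <- function(model, tokens, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- cfg$model_length
  stopifnot(ncol(tokens) == L)
  B <- nrow(tokens)
  ids <- as.vector(t(tokens))
  X <- p$embed[ids, , drop = FALSE] + model$posenc[rep(seq_len(L), B), ]
  caches <- list(ids = ids)
  blk_caches <- vector("list", cfg$n_blocks)
  for (bi in seq_len(cfg$n_blocks)) {
    bp <- p$blocks[[bi]]
    att <- attention_fwd(X, bp, L, cfg$n_heads, cfg$head_dim)
    ln1 <- layernorm_fwd(X + att$out, bp$ln1_g, bp$ln1_b)
    H_pre <- bcast_add(ln1$y %*% bp$W1, bp$b1)
    H <- lrelu(H_pre, cfg$lrelu_slope)
    ffn_out <- bcast_add(H %*% bp$W2, bp$b2)
    ln2 <- layernorm_fwd(ln1$y + ffn_out, bp$ln2_g, bp$ln2_b)
    blk_caches[[bi]] <- list(att = att$cache, ln1 = ln1, H_pre = H_pre,
                             H = H, ln1_y = ln1$y, ln2 = ln2)
    X <- ln2$y
  }
  Z <- if (cfg$pooling == "flatten")
    matrix(as.vector(t(X)), nrow = B, byrow = TRUE)
  else {
    acc <- matrix(0, B, cfg$embed_dim)
    for (i in seq_len(L)) acc <- acc + X[seq(i, B * L, by = L), , drop = FALSE]
    acc / L
  }
  k <- length(p$mlp)
  mlp_caches <- vector("list", k)
  A <- Z
  for (j in seq_len(k)) {
    lp <- p$mlp[[j]]
    pre <- bcast_add(A %*% lp$W, lp$b)
    if (j < k) {
      bn <- batchnorm_fwd(pre, lp$bn_g, lp$bn_b, model$bn_state[[j]], training)
      if (training) model$bn_state[[j]] <- bn$state
      act_pre <- bn$y
      act <- lrelu(act_pre, cfg$lrelu_slope)
      if (training && cfg$dropout > 0) {
        mask <- (runif(length(act)) >= cfg$dropout) / (1 - cfg$dropout)
        out <- act * mask
      } else {
        mask <- NULL
        out <- act
      }
      mlp_caches[[j]] <- list(input = A, pre = pre, bn = bn,
                              act_pre = act_pre, mask = mask)
      A <- out
    } else {
      mlp_caches[[j]] <- list(input = A)
      A <- pre
    }
  }
  res <- list(pred = as.vector(A), model = model)
  if (keep_cache)
    res$cache <- list(blocks = blk_caches, mlp = mlp_caches, Z = Z, B = B,
                      ids = ids)
  res
}

# backward pass from d(loss)/d(pred); returns gradients in the same nested
# structure as model$params
trn_backward <- function(model, cache, dpred) {
  cfg <- model$config
  p <- model$params
  L <- cfg$model_length
  B <- cache$B
  k <- length(p$mlp)
  grads <- list()
  dA <- matrix(dpred, ncol = 1)
  gm <- vector("list", k)
  for (j in rev(seq_len(k))) {
    lp <- p$mlp[[j]]
    mc <- cache$mlp[[j]]
    if (j < k) {
      if (!is.null(mc$mask)) dA <- dA * mc$mask
      dact_pre <- dA * lrelu_grad(mc$act_pre, cfg$lrelu_slope)
      bnb <- batchnorm_bwd(dact_pre, mc$bn, lp$bn_g)
      dpre <- bnb$dX
      gm[[j]] <- list(W = crossprod(mc$input, dpre), b = colSums(dpre),
                      bn_g = bnb$dg, bn_b = bnb$db)
    } else {
      dpre <- dA
      gm[[j]] <- list(W = crossprod(mc$input, dpre), b = colSums(dpre))
    }
    dA <- tcrossprod(dpre, lp$W)
  }
  grads$mlp <- gm
  dX <- if (cfg$pooling == "flatten")
    matrix(as.vector(t(dA)), nrow = B * L, byrow = TRUE,
           ncol = cfg$embed_dim)
  else {
    out <- matrix(0, B * L, cfg$embed_dim)
    for (i in seq_len(L)) out[seq(i, B * L, by = L), ] <- dA / L
    out
  }
  gb <- vector("list", cfg$n_blocks)
  for (bi in rev(seq_len(cfg$n_blocks))) {
    bp <- p$blocks[[bi]]
    bc <- cache$blocks[[bi]]
    l2 <- layernorm_bwd(dX, bc$ln2, bp$ln2_g)
    dffn_out <- l2$dX
    dH <- tcrossprod(dffn_out, bp$W2)
    dH_pre <- dH * lrelu_grad(bc$H_pre, cfg$lrelu_slope)
    dln1_y <- l2$dX + tcrossprod(dH_pre, bp$W1)
    l1 <- layernorm_bwd(dln1_y, bc$ln1, bp$ln1_g)
    attb <- attention_bwd(l1$dX, bc$att, bp)
    gb[[bi]] <- list(Wq = attb$dWq, bq = attb$dbq, Wk = attb$dWk,
                     bk = attb$dbk, Wv = attb$dWv, bv = attb$dbv,
                     Wo = attb$dWo, bo = attb$dbo,
                     ln1_g = l1$dg, ln1_b = l1$db,
                     W1 = crossprod(bc$ln1_y, dH_pre), b1 = colSums(dH_pre),
                     W2 = crossprod(bc$H, dffn_out), b2 = colSums(dffn_out),
                     ln2_g = l2$dg, ln2_b = l2$db)
    dX <- l1$dX + attb$dX
  }
  grads$blocks <- gb
  dE <- matrix(0, cfg$vocab_size, cfg$embed_dim)
  acc <- rowsum(dX, group = cache$ids)
  dE[as.integer(rownames(acc)), ] <- acc
  grads$embed <- dE
  grads[names(model$params)]
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: plain stochastic gradient descent
#' (no momentum, schedule or weight decay) at learning rate 0.2, 200 epochs,
#' batch size 512, mean-squared-error loss, a validation split of one quarter
#' of the training data used to select the best epoch, and 10 random seeds
#' whose metrics are averaged. Desk-scale experiments override `epochs`,
#' `learning_rate` and `n_seeds` (see the package vignette).
#'
#' @param learning_rate SGD learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param n_seeds number of independent seeded runs to average.
#' @param validation_fraction fraction of the training data held out for
#'   best-epoch selection.
#' @return list of class `trn_train_config`.
#' @export
trn_train_config <- function(learning_rate = 0.2, epochs = 200L,
                             batch_size = 512L, n_seeds = 10L,
                             validation_fraction = 0.25) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 2,
            n_seeds >= 1, validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_seeds = as.integer(n_seeds),
                 validation_fraction = validation_fraction),
            class = "trn_train_config")
}

#' Train a TRN on a labelled dataset
#'
#' Splits off the validation fraction by a seeded shuffle, minimizes MSE by
#' SGD, records validation MAE after every epoch and returns the parameters
#' of the epoch with minimal validation MAE. The seed fully determines the
#' split, the parameter initialization, the batch order and the dropout
#' masks, so equal seeds give equal results.
#'
#' @param data data.frame with columns `system` and `ap` (e.g. from
#'   [label_dataset()]).
#' @param config [trn_config()].
#' @param tcfg [trn_train_config()].
#' @param seed integer seed.
#' @param verbose print per-epoch validation MAE.
#' @return list with elements `model` (best-validation parameters), `history`
#'   (per-epoch train loss and validation MAE), `best_epoch`, `best_val_mae`,
#'   `seed`.
#' @export
trn_train <- function(data, config, tcfg = trn_train_config(), seed = 0L,
                      verbose = FALSE) {
  stopifnot(is.data.frame(data), all(c("system", "ap") %in% names(data)),
            nrow(data) >= 8L, all(is.finite(data$ap)))
  tokens <- tokenize_systems(data$system, config$model_length)
  y <- as.numeric(data$ap)
  model <- trn_build(config, seed)
  set.seed(as.integer(seed) + 1L)
  n <- nrow(tokens)
  perm <- sample.int(n)
  n_val <- max(1L, floor(n * tcfg$validation_fraction))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  val_tokens <- tokens[val_idx, , drop = FALSE]
  val_y <- y[val_idx]
  best <- list(val_mae = Inf, params = NULL, bn_state = NULL, epoch = NA_integer_)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mae = numeric())
  for (epoch in seq_len(tcfg$epochs)) {
    order_ep <- tr_idx[sample.int(length(tr_idx))]
    losses <- numeric()
    for (start in seq(1L, length(order_ep), by = tcfg$batch_size)) {
      idx <- order_ep[start:min(start + tcfg$batch_size - 1L,
                                length(order_ep))]
      if (length(idx) < 2L) next  # batch norm needs >= 2 samples
      fw <- trn_forward(model, tokens[idx, , drop = FALSE], training = TRUE,
                        keep_cache = TRUE)
      model <- fw$model  # updated batch-norm running stats
      err <- fw$pred - y[idx]
      losses <- c(losses, mean(err ^ 2))
      grads <- trn_backward(model, fw$cache, 2 * err / length(err))
      model$params <- sgd_update(model$params, grads, tcfg$learning_rate)
    }
    val_pred <- trn_predict(model, tokens = val_tokens)
    val_mae <- mean(abs(val_pred - val_y))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_mae = val_mae))
    if (is.finite(val_mae) && val_mae < best$val_mae)
      best <- list(val_mae = val_mae, params = model$params,
                   bn_state = model$bn_state, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train mse %.5f  val mae %.5f", epoch,
                      mean(losses), val_mae))
    if (!is.finite(val_mae)) break  # diverged; keep best so far
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    model$bn_state <- best$bn_state
  }
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_mae = best$val_mae, seed = as.integer(seed))
}

#' Predict AP for peptide systems
#'
#' Deterministic inference: dropout off, batch normalization using running
#' statistics, batched over the input.
#'
#' @param model a trained `trn_model` (or the `model` element of
#'   [trn_train()]'s result).
#' @param systems character vector of peptide systems; alternatively pass a
#'   pre-tokenized integer matrix as `tokens`.
#' @param tokens optional token matrix (overrides `systems`).
#' @param batch_size inference batch size.
#' @return numeric vector of predicted AP values.
#' @export
trn_predict <- function(model, systems = NULL, tokens = NULL,
                        batch_size = 2048L) {
  if (!inherits(model, "trn_model") && is.list(model) && !is.null(model$model))
    model <- model$model
  if (is.null(tokens)) {
    if (is.null(systems)) stop("supply systems or tokens", call. = FALSE)
    tokens <- tokenize_systems(systems, model$config$model_length)
  }
  n <- nrow(tokens)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- trn_forward(model, tokens[idx, , drop = FALSE],
                            training = FALSE)$pred
  }
  out
}

#' Regression evaluation metrics
#'
#' Mean absolute error, coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, and the error-ratio profile
#' `|pred - truth| / truth * 100%` averaged within bins of the true value.
#'
#' @param pred,truth aligned numeric vectors.
#' @param bins optional bin edges over `truth` for the error-ratio profile.
#' @return list with `mae`, `r2`, and `error_ratio` (data.frame of bin
#'   midpoints and mean percentage error ratios).
#' @examples
#' evaluate_predictions(c(1.05), c(1.00))$error_ratio  # 5%
#' @export
evaluate_predictions <- function(pred, truth, bins = NULL) {
  stopifnot(length(pred) == length(truth), length(truth) >= 1L)
  mae <- mean(abs(pred - truth))
  ss_res <- sum((truth - pred) ^ 2)
  ss_tot <- sum((truth - mean(truth)) ^ 2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, -Inf) else 1 - ss_res / ss_tot
  ratio <- abs(pred - truth) / truth * 100
  if (is.null(bins)) {
    er <- data.frame(mid = mean(truth), error_ratio = mean(ratio))
  } else {
    f <- cut(truth, breaks = bins, include.lowest = TRUE)
    mids <- (bins[-length(bins)] + bins[-1]) / 2
    agg <- tapply(ratio, f, mean)
    er <- data.frame(mid = mids, error_ratio = as.numeric(agg))
  }
  list(mae = mae, r2 = r2, error_ratio = er)
}

#' Seed-averaged training runs
#'
#' Repeats [trn_train()] over several seeds and averages the test metrics, the
#' reporting protocol used for all headline numbers.
#'
#' @param data training data (`system`, `ap`).
#' @param test_data held-out test data with the same columns.
#' @param config [trn_config()].
#' @param tcfg [trn_train_config()].
#' @param seeds integer vector of seeds (overrides `tcfg$n_seeds`).
#' @return list with `per_seed` (data.frame: seed, mae, r2, best_epoch) and
#'   `mean_mae`, `mean_r2`.
#' @export
trn_run_seeds <- function(data, test_data, config,
                          tcfg = trn_train_config(),
                          seeds = seq_len(tcfg$n_seeds)) {
  rows <- lapply(seeds, function(s) {
    fit <- trn_train(data, config, tcfg, seed = s)
    pred <- trn_predict(fit$model, test_data$system)
    m <- evaluate_predictions(pred, test_data$ap)
    data.frame(seed = s, mae = m$mae, r2 = m$r2, best_epoch = fit$best_epoch)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, mean_mae = mean(per_seed$mae),
       mean_r2 = mean(per_seed$r2))
}

#' Sample-efficiency curve on surrogate labels
#'
#' Trains the scaled TRN preset on nested subsets of a surrogate-labelled
#' pentapeptide pool and reports seed-averaged test metrics per training size
#' (the desk-scale analogue of a learning curve over 1000/5000/8000 training
#' samples).
#'
#' @param sizes training-set sizes (each includes its validation quarter).
#' @param n_total total pool size; the complement of the largest training set
#'   is the shared test set.
#' @param seeds seeds to average over.
#' @param params surrogate parameters for label generation.
#' @param config,tcfg architecture and training configuration.
#' @param seed seed for pool sampling and labelling.
#' @return data.frame: size, mean_mae, mean_r2.
#' @export
trn_learning_curve <- function(sizes = c(1000L, 5000L, 8000L),
                               n_total = 10000L, seeds = 1:3,
                               params = surrogate_params(),
                               config = trn_config("scaled", model_length = 5L,
                                                   dropout = 0),
                               tcfg = trn_train_config(learning_rate = 0.2,
                                                       epochs = 30L,
                                                       batch_size = 256L,
                                                       n_seeds = length(seeds)),
                               seed = 0L) {
  stopifnot(max(sizes) < n_total)
  pool <- lhs_sample(5L, n_total, seed = seed)
  labelled <- label_dataset(pool, params, seed = seed)
  test_data <- labelled[(max(sizes) + 1L):n_total, ]
  rows <- lapply(sizes, function(sz) {
    run <- trn_run_seeds(labelled[seq_len(sz), ], test_data, config, tcfg,
                         seeds = seeds)
    data.frame(size = sz, mean_mae = run$mean_mae, mean_r2 = run$mean_r2)
  })
  do.call(rbind, rows)
}
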