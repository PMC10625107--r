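test_that("configs validate head geometry and decoder shape", {
  full <- trn_config("full", model_length = 10)
  expect_identical(full$embed_dim, 512L)
  expect_identical(full$n_heads * full$head_dim, full$embed_dim)
  expect_error(trn_config("scaled", n_heads = 3), "head_dim")
  expect_error(trn_config("scaled", mlp_dims = c(16, 4)), "end at 1")
})

test_that("identical seeds give bitwise-identical initial parameters", {
  cfg <- trn_config("scaled", model_length = 5)
  m1 <- trn_build(cfg, seed = 11)
  m2 <- trn_build(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, trn_build(cfg, seed = 12)$params))
})

test_that("parameter count matches analytic layer-size bookkeeping", {
  cfg <- trn_config("scaled", model_length = 5)
  d <- cfg$embed_dim; f <- cfg$ffn_dim; v <- cfg$vocab_size
  per_block <- 4 * (d * d + d) +      # Q, K, V, O projections
    2 * d +                           # layernorm 1
    (d * f + f) + (f * d + d) +       # feed-forward
    2 * d                             # layernorm 2
  dims <- c(cfg$model_length * d, cfg$mlp_dims)
  k <- length(cfg$mlp_dims)
  mlp <- sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1]) +
    2 * sum(dims[2:k])                # batch-norm gains/shifts (not on output)
  expect_identical(trn_n_params(trn_build(cfg, 0)),
                   v * d + cfg$n_blocks * per_block + mlp)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_config(model_length = 3)
  model <- trn_build(cfg, seed = 42)
  set.seed(7)
  tokens <- matrix(sample(1:20, 12, replace = TRUE), 4, 3)
  y <- rnorm(4, 1.4, 0.2)
  fwd <- apscreen:::trn_forward
  bwd <- apscreen:::trn_backward
  loss_fn <- function(m) mean((fwd(m, tokens, training = TRUE)$pred - y)^2)
  fw <- fwd(model, tokens, training = TRUE, keep_cache = TRUE)
  grads <- bwd(model, fw$cache, 2 * (fw$pred - y) / length(y))

  get_leaf <- function(l, path) {for (p in path) l <- l[[p]]; l}
  set_leaf <- function(l, path, v) {
    if (length(path) == 1) {l[[path[[1]]]] <- v; return(l)}
    l[[path[[1]]]] <- set_leaf(l[[path[[1]]]], path[-1], v)
    l
  }
  paths <- list("embed", list("blocks", 1L, "Wq"), list("blocks", 2L, "Wo"),
                list("blocks", 1L, "ln1_g"), list("blocks", 2L, "W1"),
                list("blocks", 2L, "b2"), list("blocks", 1L, "ln2_b"),
                list("mlp", 1L, "W"), list("mlp", 1L, "bn_g"),
                list("mlp", 2L, "bn_b"), list("mlp", 3L, "W"),
                list("mlp", 3L, "b"))
  eps <- 1e-5
  for (pa in paths) {
    pa <- as.list(pa)
    P <- get_leaf(model$params, pa)
    G <- get_leaf(grads, pa)
    set.seed(sum(unlist(lapply(pa, function(x) if (is.character(x)) nchar(x)
                               else x))))
    for (k in sample(length(P), min(4, length(P)))) {
      Pp <- P; Pp[k] <- P[k] + eps
      Pm <- P; Pm[k] <- P[k] - eps
      m1 <- model; m1$params <- set_leaf(model$params, pa, Pp)
      m2 <- model; m2$params <- set_leaf(model$params, pa, Pm)
      num <- (loss_fn(m1) - loss_fn(m2)) / (2 * eps)
      expect_lt(abs(num - G[k]), 1e-6 + 1e-3 * (abs(num) + abs(G[k])))
    }
  }
})

test_that("training is seed-deterministic and selects the best epoch", {
  set.seed(0)
  data <- label_dataset(lhs_sample(3, 300, seed = 1),
                        surrogate_params(noise_sd = 0.02), seed = 1)
  cfg <- tiny_config(model_length = 3)
  tcfg <- trn_train_config(learning_rate = 0.1, epochs = 4, batch_size = 64,
                           n_seeds = 1)
  f1 <- trn_train(data, cfg, tcfg, seed = 5)
  f2 <- trn_train(data, cfg, tcfg, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$best_val_mae, min(f1$history$val_mae))
  expect_lte(f1$best_val_mae, f1$history$val_mae[nrow(f1$history)])
})

test_that("training on constant labels drives predictions to that constant", {
  systems <- lhs_sample(3, 200, seed = 2)
  data <- data.frame(system = systems, ap = rep(1.5, 200))
  fit <- trn_train(data, tiny_config(model_length = 3),
                   trn_train_config(learning_rate = 0.2, epochs = 20,
                                    batch_size = 50, n_seeds = 1), seed = 1)
  pred <- trn_predict(fit$model, systems[1:50])
  expect_lt(mean(abs(pred - 1.5)), 0.05)
  expect_lt(sd(pred), 0.05)
})

test_that("inference is deterministic and batching-invariant", {
  cfg <- tiny_config(model_length = 5)
  model <- trn_build(cfg, seed = 3)
  systems <- lhs_sample(5, 64, seed = 3)
  p1 <- trn_predict(model, systems)
  p2 <- trn_predict(model, systems)
  expect_identical(p1, p2)
  one_by_one <- vapply(systems, function(s) trn_predict(model, s), numeric(1),
                       USE.NAMES = FALSE)
  expect_equal(one_by_one, p1, tolerance = 1e-12)
})

test_that("the scaled network learns noiseless additive labels from 2000 samples", {
  data <- label_dataset(lhs_sample(3, 2500, seed = 4), additive_params(),
                        seed = 4)
  cfg <- trn_config("scaled", model_length = 3, dropout = 0)
  tcfg <- trn_train_config(learning_rate = 0.2, epochs = 30, batch_size = 128,
                           n_seeds = 1)
  fit <- trn_train(data[1:2000, ], cfg, tcfg, seed = 1)
  pred <- trn_predict(fit$model, data$system[2001:2500])
  m <- evaluate_predictions(pred, data$ap[2001:2500])
  expect_gt(m$r2, 0.85)
})

test_that("evaluation metrics match their closed forms", {
  x <- c(1.0, 1.2, 1.5, 2.0)
  perfect <- evaluate_predictions(x, x)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(evaluate_predictions(1.05, 1.00)$error_ratio$error_ratio, 5)
  const <- evaluate_predictions(rep(mean(x), 4), x)
  expect_equal(const$r2, 0)
  expect_equal(evaluate_predictions(c(1.1, 1.1), c(1.0, 1.2))$mae, 0.1)
  er <- evaluate_predictions(c(1.1, 2.2), c(1.0, 2.0),
                             bins = c(0.5, 1.5, 2.5))$error_ratio
  expect_equal(er$error_ratio, c(10, 10))
  expect_error(evaluate_predictions(1:3, 1:2), "length")
})

test_that("swap-augmented training keeps mixed predictions near-symmetric", {
  set.seed(6)
  pens <- lhs_sample(5, 60, seed = 6)
  systems <- paste(pens[1:30], pens[31:60], sep = "+")
  labels <- surrogate_ap(systems, surrogate_params(noise_sd = 0.02), seed = 6)
  aug <- augment_mixed(systems, labels)
  names(aug)[names(aug) == "label"] <- "ap"
  cfg <- tiny_config(model_length = 11)
  tcfg <- trn_train_config(learning_rate = 0.1, epochs = 5, batch_size = 30,
                           n_seeds = 1)
  fit <- trn_train(aug, cfg, tcfg, seed = 2)
  fwdv <- trn_predict(fit$model, systems)
  swapped <- vapply(strsplit(systems, "+", fixed = TRUE),
                    function(p) paste(rev(p), collapse = "+"), character(1))
  bwdv <- trn_predict(fit$model, swapped)
  # swap disagreement stays well below the prediction spread
  expect_lt(mean(abs(fwdv - bwdv)), max(sd(fwdv), 0.02))
})
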