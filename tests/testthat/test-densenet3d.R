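test_that("default architecture has the prescribed structure", {
  cfg <- model_config()
  expect_identical(cfg$growth, 18L)
  expect_identical(cfg$init_kernel, 5L)
  expect_identical(cfg$dense_blocks, 3L)
  expect_identical(cfg$fc_widths, c(512L, 256L, 128L))
  expect_identical(cfg$batch_size, 8L)
  expect_equal(cfg$init_lr, 1e-4)
  expect_identical(cfg$max_epochs, 250L)
  net <- build_model(cfg, c(11, 14, 17), seed = 1)
  expect_identical(net$embedding_dim, 128L)
  sm <- model_summary(net)
  expect_identical(sm$channels[sm$type == "fc"], c(512L, 256L, 128L))
  # concatenative growth: every dense unit adds exactly 18 feature maps
  du <- which(sm$type == "dense_unit")
  for (i in du)
    expect_identical(sm$channels[i],
                     net$nodes[[i]]$cin + 18L)
  # channels entering each transition = block entry + layers_per_block * 18
  entry <- 8L
  for (b in 1:3) {
    after_block <- entry + cfg$layers_per_block * 18L
    conv1 <- Filter(function(nd) nd$type == "conv" && nd$k == 1L, net$nodes)
    expect_identical(conv1[[b]]$cin, after_block)
    entry <- conv1[[b]]$cout
  }
  expect_error(model_config(fc_widths = c(512L, 256L, 64L)), "128")
  expect_error(model_config(growth = 0), "growth")
  expect_error(build_model(cfg, c(0, 10, 10)), "positive")
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- build_model(model_config(), c(11, 14, 17), seed = 1)
  n2 <- build_model(model_config(), c(11, 14, 17), seed = 99)
  expect_identical(n_parameters(n1), n_parameters(n2))
  # identical seed gives identical initial parameters
  n3 <- build_model(model_config(), c(11, 14, 17), seed = 1)
  expect_identical(adiponet:::net_snapshot(n1), adiponet:::net_snapshot(n3))
})

test_that("forward pass: 128-long embeddings, probabilities sum to one", {
  net <- micro_net()
  set.seed(2)
  x <- array(runif(7 * 8 * 9 * 3), c(7, 8, 9, 3))
  fw <- adiponet:::nn_forward(net, x, training = FALSE)
  expect_identical(dim(fw$embedding), c(3L, 128L))
  for (h in net$cfg$class_heads)
    expect_equal(rowSums(fw$class_probs[[h]]), rep(1, 3), tolerance = 1e-12)
  # evaluation mode is deterministic
  fw2 <- adiponet:::nn_forward(net, x, training = FALSE)
  expect_identical(fw$embedding, fw2$embedding)
  expect_error(adiponet:::nn_forward(net, array(0, c(5, 5, 5))), "match")
})

test_that("backpropagation matches numerical gradients through the trunk", {
  net <- micro_net(dims = c(6, 7, 8), seed = 8)
  set.seed(5)
  x <- array(runif(6 * 7 * 8 * 2), c(6, 7, 8, 2))
  fw <- adiponet:::nn_forward(net, x, training = TRUE)
  loss0 <- sum(fw$embedding^2) / 2
  bw <- adiponet:::nn_backward(net, fw, fw$embedding, need_dx = TRUE)
  eps <- 1e-5
  for (i in c(11, 123, 300)) {
    x2 <- x; x2[i] <- x2[i] + eps
    f2 <- adiponet:::nn_forward(net, x2, training = TRUE, keep_cache = FALSE)
    num <- (sum(f2$embedding^2) / 2 - loss0) / eps
    expect_equal(bw$dx[i], num, tolerance = 1e-3)
  }
  # a convolution weight gradient
  k1 <- net$nodes[[1]]$W
  W0 <- net$par[[k1]]
  net$par[[k1]][7] <- W0[7] + eps
  f2 <- adiponet:::nn_forward(net, x, training = TRUE, keep_cache = FALSE)
  num <- (sum(f2$embedding^2) / 2 - loss0) / eps
  net$par[[k1]] <- W0
  expect_equal(bw$grads[[k1]][7], num, tolerance = 1e-3)
})

test_that("learning-rate schedule starts at the configured initial rate", {
  cfg <- model_config()
  expect_equal(adiponet:::lr_schedule(0, cfg), 1e-4)
  lrs <- sapply(0:60, adiponet:::lr_schedule, cfg = cfg)
  expect_true(all(lrs > 0))
  expect_lt(lrs[41], lrs[1])        # decay dominates over cycles
  expect_true(all(lrs <= 1e-4 + 1e-12))
})

test_that("one optimizer step on a single batch decreases its loss", {
  net <- micro_net(dims = c(6, 7, 8), seed = 12)
  set.seed(6)
  n <- 6
  vols <- lapply(seq_len(n), function(i) array(runif(6 * 7 * 8), c(6, 7, 8)))
  lab <- data.frame(sex = rbinom(n, 1, 0.5), Da = rbinom(n, 1, 0.5),
                    Db = rbinom(n, 1, 0.5), Dg = rbinom(n, 1, 0.5),
                    age = runif(n), bmi = runif(n),
                    insulin_sensitivity = runif(n), hba1c = runif(n))
  batch_loss <- function() {
    xb <- adiponet:::assemble_batch(vols, 1:n, c(6, 7, 8))
    fw <- adiponet:::nn_forward(net, xb, training = FALSE)
    g <- new.env()
    adiponet:::head_loss(net, fw, as.matrix(lab), !is.na(as.matrix(lab)),
                         g)$loss
  }
  l0 <- batch_loss()
  folds <- data.frame(id = 1:n, fold = "train")
  train_model(net, vols, lab, folds, seed = 3, max_epochs = 3)
  expect_lt(batch_loss(), l0)
})

test_that("checkpoint selection maximizes validation diabetes AUROC", {
  fake <- structure(list(
    history = data.frame(epoch = 0:2, val_auroc_Da = c(0.6, 0.8, 0.7)),
    checkpoints = list(list(epoch = 0), list(epoch = 1), list(epoch = 2))),
    class = "adiponet_training")
  expect_identical(select_checkpoint(fake)$epoch, 1)
  fake$history$val_auroc_Da <- c(0.7, 0.7, 0.7)   # tie -> earliest epoch
  expect_identical(select_checkpoint(fake)$epoch, 0)
  fake$history <- fake$history[1, ]; fake$checkpoints <- fake$checkpoints[1]
  expect_identical(select_checkpoint(fake)$epoch, 0)
  fake$checkpoints <- list()
  expect_error(select_checkpoint(fake), "checkpoint")
})

test_that("training history records per-epoch metrics and masking works", {
  net <- micro_net(dims = c(6, 7, 8), seed = 20)
  set.seed(30)
  n <- 12
  vols <- lapply(seq_len(n), function(i) array(runif(6 * 7 * 8), c(6, 7, 8)))
  lab <- data.frame(sex = rep(0:1, 6), Da = rep(c(0, 1), each = 6),
                    Db = rbinom(n, 1, 0.5), Dg = rbinom(n, 1, 0.5),
                    age = runif(n), bmi = runif(n),
                    insulin_sensitivity = runif(n), hba1c = runif(n))
  lab$age[c(2, 5)] <- NA   # masked labels must not break training
  folds <- data.frame(id = 1:n,
                      fold = rep(c("train", "validation"), c(8, 4)))
  tr <- train_model(net, vols, lab, folds, seed = 7, max_epochs = 2)
  expect_identical(nrow(tr$history), 2L)
  expect_true(all(c("epoch", "lr", "train_loss", "val_auroc_Da",
                    "val_mae_bmi") %in% names(tr$history)))
  expect_identical(length(tr$checkpoints), 2L)
  expect_error(train_model(net, vols, lab,
                           data.frame(id = 1:n, fold = "validation"),
                           max_epochs = 1),
               "training fold is empty")
})

test_that("inference is reproducible and returns aligned embeddings", {
  net <- micro_net(dims = c(6, 7, 8), seed = 21)
  vols <- lapply(1:5, function(i) array(runif(6 * 7 * 8), c(6, 7, 8)))
  i1 <- infer(net, vols)
  i2 <- infer(net, vols)
  expect_identical(i1, i2)
  expect_identical(dim(i1$embeddings), c(5L, 128L))
  expect_identical(nrow(i1$predictions), 5L)
})
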