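# Multi-task training: masked cross-entropy (two-node softmax heads) plus
# masked mean-absolute-error regression heads, Adam updates under the cyclic
# exponentially decaying learning-rate schedule, per-epoch validation
# metrics and parameter checkpoints.

# Per-batch loss + head gradients.  Returns loss, the gradient at the
# embedding, and head parameter gradients (written into `grads`).
head_loss <- function(net, fw, ybatch, mbatch, grads) {
  par <- net$par
  cfg <- net$cfg
  emb <- fw$embedding
  B <- fw$B
  dE <- matrix(0, B, ncol(emb))
  loss <- 0
  for (h in cfg$class_heads) {
    w <- cfg$loss_weights[[h]]
    y <- ybatch[, h]
    ok <- mbatch[, h] & !is.na(y)
    if (!any(ok)) next
    p <- fw$class_probs[[h]]
    n <- sum(ok)
    loss <- loss - w * sum(log(pmax(p[cbind(which(ok), y[ok] + 1L)],
                                    1e-12))) / n
    dl <- p
    rows <- which(ok)
    hit <- cbind(rows, y[rows] + 1L)
    dl[hit] <- dl[hit] - 1
    dl[!ok, ] <- 0
    dl <- dl * (w / n)
    hd <- net$heads[[h]]
    grads[[hd$W]] <- crossprod(emb, dl)
    grads[[hd$b]] <- colSums(dl)
    dE <- dE + dl %*% t(par[[hd$W]])
  }
  for (h in cfg$reg_heads) {
    w <- cfg$loss_weights[[h]]
    y <- ybatch[, h]
    ok <- mbatch[, h] & !is.na(y)
    if (!any(ok)) next
    pred <- fw$reg[[h]]
    r <- pred - y
    n <- sum(ok)
    loss <- loss + w * sum(abs(r[ok])) / n
    dp <- ifelse(ok, sign(r), 0) * (w / n)
    hd <- net$heads[[h]]
    grads[[hd$W]] <- crossprod(emb, matrix(dp, ncol = 1))
    grads[[hd$b]] <- sum(dp)
    dE <- dE + matrix(dp, ncol = 1) %*% t(par[[hd$W]])
  }
  list(loss = loss, dE = dE)
}

adam_init <- function() new.env(parent = emptyenv())

adam_update <- function(par, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in ls(grads)) {
    g <- grads[[k]]
    mk <- paste0("m_", k); vk <- paste0("v_", k)
    m <- if (is.null(state[[mk]])) g * 0 else state[[mk]]
    v <- if (is.null(state[[vk]])) g * 0 else state[[vk]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[mk]] <- m; state[[vk]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
}

assemble_batch <- function(volumes, idx, dims, aug_cfg = NULL) {
  xb <- array(0, c(dims, length(idx)))
  for (j in seq_along(idx)) {
    v <- volumes[[idx[j]]]
    x <- if (is.list(v)) v$voxels else v
    if (!is.null(aug_cfg)) x <- augment_volume(x, aug_cfg)
    xb[, , , j] <- x
  }
  xb
}

# label matrices in head order; regression labels must already be normalized
label_matrices <- function(labels, cfg) {
  heads <- c(cfg$class_heads, cfg$reg_heads)
  missing <- setdiff(heads, names(labels))
  if (length(missing))
    stop("label table lacks head column(s): ", paste(missing, collapse = ", "))
  y <- as.matrix(labels[heads])
  m <- !is.na(y)
  list(y = y, mask = m)
}

#' Train the multi-task network
#'
#' Runs mini-batch Adam over the training fold with the cyclic exponentially
#' decaying learning-rate schedule (epoch 0 uses exactly the configured
#' initial rate), masked multi-task loss (cross-entropy for the binary
#' heads, MAE for the normalized regression heads, per-head missing-label
#' masking), optional training-time augmentation, and once-per-epoch
#' validation metrics (AUROC per binary head, normalized MAE per regression
#' head).  A full parameter snapshot is checkpointed at every evaluation.
#'
#' @param net an [build_model()] network.
#' @param volumes list of preprocessed, centred volumes (arrays or
#'   `body_volume`s) aligned with `labels` rows.
#' @param labels data.frame holding one column per head; regression columns
#'   normalized to \[0,1\] (see [normalize_labels()]); `NA` = masked.
#' @param folds data.frame from [stratified_split()] aligned with `labels`.
#' @param seed integer; shuffling, dropout and augmentation all derive
#'   from it.
#' @param augment an [augment_config()] or `NULL` for no augmentation.
#' @param max_epochs override of the configured epoch budget.
#' @param verbose print per-epoch progress.
#' @return An `adiponet_training`: history data.frame, checkpoint list and
#'   the trained network.
#' @export
train_model <- function(net, volumes, labels, folds, seed = 1L,
                        augment = NULL, max_epochs = NULL, verbose = FALSE) {
  cfg <- net$cfg
  max_epochs <- max_epochs %||% cfg$max_epochs
  train_idx <- which(folds$fold == "train")
  val_idx <- which(folds$fold == "validation")
  if (!length(train_idx)) stop("training fold is empty")
  lab <- label_matrices(labels, cfg)
  state <- adam_init()
  history <- list()
  checkpoints <- list()
  step <- 0L
  with_rng_seed(seed, {
    for (epoch in seq_len(max_epochs) - 1L) {
      lr <- lr_schedule(epoch, cfg)
      ord <- sample(train_idx)
      nbatch <- ceiling(length(ord) / cfg$batch_size)
      ep_loss <- 0
      for (bi in seq_len(nbatch)) {
        idx <- ord[((bi - 1) * cfg$batch_size + 1):
                     min(bi * cfg$batch_size, length(ord))]
        xb <- assemble_batch(volumes, idx, net$input_dims, augment)
        fw <- nn_forward(net, xb, training = TRUE)
        grads <- new.env(parent = emptyenv())
        hl <- head_loss(net, fw,
                        lab$y[idx, , drop = FALSE],
                        lab$mask[idx, , drop = FALSE], grads)
        if (!is.finite(hl$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", batch ", bi)
        bw <- nn_backward(net, fw, hl$dE, need_dx = FALSE)
        for (k in ls(bw$grads)) grads[[k]] <- bw$grads[[k]]
        step <- step + 1L
        adam_update(net$par, grads, state, lr, step)
        ep_loss <- ep_loss + hl$loss
      }
      met <- if (length(val_idx))
        evaluate_heads(net, volumes[val_idx],
                       labels[val_idx, , drop = FALSE]) else list()
      row <- c(list(epoch = epoch, lr = lr,
                    train_loss = ep_loss / nbatch), met)
      history[[length(history) + 1L]] <- as.data.frame(row)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(epoch = epoch, params = net_snapshot(net), metrics = met)
      if (verbose)
        message(sprintf("epoch %d  lr %.2e  loss %.4f  val Da AUROC %s",
                        epoch, lr, ep_loss / nbatch,
                        format(met$val_auroc_Da %||% NA)))
    }
  })
  structure(list(history = do.call(rbind, history),
                 checkpoints = checkpoints, net = net, cfg = cfg),
            class = "adiponet_training")
}

# validation metrics: AUROC per binary head (NA when single-class),
# normalized MAE per regression head.
evaluate_heads <- function(net, volumes, labels) {
  inf <- infer(net, volumes)
  out <- list()
  for (h in net$cfg$class_heads) {
    y <- labels[[h]]
    ok <- !is.na(y)
    out[[paste0("val_auroc_", h)]] <-
      if (sum(ok) && length(unique(y[ok])) == 2)
        auroc(inf$predictions[[paste0("prob_", h)]][ok], y[ok])
      else NA_real_
  }
  for (h in net$cfg$reg_heads) {
    y <- labels[[h]]
    ok <- !is.na(y)
    out[[paste0("val_mae_", h)]] <-
      if (any(ok)) mean(abs(inf$predictions[[paste0("pred_", h)]][ok] -
                              y[ok])) else NA_real_
  }
  out
}

#' Select the best checkpoint by validation diabetes AUROC
#'
#' Returns the checkpoint maximizing validation AUROC for the diabetes
#' (`Da`) head; ties are broken by the earliest epoch.
#'
#' @param training an `adiponet_training`.
#' @param metric history column to maximize.
#' @return The winning checkpoint (epoch, parameter snapshot, metrics).
#' @export
select_checkpoint <- function(training, metric = "val_auroc_Da") {
  if (!length(training$checkpoints)) stop("no evaluated checkpoints")
  scores <- training$history[[metric]]
  if (is.null(scores) || all(is.na(scores)))
    stop("no usable '", metric, "' evaluations in the history")
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  training$checkpoints[[best]]
}

#' Restore a checkpoint into a network
#' @param net an `adiponet_net`.
#' @param checkpoint from [select_checkpoint()].
#' @export
load_checkpoint <- function(net, checkpoint) {
  net_restore(net, checkpoint$params)
}

#' Run inference on preprocessed volumes
#'
#' Deterministic evaluation-mode forward pass (dropout disabled, batch-norm
#' statistics frozen): per-volume class probabilities, regression values and
#' the 128-dimensional embedding.
#'
#' @param net an `adiponet_net`.
#' @param volumes list of preprocessed, centred volumes.
#' @param batch_size forward-pass batch size.
#' @return list with `predictions` (data.frame: `prob_*` positive-class
#'   probabilities, `pred_*` regression values) and `embeddings`
#'   (n x 128 matrix).
#' @export
infer <- function(net, volumes, batch_size = 8L) {
  n <- length(volumes)
  emb <- matrix(NA_real_, n, net$embedding_dim)
  preds <- list()
  for (h in names(net$heads))
    preds[[h]] <- rep(NA_real_, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- assemble_batch(volumes, idx, net$input_dims)
    fw <- nn_forward(net, xb, training = FALSE, keep_cache = FALSE)
    emb[idx, ] <- fw$embedding
    for (h in net$cfg$class_heads)
      preds[[h]][idx] <- fw$class_probs[[h]][, 2]
    for (h in net$cfg$reg_heads)
      preds[[h]][idx] <- fw$reg[[h]]
  }
  names(preds) <- ifelse(names(preds) %in% net$cfg$class_heads,
                         paste0("prob_", names(preds)),
                         paste0("pred_", names(preds)))
  list(predictions = as.data.frame(preds), embeddings = emb)
}
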