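#' Training configuration
#'
#' Defaults follow the reported strategy: Adam at initial learning rate
#' 0.001 decayed by cosine annealing, batch size 4, up to 100 epochs, and
#' early stopping when the validation Dice fails to improve by at least
#' 0.001 over 10 consecutive epochs.
#'
#' @param batch_size mini-batch size, default 4.
#' @param max_epochs maximum epochs, default 100.
#' @param early_stop_patience epochs without improvement, default 10.
#' @param early_stop_min_delta minimum validation-Dice improvement,
#'   default 0.001.
#' @param seed integer seed governing initialisation and batch shuffling.
#' @param augmentation optional [augmentation_config()] applied on-the-fly
#'   to training batches (NULL disables augmentation).
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, max_epochs = 100L,
                         early_stop_patience = 10L,
                         early_stop_min_delta = 0.001,
                         seed = 1L, augmentation = NULL) {
  stopifnot(batch_size >= 1, max_epochs >= 1, early_stop_patience >= 1,
            early_stop_min_delta >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 seed = as.integer(seed),
                 augmentation = augmentation),
            class = "train_config")
}

#' Early-stopping decision from a validation-Dice history
#'
#' Pure function of the history: returns TRUE iff the last `patience`
#' entries all fail to improve on the best value seen before that window by
#' at least `min_delta`.
#'
#' @param history numeric vector of per-epoch validation Dice values.
#' @param patience window length in epochs.
#' @param min_delta minimum improvement.
#' @return logical stop flag.
#' @export
early_stop_check <- function(history, patience = 10L, min_delta = 0.001) {
  n <- length(history)
  if (n == 0L) stop("history must be non-empty")
  if (n <= patience) return(FALSE)
  best_before <- max(history[seq_len(n - patience)])
  window <- history[(n - patience + 1L):n]
  all(window < best_before + min_delta)
}

# Mean of f x f blocks (used to build the deep-supervision target at the
# deepest scale).
block_mean <- function(m, f) {
  n <- nrow(m) %/% f; k <- ncol(m) %/% f
  a <- array(m[seq_len(n * f), seq_len(k * f)], c(f, n, f, k))
  apply(a, c(2, 4), mean)
}

# Composite loss and its gradients on the two head outputs for one batch.
# prob: (H,W,1,B); aux: (H/8,W/8,1,B); masks: list of matrices.
batch_loss_and_grads <- function(prob, aux, masks, lcfg) {
  B <- dim(prob)[4]
  dprob <- array(0, dim(prob))
  daux <- array(0, dim(aux))
  l_main <- 0; l_aux <- 0; l_size <- 0
  aux_targets <- lapply(masks, function(m) {
    bm <- block_mean(m, nrow(m) %/% dim(aux)[1])
    (bm >= 0.5) * 1
  })
  for (bi in seq_len(B)) {
    p <- prob[, , 1, bi]; y <- masks[[bi]]
    pa <- aux[, , 1, bi]; ya <- aux_targets[[bi]]
    l_main <- l_main + (dice_loss(p, y, lcfg$epsilon) +
                          cross_entropy_loss(p, y)) / B
    l_aux <- l_aux + (dice_loss(pa, ya, lcfg$epsilon) +
                        cross_entropy_loss(pa, ya)) / B
    l_size <- l_size + size_prior_loss(p, lcfg) / B
    dprob[, , 1, bi] <- (dice_loss_grad(p, y, lcfg$epsilon) +
                           cross_entropy_loss_grad(p, y) +
                           size_prior_loss_grad(p, lcfg)) / B
    daux[, , 1, bi] <- (dice_loss_grad(pa, ya, lcfg$epsilon) +
                          cross_entropy_loss_grad(pa, ya)) / B
  }
  # global consistency term: Dice over the pooled batch
  pv <- as.vector(prob)
  yv <- as.vector(vapply(masks, as.vector, numeric(length(masks[[1]]))))
  l_glob <- dice_loss(matrix(pv, ncol = 1), matrix(yv, ncol = 1),
                      lcfg$epsilon)
  gglob <- dice_loss_grad(matrix(pv, ncol = 1), matrix(yv, ncol = 1),
                          lcfg$epsilon)
  dprob <- dprob + lcfg$lambda_global * array(gglob, dim(prob))
  total <- total_loss(c(l_main, l_aux), l_glob, l_size, lcfg)
  list(loss = total, dprob = dprob, daux = daux)
}

# Adam update applied in-place over the nested parameter list.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (fn in names(grads[[nm]])) {
      gr <- grads[[nm]][[fn]]
      key <- paste(nm, fn, sep = ".")
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- gr * 0
        state$v[[key]] <- gr * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gr
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gr^2
      mhat <- state$m[[key]] / bc1
      vhat <- state$v[[key]] / bc2
      params[[nm]][[fn]] <- params[[nm]][[fn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train a CRFE model on a phantom cohort
#'
#' Optimises the composite objective (per-head Dice + cross-entropy deep
#' supervision, a lambda-weighted batch-level Dice consistency term, and
#' the clinical size prior) with Adam under a single cosine-annealing cycle
#' spanning all scheduled iterations. The checkpoint with the best
#' validation Dice (threshold 0.5) is kept; early stopping follows
#' [early_stop_check()]. Seeded and reproducible.
#'
#' @param model_spec a [crfe_model_spec()].
#' @param cohort list with `train` and `validation`, each a list of
#'   `phantom` objects (any list with `image` and `mask` works).
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param scfg a [schedule_config()]; its `T_i` is overridden to span
#'   `max_epochs * batches_per_epoch` iterations (one cycle per run).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint) and `log` (data.frame with
#'   epoch, train_loss, val_dice, lr, plus attributes `stop_epoch` and
#'   `best_epoch`).
#' @export
crfe_train <- function(model_spec, cohort, tcfg = train_config(),
                       lcfg = loss_config(), scfg = schedule_config(),
                       verbose = FALSE) {
  if (length(cohort$train) == 0L || length(cohort$validation) == 0L) {
    stop("train and validation splits must be non-empty")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(tcfg$seed)
  model <- crfe_init(model_spec, seed = tcfg$seed)
  xs <- lapply(cohort$train, function(p) zscore(p$image))
  ys <- lapply(cohort$train, function(p) p$mask)
  vx <- lapply(cohort$validation, function(p) zscore(p$image))
  vy <- lapply(cohort$validation, function(p) p$mask)
  n <- length(xs)
  bpe <- ceiling(n / tcfg$batch_size)
  scfg$T_i <- tcfg$max_epochs * bpe
  state <- list(t = 0L, m = list(), v = list())
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric(), lr = numeric())
  best_dice <- -Inf; best_params <- model$params; best_epoch <- 0L
  iter <- 0L
  val_hist <- numeric()
  for (epoch in seq_len(tcfg$max_epochs)) {
    perm <- sample(n)
    ep_loss <- 0
    lr_last <- NA_real_
    for (bstart in seq(1L, n, tcfg$batch_size)) {
      ids <- perm[bstart:min(bstart + tcfg$batch_size - 1L, n)]
      B <- length(ids)
      H <- nrow(xs[[1]])
      xb <- array(0, c(H, H, 1L, B))
      masks <- vector("list", B)
      for (k in seq_len(B)) {
        im <- xs[[ids[k]]]; mk <- ys[[ids[k]]]
        if (!is.null(tcfg$augmentation)) {
          ph <- augment(list(image = im, mask = mk), tcfg$augmentation)
          im <- ph$image; mk <- ph$mask
        }
        xb[, , 1, k] <- im
        masks[[k]] <- mk
      }
      fw <- crfe_forward(model, xb, with_cache = TRUE)
      lg <- batch_loss_and_grads(fw$prob, fw$aux_prob, masks, lcfg)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch)
      }
      grads <- crfe_backward(model, fw$cache, lg$dprob, lg$daux)
      lr <- cosine_lr(min(iter, scfg$T_i), scfg)
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      iter <- iter + 1L
      lr_last <- lr
      ep_loss <- ep_loss + lg$loss
    }
    # validation Dice at threshold 0.5
    vd <- vapply(seq_along(vx), function(i) {
      p <- crfe_forward(model, vx[[i]])$prob[, , 1, 1]
      overlap_metrics(matrix(as.integer(p >= 0.5), nrow(p), ncol(p)),
                      vy[[i]])$dice
    }, numeric(1))
    val_dice <- mean(vd)
    val_hist <- c(val_hist, val_dice)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = ep_loss / bpe,
                                 val_dice = val_dice, lr = lr_last))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %.2e",
                      epoch, ep_loss / bpe, val_dice, lr_last))
    }
    if (val_dice > best_dice) {
      best_dice <- val_dice
      best_params <- model$params
      best_epoch <- epoch
    }
    if (early_stop_check(val_hist, tcfg$early_stop_patience,
                         tcfg$early_stop_min_delta)) {
      break
    }
  }
  model$params <- best_params
  attr(log, "stop_epoch") <- nrow(log)
  attr(log, "best_epoch") <- best_epoch
  attr(log, "best_val_dice") <- best_dice
  list(model = model, log = log)
}
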