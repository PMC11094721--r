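#' Training configuration
#'
#' The reference preset mirrors the published schedule: 250 epochs (227 of
#' cosine decay to a 1e-13 floor, then 23 epochs of exponential decay with
#' factor 1e-10), batch size 512, Adam, positive class weight 1.8 in the
#' masked binary cross-entropy, padding target 512 and 25 cross-validation
#' folds. The desk preset keeps the same shape of schedule but shrinks the
#' epoch count, batch size and padding target so a full experiment runs in
#' minutes on one CPU.
#'
#' @param preset "desk" or "paper".
#' @param epochs,cosine_epochs,exp_epochs epoch budget and its split into
#'   the cosine and exponential phases (`epochs == cosine_epochs +
#'   exp_epochs` is enforced).
#' @param batch_size sequences per batch.
#' @param base_lr Adam base learning rate (the published work does not
#'   state one; 1e-3 is the Adam convention, the desk preset uses 1e-2 for
#'   its much smaller network).
#' @param min_lr cosine floor.
#' @param exp_factor per-epoch multiplier of the exponential phase.
#' @param pos_weight positive class weight in the loss.
#' @param pad_target training padding length.
#' @param folds cross-validation fold count.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return object of class `training_config`.
#' @export
training_config <- function(preset = c("desk", "paper"),
                            epochs = NULL, cosine_epochs = NULL,
                            exp_epochs = NULL, batch_size = NULL,
                            base_lr = NULL, min_lr = 1e-13,
                            exp_factor = 1e-10, pos_weight = 1.8,
                            pad_target = NULL, folds = 25L, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    paper = list(epochs = 250L, cosine_epochs = 227L, exp_epochs = 23L,
                 batch_size = 512L, base_lr = 1e-3, pad_target = 512L),
    desk = list(epochs = 30L, cosine_epochs = 28L, exp_epochs = 2L,
                batch_size = 8L, base_lr = 2e-2, pad_target = 64L))
  cfg <- list(preset = preset,
              epochs = as.integer(epochs %||% def$epochs),
              cosine_epochs = as.integer(cosine_epochs %||%
                                           def$cosine_epochs),
              exp_epochs = as.integer(exp_epochs %||% def$exp_epochs),
              batch_size = as.integer(batch_size %||% def$batch_size),
              base_lr = base_lr %||% def$base_lr,
              min_lr = min_lr, exp_factor = exp_factor,
              pos_weight = pos_weight,
              pad_target = as.integer(pad_target %||% def$pad_target),
              folds = as.integer(folds), seed = as.integer(seed))
  if (cfg$epochs != cfg$cosine_epochs + cfg$exp_epochs) {
    fb_stop("epochs must equal cosine_epochs + exp_epochs",
            "fb_config_error")
  }
  structure(cfg, class = "training_config")
}

#' Masked weighted binary cross-entropy
#'
#' Sum over masked (real) positions of
#' `-(w_pos * t * log(y) + (1 - t) * log(1 - y))`; padded positions
#' contribute exactly zero. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` rather than raising on saturation.
#'
#' @param y predicted probabilities.
#' @param target binary targets.
#' @param mask binary mask (1 = real position).
#' @param pos_weight positive class weight.
#' @return scalar loss.
#' @export
masked_bce_loss <- function(y, target, mask = rep(1, length(y)),
                            pos_weight = 1.8) {
  stopifnot(length(y) == length(target), length(y) == length(mask))
  eps <- 1e-7
  yc <- pmin(pmax(y, eps), 1 - eps)
  sum(mask * -(pos_weight * target * log(yc) +
                 (1 - target) * log(1 - yc)))
}

masked_bce_grad <- function(y, target, mask, pos_weight = 1.8) {
  eps <- 1e-7
  yc <- pmin(pmax(y, eps), 1 - eps)
  mask * (-(pos_weight * target / yc) + (1 - target) / (1 - yc))
}

#' Learning rate at a given epoch
#'
#' Cosine interpolation from `base_lr` at epoch 0 down to `min_lr` at the
#' last cosine epoch, then per-epoch multiplication by `exp_factor`.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config a `training_config`.
#' @return learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (epoch < 0 || epoch >= config$epochs) {
    fb_stop("epoch out of range", "fb_range_error")
  }
  ce <- config$cosine_epochs
  if (epoch < ce) {
    if (ce == 1L) return(config$base_lr)
    config$min_lr + 0.5 * (config$base_lr - config$min_lr) *
      (1 + cos(pi * epoch / (ce - 1)))
  } else {
    config$min_lr * config$exp_factor^(epoch - ce + 1)
  }
}

#' Assign structural families to cross-validation folds
#'
#' Families are shuffled (seeded) and dealt round-robin, so no family is
#' ever split across folds.
#'
#' @param families list of `structure_family` objects or a character vector
#'   of family names.
#' @param k fold count.
#' @param seed integer seed.
#' @return named integer vector mapping family name to fold index in
#'   `[0, k)`.
#' @export
assign_folds <- function(families, k = 25L, seed = 1L) {
  nm <- if (is.character(families)) families
        else vapply(families, `[[`, "", "name")
  if (length(nm) < 1L) fb_stop("need at least one family", "fb_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample(length(nm))
  folds <- integer(length(nm))
  folds[ord] <- (seq_along(nm) - 1L) %% k
  setNames(folds, nm)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# ---- dataset preparation -------------------------------------------------

# flatten families into per-sequence training examples with precomputed
# ensemble tracks and targets
prepare_examples <- function(families, panel = default_panel()) {
  out <- list()
  for (fam in families) {
    for (m in fam$members) {
      tracks <- ensemble_predict(m$seq, panel)
      out[[length(out) + 1L]] <- list(
        family = fam$name,
        seq = m$seq,
        tensor = build_input(m$seq, tracks),
        tracks = tracks,
        target = pairedness(m$structure))
    }
  }
  out
}

micro_label_confusion <- function(pred_list, truth_list) {
  p <- unlist(pred_list)
  t <- unlist(truth_list)
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
    FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0))
}

confusion_f1 <- function(cm) {
  P <- if (cm[["TP"]] + cm[["FP"]] == 0) 1 else
    cm[["TP"]] / (cm[["TP"]] + cm[["FP"]])
  R <- if (cm[["TP"]] + cm[["FN"]] == 0) 1 else
    cm[["TP"]] / (cm[["TP"]] + cm[["FN"]])
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

# eval-mode probabilities for a list of prepared examples
eval_probs <- function(examples, params, state, net_config) {
  lapply(examples, function(ex)
    stage1_forward(ex$tensor, params, net_config, state, mode = "eval"))
}

partial_metrics <- function(examples, params, state, net_config,
                            pos_weight) {
  ys <- eval_probs(examples, params, state, net_config)
  loss <- sum(vapply(seq_along(ys), function(k)
    masked_bce_loss(ys[[k]], examples[[k]]$target,
                    pos_weight = pos_weight), 1.0))
  npos <- sum(lengths(ys))
  cm <- micro_label_confusion(lapply(ys, function(y) as.integer(y >= 0.5)),
                              lapply(examples, `[[`, "target"))
  c(loss = loss / npos, f1 = confusion_f1(cm))
}

#' Train the Stage-1 network on one fold
#'
#' Runs the full epoch loop (Adam, cosine-then-exponential schedule,
#' dropout on, masked weighted binary cross-entropy normalized per real
#' position) and records per-epoch partial loss and partial F1 (threshold
#' 0.5, padded positions excluded) on the training and validation
#' families. Fully seeded and deterministic on CPU; the final-epoch
#' parameters are returned.
#'
#' @param train_families,val_families disjoint lists of
#'   `structure_family` objects.
#' @param net_config a `network_config`.
#' @param train_config a `training_config`.
#' @param panel ensemble panel used for the input encoding.
#' @param verbose print a line per epoch.
#' @return list with `params`, `state`, `curves` (data.frame: epoch, lr,
#'   train_loss, val_loss, train_pf1, val_pf1), `net_config`,
#'   `train_config` and `member_order`.
#' @export
train_fold <- function(train_families, val_families, net_config,
                       train_config, panel = default_panel(),
                       verbose = FALSE) {
  if (length(train_families) == 0L) {
    fb_stop("empty training set", "fb_config_error")
  }
  tc <- train_config
  train_ex <- prepare_examples(train_families, panel)
  val_ex <- prepare_examples(val_families, panel)
  lens <- vapply(train_ex, function(e) e$tensor$true_length, 1L)
  if (any(lens > tc$pad_target)) {
    fb_stop(sprintf("training sequence of length %d exceeds pad target %d",
                    max(lens), tc$pad_target), "fb_length_error")
  }

  init <- init_stage1_params(net_config, seed = tc$seed)
  params <- init$params
  state <- init$state
  opt <- adam_init(params)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tc$seed + 1L)

  padded <- pad_batch(lapply(train_ex, `[[`, "tensor"), tc$pad_target)
  targets <- lapply(seq_along(train_ex), function(k)
    c(train_ex[[k]]$target, numeric(tc$pad_target - lens[k])))
  masks <- padded$masks

  curves <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- lr_at(epoch, tc)
    ord <- sample(length(train_ex))
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      sel <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      fw <- net_forward(padded$values[sel], params, net_config, state,
                        training = TRUE)
      state <- fw$state
      nreal <- sum(unlist(masks[sel]))
      dY <- lapply(seq_along(sel), function(k)
        masked_bce_grad(fw$y[[k]], targets[[sel[k]]], masks[[sel[k]]],
                        tc$pos_weight) / nreal)
      grads <- net_backward(dY, fw$cache, params, net_config)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$opt
    }
    tr <- partial_metrics(train_ex, params, state, net_config,
                          tc$pos_weight)
    va <- if (length(val_ex) > 0L)
      partial_metrics(val_ex, params, state, net_config, tc$pos_weight)
      else c(loss = NA_real_, f1 = NA_real_)
    curves[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = tr[["loss"]], val_loss = va[["loss"]],
      train_pf1 = tr[["f1"]], val_pf1 = va[["f1"]])
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.3g train loss %.4f F1 %.3f val loss %.4f F1 %.3f",
        epoch, lr, tr[["loss"]], tr[["f1"]], va[["loss"]], va[["f1"]]))
    }
  }
  list(params = params, state = state,
       curves = do.call(rbind, curves),
       net_config = net_config, train_config = tc,
       member_order = vapply(panel, `[[`, "", "name"))
}

#' Cross-validated training over family folds
#'
#' Assigns families to folds with [assign_folds()] and trains one model
#' per requested fold, holding that fold out for validation.
#'
#' @param families list of `structure_family` objects.
#' @param net_config,train_config,panel as in [train_fold()].
#' @param folds how many folds to actually train (defaults to all).
#' @param verbose print progress.
#' @return list of [train_fold()] results, one per trained fold.
#' @export
train_cv <- function(families, net_config, train_config,
                     panel = default_panel(),
                     folds = train_config$folds, verbose = FALSE) {
  assign <- assign_folds(families, k = train_config$folds,
                         seed = train_config$seed)
  nm <- vapply(families, `[[`, "", "name")
  lapply(seq_len(folds) - 1L, function(f) {
    val <- families[assign[nm] == f]
    train <- families[assign[nm] != f]
    train_fold(train, val, net_config, train_config, panel,
               verbose = verbose)
  })
}
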