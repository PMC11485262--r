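#' Training configuration
#'
#' Optimization protocol: AdamW mini-batch training with a cosine
#' learning-rate schedule with warm restarts (first restart after
#' `first_restart` epochs, each restart period multiplied by
#' `period_multiplier`), validation scoring at every epoch end, and
#' selection of the epoch with the best validation score.
#'
#' @param lr Peak learning rate (default 0.001).
#' @param epochs Total epochs (default 256).
#' @param first_restart Epochs before the first restart (default 64).
#' @param period_multiplier Restart-period growth factor (default 2).
#' @param selection_metric Validation score maximized for checkpoint
#'   selection; `"micro_auroc"` (default) or `"macro_auroc"`.
#' @param feature_masking Apply random feature masking during training
#'   (default TRUE); a fresh mask is drawn per record per batch.
#' @param seed Master seed; fans out to weight init, shuffling and mask
#'   sampling.
#' @param min_lr Floor of the cosine schedule (default 0).
#' @param verbose Print per-epoch progress (default FALSE).
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 0.001, epochs = 256L, first_restart = 64L,
                         period_multiplier = 2, selection_metric = "micro_auroc",
                         feature_masking = TRUE, seed = 1L, min_lr = 0,
                         verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, first_restart >= 1, period_multiplier >= 1)
  selection_metric <- match.arg(selection_metric,
                                c("micro_auroc", "macro_auroc"))
  structure(list(lr = lr, epochs = as.integer(epochs),
                 first_restart = as.integer(first_restart),
                 period_multiplier = period_multiplier,
                 selection_metric = selection_metric,
                 feature_masking = isTRUE(feature_masking),
                 seed = as.integer(seed), min_lr = min_lr,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Cosine learning rate with warm restarts
#'
#' @param epoch Epoch number (1-based).
#' @param cfg A `train_config`.
#' @return Learning rate for that epoch.
#' @export
cosine_restart_lr <- function(epoch, cfg) {
  t_cur <- epoch - 1L
  t_i <- cfg$first_restart
  while (t_cur >= t_i) {
    t_cur <- t_cur - t_i
    t_i <- t_i * cfg$period_multiplier
  }
  cfg$min_lr + 0.5 * (cfg$lr - cfg$min_lr) * (1 + cos(pi * t_cur / t_i))
}

#' Best-epoch selection
#' @param scores Per-epoch validation scores.
#' @return Index of the best epoch (first maximum on ties).
#' @export
select_best_epoch <- function(scores) which.max(scores)

# --- parameter tree plumbing -------------------------------------------------

# enumerate the trainable leaves as nested-index paths plus decay flags;
# the imaging downsampler is excluded: cohorts carry precomputed vectors,
# so only the projection participates in optimization
param_paths <- function(embed, backbone) {
  paths <- list(); decay <- logical(0)
  add <- function(p, d) { paths[[length(paths) + 1L]] <<- p
                          decay[length(decay) + 1L] <<- d }
  for (nm in names(embed$blocks)) {
    b <- embed$blocks[[nm]]
    if (!is.null(b$weight)) { add(c("embed", "blocks", nm, "weight"), TRUE)
                              add(c("embed", "blocks", nm, "bias"), FALSE) }
    if (!is.null(b$table))  add(c("embed", "blocks", nm, "table"), TRUE)
    if (!is.null(b$proj)) { add(c("embed", "blocks", nm, "proj"), TRUE)
                            add(c("embed", "blocks", nm, "proj_bias"), FALSE) }
  }
  add(c("bb", "cls"), TRUE)
  for (li in seq_along(backbone$layers)) {
    for (key in c("ln1_g", "ln1_b", "bq", "bk", "bv", "bo",
                  "ln2_g", "ln2_b", "b1", "b2"))
      add(list("bb", "layers", li, key), FALSE)
    for (key in c("wq", "wk", "wv", "wo", "w1", "w2"))
      add(list("bb", "layers", li, key), TRUE)
  }
  add(c("bb", "lnf_g"), FALSE); add(c("bb", "lnf_b"), FALSE)
  add(c("bb", "head_w"), TRUE); add(c("bb", "head_b"), FALSE)
  list(paths = paths, decay = decay)
}

tree_get <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}
tree_set <- function(tree, path, value) {
  if (length(path) == 1L) { tree[[path[[1L]]]] <- value; return(tree) }
  tree[[path[[1L]]]] <- tree_set(tree[[path[[1L]]]],
                                 path[-1L], value)
  tree
}

# embedding-parameter gradients from d(tokens)
embed_grads <- function(dtokens, x, standardizer, params, batch) {
  g <- list()
  nms <- batch$feature_names
  for (j in seq_along(nms)) {
    nm <- nms[j]; sp <- x$catalog$features[[nm]]
    idx <- which(batch$train_mask[, j])
    blk <- params$blocks[[nm]]
    if (sp$modality == "numeric") {
      gb <- list(weight = numeric(params$d_model),
                 bias = numeric(params$d_model))
      if (length(idx)) {
        v <- x$data[[nm]][idx]
        if (!is.null(standardizer))
          v <- (v - standardizer$mean[[nm]]) / standardizer$sd[[nm]]
        dt <- matrix(dtokens[idx, j, ], length(idx), params$d_model)
        gb$weight <- drop(crossprod(dt, v))
        gb$bias <- colSums(dt)
      }
      g[[nm]] <- gb
    } else if (sp$modality == "categorical") {
      gt <- matrix(0, nrow(blk$table), params$d_model)
      if (length(idx)) {
        rows <- match(x$data[[nm]][idx], rownames(blk$table))
        dt <- matrix(dtokens[idx, j, ], length(idx), params$d_model)
        for (rr in unique(rows))
          gt[rr, ] <- colSums(dt[rows == rr, , drop = FALSE])
      }
      g[[nm]] <- list(table = gt)
    } else {
      gp <- list(proj = matrix(0, nrow(blk$proj), params$d_model),
                 proj_bias = numeric(params$d_model))
      if (length(idx)) {
        dt <- matrix(dtokens[idx, j, ], length(idx), params$d_model)
        gp$proj <- crossprod(x$data[[nm]][idx, , drop = FALSE], dt)
        gp$proj_bias <- colSums(dt)
      }
      g[[nm]] <- gp
    }
  }
  g
}

#' Train the masking transformer
#'
#' Runs the full optimization protocol on subject-disjoint training and
#' validation cohorts: random feature masking (fresh per record per batch),
#' label-loss masking for unknown diagnoses, the composite focal + ranking
#' + L2 loss, AdamW with cosine warm restarts, validation at every epoch
#' end, and selection of the epoch with the highest validation score.
#' Weight decay is applied in decoupled AdamW form at rate `2 * beta` on
#' the same weight set the L2 term covers, so the reported total loss and
#' the applied regularization agree.
#'
#' @param train Training `cohort`.
#' @param val Validation `cohort` (must not share subject_ids with
#'   `train`).
#' @param model_cfg A `model_config`.
#' @param loss_cfg A `loss_config`; if `alpha` is NULL it is computed from
#'   the training labels.
#' @param train_cfg A `train_config`.
#' @return An `mmdx_checkpoint`: configs, catalog, standardizer, embedding
#'   and backbone weights of the best epoch, alpha vector, and the per-epoch
#'   training log.
#' @export
train_model <- function(train, val, model_cfg = model_config(),
                        loss_cfg = loss_config(),
                        train_cfg = train_config()) {
  stopifnot(inherits(train, "cohort"), inherits(val, "cohort"))
  if (length(intersect(train$subject_id, val$subject_id)))
    stop("training and validation cohorts share subjects")
  set.seed(train_cfg$seed)
  init_seed <- sample.int(2^31 - 1, 2)
  standardizer <- fit_standardizer(train)
  if (is.null(loss_cfg$alpha))
    loss_cfg$alpha <- compute_alpha(train$labels)
  embed <- embedding_params(train$catalog, d_model = model_cfg$d_model,
                            seed = init_seed[1])
  bb <- init_backbone_weights(model_cfg, seed = init_seed[2])
  pp <- param_paths(embed, bb)
  tree <- list(embed = embed, bb = bb)
  nleaf <- length(pp$paths)
  m_st <- v_st <- lapply(pp$paths, function(p) tree_get(tree, p) * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  wd <- 2 * loss_cfg$beta
  n_tr <- length(train$subject_id)
  bs <- loss_cfg$batch_size
  obs_val <- observed_matrix(val)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        loss = numeric(), focal = numeric(),
                        ranking = numeric(), val_score = numeric())
  best <- list(score = -Inf, epoch = NA_integer_, tree = tree)
  val_metric <- if (train_cfg$selection_metric == "micro_auroc")
    "micro" else "macro"
  for (ep in seq_len(train_cfg$epochs)) {
    lr <- cosine_restart_lr(ep, train_cfg)
    ord <- sample.int(n_tr)
    ep_loss <- ep_fl <- ep_rl <- 0; nb <- 0
    for (start in seq(1L, n_tr, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_tr)]
      xb <- train[idx]
      obs <- observed_matrix(xb)
      tm <- if (train_cfg$feature_masking) sample_train_mask(obs) else obs
      batch <- assemble_tokens(xb, tree$embed, standardizer, train_mask = tm)
      fw <- backbone_forward(batch, tree$bb, model_cfg,
                             training = model_cfg$dropout > 0,
                             keep_cache = TRUE)
      probs <- clamp_probs(fw$probs)
      fl <- focal_loss(probs, xb$labels, cfg = loss_cfg)
      rl <- ranking_loss(probs, xb$labels, cfg = loss_cfg)
      lo <- fl + loss_cfg$lambda * rl +
        loss_cfg$beta * collect_decay_sq(list(tree$embed, tree$bb))
      if (!is.finite(lo))
        stop("training diverged at epoch ", ep, " (non-finite loss); ",
             "state: lr=", lr, ", batch of ", length(idx))
      dlogits <- loss_grad_logits(probs, xb$labels, cfg = loss_cfg)
      bw <- backbone_backward(dlogits, batch, tree$bb, model_cfg, fw$cache)
      ge <- embed_grads(bw$dtokens, xb, standardizer, tree$embed, batch)
      gtree <- list(embed = list(blocks = ge),
                    bb = list(cls = bw$cls, layers = bw$layers,
                              lnf_g = bw$lnf_g, lnf_b = bw$lnf_b,
                              head_w = bw$head_w, head_b = bw$head_b))
      step <- step + 1
      bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
      for (li in seq_len(nleaf)) {
        p <- pp$paths[[li]]
        grad <- tree_get(gtree, p)
        par <- tree_get(tree, p)
        m_st[[li]] <- b1 * m_st[[li]] + (1 - b1) * grad
        v_st[[li]] <- b2 * v_st[[li]] + (1 - b2) * grad^2
        upd <- (m_st[[li]] / bc1) / (sqrt(v_st[[li]] / bc2) + eps)
        par <- par - lr * upd
        if (pp$decay[li]) par <- par - lr * wd * par
        tree <- tree_set(tree, p, par)
      }
      ep_loss <- ep_loss + lo; ep_fl <- ep_fl + fl; ep_rl <- ep_rl + rl
      nb <- nb + 1
    }
    vp <- predict_with(tree$embed, tree$bb, model_cfg, standardizer, val,
                       train_mask = obs_val)
    vs <- tryCatch(average_metrics(vp$probs, val$labels, val_metric, "auroc"),
                   error = function(e) NA_real_)
    history <- rbind(history, data.frame(
      epoch = ep, lr = lr, loss = ep_loss / nb, focal = ep_fl / nb,
      ranking = ep_rl / nb, val_score = vs))
    if (!is.na(vs) && vs > best$score)
      best <- list(score = vs, epoch = ep, tree = tree)
    if (train_cfg$verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val %.4f",
                      ep, lr, ep_loss / nb, vs))
  }
  structure(list(model_config = model_cfg, loss_config = loss_cfg,
                 train_config = train_cfg, catalog = train$catalog,
                 standardizer = standardizer,
                 embed = best$tree$embed, weights = best$tree$bb,
                 alpha = loss_cfg$alpha, best_epoch = best$epoch,
                 best_score = best$score, history = history),
            class = "mmdx_checkpoint")
}

predict_with <- function(embed, weights, model_cfg, standardizer, x,
                         train_mask = NULL, allow_empty = FALSE) {
  batch <- assemble_tokens(x, embed, standardizer, train_mask = train_mask)
  out <- backbone_forward(batch, weights, model_cfg, training = FALSE,
                          allow_empty = allow_empty)
  out$subject_id <- x$subject_id
  out
}

#' Score a cohort with a trained checkpoint
#'
#' @param checkpoint An `mmdx_checkpoint`.
#' @param x A `cohort` on the same catalog.
#' @param train_mask Optional visibility mask (n x F logical, subset of the
#'   observation mask), e.g. for missingness sweeps; defaults to the
#'   observation mask.
#' @param allow_empty Permit records with no visible feature.
#' @return A `prediction_set` with `logits`, `probs` and `subject_id`.
#' @export
predict_cohort <- function(checkpoint, x, train_mask = NULL,
                           allow_empty = FALSE) {
  stopifnot(inherits(checkpoint, "mmdx_checkpoint"), inherits(x, "cohort"))
  predict_with(checkpoint$embed, checkpoint$weights, checkpoint$model_config,
               checkpoint$standardizer, x, train_mask = train_mask,
               allow_empty = allow_empty)
}

#' @export
print.mmdx_checkpoint <- function(x, ...) {
  cat("<mmdx_checkpoint> d_model=", x$model_config$d_model,
      ", layers=", x$model_config$n_layers,
      ", best epoch ", x$best_epoch, " (val ",
      round(x$best_score, 4), ")\n", sep = "")
  invisible(x)
}

#' Save / load a checkpoint
#'
#' The checkpoint archive bundles configs, catalog, training statistics
#' (feature means/sds, alpha vector) and all parameters in one RDS file.
#'
#' @param checkpoint An `mmdx_checkpoint`.
#' @param path File path.
#' @return `path` invisibly; `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "mmdx_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "mmdx_checkpoint")) stop("not an mmdx checkpoint: ", path)
  ck
}
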