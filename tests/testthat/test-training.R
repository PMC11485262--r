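test_that("backpropagation matches finite differences end to end", {
  sim <- simulate_cohort(synthetic_config(n_subjects = 5, seed = 3))
  x <- apply_missingness(sim$cohort, 0.3,
                         label_rates = c(rep(0, 3), rep(0.3, 10)))
  cfg <- model_config(d_model = 8, n_layers = 2, n_heads = 2, ff_width = 12,
                      dropout = 0, seed = 1)
  ep <- embedding_params(x$catalog, d_model = 8, seed = 2)
  bb <- init_backbone_weights(cfg, seed = 4)
  st <- fit_standardizer(x)
  lcfg <- loss_config(alpha = compute_alpha(x$labels))
  set.seed(9)
  tm <- mmdx:::sample_train_mask(observed_matrix(x))
  loss_at <- function(ep, bb) {
    tb <- assemble_tokens(x, ep, st, train_mask = tm)
    p <- clamp_probs(backbone_forward(tb, bb, cfg)$probs)
    focal_loss(p, x$labels, cfg = lcfg) +
      lcfg$lambda * ranking_loss(p, x$labels, cfg = lcfg)
  }
  tb <- assemble_tokens(x, ep, st, train_mask = tm)
  fw <- backbone_forward(tb, bb, cfg, keep_cache = TRUE)
  p <- clamp_probs(fw$probs)
  dlog <- mmdx:::loss_grad_logits(p, x$labels, cfg = lcfg)
  bw <- mmdx:::backbone_backward(dlog, tb, bb, cfg, fw$cache)
  ge <- mmdx:::embed_grads(bw$dtokens, x, st, ep, tb)
  gtree <- list(embed = list(blocks = ge),
                bb = list(cls = bw$cls, layers = bw$layers, lnf_g = bw$lnf_g,
                          lnf_b = bw$lnf_b, head_w = bw$head_w,
                          head_b = bw$head_b))
  pp <- mmdx:::param_paths(ep, bb)
  tree <- list(embed = ep, bb = bb)
  h <- 1e-5
  set.seed(33)
  for (li in sample(seq_along(pp$paths), 12)) {
    path <- pp$paths[[li]]
    par <- mmdx:::tree_get(tree, path)
    g <- mmdx:::tree_get(gtree, path)
    k <- sample(length(par), 1)
    par2 <- par; par2[k] <- par[k] + h
    t2 <- mmdx:::tree_set(tree, path, par2)
    lp <- loss_at(t2$embed, t2$bb)
    par2[k] <- par[k] - h
    t2 <- mmdx:::tree_set(tree, path, par2)
    lm <- loss_at(t2$embed, t2$bb)
    fd <- (lp - lm) / (2 * h)
    expect_equal(unname(g[k]), fd, tolerance = 1e-3)
  }
})

test_that("the cosine schedule restarts after 64 epochs and doubles", {
  tc <- train_config(lr = 0.001, epochs = 256)
  expect_equal(cosine_restart_lr(1, tc), 0.001)           # peak at start
  expect_lt(cosine_restart_lr(64, tc), 1e-5)              # trough before restart
  expect_equal(cosine_restart_lr(65, tc), 0.001)          # first warm restart
  expect_equal(cosine_restart_lr(64 + 129, tc), 0.001)    # second, 128 later
  expect_lt(cosine_restart_lr(64 + 128, tc), 1e-5)
  expect_equal(cosine_restart_lr(33, tc), 0.0005)         # halfway: lr/2
})

test_that("checkpoint selection takes the argmax validation epoch", {
  expect_equal(select_best_epoch(c(0.6, 0.9, 0.7)), 2)
  expect_equal(select_best_epoch(c(0.9, 0.9, 0.7)), 1)    # first on ties
})

test_that("training reduces the loss on a separable synthetic cohort", {
  sim <- simulate_cohort(synthetic_config(n_subjects = 260, seed = 21))
  x <- sim$cohort
  mc <- model_config(d_model = 16, n_layers = 1, n_heads = 2, ff_width = 32,
                     dropout = 0, seed = 2)
  ck <- train_model(x[1:200], x[201:260], mc, loss_config(),
                    train_config(epochs = 6, seed = 11))
  expect_lt(tail(ck$history$loss, 1), ck$history$loss[1])
  expect_true(all(is.finite(ck$history$loss)))
  expect_equal(ck$best_epoch, select_best_epoch(ck$history$val_score))
})

test_that("a fixed seed reproduces the training trajectory exactly", {
  sim <- simulate_cohort(synthetic_config(n_subjects = 120, seed = 8))
  x <- sim$cohort
  mc <- model_config(d_model = 8, n_layers = 1, n_heads = 2, ff_width = 16,
                     dropout = 0.1, seed = 2)
  run <- function() train_model(x[1:90], x[91:120], mc, loss_config(),
                                train_config(epochs = 3, seed = 13))
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$weights$head_w, b$weights$head_w)
})

test_that("train/validation subject overlap is rejected", {
  x <- tiny_cohort(6)
  expect_error(train_model(x[1:4], x[4:6]), "share subjects")
})

test_that("checkpoints round-trip through save/load and score cohorts", {
  fx <- fixture_checkpoint()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$ck, path)
  ck2 <- load_checkpoint(path)
  p1 <- predict_cohort(fx$ck, fx$test)
  p2 <- predict_cohort(ck2, fx$test)
  expect_identical(p1$logits, p2$logits)
  expect_equal(dim(p1$probs), c(length(fx$test$subject_id), 13))
  expect_true(all(p1$probs > 0 & p1$probs < 1))
})
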