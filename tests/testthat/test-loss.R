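# brute-force re-statements of the loss sums, kept deliberately naive so
# they stay independent of the vectorized implementations
brute_focal <- function(p, y, m, alpha, gamma) {
  n <- nrow(p); tot <- 0
  for (k in seq_len(n)) for (i in 1:13) {
    if (!m[k, i]) next
    tot <- tot - y[k, i] * alpha[i] * (1 - p[k, i])^gamma * log(p[k, i]) -
      (1 - y[k, i]) * (1 - alpha[i]) * p[k, i]^gamma * log(1 - p[k, i])
  }
  as.numeric(tot / n)
}
brute_ranking <- function(p, y, m, eps) {
  n <- nrow(p); tot <- 0
  for (k in seq_len(n)) for (i in 1:12) for (j in (i + 1):13) {
    if (!m[k, i] || !m[k, j]) next
    tot <- tot + max(0, (p[k, i] - p[k, j]) * (y[k, j] - y[k, i]) + eps)
  }
  as.numeric(tot / n)
}
rand_instance <- function(n, seed) {
  set.seed(seed)
  p <- matrix(runif(n * 13, 0.01, 0.99), n, 13)
  y <- matrix(rbinom(n * 13, 1, 0.4), n, 13,
              dimnames = list(NULL, diagnostic_labels()))
  y[matrix(runif(n * 13) < 0.2, n, 13)] <- NA
  list(p = p, y = y)
}

test_that("alpha is the squared complement of the positive fraction", {
  y <- matrix(NA_real_, 5, 13, dimnames = list(NULL, diagnostic_labels()))
  y[, 1] <- c(1, 1, 0, 0, NA)         # f = 0.5 ignoring the unknown
  y[, 2] <- c(0, 0, 0, 0, 0)          # f = 0
  y[, 3] <- c(1, 1, 1, 1, 1)          # f = 1
  y[1, 4:13] <- 0
  a <- compute_alpha(y)
  expect_equal(unname(a[1]), 0.25)
  expect_equal(unname(a[2]), 1)
  expect_equal(unname(a[3]), 0)
  y2 <- y; y2[, 5] <- NA
  expect_error(compute_alpha(y2), "zero known")
})

test_that("focal loss matches the hand-computed single-term values", {
  mk <- function(p1, y1, a1) {
    p <- matrix(0.5, 1, 13); p[1, 1] <- p1
    y <- matrix(NA_real_, 1, 13, dimnames = list(NULL, diagnostic_labels()))
    y[1, 1] <- y1
    cfg <- loss_config(alpha = c(a1, rep(0.5, 12)))
    focal_loss(p, y, cfg = cfg)
  }
  expect_equal(mk(0.5, 1, 0.75), 0.75 * 0.25 * log(2), tolerance = 1e-9)
  expect_equal(mk(0.5, 0, 0.25), 0.75 * 0.25 * log(2), tolerance = 1e-9)
  # perfect predictions drive the loss to zero
  p <- matrix(1 - 1e-9, 2, 13)
  y <- matrix(1, 2, 13, dimnames = list(NULL, diagnostic_labels()))
  expect_lt(focal_loss(clamp_probs(p, 1e-10), y,
                       cfg = loss_config(alpha = rep(0.5, 13))), 1e-15)
  expect_error(focal_loss(matrix(1, 1, 13), y[1, , drop = FALSE],
                          cfg = loss_config(alpha = rep(0.5, 13))), "clamp")
})

test_that("ranking loss matches the hand-computed pair values", {
  pair_rl <- function(pi, pj, yi, yj) {
    p <- matrix(0.5, 1, 13); p[1, 1] <- pi; p[1, 2] <- pj
    y <- matrix(NA_real_, 1, 13, dimnames = list(NULL, diagnostic_labels()))
    y[1, 1] <- yi; y[1, 2] <- yj
    ranking_loss(p, y, cfg = loss_config(alpha = rep(0.5, 13)))
  }
  expect_equal(pair_rl(0.9, 0.2, 1, 0), 0)          # margin satisfied
  expect_equal(pair_rl(0.3, 0.4, 1, 0), 0.35)       # violated: 0.1 + 0.25
  expect_equal(pair_rl(0.7, 0.7, 1, 1), 0.25)       # equal labels: constant
})

test_that("both losses match brute-force evaluation on random instances", {
  cfg <- loss_config(alpha = runif(13))
  for (seed in 1:25) {
    z <- rand_instance(8, seed)
    m <- label_loss_mask(z$y)
    expect_equal(focal_loss(z$p, z$y, cfg = cfg),
                 brute_focal(z$p, z$y, m, cfg$alpha, cfg$gamma),
                 tolerance = 1e-8)
    expect_equal(ranking_loss(z$p, z$y, cfg = cfg),
                 brute_ranking(z$p, z$y, m, cfg$epsilon),
                 tolerance = 1e-8)
  }
})

test_that("total loss is the exact weighted component sum", {
  cfg <- loss_config(alpha = runif(13))
  z <- rand_instance(6, 99)
  w <- rnorm(40)
  expect_equal(total_loss(z$p, z$y, weights = w, cfg = cfg),
               focal_loss(z$p, z$y, cfg = cfg) +
                 cfg$lambda * ranking_loss(z$p, z$y, cfg = cfg) +
                 cfg$beta * sum(w^2), tolerance = 1e-10)
  cfg0 <- loss_config(lambda = 0, beta = 0, alpha = cfg$alpha)
  expect_equal(total_loss(z$p, z$y, weights = w, cfg = cfg0),
               focal_loss(z$p, z$y, cfg = cfg0))
  # ||w||^2 excludes biases and layer-norm parameters
  cfgm <- model_config(d_model = 8, n_layers = 1, n_heads = 2, ff_width = 8,
                       seed = 1)
  bb <- init_backbone_weights(cfgm)
  manual <- sum(bb$cls^2) + sum(bb$head_w^2) +
    sum(sapply(bb$layers[[1]][c("wq", "wk", "wv", "wo", "w1", "w2")],
               function(m) sum(m^2)))
  expect_equal(mmdx:::collect_decay_sq(bb), manual)
})

test_that("unknown labels contribute no loss and no gradient", {
  cfg <- loss_config(alpha = runif(13))
  z <- rand_instance(6, 5)
  m <- label_loss_mask(z$y)
  expect_identical(m, !is.na(z$y))
  # analytic gradient is zero at masked positions
  g <- mmdx:::loss_grad_logits(z$p, z$y, cfg = cfg)
  expect_true(all(g[!m] == 0))
  # finite differences on the logit scale confirm it
  lg <- qlogis(z$p)
  for (pos in which(!m)[1:5]) {
    lg2 <- lg; lg2[pos] <- lg2[pos] + 1e-4
    p2 <- plogis(lg2)
    l1 <- focal_loss(z$p, z$y, cfg = cfg) +
      cfg$lambda * ranking_loss(z$p, z$y, cfg = cfg)
    l2 <- focal_loss(p2, z$y, cfg = cfg) +
      cfg$lambda * ranking_loss(p2, z$y, cfg = cfg)
    expect_lt(abs(l2 - l1) / 1e-4, 1e-6)
  }
  # an all-unknown record leaves its row of the gradient at zero
  y2 <- z$y; y2[2, ] <- NA
  g2 <- mmdx:::loss_grad_logits(z$p, y2, cfg = cfg)
  expect_true(all(g2[2, ] == 0))
})

test_that("equal-label pairs add a constant that carries no gradient", {
  cfg <- loss_config(alpha = runif(13))
  z <- rand_instance(5, 17)
  y_allknown <- z$y; y_allknown[is.na(y_allknown)] <- 0
  full <- ranking_loss(z$p, y_allknown, cfg = cfg)
  noeq <- ranking_loss(z$p, y_allknown, cfg = cfg, include_constant = FALSE)
  n_eq <- sum(apply(y_allknown, 1, function(r)
    sum(outer(r, r, `==`)[upper.tri(diag(13))])))
  expect_equal(full - noeq, cfg$epsilon * n_eq / nrow(z$p), tolerance = 1e-10)
  # gradients identical whether the constant is included or not: finite
  # differences of both versions agree
  g <- mmdx:::ranking_loss_grad(z$p, y_allknown, cfg = cfg)
  h <- 1e-6
  for (pos in sample(length(z$p), 8)) {
    p2 <- z$p; p2[pos] <- p2[pos] + h
    fd_full <- (ranking_loss(p2, y_allknown, cfg = cfg) - full) / h
    fd_noeq <- (ranking_loss(p2, y_allknown, cfg = cfg,
                             include_constant = FALSE) - noeq) / h
    expect_equal(fd_full, fd_noeq, tolerance = 1e-6)
    expect_equal(g[pos], fd_full, tolerance = 1e-3)
  }
})

test_that("feature-mask sampling keeps a uniform number of features", {
  expect_error(sample_feature_mask(integer(0)), "no observed feature")
  # |S| = 1: the single feature always survives
  set.seed(1)
  expect_true(all(replicate(50, length(sample_feature_mask(4L))) == 0))
  # kept-count uniform on {1..|S|}, masked subset of the input
  set.seed(2)
  s <- 6L; draws <- 6000
  kept <- integer(draws); legal <- TRUE
  for (i in seq_len(draws)) {
    masked <- sample_feature_mask(seq_len(s))
    legal <- legal && all(masked %in% seq_len(s))
    kept[i] <- s - length(masked)
  }
  expect_true(legal)
  expect_true(all(sort(unique(kept)) == 1:s))
  chi <- suppressWarnings(chisq.test(table(factor(kept, levels = 1:s))))
  expect_gt(chi$p.value, 0.001)
  # masked features are a subset of the observed set, never resurrected
  set.seed(3)
  obs <- c(2L, 5L, 9L)
  for (i in 1:50) expect_true(all(sample_feature_mask(obs) %in% obs))
})
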