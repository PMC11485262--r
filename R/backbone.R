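#' Model configuration
#'
#' Architecture of the transformer backbone. Tokens are an unordered set
#' (no positional encoding); a learned classification token (or a masked
#' mean) pools the encoded tokens, and an affine head maps the pooled
#' representation to 13 logits, one per diagnostic label. Attention masking
#' is additive: masked keys receive a -Inf score before normalization, so
#' no information flows from masked features to any visible position, and
#' the pooled representation never attends to masked tokens.
#'
#' @param d_model Token width; must be divisible by `n_heads`.
#' @param n_layers Number of encoder layers (default 4).
#' @param n_heads Attention heads per layer (default 4).
#' @param ff_width Feed-forward hidden width (default `4 * d_model`).
#' @param pooling `"cls"` (learned classification token, default) or
#'   `"masked_mean"` (mean over visible positions).
#' @param dropout Standard dropout rate on attention output and FFN hidden
#'   units during training (default 0.1); distinct from feature masking.
#' @param seed Weight-initialization seed.
#' @return A `model_config` object.
#' @export
model_config <- function(d_model = 256L, n_layers = 4L, n_heads = 4L,
                         ff_width = 4L * d_model,
                         pooling = c("cls", "masked_mean"),
                         dropout = 0.1, seed = 1L) {
  pooling <- match.arg(pooling)
  d_model <- as.integer(d_model); n_heads <- as.integer(n_heads)
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads")
  stopifnot(n_layers >= 1, ff_width >= 1, dropout >= 0, dropout < 1)
  structure(list(d_model = d_model, n_layers = as.integer(n_layers),
                 n_heads = n_heads, ff_width = as.integer(ff_width),
                 pooling = pooling, dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize backbone weights
#' @param config A `model_config`.
#' @param seed Seed; defaults to `config$seed`.
#' @return Nested list of weight arrays (`backbone_weights`).
#' @export
init_backbone_weights <- function(config, seed = config$seed) {
  rng <- local_rng(seed)
  d <- config$d_model; ff <- config$ff_width
  xavier <- function(fi, fo)
    matrix(rng$norm(fi * fo, sd = sqrt(2 / (fi + fo))), fi, fo)
  layer <- function() list(
    ln1_g = rep(1, d), ln1_b = numeric(d),
    wq = xavier(d, d), bq = numeric(d),
    wk = xavier(d, d), bk = numeric(d),
    wv = xavier(d, d), bv = numeric(d),
    wo = xavier(d, d), bo = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d),
    w1 = xavier(d, ff), b1 = numeric(ff),
    w2 = xavier(ff, d), b2 = numeric(d))
  structure(list(
    cls = rng$norm(d, sd = 1 / sqrt(d)),
    layers = replicate(config$n_layers, layer(), simplify = FALSE),
    lnf_g = rep(1, d), lnf_b = numeric(d),
    head_w = matrix(rng$norm(d * 13L, sd = 0.02), d, 13L),
    head_b = numeric(13L)), class = "backbone_weights")
}

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  istd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * istd
  list(y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       xhat = xhat, istd = istd)
}

layer_norm_bwd <- function(dy, cache, g) {
  d <- ncol(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (dxhat - (s1 + cache$xhat * s2) / d) * cache$istd
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

row_softmax <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Transformer forward pass
#'
#' Runs the masked transformer over a [token_batch()] and returns logits
#' for the 13 diagnostic heads. Logits depend only on tokens whose
#' `train_mask` entry is TRUE: masked keys receive zero attention weight in
#' every layer and are excluded from pooling, so perturbing a masked
#' token's value can never change any output.
#'
#' @param batch A `token_batch`.
#' @param weights `backbone_weights`.
#' @param config `model_config`.
#' @param training If TRUE, apply dropout (uses the current RNG stream).
#' @param keep_cache If TRUE, retain intermediates for backpropagation.
#' @param allow_empty Permit records with no visible feature token (the
#'   classification token alone carries the prediction); used by the
#'   Shapley empty-coalition payoff. Default FALSE: an all-masked record
#'   is an error.
#' @return A `prediction_set`: list with `logits` and `probs` (n x 13), and
#'   `cache` when requested.
#' @export
backbone_forward <- function(batch, weights, config, training = FALSE,
                             keep_cache = FALSE, allow_empty = FALSE) {
  stopifnot(inherits(batch, "token_batch"))
  n <- dim(batch$tokens)[1]; f <- dim(batch$tokens)[2]; d <- config$d_model
  if (dim(batch$tokens)[3] != d)
    stop("token width ", dim(batch$tokens)[3], " != d_model ", d)
  if (!allow_empty && n > 0 && any(rowSums(batch$train_mask) == 0))
    stop("record(s) with all features masked; no visible token")
  tt <- f + 1L                       # sequence length with CLS at position 1
  vis <- cbind(TRUE, batch$train_mask)             # n x tt
  # zero-fill masked tokens so the contract is visible in the numerics too
  tok <- batch$tokens
  if (any(!batch$train_mask))
    tok <- tok * array(rep(batch$train_mask, d), c(n, f, d))
  x <- array(0, c(tt, n, d))
  x[1, , ] <- matrix(weights$cls, n, d, byrow = TRUE)
  x[2:tt, , ] <- aperm(tok, c(2, 1, 3))
  h <- matrix(x, tt * n, d)          # row t + (s-1)*tt
  nh <- config$n_heads; dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  drop_p <- if (training) config$dropout else 0
  cache <- if (keep_cache) list(vis = vis, tt = tt, n = n, layers = list())
  rows_of <- function(s) ((s - 1L) * tt + 1L):(s * tt)
  for (li in seq_along(weights$layers)) {
    w <- weights$layers[[li]]
    ln1 <- layer_norm_fwd(h, w$ln1_g, w$ln1_b)
    a <- ln1$y
    q <- a %*% w$wq + matrix(w$bq, nrow(a), d, byrow = TRUE)
    k <- a %*% w$wk + matrix(w$bk, nrow(a), d, byrow = TRUE)
    v <- a %*% w$wv + matrix(w$bv, nrow(a), d, byrow = TRUE)
    o <- matrix(0, tt * n, d)
    ps <- if (keep_cache) vector("list", n)
    for (s in seq_len(n)) {
      r <- rows_of(s)
      mask_row <- vis[s, ]
      pcs <- if (keep_cache) vector("list", nh)
      for (hh in seq_len(nh)) {
        cc <- ((hh - 1L) * dh + 1L):(hh * dh)
        sc <- (q[r, cc, drop = FALSE] %*% t(k[r, cc, drop = FALSE])) * scale
        sc[, !mask_row] <- -Inf
        p <- row_softmax(sc)
        o[r, cc] <- p %*% v[r, cc, drop = FALSE]
        if (keep_cache) pcs[[hh]] <- p
      }
      if (keep_cache) ps[[s]] <- pcs
    }
    m <- o %*% w$wo + matrix(w$bo, nrow(o), d, byrow = TRUE)
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(stats::rbinom(length(m), 1, 1 - drop_p) / (1 - drop_p),
                    nrow(m), ncol(m))
      m <- m * dm1
    }
    h2 <- h + m
    ln2 <- layer_norm_fwd(h2, w$ln2_g, w$ln2_b)
    f1 <- pmax(ln2$y %*% w$w1 +
                 matrix(w$b1, nrow(h2), config$ff_width, byrow = TRUE), 0)
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(stats::rbinom(length(f1), 1, 1 - drop_p) / (1 - drop_p),
                    nrow(f1), ncol(f1))
      f1 <- f1 * dm2
    }
    f2 <- f1 %*% w$w2 + matrix(w$b2, nrow(h2), d, byrow = TRUE)
    hout <- h2 + f2
    if (keep_cache)
      cache$layers[[li]] <- list(ln1 = ln1, a = a, q = q, k = k, v = v,
                                 o = o, ps = ps, dm1 = dm1, h2 = h2,
                                 ln2 = ln2, f1 = f1, dm2 = dm2, h_in = h)
    h <- hout
  }
  lnf <- layer_norm_fwd(h, weights$lnf_g, weights$lnf_b)
  z <- lnf$y
  if (config$pooling == "cls") {
    pooled <- z[seq(1L, tt * n, by = tt), , drop = FALSE]
  } else {
    pooled <- matrix(0, n, d)
    for (s in seq_len(n)) {
      r <- rows_of(s)[vis[s, ]]
      pooled[s, ] <- colMeans(z[r, , drop = FALSE])
    }
  }
  logits <- pooled %*% weights$head_w +
    matrix(weights$head_b, n, 13L, byrow = TRUE)
  colnames(logits) <- diagnostic_labels()
  out <- list(logits = logits, probs = predict_proba(logits))
  if (keep_cache) {
    cache$lnf <- lnf; cache$z <- z; cache$pooled <- pooled; cache$h_final <- h
    out$cache <- cache
  }
  class(out) <- "prediction_set"
  out
}

#' Sigmoid link for the 13 independent heads
#'
#' Elementwise sigmoid; no softmax coupling across heads, because the
#' diagnostic labels are not mutually exclusive.
#'
#' @param logits Numeric vector or matrix of logits.
#' @return Probabilities in (0, 1), same shape.
#' @export
predict_proba <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  1 / (1 + exp(-logits))
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", nrow(x$logits), " records x 13 labels\n", sep = "")
  invisible(x)
}

# Backward pass: returns gradients for all backbone weights plus d(tokens).
# `dlogits` is n x 13. Gradients at masked token positions are zeroed.
backbone_backward <- function(dlogits, batch, weights, config, cache) {
  n <- cache$n; tt <- cache$tt; d <- config$d_model
  nh <- config$n_heads; dh <- d %/% nh; scale <- 1 / sqrt(dh)
  vis <- cache$vis
  rows_of <- function(s) ((s - 1L) * tt + 1L):(s * tt)
  g <- list(head_w = t(cache$pooled) %*% dlogits,
            head_b = colSums(dlogits))
  dpooled <- dlogits %*% t(weights$head_w)
  dz <- matrix(0, tt * n, d)
  if (config$pooling == "cls") {
    dz[seq(1L, tt * n, by = tt), ] <- dpooled
  } else {
    for (s in seq_len(n)) {
      r <- rows_of(s)[vis[s, ]]
      dz[r, ] <- matrix(dpooled[s, ] / length(r), length(r), d, byrow = TRUE)
    }
  }
  lb <- layer_norm_bwd(dz, cache$lnf, weights$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dh_ <- lb$dx
  g$layers <- vector("list", length(weights$layers))
  for (li in rev(seq_along(weights$layers))) {
    w <- weights$layers[[li]]; cc_ <- cache$layers[[li]]
    gl <- list()
    # FFN block
    df2 <- dh_
    gl$w2 <- t(cc_$f1) %*% df2
    gl$b2 <- colSums(df2)
    df1 <- df2 %*% t(w$w2)
    if (!is.null(cc_$dm2)) df1 <- df1 * cc_$dm2
    df1 <- df1 * (cc_$f1 > 0)
    gl$w1 <- t(cc_$ln2$y) %*% df1
    gl$b1 <- colSums(df1)
    dln2y <- df1 %*% t(w$w1)
    lb2 <- layer_norm_bwd(dln2y, cc_$ln2, w$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dh2 <- dh_ + lb2$dx
    # attention block
    dm <- dh2
    if (!is.null(cc_$dm1)) dm <- dm * cc_$dm1
    gl$wo <- t(cc_$o) %*% dm
    gl$bo <- colSums(dm)
    do_ <- dm %*% t(w$wo)
    dq <- matrix(0, tt * n, d); dk <- matrix(0, tt * n, d)
    dv <- matrix(0, tt * n, d)
    for (s in seq_len(n)) {
      r <- rows_of(s)
      for (hh in seq_len(nh)) {
        cc <- ((hh - 1L) * dh + 1L):(hh * dh)
        p <- cc_$ps[[s]][[hh]]
        doh <- do_[r, cc, drop = FALSE]
        dv[r, cc] <- t(p) %*% doh
        dp <- doh %*% t(cc_$v[r, cc, drop = FALSE])
        dsc <- p * (dp - rowSums(dp * p))
        dsc <- dsc * scale
        dq[r, cc] <- dsc %*% cc_$k[r, cc, drop = FALSE]
        dk[r, cc] <- t(dsc) %*% cc_$q[r, cc, drop = FALSE]
      }
    }
    a <- cc_$a
    gl$wq <- t(a) %*% dq; gl$bq <- colSums(dq)
    gl$wk <- t(a) %*% dk; gl$bk <- colSums(dk)
    gl$wv <- t(a) %*% dv; gl$bv <- colSums(dv)
    da <- dq %*% t(w$wq) + dk %*% t(w$wk) + dv %*% t(w$wv)
    lb1 <- layer_norm_bwd(da, cc_$ln1, w$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dh_ <- dh2 + lb1$dx
    g$layers[[li]] <- gl
  }
  # split into CLS gradient and token gradients
  dx <- array(dh_, c(tt, n, d))
  g$cls <- colSums(matrix(dx[1, , ], n, d))
  dtokens <- aperm(dx[2:tt, , , drop = FALSE], c(2, 1, 3))
  # masked positions are contractually unread; their gradient is exactly 0
  # under CLS pooling, and we zero them for the masked-mean path too
  dtokens <- dtokens * array(rep(batch$train_mask, d), dim(dtokens))
  g$dtokens <- dtokens
  g
}
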