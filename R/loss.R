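#' Loss configuration
#'
#' Hyperparameters of the composite training loss
#' `L = L_FL + lambda * L_RL + beta * ||w||^2`:
#' a class-balanced focal loss over the 13 binary heads, a pairwise margin
#' ranking loss between heads within each subject, and L2 regularization
#' over the trainable weights.
#'
#' @param gamma Focusing exponent of the focal loss (default 2).
#' @param epsilon Ranking margin (default 0.25).
#' @param lambda Weight of the ranking loss (default 0.005).
#' @param beta Weight of the L2 term (default 0.0005).
#' @param alpha 13-vector of per-label balance weights in \[0, 1\], or NULL
#'   to compute `(1 - f_i)^2` from the training labels (see
#'   [compute_alpha()]).
#' @param batch_size Mini-batch size N (default 128).
#' @return A `loss_config` object.
#' @export
loss_config <- function(gamma = 2, epsilon = 0.25, lambda = 0.005,
                        beta = 0.0005, alpha = NULL, batch_size = 128L) {
  stopifnot(gamma >= 0, epsilon >= 0, lambda >= 0, beta >= 0, batch_size >= 1)
  if (!is.null(alpha)) {
    if (length(alpha) != 13 || any(alpha < 0 | alpha > 1))
      stop("alpha must be a 13-vector in [0, 1]")
  }
  structure(list(gamma = gamma, epsilon = epsilon, lambda = lambda,
                 beta = beta, alpha = alpha,
                 batch_size = as.integer(batch_size)),
            class = "loss_config")
}

#' Per-label balance weights from class prevalence
#'
#' For each label i, `alpha_i = (1 - f_i)^2` where `f_i` is the fraction of
#' known (non-unknown) training entries labelled 1. Rare labels therefore
#' get weights near 1, common labels smaller weights.
#'
#' @param labels n-by-13 matrix over \{0, 1, NA\}.
#' @return Named 13-vector of alpha weights.
#' @export
compute_alpha <- function(labels) {
  labels <- check_label_matrix(labels)
  known <- colSums(!is.na(labels))
  if (any(known == 0))
    stop("label(s) with zero known entries: ",
         paste(colnames(labels)[known == 0], collapse = ", "))
  f <- colSums(labels == 1, na.rm = TRUE) / known
  stats::setNames((1 - f)^2, colnames(labels))
}

#' Loss mask from trinary labels
#'
#' TRUE where the label is known (0 or 1), FALSE where unknown. Loss terms
#' at FALSE positions contribute zero and pass zero gradient, so subjects
#' lacking specific diagnoses still train the remaining heads.
#'
#' @param labels n-by-13 matrix over \{0, 1, NA\}.
#' @return Logical matrix of the same shape.
#' @export
label_loss_mask <- function(labels) !is.na(labels)

check_probs <- function(probs, label_mask) {
  bad <- label_mask & (probs <= 0 | probs >= 1)
  if (any(bad, na.rm = TRUE))
    stop("probabilities at exactly 0 or 1; clamp before the loss ",
         "(see clamp_probs)")
}

#' Clamp probabilities away from 0 and 1
#' @param probs Numeric probabilities.
#' @param eps Clamp margin (default 1e-7).
#' @return Probabilities in `[eps, 1 - eps]`.
#' @export
clamp_probs <- function(probs, eps = 1e-7) pmin(pmax(probs, eps), 1 - eps)

prep_loss_inputs <- function(probs, labels, label_mask, cfg) {
  stopifnot(is.matrix(probs), ncol(probs) == 13)
  labels <- check_label_matrix(labels)
  stopifnot(nrow(labels) == nrow(probs))
  if (is.null(label_mask)) label_mask <- label_loss_mask(labels)
  alpha <- cfg$alpha
  if (is.null(alpha)) stop("loss_config$alpha is unset; call compute_alpha()")
  y <- labels; y[!label_mask] <- 0          # placeholder; terms are zeroed
  check_probs(probs, label_mask)
  list(y = y, m = label_mask, alpha = alpha)
}

#' Focal loss over the 13 diagnostic heads
#'
#' The class-balanced focal loss
#' `(1/N) * sum_k sum_i [ -y a_i (1-p)^g log p - (1-y)(1-a_i) p^g log(1-p) ]`
#' with unknown-label terms contributing exactly zero. Normalization is by
#' the batch size N, not by the count of unmasked terms, exactly as the
#' defining sum reads; masked terms are zeroed inside the sum.
#'
#' @param probs n-by-13 matrix of sigmoid outputs in (0, 1).
#' @param labels n-by-13 matrix over \{0, 1, NA\}.
#' @param label_mask Logical matrix; defaults to [label_loss_mask()].
#' @param cfg A `loss_config` with `alpha` set.
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, labels, label_mask = NULL, cfg = loss_config()) {
  z <- prep_loss_inputs(probs, labels, label_mask, cfg)
  a <- matrix(z$alpha, nrow(probs), 13, byrow = TRUE)
  term <- -z$y * a * (1 - probs)^cfg$gamma * log(probs) -
    (1 - z$y) * (1 - a) * probs^cfg$gamma * log(1 - probs)
  term[!z$m] <- 0
  sum(term) / nrow(probs)
}

# d(focal)/d(probs), masked entries zero, already divided by N
focal_loss_grad <- function(probs, labels, label_mask = NULL,
                            cfg = loss_config()) {
  z <- prep_loss_inputs(probs, labels, label_mask, cfg)
  a <- matrix(z$alpha, nrow(probs), 13, byrow = TRUE)
  g <- cfg$gamma
  dpos <- a * (g * (1 - probs)^(g - 1) * log(probs) - (1 - probs)^g / probs)
  dneg <- -(1 - a) * (g * probs^(g - 1) * log(1 - probs) -
                        probs^g / (1 - probs))
  d <- z$y * dpos + (1 - z$y) * dneg
  d[!z$m] <- 0
  d / nrow(probs)
}

#' Pairwise margin ranking loss
#'
#' For each subject k and each unordered label pair (i, j), the hinge
#' `max(0, (p_i - p_j) * (y_j - y_i) + epsilon)` penalizes a head labelled
#' 0 whose sigmoid output is not below a head labelled 1 by the margin.
#' Pairs with equal labels contribute the constant `epsilon` exactly as the
#' formula dictates — a gradient-free offset. Pairs involving an unknown
#' label are excluded. Normalized by the batch size N.
#'
#' @inheritParams focal_loss
#' @param include_constant If FALSE, subtract the equal-label constant
#'   (`epsilon` per equal-label pair) for interpretability; gradients are
#'   identical either way. Default TRUE (the literal formula).
#' @return Scalar loss.
#' @export
ranking_loss <- function(probs, labels, label_mask = NULL, cfg = loss_config(),
                         include_constant = TRUE) {
  z <- prep_loss_inputs(probs, labels, label_mask, cfg)
  n <- nrow(probs)
  ut <- upper.tri(matrix(0, 13, 13))
  total <- 0
  for (k in seq_len(n)) {
    ok <- z$m[k, ]
    if (sum(ok) < 2) next
    p <- probs[k, ]; y <- z$y[k, ]
    hinge <- pmax(0, outer(p, p, `-`) * outer(y, y, function(a, b) b - a) +
                    cfg$epsilon)
    keep <- ut & outer(ok, ok, `&`)
    total <- total + sum(hinge[keep])
    if (!include_constant) {
      eq <- keep & outer(y, y, `==`)
      total <- total - cfg$epsilon * sum(eq)
    }
  }
  total / n
}

# d(ranking)/d(probs), divided by N
ranking_loss_grad <- function(probs, labels, label_mask = NULL,
                              cfg = loss_config()) {
  z <- prep_loss_inputs(probs, labels, label_mask, cfg)
  n <- nrow(probs)
  d <- matrix(0, n, 13)
  ut <- upper.tri(matrix(0, 13, 13))
  for (k in seq_len(n)) {
    ok <- z$m[k, ]
    if (sum(ok) < 2) next
    p <- probs[k, ]; y <- z$y[k, ]
    sgn <- outer(y, y, function(a, b) b - a)       # y_j - y_i
    act <- (outer(p, p, `-`) * sgn + cfg$epsilon > 0) &
      ut & outer(ok, ok, `&`) & sgn != 0
    if (!any(act)) next
    contrib <- sgn * act
    d[k, ] <- d[k, ] + rowSums(contrib) - colSums(contrib)
  }
  d / n
}

# sum of squares of decaying weights: all trainable weight matrices/vectors
# except biases and layer-norm gains/biases
collect_decay_sq <- function(w) {
  if (is.null(w)) return(0)
  if (is.numeric(w)) return(sum(w^2))
  if (inherits(w, "embedding_params")) {
    tot <- 0
    for (b in w$blocks) {
      if (!is.null(b$weight)) tot <- tot + sum(b$weight^2)
      if (!is.null(b$table)) tot <- tot + sum(b$table^2)
      if (!is.null(b$proj)) tot <- tot + sum(b$proj^2)
      if (!is.null(b$downsampler))
        tot <- tot + sum(vapply(b$downsampler[c("w1", "w2", "w3", "w4")],
                                function(m) sum(m^2), numeric(1)))
    }
    return(tot)
  }
  if (inherits(w, "backbone_weights")) {
    tot <- sum(w$cls^2) + sum(w$head_w^2)
    for (l in w$layers)
      tot <- tot + sum(vapply(l[c("wq", "wk", "wv", "wo", "w1", "w2")],
                              function(m) sum(m^2), numeric(1)))
    return(tot)
  }
  if (is.list(w)) return(sum(vapply(w, collect_decay_sq, numeric(1))))
  stop("cannot compute ||w||^2 for object of class ", class(w)[1])
}

#' Composite training loss
#'
#' `L = L_FL + lambda * L_RL + beta * ||w||^2`. The L2 norm sums the
#' squares of all trainable weight matrices (attention, feed-forward, head,
#' embedding weights/tables/projections, classification token) and excludes
#' biases and layer-norm parameters.
#'
#' @inheritParams focal_loss
#' @param weights Trainable weights: a numeric vector, an
#'   `embedding_params`, a `backbone_weights`, a list of these, or NULL
#'   (treated as zero).
#' @return Scalar loss.
#' @export
total_loss <- function(probs, labels, label_mask = NULL, weights = NULL,
                       cfg = loss_config()) {
  focal_loss(probs, labels, label_mask, cfg) +
    cfg$lambda * ranking_loss(probs, labels, label_mask, cfg) +
    cfg$beta * collect_decay_sq(weights)
}

# gradient of (FL + lambda RL) with respect to logits
loss_grad_logits <- function(probs, labels, label_mask = NULL,
                             cfg = loss_config()) {
  dp <- focal_loss_grad(probs, labels, label_mask, cfg) +
    cfg$lambda * ranking_loss_grad(probs, labels, label_mask, cfg)
  dp * probs * (1 - probs)
}

#' Random feature-mask sampling
#'
#' Training-time feature dropout: the observed feature set S is randomly
#' permuted as sigma, an integer i is drawn uniformly from \{1, ..., |S|\},
#' and the features sigma_(i+1), ..., sigma_(|S|) are dropped. The number
#' of kept features is therefore uniform on \{1, ..., |S|\} — at least one
#' feature always survives — and the expected number masked is
#' (|S| - 1) / 2. A fresh draw is made for every record in every batch.
#' Only observed features are permuted, so structural missingness and
#' simulated missingness compose into one mask.
#'
#' @param observed Vector identifying the observed features of one record
#'   (indices or names); must be non-empty.
#' @return Vector of the features to mask (possibly empty), same type as
#'   the input. Uses the current RNG stream.
#' @export
sample_feature_mask <- function(observed) {
  s <- length(observed)
  if (s < 1) stop("record has no observed feature")
  sigma <- sample.int(s)
  i <- sample.int(s, 1L)
  if (i == s) return(observed[0])
  observed[sigma[(i + 1L):s]]
}

# draw a full n x F train mask from an observation mask
sample_train_mask <- function(observed_mask) {
  tm <- observed_mask
  for (r in seq_len(nrow(tm))) {
    obs <- which(observed_mask[r, ])
    drop_idx <- sample_feature_mask(obs)
    if (length(drop_idx)) tm[r, drop_idx] <- FALSE
  }
  tm
}
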