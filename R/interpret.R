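#' Shapley attribution by permutation sampling
#'
#' Each record is a cooperative game whose players are its observed
#' features and whose payoff is the model output for a chosen label with a
#' coalition of features revealed through the backbone's attention mask
#' (no retraining, no imputation). The Shapley value of feature j is the
#' average, over orderings, of the marginal payoff change when j joins the
#' features before it. Sampling orderings uniformly gives an unbiased
#' estimator; `exact = TRUE` enumerates every ordering (payoffs are cached
#' per coalition, feasible for up to ~10 observed features). Unobserved
#' features receive exactly 0. The empty coalition is evaluated with only
#' the pooled classification-token pathway active, so its payoff is a
#' model constant, identical for every record.
#'
#' @param checkpoint An `mmdx_checkpoint`.
#' @param x A `cohort`.
#' @param subject Subject index or subject_id (one record).
#' @param label Label name or index in 1..13.
#' @param n_perms Number of sampled permutations (default 128); ignored
#'   when `exact = TRUE`.
#' @param payoff Model output used as payoff: `"prob"` (sigmoid output,
#'   default) or `"logit"`.
#' @param exact Enumerate all permutations of the observed features.
#' @return A `shapley_result`: named per-feature values (catalog order),
#'   with `n_perms`, `payoff`, and the empty/full-coalition payoffs as
#'   attributes.
#' @export
shapley_estimate <- function(checkpoint, x, subject, label, n_perms = 128L,
                             payoff = c("prob", "logit"), exact = FALSE) {
  payoff <- match.arg(payoff)
  if (!exact && n_perms < 1) stop("n_perms must be >= 1")
  rec <- x[subject]
  if (length(rec$subject_id) != 1) stop("subject must select exactly one record")
  li <- if (is.character(label)) match(label, diagnostic_labels())
        else as.integer(label)
  if (is.na(li) || li < 1 || li > 13) stop("unknown label: ", label)
  obs <- which(observed_matrix(rec)[1, ])
  if (!length(obs)) stop("record has no observed feature")
  s <- length(obs)
  nms <- catalog_names(x$catalog)
  batch1 <- assemble_tokens(rec, checkpoint$embed, checkpoint$standardizer)
  f <- length(nms); d <- checkpoint$model_config$d_model
  eval_coalitions <- function(masks) {     # masks: k x F logical
    k <- nrow(masks)
    tokens <- array(batch1$tokens[rep(1L, k), , , drop = FALSE], c(k, f, d))
    tb <- structure(list(tokens = tokens,
                         observed_mask = batch1$observed_mask[rep(1L, k), ,
                                                              drop = FALSE],
                         train_mask = masks, feature_names = nms),
                    class = "token_batch")
    out <- backbone_forward(tb, checkpoint$weights, checkpoint$model_config,
                            allow_empty = TRUE)
    if (payoff == "prob") out$probs[, li] else out$logits[, li]
  }
  phi <- stats::setNames(numeric(f), nms)
  if (exact) {
    if (s > 10) stop("exact enumeration supported for <= 10 observed features")
    # payoff per coalition (bitmask over the observed features)
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), s)))
    masks <- matrix(FALSE, nrow(subsets), f)
    masks[, obs] <- subsets
    pays <- eval_coalitions(masks)
    code <- function(member) sum(2^(which(member) - 1)) + 1
    perms <- all_permutations(s)
    for (pi in seq_len(nrow(perms))) {
      member <- rep(FALSE, s)
      prev <- pays[code(member)]
      for (j in perms[pi, ]) {
        member[j] <- TRUE
        cur <- pays[code(member)]
        phi[obs[j]] <- phi[obs[j]] + (cur - prev)
        prev <- cur
      }
    }
    phi <- phi / nrow(perms)
    n_used <- nrow(perms)
  } else {
    for (p in seq_len(n_perms)) {
      sigma <- sample.int(s)
      masks <- matrix(FALSE, s + 1L, f)
      for (k in seq_len(s)) masks[(k + 1L):(s + 1L), obs[sigma[k]]] <- TRUE
      pays <- eval_coalitions(masks)
      phi[obs[sigma]] <- phi[obs[sigma]] + diff(pays)
    }
    phi <- phi / n_perms
    n_used <- n_perms
  }
  empty_full <- eval_coalitions(rbind(rep(FALSE, f),
                                      seq_len(f) %in% obs))
  structure(phi, class = "shapley_result", n_perms = n_used,
            payoff = payoff, label = diagnostic_labels()[li],
            payoff_empty = empty_full[1], payoff_full = empty_full[2])
}

# rows = all permutations of 1..n
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' @export
print.shapley_result <- function(x, ...) {
  cat("<shapley_result> label ", attr(x, "label"), ", payoff = ",
      attr(x, "payoff"), ", ", attr(x, "n_perms"), " permutations\n", sep = "")
  v <- sort(unclass(x), decreasing = TRUE)
  print(utils::head(v, 10))
  invisible(x)
}

#' Global feature ranking from per-case Shapley values
#'
#' The case-selection protocol for a diagnostic group: score the test
#' cohort, keep the cases whose logit for the target label exceeds 0, take
#' the `n_cases` with the most observed features (ties broken by
#' subject_id order, recorded in the result), estimate per-case Shapley
#' values, assign exactly 0 to absent features, average per feature over
#' the selected cases (zeros included), and rank descending by mean value.
#'
#' @param checkpoint An `mmdx_checkpoint`.
#' @param x Test `cohort`.
#' @param label Label name (typically NC, MCI or DE) or index.
#' @param n_cases Number of cases to keep (default 500).
#' @param n_perms Sampled permutations per case (default 32).
#' @param payoff Passed to [shapley_estimate()].
#' @return Data.frame with `feature`, `mean_value`, `rank` (descending by
#'   mean value); selected subject_ids as attribute `cases`.
#' @export
rank_global_features <- function(checkpoint, x, label, n_cases = 500L,
                                 n_perms = 32L, payoff = "prob") {
  li <- if (is.character(label)) match(label, diagnostic_labels())
        else as.integer(label)
  if (is.na(li) || li < 1 || li > 13) stop("unknown label: ", label)
  preds <- predict_cohort(checkpoint, x)
  qual <- which(preds$logits[, li] > 0)
  if (!length(qual))
    stop("no qualifying cases: no subject has logit > 0 for ",
         diagnostic_labels()[li])
  n_obs <- rowSums(observed_matrix(x))[qual]
  ord <- qual[order(-n_obs, x$subject_id[qual])]
  take <- utils::head(ord, n_cases)
  nms <- catalog_names(x$catalog)
  vals <- matrix(0, length(take), length(nms), dimnames = list(NULL, nms))
  for (i in seq_along(take))
    vals[i, ] <- as.numeric(shapley_estimate(checkpoint, x, take[i], li,
                                             n_perms = n_perms,
                                             payoff = payoff))
  mv <- colMeans(vals)           # absent features contribute their zeros
  out <- data.frame(feature = nms, mean_value = mv)
  out <- out[order(-out$mean_value), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "cases") <- x$subject_id[take]
  attr(out, "label") <- diagnostic_labels()[li]
  out
}
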