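#' ROC and PR curve metrics for one binary label
#'
#' AUROC is computed with the midrank (tie = 1/2) convention, so it equals
#' the tie-corrected Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as half. AUPR is the
#' step-wise average precision (the integral of precision over recall
#' increments, with tied scores processed as one block).
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1) of the same length; NA pairs dropped.
#' @return List with `auroc`, `aupr`, `roc` (data.frame fpr/tpr) and `pr`
#'   (data.frame recall/precision), plus `n_pos`, `n_neg`. With a single
#'   class present, `auroc` and `aupr` are `NA` (undefined, not 0).
#' @export
binary_curve_metrics <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(labels) && !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0)
    return(list(auroc = NA_real_, aupr = NA_real_, roc = NULL, pr = NULL,
                n_pos = m, n_neg = n))
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
  # step curves over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))           # tie blocks share a threshold
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- tp / m; fpr <- fp / n
  prec <- tp / (tp + fp)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(recall = c(0, tpr), precision = c(1, prec))
  aupr <- sum(diff(c(0, tpr)) * prec)
  list(auroc = auroc, aupr = aupr, roc = roc, pr = pr, n_pos = m, n_neg = n)
}

#' Average per-label metrics across the 13 heads
#'
#' \describe{
#'   \item{micro}{pools every (score, label) pair from all scoreable labels
#'     into one curve;}
#'   \item{macro}{unweighted mean of the per-label values;}
#'   \item{weighted}{mean weighted by each label's positive count.}
#' }
#' Labels with a single class (AUROC undefined) are excluded from all three
#' averages' per-label parts; their pairs still enter the micro pool only
#' if both classes are present for that label.
#'
#' @param scores n-by-L score matrix.
#' @param labels n-by-L binary/NA label matrix.
#' @param scheme One of `"micro"`, `"macro"`, `"weighted"`.
#' @param metric `"auroc"` or `"aupr"`.
#' @return Scalar averaged metric.
#' @export
average_metrics <- function(scores, labels,
                            scheme = c("micro", "macro", "weighted"),
                            metric = c("auroc", "aupr")) {
  scheme <- match.arg(scheme); metric <- match.arg(metric)
  stopifnot(is.matrix(scores), is.matrix(labels),
            all(dim(scores) == dim(labels)))
  per <- lapply(seq_len(ncol(scores)), function(j)
    binary_curve_metrics(scores[, j], labels[, j]))
  ok <- which(!vapply(per, function(p) is.na(p$auroc), logical(1)))
  if (!length(ok)) stop("no scoreable label (need both classes in some label)")
  if (scheme == "micro") {
    keep <- !is.na(labels)
    return(binary_curve_metrics(scores[keep], labels[keep])[[metric]])
  }
  vals <- vapply(per[ok], `[[`, numeric(1), metric)
  if (scheme == "macro") return(mean(vals))
  w <- vapply(per[ok], `[[`, numeric(1), "n_pos")
  sum(vals * w) / sum(w)
}

#' Confusion-table statistics at a threshold
#'
#' Accuracy, sensitivity, specificity and the Matthews correlation
#' coefficient from the confusion table at `scores >= threshold`. MCC is
#' `NA` when a margin of the table is zero (undefined, not 0).
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels (NA dropped).
#' @param threshold Decision threshold (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `mcc`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Minimum positive count for a variance-bounded AUROC
#'
#' The distribution-free maximum variance of an empirical AUROC is
#' `1 / (4 * min(m, n))` where m, n are the class counts. Anchoring the
#' bound to the positive count, the smallest admissible count is
#' `ceil(1 / (4 * bound))`; a bound of 0.01 yields 25, the admission floor
#' used by the co-occurrence evaluation.
#'
#' @param variance_bound Positive bound on the AUROC variance, at most 0.25.
#' @return Integer minimum positive-class count.
#' @export
min_positive_samples <- function(variance_bound) {
  if (!is.numeric(variance_bound) || length(variance_bound) != 1 ||
      is.na(variance_bound) || variance_bound <= 0)
    stop("variance_bound must be a positive number")
  as.integer(ceiling(1 / (4 * variance_bound)))
}

#' Co-occurring etiology evaluation
#'
#' Enumerates combinations of two or more of the ten etiology labels and
#' scores each combination with at least [min_positive_samples()] jointly
#' positive subjects. Positives are subjects with every combination label
#' equal to 1; negatives are all remaining subjects; subjects with an
#' unknown label in the combination are dropped. The scalar score for a
#' combination is, by default, the mean of the model probabilities of its
#' labels (`"min"` and `"product"` are available alternatives); the choice
#' is recorded in the report.
#'
#' @param probs n-by-13 probability matrix (columns in label-schema order).
#' @param labels n-by-13 matrix over \{0, 1, NA\}.
#' @param variance_bound AUROC variance bound for admission (default 0.01,
#'   i.e. a floor of 25 positives).
#' @param statistic How to collapse a combination's probabilities to one
#'   score: `"mean"` (default), `"min"` or `"product"`.
#' @param max_order Largest combination size to enumerate (default 3).
#' @return A data.frame (`cooccurrence_report`): one row per admitted
#'   combination with counts, AUROC and AUPR; the admission floor and
#'   statistic are attached as attributes.
#' @export
cooccurrence_report <- function(probs, labels, variance_bound = 0.01,
                                statistic = c("mean", "min", "product"),
                                max_order = 3L) {
  statistic <- match.arg(statistic)
  labels <- check_label_matrix(labels)
  stopifnot(is.matrix(probs), all(dim(probs) == dim(labels)))
  floor_n <- min_positive_samples(variance_bound)
  eti <- match(etiology_labels(), diagnostic_labels())
  rows <- list()
  for (ord in 2:max_order) {
    combs <- utils::combn(eti, ord, simplify = FALSE)
    for (cb in combs) {
      lab <- labels[, cb, drop = FALSE]
      known <- rowSums(is.na(lab)) == 0
      pos <- known & rowSums(lab == 1) == ord
      if (sum(pos) < floor_n) next
      y <- as.numeric(pos[known])
      p <- probs[known, cb, drop = FALSE]
      s <- switch(statistic,
                  mean = rowMeans(p),
                  min = apply(p, 1, min),
                  product = apply(p, 1, prod))
      bm <- binary_curve_metrics(s, y)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste(diagnostic_labels()[cb], collapse = "&"),
        order = ord, n_pos = sum(pos), n_neg = sum(known) - sum(pos),
        auroc = bm$auroc, aupr = bm$aupr)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(combination = character(), order = integer(),
               n_pos = integer(), n_neg = integer(),
               auroc = numeric(), aupr = numeric())
  attr(out, "min_positive") <- floor_n
  attr(out, "statistic") <- statistic
  class(out) <- c("cooccurrence_report", class(out))
  out
}

#' Full metric report
#'
#' Per-label AUROC/AUPR plus confusion statistics at a threshold, the
#' micro/macro/weighted averages, and optional subgroup breakdowns by the
#' cohort strata (age_bin, gender, race).
#'
#' @param probs n-by-13 probability matrix.
#' @param labels n-by-13 matrix over \{0, 1, NA\}.
#' @param strata Optional data.frame with columns among age_bin, gender,
#'   race.
#' @param threshold Confusion threshold (default 0.5).
#' @return A `metric_report` list: `per_label` data.frame, `averages`
#'   data.frame, and `strata` (named list of metric_reports) when strata
#'   are given.
#' @export
metric_report <- function(probs, labels, strata = NULL, threshold = 0.5) {
  labels <- check_label_matrix(labels)
  per <- lapply(seq_len(13), function(j) {
    bm <- binary_curve_metrics(probs[, j], labels[, j])
    cm <- confusion_metrics(probs[, j], labels[, j], threshold)
    data.frame(label = diagnostic_labels()[j], n_pos = bm$n_pos,
               n_neg = bm$n_neg, auroc = bm$auroc, aupr = bm$aupr,
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity, mcc = cm$mcc)
  })
  per <- do.call(rbind, per)
  avg <- expand.grid(scheme = c("micro", "macro", "weighted"),
                     metric = c("auroc", "aupr"), stringsAsFactors = FALSE)
  avg$value <- mapply(function(s, m)
    tryCatch(average_metrics(probs, labels, s, m), error = function(e) NA_real_),
    avg$scheme, avg$metric)
  out <- list(per_label = per, averages = avg, threshold = threshold)
  if (!is.null(strata)) {
    out$strata <- list()
    for (sc in intersect(strata_columns, names(strata))) {
      for (lv in unique(stats::na.omit(strata[[sc]]))) {
        idx <- which(!is.na(strata[[sc]]) & strata[[sc]] == lv)
        if (length(idx) < 2) next
        out$strata[[paste0(sc, "=", lv)]] <-
          metric_report(probs[idx, , drop = FALSE],
                        labels[idx, , drop = FALSE], threshold = threshold)
      }
    }
  }
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$per_label, row.names = FALSE, digits = 3)
  cat("averages:\n")
  print(x$averages, row.names = FALSE, digits = 3)
  if (!is.null(x$strata))
    cat("strata:", paste(names(x$strata), collapse = ", "), "\n")
  invisible(x)
}

#' Missingness sweep
#'
#' Re-scores a cohort under scenarios that mask whole feature groups
#' (e.g. MRI, FAQ, GDS, NPIQ, UPDRS, NP tests) and reports per-label AUROC
#' for each scenario. The baseline scenario masks nothing; an empty
#' scenario reproduces it exactly.
#'
#' @param checkpoint A trained `mmdx_checkpoint`.
#' @param x Evaluation `cohort`.
#' @param scenarios Named list of character vectors of group tags to mask;
#'   a `"baseline"` scenario (no masking) is always included first.
#' @param labels Which label columns to report (default NC, MCI, DE).
#' @return Data.frame: one row per scenario x label with AUROC.
#' @export
missingness_sweep <- function(checkpoint, x, scenarios,
                              labels = status_labels()) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(names(scenarios)) && length(scenarios))
    names(scenarios) <- vapply(scenarios, function(g)
      if (length(g)) paste(g, collapse = "+") else "none", character(1))
  scenarios <- c(list(baseline = character(0)), scenarios)
  obs <- observed_matrix(x)
  li <- match(labels, diagnostic_labels())
  rows <- list()
  for (sn in names(scenarios)) {
    gs <- scenarios[[sn]]
    mask <- obs
    if (length(gs)) {
      feats <- catalog_group_features(x$catalog, gs)
      mask[, feats] <- FALSE
    }
    if (any(rowSums(mask) == 0))
      stop("scenario '", sn, "' leaves record(s) with no observed feature")
    pr <- predict_cohort(checkpoint, x, train_mask = mask)
    for (j in seq_along(li)) {
      bm <- binary_curve_metrics(pr$probs[, li[j]], x$labels[, li[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sn, label = labels[j], auroc = bm$auroc, aupr = bm$aupr)
    }
  }
  do.call(rbind, rows)
}

#' Fuse clinician confidence scores with model probabilities
#'
#' AI-augmented assessment: the clinician's 0-100 confidence score is
#' rescaled to \[0, 1\] and averaged with the model's predicted
#' probability. The fusion is symmetric in its two rescaled arguments and
#' idempotent when they agree.
#'
#' @param clinician_scores Numeric scores on the 0-100 scale (vector or
#'   matrix).
#' @param model_probs Model probabilities in \[0, 1\], same shape.
#' @return Fused scores in \[0, 1\], same shape.
#' @export
augment_confidence <- function(clinician_scores, model_probs) {
  if (any(clinician_scores < 0 | clinician_scores > 100, na.rm = TRUE))
    stop("clinician scores must lie in [0, 100]")
  if (any(model_probs < 0 | model_probs > 1, na.rm = TRUE))
    stop("model probabilities must lie in [0, 1]")
  (clinician_scores / 100 + model_probs) / 2
}
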