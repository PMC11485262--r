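#' Cohort tables
#'
#' A `cohort` holds one row per subject: feature values with explicit
#' missingness, a 13-slot trinary label vector (0 / 1 / unknown) and
#' optional evaluation-only strata (age_bin, gender, race). Missing feature
#' values and unknown labels are represented by `NA` — a sentinel distinct
#' from every legal value, never a reinterpreted 0 or empty string — because
#' the masking semantics of the model require unambiguous observation flags.
#' Strata are carried as metadata only and are never fed to the model unless
#' also declared as catalog features.
#'
#' Internally the object is columnar: `data` is a named list holding, per
#' catalog feature, a numeric vector, a character vector of category codes,
#' or an n-by-width embedding matrix (all-NA row = missing).
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param data Named list of feature columns (see Details).
#' @param labels n-by-13 matrix with entries in {0, 1, NA}.
#' @param catalog The `feature_catalog` the data must conform to.
#' @param strata Optional data.frame with columns among
#'   `age_bin`, `gender`, `race`.
#' @return A `cohort` object.
#' @export
cohort <- function(subject_id, data, labels, catalog, strata = NULL) {
  stopifnot(inherits(catalog, "feature_catalog"))
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique")
  labels <- check_label_matrix(labels)
  if (nrow(labels) != n) stop("labels must have one row per subject")
  unknown <- setdiff(names(data), catalog_names(catalog))
  if (length(unknown))
    stop("feature(s) not in catalog: ", paste(unknown, collapse = ", "))
  for (nm in names(data)) {
    sp <- catalog$features[[nm]]
    col <- data[[nm]]
    if (sp$modality == "numeric") {
      col <- as.numeric(col)
      if (length(col) != n) stop("feature '", nm, "': wrong length")
      if (any(is.infinite(col) | is.nan(col)))
        stop("feature '", nm, "': non-finite numeric value")
      data[[nm]] <- col
    } else if (sp$modality == "categorical") {
      col <- as.character(col)
      if (length(col) != n) stop("feature '", nm, "': wrong length")
      bad <- which(!is.na(col) & !(col %in% sp$categories))
      if (length(bad))
        stop("feature '", nm, "', row ", bad[1], ": category '", col[bad[1]],
             "' not in declared set {", paste(sp$categories, collapse = ", "), "}")
      data[[nm]] <- col
    } else {
      if (!is.matrix(col) || nrow(col) != n || ncol(col) != sp$embedding_width)
        stop("feature '", nm, "': embedding matrix must be ", n, " x ",
             sp$embedding_width)
      part <- rowSums(is.na(col))
      if (any(part > 0 & part < ncol(col)))
        stop("feature '", nm, "': embedding rows must be fully observed or fully NA")
      if (any(is.infinite(col) | is.nan(col)))
        stop("feature '", nm, "': non-finite embedding value")
      data[[nm]] <- col
    }
  }
  # features absent from `data` are missing for everyone
  for (nm in setdiff(catalog_names(catalog), names(data))) {
    sp <- catalog$features[[nm]]
    data[[nm]] <- if (sp$modality == "image_embedding")
      matrix(NA_real_, n, sp$embedding_width)
    else if (sp$modality == "numeric") rep(NA_real_, n)
    else rep(NA_character_, n)
  }
  data <- data[catalog_names(catalog)]
  obs <- observed_matrix_from_data(data, catalog, n)
  none <- which(rowSums(obs) == 0)
  if (length(none))
    stop("subject(s) with no observed feature: ",
         paste(subject_id[utils::head(none, 5)], collapse = ", "))
  if (!is.null(strata)) {
    strata <- as.data.frame(strata, stringsAsFactors = FALSE)
    extra <- setdiff(names(strata), c("age_bin", "gender", "race"))
    if (length(extra)) stop("unknown strata column(s): ", paste(extra, collapse = ", "))
    if (nrow(strata) != n) stop("strata must have one row per subject")
  }
  structure(list(subject_id = subject_id, data = data, labels = labels,
                 strata = strata, catalog = catalog),
            class = "cohort")
}

observed_matrix_from_data <- function(data, catalog, n) {
  nms <- catalog_names(catalog)
  obs <- matrix(FALSE, n, length(nms), dimnames = list(NULL, nms))
  for (nm in nms) {
    col <- data[[nm]]
    obs[, nm] <- if (is.matrix(col)) rowSums(is.na(col)) == 0 else !is.na(col)
  }
  obs
}

#' Observation indicator matrix
#' @param x A `cohort`.
#' @return Logical n-by-F matrix, TRUE where the feature is observed.
#' @export
observed_matrix <- function(x) {
  stopifnot(inherits(x, "cohort"))
  observed_matrix_from_data(x$data, x$catalog, length(x$subject_id))
}

#' @export
print.cohort <- function(x, ...) {
  obs <- observed_matrix(x)
  cat("<cohort> ", length(x$subject_id), " subjects x ", ncol(obs),
      " features (", round(100 * mean(!obs), 1), "% feature values missing, ",
      round(100 * mean(is.na(x$labels)), 1), "% labels unknown)\n", sep = "")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subject_id)

#' Subset a cohort by subject
#' @param x A `cohort`.
#' @param i Row index (integer, logical or subject_id character).
#' @param ... Unused.
#' @export
`[.cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$subject_id)
  data <- lapply(x$data, function(col)
    if (is.matrix(col)) col[i, , drop = FALSE] else col[i])
  structure(list(subject_id = x$subject_id[i], data = data,
                 labels = x$labels[i, , drop = FALSE],
                 strata = if (!is.null(x$strata)) x$strata[i, , drop = FALSE],
                 catalog = x$catalog),
            class = "cohort")
}

strata_columns <- c("age_bin", "gender", "race")

# full-precision numeric formatting so CSV round-trips are bit-exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

embedding_to_json <- function(m) {
  apply(m, 1, function(r) {
    if (all(is.na(r))) "" else
      paste0("[", paste(sprintf("%.17g", r), collapse = ","), "]")
  })
}

parse_embedding_cell <- function(cell, width, dir, row, nm) {
  if (is.na(cell) || !nzchar(cell)) return(rep(NA_real_, width))
  cell <- trimws(cell)
  v <- if (startsWith(cell, "[")) {
    as.numeric(jsonlite::fromJSON(cell))
  } else {
    p <- if (file.exists(cell)) cell else file.path(dir, cell)
    if (!file.exists(p))
      stop("feature '", nm, "', row ", row, ": sidecar file not found: ", cell)
    as.numeric(utils::read.csv(p, header = FALSE)[1, ])
  }
  if (length(v) != width)
    stop("feature '", nm, "', row ", row, ": embedding has length ", length(v),
         ", declared width is ", width)
  v
}

#' Read a cohort table
#'
#' Reads a CSV or Parquet cohort table (one row per subject; columns =
#' `subject_id` + features + 13 label columns + optional strata) against a
#' catalog. Empty cells become missing features or unknown labels; category
#' codes outside the declared set and non-finite numerics are errors, never
#' silently coerced. Image-embedding cells hold an inline JSON array or the
#' path of a one-row CSV sidecar (relative to the table).
#'
#' @param path CSV (`.csv`) or Parquet (`.parquet`) file.
#' @param catalog A `feature_catalog`.
#' @param labels Ordered label names; defaults to [diagnostic_labels()].
#' @return A `cohort`.
#' @export
read_cohort_table <- function(path, catalog, labels = diagnostic_labels()) {
  stopifnot(inherits(catalog, "feature_catalog"))
  if (!file.exists(path)) stop("cohort table not found: ", path)
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading Parquet requires the 'arrow' package")
    df <- as.data.frame(arrow::read_parquet(path))
  } else {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  }
  if (!"subject_id" %in% names(df)) stop("table lacks a subject_id column")
  known <- c("subject_id", catalog_names(catalog), labels, strata_columns)
  extra <- setdiff(names(df), known)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  n <- nrow(df)
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  to_num <- function(x, what) {
    x <- as.character(x)
    out <- rep(NA_real_, length(x))
    ok <- !blank(x)
    out[ok] <- suppressWarnings(as.numeric(x[ok]))
    bad <- which(ok & is.na(out))
    if (length(bad))
      stop(what, ", row ", bad[1], ": not a number: '", x[bad[1]], "'")
    out
  }
  dir <- dirname(path)
  data <- list()
  for (nm in intersect(catalog_names(catalog), names(df))) {
    sp <- catalog$features[[nm]]
    col <- df[[nm]]
    data[[nm]] <- switch(sp$modality,
      numeric = to_num(col, paste0("feature '", nm, "'")),
      categorical = {
        x <- as.character(col); x[blank(x)] <- NA_character_; x
      },
      image_embedding = {
        x <- as.character(col)
        t(vapply(seq_along(x), function(i)
          parse_embedding_cell(x[i], sp$embedding_width, dir, i, nm),
          numeric(sp$embedding_width)))
      })
  }
  lab <- matrix(NA_real_, n, length(labels), dimnames = list(NULL, labels))
  for (nm in intersect(labels, names(df)))
    lab[, nm] <- to_num(df[[nm]], paste0("label '", nm, "'"))
  strata <- NULL
  sc <- intersect(strata_columns, names(df))
  if (length(sc)) {
    strata <- df[sc]
    for (s in sc) {
      x <- as.character(strata[[s]]); x[blank(x)] <- NA_character_
      strata[[s]] <- x
    }
  }
  cohort(df$subject_id, data, lab, catalog, strata = strata)
}

#' Write a cohort table
#'
#' Writes a `cohort` to CSV (embeddings inline as JSON arrays) or Parquet.
#' Numeric cells are written at full precision so that
#' `read_cohort_table(write_cohort_table(x))` reproduces values, missing
#' markers and unknown labels exactly.
#'
#' @param x A `cohort`.
#' @param path Output path (`.csv` or `.parquet`).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  cols <- list(subject_id = x$subject_id)
  for (nm in catalog_names(x$catalog)) {
    sp <- x$catalog$features[[nm]]
    col <- x$data[[nm]]
    cols[[nm]] <- switch(sp$modality,
      numeric = fmt_num(col),
      categorical = ifelse(is.na(col), "", col),
      image_embedding = embedding_to_json(col))
  }
  for (j in seq_len(ncol(x$labels)))
    cols[[colnames(x$labels)[j]]] <- fmt_num(x$labels[, j])
  if (!is.null(x$strata))
    for (s in names(x$strata))
      cols[[s]] <- ifelse(is.na(x$strata[[s]]), "", x$strata[[s]])
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing Parquet requires the 'arrow' package")
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(path)
}

#' Write and read model predictions
#'
#' Predictions are stored as CSV with `subject_id`, thirteen probability
#' columns (`prob_<label>`) and thirteen logit columns (`logit_<label>`),
#' in fixed label-schema order, at full precision so read-back reproduces
#' the values.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param probs n-by-13 matrix of probabilities in \[0, 1\].
#' @param logits n-by-13 matrix of logits.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(subject_id, probs, logits, path) {
  n <- length(subject_id)
  labs <- diagnostic_labels()
  if (!is.matrix(probs) || nrow(probs) != n || ncol(probs) != 13)
    stop("probs must be a ", n, " x 13 matrix (one row per subject)")
  if (!is.matrix(logits) || nrow(logits) != n || ncol(logits) != 13)
    stop("logits must be a ", n, " x 13 matrix (one row per subject)")
  cols <- list(subject_id = as.character(subject_id))
  for (j in 1:13) cols[[paste0("prob_", labs[j])]] <- fmt_num(probs[, j])
  for (j in 1:13) cols[[paste0("logit_", labs[j])]] <- fmt_num(logits[, j])
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  labs <- diagnostic_labels()
  probs <- sapply(paste0("prob_", labs), function(cn) as.numeric(df[[cn]]))
  logits <- sapply(paste0("logit_", labs), function(cn) as.numeric(df[[cn]]))
  if (nrow(df) == 1) { probs <- matrix(probs, 1); logits <- matrix(logits, 1) }
  colnames(probs) <- colnames(logits) <- labs
  list(subject_id = df$subject_id, probs = probs, logits = logits)
}
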