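#' Feature catalogs
#'
#' A feature catalog declares every input feature the model may see: its
#' name, its modality (`numeric`, `categorical` or `image_embedding`), the
#' admissible category codes for categorical features, the embedding width
#' for imaging features, and an optional group tag (e.g. "MRI", "FAQ",
#' "NP tests") used by missingness sweeps. The catalog is the contract
#' between cohort tables, the embedding layer and the attention masks:
#' token order always follows catalog order.
#'
#' @param entries List of feature specifications. Each element is a list
#'   with fields `name`, `modality`, and (per modality) `categories`
#'   (categorical, >= 2 codes), `embedding_width` (image_embedding,
#'   default 256) and optional `group`.
#' @param groups Optional character vector declaring the admissible group
#'   tags; defaults to the tags present in `entries`.
#' @return A `feature_catalog` object.
#' @export
feature_catalog <- function(entries, groups = NULL) {
  if (!length(entries)) stop("catalog must declare at least one feature")
  specs <- lapply(entries, validate_feature_spec)
  nms <- vapply(specs, `[[`, character(1), "name")
  dup <- nms[duplicated(nms)]
  if (length(dup))
    stop("duplicate feature name(s) in catalog: ", paste(unique(dup), collapse = ", "))
  tags <- unlist(lapply(specs, `[[`, "group"))
  if (is.null(groups)) groups <- unique(tags)
  bad <- setdiff(tags, groups)
  if (length(bad))
    stop("group tag(s) not in declared set: ", paste(unique(bad), collapse = ", "))
  names(specs) <- nms
  structure(list(features = specs, groups = groups),
            class = "feature_catalog")
}

validate_feature_spec <- function(sp) {
  if (is.null(sp$name) || !nzchar(sp$name))
    stop("every catalog entry needs a non-empty 'name'")
  mod <- sp$modality
  if (is.null(mod) || !mod %in% c("numeric", "categorical", "image_embedding"))
    stop("feature '", sp$name,
         "': modality must be numeric, categorical or image_embedding")
  out <- list(name = as.character(sp$name), modality = mod,
              group = if (!is.null(sp$group)) as.character(sp$group) else NULL)
  if (mod == "categorical") {
    cats <- as.character(unlist(sp$categories))
    if (length(cats) < 2)
      stop("feature '", sp$name, "': categorical features need >= 2 categories")
    if (anyDuplicated(cats))
      stop("feature '", sp$name, "': duplicate category codes")
    out$categories <- cats
  } else if (mod == "image_embedding") {
    w <- sp$embedding_width
    if (is.null(w)) w <- 256L
    w <- as.integer(w)
    if (is.na(w) || w <= 0)
      stop("feature '", sp$name, "': embedding_width must be a positive integer")
    out$embedding_width <- w
  }
  out
}

#' Load a feature catalog from JSON
#'
#' The catalog file is a top-level JSON array of feature objects, each with
#' `name`, `modality` and the modality-specific fields (see
#' [feature_catalog()]). Validation is total: any malformed entry raises an
#' error naming the offending feature; a partially built catalog is never
#' returned.
#'
#' @param path Path to the JSON catalog file.
#' @param groups Optional declared set of group tags.
#' @return A validated `feature_catalog`.
#' @export
load_feature_catalog <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("catalog must be a JSON array of feature objects")
  feature_catalog(raw, groups = groups)
}

#' Write a feature catalog to JSON
#' @param catalog A `feature_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "feature_catalog"))
  entries <- lapply(unname(catalog$features), function(sp) sp[!vapply(sp, is.null, logical(1))])
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.feature_catalog <- function(x, ...) {
  mods <- vapply(x$features, `[[`, character(1), "modality")
  cat("<feature_catalog> ", length(x$features), " features (",
      sum(mods == "numeric"), " numeric, ",
      sum(mods == "categorical"), " categorical, ",
      sum(mods == "image_embedding"), " image_embedding)\n", sep = "")
  if (length(x$groups))
    cat("  groups: ", paste(x$groups, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.feature_catalog <- function(x) length(x$features)

catalog_names <- function(catalog) names(catalog$features)

catalog_group_features <- function(catalog, groups) {
  bad <- setdiff(groups, catalog$groups)
  if (length(bad)) stop("unknown group tag(s): ", paste(bad, collapse = ", "))
  nms <- names(catalog$features)
  keep <- vapply(catalog$features, function(sp)
    !is.null(sp$group) && sp$group %in% groups, logical(1))
  nms[keep]
}
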