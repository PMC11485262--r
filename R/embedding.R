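#' Embedding parameters
#'
#' Every catalog feature owns a parameter block mapping its observed value
#' to a fixed-length token of width `d_model`:
#' \itemize{
#'   \item numeric — a single linear layer, `value * weight + bias`
#'     (both of width `d_model`); values are z-scored with training-split
#'     statistics first, because an affine embedding is scale-sensitive;
#'   \item categorical — a lookup table with one independent row per
#'     category code (equivalent to a linear map on the one-hot encoding);
#'   \item image_embedding — an optional learnable downsampling adapter
#'     from an encoder-output grid to a 256-vector (see
#'     [downsampler_params()]), followed by a linear projection to
#'     `d_model` so the token width is decoupled from the vector width.
#' }
#' Tokens carry no positional encoding: the input is an unordered feature
#' set, and each feature is identified by its own parameters.
#'
#' @param catalog A `feature_catalog`.
#' @param d_model Token width (default 256).
#' @param seed Integer seed for weight initialization.
#' @param identity_projection If TRUE and `d_model` equals the embedding
#'   width, initialize image projections to the identity.
#' @return An `embedding_params` object.
#' @export
embedding_params <- function(catalog, d_model = 256L, seed = 1L,
                             identity_projection = FALSE) {
  stopifnot(inherits(catalog, "feature_catalog"), d_model >= 1)
  d_model <- as.integer(d_model)
  rng <- local_rng(seed)
  sd0 <- 1 / sqrt(d_model)
  blocks <- lapply(catalog$features, function(sp) {
    switch(sp$modality,
      numeric = list(weight = rng$norm(d_model, sd = sd0),
                     bias = numeric(d_model)),
      categorical = list(table = matrix(rng$norm(length(sp$categories) * d_model,
                                                 sd = sd0),
                                        length(sp$categories), d_model,
                                        dimnames = list(sp$categories, NULL))),
      image_embedding = {
        w <- sp$embedding_width
        proj <- if (identity_projection && w == d_model) diag(1, w, d_model)
                else matrix(rng$norm(w * d_model, sd = 1 / sqrt(w)), w, d_model)
        list(downsampler = if (w == 256L) downsampler_params(seed = rng$int()),
             proj = proj, proj_bias = numeric(d_model))
      })
  })
  names(blocks) <- catalog_names(catalog)
  structure(list(d_model = d_model, blocks = blocks), class = "embedding_params")
}

# small rng helper so parameter init never disturbs the global stream order
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed); s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(
    norm = function(n, sd = 1) with_state(function() stats::rnorm(n, sd = sd)),
    unif = function(n) with_state(function() stats::runif(n)),
    int = function(n = 1) with_state(function()
      sample.int(.Machine$integer.max - 1L, n)),
    perm = function(n) with_state(function() sample.int(n)),
    sample_int = function(n, size, replace = FALSE) with_state(function()
      sample.int(n, size, replace = replace))
  )
}

#' Embed a numeric value
#'
#' A single linear layer: `value * weight + bias`. The value is expected to
#' be standardized (z-scored with training statistics) upstream.
#'
#' @param value Finite numeric scalar (or vector, embedded row-wise).
#' @param block Parameter block with `weight` and `bias` of width d_model.
#' @return Vector of width d_model (or a matrix, one row per value).
#' @export
embed_numeric <- function(value, block) {
  if (any(!is.finite(value))) stop("embed_numeric: non-finite input")
  out <- outer(value, block$weight) +
    matrix(block$bias, length(value), length(block$bias), byrow = TRUE)
  if (length(value) == 1L) drop(out) else out
}

#' Embed a categorical code
#'
#' Lookup-table embedding: returns the parameter row of the given category.
#' Codes may be 1-based integer indices or category names (table rownames).
#'
#' @param code Integer index in `1..cardinality`, or category code string.
#' @param table Lookup table, one row per category.
#' @return Vector of width d_model.
#' @export
embed_categorical <- function(code, table) {
  if (is.character(code)) {
    idx <- match(code, rownames(table))
    if (is.na(idx)) stop("embed_categorical: unknown category '", code, "'")
  } else {
    idx <- as.integer(code)
    if (is.na(idx) || idx < 1L || idx > nrow(table))
      stop("embed_categorical: code ", code, " out of range 1..", nrow(table))
  }
  table[idx, ]
}

#' Downsampling adapter parameters
#'
#' The adapter reduces an encoder-output grid of shape 768 x 4 x 4 x 4
#' (channels x depth x height x width) to a 256-vector through four
#' convolutional blocks: two stride-2 kernel-2 convolutions (implemented as
#' patch-gather + matrix multiply, which is exactly a non-overlapping
#' strided convolution) that collapse the spatial grid 4->2->1 while mapping
#' channels 768->256->256, followed by two 1x1x1 convolutions 256->256.
#' ReLU follows every block but the last. The output length is 256 for any
#' parameter values.
#'
#' @param seed Integer seed.
#' @param in_channels Encoder channel count (default 768).
#' @param grid Spatial edge length of the encoder grid (default 4).
#' @param channels Adapter channel width and output length (default 256).
#' @return A `downsampler_params` object.
#' @export
downsampler_params <- function(seed = 1L, in_channels = 768L, grid = 4L,
                               channels = 256L) {
  rng <- local_rng(seed)
  mk <- function(fan_in, fan_out)
    matrix(rng$norm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  structure(list(
    in_channels = as.integer(in_channels), grid = as.integer(grid),
    channels = as.integer(channels),
    w1 = mk(in_channels * 8L, channels), b1 = numeric(channels),
    w2 = mk(channels * 8L, channels),    b2 = numeric(channels),
    w3 = mk(channels, channels),         b3 = numeric(channels),
    w4 = mk(channels, channels),         b4 = numeric(channels)
  ), class = "downsampler_params")
}

# gather non-overlapping k^3 patches of a [C, D, H, W] array into rows
patchify3d <- function(arr, k) {
  d <- dim(arr)
  stopifnot(length(d) == 4, d[2] %% k == 0)
  nb <- d[2] %/% k
  out <- matrix(0, nb^3, d[1] * k^3)
  r <- 1L
  for (z in seq_len(nb)) for (y in seq_len(nb)) for (x in seq_len(nb)) {
    blk <- arr[, ((x - 1) * k + 1):(x * k),
                 ((y - 1) * k + 1):(y * k),
                 ((z - 1) * k + 1):(z * k), drop = FALSE]
    out[r, ] <- as.vector(blk)
    r <- r + 1L
  }
  out
}

#' Downsample an encoder-output grid to a 256-vector
#'
#' @param grid Numeric array of dim `c(768, 4, 4, 4)` (channels first).
#' @param dp A `downsampler_params` object.
#' @return Numeric vector of length 256.
#' @export
downsample_grid <- function(grid, dp) {
  stopifnot(inherits(dp, "downsampler_params"))
  want <- c(dp$in_channels, dp$grid, dp$grid, dp$grid)
  if (!is.array(grid) || !identical(as.integer(dim(grid)), as.integer(want)))
    stop("grid shape mismatch: expected ", paste(want, collapse = " x "))
  h1 <- pmax(patchify3d(grid, 2L) %*% dp$w1 +
               matrix(dp$b1, 8, dp$channels, byrow = TRUE), 0)       # 8 x C
  a1 <- array(t(h1), c(dp$channels, 2L, 2L, 2L))
  h2 <- pmax(patchify3d(a1, 2L) %*% dp$w2 + dp$b2, 0)               # 1 x C
  h3 <- pmax(h2 %*% dp$w3 + dp$b3, 0)
  drop(h3 %*% dp$w4 + dp$b4)
}

#' Embed an imaging feature
#'
#' A precomputed embedding vector bypasses the downsampler and only passes
#' through the linear projection; an encoder-output grid is first reduced
#' by [downsample_grid()].
#'
#' @param input Numeric vector of the declared embedding width, or an
#'   encoder grid array of dim `c(768, 4, 4, 4)`.
#' @param block Image parameter block (`downsampler`, `proj`, `proj_bias`).
#' @return Vector of width d_model.
#' @export
embed_image <- function(input, block) {
  v <- if (is.array(input) && length(dim(input)) == 4) {
    if (is.null(block$downsampler))
      stop("no downsampler parameters for grid input")
    downsample_grid(input, block$downsampler)
  } else {
    input <- as.numeric(input)
    if (length(input) != nrow(block$proj))
      stop("embedding vector length ", length(input),
           " does not match projection input ", nrow(block$proj))
    input
  }
  drop(v %*% block$proj) + block$proj_bias
}

#' Fit numeric standardization statistics
#'
#' Computes per-feature mean and standard deviation of every numeric
#' feature over its observed entries in the training split. These are
#' frozen at fit time and applied before the affine numeric embedding.
#'
#' @param x Training `cohort`.
#' @return Named list with `mean` and `sd` vectors (sd floor of 1e-8; a
#'   constant feature standardizes to 0).
#' @export
fit_standardizer <- function(x) {
  stopifnot(inherits(x, "cohort"))
  num <- names(which(vapply(x$catalog$features, function(sp)
    sp$modality == "numeric", logical(1))))
  mu <- sd <- stats::setNames(numeric(length(num)), num)
  for (nm in num) {
    v <- x$data[[nm]][!is.na(x$data[[nm]])]
    mu[nm] <- if (length(v)) mean(v) else 0
    s <- if (length(v) > 1) stats::sd(v) else 0
    sd[nm] <- if (is.finite(s) && s > 1e-8) s else 1
  }
  list(mean = mu, sd = sd)
}

#' Assemble the transformer input tokens for a cohort
#'
#' Maps every observed feature value to its token via the modality-specific
#' embedding, in catalog order. Unobserved positions are zero-filled (never
#' NaN) and flagged FALSE in `observed_mask`; they are contractually unread
#' downstream. `train_mask` (feature visibility after random dropout)
#' defaults to `observed_mask` and must be a subset of it.
#'
#' @param x A `cohort`.
#' @param params An `embedding_params` for the same catalog.
#' @param standardizer Output of [fit_standardizer()]; identity if NULL.
#' @param train_mask Optional logical n-by-F matrix, subset of the
#'   observation mask.
#' @return A `token_batch`: list with `tokens` (n x F x d_model array),
#'   `observed_mask`, `train_mask`, `feature_names`.
#' @export
assemble_tokens <- function(x, params, standardizer = NULL, train_mask = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(params, "embedding_params"))
  nms <- catalog_names(x$catalog)
  if (!identical(nms, names(params$blocks)))
    stop("embedding params do not match the cohort's catalog")
  n <- length(x$subject_id); f <- length(nms); d <- params$d_model
  obs <- observed_matrix(x)
  tokens <- array(0, c(n, f, d))
  for (j in seq_along(nms)) {
    nm <- nms[j]; sp <- x$catalog$features[[nm]]
    blk <- params$blocks[[nm]]
    idx <- which(obs[, j])
    if (!length(idx)) next
    if (sp$modality == "numeric") {
      v <- x$data[[nm]][idx]
      if (!is.null(standardizer) && nm %in% names(standardizer$mean))
        v <- (v - standardizer$mean[[nm]]) / standardizer$sd[[nm]]
      tokens[idx, j, ] <- outer(v, blk$weight) +
        matrix(blk$bias, length(idx), d, byrow = TRUE)
    } else if (sp$modality == "categorical") {
      rows <- match(x$data[[nm]][idx], rownames(blk$table))
      tokens[idx, j, ] <- blk$table[rows, , drop = FALSE]
    } else {
      tokens[idx, j, ] <- x$data[[nm]][idx, , drop = FALSE] %*% blk$proj +
        matrix(blk$proj_bias, length(idx), d, byrow = TRUE)
    }
  }
  if (is.null(train_mask)) train_mask <- obs
  if (!is.matrix(train_mask) || !identical(dim(train_mask), dim(obs)))
    stop("train_mask must be an n x F logical matrix")
  if (any(train_mask & !obs))
    stop("train_mask may not reveal unobserved features")
  structure(list(tokens = tokens, observed_mask = obs,
                 train_mask = train_mask, feature_names = nms),
            class = "token_batch")
}

#' @export
print.token_batch <- function(x, ...) {
  d <- dim(x$tokens)
  cat("<token_batch> ", d[1], " records x ", d[2], " features x d_model=",
      d[3], " (", sum(x$train_mask), " visible tokens)\n", sep = "")
  invisible(x)
}

#' Count embedding parameters
#' @param params An `embedding_params`.
#' @return Named numeric vector of per-feature parameter counts, with the
#'   total as attribute `total`.
#' @export
count_parameters <- function(params) {
  stopifnot(inherits(params, "embedding_params"))
  cnt <- vapply(params$blocks, function(b) {
    n <- 0
    for (p in b) {
      if (inherits(p, "downsampler_params"))
        n <- n + sum(vapply(p[c("w1","b1","w2","b2","w3","b3","w4","b4")],
                            length, numeric(1)))
      else n <- n + length(p)
    }
    n
  }, numeric(1))
  structure(cnt, total = sum(cnt))
}
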