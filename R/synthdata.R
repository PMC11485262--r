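#' Synthetic cohort configuration
#'
#' Declares the generative model for desk-scale synthetic cohorts with the
#' statistical structure the framework assumes: a hierarchical label model
#' (cognitive status NC/MCI/DE, then etiologies conditional on DE with
#' pairwise co-occurrence boosts and at least one etiology per dementia
#' case), label-dependent feature distributions (additive effects on
#' standardized numeric scales, logistic links for categoricals, mean
#' shifts on image-embedding blocks), and a missingness model with named
#' cohort sparsity profiles. The defaults are the package's reference
#' study conditions; see the methods vignette for their rationale.
#'
#' @param n_subjects Number of subjects.
#' @param status_prev Named probabilities for NC/MCI/DE (sum to 1).
#' @param etiology_prev Named per-etiology prevalence conditional on DE.
#' @param cooccurrence List of pairwise boosts `list(c("AD","VD"), prob)`
#'   applied as extra probability of the second label when the first is
#'   positive.
#' @param effects Label-by-feature numeric effect matrix on the
#'   standardized scale; defaults to the built-in planted-signal pattern.
#' @param noise_sd Residual standard deviation of numeric features.
#' @param embedding_width Width of the synthetic MRI embedding feature.
#' @param label_missing Per-label probability that a label is unknown.
#' @param seed Integer seed.
#' @return A `synthetic_config` object (includes the default catalog).
#' @export
synthetic_config <- function(n_subjects = 1000L,
                             status_prev = c(NC = 0.35, MCI = 0.25, DE = 0.40),
                             etiology_prev = c(AD = 0.60, LBD = 0.12, VD = 0.18,
                                               PRD = 0.02, FTD = 0.09,
                                               NPH = 0.05, SEF = 0.07,
                                               PSY = 0.12, TBI = 0.04,
                                               ODE = 0.10),
                             cooccurrence = list(list(pair = c("AD", "VD"),
                                                      boost = 0.15),
                                                 list(pair = c("LBD", "PSY"),
                                                      boost = 0.10)),
                             effects = NULL, noise_sd = 1,
                             embedding_width = 32L,
                             label_missing = c(rep(0, 3), rep(0.1, 10)),
                             seed = 1L) {
  if (abs(sum(status_prev) - 1) > 1e-8)
    stop("status prevalences must sum to 1")
  if (any(status_prev < 0 | status_prev > 1) ||
      any(etiology_prev < 0 | etiology_prev > 1))
    stop("prevalences must lie in [0, 1]")
  if (all(etiology_prev == 0))
    stop("inconsistent config: DE requires at least one possible etiology")
  if (length(label_missing) != 13 || any(label_missing < 0 | label_missing > 1))
    stop("label_missing must be a 13-vector of rates in [0, 1]")
  catalog <- default_synthetic_catalog(embedding_width)
  if (is.null(effects)) effects <- default_effects(catalog)
  structure(list(n_subjects = as.integer(n_subjects),
                 status_prev = status_prev, etiology_prev = etiology_prev,
                 cooccurrence = cooccurrence, effects = effects,
                 noise_sd = noise_sd,
                 embedding_width = as.integer(embedding_width),
                 label_missing = label_missing, catalog = catalog,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic feature catalog
#' @param embedding_width Width of the synthetic MRI embedding.
#' @return A `feature_catalog` with demographic, neuropsychological,
#'   functional, psychiatric, motor and imaging features.
#' @export
default_synthetic_catalog <- function(embedding_width = 32L) {
  feature_catalog(list(
    list(name = "age", modality = "numeric", group = "Demographics"),
    list(name = "education", modality = "numeric", group = "Demographics"),
    list(name = "sex", modality = "categorical",
         categories = c("female", "male"), group = "Demographics"),
    list(name = "apoe4", modality = "categorical",
         categories = c("0", "1", "2"), group = "Demographics"),
    list(name = "mmse", modality = "numeric", group = "NP tests"),
    list(name = "moca", modality = "numeric", group = "NP tests"),
    list(name = "trails_b", modality = "numeric", group = "NP tests"),
    list(name = "faq", modality = "numeric", group = "FAQ"),
    list(name = "gds", modality = "numeric", group = "GDS"),
    list(name = "npiq", modality = "numeric", group = "NPIQ"),
    list(name = "updrs", modality = "numeric", group = "UPDRS"),
    list(name = "mri_t1", modality = "image_embedding",
         embedding_width = embedding_width, group = "MRI")),
    groups = c("Demographics", "NP tests", "FAQ", "GDS", "NPIQ", "UPDRS",
               "MRI"))
}

# planted effect sizes on the standardized scale: cognitive scores fall
# with MCI/DE, functional and behavioural scales rise with DE and specific
# etiologies (UPDRS with LBD, GDS with PSY, NPIQ with FTD)
default_effects <- function(catalog) {
  nms <- catalog_names(catalog)
  e <- matrix(0, 13, length(nms),
              dimnames = list(diagnostic_labels(), nms))
  e["DE", c("mmse", "moca")] <- -1.8
  e["DE", "trails_b"] <- 1.2
  e["DE", "faq"] <- 2.0
  e["DE", "npiq"] <- 1.0
  e["DE", "age"] <- 0.5
  e["DE", "mri_t1"] <- 1.2
  e["AD", "mri_t1"] <- 1.0
  e["VD", "mri_t1"] <- 0.8
  e["AD", "apoe4"] <- 1.2
  e["MCI", c("mmse", "moca")] <- -0.8
  e["MCI", "trails_b"] <- 0.5
  e["MCI", "faq"] <- 0.6
  e["AD", "moca"] <- -0.5
  e["LBD", "updrs"] <- 3.0
  e["VD", "trails_b"] <- 0.8
  e["FTD", "npiq"] <- 2.5
  e["PSY", "gds"] <- 3.0
  e
}

#' Simulate a synthetic multimodal cohort
#'
#' Draws labels from the hierarchical status/etiology scheme, then
#' features: numeric features are the label effects plus Gaussian noise on
#' a standardized scale; binary-link categoricals (apoe4 loads on AD, sex
#' is balanced); the image embedding is a Gaussian vector whose leading
#' block is shifted by DE/AD/VD. Returns the generator's true effect
#' matrix so recovery tests can check the pipeline end to end. Evaluation
#' strata (age_bin, gender, race) are attached as metadata.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `cohort` (a [cohort()]) and `truth` (effects matrix,
#'   label draws, config).
#' @export
simulate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  labs <- diagnostic_labels()
  y <- matrix(0, n, 13, dimnames = list(NULL, labs))
  status <- sample(names(cfg$status_prev), n, replace = TRUE,
                   prob = cfg$status_prev)
  y[cbind(seq_len(n), match(status, labs))] <- 1
  de <- which(status == "DE")
  eti <- etiology_labels()
  for (i in de) {
    draw <- as.numeric(stats::runif(10) < cfg$etiology_prev[eti])
    names(draw) <- eti
    for (cb in cfg$cooccurrence) {
      a <- cb$pair[1]; b <- cb$pair[2]
      if (draw[a] == 1 && draw[b] == 0 && stats::runif(1) < cb$boost)
        draw[b] <- 1
    }
    if (sum(draw) == 0)
      draw[sample(eti, 1, prob = cfg$etiology_prev[eti])] <- 1
    y[i, eti] <- draw
  }
  e <- cfg$effects
  nms <- catalog_names(cfg$catalog)
  data <- list()
  lin <- y %*% e                       # n x F standardized signal
  for (nm in nms) {
    sp <- cfg$catalog$features[[nm]]
    if (sp$modality == "numeric") {
      data[[nm]] <- lin[, nm] + stats::rnorm(n, sd = cfg$noise_sd)
    } else if (sp$modality == "categorical") {
      # logistic link on the label signal; a binomial index over the codes
      base_p <- if (nm == "apoe4") 0.2 else 0.5
      kmax <- length(sp$categories) - 1L
      pr <- stats::plogis(stats::qlogis(base_p) + lin[, nm])
      data[[nm]] <- sp$categories[1L + stats::rbinom(n, kmax, pr)]
    } else {
      # Gaussian embedding with the label signal on its leading block
      w <- sp$embedding_width
      m <- matrix(stats::rnorm(n * w), n, w)
      blk <- max(1L, w %/% 4L)
      m[, 1:blk] <- m[, 1:blk] + lin[, nm]
      data[[nm]] <- m
    }
  }
  # map to realistic clinical scales (affine, clipped at instrument bounds)
  data$age <- 72 + 8 * data$age
  data$education <- 14 + 3 * data$education
  data$mmse <- pmin(30, pmax(0, 27 + 3 * data$mmse))
  data$moca <- pmin(30, pmax(0, 25 + 4 * data$moca))
  data$trails_b <- pmax(20, 90 + 50 * data$trails_b)
  data$faq <- pmin(30, pmax(0, 4 + 6 * data$faq))
  data$gds <- pmin(15, pmax(0, 3 + 3 * data$gds))
  data$npiq <- pmin(36, pmax(0, 3 + 5 * data$npiq))
  data$updrs <- pmax(0, 10 + 15 * data$updrs)
  strata <- data.frame(
    age_bin = cut(data$age, c(-Inf, 65, 75, 85, Inf),
                  labels = c("<65", "65-75", "75-85", "85+")),
    gender = data$sex,
    race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.08, 0.07)),
    stringsAsFactors = FALSE)
  strata$age_bin <- as.character(strata$age_bin)
  labels <- y
  # seed-scoped ids so cohorts simulated under different seeds stay disjoint
  co <- cohort(sprintf("S%d_%05d", cfg$seed, seq_len(n)), data, labels,
               cfg$catalog,
               strata = strata)
  list(cohort = co,
       truth = list(effects = e, status = status, labels = y, config = cfg))
}

#' Inject feature and label missingness
#'
#' Masks features completely at random (MCAR) at per-group rates and
#' replaces labels with unknown at per-label rates. Named sparsity
#' profiles mimic the contrast between a reference cohort and sparser
#' external cohorts: `"NACC"` (light, 10%), `"ADNI"` (about 69% of feature
#' values absent) and `"FHS"` (about 94% absent). A subject's last
#' observed feature is never removed. Realized rates are attached as
#' attribute `realized_rates`.
#'
#' @param x A `cohort`.
#' @param rates Single MCAR rate, named per-group rate vector, or a
#'   profile name ("NACC", "ADNI", "FHS").
#' @param label_rates Optional 13-vector of per-label unknown rates.
#' @param protect Optional character vector of feature names never masked.
#' @param mar Optional MAR hook (off by default): a list
#'   `list(label =, odds_ratio =)` multiplying each subject's masking odds
#'   by `odds_ratio` when the named label is 1, making missingness depend
#'   on the diagnosis rather than completely at random.
#' @return The cohort with NA injected.
#' @export
apply_missingness <- function(x, rates = 0.1, label_rates = NULL,
                              protect = character(0), mar = NULL) {
  stopifnot(inherits(x, "cohort"))
  profiles <- c(NACC = 0.10, ADNI = 0.69, FHS = 0.94)
  if (is.character(rates)) {
    if (!rates %in% names(profiles)) stop("unknown profile: ", rates)
    rates <- profiles[[rates]]
  }
  groups <- x$catalog$groups
  if (is.null(names(rates))) {
    if (length(rates) != 1) stop("rates must be named per group or scalar")
    rates <- stats::setNames(rep(rates, length(groups)), groups)
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  bad <- setdiff(names(rates), groups)
  if (length(bad)) stop("unknown group tag(s): ", paste(bad, collapse = ", "))
  n <- length(x$subject_id)
  obs0 <- observed_matrix(x)
  tilt <- rep(1, n)
  if (!is.null(mar)) {
    li <- match(mar$label, colnames(x$labels))
    if (is.na(li)) stop("mar$label must name a diagnostic label")
    pos <- !is.na(x$labels[, li]) & x$labels[, li] == 1
    tilt[pos] <- mar$odds_ratio
  }
  drop_mask <- matrix(FALSE, n, ncol(obs0), dimnames = dimnames(obs0))
  for (g in names(rates)) {
    feats <- setdiff(catalog_group_features(x$catalog, g), protect)
    r <- rates[[g]]
    p <- stats::plogis(stats::qlogis(pmin(pmax(r, 1e-12), 1 - 1e-12)) +
                         log(tilt))
    p <- if (r %in% c(0, 1)) rep(r, n) else p
    for (nm in feats)
      drop_mask[, nm] <- obs0[, nm] & stats::runif(n) < p
  }
  # never remove a subject's last observed feature
  left <- rowSums(obs0 & !drop_mask)
  for (r in which(left == 0)) {
    keep <- sample(which(drop_mask[r, ]), 1)
    drop_mask[r, keep] <- FALSE
  }
  for (nm in colnames(drop_mask)) {
    idx <- which(drop_mask[, nm])
    if (!length(idx)) next
    if (is.matrix(x$data[[nm]])) x$data[[nm]][idx, ] <- NA_real_
    else x$data[[nm]][idx] <- NA
  }
  if (!is.null(label_rates)) {
    if (length(label_rates) != 13 || any(label_rates < 0 | label_rates > 1))
      stop("label_rates must be a 13-vector of rates in [0, 1]")
    for (j in seq_len(13)) {
      hit <- stats::runif(n) < label_rates[j]
      x$labels[hit, j] <- NA
    }
  }
  obs1 <- observed_matrix(x)
  attr(x, "realized_rates") <- 1 - sum(obs1) / sum(obs0)
  x
}
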