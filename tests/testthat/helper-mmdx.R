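# shared fixtures, built in code; the trained mini-checkpoint is memoized so
# several test files can reuse it without retraining

tiny_catalog <- function() {
  feature_catalog(list(
    list(name = "age", modality = "numeric", group = "Demographics"),
    list(name = "sex", modality = "categorical",
         categories = c("female", "male"), group = "Demographics"),
    list(name = "moca", modality = "numeric", group = "NP tests"),
    list(name = "mri", modality = "image_embedding", embedding_width = 4,
         group = "MRI")),
    groups = c("Demographics", "NP tests", "MRI"))
}

tiny_cohort <- function(n = 5, seed = 42) {
  set.seed(seed)
  cat <- tiny_catalog()
  emb <- matrix(rnorm(n * 4), n, 4)
  lab <- matrix(rbinom(n * 13, 1, 0.3), n, 13,
                dimnames = list(NULL, diagnostic_labels()))
  cohort(sprintf("T%03d", seq_len(n)),
         list(age = rnorm(n, 70, 5),
              sex = sample(c("female", "male"), n, TRUE),
              moca = rnorm(n, 24, 3),
              mri = emb),
         lab, cat)
}

# random (untrained) model pieces over a cohort's catalog
random_model <- function(catalog, d_model = 8, n_layers = 2, n_heads = 2,
                         seed = 1) {
  cfg <- model_config(d_model = d_model, n_layers = n_layers,
                      n_heads = n_heads, ff_width = 2 * d_model,
                      dropout = 0, seed = seed)
  list(cfg = cfg,
       embed = embedding_params(catalog, d_model = d_model, seed = seed + 1),
       weights = init_backbone_weights(cfg, seed = seed + 2))
}

.fixture_env <- new.env(parent = emptyenv())

# a small trained checkpoint plus its held-out cohort, trained once per run
fixture_checkpoint <- function() {
  if (is.null(.fixture_env$ck)) {
    sim <- simulate_cohort(synthetic_config(n_subjects = 700, seed = 202))
    x <- apply_missingness(sim$cohort, 0.15,
                           label_rates = c(rep(0, 3), rep(0.1, 10)))
    mc <- model_config(d_model = 32, n_layers = 2, n_heads = 2,
                       ff_width = 64, dropout = 0.1, seed = 5)
    tc <- train_config(epochs = 20, seed = 7)
    .fixture_env$ck <- train_model(x[1:450], x[451:550], mc, loss_config(), tc)
    .fixture_env$test_cohort <- x[551:700]
    .fixture_env$truth <- sim$truth
  }
  list(ck = .fixture_env$ck, test = .fixture_env$test_cohort,
       truth = .fixture_env$truth)
}
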