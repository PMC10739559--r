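# shared fixtures, built in code and memoized so expensive fits happen once

toy_cigt_df <- function() {
  data.frame(
    ID = c("P1", "P2", "P3", "P4"),
    Type = c(0, 0, 1, 1),
    g1 = c(1.0, 2.0, 3.0, 4.0),
    g2 = c(0.5, 0.4, 0.9, 1.1)
  )
}

# fake attribution object from a plain phi matrix (for scoring unit tests)
fake_attribution <- function(phi, classifier = "toy", baseline = 0.5,
                             fx = NULL) {
  structure(
    list(classifier = classifier, phi = phi, baseline = baseline,
         fx = fx %||% (baseline + rowSums(phi)),
         target = "case_probability",
         sample_ids = rownames(phi), feature_names = colnames(phi),
         method = "exact"),
    class = "igene_attribution"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# small well-separated cohort + fitted full ensemble, reused across files
small_fit <- function() {
  cached("small_fit", {
    sim <- simulate_cigt(n_cases = 40, n_controls = 40, n_genes = 12,
                         n_informative = 3, effect_size = 2, seed = 11)
    parts <- split_cigt(sim$data, test_fraction = 0.3, seed = 11)
    model <- train_ensemble(parts$train, cigt_features(sim$data)[1:6],
                            seed = 11,
                            control = ensemble_control(mlp_size = 10))
    list(sim = sim, parts = parts, model = model)
  })
}
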