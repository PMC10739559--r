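BASE_MEMBERS <- c("rf", "svm", "xgb", "knn", "mlp")

#' Ensemble hyperparameter defaults
#'
#' Fixed, sensible defaults for the five base classifiers; none are tuned.
#' Every value can be overridden here and passed to [train_ensemble()].
#'
#' @param rf_trees random-forest trees. Default 100.
#' @param svm_cost,svm_gamma RBF-kernel SVM cost and kernel width;
#'   `svm_gamma = NULL` uses 1/n_features.
#' @param knn_k neighbours for k-NN. Default 5.
#' @param mlp_size,mlp_maxit,mlp_decay single hidden layer width (default
#'   100), iteration cap (default 500), and weight decay for the
#'   multi-layer perceptron.
#' @param xgb_nrounds,xgb_depth,xgb_eta boosting rounds, tree depth and
#'   learning rate for XGBoost.
#' @return a named list of hyperparameters.
#' @export
ensemble_control <- function(rf_trees = 100, svm_cost = 1, svm_gamma = NULL,
                             knn_k = 5, mlp_size = 100, mlp_maxit = 500,
                             mlp_decay = 1e-4, xgb_nrounds = 100,
                             xgb_depth = 6, xgb_eta = 0.3) {
  list(rf_trees = rf_trees, svm_cost = svm_cost, svm_gamma = svm_gamma,
       knn_k = knn_k, mlp_size = mlp_size, mlp_maxit = mlp_maxit,
       mlp_decay = mlp_decay, xgb_nrounds = xgb_nrounds,
       xgb_depth = xgb_depth, xgb_eta = xgb_eta)
}

#' Train the classifier ensemble
#'
#' Fits up to five base classifiers — random forest (`rf`), RBF-kernel SVM
#' (`svm`), gradient-boosted trees (`xgb`), k-nearest neighbours (`knn`),
#' and a single-hidden-layer perceptron (`mlp`) — on the selected features,
#' plus soft- and hard-voting aggregators defined over the enabled members.
#' One z-score standardization, fitted on the training rows only, is shared
#' by all members (the scale-sensitive members need it; tree models are
#' scale-invariant, so sharing one matrix is harmless). SVM case
#' probabilities come from Platt scaling: a logistic fit of the training
#' labels on the SVM decision values, which is deterministic for a fixed
#' seed. Refitting with identical inputs and seed reproduces the model and
#' all of its predictions exactly.
#'
#' @param train a [cigt][as_cigt] tibble with at least 2 samples per class.
#' @param features a `feature_set` tibble from [select_features()] /
#'   [combine_selections()], or a character vector of feature names; every
#'   feature must exist in `train`.
#' @param members which base classifiers to enable. Default all five.
#' @param seed integer seed controlling every stochastic fit.
#' @param control hyperparameters from [ensemble_control()].
#' @return an object of class `igene_ensemble`.
#' @examples
#' sim <- simulate_cigt(n_cases = 30, n_controls = 30, n_genes = 10,
#'                      n_informative = 2, seed = 1)
#' fit <- train_ensemble(sim$data, c("gene_001", "gene_002"),
#'                       members = "rf", seed = 1)
#' predict(fit, sim$data)
#' @export
train_ensemble <- function(train, features, members = BASE_MEMBERS,
                           seed = 1, control = ensemble_control()) {
  stopifnot(inherits(train, "cigt"))
  members <- match.arg(members, BASE_MEMBERS, several.ok = TRUE)
  if (inherits(features, "feature_set")) features <- features$feature
  features <- as.character(features)
  missing_feats <- setdiff(features, cigt_features(train))
  if (length(missing_feats) > 0) {
    igene_abort(sprintf("feature(s) not present in training data: %s",
                        paste(missing_feats, collapse = ", ")))
  }
  y <- cigt_labels(train)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    igene_abort("training data must contain at least 2 samples per class")
  }
  x <- cigt_matrix(train)[, features, drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = center, scale = scale)

  fits <- purrr::map(stats::setNames(members, members), function(m) {
    with_seed(substream_seed(seed, paste0("fit_", m)), {
      fit_member(m, xs, y, control)
    })
  })

  structure(
    list(members = fits, scaler = list(center = center, scale = scale),
         feature_names = features, enabled = members, seed = seed,
         control = control, n_train = nrow(x)),
    class = "igene_ensemble"
  )
}

fit_member <- function(name, xs, y, control) {
  switch(name,
    rf = randomForest::randomForest(xs, factor(y, levels = c(0, 1)),
                                    ntree = control$rf_trees),
    svm = {
      gamma <- control$svm_gamma %||% (1 / ncol(xs))
      fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "radial",
                        cost = control$svm_cost, gamma = gamma, scale = FALSE)
      dv <- as.numeric(attr(stats::predict(fit, xs, decision.values = TRUE),
                            "decision.values"))
      platt <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial(),
                   data = data.frame(y = y, dv = dv))
      )
      list(fit = fit, platt = stats::coef(platt))
    },
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = control$xgb_depth, eta = control$xgb_eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(xs, label = y, nthread = 1),
      nrounds = control$xgb_nrounds, verbose = 0
    ),
    knn = list(x = xs, y = factor(y, levels = c(0, 1)), k = control$knn_k),
    mlp = nnet::nnet(xs, y, size = control$mlp_size, entropy = TRUE,
                     decay = control$mlp_decay, maxit = control$mlp_maxit,
                     MaxNWts = 1e5, trace = FALSE)
  )
}

# case (class 1) probability for one member on an already-standardized matrix
member_prob <- function(model, name, xs) {
  fit <- model$members[[name]]
  p <- switch(name,
    rf = stats::predict(fit, xs, type = "prob")[, "1"],
    svm = {
      dv <- as.numeric(attr(stats::predict(fit$fit, xs, decision.values = TRUE),
                            "decision.values"))
      stats::plogis(fit$platt[1] + fit$platt[2] * dv)
    },
    xgb = stats::predict(fit, xgboost::xgb.DMatrix(xs, nthread = 1)),
    knn = with_seed(substream_seed(model$seed, "knn_predict"), {
      pred <- class::knn(fit$x, xs, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    }),
    mlp = as.numeric(stats::predict(fit, xs))
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# standardized matrix restricted to model features, from a cigt or matrix
ensemble_xs <- function(model, data) {
  x <- if (inherits(data, "cigt")) cigt_matrix(data) else as.matrix(data)
  missing_feats <- setdiff(model$feature_names, colnames(x))
  if (length(missing_feats) > 0) {
    igene_abort(sprintf("feature(s) missing from data: %s",
                        paste(missing_feats, collapse = ", ")))
  }
  x <- x[, model$feature_names, drop = FALSE]
  scale(x, center = model$scaler$center, scale = model$scaler$scale)
}

# n x members matrix of case probabilities
member_prob_matrix <- function(model, data) {
  xs <- ensemble_xs(model, data)
  probs <- vapply(model$enabled, function(m) member_prob(model, m, xs),
                  numeric(nrow(xs)))
  if (is.null(dim(probs))) {
    probs <- matrix(probs, nrow = 1, dimnames = list(NULL, model$enabled))
  }
  probs
}

#' Soft-vote aggregation
#'
#' The soft voter averages the enabled members' case probabilities without
#' weights; the label is case (1) when the mean probability is at least
#' 0.5, so an exact 0.5 tie is called a case.
#'
#' @param probabilities numeric vector of member case probabilities for one
#'   sample, each in `[0, 1]`.
#' @return a list with `probability` (the mean) and `label` (0/1).
#' @examples
#' soft_vote(c(0.6, 0.8, 0.7, 0.9, 0.55)) # probability 0.71, label 1
#' @export
soft_vote <- function(probabilities) {
  if (length(probabilities) == 0) igene_abort("no member probabilities given")
  if (any(probabilities < 0 | probabilities > 1)) {
    igene_abort("probabilities must lie in [0, 1]")
  }
  p <- mean(probabilities)
  list(probability = p, label = as.integer(p >= 0.5))
}

#' Hard-vote aggregation
#'
#' The hard voter takes the majority of the enabled members' 0/1 labels.
#' An exact tie — possible when an even number of members is enabled —
#' resolves to 0 (control) and signals an `igenes_tie` condition, so voters
#' never silently flip a tied patient to a case.
#'
#' @param labels integer vector of member labels (0/1) for one sample.
#' @return the majority label (0/1).
#' @examples
#' hard_vote(c(1, 1, 1, 0, 0)) # 1
#' @export
hard_vote <- function(labels) {
  if (length(labels) == 0) igene_abort("no member labels given")
  if (!all(labels %in% c(0, 1))) igene_abort("labels must be 0/1")
  ones <- sum(labels == 1)
  zeros <- sum(labels == 0)
  if (ones == zeros) {
    rlang::inform("hard vote tie resolved to control (0)",
                  class = "igenes_tie")
    return(0L)
  }
  as.integer(ones > zeros)
}

#' Per-patient predictions from the ensemble
#'
#' @param object an `igene_ensemble` from [train_ensemble()].
#' @param newdata a [cigt][as_cigt] tibble (labels are not used).
#' @param ... unused.
#' @return a tibble with one row per patient: `sample_id`, a
#'   `<member>_prob` and `<member>_label` column pair per enabled member,
#'   and `soft_vote_prob`, `soft_vote_label`, `hard_vote_label`. Member
#'   labels are 1 when the member's case probability is at least 0.5.
#' @export
predict.igene_ensemble <- function(object, newdata, ...) {
  probs <- member_prob_matrix(object, newdata)
  labels <- matrix(as.integer(probs >= 0.5), nrow = nrow(probs),
                   dimnames = dimnames(probs))
  soft <- rowMeans(probs)
  ones <- rowSums(labels == 1)
  zeros <- rowSums(labels == 0)
  n_tie <- sum(ones == zeros)
  if (n_tie > 0) {
    rlang::inform(sprintf(
      "hard vote tie resolved to control (0) for %d sample(s)", n_tie),
      class = "igenes_tie")
  }
  hard <- as.integer(ones > zeros)

  out <- tibble::tibble(sample_id = if (inherits(newdata, "cigt")) {
    cigt_ids(newdata)
  } else {
    sprintf("row_%d", seq_len(nrow(probs)))
  })
  for (m in object$enabled) {
    out[[paste0(m, "_prob")]] <- probs[, m]
    out[[paste0(m, "_label")]] <- labels[, m]
  }
  out$soft_vote_prob <- soft
  out$soft_vote_label <- as.integer(soft >= 0.5)
  out$hard_vote_label <- hard
  out
}

#' Evaluate the ensemble on a labeled set
#'
#' Computes per-classifier accuracy, F1 (positive class = case) and ROC
#' AUC, including the two voters. AUC uses each member's case probability;
#' the hard voter has no probability, so its AUC is computed from its 0/1
#' labels. On a single-class evaluation set the AUC is undefined and
#' reported as `NA` with a warning.
#'
#' @param model an `igene_ensemble`.
#' @param test a labeled [cigt][as_cigt] tibble.
#' @return a list with `predictions` (see [predict.igene_ensemble()]) and
#'   `metrics`, a tibble with columns `classifier`, `accuracy`, `f1`,
#'   `auc`, `n_eval`.
#' @export
evaluate_ensemble <- function(model, test) {
  preds <- stats::predict(model, test)
  y <- cigt_labels(test)
  single_class <- length(unique(y)) < 2
  if (single_class) {
    rlang::warn("evaluation set has a single class; AUC is undefined (NA)")
  }
  classifiers <- c(model$enabled, "soft_vote", "hard_vote")
  metrics <- purrr::map_dfr(classifiers, function(cl) {
    lab <- preds[[paste0(cl, "_label")]]
    score <- if (cl == "hard_vote") lab else preds[[paste0(cl, "_prob")]]
    tibble::tibble(
      classifier = cl,
      accuracy = mean(lab == y),
      f1 = f1_score(y, lab),
      auc = if (single_class) NA_real_ else auc_score(y, score),
      n_eval = length(y)
    )
  })
  list(predictions = preds, metrics = metrics)
}

# F1 for positive class 1; NA when no true or predicted positives exist
f1_score <- function(truth, predicted) {
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

auc_score <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' @export
print.igene_ensemble <- function(x, ...) {
  cat("<igene_ensemble>\n")
  cat("  members: ", paste(x$enabled, collapse = ", "),
      " (+ soft/hard voters)\n", sep = "")
  cat("  features:", length(x$feature_names), "\n")
  cat("  trained on", x$n_train, "samples, seed", x$seed, "\n")
  invisible(x)
}
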