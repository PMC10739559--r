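#' Per-feature importance shares of one classifier
#'
#' A classifier's raw global importance for a feature is the mean absolute
#' attribution of that feature over the explained samples; shares are the
#' raw importances normalized to sum to one. A classifier with all-zero
#' attributions carries no importance information and is flagged degenerate
#' (attribute `degenerate = TRUE`, shares all `NA`) rather than raising.
#'
#' @param att an `igene_attribution` from [compute_attributions()].
#' @return a tibble with columns `feature`, `raw` (mean `|phi|`) and
#'   `share`; attributes `classifier` and `degenerate`.
#' @examples
#' att <- structure(list(classifier = "toy",
#'                       phi = cbind(a = c(2, -2), b = c(1, 1),
#'                                   c = c(-1, 1))),
#'                  class = "igene_attribution")
#' importance_shares(att)$share # 0.5 0.25 0.25
#' @export
importance_shares <- function(att) {
  stopifnot(inherits(att, "igene_attribution"))
  raw <- colMeans(abs(att$phi))
  total <- sum(raw)
  degenerate <- total == 0
  share <- if (degenerate) rep(NA_real_, length(raw)) else raw / total
  structure(
    tibble::tibble(feature = colnames(att$phi), raw = unname(raw),
                   share = unname(share)),
    classifier = att$classifier, degenerate = degenerate,
    class = c("igene_shares", class(tibble::tibble()))
  )
}

#' Herfindahl-Hirschman concentration index
#'
#' `sum(shares^2)` on the unit-interval scale: 1/n for perfectly uniform
#' shares over n features, 1 when a single feature holds all importance.
#' HHI measures concentration — how narrowly a classifier relies on few
#' features — which is the quantity used to weight classifiers when
#' aggregating importance into I-Gene scores.
#'
#' @param shares non-negative numeric vector summing to 1 (within 1e-9).
#' @return the concentration index, in `[1/n, 1]`.
#' @examples
#' hhi(c(0.5, 0.3, 0.2)) # 0.38
#' @export
hhi <- function(shares) {
  if (any(shares < 0)) igene_abort("shares must be non-negative")
  if (abs(sum(shares) - 1) > 1e-9) {
    igene_abort("shares must sum to 1 (within 1e-9)")
  }
  sum(shares^2)
}

#' HHI-proportional classifier weights
#'
#' Classifiers whose predictions rest on fewer features (higher HHI)
#' receive proportionally greater weight: `weight_c = HHI_c / sum(HHI)`.
#' The mapping is monotone — a higher concentration never yields a lower
#' weight — and the weights sum to one.
#'
#' @param hhis named numeric vector of per-classifier HHI values
#'   (degenerate classifiers must already be removed).
#' @return a named numeric vector of weights summing to 1.
#' @examples
#' classifier_weights(c(a = 0.38, b = 0.62))
#' @export
classifier_weights <- function(hhis) {
  hhis <- hhis[!is.na(hhis)]
  if (length(hhis) == 0) {
    igene_abort("all classifiers are degenerate; no scoring possible")
  }
  if (any(hhis <= 0)) igene_abort("HHI values must be positive")
  hhis / sum(hhis)
}

#' Aggregate importance shares into I-Gene scores
#'
#' The raw I-Gene score of a feature is the HHI-weighted sum of its
#' importance shares across classifiers:
#' `raw_f = sum_c weight_c * share_{c,f}`. Because both the weights and
#' each classifier's shares sum to one, the raw scores always sum to one
#' across features. The displayed score rescales to 0-100 with the top
#' feature at 100.
#'
#' @param shares_by_classifier named list of per-classifier share tibbles
#'   (from [importance_shares()]) or numeric share vectors, all over the
#'   same ordered feature list.
#' @param weights named per-classifier weights from [classifier_weights()];
#'   names must match `shares_by_classifier`.
#' @return a tibble with columns `feature`, `raw` and `igene_score`
#'   (0-100), ordered as the input feature list.
#' @export
igene_scores <- function(shares_by_classifier, weights) {
  if (!setequal(names(shares_by_classifier), names(weights))) {
    igene_abort("shares and weights must cover the same classifiers")
  }
  share_vecs <- purrr::imap(shares_by_classifier, function(s, nm) {
    if (inherits(s, "data.frame")) stats::setNames(s$share, s$feature) else s
  })
  feats <- names(share_vecs[[1]])
  if (is.null(feats)) {
    igene_abort("shares must be named by feature")
  }
  for (s in share_vecs) {
    if (!identical(names(s), feats)) {
      igene_abort("all classifiers must share one ordered feature list")
    }
  }
  raw <- Reduce(`+`, purrr::imap(share_vecs, function(s, nm) {
    weights[[nm]] * s
  }))
  score <- if (max(raw) > 0) 100 * raw / max(raw) else raw
  tibble::tibble(feature = feats, raw = unname(raw),
                 igene_score = unname(score))
}

#' Expression directionality of features
#'
#' Labels each feature by how its expression level pushes the ensemble
#' toward a case prediction. For every classifier, the Pearson correlation
#' between the feature's values and its per-sample attributions is
#' computed; the correlations are averaged across classifiers with the HHI
#' weights. A weighted correlation above `tau` means high values push
#' toward case — the feature is called `overexpressed`; below `-tau`,
#' `underexpressed`; otherwise `neutral` (noise-level association is not
#' labeled). Zero-variance features, and features with all-zero
#' attributions everywhere, are `neutral`.
#'
#' @param attributions named list of `igene_attribution` objects.
#' @param x evaluation matrix (samples x features) on which the
#'   attributions were computed.
#' @param weights named per-classifier weights from [classifier_weights()].
#' @param tau correlation threshold separating a direction call from
#'   `neutral`. Default 0.1.
#' @return a tibble with columns `feature`, `correlation` (weighted
#'   value-attribution correlation) and `direction`.
#' @export
igene_direction <- function(attributions, x, weights, tau = 0.1) {
  x <- as.matrix(x)
  feats <- attributions[[1]]$feature_names %||% colnames(attributions[[1]]$phi)
  zero_var <- apply(x[, feats, drop = FALSE], 2, stats::sd) == 0
  if (any(zero_var)) {
    rlang::warn(sprintf("zero-variance feature(s) labeled neutral: %s",
                        paste(feats[zero_var], collapse = ", ")))
  }
  cors <- purrr::map(attributions, function(att) {
    vapply(seq_along(feats), function(j) {
      v <- x[, feats[j]]
      p <- att$phi[, j]
      if (stats::sd(v) == 0 || stats::sd(p) == 0) 0 else stats::cor(v, p)
    }, numeric(1))
  })
  wcor <- Reduce(`+`, purrr::imap(cors, function(cv, nm) weights[[nm]] * cv))
  wcor[zero_var] <- NA_real_
  direction <- dplyr::case_when(
    is.na(wcor) ~ "neutral",
    wcor > tau ~ "overexpressed",
    wcor < -tau ~ "underexpressed",
    TRUE ~ "neutral"
  )
  tibble::tibble(feature = feats, correlation = wcor, direction = direction)
}

#' I-Gene biomarker profile of a fitted ensemble
#'
#' The end-to-end scoring chain: Shapley attributions per base classifier
#' (see [explain_ensemble()]) are turned into per-classifier importance
#' shares, each classifier's concentration (HHI) becomes its weight, and
#' the weighted shares are summed into per-feature I-Gene scores with
#' directionality labels. Degenerate classifiers (all-zero attributions)
#' are excluded from the aggregation with a warning.
#'
#' @param model an `igene_ensemble` from [train_ensemble()].
#' @param data samples to explain — typically the held-out evaluation set.
#' @param background reference cohort for the explainers — typically the
#'   training set; subsampled to `background_size` rows (seeded).
#' @param tau direction threshold, see [igene_direction()]. Default 0.1.
#' @inheritParams explain_ensemble
#' @return a tibble of class `igene_profile`, one row per feature:
#'   `feature`, `igene_score` (0-100, top feature = 100), `raw_score`,
#'   `rank`, `direction`, `correlation`, and one `share_<classifier>`
#'   column per included classifier. The per-classifier HHI values and
#'   weights are attached as attribute `classifier_weights` (a tibble),
#'   the attribution objects as attribute `attributions`.
#' @examples
#' sim <- simulate_cigt(n_cases = 25, n_controls = 25, n_genes = 6,
#'                      n_informative = 2, seed = 1)
#' fit <- train_ensemble(sim$data, cigt_features(sim$data),
#'                       members = c("rf", "xgb"), seed = 1)
#' igene_profile(fit, sim$data, sim$data, background_size = 20)
#' @export
igene_profile <- function(model, data, background, background_size = 100,
                          method = "auto", n_perm = 8, tau = 0.1, seed = 1) {
  atts <- explain_ensemble(model, data, background,
                           background_size = background_size,
                           method = method, n_perm = n_perm, seed = seed)
  shares <- purrr::map(atts, importance_shares)
  degenerate <- purrr::map_lgl(shares, ~ isTRUE(attr(.x, "degenerate")))
  if (any(degenerate)) {
    rlang::warn(sprintf("degenerate classifier(s) excluded from scoring: %s",
                        paste(names(shares)[degenerate], collapse = ", ")))
  }
  shares <- shares[!degenerate]
  atts_used <- atts[!degenerate]
  if (length(shares) == 0) {
    igene_abort("all classifiers are degenerate; no scoring possible")
  }
  hhis <- purrr::map_dbl(shares, ~ hhi(.x$share))
  weights <- classifier_weights(hhis)
  scores <- igene_scores(shares, weights)
  x <- raw_feature_matrix(model, data)
  dir <- igene_direction(atts_used, x, weights, tau = tau)

  profile <- dplyr::left_join(scores, dir, by = "feature")
  profile$rank <- rank(-profile$raw, ties.method = "first")
  for (nm in names(shares)) {
    profile[[paste0("share_", nm)]] <- shares[[nm]]$share
  }
  profile <- dplyr::rename(profile, raw_score = "raw")
  profile <- profile[order(profile$rank), ]
  structure(
    profile,
    classifier_weights = tibble::tibble(
      classifier = names(weights), hhi = unname(hhis[names(weights)]),
      weight = unname(weights)),
    degenerate = names(degenerate)[degenerate],
    tau = tau,
    attributions = atts,
    class = c("igene_profile", class(tibble::tibble()))
  )
}
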