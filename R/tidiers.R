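#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an ensemble fit
#'
#' @param x an `igene_ensemble`.
#' @param ... unused.
#' @return one row per classifier (base members and voters) with its role.
#' @exportS3Method generics::tidy
tidy.igene_ensemble <- function(x, ...) {
  tibble::tibble(
    classifier = c(x$enabled, "soft_vote", "hard_vote"),
    role = c(rep("base", length(x$enabled)), "voter", "voter")
  )
}

#' @rdname tidy.igene_ensemble
#' @exportS3Method generics::glance
glance.igene_ensemble <- function(x, ...) {
  tibble::tibble(n_members = length(x$enabled),
                 n_features = length(x$feature_names),
                 n_train = x$n_train, seed = x$seed)
}

#' Tidy an I-Gene profile
#'
#' @param x an `igene_profile`.
#' @param ... unused.
#' @return `tidy()` returns the per-feature score table as a plain tibble;
#'   `glance()` a one-row summary with the per-classifier weights available
#'   through `attr(x, "classifier_weights")`.
#' @exportS3Method generics::tidy
tidy.igene_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.igene_profile
#' @exportS3Method generics::glance
glance.igene_profile <- function(x, ...) {
  w <- attr(x, "classifier_weights")
  tibble::tibble(
    n_features = nrow(x),
    n_classifiers = nrow(w),
    top_feature = x$feature[which.min(x$rank)],
    top_weight_classifier = w$classifier[which.max(w$weight)],
    raw_score_total = sum(x$raw_score)
  )
}

#' Tidy a selector result
#'
#' @param x a `selector_result` tibble.
#' @param ... unused.
#' @return the result with a `selector` column prepended.
#' @exportS3Method generics::tidy
tidy.selector_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(selector = attr(x, "selector")),
                   tibble::as_tibble(x))
}
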