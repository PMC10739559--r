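#' Feature selectors for case/control cohorts
#'
#' Four selectors extract disease-associated features from a CIGT cohort:
#' three classical univariate statistics — point-biserial (Pearson)
#' correlation against the 0/1 label, a chi-square contingency test on
#' median-dichotomized features, and a one-way ANOVA F test — plus recursive feature
#' elimination (RFE) backed by random-forest importance. Each returns a
#' tibble with one row per feature; [combine_selections()] merges their
#' selected sets.
#'
#' Features with zero variance (or all-equal values, for the chi-square
#' score) cannot be tested; they are excluded with a warning and reported
#' with `NA` statistics and `selected = FALSE`.
#'
#' @param data a [cigt][as_cigt] tibble.
#' @param alpha significance level for selection. Default 0.05.
#' @param adjust multiple-testing correction applied before thresholding:
#'   `"none"` (default, raw p values) or `"BH"` (Benjamini-Hochberg; adds a
#'   `p_adjusted` column and selects on it).
#' @return a tibble of class `selector_result` with columns `feature`,
#'   `statistic`, `p_value` (`p_adjusted` when `adjust = "BH"`), `rank`
#'   (1 = strongest), and `selected`; the selector name is stored in
#'   attribute `selector`.
#' @examples
#' sim <- simulate_cigt(n_cases = 30, n_controls = 30, n_genes = 20,
#'                      n_informative = 3, seed = 1)
#' dplyr::filter(pearson_select(sim$data), selected)
#' @name selectors
NULL

selector_result <- function(selector, feature, statistic, p_value, rank,
                            selected, extra = NULL) {
  out <- tibble::tibble(feature = unname(feature),
                        statistic = unname(statistic),
                        p_value = unname(p_value))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out$rank <- unname(rank)
  out$selected <- unname(selected)
  structure(out, selector = selector,
            class = c("selector_result", class(tibble::tibble())))
}

check_selector_input <- function(data) {
  stopifnot(inherits(data, "cigt"))
  y <- cigt_labels(data)
  if (length(unique(y)) < 2) {
    igene_abort("both classes must be present for feature selection")
  }
  list(x = cigt_matrix(data), y = y)
}

warn_excluded <- function(features, reason) {
  if (length(features) > 0) {
    rlang::warn(sprintf("excluding %d feature(s) (%s): %s",
                        length(features), reason,
                        paste(features, collapse = ", ")))
  }
}

p_rank_selected <- function(p, alpha, adjust) {
  p_sel <- p
  extra <- NULL
  if (adjust == "BH") {
    p_sel <- stats::p.adjust(p, method = "BH")
    extra <- tibble::tibble(p_adjusted = p_sel)
  }
  list(rank = rank(p_sel, ties.method = "min", na.last = "keep"),
       selected = !is.na(p_sel) & p_sel < alpha,
       extra = extra)
}

#' @rdname selectors
#' @export
pearson_select <- function(data, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  inp <- check_selector_input(data)
  n <- nrow(inp$x)
  if (n < 3) igene_abort("at least 3 samples are required")
  sds <- apply(inp$x, 2, stats::sd)
  zero_var <- colnames(inp$x)[sds == 0]
  if (length(zero_var) == ncol(inp$x)) {
    igene_abort("all features have zero variance")
  }
  warn_excluded(zero_var, "zero variance")
  r <- suppressWarnings(as.vector(stats::cor(inp$x, inp$y)))
  r[sds == 0] <- NA_real_
  # two-sided p from the t transform with n - 2 df
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  sel <- p_rank_selected(p, alpha, adjust)
  selector_result("pearson", colnames(inp$x), r, p, sel$rank, sel$selected,
                  sel$extra)
}

#' Chi-square statistic of an observed table
#'
#' The shared chi-square core: `sum((observed - expected)^2 / expected)`.
#' When `expected` is omitted and `observed` is a matrix, expected counts
#' come from the table margins (the classical Pearson contingency test,
#' without continuity correction).
#'
#' @param observed numeric vector or matrix of observed counts/totals.
#' @param expected expected counts, same shape as `observed`; computed from
#'   the margins when `NULL`.
#' @return the chi-square statistic (a scalar).
#' @examples
#' chi2_stat(matrix(c(20, 10, 10, 20), nrow = 2)) # 6.667
#' @export
chi2_stat <- function(observed, expected = NULL) {
  if (is.null(expected)) {
    if (!is.matrix(observed)) {
      igene_abort("expected counts are required for non-matrix input")
    }
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  }
  if (any(expected <= 0)) igene_abort("expected counts must be positive")
  sum((observed - expected)^2 / expected)
}

#' Chi-square selection
#'
#' `chi2_select()` applies the classical Pearson chi-square contingency
#' test of each feature against the class label. Because expression values
#' are continuous (and can be negative after upstream normalization), each
#' feature is first dichotomized at its own mean — a label-free,
#' monotone reduction — giving a 2 x 2 class-by-level table tested with
#' [chi2_stat()] (margin-based expected counts, no continuity correction,
#' 1 degree of freedom). This keeps the test well defined on any numeric
#' feature and correctly calibrated under the null. Features that are
#' constant, or constant after dichotomization, are excluded with a
#' warning.
#'
#' @rdname selectors
#' @export
chi2_select <- function(data, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  inp <- check_selector_input(data)
  x <- inp$x
  rng <- apply(x, 2, function(v) diff(range(v)))
  flat <- colnames(x)[rng == 0]
  warn_excluded(flat, "all values equal; dichotomization undefined")
  stat <- rep(NA_real_, ncol(x))
  names(stat) <- colnames(x)
  degenerate <- character()
  for (j in which(rng > 0)) {
    high <- x[, j] > mean(x[, j])
    observed <- table(factor(inp$y, levels = c(0, 1)),
                      factor(high, levels = c(FALSE, TRUE)))
    if (any(colSums(observed) == 0)) {
      degenerate <- c(degenerate, colnames(x)[j])
      next
    }
    stat[j] <- chi2_stat(unclass(observed))
  }
  warn_excluded(degenerate, "constant after dichotomization")
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  sel <- p_rank_selected(p, alpha, adjust)
  selector_result("chi2", colnames(x), stat, p, sel$rank, sel$selected,
                  sel$extra)
}

#' @rdname selectors
#' @export
anova_select <- function(data, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  inp <- check_selector_input(data)
  x <- inp$x
  y <- inp$y
  if (min(table(y)) < 2) {
    igene_abort("each class needs at least 2 samples for ANOVA")
  }
  n <- nrow(x)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- colSums((t(t(x[y == 0, , drop = FALSE]) - m0))^2) +
    colSums((t(t(x[y == 1, , drop = FALSE]) - m1))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  undefined <- colnames(x)[ssw == 0 & ssb == 0]
  f[ssw == 0 & ssb == 0] <- NA_real_
  f[ssw == 0 & ssb > 0] <- Inf
  warn_excluded(undefined, "zero within- and between-class variance")
  p <- stats::pf(f, df1 = 1, df2 = n - 2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  sel <- p_rank_selected(p, alpha, adjust)
  selector_result("anova", colnames(x), f, p, sel$rank, sel$selected,
                  sel$extra)
}

#' Recursive feature elimination with a random-forest backend
#'
#' Repeatedly fits a random forest and removes the single least important
#' feature (mean decrease in Gini impurity) until `n_keep` features remain.
#' Deterministic for a fixed seed.
#'
#' @inheritParams selectors
#' @param n_keep number of features to retain. Defaults to
#'   `max(1, round(0.10 * n_features))` — the top 10 percent.
#' @param seed integer seed for the forest fits.
#' @param num_trees trees per forest fit. Default 100.
#' @return a `selector_result` tibble; `statistic` holds the full-model
#'   importance, `rank` is 1 for every kept feature and counts upward in
#'   reverse elimination order, and `selected` marks the kept set.
#' @export
rfe_select <- function(data, n_keep = NULL, seed = 1, num_trees = 100) {
  inp <- check_selector_input(data)
  x <- inp$x
  n_features <- ncol(x)
  n_keep <- n_keep %||% max(1L, round(0.10 * n_features))
  if (n_keep < 1 || n_keep > n_features) {
    igene_abort(sprintf("n_keep must be in [1, %d]", n_features))
  }
  y <- factor(inp$y, levels = c(0, 1))
  ranks <- stats::setNames(rep(1L, n_features), colnames(x))
  full_importance <- NULL
  remaining <- colnames(x)
  with_seed(substream_seed(seed, "rfe"), {
    next_rank <- n_features - n_keep + 1L
    while (length(remaining) > n_keep) {
      fit <- randomForest::randomForest(x[, remaining, drop = FALSE], y,
                                        ntree = num_trees)
      imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
      if (is.null(full_importance)) full_importance <- imp
      drop <- remaining[which.min(imp)]
      ranks[drop] <- next_rank
      next_rank <- next_rank - 1L
      remaining <- setdiff(remaining, drop)
    }
    if (is.null(full_importance)) {
      fit <- randomForest::randomForest(x, y, ntree = num_trees)
      full_importance <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    }
  })
  selector_result("rfe", colnames(x),
                  as.numeric(full_importance[colnames(x)]),
                  rep(NA_real_, n_features),
                  as.integer(ranks),
                  colnames(x) %in% remaining)
}

#' Combine selector results into one feature set
#'
#' Merges the `selected` sets of several selectors by union, intersection,
#' or an at-least-k vote. Output preserves the cohort's original column
#' order and records, per feature, which selectors chose it.
#'
#' @param results a list of `selector_result` tibbles.
#' @param mode `"union"` (default), `"intersection"`, or `"vote"`.
#' @param vote_k minimum number of selectors that must agree when
#'   `mode = "vote"`. Default 2.
#' @return a tibble of class `feature_set` with columns `feature`,
#'   `n_votes`, and `selectors` (comma-separated provenance).
#' @export
combine_selections <- function(results, mode = c("union", "intersection", "vote"),
                               vote_k = 2) {
  mode <- match.arg(mode)
  if (length(results) < 1) igene_abort("at least one selector result is required")
  if (mode == "vote" && vote_k > length(results)) {
    igene_abort("vote_k must not exceed the number of selector results")
  }
  feature_order <- results[[1]]$feature
  sel_names <- vapply(results, function(r) attr(r, "selector") %||% "selector",
                      character(1))
  sel_names <- make.unique(sel_names)
  chosen <- purrr::map(results, ~ .x$feature[.x$selected])
  votes <- table(factor(unlist(chosen), levels = feature_order))
  keep <- switch(mode,
    union = names(votes)[votes >= 1],
    intersection = names(votes)[votes == length(results)],
    vote = names(votes)[votes >= vote_k]
  )
  keep <- feature_order[feature_order %in% keep]
  if (length(keep) == 0) {
    igene_abort(paste(
      "no features survived the combination; relax alpha, lower vote_k,",
      "or use mode = 'union'"), class = "igenes_empty_selection")
  }
  provenance <- unname(vapply(keep, function(f) {
    paste(sel_names[vapply(chosen, function(s) f %in% s, logical(1))],
          collapse = ",")
  }, character(1)))
  structure(
    tibble::tibble(feature = keep,
                   n_votes = as.integer(votes[keep]),
                   selectors = provenance),
    combine_mode = mode, vote_k = if (mode == "vote") vote_k else NA_integer_,
    class = c("feature_set", class(tibble::tibble()))
  )
}

#' Run the full selector nexus
#'
#' Convenience wrapper running any subset of the four selectors and
#' combining their selections. Demographic features compete like any other
#' feature by default; `force_demographics = TRUE` appends them to the
#' final set regardless of the selectors' verdicts.
#'
#' @inheritParams selectors
#' @inheritParams rfe_select
#' @inheritParams combine_selections
#' @param selectors which selectors to run; any subset of
#'   `c("pearson", "chi2", "anova", "rfe")`.
#' @param force_demographics always include demographic features. Default
#'   `FALSE`.
#' @return a `feature_set` tibble (see [combine_selections()]); the
#'   individual selector results are attached as attribute `results`.
#' @export
select_features <- function(data, selectors = c("pearson", "chi2", "anova", "rfe"),
                            alpha = 0.05, adjust = c("none", "BH"),
                            n_keep = NULL, mode = c("union", "intersection", "vote"),
                            vote_k = 2, seed = 1, force_demographics = FALSE) {
  adjust <- match.arg(adjust)
  mode <- match.arg(mode)
  selectors <- match.arg(selectors, several.ok = TRUE)
  results <- purrr::map(selectors, function(s) {
    switch(s,
      pearson = pearson_select(data, alpha, adjust),
      chi2 = chi2_select(data, alpha, adjust),
      anova = anova_select(data, alpha, adjust),
      rfe = rfe_select(data, n_keep = n_keep, seed = seed)
    )
  })
  names(results) <- selectors
  fs <- combine_selections(results, mode = mode, vote_k = vote_k)
  if (force_demographics) {
    demo <- names(cigt_kinds(data))[cigt_kinds(data) != "expression"]
    add <- setdiff(demo, fs$feature)
    if (length(add) > 0) {
      extra <- tibble::tibble(feature = add, n_votes = 0L,
                              selectors = "forced")
      all_feats <- cigt_features(data)
      merged <- dplyr::bind_rows(tibble::as_tibble(fs), extra)
      merged <- merged[order(match(merged$feature, all_feats)), ]
      fs <- structure(merged,
                      combine_mode = attr(fs, "combine_mode"),
                      vote_k = attr(fs, "vote_k"),
                      class = c("feature_set", class(tibble::tibble())))
    }
  }
  attr(fs, "results") <- results
  fs
}
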