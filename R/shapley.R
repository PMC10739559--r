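#' Interventional Shapley-value feature attributions
#'
#' Computes signed additive per-sample, per-feature attributions for an
#' arbitrary prediction function. The value of a feature coalition is the
#' model output with in-coalition features taken from the explained sample
#' and the rest marginalized over a background (reference) set — the
#' interventional expectation. Two estimators are provided:
#'
#' * `exact`: enumerates all `2^M` coalitions and applies the Shapley
#'   subset weights `|S|! (M - |S| - 1)! / M!`; exact, feasible for small
#'   feature counts.
#' * `sampling`: averages marginal contributions along random feature
#'   orderings (permutation sampling). Because contributions telescope
#'   within each ordering, the additivity identity
#'   `baseline + sum(phi) = f(x)` holds exactly for any number of
#'   permutations; only the split of credit between features is estimated.
#'
#' `method = "auto"` (default) uses `exact` for up to 8 features and
#' `sampling` otherwise.
#'
#' @param f prediction function mapping a numeric matrix (rows = samples,
#'   columns = the model's features, on the raw feature scale) to a
#'   numeric vector of case probabilities.
#' @param x matrix of samples to explain.
#' @param background matrix of reference samples used to marginalize
#'   absent features.
#' @param method `"auto"`, `"exact"`, or `"sampling"`.
#' @param n_perm permutations for the sampling estimator. Default 8.
#' @param seed integer seed (sampling estimator only).
#' @return a list with `phi` (samples x features attribution matrix),
#'   `baseline` (mean background prediction), `fx` (predictions for `x`),
#'   and `method`.
#' @export
shapley_values <- function(f, x, background, method = c("auto", "exact", "sampling"),
                           n_perm = 8, seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) == 0) igene_abort("background must be non-empty")
  if (ncol(x) != ncol(background)) {
    igene_abort("x and background must have the same columns")
  }
  m <- ncol(x)
  if (method == "auto") method <- if (m <= 8) "exact" else "sampling"
  baseline <- mean(f(background))
  fx <- as.numeric(f(x))
  phi <- if (m == 0) {
    matrix(numeric(0), nrow = nrow(x), ncol = 0)
  } else if (method == "exact") {
    shapley_exact(f, x, background, baseline)
  } else {
    shapley_sampling(f, x, background, baseline, n_perm, seed)
  }
  dimnames(phi) <- dimnames(x)
  list(phi = phi, baseline = baseline, fx = fx, method = method)
}

# composite value matrix: for each explained sample, background rows with
# the coalition's columns overwritten by the sample's values; returns the
# per-sample mean prediction.
coalition_value <- function(f, x, background, coalition) {
  n <- nrow(x)
  nb <- nrow(background)
  big <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  if (length(coalition) > 0) {
    rows_x <- rep(seq_len(n), each = nb)
    big[, coalition] <- x[rows_x, coalition, drop = FALSE]
  }
  pred <- f(big)
  colMeans(matrix(pred, nrow = nb, ncol = n))
}

shapley_exact <- function(f, x, background, baseline) {
  m <- ncol(x)
  n <- nrow(x)
  n_coal <- 2L^m
  # coalition k (0-based) contains feature j iff bit j of k is set
  members <- lapply(seq_len(n_coal) - 1L, function(k) {
    which(bitwAnd(k, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
  })
  v <- matrix(NA_real_, nrow = n_coal, ncol = n)
  v[1, ] <- baseline
  for (k in 2:n_coal) {
    v[k, ] <- coalition_value(f, x, background, members[[k]])
  }
  sizes <- lengths(members)
  w <- ifelse(sizes < m,
              factorial(sizes) * factorial(pmax(m - sizes - 1, 0)) / factorial(m),
              0)
  phi <- matrix(0, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_coal) - 1L, bit) == 0L)
    for (k in without) {
      k_with <- k + bit
      phi[, j] <- phi[, j] + w[k] * (v[k_with, ] - v[k, ])
    }
  }
  phi
}

shapley_sampling <- function(f, x, background, baseline, n_perm, seed) {
  m <- ncol(x)
  n <- nrow(x)
  nb <- nrow(background)
  phi <- matrix(0, nrow = n, ncol = m)
  orders <- with_seed(substream_seed(seed, "shapley"), {
    lapply(seq_len(n_perm), function(p) sample.int(m))
  })
  # chunk explained samples so one permutation's composite matrix stays small
  chunk <- max(1L, floor(2e6 / (m * nb)))
  starts <- seq(1L, n, by = chunk)
  for (ord in orders) {
    for (s in starts) {
      idx <- s:min(s + chunk - 1L, n)
      xi <- x[idx, , drop = FALSE]
      ni <- length(idx)
      # rows: for each sample, for each prefix length k = 1..m, background
      # rows with features ord[1..k] taken from the sample
      big <- background[rep(seq_len(nb), times = ni * m), , drop = FALSE]
      rows_x <- rep(rep(seq_len(ni), each = m * nb))
      prefix <- rep(rep(seq_len(m), each = nb), times = ni)
      for (k in seq_len(m)) {
        cols <- ord[seq_len(k)]
        sel <- prefix == k
        big[sel, cols] <- xi[rows_x[sel], cols, drop = FALSE]
      }
      pred <- f(big)
      # v[k, i]: mean over background of the prefix-k composite
      v <- matrix(colMeans(matrix(pred, nrow = nb)), nrow = m, ncol = ni)
      v_prev <- rbind(rep(baseline, ni), v[-m, , drop = FALSE])
      marg <- v - v_prev
      phi[idx, ord] <- phi[idx, ord] + t(marg)
    }
  }
  phi / n_perm
}

#' Attributions for one ensemble member
#'
#' Wraps [shapley_values()] around a fitted base member's case-probability
#' output. Attributions therefore explain the probability of disease, not
#' the hard decision, so their signs and magnitudes are informative.
#'
#' @param model an `igene_ensemble` from [train_ensemble()].
#' @param member name of an enabled base member.
#' @param data samples to explain (a [cigt][as_cigt] tibble or a matrix
#'   containing the model's feature columns).
#' @param background reference samples (typically the training cohort).
#' @inheritParams shapley_values
#' @return an object of class `igene_attribution`: a list with
#'   `classifier`, `phi`, `baseline`, `fx`, `target`, `sample_ids`,
#'   `feature_names`, and `method`.
#' @export
compute_attributions <- function(model, member, data, background,
                                 method = "auto", n_perm = 8, seed = 1) {
  stopifnot(inherits(model, "igene_ensemble"))
  if (!member %in% model$enabled) {
    igene_abort(sprintf("'%s' is not an enabled member", member))
  }
  x <- raw_feature_matrix(model, data)
  bg <- raw_feature_matrix(model, background)
  f <- function(mat) {
    xs <- scale(mat, center = model$scaler$center, scale = model$scaler$scale)
    member_prob(model, member, xs)
  }
  sv <- shapley_values(f, x, bg, method = method, n_perm = n_perm,
                       seed = substream_seed(seed, paste0("shap_", member)))
  structure(
    list(classifier = member, phi = sv$phi, baseline = sv$baseline,
         fx = sv$fx, target = "case_probability",
         sample_ids = rownames(x), feature_names = colnames(x),
         method = sv$method),
    class = "igene_attribution"
  )
}

raw_feature_matrix <- function(model, data) {
  x <- if (inherits(data, "cigt")) cigt_matrix(data) else as.matrix(data)
  missing_feats <- setdiff(model$feature_names, colnames(x))
  if (length(missing_feats) > 0) {
    igene_abort(sprintf("feature(s) missing from data: %s",
                        paste(missing_feats, collapse = ", ")))
  }
  x[, model$feature_names, drop = FALSE]
}

#' Attributions for every enabled base member
#'
#' Runs [compute_attributions()] for each enabled base classifier. The
#' background is subsampled (seeded) to at most `background_size` rows. A
#' member whose explainer fails is dropped with a warning — never silently
#' zero-filled.
#'
#' @inheritParams compute_attributions
#' @param background_size maximum background rows. Default 100.
#' @param members members to explain; defaults to all enabled base members.
#' @return a named list of `igene_attribution` objects.
#' @export
explain_ensemble <- function(model, data, background, members = model$enabled,
                             background_size = 100, method = "auto",
                             n_perm = 8, seed = 1) {
  bg <- raw_feature_matrix(model, background)
  if (nrow(bg) > background_size) {
    keep <- with_seed(substream_seed(seed, "background"), {
      sort(sample.int(nrow(bg), background_size))
    })
    bg <- bg[keep, , drop = FALSE]
  }
  atts <- list()
  for (m in members) {
    att <- tryCatch(
      compute_attributions(model, m, data, bg, method = method,
                           n_perm = n_perm, seed = seed),
      error = function(e) {
        rlang::warn(sprintf(
          "attribution failed for member '%s' (%s); excluding it from scoring",
          m, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(att)) atts[[m]] <- att
  }
  if (length(atts) == 0) {
    igene_abort("attribution failed for every member; no scoring possible")
  }
  atts
}

#' Worst-case additivity error of an attribution
#'
#' The additive-explanation identity requires, for every explained sample,
#' `baseline + sum(phi) = model output`. Returns the largest absolute
#' violation across samples; exact enumeration should be at machine
#' precision, permutation sampling within its stated tolerance.
#'
#' @param att an `igene_attribution`.
#' @return the maximum absolute per-sample violation.
#' @export
local_accuracy_error <- function(att) {
  stopifnot(inherits(att, "igene_attribution"))
  max(abs(att$baseline + rowSums(att$phi) - att$fx))
}
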