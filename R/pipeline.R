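#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates the end-to-end analysis: read/validate the cohort,
#' stratified train/test split, feature selection, ensemble training,
#' held-out evaluation, I-Gene scoring, and reporting. All randomness
#' derives from the single `seed`, so two runs with the same inputs and
#' seed write byte-identical CSV outputs.
#'
#' Files written to `output_dir`:
#' \describe{
#'   \item{selected_features.csv}{the combined feature set with
#'     per-selector statistics, p values and ranks.}
#'   \item{predictions.csv}{per-patient label and case probability for
#'     every classifier including the voters (held-out set).}
#'   \item{metrics.csv}{per-classifier accuracy, F1 and ROC AUC.}
#'   \item{igene_profile.csv}{per-feature I-Gene score, direction,
#'     per-classifier shares and rank.}
#'   \item{classifier_weights.csv}{per-classifier HHI and weight.}
#'   \item{attribution_summary.png, importance_bar.png}{summary plots for
#'     the highest-weighted classifier.}
#'   \item{run_log.txt}{configuration and package versions.}
#'   \item{MANIFEST.txt}{list of outputs; marks an aborted run INCOMPLETE.}
#' }
#'
#' @param input path to a CIGT CSV, or a [cigt][as_cigt] tibble.
#' @param output_dir directory for outputs (created if needed).
#' @param id_column,label_column CIGT column names (used when `input` is a
#'   path).
#' @param selectors,alpha,adjust,n_keep,mode,vote_k selection settings, see
#'   [select_features()].
#' @param members,control ensemble settings, see [train_ensemble()].
#' @param test_fraction held-out fraction for the stratified split.
#'   Default 0.3.
#' @param background_size,n_perm,tau scoring settings, see
#'   [igene_profile()].
#' @param top_fraction when non-`NULL`, additionally writes
#'   `top_features.csv` holding this top fraction of ranked biomarkers.
#' @param seed master integer seed for every stochastic stage.
#' @return (invisibly) a list with the in-memory results: `split`,
#'   `features`, `model`, `evaluation`, `profile`, and `files` (paths
#'   written).
#' @export
run_pipeline <- function(input, output_dir,
                         id_column = "ID", label_column = "Type",
                         selectors = c("pearson", "chi2", "anova", "rfe"),
                         alpha = 0.05, adjust = "none", n_keep = NULL,
                         mode = "union", vote_k = 2,
                         members = BASE_MEMBERS,
                         control = ensemble_control(),
                         test_fraction = 0.3,
                         background_size = 100, n_perm = 8, tau = 0.1,
                         top_fraction = NULL, seed = 1) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(sprintf("INCOMPLETE: failed at stage '%s'", name),
                   files),
                 file.path(output_dir, "MANIFEST.txt"))
      igene_abort(sprintf("[%s] %s", name, conditionMessage(e)),
                  class = "igenes_stage_error", stage = name)
    })
  }
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    files <<- c(files, name)
    path
  }

  ds <- stage("read", {
    if (inherits(input, "cigt")) input
    else read_cigt(input, id_column = id_column, label_column = label_column)
  })

  parts <- stage("split", split_cigt(ds, test_fraction = test_fraction,
                                     seed = seed))

  features <- stage("select", {
    fs <- select_features(parts$train, selectors = selectors, alpha = alpha,
                          adjust = adjust, n_keep = n_keep, mode = mode,
                          vote_k = vote_k, seed = seed)
    wide <- tibble::as_tibble(fs)
    for (nm in names(attr(fs, "results"))) {
      r <- attr(fs, "results")[[nm]]
      cols <- tibble::tibble(statistic = r$statistic, p_value = r$p_value,
                             rank = r$rank)
      names(cols) <- paste0(nm, "_", names(cols))
      cols$feature <- r$feature
      wide <- dplyr::left_join(wide, cols, by = "feature")
    }
    emit(wide, "selected_features.csv")
    fs
  })

  model <- stage("train", train_ensemble(parts$train, features,
                                         members = members, seed = seed,
                                         control = control))

  evaluation <- stage("evaluate", {
    ev <- evaluate_ensemble(model, parts$test)
    emit(ev$predictions, "predictions.csv")
    emit(ev$metrics, "metrics.csv")
    ev
  })

  profile <- stage("score", {
    pr <- igene_profile(model, parts$test, parts$train,
                        background_size = background_size, n_perm = n_perm,
                        tau = tau, seed = seed)
    emit(tibble::as_tibble(pr), "igene_profile.csv")
    emit(attr(pr, "classifier_weights"), "classifier_weights.csv")
    if (!is.null(top_fraction)) {
      n_top <- max(1L, round(top_fraction * nrow(pr)))
      emit(tibble::as_tibble(pr)[seq_len(n_top), ], "top_features.csv")
    }
    pr
  })

  stage("report", {
    w <- attr(profile, "classifier_weights")
    best <- w$classifier[which.max(w$weight)]
    att <- attr(profile, "attributions")[[best]]
    x <- raw_feature_matrix(model, parts$test)
    for (p in list(list(plot_attribution_summary(att, x),
                        "attribution_summary.png"),
                   list(plot_importance_bar(att), "importance_bar.png"))) {
      ggplot2::ggsave(file.path(output_dir, p[[2]]), p[[1]],
                      width = 7, height = 5, dpi = 150)
      files <<- c(files, p[[2]])
    }
    log_lines <- c(
      sprintf("igenes version: %s", as.character(utils::packageVersion("igenes"))),
      sprintf("R version: %s", R.version.string),
      sprintf("seed: %d", seed),
      sprintf("selectors: %s", paste(selectors, collapse = ",")),
      sprintf("alpha: %g | adjust: %s | mode: %s | vote_k: %d",
              alpha, adjust, mode, vote_k),
      sprintf("n_keep: %s", n_keep %||% "default (top 10%)"),
      sprintf("members: %s", paste(members, collapse = ",")),
      sprintf("test_fraction: %g", test_fraction),
      sprintf("background_size: %d | n_perm: %d | tau: %g",
              background_size, n_perm, tau),
      sprintf("n_samples: %d | n_features: %d", nrow(ds),
              length(cigt_features(ds))),
      sprintf("selected features: %d", nrow(features)),
      "hyperparameters:",
      paste0("  ", names(control), ": ",
             vapply(control, function(v) paste(format(v %||% "auto"),
                                               collapse = ","),
                    character(1)))
    )
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
    files <<- c(files, "run_log.txt")
    writeLines(c("COMPLETE", files), file.path(output_dir, "MANIFEST.txt"))
  })

  invisible(list(split = parts, features = features, model = model,
                 evaluation = evaluation, profile = profile,
                 files = file.path(output_dir, files)))
}
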