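#' Clinically integrated cohort tables (CIGT)
#'
#' A CIGT table is a patient-by-feature table: one patient identifier
#' column, one binary diagnosis column (0 = control, 1 = case), and any
#' number of feature columns holding demographic attributes and per-gene
#' expression values. `as_cigt()` validates a data frame and returns it as
#' a `cigt` tibble carrying the identifier/label column names and a
#' per-feature kind tag (`expression`, `demographic_numeric`, or
#' `demographic_categorical_encoded`) as attributes. Categorical
#' demographic columns are integer-encoded deterministically, by
#' lexicographic category order, so that each input column remains a single
#' feature downstream.
#'
#' @param data a data frame with one row per patient.
#' @param id_column name of the patient identifier column. Default `"ID"`.
#' @param label_column name of the binary diagnosis column. Default `"Type"`.
#' @param demographic_columns optional character vector naming numeric
#'   columns that are demographic attributes rather than expression values.
#'   Non-numeric columns are always treated as categorical demographics.
#' @param missing `"error"` (default) rejects missing values;
#'   `"keep"` retains them (impute later with [impute_cigt()]).
#' @return a tibble of class `cigt` with attributes `id_column`,
#'   `label_column`, `feature_kinds` (named character vector), and
#'   `encodings` (the category-to-code maps used).
#' @seealso [read_cigt()], [write_cigt()], [split_cigt()], [validate_cigt()]
#' @examples
#' df <- data.frame(ID = c("P1", "P2", "P3", "P4"),
#'                  Type = c(0, 0, 1, 1),
#'                  gender = c("F", "M", "F", "M"),
#'                  g1 = c(1.2, 0.8, 2.5, 2.9))
#' ds <- as_cigt(df)
#' cigt_kinds(ds)
#' @export
as_cigt <- function(data, id_column = "ID", label_column = "Type",
                    demographic_columns = NULL,
                    missing = c("error", "keep")) {
  missing <- match.arg(missing)
  report <- validate_cigt(data, id_column, label_column, missing = missing)
  if (!report$passed) {
    igene_abort(
      c("invalid CIGT table:",
        stats::setNames(report$errors$message, rep("x", nrow(report$errors)))),
      class = "igenes_validation_error"
    )
  }
  for (w in report$warnings$message) rlang::warn(w)

  data <- tibble::as_tibble(data)
  feature_names <- setdiff(names(data), c(id_column, label_column))
  kinds <- character(length(feature_names))
  names(kinds) <- feature_names
  encodings <- list()
  for (f in feature_names) {
    col <- data[[f]]
    if (is.numeric(col)) {
      kinds[f] <- if (f %in% demographic_columns) "demographic_numeric" else "expression"
    } else {
      levels <- sort(unique(as.character(col[!is.na(col)])))
      codes <- as.integer(factor(as.character(col), levels = levels)) - 1L
      data[[f]] <- codes
      encodings[[f]] <- stats::setNames(seq_along(levels) - 1L, levels)
      kinds[f] <- "demographic_categorical_encoded"
    }
  }
  data[[label_column]] <- as.integer(data[[label_column]])
  data[[id_column]] <- as.character(data[[id_column]])

  structure(
    data,
    id_column = id_column,
    label_column = label_column,
    feature_kinds = kinds,
    encodings = encodings,
    class = c("cigt", class(tibble::tibble()))
  )
}

#' Validate a CIGT data frame
#'
#' Checks structural requirements without modifying the data: presence of
#' the identifier and label columns, uniqueness of patient identifiers,
#' binary (0/1) diagnosis labels, and absence of missing values. Returns a
#' report rather than raising, so callers can surface all problems at once.
#'
#' @inheritParams as_cigt
#' @return a list with `errors` and `warnings` tibbles
#'   (columns `code`, `message`, `location`) and a logical `passed`
#'   (`TRUE` iff there are no errors).
#' @export
validate_cigt <- function(data, id_column = "ID", label_column = "Type",
                          missing = c("error", "keep")) {
  missing <- match.arg(missing)
  errors <- list()
  warnings <- list()
  note <- function(code, message, location = NA_character_) {
    tibble::tibble(code = code, message = message, location = location)
  }

  for (col in c(id_column, label_column)) {
    if (!col %in% names(data)) {
      errors <- c(errors, list(note(
        "missing_column", sprintf("required column '%s' is absent", col), col
      )))
    }
  }

  if (id_column %in% names(data)) {
    ids <- as.character(data[[id_column]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0) {
      errors <- c(errors, list(note(
        "duplicate_id",
        sprintf("duplicate sample IDs: %s", paste(dup, collapse = ", ")),
        id_column
      )))
    }
  }

  if (label_column %in% names(data)) {
    lab <- data[[label_column]]
    bad <- unique(lab[!(lab %in% c(0, 1)) | is.na(lab)])
    if (length(bad) > 0) {
      errors <- c(errors, list(note(
        "label_values",
        sprintf("labels must be 0/1; offending values: %s",
                paste(format(bad), collapse = ", ")),
        label_column
      )))
    } else {
      counts <- table(factor(lab, levels = c(0, 1)))
      if (any(counts < 2)) {
        warnings <- c(warnings, list(note(
          "small_class",
          "a diagnosis class has fewer than 2 samples; model fitting will fail",
          label_column
        )))
      }
    }
  }

  feats <- setdiff(names(data), c(id_column, label_column))
  n_missing <- sum(vapply(data[feats], function(x) sum(is.na(x)), 0L))
  if (n_missing > 0) {
    msg <- sprintf("%d missing value(s) in feature columns", n_missing)
    if (missing == "error") {
      errors <- c(errors, list(note("missing_values", msg)))
    } else {
      warnings <- c(warnings, list(note("missing_values", msg)))
    }
  }

  empty <- tibble::tibble(code = character(), message = character(),
                          location = character())
  errors <- if (length(errors)) dplyr::bind_rows(errors) else empty
  warnings <- if (length(warnings)) dplyr::bind_rows(warnings) else empty
  list(errors = errors, warnings = warnings, passed = nrow(errors) == 0L)
}

#' Read a CIGT cohort table from a delimited file
#'
#' Reads a comma-separated UTF-8 file with a header row and validates it
#' via [as_cigt()]. The file's column order is preserved.
#'
#' @param path path to the CSV file.
#' @inheritParams as_cigt
#' @return a `cigt` tibble.
#' @export
read_cigt <- function(path, id_column = "ID", label_column = "Type",
                      demographic_columns = NULL,
                      missing = c("error", "keep")) {
  if (!file.exists(path)) {
    igene_abort(sprintf("file not found: %s", path), "igenes_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cigt(data, id_column = id_column, label_column = label_column,
          demographic_columns = demographic_columns, missing = missing)
}

#' Write a CIGT table to CSV
#'
#' Writes the validated (encoded) table; categorical demographics are
#' written as their integer codes, so a read/write round trip reproduces
#' numeric values and category codes exactly.
#'
#' @param data a `cigt` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cigt <- function(data, path) {
  readr::write_csv(tibble::as_tibble(unclass_cigt(data)), path, progress = FALSE)
  invisible(path)
}

#' Stratified train/test split of a CIGT table
#'
#' Splits patients into training and test parts while keeping the class
#' proportions of each part within one sample of the overall proportion
#' (largest-remainder allocation per class, ties broken by ascending class
#' label). Identical seed and inputs give identical splits.
#'
#' @param data a `cigt` tibble.
#' @param test_fraction proportion of samples assigned to the test part;
#'   strictly between 0 and 1. Default 0.3.
#' @param seed integer seed controlling the split.
#' @return a list with `cigt` elements `train` and `test`; together they
#'   partition the input rows.
#' @export
split_cigt <- function(data, test_fraction = 0.3, seed = 1) {
  stopifnot(inherits(data, "cigt"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    igene_abort("test_fraction must be strictly between 0 and 1")
  }
  labels <- cigt_labels(data)
  n <- length(labels)
  n_test <- round(n * test_fraction)
  # largest-remainder allocation of the test quota across classes
  classes <- sort(unique(labels))
  quota <- n_test * as.numeric(table(factor(labels, levels = classes))) / n
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(-(quota - take), classes)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  test_idx <- with_seed(substream_seed(seed, "split"), {
    unlist(lapply(seq_along(classes), function(k) {
      pool <- which(labels == classes[k])
      sample(pool, size = take[k])
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  for (k in classes) {
    if (!any(labels[train_idx] == k)) {
      igene_abort(sprintf("class %s would receive 0 training samples", k))
    }
  }
  list(train = cigt_subset(data, train_idx), test = cigt_subset(data, test_idx))
}

#' Median-impute missing feature values
#'
#' Replaces missing feature values with per-feature medians. To avoid
#' information leakage, compute the medians on the training part and reuse
#' them for the test part via the `stats` argument.
#'
#' @param data a `cigt` tibble (read with `missing = "keep"`).
#' @param stats optional named numeric vector of per-feature medians from a
#'   previous call; when `NULL`, medians are computed from `data`.
#' @return the imputed `cigt` tibble, with the medians used stored in
#'   attribute `impute_stats`.
#' @export
impute_cigt <- function(data, stats = NULL) {
  stopifnot(inherits(data, "cigt"))
  feats <- cigt_features(data)
  if (is.null(stats)) {
    stats <- vapply(feats, function(f) stats::median(data[[f]], na.rm = TRUE),
                    numeric(1))
  }
  for (f in feats) {
    miss <- is.na(data[[f]])
    if (any(miss)) data[[f]][miss] <- stats[[f]]
  }
  attr(data, "impute_stats") <- stats
  data
}

# --- accessors ---------------------------------------------------------

#' CIGT accessors
#'
#' Small helpers extracting the parts of a `cigt` tibble: the numeric
#' feature matrix (patients x features), the 0/1 label vector, patient
#' identifiers, feature names, and per-feature kind tags.
#'
#' @param data a `cigt` tibble.
#' @return `cigt_matrix()` a numeric matrix; `cigt_labels()` an integer
#'   vector; `cigt_ids()` and `cigt_features()` character vectors;
#'   `cigt_kinds()` a named character vector.
#' @name cigt-accessors
NULL

#' @rdname cigt-accessors
#' @export
cigt_matrix <- function(data) {
  stopifnot(inherits(data, "cigt"))
  feats <- cigt_features(data)
  m <- as.matrix(tibble::as_tibble(unclass_cigt(data))[feats])
  rownames(m) <- cigt_ids(data)
  storage.mode(m) <- "double"
  m
}

#' @rdname cigt-accessors
#' @export
cigt_labels <- function(data) as.integer(data[[attr(data, "label_column")]])

#' @rdname cigt-accessors
#' @export
cigt_ids <- function(data) as.character(data[[attr(data, "id_column")]])

#' @rdname cigt-accessors
#' @export
cigt_features <- function(data) names(attr(data, "feature_kinds"))

#' @rdname cigt-accessors
#' @export
cigt_kinds <- function(data) attr(data, "feature_kinds")

# subset rows, preserving cigt attributes
cigt_subset <- function(data, idx) {
  out <- tibble::as_tibble(unclass_cigt(data))[idx, , drop = FALSE]
  structure(
    out,
    id_column = attr(data, "id_column"),
    label_column = attr(data, "label_column"),
    feature_kinds = attr(data, "feature_kinds"),
    encodings = attr(data, "encodings"),
    class = c("cigt", class(tibble::tibble()))
  )
}

# subset feature columns (keeping id/label), preserving attributes
cigt_select_features <- function(data, features) {
  keep <- c(attr(data, "id_column"), attr(data, "label_column"), features)
  out <- tibble::as_tibble(unclass_cigt(data))[keep]
  structure(
    out,
    id_column = attr(data, "id_column"),
    label_column = attr(data, "label_column"),
    feature_kinds = attr(data, "feature_kinds")[features],
    encodings = attr(data, "encodings")[
      intersect(names(attr(data, "encodings")), features)],
    class = c("cigt", class(tibble::tibble()))
  )
}

unclass_cigt <- function(data) {
  class(data) <- setdiff(class(data), "cigt")
  attr(data, "feature_kinds") <- NULL
  attr(data, "encodings") <- NULL
  attr(data, "id_column") <- NULL
  attr(data, "label_column") <- NULL
  attr(data, "impute_stats") <- NULL
  data
}
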