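#' Simulate a case/control CIGT cohort with known ground truth
#'
#' Generates a patient-by-feature cohort table mimicking processed (e.g.
#' log-scale, normalized) RNA-seq expression: uninformative genes are drawn
#' i.i.d. Normal(`base_mean`, `noise_sd`^2) in both classes, while the
#' first `n_informative` genes have their case-class mean shifted by
#' `effect_size * noise_sd` (a standardized Cohen's d shift). Shift
#' directions alternate up/down deterministically by gene index (gene 1 up
#' in cases, gene 2 down, ...), so downstream directionality calls can be
#' checked in both polarities from a single cohort. Optional demographic
#' columns are generated independently of the diagnosis label.
#'
#' @param n_cases,n_controls class sizes. Defaults 100/100.
#' @param n_genes total number of gene expression features. Default 50.
#' @param n_informative number of genes with a true class shift
#'   (`<= n_genes`). Default 5.
#' @param effect_size standardized mean shift (Cohen's d units) applied to
#'   informative genes in cases; `>= 0`. Default 2.
#' @param base_mean expression location for all genes. Default 8 (a typical
#'   log2-scale magnitude).
#' @param noise_sd expression standard deviation; `> 0`. Default 1.
#' @param demographics optional named list describing demographic columns,
#'   each element a list with `type = "numeric"` (fields `mean`, `sd`) or
#'   `type = "categorical"` (fields `levels`, optional `probs`). Generated
#'   independently of the label.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a list with elements `data` (a [cigt][as_cigt] tibble; cases
#'   first, IDs `S0001`, `S0002`, ...) and `truth` (a tibble with columns
#'   `gene` and `direction` in `{up_in_cases, down_in_cases}` for the
#'   informative genes).
#' @examples
#' sim <- simulate_cigt(n_cases = 20, n_controls = 20, n_genes = 10,
#'                      n_informative = 2, effect_size = 2, seed = 1)
#' sim$truth
#' @export
simulate_cigt <- function(n_cases = 100, n_controls = 100, n_genes = 50,
                          n_informative = 5, effect_size = 2,
                          base_mean = 8, noise_sd = 1,
                          demographics = NULL, seed = 1) {
  if (n_informative > n_genes) {
    igene_abort("n_informative must not exceed n_genes")
  }
  if (effect_size < 0) igene_abort("effect_size must be >= 0")
  if (noise_sd <= 0) igene_abort("noise_sd must be > 0")
  if (min(n_cases, n_controls, n_genes) < 0) {
    igene_abort("counts must be non-negative")
  }

  n <- n_cases + n_controls
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  gene_names <- sprintf("gene_%03d", seq_len(n_genes))
  directions <- rep_len(c("up_in_cases", "down_in_cases"),
                        max(n_informative, 1L))[seq_len(n_informative)]

  mat <- with_seed(substream_seed(seed, "expression"), {
    m <- matrix(stats::rnorm(n * n_genes, mean = base_mean, sd = noise_sd),
                nrow = n, ncol = n_genes)
    if (n_informative > 0 && n_cases > 0) {
      shift <- ifelse(directions == "up_in_cases", 1, -1) *
        effect_size * noise_sd
      cases <- which(labels == 1L)
      for (j in seq_len(n_informative)) {
        m[cases, j] <- m[cases, j] + shift[j]
      }
    }
    m
  })
  colnames(mat) <- gene_names

  df <- tibble::tibble(
    ID = sprintf("S%04d", seq_len(n)),
    Type = labels
  )
  df <- dplyr::bind_cols(df, tibble::as_tibble(mat))

  demo_numeric <- character()
  if (!is.null(demographics)) {
    demo <- with_seed(substream_seed(seed, "demographics"), {
      purrr::imap(demographics, function(spec, name) {
        type <- spec$type %||% "numeric"
        if (type == "numeric") {
          stats::rnorm(n, mean = spec$mean %||% 0, sd = spec$sd %||% 1)
        } else if (type == "categorical") {
          levels <- spec$levels
          probs <- spec$probs %||% rep(1 / length(levels), length(levels))
          sample(levels, n, replace = TRUE, prob = probs)
        } else {
          igene_abort(sprintf("unknown demographic type '%s' for '%s'",
                              type, name))
        }
      })
    })
    demo_numeric <- names(demographics)[
      vapply(demographics, function(s) (s$type %||% "numeric") == "numeric",
             logical(1))]
    df <- dplyr::bind_cols(df, tibble::as_tibble(demo))
  }

  data <- as_cigt(df, id_column = "ID", label_column = "Type",
                  demographic_columns = demo_numeric)
  truth <- tibble::tibble(
    gene = gene_names[seq_len(n_informative)],
    direction = directions
  )
  list(data = data, truth = truth)
}
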