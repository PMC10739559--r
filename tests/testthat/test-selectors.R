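make_cigt <- function(values, labels) {
  df <- data.frame(ID = sprintf("P%d", seq_along(labels)), Type = labels)
  suppressWarnings(as_cigt(cbind(df, as.data.frame(values))))
}

test_that("point-biserial selection matches the closed form and cor.test", {
  ds <- make_cigt(list(f = c(1, 2, 3, 4)), c(0, 0, 1, 1))
  res <- pearson_select(ds)
  expect_equal(res$statistic, 2 / sqrt(5), tolerance = 1e-12) # 0.8944...
  oracle <- cor.test(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)

  # a feature identical to the label is perfectly correlated and selected
  ds2 <- make_cigt(list(f = c(0, 0, 0, 1, 1, 1)), c(0, 0, 0, 1, 1, 1))
  res2 <- pearson_select(ds2)
  expect_equal(res2$statistic, 1.0)
  expect_true(res2$selected)

  expect_error(pearson_select(make_cigt(list(f = c(1, 2)), c(0, 1))),
               "3 samples")
})

test_that("chi-square core reproduces the contingency-table statistic", {
  tab <- matrix(c(20, 10, 10, 20), nrow = 2)
  expect_equal(chi2_stat(tab), 20 / 3, tolerance = 1e-12)
  expect_equal(chi2_stat(tab),
               unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-10)
  # perfect homogeneity: equal per-class totals with equal class sizes
  expect_equal(chi2_stat(c(10, 10), c(10, 10)), 0)
  expect_error(chi2_stat(c(1, 2)), "expected")
})

test_that("chi-square selection excludes flat features and is calibrated", {
  ds <- make_cigt(list(f = c(5, 5, 5, 5), g = c(1, 2, 3, 9)), c(0, 0, 1, 1))
  expect_warning(res <- chi2_select(ds), "all values equal")
  expect_true(is.na(res$statistic[res$feature == "f"]))
  expect_false(res$selected[res$feature == "f"])
  # homogeneous scaled totals give statistic 0 and no selection
  ds2 <- make_cigt(list(h = c(0, 1, 0, 1)), c(0, 0, 1, 1))
  res2 <- chi2_select(ds2)
  expect_equal(res2$statistic, 0)
  expect_false(res2$selected)
})

test_that("ANOVA F matches the toy oracle and the t-squared identity", {
  ds <- make_cigt(list(f = c(1, 2, 3, 2, 3, 4)), c(0, 0, 0, 1, 1, 1))
  res <- anova_select(ds)
  expect_equal(res$statistic, 1.5, tolerance = 1e-12)
  fit <- oneway.test(v ~ g, data = data.frame(v = c(1, 2, 3, 2, 3, 4),
                                              g = rep(0:1, each = 3)),
                     var.equal = TRUE)
  expect_equal(res$statistic, unname(fit$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, fit$p.value, tolerance = 1e-10)

  # F == t^2 for every feature (algebraic identity, random cases)
  sim <- simulate_cigt(n_cases = 20, n_controls = 25, n_genes = 15,
                       n_informative = 5, seed = 13)
  resf <- anova_select(sim$data)
  x <- cigt_matrix(sim$data)
  y <- cigt_labels(sim$data)
  t2 <- apply(x, 2, function(v) {
    unname(t.test(v[y == 1], v[y == 0], var.equal = TRUE)$statistic)^2
  })
  expect_equal(resf$statistic, unname(t2), tolerance = 1e-9)

  # degenerate: both groups identical constants -> excluded with warning
  dsc <- make_cigt(list(f = rep(2, 6), g = c(1, 2, 3, 2, 3, 4)),
                   c(0, 0, 0, 1, 1, 1))
  expect_warning(resc <- anova_select(dsc), "zero within")
  expect_true(is.na(resc$statistic[resc$feature == "f"]))
  expect_error(anova_select(make_cigt(list(f = c(1, 2, 3)), c(0, 1, 1))),
               "at least 2 samples")
})

test_that("RFE keeps planted genes, ranks consistently, deterministic", {
  sim <- simulate_cigt(n_cases = 50, n_controls = 50, n_genes = 25,
                       n_informative = 3, effect_size = 2, seed = 17)
  res <- rfe_select(sim$data, n_keep = 3, seed = 17)
  expect_equal(sum(res$selected), 3)
  expect_true(all(res$rank[res$selected] == 1))
  expect_setequal(res$rank, c(rep(1, 3), 2:23))
  expect_gte(length(intersect(res$feature[res$selected], sim$truth$gene)), 2)

  res2 <- rfe_select(sim$data, n_keep = 3, seed = 17)
  expect_identical(res$rank, res2$rank)

  # n_keep = n_features: nothing eliminated
  all_kept <- rfe_select(sim$data, n_keep = 25, seed = 1)
  expect_true(all(all_kept$selected))
  expect_true(all(all_kept$rank == 1))
  expect_error(rfe_select(sim$data, n_keep = 0), "n_keep")
  expect_error(rfe_select(sim$data, n_keep = 26), "n_keep")
})

test_that("selector outputs are invariant to feature column order", {
  sim <- simulate_cigt(n_cases = 25, n_controls = 25, n_genes = 8,
                       n_informative = 2, seed = 19)
  df <- tibble::as_tibble(sim$data)
  perm <- c("ID", "Type", sample(cigt_features(sim$data)))
  dsp <- as_cigt(df[perm])
  for (fn in list(pearson_select, chi2_select, anova_select)) {
    a <- fn(sim$data)
    b <- fn(dsp)
    b <- b[match(a$feature, b$feature), ]
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$selected, b$selected)
  }
})

test_that("selections combine by union, intersection and vote", {
  mk <- function(name, feats, sel) {
    structure(tibble::tibble(feature = feats,
                             statistic = seq_along(feats),
                             p_value = 0.5, rank = seq_along(feats),
                             selected = feats %in% sel),
              selector = name,
              class = c("selector_result", class(tibble::tibble())))
  }
  feats <- c("a", "b", "c", "d")
  r1 <- mk("pearson", feats, c("a", "b"))
  r2 <- mk("chi2", feats, c("b", "c"))
  r3 <- mk("anova", feats, c("b", "d"))

  expect_equal(combine_selections(list(r1, r2))$feature, c("a", "b", "c"))
  expect_equal(combine_selections(list(r1, r2), "intersection")$feature, "b")
  fs <- combine_selections(list(r1, r2, r3), "vote", vote_k = 2)
  expect_equal(fs$feature, "b")
  expect_equal(fs$selectors, "pearson,chi2,anova")
  expect_error(combine_selections(list(mk("p", feats, character()))),
               "relax", class = "igenes_empty_selection")
  expect_error(combine_selections(list(r1), "vote", vote_k = 3), "vote_k")
})

test_that("BH adjustment and the selector wrapper work end to end", {
  sim <- simulate_cigt(n_cases = 40, n_controls = 40, n_genes = 30,
                       n_informative = 3, effect_size = 2, seed = 23)
  raw <- pearson_select(sim$data)
  bh <- pearson_select(sim$data, adjust = "BH")
  expect_true(all(bh$p_adjusted >= bh$p_value))
  expect_lte(sum(bh$selected), sum(raw$selected))

  fs <- select_features(sim$data, seed = 23)
  expect_s3_class(fs, "feature_set")
  expect_true(all(sim$truth$gene %in% fs$feature))
  expect_named(attr(fs, "results"), c("pearson", "chi2", "anova", "rfe"))
  # output order follows the cohort's column order
  expect_identical(fs$feature,
                   intersect(cigt_features(sim$data), fs$feature))
})
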