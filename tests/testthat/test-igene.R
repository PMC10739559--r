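test_that("importance shares normalize mean absolute attributions", {
  phi <- cbind(a = c(2, -2), b = c(1, 1), c = c(-1, 1))
  sh <- importance_shares(fake_attribution(phi))
  expect_equal(sh$share, c(0.5, 0.25, 0.25))
  expect_false(attr(sh, "degenerate"))

  single <- importance_shares(fake_attribution(cbind(a = c(0.3, -0.7))))
  expect_equal(single$share, 1.0)

  degen <- importance_shares(fake_attribution(cbind(a = c(0, 0), b = c(0, 0))))
  expect_true(attr(degen, "degenerate"))
  expect_true(all(is.na(degen$share)))
})

test_that("HHI obeys the uniform and monopoly laws", {
  expect_equal(hhi(rep(0.25, 4)), 0.25)
  expect_equal(hhi(c(1, 0, 0)), 1.0)
  expect_equal(hhi(c(0.5, 0.3, 0.2)), 0.38)
  for (n in c(2, 5, 10)) expect_equal(hhi(rep(1 / n, n)), 1 / n)
  expect_error(hhi(c(0.5, 0.2)), "sum to 1")
  expect_error(hhi(c(1.2, -0.2)), "non-negative")
})

test_that("classifier weights are HHI-proportional, monotone, sum to one", {
  w <- classifier_weights(c(a = 0.38, b = 0.62))
  expect_equal(unname(w), c(0.38, 0.62))
  expect_equal(unname(classifier_weights(c(only = 0.7))), 1.0)
  expect_equal(unname(classifier_weights(rep(0.3, 5) |>
                                           setNames(letters[1:5]))),
               rep(0.2, 5))
  h <- c(x = 0.2, y = 0.5, z = 0.9)
  w2 <- classifier_weights(h)
  expect_equal(sum(w2), 1)
  expect_identical(order(w2), order(h))
  expect_error(classifier_weights(c(a = NA_real_)), "degenerate")
})

test_that("I-Gene scores are HHI-weighted share sums that conserve mass", {
  one <- igene_scores(list(rf = c(a = 0.5, b = 0.25, c = 0.25)),
                      c(rf = 1))
  expect_equal(one$raw, c(0.5, 0.25, 0.25))
  expect_equal(one$igene_score, c(100, 50, 50))

  two <- igene_scores(list(m1 = c(a = 1, b = 0), m2 = c(a = 0, b = 1)),
                      c(m1 = 0.5, m2 = 0.5))
  expect_equal(two$raw, c(0.5, 0.5))
  expect_equal(two$igene_score, c(100, 100))

  # conservation holds for random inputs
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p <- sample(3:8, 1)
    shares <- lapply(seq_len(k), function(j) {
      s <- runif(p); s <- s / sum(s); names(s) <- paste0("f", seq_len(p)); s
    })
    names(shares) <- paste0("c", seq_len(k))
    w <- classifier_weights(vapply(shares, hhi, numeric(1)))
    sc <- igene_scores(shares, w)
    expect_equal(sum(sc$raw), 1, tolerance = 1e-9)
    expect_equal(max(sc$igene_score), 100)
  }

  expect_error(igene_scores(list(m1 = c(a = 1), m2 = c(b = 1)),
                            c(m1 = 0.5, m2 = 0.5)),
               "feature list")
})

test_that("directionality follows the value-attribution correlation rule", {
  # attributions rising with the feature value -> overexpressed
  v <- seq(-2, 2, length.out = 20)
  up <- fake_attribution(cbind(g_up = v * 0.1, g_dn = -v * 0.1,
                               g_null = rep(0, 20)))
  x <- cbind(g_up = v, g_dn = v, g_null = v)
  dir <- igene_direction(list(toy = up), x, c(toy = 1))
  expect_equal(dir$direction, c("overexpressed", "underexpressed", "neutral"))

  # zero-variance feature is neutral with a warning
  x2 <- cbind(g_up = v, g_dn = v, g_null = rep(1, 20))
  expect_warning(dir2 <- igene_direction(list(toy = up), x2, c(toy = 1)),
                 "zero-variance")
  expect_equal(dir2$direction[3], "neutral")
})

test_that("profiles recover planted genes with correct directions", {
  sf <- small_fit()
  pr <- igene_profile(sf$model, sf$parts$test, sf$parts$train,
                      background_size = 30, n_perm = 4, seed = 11)
  expect_s3_class(pr, "igene_profile")
  expect_equal(sum(pr$raw_score), 1, tolerance = 1e-9)
  expect_setequal(pr$rank, seq_len(nrow(pr)))
  expect_equal(max(pr$igene_score), 100)

  w <- attr(pr, "classifier_weights")
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
  share_cols <- paste0("share_", w$classifier)
  for (sc in share_cols) expect_equal(sum(pr[[sc]]), 1, tolerance = 1e-9)

  truth <- sf$sim$truth
  top3 <- pr$feature[pr$rank <= 3]
  expect_gte(length(intersect(top3, truth$gene)), 2)
  called <- pr[match(truth$gene, pr$feature), ]
  expected_dir <- ifelse(truth$direction == "up_in_cases",
                         "overexpressed", "underexpressed")
  expect_equal(called$direction, expected_dir)

  gl <- generics::glance(pr)
  expect_equal(gl$raw_score_total, 1, tolerance = 1e-9)
  expect_equal(gl$n_classifiers, nrow(w))
})

test_that("profile scores are invariant to input column order", {
  sf <- small_fit()
  m1 <- train_ensemble(sf$parts$train, sf$model$feature_names,
                       members = "rf", seed = 5)
  permute_cols <- function(ds) {
    cols <- c("ID", "Type", rev(cigt_features(ds)))
    as_cigt(as.data.frame(ds)[cols])
  }
  p1 <- igene_profile(m1, sf$parts$test, sf$parts$train, method = "exact",
                      background_size = 15, seed = 5)
  p2 <- igene_profile(m1, permute_cols(sf$parts$test),
                      permute_cols(sf$parts$train), method = "exact",
                      background_size = 15, seed = 5)
  expect_equal(p1$raw_score, p2$raw_score[match(p1$feature, p2$feature)],
               tolerance = 1e-9)
  expect_equal(p1$direction, p2$direction[match(p1$feature, p2$feature)])
})
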