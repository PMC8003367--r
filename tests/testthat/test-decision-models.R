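fig4a <- c(ADCt_mean = 0.928, rADC_skewness = 0.051,
           ln_short_axis = 1.506, ADCln_skewness = 0.413e-2)
fig4b <- c(ADCt_mean = 0.779, rADC_skewness = 2.3263,
           ln_short_axis = 3.364, ADCln_skewness = 2.178e-2)

test_that("RadScore reproduces the published false-negative audits", {
  a <- radscore(fig4a); b <- radscore(fig4b)
  expect_equal(a$prediction, 0L)
  expect_equal(b$prediction, 0L)
  # decision paths are auditable and consistent with the topology
  expect_equal(a$path$feature[1], "ln_short_axis")
  expect_equal(a$path$branch[1], "left")
  # sub-threshold node size forces negativity whatever the other features
  set.seed(61)
  for (i in 1:25) {
    f <- c(ADCt_mean = runif(1, 0.5, 1.5), rADC_skewness = runif(1, 0, 3),
           ln_short_axis = 0.5, ADCln_skewness = runif(1, -0.2, 0.3))
    expect_equal(radscore(f)$prediction, 0L)
  }
  expect_error(radscore(fig4a[-2]), "missing feature")
})

test_that("RadSignature composes RadScore with grade and size as specified", {
  expect_equal(radsignature(radscore(fig4b), grade = 2, tumor_size_mm = 10)$prediction, 0L)
  expect_equal(radsignature(radscore(fig4a), grade = 2, tumor_size_mm = 65)$prediction, 0L)
  expect_equal(radsignature(1L, grade = 3, tumor_size_mm = 5)$prediction, 1L)
  expect_equal(radsignature(1L, grade = 1, tumor_size_mm = 25)$prediction, 1L)
  # grade 1-2 under 20 mm is always negative (clinical low-risk exclusion)
  expect_equal(radsignature(1L, grade = 2, tumor_size_mm = 19.9)$prediction, 0L)
  expect_error(radsignature(1L, grade = 4, tumor_size_mm = 10), "grade")
})

test_that("RadSignature positivity implies RadScore positivity (rule nesting)", {
  set.seed(62)
  for (i in 1:200) {
    f <- c(ADCt_mean = runif(1, 0.5, 1.5), rADC_skewness = runif(1, 0, 3),
           ln_short_axis = runif(1, 0.3, 5), ADCln_skewness = runif(1, -0.2, 0.3))
    rs <- radscore(f)
    sig <- radsignature(rs, grade = sample(3, 1), tumor_size_mm = runif(1, 5, 60))
    if (sig$prediction == 1L) expect_equal(rs$prediction, 1L)
  }
})

test_that("threshold models use strict comparisons and are monotone", {
  expect_equal(threshold_model(1.0e0, 1.1, "below"), 1L)   # ADC model positive
  expect_equal(threshold_model(5.0, 5, "above"), 0L)       # boundary is negative
  expect_equal(threshold_model(5.1, 5, "above"), 1L)
  x <- sort(runif(50, 0, 10))
  p <- threshold_model(x, 5, "above")
  expect_true(all(diff(p) >= 0))                           # monotone in the feature
  p2 <- threshold_model(x, 5, "below")
  expect_true(all(diff(p2) <= 0))
  expect_error(threshold_model(NA_real_, 1, "below"), "finite")
})

test_that("CART fits a perfectly separable single feature with a gap cutoff", {
  d <- data.frame(x = c(1, 2, 3, 4, 8, 9, 10, 11),
                  z = c(5, 2, 7, 1, 9, 3, 8, 2),
                  label = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- fit_cart(label ~ ., d)
  expect_equal(tree_n_leaves(fit$root), 2L)
  expect_equal(fit$root$feature, "x")
  expect_gt(fit$root$cutoff, 4); expect_lte(fit$root$cutoff, 8)
  expect_equal(predict(fit, d), d$label)
})

test_that("CART stopping rules: minsplit gate and single-class input", {
  d4 <- data.frame(x = 1:4, label = c(0, 0, 0, 1))
  fit <- fit_cart(label ~ x, d4, minsplit = 5)
  expect_true(fit$root$leaf)
  expect_equal(fit$root$class, 0L)   # majority class
  expect_warning(f1 <- fit_cart(label ~ x, data.frame(x = 1:6, label = rep(1, 6))),
                 "single-class")
  expect_true(f1$root$leaf); expect_equal(f1$root$class, 1L)
})

test_that("fitted trees respect maxdepth and minsplit structurally", {
  audit <- function(node, minsplit) {
    if (isTRUE(node$leaf)) return(invisible())
    expect_gte(node$n, minsplit)
    audit(node$left, minsplit); audit(node$right, minsplit)
  }
  set.seed(63)
  for (i in 1:50) {
    n <- sample(20:120, 1)
    d <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    d$label <- as.integer(d$a + 0.5 * d$b + rnorm(n, 0, 0.3) > 0.8)
    if (length(unique(d$label)) < 2) next
    md <- sample(1:4, 1); ms <- sample(c(2, 5, 10), 1)
    fit <- fit_cart(label ~ ., d, cp = 0.001, minsplit = ms, maxdepth = md)
    expect_lte(lnradiomics:::tree_depth(fit$root), md)
    audit(fit$root, ms)
  }
})

test_that("CART recovers the RadScore rule from noise-free labelled regions", {
  d <- generate_rule_labelled_regions(5000, radscore_model(), noise_rate = 0, seed = 17)
  feats <- setdiff(names(d), c("label", "rule_label"))
  fit <- fit_cart(stats::as.formula(paste("label ~", paste(feats, collapse = "+"))), d,
                  cp = 0.01, minsplit = 5, maxdepth = 4)
  expect_gte(mean(predict(fit, d) == d$label), 0.99)
  # every recovered cutoff lies at (or within a band half-width of) the
  # generator's exclusion band around its true cutoff
  truth <- c(ln_short_axis = 1.7, ADCt_mean = 1.1, ADCln_skewness = 0.072,
             rADC_skewness = 1.2)
  gaps <- attr(d, "gaps")
  for (sp in collect_splits(fit$root, d)) {
    if (sp$feature %in% names(truth)) {
      band_dist <- max(0, abs(sp$cutoff - truth[sp$feature]) - gaps[[sp$feature]])
      expect_lte(band_dist, gaps[[sp$feature]] + 1e-12)
    }
  }
})

test_that("CART agrees with an independent rpart fit on separable data", {
  library(rpart)
  d <- generate_rule_labelled_regions(1500, radscore_model(), noise_rate = 0, seed = 19)
  feats <- setdiff(names(d), c("label", "rule_label"))
  fml <- stats::as.formula(paste("label ~", paste(feats, collapse = "+")))
  mine <- fit_cart(fml, d, class_weights = "equal", cp = 0.01, minsplit = 5, maxdepth = 4)
  ref <- rpart(factor(label) ~ ., data = d[c(feats, "label")], method = "class",
               control = rpart.control(cp = 0.01, minsplit = 5, maxdepth = 4, xval = 0))
  pred_ref <- as.integer(as.character(predict(ref, d, type = "class")))
  expect_gte(mean(predict(mine, d) == pred_ref), 0.99)
  ref_feats <- unique(as.character(ref$frame$var[ref$frame$var != "<leaf>"]))
  expect_setequal(lnradiomics:::tree_features(mine$root), ref_feats)
})

test_that("repeated cross-validation selects and prunes as specified", {
  # noiseless separable data: selection equals the plain fit
  d <- generate_rule_labelled_regions(600, radscore_model(), noise_rate = 0, seed = 23)
  feats <- setdiff(names(d), c("label", "rule_label"))
  fml <- stats::as.formula(paste("label ~", paste(feats, collapse = "+")))
  cv <- repeated_cv(fml, d, folds = 5, repeats = 2, cp_grid = c(0.001, 0.01, 0.05),
                    seed = 3)
  full <- fit_cart(fml, d, cp = cv$selected_cp)
  expect_identical(predict(cv$model, d), predict(full, d))
  expect_gte(mean(predict(cv$model, d) == d$label), 0.99)
  # pure-noise labels: a coarse grid selects the root leaf
  set.seed(24)
  dn <- data.frame(a = runif(300), b = runif(300), label = rbinom(300, 1, 0.5))
  cvn <- repeated_cv(label ~ ., dn, folds = 5, repeats = 2,
                     cp_grid = c(0.01, 0.1, 0.5), seed = 4)
  expect_true(cvn$model$root$leaf)
  # determinism under a fixed seed
  cv2 <- repeated_cv(fml, d, folds = 5, repeats = 2, cp_grid = c(0.001, 0.01, 0.05),
                     seed = 3)
  expect_identical(cv$cv_table, cv2$cv_table)
  expect_identical(cv$selected_cp, cv2$selected_cp)
  # fewer positives than folds: folds reduced with a warning
  ds <- data.frame(x = c(rnorm(40), rnorm(3, 4)), label = rep(c(0, 1), c(40, 3)))
  expect_warning(repeated_cv(label ~ x, ds, folds = 10, repeats = 1, seed = 1),
                 "folds")
})

test_that("Youden cutoffs match exhaustive threshold enumeration", {
  # perfect separation
  y <- youden_cutoff(c(1, 2, 8, 9), c(1, 1, 0, 0), direction = "below")
  expect_equal(y$J, 1); expect_equal(y$cutoff, 5)
  # uninformative marker: identical score multisets per class
  y0 <- youden_cutoff(rep(c(1, 2, 3), each = 2), rep(c(0, 1), 3), direction = "above")
  expect_equal(y0$J, 0)
  set.seed(64)
  for (i in 1:100) {
    sc <- round(rnorm(40), 2)
    lb <- rbinom(40, 1, 0.4)
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    dir <- sample(c("above", "below"), 1)
    got <- youden_cutoff(sc, lb, dir)
    want <- oracle_youden(sc, lb, dir)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
  expect_error(youden_cutoff(1:5, rep(1, 5), "above"), "both classes")
})

test_that("tree JSON serialisation round-trips structurally", {
  m <- radscore_model()
  m2 <- tree_from_json(tree_to_json(m))
  expect_equal(m2$root, m$root)
  expect_equal(m2$provenance, m$provenance)
  f <- tempfile(fileext = ".json")
  tree_to_json(m, f)
  m3 <- tree_from_json(path = f)
  d <- generate_rule_labelled_regions(200, m, seed = 2)
  expect_identical(predict(m3, d), predict(m, d))
})
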