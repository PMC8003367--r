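test_that("confusion counts match the elementwise tally oracle", {
  c1 <- confusion(rep(1, 4), rep(1, 4))
  expect_equal(unlist(c1[c("TP", "TN", "FP", "FN")]), c(TP = 4L, TN = 0L, FP = 0L, FN = 0L))
  c2 <- confusion(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(c2$TP + c2$TN, 0L)
  set.seed(71)
  for (i in 1:50) {
    pred <- rbinom(100, 1, 0.4); truth <- rbinom(100, 1, 0.2)
    got <- confusion(pred, truth)
    want <- oracle_confusion(pred, truth)
    expect_equal(unlist(got[c("TP", "TN", "FP", "FN")]), want)
  }
  expect_error(confusion(1, c(1, 0)), "length")
})

test_that("metrics carry exact Clopper-Pearson intervals and handle boundaries", {
  m <- metrics_with_ci(confusion_counts(TP = 22, TN = 267, FP = 40, FN = 1))
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(as_pct(sens$estimate), 95.7)
  expect_equal(as_pct(sens$lower), 78.1)
  expect_equal(as_pct(sens$upper), 99.9)
  # n/n boundary: one-sided exact bound
  m2 <- metrics_with_ci(confusion_counts(TP = 14, TN = 14, FP = 7, FN = 0))
  s2 <- m2[m2$metric == "sensitivity", ]
  expect_equal(as_pct(s2$estimate), 100.0)
  expect_equal(as_pct(s2$lower), 76.8)
  expect_equal(s2$upper, 1)
  # zero denominator: undefined, not an error
  m3 <- metrics_with_ci(confusion_counts(TP = 0, TN = 5, FP = 2, FN = 0))
  expect_true(is.na(m3$estimate[m3$metric == "sensitivity"]))
  # intervals always bracket the estimate
  set.seed(72)
  for (i in 1:50) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    mm <- metrics_with_ci(cc)
    ok <- !is.na(mm$estimate)
    expect_true(all(mm$lower[ok] <= mm$estimate[ok] + 1e-12))
    expect_true(all(mm$upper[ok] >= mm$estimate[ok] - 1e-12))
    expect_true(all(mm$lower[ok] >= 0 & mm$upper[ok] <= 1))
  }
})

test_that("exact McNemar equals binomial tail enumeration", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(6, 0), 0.03125)
  expect_equal(mcnemar_exact(7, 0), 0.015625)
  expect_equal(mcnemar_exact(3, 5), mcnemar_exact(5, 3))
  for (b in 0:8) for (cc in 0:8)
    expect_equal(mcnemar_exact(b, cc), oracle_mcnemar(b, cc), tolerance = 1e-14)
})

test_that("DeLong AUC equals the Mann-Whitney/trapezoidal area and pROC agrees", {
  set.seed(73)
  truth <- rep(c(1, 0), c(15, 15))
  sa <- rnorm(30) + truth; sb <- rnorm(30) + 0.5 * truth
  # identical models: zero difference, p = 1
  same <- delong_test(sa, sa, truth)
  expect_equal(same$diff, 0); expect_equal(same$p_value, 1)
  # perfect ranking
  expect_equal(auc_mw(truth * 2 + truth, truth), 1)
  # tie-free data: AUC equals pROC trapezoidal area to 1e-12
  library(pROC)
  r_a <- roc(truth, sa, quiet = TRUE, direction = "<")
  expect_equal(auc_mw(sa, truth), as.numeric(auc(r_a)), tolerance = 1e-12)
  # full paired test agrees with pROC's DeLong implementation
  got <- delong_test(sa, sb, truth)
  ref <- roc.test(r_a, roc(truth, sb, quiet = TRUE, direction = "<"),
                  method = "delong", paired = TRUE)
  expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(got$auc_a - got$auc_b,
               as.numeric(auc(r_a)) - as.numeric(ref$roc2$auc), tolerance = 1e-12)
  expect_error(delong_test(sa, sb, rep(1, 30)), "both classes")
})

test_that("bootstrap metric intervals behave as specified", {
  truth <- rep(c(1, 0), c(20, 40))
  # degenerate perfect classifier: intervals collapse at 100%
  bs <- bootstrap_metrics(truth, truth, reps = 200, seed = 5)
  expect_true(all(bs$ci == 1))
  # seed determinism
  pred <- c(rep(1, 15), rep(0, 5), rep(1, 8), rep(0, 32))
  b1 <- bootstrap_metrics(pred, truth, reps = 300, seed = 9)
  b2 <- bootstrap_metrics(pred, truth, reps = 300, seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_error(bootstrap_metrics(pred, truth, reps = 50), "reps")
  # large-n Bernoulli: bootstrap CI width within 20% of the analytic exact width
  set.seed(74)
  n <- 4000
  tr <- rep(1, n); pr <- rbinom(n, 1, 0.9)   # sensitivity-only setup
  bb <- bootstrap_metrics(pr, tr, reps = 600, seed = 6)
  ana <- clopper_pearson(sum(pr), n)
  expect_lt(abs(diff(bb$ci["sensitivity", ]) - diff(ana)) / diff(ana), 0.2)
  # cluster bootstrap keeps patients together and stays seed-deterministic
  cl <- rep(1:30, each = 2)
  cb <- bootstrap_metrics(pred, truth, reps = 200, seed = 2, cluster = cl)
  expect_identical(cb$ci, bootstrap_metrics(pred, truth, reps = 200, seed = 2, cluster = cl)$ci)
})

test_that("stratified patient-level split reproduces the 70/30 bookkeeping", {
  p <- data.frame(patient_id = sprintf("P%03d", 1:236),
                  label = rep(c(1, 0), c(23, 213)))
  s <- split_train_test(p, fraction = 0.70, seed = 31)
  expect_length(s$train, 165); expect_length(s$test, 71)
  expect_equal(sum(p$label[p$patient_id %in% s$train]), 16)
  expect_equal(sum(p$label[p$patient_id %in% s$test]), 7)
  expect_length(intersect(s$train, s$test), 0)
  # boundary and determinism
  s1 <- split_train_test(p, fraction = 1.0, seed = 1)
  expect_length(s1$test, 0)
  expect_identical(split_train_test(p, seed = 8), split_train_test(p, seed = 8))
  expect_warning(split_train_test(data.frame(patient_id = 1:3, label = c(1, 0, 0)),
                                  0.5, seed = 1),
                 "single member")
})

test_that("patient aggregation is the OR rule and matches a group-by oracle", {
  r <- data.frame(patient_id = c("a", "a", "b", "b"), pred = c(0, 1, 0, 0))
  a <- aggregate_to_patient(r)
  expect_equal(a$pred[a$patient_id == "a"], 1L)
  expect_equal(a$pred[a$patient_id == "b"], 0L)
  set.seed(75)
  rr <- data.frame(patient_id = rep(sprintf("p%02d", 1:100), each = 2),
                   pred = rbinom(200, 1, 0.3), label = rbinom(200, 1, 0.1))
  got <- aggregate_to_patient(rr, c("pred", "label"))
  for (cn in c("pred", "label")) {
    want <- tapply(rr[[cn]], rr$patient_id, function(v) as.integer(any(v == 1)))
    expect_equal(got[[cn]], as.integer(want[got$patient_id]))
    # never more patient positives than region positives
    expect_lte(sum(got[[cn]]), sum(rr[[cn]]))
  }
  expect_error(aggregate_to_patient(data.frame(x = 1)), "patient")
  expect_error(aggregate_to_patient(r, "nope"), "unknown column")
})

test_that("ESGO-ESMO risk groups follow the guideline definitions", {
  expect_equal(risk_group("IA", 1, 0), "low")
  expect_equal(risk_group("IA", 2, 0), "low")
  expect_equal(risk_group("IB", 2, 0), "intermediate")
  expect_equal(risk_group("IA", 3, 0), "intermediate")
  expect_equal(risk_group("IB", 3, 0), "high")
  # non-endometrioid is high at any stage and grade
  expect_equal(risk_group("IA", 1, 1), "high")
  expect_equal(risk_group(c("IA", "IB", "II"), c(1, 2, 1), c(0, 0, 0)),
               c("low", "intermediate", "high"))
  expect_error(risk_group("IA", 5, 0), "grade")
})
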