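#' Confusion counts from paired predictions and truth
#'
#' @param pred,truth equal-length binary vectors (0/1 or logical).
#' @return list of class `confusion` with integer fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least one pair")
  if (!all(pred %in% 0:1) || !all(truth %in% 0:1)) stop("inputs must be binary")
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion")
}

#' @rdname confusion
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN >= 1)
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (n=%d)\n", x$TP, x$TN, x$FP, x$FN,
              x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x successes; @param n trials; @param level confidence level.
#' @return numeric c(lower, upper) as proportions; boundary cases 0/n and n/n
#'   take one-sided exact bounds.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1L) return(c(NA_real_, NA_real_))
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from a 2x2 table, each with
#' an exact Clopper-Pearson interval. A metric whose denominator is zero is
#' reported as `NA` (undefined), not an error.
#'
#' @param c a `confusion` object (see [confusion()] / [confusion_counts()]).
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `x`, `n`, `method`; proportions in [0, 1].
#' @export
metrics_with_ci <- function(c, level = 0.95) {
  defs <- list(sensitivity = c(c$TP, c$TP + c$FN),
               specificity = c(c$TN, c$TN + c$FP),
               accuracy = c(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN),
               ppv = c(c$TP, c$TP + c$FP),
               npv = c(c$TN, c$TN + c$FN))
  rows <- lapply(names(defs), function(m) {
    x <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0) return(data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                                  upper = NA_real_, x = x, n = n,
                                  method = "clopper-pearson"))
    ci <- clopper_pearson(x, n, level)
    data.frame(metric = m, estimate = x / n, lower = ci[1], upper = ci[2],
               x = x, n = n, method = "clopper-pearson")
  })
  do.call(rbind, rows)
}

#' Percentage rounding matching diagnostic-accuracy table formatting
#'
#' Half-up rounding of a proportion to one decimal, in percent (base R's
#' `round` rounds half to even, which does not match printed tables).
#'
#' @param p proportion in [0, 1]; @param digits decimals (default 1).
#' @export
as_pct <- function(p, digits = 1) {
  floor(p * 100 * 10^digits + 0.5) / 10^digits
}

#' Exact McNemar test on discordant pairs
#'
#' Exact two-sided binomial test of the discordant counts between two paired
#' classifiers at p = 0.5: p-value = min(1, 2 x smaller binomial tail). With
#' no discordant pairs the p-value is 1.
#'
#' @param b discordant count where only model A is correct.
#' @param c discordant count where only model B is correct.
#' @return The exact two-sided p-value.
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Paired AUC comparison by the DeLong method
#'
#' AUC is the tie-corrected Mann-Whitney statistic (ties count 1/2). The
#' variance of the paired AUC difference uses DeLong placement values: with
#' placements V10 (per positive case) and V01 (per negative case) for each
#' model, var(dAUC) = [s10_aa + s10_bb - 2 s10_ab]/m + [s01_aa + s01_bb -
#' 2 s01_ab]/n_neg, and the two-sided p-value is normal-based.
#'
#' @param scores_a,scores_b paired marker values (higher = more positive).
#' @param truth binary truth, both classes present.
#' @param k_comparisons number of pairwise comparisons for the Bonferroni
#'   significance flag (default 1).
#' @param alpha family significance level (default 0.05).
#' @return list of class `roc_comparison`: `auc_a`, `auc_b`, `diff`, `var`,
#'   `z`, `p_value`, `bonferroni_significant`.
#' @export
delong_test <- function(scores_a, scores_b, truth, k_comparisons = 1, alpha = 0.05) {
  truth <- as.integer(truth)
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth))
    stop("length mismatch")
  pos <- truth == 1L; neg <- truth == 0L
  if (!any(pos) || !any(neg)) stop("both classes must be present in `truth`")
  m <- sum(pos); n0 <- sum(neg)

  placements <- function(s) {
    psi <- outer(s[pos], s[neg], function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  cov0 <- function(x, y) if (length(x) < 2) 0 else stats::cov(x, y)
  v <- (cov0(pa$v10, pa$v10) + cov0(pb$v10, pb$v10) - 2 * cov0(pa$v10, pb$v10)) / m +
       (cov0(pa$v01, pa$v01) + cov0(pb$v01, pb$v01) - 2 * cov0(pa$v01, pb$v01)) / n0
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(d) < 1e-15) 0 else sign(d) * Inf
  } else z <- d / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, var = v, z = z,
                 p_value = p,
                 bonferroni_significant = p < alpha / k_comparisons),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC A = %.4f, AUC B = %.4f, diff = %+.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$diff, x$z, x$p_value,
              if (x$bonferroni_significant) " (significant after Bonferroni)" else ""))
  invisible(x)
}

#' AUC of a single marker (tie-corrected Mann-Whitney)
#'
#' @inheritParams delong_test
#' @param scores marker values (higher = more positive).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, truth) {
  truth <- as.integer(truth)
  pos <- scores[truth == 1L]; neg <- scores[truth == 0L]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  mean(outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y)))
}

#' Bootstrap confidence intervals for diagnostic metrics
#'
#' Resamples cases (or whole patients, when `cluster` is given) with
#' replacement, recomputes the five metrics per replicate and reports
#' percentile 2.5/97.5 intervals. Replicates whose resample lacks positive
#' (or negative) truth are skipped and counted.
#'
#' @param pred,truth binary vectors.
#' @param reps replicates (>= 100).
#' @param seed RNG seed (results are seed-deterministic).
#' @param cluster optional vector of patient ids; resampling is then by
#'   cluster (all of a patient's regions enter together).
#' @param level confidence level.
#' @return list: `ci` (matrix metric x lower/upper), `estimate`, `reps_used`,
#'   `skipped`.
#' @export
bootstrap_metrics <- function(pred, truth, reps = 1000, seed = 1L,
                              cluster = NULL, level = 0.95) {
  if (reps < 100) stop("reps must be >= 100")
  pred <- as.integer(pred); truth <- as.integer(truth)
  set.seed(seed)
  mets <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  point <- stats::setNames(metrics_with_ci(confusion(pred, truth))$estimate, mets)
  draws <- matrix(NA_real_, reps, length(mets), dimnames = list(NULL, mets))
  skipped <- 0L
  cl <- if (is.null(cluster)) NULL else split(seq_along(pred), cluster)
  for (r in seq_len(reps)) {
    idx <- if (is.null(cl)) sample(length(pred), replace = TRUE)
           else unlist(cl[sample(length(cl), replace = TRUE)], use.names = FALSE)
    tr <- truth[idx]
    if (!any(tr == 1L)) { skipped <- skipped + 1L; next }
    draws[r, ] <- metrics_with_ci(confusion(pred[idx], tr))$estimate
  }
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_) else stats::quantile(v, c(a, 1 - a))
  }))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimate = point, reps_used = reps - skipped, skipped = skipped)
}

#' Stratified patient-level train/test split
#'
#' Splits patients (never regions) so that no patient's regions straddle the
#' sets; stratification is by the patient-level label, with per-class training
#' counts `round(fraction * n_class)`. A 236-patient cohort with 23 positives
#' at fraction 0.70 yields 165 training (16 positive) and 71 test (7
#' positive) patients.
#'
#' @param patients data.frame with columns `patient_id` and `label` (0/1).
#' @param fraction training fraction (default 0.70).
#' @param stratified stratify by label (default TRUE).
#' @param seed RNG seed.
#' @return list with `train` and `test` patient-id vectors.
#' @export
split_train_test <- function(patients, fraction = 0.70, stratified = TRUE, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(patients)),
            fraction >= 0, fraction <= 1)
  set.seed(seed)
  ids <- patients$patient_id; lab <- as.integer(patients$label)
  train <- c()
  groups <- if (stratified) split(ids, lab) else list(ids)
  for (g in groups) {
    if (length(g) == 1L) {
      warning("class with a single member assigned to the training set")
      train <- c(train, g)
    } else {
      k <- round(fraction * length(g))
      train <- c(train, sample(g, k))
    }
  }
  list(train = train, test = setdiff(ids, train))
}

#' Aggregate region-level predictions to the patient level
#'
#' A patient is positive when any of their regions is positive (logical OR) —
#' the only order-preserving aggregation rule.
#'
#' @param regions data.frame with a `patient_id` column.
#' @param cols names of binary columns to aggregate (default `"pred"`).
#' @return data.frame with one row per patient, `patient_id` plus the
#'   OR-aggregated columns.
#' @export
aggregate_to_patient <- function(regions, cols = "pred") {
  if (!"patient_id" %in% names(regions)) stop("unknown patient key: need `patient_id`")
  missing <- setdiff(cols, names(regions))
  if (length(missing)) stop(sprintf("unknown column(s): %s", paste(missing, collapse = ", ")))
  ids <- unique(regions$patient_id)
  out <- data.frame(patient_id = ids)
  for (cn in cols) {
    agg <- tapply(as.integer(regions[[cn]]), regions$patient_id, function(v) as.integer(any(v == 1L)))
    out[[cn]] <- as.integer(agg[as.character(ids)])
  }
  out
}

#' ESGO-ESMO risk group classification
#'
#' Low risk: stage IA, grade 1-2, endometrioid. Intermediate: stage IA
#' grade 3 endometrioid, or stage IB grade 1-2 endometrioid. High: stage IB
#' grade 3 endometrioid, or non-endometrioid histology at any stage and
#' grade; endometrioid disease beyond stage IB is also classified high.
#'
#' @param stage character vector, `"IA"`, `"IB"` or other.
#' @param grade integer vector in \{1, 2, 3\}.
#' @param histology 0 = endometrioid, 1 = non-endometrioid (logical accepted).
#' @return character vector: `"low"`, `"intermediate"` or `"high"`.
#' @export
risk_group <- function(stage, grade, histology) {
  grade <- as.integer(grade)
  if (!all(grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  histology <- as.integer(histology)
  n <- max(length(stage), length(grade), length(histology))
  stage <- rep_len(as.character(stage), n)
  grade <- rep_len(grade, n); histology <- rep_len(histology, n)
  out <- rep("high", n)
  endo <- histology == 0L
  out[endo & stage == "IA" & grade <= 2L] <- "low"
  out[endo & ((stage == "IA" & grade == 3L) | (stage == "IB" & grade <= 2L))] <- "intermediate"
  out
}
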