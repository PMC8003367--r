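#' First-order histogram statistics of an ADC value set
#'
#' The 12 histogram-derived statistics computed for every ADC class: mean,
#' minimum, maximum, the 10th/25th/50th/75th/90th percentiles, skewness,
#' kurtosis, standard deviation and variation (coefficient of variation).
#'
#' Moments use population (n) normalisation: skewness = m3 / m2^1.5 and
#' kurtosis = m4 / m2^2 (not excess kurtosis) with mk the k-th central moment;
#' SD = sqrt(m2). Percentiles interpolate linearly between order statistics
#' (type 7); the convention matters here because most lymph-node regions hold
#' fewer than 100 voxels. A constant input has SD 0 and skewness, kurtosis and
#' variation defined as 0.
#'
#' @param values numeric vector of at least one finite value.
#' @param bias_correct logical; if `TRUE` use the sample (n-1) SD and the
#'   adjusted Fisher-Pearson skewness/kurtosis instead of the population forms.
#' @return Named numeric vector of length 12, names
#'   `mean, min, max, p10, p25, p50, p75, p90, skewness, kurtosis, sd, variation`.
#' @export
histogram_stats <- function(values, bias_correct = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("`values` must contain at least one finite value and no NA/Inf")
  n <- length(values)
  mu <- mean(values)
  q <- stats::quantile(values, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
  d <- values - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (m2 <= 0) {
    sk <- 0; ku <- 0; sdv <- 0; cv <- 0
  } else {
    sk <- m3 / m2^1.5
    ku <- m4 / m2^2
    sdv <- sqrt(m2)
    if (bias_correct) {
      sdv <- sqrt(m2 * n / (n - 1))
      if (n > 2) sk <- sk * sqrt(n * (n - 1)) / (n - 2)
      if (n > 3) ku <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (ku - 3) + 6) + 3
    }
    cv <- if (mu != 0) sdv / mu else 0
  }
  c(mean = mu, min = min(values), max = max(values),
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    skewness = sk, kurtosis = ku, sd = sdv, variation = cv)
}

hist_stat_names <- c("mean", "min", "max", "p10", "p25", "p50", "p75", "p90",
                     "skewness", "kurtosis", "sd", "variation")
# statistics that carry ADC units (affected by bladder normalisation)
unit_stat_names <- c("mean", "min", "max", "p10", "p25", "p50", "p75", "p90", "sd")

#' Relative ADC feature classes (rADC, rmADC)
#'
#' Two classes of relative features between the lymph-node and tumor ADC
#' distributions. `rmADC` is the full histogram of per-voxel absolute
#' differences from the tumor mean, `{|v - mean(tumor)| : v in LN}`. `rADC`
#' is the statistic-wise absolute difference `|stat(LN) - stat(tumor)|` for
#' each of the 12 statistics — node and tumor hold different voxel counts, so
#' no voxel pairing exists and the statistic-wise definition is the one that
#' keeps quantities like the rADC skewness well defined.
#'
#' @param ln_values,tumor_values nonempty numeric vectors of ADC values.
#' @inheritParams histogram_stats
#' @return list with elements `rADC` and `rmADC`, each a 12-statistic vector
#'   as from [histogram_stats()].
#' @export
relative_features <- function(ln_values, tumor_values, bias_correct = FALSE) {
  if (length(ln_values) == 0L || length(tumor_values) == 0L)
    stop("LN and tumor value sets must be nonempty")
  s_ln <- histogram_stats(ln_values, bias_correct)
  s_t  <- histogram_stats(tumor_values, bias_correct)
  list(rADC  = abs(s_ln - s_t),
       rmADC = histogram_stats(abs(ln_values - mean(tumor_values)), bias_correct))
}

#' Bladder-normalised ADC features (nADC)
#'
#' Normalises the 48 raw ADC features by the bladder (urine) reference to
#' reduce scanner variability. Unit-carrying statistics (mean, min, max,
#' percentiles, SD) are divided by the bladder mean ADC; dimensionless
#' statistics (skewness, kurtosis, variation) are scale-free and pass through
#' unchanged — equivalently, the nADC features are the statistics of the
#' bladder-normalised voxel values, so rescaling every ADC input by a common
#' factor leaves all 48 nADC features exactly fixed.
#'
#' @param features named numeric vector of raw ADC features, names of the form
#'   `<class>_<stat>` (e.g. `ADCt_mean`).
#' @param bladder_values numeric vector of bladder-ROI ADC values (or a single
#'   precomputed bladder reference value).
#' @param reference `"mean"` (default) or `"median"` of the bladder values.
#' @return Named numeric vector of the same length, names prefixed with `n`.
#' @export
normalize_by_bladder <- function(features, bladder_values, reference = c("mean", "median")) {
  reference <- match.arg(reference)
  if (length(bladder_values) == 0L) stop("bladder ROI must be nonempty")
  ref <- if (length(bladder_values) == 1L) bladder_values
         else if (reference == "mean") mean(bladder_values) else stats::median(bladder_values)
  if (!is.finite(ref) || ref <= 0) stop("bladder reference ADC must be positive")
  stat <- sub("^.*_", "", names(features))
  out <- ifelse(stat %in% unit_stat_names, features / ref, features)
  names(out) <- paste0("n", names(features))
  out
}

#' Canonical 109-parameter feature dictionary
#'
#' The stable names and order of the full feature vector: 48 raw ADC features
#' (classes `ADCt`, `ADCln`, `rADC`, `rmADC` x 12 statistics), their 48
#' bladder-normalised twins (`n` prefix), 6 anatomical parameters and 7
#' clinical parameters.
#'
#' @return Character vector of length 109.
#' @export
feature_dictionary <- function() {
  raw <- as.vector(t(outer(c("ADCt", "ADCln", "rADC", "rmADC"),
                           hist_stat_names, paste, sep = "_")))
  c(raw, paste0("n", raw),
    c("tumor_volume", "ln_area", "ln_long_axis", "ln_short_axis",
      "ln_mean_diameter", "ln_axis_ratio"),
    clinical_fields())
}

clinical_fields <- function() {
  c("histology", "grade", "tumor_size", "low_segment",
    "deep_myometrial_invasion", "mr_ln_positive", "ca125")
}

#' Assemble the 109-parameter feature vector for one region
#'
#' Combines the four ADC histogram classes, their bladder-normalised twins,
#' the anatomical measurements and the clinical record into the canonical
#' named vector used for model development.
#'
#' @param adc an [adc_volume()] (the ADC map).
#' @param tumor_mask,ln_mask,bladder_mask `roi_mask` objects (all nonempty).
#' @param morphometry result of [compute_morphometry()] for the LN mask.
#' @param clinical named list with fields `histology` (0 endometrioid /
#'   1 non-endometrioid), `grade` (1, 2 or 3), `tumor_size` (mm),
#'   `low_segment` (0/1), `deep_myometrial_invasion` (0/1),
#'   `mr_ln_positive` (0/1), `ca125` (U/mL).
#' @inheritParams histogram_stats
#' @return Named numeric vector of length 109 in [feature_dictionary()] order.
#' @export
assemble_feature_vector <- function(adc, tumor_mask, ln_mask, bladder_mask,
                                    morphometry, clinical, bias_correct = FALSE) {
  for (f in clinical_fields())
    if (is.null(clinical[[f]]) || is.na(clinical[[f]]))
      stop(sprintf("missing clinical field '%s'", f))
  tum <- mask_to_adc_values(tumor_mask, adc)
  ln  <- mask_to_adc_values(ln_mask, adc)
  bla <- mask_to_adc_values(bladder_mask, adc)
  if (!length(tum) || !length(ln) || !length(bla)) stop("all ROIs must be nonempty")

  s_t  <- histogram_stats(tum, bias_correct)
  s_ln <- histogram_stats(ln, bias_correct)
  rel  <- relative_features(ln, tum, bias_correct)
  raw <- c(stats::setNames(s_t,  paste0("ADCt_",  hist_stat_names)),
           stats::setNames(s_ln, paste0("ADCln_", hist_stat_names)),
           stats::setNames(rel$rADC,  paste0("rADC_",  hist_stat_names)),
           stats::setNames(rel$rmADC, paste0("rmADC_", hist_stat_names)))
  nadc <- normalize_by_bladder(raw, bla)

  anat <- c(tumor_volume = sum(as_mask_array(tumor_mask)) * prod(adc$spacing),
            ln_area = morphometry$area,
            ln_long_axis = morphometry$long_axis,
            ln_short_axis = morphometry$short_axis,
            ln_mean_diameter = morphometry$mean_diameter,
            ln_axis_ratio = morphometry$axis_ratio)
  clin <- vapply(clinical_fields(), function(f) as.numeric(clinical[[f]]), numeric(1))
  out <- c(raw, nadc, anat, clin)
  stopifnot(identical(names(out), feature_dictionary()))
  out
}
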