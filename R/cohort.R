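#' Specify a synthetic endometrial-cancer cohort
#'
#' Defines the statistical structure of a simulated cohort: one row per
#' patient plus `regions_per_patient` pelvic-sidewall regions each (left and
#' right by default, matching 472 regions from 236 patients). The defaults
#' emulate the published study conditions: 9.7% patient-level positivity with
#' a bilateral-involvement rate chosen so ~7.0% of regions are positive;
#' covariate frequencies drawn class-conditionally so their marginals match
#' the published demographics table (grade 3: 18.6%, non-endometrioid: 7.2%,
#' tumor >= 20 mm: 59.3%, deep myometrial invasion: 23.3%, low-segment
#' involvement: 58.5%); metastatic nodes and the tumors of node-positive
#' patients have lower ADC; node sizes straddle the 1.7 mm short-axis cutoff.
#' CA-125 is log-normal with a class-specific location (only directionality is
#' preserved — the published means carry enormous SDs). FIGO stage is derived
#' as IB iff deep myometrial invasion is present, else IA (a documented
#' synthetic convention).
#'
#' @param n_patients number of patients (>= 2).
#' @param regions_per_patient regions per patient (default 2).
#' @param patient_pos_rate patient-level positivity probability.
#' @param bilateral_pos_rate probability that a positive patient has a second
#'   positive region (default 10/23, giving 33 positive regions per 23
#'   positive patients on average).
#' @param covariates named list of `c(neg, pos)` class-conditional
#'   probabilities for `grade3`, `non_endometrioid`, `size_ge20` (implied by
#'   the size distributions), `dmi`, `low_segment`, `mr_ln_positive`.
#' @param continuous named list of class-conditional distribution parameters
#'   for age, tumor size, the ADC features and node morphometry (see
#'   defaults).
#' @param seed RNG seed; fixes the output.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 236L,
                        regions_per_patient = 2L,
                        patient_pos_rate = 23 / 236,
                        bilateral_pos_rate = 10 / 23,
                        covariates = list(
                          grade3          = c(neg = 30 / 213, pos = 14 / 23),
                          non_endometrioid = c(neg = 9 / 213, pos = 8 / 23),
                          dmi             = c(neg = 39 / 213, pos = 16 / 23),
                          low_segment     = c(neg = 117 / 213, pos = 21 / 23),
                          mr_ln_positive  = c(neg = 0.05, pos = 0.50)),
                        continuous = list(
                          age        = list(neg = c(50.6, 11.8), pos = c(56.2, 7.7)),
                          tumor_size = list(neg = c(log(22), 0.60), pos = c(log(40), 0.60)),
                          ca125      = list(neg = c(log(25), 0.80), pos = c(log(60), 1.20)),
                          ADCt_mean  = list(neg = c(1.15, 0.12), pos = c(0.90, 0.10)),
                          ADCln_mean = list(neg = c(1.30, 0.15), pos = c(0.95, 0.12)),
                          ADCln_skewness = list(neg = c(0.00, 0.05), pos = c(0.15, 0.10)),
                          rADC_skewness  = list(neg = c(1.60, 0.50), pos = c(0.70, 0.40)),
                          ln_short_axis  = list(neg = c(log(1.2), 0.35), pos = c(log(3.0), 0.40)),
                          ln_axis_ratio  = list(neg = c(0.4, 0.8), pos = c(0.6, 0.95))),
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               regions_per_patient = as.integer(regions_per_patient),
               patient_pos_rate = patient_pos_rate,
               bilateral_pos_rate = bilateral_pos_rate,
               covariates = covariates, continuous = continuous,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_patients >= 2L, spec$regions_per_patient >= 1L)
  rates <- c(spec$patient_pos_rate, spec$bilateral_pos_rate,
             unlist(spec$covariates))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  invisible(spec)
}

draw_cc <- function(p, label) stats::rbinom(length(label), 1L, ifelse(label == 1L, p["pos"], p["neg"]))

#' Generate a synthetic patient cohort with region-level truth
#'
#' Draws patient labels, class-conditional clinical covariates and
#' region-level node features according to a [cohort_spec()]. A patient is
#' positive iff at least one of their regions is positive; region features
#' (node ADC statistics and morphometry) are drawn conditionally on the
#' region's own label, patient-level features (tumor ADC, clinical
#' covariates) on the patient label.
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` (one row per patient: id, label, clinical
#'   covariates, stage, risk group) and `regions` (one row per sidewall:
#'   patient and region keys, `label`, model features named as in
#'   [feature_dictionary()]).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  if (spec$patient_pos_rate > 0 && spec$n_patients * spec$patient_pos_rate < 1)
    warning("expected number of positive patients is below 1")
  set.seed(spec$seed)
  n <- spec$n_patients
  lab <- stats::rbinom(n, 1L, spec$patient_pos_rate)

  cc <- spec$continuous
  rnorm_cc <- function(par) stats::rnorm(n, ifelse(lab == 1L, par$pos[1], par$neg[1]),
                                         ifelse(lab == 1L, par$pos[2], par$neg[2]))
  rlnorm_cc <- function(par) stats::rlnorm(n, ifelse(lab == 1L, par$pos[1], par$neg[1]),
                                           ifelse(lab == 1L, par$pos[2], par$neg[2]))
  grade3 <- draw_cc(spec$covariates$grade3, lab)
  grade <- ifelse(grade3 == 1L, 3L, 1L + stats::rbinom(n, 1L, 0.5))
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    label = lab,
    age = rnorm_cc(cc$age),
    histology = draw_cc(spec$covariates$non_endometrioid, lab),
    grade = grade,
    tumor_size = rlnorm_cc(cc$tumor_size),
    low_segment = draw_cc(spec$covariates$low_segment, lab),
    deep_myometrial_invasion = draw_cc(spec$covariates$dmi, lab),
    mr_ln_positive = draw_cc(spec$covariates$mr_ln_positive, lab),
    ca125 = rlnorm_cc(cc$ca125),
    ADCt_mean = rnorm_cc(cc$ADCt_mean))
  patients$stage <- ifelse(patients$deep_myometrial_invasion == 1L, "IB", "IA")
  patients$risk_group <- risk_group(patients$stage, patients$grade, patients$histology)

  # region labels: a positive patient has one positive region, a second with
  # probability bilateral_pos_rate; negative patients have none
  k <- spec$regions_per_patient
  region_label <- matrix(0L, n, k)
  pos_idx <- which(lab == 1L)
  if (length(pos_idx)) {
    first <- sample(k, length(pos_idx), replace = TRUE)
    region_label[cbind(pos_idx, first)] <- 1L
    if (k > 1L) {
      extra <- stats::rbinom(length(pos_idx), 1L, spec$bilateral_pos_rate)
      for (j in seq_along(pos_idx)) {
        if (extra[j] == 1L) {
          others <- setdiff(seq_len(k), first[j])
          region_label[pos_idx[j], if (length(others) == 1L) others else sample(others, 1L)] <- 1L
        }
      }
    }
  }

  m <- n * k
  rl <- as.vector(t(region_label))
  rnormr <- function(par) stats::rnorm(m, ifelse(rl == 1L, par$pos[1], par$neg[1]),
                                       ifelse(rl == 1L, par$pos[2], par$neg[2]))
  short <- stats::rlnorm(m, ifelse(rl == 1L, cc$ln_short_axis$pos[1], cc$ln_short_axis$neg[1]),
                         ifelse(rl == 1L, cc$ln_short_axis$pos[2], cc$ln_short_axis$neg[2]))
  ratio <- stats::runif(m, ifelse(rl == 1L, cc$ln_axis_ratio$pos[1], cc$ln_axis_ratio$neg[1]),
                        ifelse(rl == 1L, cc$ln_axis_ratio$pos[2], cc$ln_axis_ratio$neg[2]))
  long <- short / ratio
  pidx <- rep(seq_len(n), each = k)
  regions <- data.frame(
    patient_id = patients$patient_id[pidx],
    region_id = paste0(patients$patient_id[pidx], "_", rep(c("L", "R", letters)[seq_len(k)], n)),
    side = rep(c("L", "R", letters)[seq_len(k)], n),
    label = rl,
    ADCt_mean = patients$ADCt_mean[pidx],
    ADCln_mean = rnormr(cc$ADCln_mean),
    ADCln_skewness = rnormr(cc$ADCln_skewness),
    rADC_skewness = rnormr(cc$rADC_skewness),
    ln_short_axis = short,
    ln_long_axis = long,
    ln_mean_diameter = (short + long) / 2,
    ln_axis_ratio = ratio,
    ln_area = pi / 4 * short * long,
    grade = patients$grade[pidx],
    histology = patients$histology[pidx],
    tumor_size = patients$tumor_size[pidx],
    low_segment = patients$low_segment[pidx],
    deep_myometrial_invasion = patients$deep_myometrial_invasion[pidx],
    mr_ln_positive = patients$mr_ln_positive[pidx],
    ca125 = patients$ca125[pidx])
  list(patients = patients, regions = regions)
}

#' Generate regions labelled by a known tree rule
#'
#' Draws feature values independently and uniformly over ranges straddling
#' the printed cutoffs, labels every region by the supplied rule, and flips
#' each label independently with probability `noise_rate`. Around every
#' cutoff the rule uses, an exclusion band of half-width
#' `gap_frac * (hi - lo)` is left empty, giving the generator a known
#' inter-class feature gap: with zero noise the cutoffs recovered by
#' [fit_cart()] can be compared against this gap.
#'
#' @param n number of regions.
#' @param rule a `tree_model`; it must reference only features present in
#'   `ranges`.
#' @param noise_rate independent label-flip probability in [0, 1].
#' @param seed RNG seed.
#' @param ranges named list of `c(lo, hi)` uniform ranges per feature; the
#'   defaults cover the four RadScore features plus two uninformative
#'   nuisance features.
#' @param gap_frac half-width of the empty band around each rule cutoff, as a
#'   fraction of the feature range (default 0.02; 0 disables the gap).
#' @return data.frame of features plus `label` (0/1) and `rule_label` (the
#'   noise-free rule output); attribute `"gaps"` records each rule feature's
#'   cutoff band half-width.
#' @export
generate_rule_labelled_regions <- function(n, rule = radscore_model(), noise_rate = 0,
                                           seed = 1L,
                                           ranges = list(ln_short_axis = c(0.5, 3.5),
                                                         ADCt_mean = c(0.7, 1.5),
                                                         ADCln_skewness = c(-0.1, 0.25),
                                                         rADC_skewness = c(0, 2.4),
                                                         ADCln_mean = c(0.7, 1.6),
                                                         ln_axis_ratio = c(0.3, 1.0)),
                                           gap_frac = 0.02) {
  stopifnot(noise_rate >= 0, noise_rate <= 1, gap_frac >= 0, gap_frac < 0.5)
  missing <- setdiff(tree_features(rule$root), names(ranges))
  if (length(missing))
    stop(sprintf("rule references feature(s) absent from `ranges`: %s",
                 paste(missing, collapse = ", ")))
  cuts <- tree_cutoffs(rule$root)
  set.seed(seed)
  gaps <- list()
  df <- as.data.frame(lapply(stats::setNames(names(ranges), names(ranges)), function(f) {
    r <- ranges[[f]]
    g <- gap_frac * (r[2] - r[1])
    cs <- cuts[[f]]
    if (is.null(cs) || g == 0) return(stats::runif(n, r[1], r[2]))
    gaps[[f]] <<- g
    # sample uniformly from the range minus the exclusion bands
    bands <- cbind(pmax(cs - g, r[1]), pmin(cs + g, r[2]))
    bands <- bands[order(bands[, 1]), , drop = FALSE]
    lo <- c(r[1], bands[, 2]); hi <- c(bands[, 1], r[2])
    keep <- hi > lo
    lo <- lo[keep]; hi <- hi[keep]
    len <- hi - lo
    u <- stats::runif(n, 0, sum(len))
    brk <- cumsum(c(0, len))
    seg <- findInterval(u, brk, rightmost.closed = TRUE)
    lo[seg] + (u - brk[seg])
  }))
  df$rule_label <- predict(rule, df)
  flip <- stats::rbinom(n, 1L, noise_rate)
  df$label <- as.integer(xor(df$rule_label == 1L, flip == 1L))
  attr(df, "gaps") <- gaps
  df
}
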