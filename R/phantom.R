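#' Specify a synthetic MR phantom
#'
#' Describes a 3-D digital phantom on a regular voxel grid: a Gaussian
#' background, an ellipsoidal tumor, a bladder (urine reference, high ADC), and
#' any number of ellipsoidal lymph-node lesions. Ellipsoid membership is by
#' voxel-centre inclusion; physical positions are (index - 1) * spacing.
#' ADC values are in 1e-3 mm^2/s, the scale on which the clinical cutoffs
#' (e.g. tumor mean ADC 1.1) are printed.
#'
#' @param shape integer vector (3), grid size in voxels.
#' @param spacing numeric (3), voxel spacing in mm.
#' @param background list(mean, sd): background ADC distribution.
#' @param tumor list(center, semi_axes, mean, sd) in mm, or `NULL`.
#' @param lesions list of lists(center, semi_axes, mean, sd, positive): LN
#'   lesions with their true metastasis label.
#' @param bladder list(center, semi_axes, mean, sd), or `NULL`.
#' @param dwi_contrast scalar mapping low ADC to high DWI signal:
#'   DWI = dwi_contrast * (adc_ceiling - ADC) + noise.
#' @param adc_ceiling ADC value mapped to zero DWI signal (default 3.5).
#' @param noise_sd Gaussian noise SD added to the DWI volume.
#' @param seed RNG seed; fixes the output bit-for-bit.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L),
                         spacing = c(0.5, 0.5, 3),
                         background = list(mean = 1.4, sd = 0.05),
                         tumor = list(center = c(10, 10, 12), semi_axes = c(6, 5, 6),
                                      mean = 0.9, sd = 0.08),
                         lesions = list(list(center = c(24, 22, 24),
                                             semi_axes = c(2.5, 1.5, 3),
                                             mean = 0.85, sd = 0.06,
                                             positive = TRUE)),
                         bladder = list(center = c(12, 24, 30), semi_axes = c(5, 5, 6),
                                        mean = 3.0, sd = 0.05),
                         dwi_contrast = 100,
                         adc_ceiling = 3.5,
                         noise_sd = 2,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               background = background, tumor = tumor, lesions = lesions,
               bladder = bladder, dwi_contrast = dwi_contrast,
               adc_ceiling = adc_ceiling, noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$shape) == 3L, all(spec$shape >= 1L),
            length(spec$spacing) == 3L, all(spec$spacing > 0),
            spec$noise_sd >= 0, spec$dwi_contrast > 0)
  check_ell <- function(e, what) {
    if (is.null(e)) return(invisible())
    if (any(e$semi_axes <= 0)) stop(sprintf("%s semi-axes must be > 0", what))
    if (!is.null(e$sd) && e$sd < 0) stop(sprintf("%s sd must be >= 0", what))
  }
  check_ell(spec$tumor, "tumor")
  check_ell(spec$bladder, "bladder")
  for (l in spec$lesions) check_ell(l, "lesion")
  # lesions must not overlap the bladder (the urine reference must stay clean)
  if (!is.null(spec$bladder) && length(spec$lesions)) {
    bl <- ellipsoid_mask(spec$shape, spec$spacing, spec$bladder$center,
                         spec$bladder$semi_axes)
    for (l in spec$lesions) {
      lm <- ellipsoid_mask(spec$shape, spec$spacing, l$center, l$semi_axes)
      if (any(lm & bl)) stop("validation error: lesion overlaps bladder")
    }
  }
  invisible(spec)
}

# Boolean mask of voxels whose centres fall inside the ellipsoid.
ellipsoid_mask <- function(shape, spacing, center, semi_axes) {
  ax <- lapply(1:3, function(k) ((seq_len(shape[k]) - 1) * spacing[k] - center[k]) / semi_axes[k])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  q <= 1
}

#' Generate a phantom ADC/DWI volume pair with ground-truth masks
#'
#' Voxel ADC values are drawn from each structure's Gaussian (structures are
#' painted in order background, tumor, bladder, lesions; later structures
#' overwrite earlier ones). The DWI volume is an affine decreasing function of
#' ADC plus Gaussian noise, so lymph nodes (low ADC) are bright on DWI.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `adc` (`adc_volume`), `dwi` (`adc_volume`, kind
#'   `"dwi"`), and `masks`: named list of `roi_mask` objects (`tumor`,
#'   `bladder`, `lesion1`, ...) plus `lesion_labels`, the true labels.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  sh <- spec$shape; sp <- spec$spacing
  n <- prod(sh)
  adc <- array(stats::rnorm(n, spec$background$mean, spec$background$sd), dim = sh)

  masks <- list()
  paint <- function(adc, e, tag) {
    m <- ellipsoid_mask(sh, sp, e$center, e$semi_axes)
    k <- sum(m)
    if (k > 0) adc[m] <- stats::rnorm(k, e$mean, e$sd)
    masks[[tag]] <<- roi_mask(m, structure = tag)
    adc
  }
  if (!is.null(spec$tumor))   adc <- paint(adc, spec$tumor, "tumor")
  if (!is.null(spec$bladder)) adc <- paint(adc, spec$bladder, "bladder")
  labels <- logical(0)
  if (length(spec$lesions)) {
    for (i in seq_along(spec$lesions)) {
      l <- spec$lesions[[i]]
      adc <- paint(adc, l, paste0("lesion", i))
      labels[i] <- isTRUE(l$positive)
    }
  }
  adc[adc < 0] <- 0
  dwi <- spec$dwi_contrast * (spec$adc_ceiling - adc)
  if (spec$noise_sd > 0) dwi <- dwi + stats::rnorm(n, 0, spec$noise_sd)

  list(adc = adc_volume(adc, sp, kind = "adc"),
       dwi = adc_volume(dwi, sp, kind = "dwi"),
       masks = masks,
       lesion_labels = labels)
}
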