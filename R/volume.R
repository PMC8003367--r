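#' ADC volume container
#'
#' A light container for a voxel grid with physical spacing, the substrate for
#' segmentation and histogram statistics. Values are apparent diffusion
#' coefficients in 1e-3 mm^2/s for ADC maps, or arbitrary intensity for
#' diffusion-weighted (DWI) volumes. Voxel indices are 1-based in R; physical
#' positions are (index - 1) * spacing at voxel centres.
#'
#' @param values numeric array (2-D or 3-D) of voxel values; all finite.
#' @param spacing numeric vector of voxel spacing in mm, one entry per axis.
#' @param kind character tag, `"adc"` or `"dwi"` (informational).
#' @return An object of class `adc_volume`: a list with elements `values`,
#'   `spacing`, `kind`.
#' @export
adc_volume <- function(values, spacing, kind = "adc") {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("`values` must be a 2-D or 3-D array")
  if (any(!is.finite(values))) stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd) stop("`spacing` must have one entry per axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("`spacing` must be positive")
  structure(list(values = values, spacing = spacing, kind = kind),
            class = "adc_volume")
}

#' @export
print.adc_volume <- function(x, ...) {
  cat(sprintf("<adc_volume [%s] spacing %s mm, kind '%s'>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$kind))
  invisible(x)
}

#' ROI mask aligned to a volume
#'
#' @param mask logical array with the shape of the parent volume.
#' @param structure character tag: `"tumor"`, `"LN"`, `"bladder"` or other.
#' @return An object of class `roi_mask` (list with `mask`, `structure`).
#' @export
roi_mask <- function(mask, structure = "LN") {
  mask <- as.array(mask)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (any(is.na(mask))) stop("mask must not contain NA")
  base::structure(list(mask = mask, structure = structure), class = "roi_mask")
}

as_mask_array <- function(x) {
  if (inherits(x, "roi_mask")) x$mask else {
    m <- as.array(x); storage.mode(m) <- "logical"; m
  }
}

as_volume_array <- function(x) {
  if (inherits(x, "adc_volume")) x$values else as.array(x)
}

volume_spacing <- function(x, spacing = NULL) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(x, "adc_volume")) return(x$spacing)
  stop("spacing must be supplied for plain arrays")
}

#' Read / write volumes and masks as NIfTI
#'
#' Volumes are written as NIfTI-1 with voxel spacing in the header (`pixdim`);
#' masks as uint8. Values round-trip at float32 precision.
#'
#' @param x an `adc_volume` or `roi_mask`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `adc_volume`; `read_mask` returns an `roi_mask`.
#' @export
write_volume <- function(x, path) {
  arr <- as_volume_array(x)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume_spacing(x)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @param kind passed to [adc_volume()].
#' @export
read_volume <- function(path, kind = "adc") {
  img <- RNifti::readNifti(path)
  adc_volume(as.array(img), RNifti::pixdim(img)[seq_along(dim(img))], kind = kind)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  arr <- as_mask_array(x)
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume
#' @param structure structure tag for the returned mask.
#' @export
read_mask <- function(path, structure = "LN") {
  img <- RNifti::readNifti(path)
  roi_mask(as.array(img) != 0, structure = structure)
}
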