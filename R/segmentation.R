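#' Seeded region growing segmentation
#'
#' Grows a region from a seed voxel on an intensity volume (typically the
#' DWI-contrast volume, on which lymph nodes are bright). Growth is queue
#' based with an adaptive mean: a candidate voxel is accepted when its
#' intensity lies within `tolerance` of the current region mean, and the mean
#' is updated on every acceptance. Each voxel is examined at most once, in a
#' deterministic first-in-first-out order, so the result is reproducible for a
#' given volume, seed and tolerance.
#'
#' @param volume an [adc_volume()] or numeric array.
#' @param seed_voxel integer vector of 1-based voxel indices (length = number
#'   of axes).
#' @param tolerance nonnegative intensity half-width around the running mean.
#' @param connectivity `"face"` (4-neighbourhood in 2-D, 6 in 3-D; default) or
#'   `"full"` (8 / 26).
#' @param max_voxels growth stops with a warning once this many voxels are
#'   accepted.
#' @return An `roi_mask` containing the seed; connected under the chosen
#'   neighbourhood by construction.
#' @export
region_grow <- function(volume, seed_voxel, tolerance, connectivity = c("face", "full"),
                        max_voxels = Inf) {
  connectivity <- match.arg(connectivity)
  arr <- as_volume_array(volume)
  dm <- dim(arr)
  nd <- length(dm)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != nd) stop("seed must have one index per axis")
  if (any(seed_voxel < 1L) || any(seed_voxel > dm)) stop("seed outside grid")
  if (!is.finite(arr[matrix(seed_voxel, 1)])) stop("seed intensity is not finite")
  if (tolerance < 0) stop("tolerance must be >= 0")

  offsets <- neighbour_offsets(nd, connectivity)
  visited <- array(FALSE, dm)
  mask <- array(FALSE, dm)

  # FIFO queue of candidate voxel coordinates (rows)
  queue <- matrix(seed_voxel, nrow = 1)
  visited[matrix(seed_voxel, 1)] <- TRUE
  total <- 0; count <- 0L
  head <- 1L
  truncated <- FALSE
  while (head <= nrow(queue)) {
    v <- queue[head, , drop = TRUE]; head <- head + 1L
    val <- arr[matrix(v, 1)]
    accept <- count == 0L || abs(val - total / count) <= tolerance
    if (!accept) next
    mask[matrix(v, 1)] <- TRUE
    total <- total + val; count <- count + 1L
    if (count >= max_voxels) { truncated <- head <= nrow(queue); break }
    nb <- sweep(offsets, 2, v, `+`)
    ok <- rep(TRUE, nrow(nb))
    for (k in seq_len(nd)) ok <- ok & nb[, k] >= 1L & nb[, k] <= dm[k]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb)) {
      new <- !visited[nb]
      nb <- nb[new, , drop = FALSE]
      if (nrow(nb)) {
        visited[nb] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  if (truncated) warning("region growing halted at max_voxels")
  roi_mask(mask, structure = "LN")
}

# Deterministic neighbour offsets: face neighbours in axis order, or the full
# Moore neighbourhood in lexicographic order.
neighbour_offsets <- function(nd, connectivity) {
  if (connectivity == "face") {
    out <- matrix(0L, 2L * nd, nd)
    for (k in seq_len(nd)) {
      out[2L * k - 1L, k] <- -1L
      out[2L * k, k] <- 1L
    }
    out
  } else {
    g <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
    g[rowSums(abs(g)) > 0L, , drop = FALSE]
  }
}

#' Automatic lymph-node morphometry
#'
#' Measures a segmented node on its largest-area axial slice (ties broken
#' toward the lowest slice index): area = voxel count x in-plane voxel area;
#' long axis = maximal pairwise distance between in-slice voxel centres (mm);
#' short axis = maximal extent perpendicular to the long-axis direction.
#' A single-voxel slice takes the voxel footprint as its axes (long = larger
#' in-plane spacing, short = smaller); a one-voxel-wide line takes the smaller
#' in-plane spacing as its short axis.
#'
#' @param mask an `roi_mask` or logical array (2-D slice or 3-D volume);
#'   nonempty.
#' @param spacing voxel spacing in mm (taken from the mask's parent volume
#'   convention: x, y in plane, z across slices).
#' @return list of class `morphometry`: `area` (mm^2), `long_axis`,
#'   `short_axis`, `mean_diameter` (mm), `axis_ratio` (short/long), `slice`
#'   (index of the measured slice, `NA` for 2-D input).
#' @export
compute_morphometry <- function(mask, spacing) {
  m <- as_mask_array(mask)
  spacing <- as.numeric(spacing)
  if (!any(m)) stop("mask is empty")
  nd <- length(dim(m))
  if (length(spacing) != nd) stop("spacing must match mask dimensionality")
  if (nd == 3L) {
    counts <- apply(m, 3, sum)
    z <- which.max(counts)            # which.max takes the lowest index on ties
    sl <- m[, , z]
  } else {
    z <- NA_integer_
    sl <- m
  }
  sp <- spacing[1:2]
  idx <- which(sl, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2])
  area <- nrow(pts) * sp[1] * sp[2]

  if (nrow(pts) == 1L) {
    long <- max(sp); short <- min(sp)
  } else {
    dmat <- as.matrix(stats::dist(pts))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    long <- dmat[ij[1], ij[2]]
    u <- pts[ij[2], ] - pts[ij[1], ]
    u <- u / sqrt(sum(u^2))
    perp <- c(-u[2], u[1])
    proj <- pts %*% perp
    short <- max(proj) - min(proj)
    if (short <= 0) short <- min(sp)   # one-voxel-wide line
    short <- min(short, long)
  }
  structure(list(area = area, long_axis = long, short_axis = short,
                 mean_diameter = (long + short) / 2,
                 axis_ratio = short / long, slice = z),
            class = "morphometry")
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf("<morphometry: area %.2f mm^2, long %.2f mm, short %.2f mm, ratio %.2f>\n",
              x$area, x$long_axis, x$short_axis, x$axis_ratio))
  invisible(x)
}

#' Extract ADC values under a mask
#'
#' Applies a (DWI-space) mask to the co-registered ADC map and returns the
#' masked voxel values in deterministic (column-major) order.
#'
#' @param mask `roi_mask` or logical array.
#' @param adc [adc_volume()] or numeric array of the same shape.
#' @return Numeric vector, one value per masked voxel.
#' @export
mask_to_adc_values <- function(mask, adc) {
  m <- as_mask_array(mask)
  a <- as_volume_array(adc)
  if (!identical(dim(m), dim(a))) stop("mask and volume shapes differ")
  a[m]
}
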