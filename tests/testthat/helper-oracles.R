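# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / enumeration, sharing no code with the package internals.

# Central moments and percentiles by direct summation over the raw values.
oracle_hist_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  # linear interpolation between order statistics: h = (n-1)p + 1
  pct <- function(p) {
    s <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  sk <- if (m2 > 0) m3 / m2^1.5 else 0
  ku <- if (m2 > 0) m4 / m2^2 else 0
  sdv <- sqrt(m2)
  cv <- if (sdv == 0) 0 else if (mu != 0) sdv / mu else 0
  c(mean = mu, min = min(x), max = max(x),
    p10 = pct(.10), p25 = pct(.25), p50 = pct(.50), p75 = pct(.75), p90 = pct(.90),
    skewness = sk, kurtosis = ku, sd = sdv, variation = cv)
}

# Voxel count of a discrete ball by brute-force centre-inclusion enumeration.
oracle_ball_count <- function(shape, spacing, center, radius) {
  count <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) for (k in seq_len(shape[3])) {
    p <- (c(i, j, k) - 1) * spacing
    if (sum(((p - center) / radius)^2) <= 1) count <- count + 1L
  }
  count
}

# Flood fill from a seed over a fixed acceptance set (|value - ref| <= tol),
# face connectivity. On two-level images this equals the adaptive-mean
# region-growing predicate.
oracle_flood_fill <- function(arr, seed, tol, ref = arr[matrix(seed, 1)]) {
  dm <- dim(arr); nd <- length(dm)
  accept <- abs(arr - ref) <= tol
  mask <- array(FALSE, dm)
  if (!accept[matrix(seed, 1)]) return(mask)
  stack <- list(seed)
  mask[matrix(seed, 1)] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (ax in seq_len(nd)) for (d in c(-1L, 1L)) {
      nb <- v; nb[ax] <- nb[ax] + d
      if (nb[ax] < 1L || nb[ax] > dm[ax]) next
      if (accept[matrix(nb, 1)] && !mask[matrix(nb, 1)]) {
        mask[matrix(nb, 1)] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  mask
}

# Long/short axes of a 2-D point set by exhaustive pairwise scan.
oracle_axes <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(c(long = 0, short = 0))
  best <- 0; bi <- c(1L, 2L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) { best <- d; bi <- c(i, j) }
  }
  u <- pts[bi[2], ] - pts[bi[1], ]; u <- u / sqrt(sum(u^2))
  proj <- numeric(n)
  for (i in 1:n) proj[i] <- -pts[i, 1] * u[2] + pts[i, 2] * u[1]
  c(long = best, short = max(proj) - min(proj))
}

# 2x2 tally by explicit elementwise loop.
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Youden scan: every midpoint, explicit counting, spec tie-breaking.
oracle_youden <- function(scores, labels, direction) {
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  best <- NULL
  for (cut in cand) {
    pred <- if (direction == "below") as.integer(scores < cut) else as.integer(scores > cut)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cutoff = cut, J = J, sens = sens)
    }
  }
  best
}

# Exact two-sided McNemar by explicit binomial tail enumeration.
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail <- sum(sapply(0:k, function(i) choose(n, i))) / 2^n
  min(1, 2 * tail)
}

# 2-D two-level fixture: background plus bright disks.
make_disks <- function(shape, bg, fg, disks) {
  arr <- array(bg, shape)
  for (d in disks) {
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
      if ((i - d$center[1])^2 + (j - d$center[2])^2 <= d$radius^2) arr[i, j] <- fg
    }
  }
  arr
}

# Digital ellipse mask (2-D), centre-inclusion.
make_ellipse_mask <- function(shape, spacing, center, semi_axes) {
  m <- array(FALSE, shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    p <- (c(i, j) - 1) * spacing
    if (sum(((p - center) / semi_axes)^2) <= 1) m[i, j] <- TRUE
  }
  m
}

# Preorder list of a fitted tree's splits with the row subset reaching each
# node (shallowest split on a feature comes first).
collect_splits <- function(node, data, rows = seq_len(nrow(data))) {
  if (isTRUE(node$leaf)) return(list())
  v <- data[[node$feature]][rows]
  c(list(list(feature = node$feature, cutoff = node$cutoff, rows = rows)),
    collect_splits(node$left, data, rows[v < node$cutoff]),
    collect_splits(node$right, data, rows[v >= node$cutoff]))
}

# First (shallowest) split on a feature: cutoff plus the empirical inter-class
# gap straddling the true cutoff within that node's subset.
first_split_gap <- function(fit, data, feature, truth_cut) {
  for (s in collect_splits(fit$root, data)) {
    if (s$feature == feature) {
      x <- data[[feature]][s$rows]
      below <- x[x < truth_cut]; above <- x[x >= truth_cut]
      if (!length(below) || !length(above)) return(NULL)
      return(list(cutoff = s$cutoff, lo = max(below), hi = min(above)))
    }
  }
  NULL
}
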