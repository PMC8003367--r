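#' Fit a weighted classification tree (CART)
#'
#' De-novo induction of a binary classification tree by greedy recursive
#' partitioning: at each node the split maximising the decrease in weighted
#' Gini impurity is taken, candidate cutoffs being midpoints between adjacent
#' distinct feature values. Growth stops at nodes with fewer than `minsplit`
#' rows, at `maxdepth`, or at purity. The grown tree is then pruned by
#' weakest-link cost-complexity pruning on weighted misclassification risk: a
#' subtree is kept only when its risk improvement per additional leaf exceeds
#' `cp` times the root risk (the standard scaled-risk-improvement convention).
#'
#' The procedure is fully deterministic given the data and column order: ties
#' between splits are broken toward the first feature in schema order, then
#' the lower cutoff; leaf-class ties go to the negative class. `seed` is
#' accepted for interface uniformity and recorded but unused (no randomness).
#'
#' @param formula model formula, e.g. `label ~ .`; the response must be
#'   binary (0/1, logical, or a two-level factor whose second level is
#'   positive).
#' @param data data.frame of numeric features.
#' @param class_weights `"inverse"` (default) for inverse-prevalence weights
#'   normalised to sum to n, `"equal"`, or a named numeric vector
#'   `c(neg = , pos = )` of per-case class weights.
#' @param cp complexity parameter (default 0.01).
#' @param minsplit minimum rows in a node to attempt a split (default 5).
#' @param maxdepth maximum tree depth (default 4; root = depth 0).
#' @param seed recorded in the fit, unused.
#' @return Object of class `c("cart_tree", "tree_model")`; supports
#'   [predict.tree_model()], `print`, `summary`, and [prune_cart()].
#' @export
fit_cart <- function(formula, data, class_weights = "inverse",
                     cp = 0.01, minsplit = 5, maxdepth = 4, seed = NULL) {
  mf <- parse_cart_formula(formula, data)
  y <- mf$y; X <- mf$X
  n <- length(y)
  if (n < 1L) stop("no rows")
  w <- resolve_class_weights(class_weights, y)
  cw <- c(neg = w[1], pos = w[2])
  wi <- ifelse(y == 1L, cw["pos"], cw["neg"])

  if (length(unique(y)) < 2L) {
    warning("single-class input: returning a root leaf")
    root <- tree_leaf(unique(y), n = n)
    root$risk <- 0
    return(new_cart(root, root, mf, cw, cp, minsplit, maxdepth, seed, root_risk = 0))
  }

  root_full <- grow_node(X, y, wi, seq_len(n), 0L, minsplit, maxdepth)
  root_risk <- node_risk(y, wi, seq_len(n))
  root <- prune_node(root_full, cp * root_risk)
  new_cart(root, root_full, mf, cw, cp, minsplit, maxdepth, seed, root_risk)
}

new_cart <- function(root, root_full, mf, cw, cp, minsplit, maxdepth, seed, root_risk) {
  structure(list(root = root, root_full = root_full,
                 provenance = "fitted",
                 control = list(cp = cp, minsplit = minsplit, maxdepth = maxdepth),
                 class_weights = cw, root_risk = root_risk,
                 response = mf$response, features = names(mf$X),
                 n = length(mf$y), seed = seed),
            class = c("cart_tree", "tree_model"))
}

parse_cart_formula <- function(formula, data) {
  response <- all.vars(formula[[2]])
  if (length(response) != 1L || !response %in% names(data))
    stop("formula must name one response present in `data`")
  rhs <- formula[[3]]
  feats <- if (identical(rhs, as.name("."))) setdiff(names(data), response)
           else intersect(all.vars(rhs), names(data))
  if (!length(feats)) stop("no predictor columns")
  y <- data[[response]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("response must be binary 0/1")
  X <- data[feats]
  for (f in feats) {
    if (!is.numeric(X[[f]])) stop(sprintf("feature '%s' must be numeric", f))
    if (any(!is.finite(X[[f]]))) stop(sprintf("feature '%s' has non-finite values", f))
  }
  list(y = y, X = X, response = response)
}

resolve_class_weights <- function(class_weights, y) {
  n <- length(y); n1 <- sum(y == 1L); n0 <- n - n1
  if (is.character(class_weights)) {
    switch(match.arg(class_weights, c("inverse", "equal")),
           inverse = c(n / (2 * max(n0, 1L)), n / (2 * max(n1, 1L))),
           equal = c(1, 1))
  } else {
    stopifnot(length(class_weights) == 2L, all(class_weights > 0))
    if (!is.null(names(class_weights)) && all(c("neg", "pos") %in% names(class_weights)))
      as.numeric(class_weights[c("neg", "pos")])
    else as.numeric(class_weights)
  }
}

# weighted misclassification risk of a node treated as a leaf
node_risk <- function(y, wi, rows) {
  w1 <- sum(wi[rows][y[rows] == 1L]); w0 <- sum(wi[rows]) - w1
  min(w0, w1)
}

node_class <- function(y, wi, rows) {
  w1 <- sum(wi[rows][y[rows] == 1L]); w0 <- sum(wi[rows]) - w1
  if (w1 > w0) 1L else 0L   # tie -> negative
}

grow_node <- function(X, y, wi, rows, depth, minsplit, maxdepth) {
  cls <- node_class(y, wi, rows)
  risk <- node_risk(y, wi, rows)
  mk_leaf <- function() { lf <- tree_leaf(cls, n = length(rows)); lf$risk <- risk; lf }
  if (length(rows) < minsplit || depth >= maxdepth || risk == 0) return(mk_leaf())

  best <- find_best_split(X, y, wi, rows)
  if (is.null(best)) return(mk_leaf())
  v <- X[[best$feature]][rows]
  left_rows <- rows[v < best$cutoff]
  right_rows <- rows[v >= best$cutoff]
  node <- tree_split(best$feature, best$cutoff,
                     grow_node(X, y, wi, left_rows, depth + 1L, minsplit, maxdepth),
                     grow_node(X, y, wi, right_rows, depth + 1L, minsplit, maxdepth))
  node$risk <- risk; node$class <- cls; node$n <- length(rows)
  node
}

# Best weighted-Gini split over all features and midpoints between adjacent
# distinct values. Strict improvement comparisons preserve schema-order /
# lower-cutoff tie-breaking.
find_best_split <- function(X, y, wi, rows) {
  yw1 <- wi[rows] * (y[rows] == 1L)
  yw <- wi[rows]
  W <- sum(yw); W1 <- sum(yw1); W0 <- W - W1
  g_node <- W - (W0^2 + W1^2) / W    # W * gini
  best <- NULL; best_gain <- 1e-12
  for (f in names(X)) {
    x <- X[[f]][rows]
    ord <- order(x)
    xs <- x[ord]
    c1 <- cumsum(yw1[ord]); cw <- cumsum(yw[ord])
    k <- length(xs)
    pos <- which(xs[-k] < xs[-1])    # valid cut positions
    if (!length(pos)) next
    WL <- cw[pos]; WL1 <- c1[pos]; WL0 <- WL - WL1
    WR <- W - WL; WR1 <- W1 - WL1; WR0 <- W0 - WL0
    gl <- WL - (WL0^2 + WL1^2) / WL
    gr <- WR - (WR0^2 + WR1^2) / WR
    gain <- g_node - gl - gr
    i <- which.max(gain)             # lowest position on ties
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      best <- list(feature = f, cutoff = (xs[pos[i]] + xs[pos[i] + 1]) / 2,
                   gain = gain[i])
    }
  }
  best
}

# Weakest-link cost-complexity pruning at penalty alpha (= cp * root risk):
# bottom-up, collapse a subtree when its risk improvement does not exceed
# alpha per additional leaf.
prune_node <- function(node, alpha) {
  if (isTRUE(node$leaf)) {
    node$subtree_risk <- node$risk; node$leaves <- 1L
    return(node)
  }
  node$left <- prune_node(node$left, alpha)
  node$right <- prune_node(node$right, alpha)
  sub_risk <- node$left$subtree_risk + node$right$subtree_risk
  leaves <- node$left$leaves + node$right$leaves
  if (node$risk - sub_risk <= alpha * (leaves - 1L) + 1e-12) {
    lf <- tree_leaf(node$class, n = node$n)
    lf$risk <- node$risk; lf$subtree_risk <- node$risk; lf$leaves <- 1L
    return(lf)
  }
  node$subtree_risk <- sub_risk; node$leaves <- leaves
  node
}

#' Re-prune a fitted tree at a different complexity parameter
#'
#' Prunes the stored fully-grown tree at a new `cp`, without refitting.
#'
#' @param model a `cart_tree`.
#' @param cp new complexity parameter.
#' @return The re-pruned `cart_tree`.
#' @export
prune_cart <- function(model, cp) {
  stopifnot(inherits(model, "cart_tree"))
  model$root <- prune_node(model$root_full, cp * model$root_risk)
  model$control$cp <- cp
  model
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("Weighted classification tree (cp = %g, minsplit = %d, maxdepth = %d)\n",
              x$control$cp, x$control$minsplit, x$control$maxdepth))
  cat(sprintf("n = %d, class weights neg/pos = %.3g/%.3g\n",
              x$n, x$class_weights["neg"], x$class_weights["pos"]))
  print_node(x$root, "")
  invisible(x)
}

#' @export
summary.cart_tree <- function(object, ...) {
  cat(sprintf("Weighted CART fit: %d rows, %d features\n", object$n, length(object$features)))
  cat(sprintf("Pruned tree: %d leaves, depth %d; root risk %.4g\n",
              tree_n_leaves(object$root), tree_depth(object$root), object$root_risk))
  cat("Features used:", paste(tree_features(object$root), collapse = ", "), "\n")
  print_node(object$root, "")
  invisible(object)
}

#' Repeated stratified cross-validation for cp selection
#'
#' Ten-fold cross-validation repeated ten times (by default): fold assignment
#' is stratified by class; for every `cp` in the grid the fully grown
#' per-fold trees are re-pruned and the held-out weighted misclassification
#' risk is averaged over all folds and repeats. The returned model is refit on
#' the full data at the risk-minimising cp (ties toward the larger cp /
#' smaller tree); the 1-SE rule is available as an option.
#'
#' @inheritParams fit_cart
#' @param folds number of folds (default 10); reduced with a warning when the
#'   minority class is smaller than `folds`.
#' @param repeats number of repetitions (default 10).
#' @param cp_grid numeric vector of complexity parameters to evaluate.
#' @param one_se if `TRUE`, select the largest cp whose mean risk is within
#'   one standard error of the minimum.
#' @param seed integer seed fixing fold assignment.
#' @return list of class `cart_cv`: `model` (the refit `cart_tree`),
#'   `cv_table` (data.frame cp / mean risk / SE), `selected_cp`.
#' @export
repeated_cv <- function(formula, data, folds = 10, repeats = 10,
                        cp_grid = c(0, 0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                        class_weights = "inverse", minsplit = 5, maxdepth = 4,
                        one_se = FALSE, seed = 1L) {
  mf <- parse_cart_formula(formula, data)
  y <- mf$y; n <- length(y)
  if (n < folds) stop("need at least `folds` rows")
  npos <- sum(y == 1L)
  if (min(npos, n - npos) < folds) {
    folds <- max(2L, min(folds, npos, n - npos))
    warning(sprintf("minority class smaller than requested folds; using %d folds", folds))
  }
  cp_grid <- sort(unique(cp_grid))
  set.seed(seed)
  risks <- matrix(NA_real_, nrow = folds * repeats, ncol = length(cp_grid))
  w_full <- resolve_class_weights(class_weights, y)
  row_w <- ifelse(y == 1L, w_full[2], w_full[1])
  r <- 0L
  for (rep in seq_len(repeats)) {
    fold_id <- integer(n)
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      r <- r + 1L
      train <- which(fold_id != f); test <- which(fold_id == f)
      fit <- suppressWarnings(
        fit_cart(formula, data[train, , drop = FALSE], class_weights = class_weights,
                 cp = 0, minsplit = minsplit, maxdepth = maxdepth))
      for (ci in seq_along(cp_grid)) {
        m <- prune_cart(fit, cp_grid[ci])
        pred <- predict(m, data[test, , drop = FALSE])
        risks[r, ci] <- sum(row_w[test] * (pred != y[test])) / sum(row_w[test])
      }
    }
  }
  mean_risk <- colMeans(risks)
  se_risk <- apply(risks, 2, stats::sd) / sqrt(nrow(risks))
  best <- if (one_se) {
    i_min <- which.min(mean_risk)
    max(which(mean_risk <= mean_risk[i_min] + se_risk[i_min]))
  } else max(which(mean_risk == min(mean_risk)))   # ties -> larger cp
  selected_cp <- cp_grid[best]
  model <- fit_cart(formula, data, class_weights = class_weights, cp = selected_cp,
                    minsplit = minsplit, maxdepth = maxdepth, seed = seed)
  structure(list(model = model,
                 cv_table = data.frame(cp = cp_grid, risk = mean_risk, se = se_risk),
                 selected_cp = selected_cp),
            class = "cart_cv")
}

#' @export
print.cart_cv <- function(x, ...) {
  cat(sprintf("Repeated CV cp selection: selected cp = %g\n", x$selected_cp))
  print(x$cv_table)
  print(x$model)
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Scans all midpoints between adjacent distinct scores and returns the cutoff
#' maximising J = sensitivity + specificity - 1. Ties are broken toward higher
#' sensitivity, then the lower cutoff. Positivity is strict in the stated
#' direction, matching [threshold_model()].
#'
#' @param scores numeric marker values.
#' @param labels binary truth (0/1 or logical).
#' @param direction `"above"`: positive iff score > cutoff (e.g. node size);
#'   `"below"`: positive iff score < cutoff (e.g. ADC).
#' @return list with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels, direction = c("above", "below")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("scores are constant")
  cand <- (s[-1] + s[-length(s)]) / 2
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  stat <- vapply(cand, function(cut) {
    pred <- threshold_model(scores, cut, direction)
    c(sens = sum(pred == 1L & labels == 1L) / npos,
      spec = sum(pred == 0L & labels == 0L) / nneg)
  }, c(sens = 0, spec = 0))
  J <- stat["sens", ] + stat["spec", ] - 1
  eps <- 1e-12
  best <- which(J > max(J) - eps)
  best <- best[stat["sens", best] >= max(stat["sens", best]) - eps]
  best <- best[which.min(cand[best])]
  list(cutoff = cand[best], J = J[best],
       sensitivity = stat["sens", best], specificity = stat["spec", best])
}
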