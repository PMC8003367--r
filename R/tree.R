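#' Binary decision-tree model
#'
#' The shared representation for both fitted CART trees and the fixed printed
#' rules. A node is either a leaf carrying a class in \{0, 1\} (negative /
#' positive) or an internal node testing `feature < cutoff`: rows with value
#' strictly below the cutoff descend to the `left` child, rows at or above it
#' to the `right`. All printed cutoffs therefore apply as strict `<` on the
#' low side and `>=` on the high side.
#'
#' @param root recursive node list (see [tree_leaf()] / [tree_split()]).
#' @param provenance `"fixed-printed"` or `"fitted"`.
#' @param control list of growth controls (`cp`, `minsplit`, `maxdepth`) for
#'   fitted trees.
#' @param class_weights named numeric weights for classes `neg`, `pos`.
#' @return Object of class `tree_model`.
#' @export
tree_model <- function(root, provenance = "fixed-printed",
                       control = NULL, class_weights = NULL) {
  validate_node(root)
  structure(list(root = root, provenance = provenance, control = control,
                 class_weights = class_weights),
            class = "tree_model")
}

#' @rdname tree_model
#' @param class leaf class, 0 (negative) or 1 (positive).
#' @param n optional training-row count at the node.
#' @export
tree_leaf <- function(class, n = NA_integer_) {
  list(leaf = TRUE, class = as.integer(class), n = n)
}

#' @rdname tree_model
#' @param feature split feature name.
#' @param cutoff split threshold; `value < cutoff` goes left.
#' @param left,right child nodes.
#' @export
tree_split <- function(feature, cutoff, left, right) {
  list(leaf = FALSE, feature = feature, cutoff = as.numeric(cutoff),
       left = left, right = right)
}

validate_node <- function(node) {
  if (isTRUE(node$leaf)) {
    if (!node$class %in% c(0L, 1L)) stop("leaf class must be 0 or 1")
  } else {
    if (is.null(node$feature) || is.null(node$cutoff))
      stop("internal node needs feature and cutoff")
    validate_node(node$left); validate_node(node$right)
  }
  invisible(node)
}

# feature -> vector of cutoffs used anywhere in the tree
tree_cutoffs <- function(node) {
  if (isTRUE(node$leaf)) return(list())
  out <- tree_cutoffs(node$left)
  r <- tree_cutoffs(node$right)
  for (nm in names(r)) out[[nm]] <- c(out[[nm]], r[[nm]])
  out[[node$feature]] <- unique(c(out[[node$feature]], node$cutoff))
  out
}

tree_features <- function(node) {
  if (isTRUE(node$leaf)) character(0)
  else unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

tree_depth <- function(node) {
  if (isTRUE(node$leaf)) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_leaves <- function(node) {
  if (isTRUE(node$leaf)) 1L else tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

#' Predict from a decision-tree model
#'
#' @param object a `tree_model` (or fitted `cart_tree`).
#' @param newdata data.frame (or named vector/list for a single case) holding
#'   every feature the tree references.
#' @param type `"class"` for a 0/1 integer vector, `"path"` for the audited
#'   decision path (single case only): a data.frame of
#'   (feature, value, cutoff, branch) rows plus the final class.
#' @param ... unused.
#' @return Integer vector of predictions, or a `rule_output` for
#'   `type = "path"`.
#' @export
predict.tree_model <- function(object, newdata, type = c("class", "path"), ...) {
  type <- match.arg(type)
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  feats <- tree_features(object$root)
  missing <- setdiff(feats, names(newdata))
  if (length(missing))
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  for (f in feats)
    if (any(!is.finite(newdata[[f]]))) stop(sprintf("feature '%s' has non-finite values", f))
  if (type == "path") {
    if (nrow(newdata) != 1L) stop("type='path' requires a single case")
    return(descend_path(object$root, newdata))
  }
  out <- integer(nrow(newdata))
  descend <- function(node, rows) {
    if (!length(rows)) return()
    if (isTRUE(node$leaf)) { out[rows] <<- node$class; return() }
    v <- newdata[[node$feature]][rows]
    left <- v < node$cutoff
    descend(node$left, rows[left])
    descend(node$right, rows[!left])
  }
  descend(object$root, seq_len(nrow(newdata)))
  out
}

descend_path <- function(node, row) {
  steps <- list()
  while (!isTRUE(node$leaf)) {
    v <- row[[node$feature]]
    br <- if (v < node$cutoff) "left" else "right"
    steps[[length(steps) + 1L]] <- data.frame(feature = node$feature, value = v,
                                              cutoff = node$cutoff, branch = br,
                                              stringsAsFactors = FALSE)
    node <- node[[br]]
  }
  structure(list(prediction = node$class,
                 path = do.call(rbind, c(steps, list(make.row.names = FALSE)))),
            class = "rule_output")
}

#' @export
print.rule_output <- function(x, ...) {
  cat(sprintf("prediction: %s\n", if (x$prediction == 1L) "positive" else "negative"))
  if (!is.null(x$path)) print(x$path)
  invisible(x)
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("<tree_model (%s): %d leaves, depth %d>\n", x$provenance,
              tree_n_leaves(x$root), tree_depth(x$root)))
  print_node(x$root, "")
  invisible(x)
}

print_node <- function(node, indent) {
  if (isTRUE(node$leaf)) {
    cat(indent, "-> ", if (node$class == 1L) "positive" else "negative", "\n", sep = "")
  } else {
    cat(indent, node$feature, " < ", format(node$cutoff), "?\n", sep = "")
    print_node(node$left, paste0(indent, "  [yes] "))
    print_node(node$right, paste0(indent, "  [no]  "))
  }
}

# ---- fixed printed rules ----------------------------------------------------

#' The RadScore rule (image-only decision tree)
#'
#' The four-cutoff image-only rule: a region is called positive when the LN
#' short-axis diameter is at least 1.7 mm, the tumor mean ADC is below
#' 1.1 (x 1e-3 mm^2/s), and either the LN ADC skewness is at least 7.2e-2 or
#' the relative-ADC skewness is below 1.2. The exact printed tree topology is
#' not fully recoverable, so this default topology — consistent with both
#' published false-negative cases — is used; any alternative can be supplied
#' as a `tree_model` (e.g. loaded from JSON via [tree_from_json()]).
#'
#' @return `radscore_model()`: the rule as a `tree_model`.
#' @export
radscore_model <- function() {
  inner <- tree_split("ADCln_skewness", 0.072,
                      left = tree_split("rADC_skewness", 1.2,
                                        left = tree_leaf(1L), right = tree_leaf(0L)),
                      right = tree_leaf(1L))
  root <- tree_split("ln_short_axis", 1.7,
                     left = tree_leaf(0L),
                     right = tree_split("ADCt_mean", 1.1,
                                        left = inner, right = tree_leaf(0L)))
  tree_model(root, provenance = "fixed-printed")
}

#' @rdname radscore_model
#' @param features named vector/list/1-row data.frame with `ln_short_axis`
#'   (mm), `ADCt_mean` (1e-3 mm^2/s), `ADCln_skewness`, `rADC_skewness`.
#' @param model alternative rule topology as a `tree_model`.
#' @return `radscore()`: a `rule_output` (binary prediction + decision path).
#' @export
radscore <- function(features, model = radscore_model()) {
  predict(model, features, type = "path")
}

#' The RadSignature composite rule
#'
#' Combines the RadScore with tumor grade (1–2 vs 3) and clinical tumor size
#' (20 mm cutoff): positive only when the RadScore is positive and the tumor
#' is grade 3 or at least 20 mm — so a grade 1–2 tumor under 20 mm is always
#' called negative, the clinical low-risk exclusion.
#'
#' @param rad a `rule_output` from [radscore()], or a 0/1/logical value.
#' @param grade tumor grade, 1, 2 or 3.
#' @param tumor_size_mm clinical tumor size in mm (>= 0).
#' @return A `rule_output` with the composite prediction and audit path.
#' @export
radsignature <- function(rad, grade, tumor_size_mm) {
  if (inherits(rad, "rule_output")) rad <- rad$prediction
  rad <- as.integer(rad)
  if (!grade %in% c(1, 2, 3)) stop("grade must be 1, 2 or 3")
  if (!is.finite(tumor_size_mm) || tumor_size_mm < 0) stop("invalid tumor size")
  clin <- grade == 3 || tumor_size_mm >= 20
  pred <- as.integer(rad == 1L && clin)
  path <- data.frame(
    feature = c("radscore", "grade", "tumor_size"),
    value = c(rad, grade, tumor_size_mm),
    cutoff = c(1, 3, 20),
    branch = c(ifelse(rad == 1L, "positive", "negative"),
               ifelse(grade == 3, "grade3", "grade1-2"),
               ifelse(tumor_size_mm >= 20, ">=20mm", "<20mm")),
    stringsAsFactors = FALSE)
  structure(list(prediction = pred, path = path), class = "rule_output")
}

#' Single-threshold models (ADC model, SA model)
#'
#' Conventional single-parameter criteria: the ADC model calls a region
#' positive when the LN mean ADC is strictly below 1.1 (x 1e-3 mm^2/s); the
#' short-axis (SA) model when the LN short-axis diameter is strictly above
#' 5 mm. Comparisons are strict in the stated direction, so a value exactly at
#' the cutoff is negative.
#'
#' @param x numeric feature values.
#' @param cutoff threshold on the same scale.
#' @param direction `"below"` (positive iff `x < cutoff`) or `"above"`
#'   (positive iff `x > cutoff`).
#' @return Integer 0/1 vector.
#' @export
threshold_model <- function(x, cutoff, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (any(!is.finite(x)) || !is.finite(cutoff)) stop("inputs must be finite")
  as.integer(if (direction == "below") x < cutoff else x > cutoff)
}

# ---- JSON serialisation -----------------------------------------------------

#' Serialise a tree model to / from JSON
#'
#' Trees round-trip structurally: nodes, cutoffs, provenance and controls are
#' preserved exactly.
#'
#' @param model a `tree_model`.
#' @param path optional file path; when given, JSON is written/read there.
#' @return `tree_to_json` returns the JSON string (invisibly if written to a
#'   file); `tree_from_json` returns the `tree_model`.
#' @export
tree_to_json <- function(model, path = NULL) {
  clean <- function(node) {
    if (isTRUE(node$leaf)) {
      out <- list(leaf = TRUE, class = node$class)
      if (!is.na(node$n)) out$n <- node$n
      out
    } else {
      list(leaf = FALSE, feature = node$feature, cutoff = node$cutoff,
           left = clean(node$left), right = clean(node$right))
    }
  }
  js <- jsonlite::toJSON(list(provenance = model$provenance,
                              control = model$control,
                              class_weights = model$class_weights,
                              root = clean(model$root)),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname tree_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
tree_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fix <- function(node) {
    if (isTRUE(node$leaf))
      tree_leaf(node$class,
                if (is.null(node$n)) NA_integer_ else as.integer(node$n))
    else tree_split(node$feature, node$cutoff, fix(node$left), fix(node$right))
  }
  tree_model(fix(x$root), provenance = x$provenance,
             control = x$control,
             class_weights = if (is.null(x$class_weights)) NULL else unlist(x$class_weights))
}
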