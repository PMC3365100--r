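# Prediction, manual tree construction, serialization and reporting.

route_one <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$split_var]]
    go_left <- if (is.null(v) || is.na(v)) node$surrogate == "left" else
      v < node$threshold
    node <- if (go_left) node$left else node$right
  }
  node$predicted
}

#' Predict classes from a classification tree
#'
#' Routes each row through the tree: `value < threshold` goes left,
#' missing values follow the majority (surrogate) branch recorded at the
#' split.
#'
#' @param object A `cart_tree`.
#' @param newdata Data frame containing the tree's split variables.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  vapply(seq_len(nrow(df)), function(i) route_one(object$node, df[i, , drop = FALSE]),
         character(1))
}

#' Build a tree node by hand
#'
#' Constructors for hand-specified trees (e.g. published decision rules):
#' `split_node()` makes an internal node, `leaf_node()` a terminal node.
#' Use [manual_tree()] to wrap the root into a predictable `cart_tree`.
#'
#' @param split_var Predictor name tested at this node.
#' @param threshold Split value; `value < threshold` goes left.
#' @param left,right Child nodes.
#' @param surrogate Branch taken when the value is missing.
#' @param class Leaf class label.
#' @return A tree node list.
#' @export
split_node <- function(split_var, threshold, left, right,
                       surrogate = c("left", "right")) {
  surrogate <- match.arg(surrogate)
  counts <- merge_counts(left$class_counts, right$class_counts)
  list(leaf = FALSE, predicted = names(counts)[which.max(counts)],
       class_counts = counts, n = sum(counts), split_var = split_var,
       threshold = threshold, surrogate = surrogate,
       left = left, right = right)
}

#' @rdname split_node
#' @param n Training count to record at the leaf (optional).
#' @export
leaf_node <- function(class, n = 1) {
  counts <- setNames(n, class)
  list(leaf = TRUE, predicted = class, class_counts = counts, n = sum(n))
}

merge_counts <- function(a, b) {
  classes <- sort(unique(c(names(a), names(b))))
  out <- setNames(numeric(length(classes)), classes)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' @rdname split_node
#' @param root Root node built from `split_node()` / `leaf_node()`.
#' @export
manual_tree <- function(root) {
  structure(list(node = root, classes = sort(names(root$class_counts)),
                 predictors = collect_vars(root), n = root$n,
                 control = tree_control(), response = "class"),
            class = "cart_tree")
}

collect_vars <- function(node) {
  if (node$leaf) character(0) else
    unique(c(node$split_var, collect_vars(node$left),
             collect_vars(node$right)))
}

#' Decision rules of a tree as text
#'
#' @param tree A `cart_tree`.
#' @return Character vector, one line per node, indented by depth.
#' @export
tree_rules <- function(tree) {
  walk <- function(node, prefix, depth) {
    pad <- strrep("  ", depth)
    if (node$leaf) {
      sprintf("%s%s-> %s (n = %d)", pad, prefix, node$predicted,
              as.integer(node$n))
    } else {
      c(sprintf("%s%s%s < %.4g ?", pad, prefix, node$split_var,
                node$threshold),
        walk(node$left, "yes: ", depth + 1),
        walk(node$right, "no:  ", depth + 1))
    }
  }
  walk(tree$node, "", 0)
}

#' Serialize a tree to JSON and back
#'
#' The JSON carries the full node structure (split variable, threshold,
#' surrogate direction, class counts, predicted class), so a reloaded
#' tree predicts identically.
#'
#' @param tree A `cart_tree`.
#' @param path Optional file; when `NULL`, the JSON string is returned.
#' @return `tree_to_json()`: the JSON string (invisibly when written to a
#'   file); `tree_from_json()`: the `cart_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  ser <- function(node) {
    base <- list(predicted = node$predicted,
                 class_counts = as.list(node$class_counts),
                 n = node$n)
    if (node$leaf) c(base, list(leaf = TRUE)) else
      c(base, list(leaf = FALSE, split_var = node$split_var,
                   threshold = node$threshold, surrogate = node$surrogate,
                   left = ser(node$left), right = ser(node$right)))
  }
  obj <- list(classes = tree$classes, predictors = tree$predictors,
              n = tree$n, response = tree$response, node = ser(tree$node))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  write_lines_csv(path, as.character(json))
  invisible(as.character(json))
}

#' @rdname tree_to_json
#' @param json A JSON string or file path produced by [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  de <- function(nd) {
    counts <- unlist(nd$class_counts)
    out <- list(leaf = isTRUE(nd$leaf), predicted = nd$predicted,
                class_counts = counts, n = nd$n)
    if (!out$leaf) {
      out$split_var <- nd$split_var
      out$threshold <- nd$threshold
      out$surrogate <- nd$surrogate
      out$left <- de(nd$left)
      out$right <- de(nd$right)
    }
    out
  }
  structure(list(node = de(obj$node),
                 classes = unlist(obj$classes),
                 predictors = as.character(unlist(obj$predictors)),
                 n = obj$n, control = tree_control(),
                 response = obj$response),
            class = "cart_tree")
}

#' Confusion matrix and per-class misclassification rates
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A list with `matrix` (square table over the union of classes,
#'   rows = truth, columns = predicted), `rates` (per-true-class
#'   misclassification fraction) and `error` (overall misclassification
#'   fraction).
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  classes <- sort(unique(c(truth, predicted)))
  f <- function(v) factor(v, levels = classes)
  m <- table(truth = f(truth), predicted = f(predicted))
  diag_n <- diag(as.matrix(m))
  row_n <- rowSums(m)
  rates <- ifelse(row_n > 0, 1 - diag_n / row_n, NA_real_)
  list(matrix = m, rates = setNames(as.numeric(rates), classes),
       error = 1 - sum(diag_n) / length(truth))
}
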