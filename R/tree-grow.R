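# Classification-tree engine: greedy binary recursive partitioning on
# continuous predictors minimizing weighted Gini impurity, followed by
# weakest-link cost-complexity pruning, k-fold cross-validation of the
# pruning path, and one-standard-deviation tree selection. Split goodness
# is evaluated on the observations where the predictor is observed;
# records with a missing value are routed down the branch that received
# the majority of the node's observed values (a majority-branch
# surrogate).

#' Growth controls for a classification tree
#'
#' Defaults grow the maximal (over-fitted) tree that cost-complexity
#' pruning then cuts back: any node with at least two observations and
#' any impurity decrease is split.
#'
#' @param min_split Minimum node size eligible for splitting.
#' @param min_leaf Minimum observations in a child.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param impurity `"gini"` (default) or `"entropy"`.
#' @return A `tree_control` list.
#' @export
tree_control <- function(min_split = 2, min_leaf = 1, max_depth = 30,
                         impurity = c("gini", "entropy")) {
  impurity <- match.arg(impurity)
  stopifnot(min_split >= 2, min_leaf >= 1, max_depth >= 1)
  structure(list(min_split = min_split, min_leaf = min_leaf,
                 max_depth = max_depth, impurity = impurity),
            class = "tree_control")
}

node_impurity <- function(counts, impurity) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  if (impurity == "gini") 1 - sum(p^2) else {
    p <- p[p > 0]
    -sum(p * log(p))
  }
}

# best split of one predictor at one node; returns NULL or
# list(threshold, decrease, surrogate)
best_split_var <- function(v, yi, n_class, min_leaf, impurity) {
  obs <- !is.na(v)
  n_miss <- sum(!obs)
  v <- v[obs]; yi <- yi[obs]
  n <- length(v)
  if (n < 2) return(NULL)
  o <- order(v)
  v <- v[o]; yi <- yi[o]
  # cumulative class counts after each sorted observation
  cum <- vapply(seq_len(n_class), function(c) cumsum(yi == c),
                numeric(n))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  tot <- cum[n, ]
  cut_ok <- which(diff(v) > 0)           # between distinct adjacent values
  if (length(cut_ok) == 0) return(NULL)
  nl <- cut_ok
  nr <- n - nl
  left_counts <- cum[cut_ok, , drop = FALSE]
  right_counts <- matrix(tot, nrow = length(cut_ok), ncol = n_class,
                         byrow = TRUE) - left_counts
  imp_parent <- node_impurity(tot, impurity)
  imp_l <- apply(left_counts, 1, node_impurity, impurity = impurity)
  imp_r <- apply(right_counts, 1, node_impurity, impurity = impurity)
  dec <- imp_parent - (nl * imp_l + nr * imp_r) / n
  # child sizes include missing values routed to the majority branch
  nl_eff <- nl + ifelse(nl >= nr, n_miss, 0)
  nr_eff <- nr + ifelse(nl >= nr, 0, n_miss)
  ok <- nl_eff >= min_leaf & nr_eff >= min_leaf & dec > 1e-12
  if (!any(ok)) return(NULL)
  dec[!ok] <- -Inf
  best <- which.max(dec)                  # first max: lowest threshold wins
  thr <- (v[cut_ok[best]] + v[cut_ok[best] + 1]) / 2
  list(threshold = thr, decrease = dec[best],
       surrogate = if (nl[best] >= nr[best]) "left" else "right")
}

grow_node <- function(X, yi, classes, control, depth) {
  n_class <- length(classes)
  counts <- tabulate(yi, nbins = n_class)
  names(counts) <- classes
  predicted <- classes[which.max(counts)]   # ties: first class in order
  leaf <- list(leaf = TRUE, predicted = predicted, class_counts = counts,
               n = sum(counts))
  if (sum(counts > 0) <= 1 || sum(counts) < control$min_split ||
      depth >= control$max_depth) {
    return(leaf)
  }
  best <- NULL
  for (j in seq_along(X)) {
    cand <- best_split_var(X[[j]], yi, n_class, control$min_leaf,
                           control$impurity)
    if (!is.null(cand) &&
        (is.null(best) || cand$decrease > best$decrease + 1e-12)) {
      best <- cand
      best$var <- names(X)[j]
      best$j <- j
    }
  }
  if (is.null(best)) return(leaf)
  v <- X[[best$j]]
  go_left <- ifelse(is.na(v), best$surrogate == "left", v < best$threshold)
  list(leaf = FALSE, predicted = predicted, class_counts = counts,
       n = sum(counts),
       split_var = best$var, threshold = best$threshold,
       surrogate = best$surrogate,
       left = grow_node(X[go_left, , drop = FALSE], yi[go_left], classes,
                        control, depth + 1),
       right = grow_node(X[!go_left, , drop = FALSE], yi[!go_left], classes,
                         control, depth + 1))
}

#' Grow a maximal classification tree
#'
#' Greedy binary recursive partitioning on continuous predictors,
#' minimizing weighted impurity (Gini by default). Candidate thresholds
#' are midpoints between consecutive distinct observed values; ties in
#' impurity go to the earlier predictor column, then the lower threshold.
#' Missing predictor values are allowed and follow the majority branch of
#' the split.
#'
#' @param data A data frame holding the response and the predictors.
#' @param formula `response ~ predictors`, e.g. `class ~ odbaX + dpsZ` or
#'   `class ~ .`.
#' @param control A [tree_control()].
#' @return A `cart_tree` object.
#' @export
#' @examples
#' d <- data.frame(x = c(.1, .2, .3, 2, 2.1),
#'                 class = c("a", "a", "a", "b", "b"))
#' fit <- grow_tree(d, class ~ x)
#' tree_rules(fit)
grow_tree <- function(data, formula, control = tree_control()) {
  mf <- parse_tree_formula(data, formula)
  X <- mf$X; y <- mf$y
  if (nrow(X) == 0) stop("no observations to fit", call. = FALSE)
  if (anyNA(y)) stop("missing class labels are not allowed", call. = FALSE)
  bad <- vapply(X, function(v) any(!is.finite(v) & !is.na(v)), logical(1))
  if (any(bad))
    stop("non-finite feature values (other than NA) in: ",
         paste(names(X)[bad], collapse = ", "), call. = FALSE)
  classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  root <- grow_node(X, yi, classes, control, depth = 0)
  structure(list(node = root, classes = classes, predictors = names(X),
                 n = nrow(X), control = control,
                 response = mf$response),
            class = "cart_tree")
}

parse_tree_formula <- function(data, formula) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3)
  response <- all.vars(formula[[2]])
  stopifnot(length(response) == 1, response %in% names(data))
  rhs <- formula[[3]]
  preds <- if (identical(rhs, quote(.))) {
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  } else {
    all.vars(rhs)
  }
  miss <- setdiff(preds, names(data))
  if (length(miss) > 0)
    stop("predictor(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.data.frame(data)[preds]
  not_num <- !vapply(X, is.numeric, logical(1))
  if (any(not_num))
    stop("predictors must be numeric: ",
         paste(preds[not_num], collapse = ", "), call. = FALSE)
  list(X = X, y = as.data.frame(data)[[response]], response = response)
}

n_leaves <- function(node) {
  if (node$leaf) 1L else n_leaves(node$left) + n_leaves(node$right)
}

# resubstitution misclassification count of a subtree
subtree_errors <- function(node) {
  if (node$leaf) {
    sum(node$class_counts) - max(node$class_counts)
  } else {
    subtree_errors(node$left) + subtree_errors(node$right)
  }
}

#' @export
print.cart_tree <- function(x, ...) {
  cat("<cart_tree> ", n_leaves(x$node), " leaves, classes: ",
      paste(x$classes, collapse = ", "), ", n = ", x$n, "\n", sep = "")
  cat(tree_rules(x), sep = "\n")
  invisible(x)
}
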