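# Weakest-link cost-complexity pruning. For an internal node t with
# subtree T_t, g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1), where R is
# the resubstitution misclassification cost as a fraction of the training
# sample. Repeatedly collapsing every node attaining the minimal g yields
# the nested sequence of optimal subtrees; the critical alpha of each step
# is that minimal g.

# minimum g(t) over internal nodes of a subtree
min_g <- function(node, n_total) {
  if (node$leaf) return(Inf)
  r_node <- (node$n - max(node$class_counts)) / n_total
  r_sub <- subtree_errors(node) / n_total
  g <- (r_node - r_sub) / (n_leaves(node) - 1)
  min(g, min_g(node$left, n_total), min_g(node$right, n_total))
}

collapse_at <- function(node, n_total, g_star, eps = 1e-12) {
  if (node$leaf) return(node)
  node$left <- collapse_at(node$left, n_total, g_star, eps)
  node$right <- collapse_at(node$right, n_total, g_star, eps)
  r_node <- (node$n - max(node$class_counts)) / n_total
  r_sub <- subtree_errors(node) / n_total
  g <- (r_node - r_sub) / (n_leaves(node) - 1)
  if (g <= g_star + eps) {
    list(leaf = TRUE, predicted = node$predicted,
         class_counts = node$class_counts, n = node$n)
  } else node
}

#' Cost-complexity pruning path of a tree
#'
#' Computes the nested sequence of optimal subtrees by weakest-link
#' pruning, from the full tree (`alpha = 0`) down to the root leaf.
#'
#' @param tree A `cart_tree` from [grow_tree()].
#' @return A `prune_path`: a list of elements with `alpha` (critical
#'   complexity penalty), `tree` (the `cart_tree` pruned to that alpha),
#'   `n_leaves` and `resub_error` (training misclassification fraction).
#'   Alphas are strictly increasing and subtree sizes strictly decreasing.
#' @export
prune_path <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  n_total <- tree$n
  cur <- tree$node
  path <- list(list(alpha = 0, tree = replace_node(tree, cur),
                    n_leaves = n_leaves(cur),
                    resub_error = subtree_errors(cur) / n_total))
  while (!cur$leaf) {
    g_star <- min_g(cur, n_total)
    cur <- collapse_at(cur, n_total, g_star)
    path[[length(path) + 1]] <- list(
      alpha = max(g_star, 0), tree = replace_node(tree, cur),
      n_leaves = n_leaves(cur),
      resub_error = subtree_errors(cur) / n_total)
  }
  # a first collapse at alpha ~ 0 supersedes the full tree
  if (length(path) > 1 && path[[2]]$alpha <= 1e-12) path <- path[-1]
  structure(path, class = "prune_path")
}

replace_node <- function(tree, node) {
  tree$node <- node
  tree
}

#' @export
print.prune_path <- function(x, ...) {
  cat("<prune_path> ", length(x), " subtree(s)\n", sep = "")
  for (el in x) {
    cat(sprintf("  alpha = %-10.5g leaves = %-4d resub error = %.4f\n",
                el$alpha, el$n_leaves, el$resub_error))
  }
  invisible(x)
}

#' Select a subtree by the one-standard-deviation rule
#'
#' Returns the subtree with the fewest leaves whose cross-validation
#' error does not exceed the minimum cross-validation error plus one
#' standard error (the SE at the minimizer).
#'
#' @param path A [prune_path()].
#' @param cv The matching [cross_validate()] table (one row per path
#'   element, columns `cv_error` and `se`).
#' @return The selected `cart_tree`.
#' @export
select_one_sd <- function(path, cv) {
  stopifnot(inherits(path, "prune_path"), nrow(cv) == length(path))
  sizes <- vapply(path, `[[`, 0, "n_leaves")
  err <- cv$cv_error
  # minimizer: smallest tree attaining the minimum CV error
  at_min <- which(err <= min(err) + 1e-12)
  m <- at_min[which.min(sizes[at_min])]
  thr <- err[m] + cv$se[m]
  ok <- which(err <= thr + 1e-12)
  pick <- ok[which.min(sizes[ok])]
  path[[pick]]$tree
}
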