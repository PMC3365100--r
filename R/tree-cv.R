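# k-fold cross-validation of a pruning path. The alphas of the full-data
# path define the candidate complexities; each fold grows and prunes its
# own tree on the remaining folds and is evaluated at the geometric-mean
# representative of each alpha interval, the standard choice for
# comparing pruning sequences across trees.

#' Cross-validate a classification-tree pruning path
#'
#' Assigns observations to `k` folds uniformly at random (from `seed`),
#' grows and prunes a tree on each training split, and scores every
#' complexity value of the full-data pruning path on the held-out folds.
#' The standard error is the standard deviation of the n held-out 0/1
#' losses divided by `sqrt(n)`.
#'
#' @param data,formula As in [grow_tree()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param control A [tree_control()].
#' @param path Optionally, a precomputed [prune_path()] of the full-data
#'   tree.
#' @param stratify Stratify fold assignment by class (default FALSE:
#'   unstratified uniform assignment).
#' @return A `cv_table` tibble with one row per path element: `size`
#'   (leaves), `alpha`, `resub_error`, `cv_error`, `se`. The matching
#'   `prune_path` is attached as `attr(, "path")`.
#' @export
cross_validate <- function(data, formula, k = 10, seed = 1,
                           control = tree_control(), path = NULL,
                           stratify = FALSE) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  mf <- parse_tree_formula(data, formula)
  n <- nrow(mf$X)
  if (n < k) stop("need at least k observations", call. = FALSE)
  if (is.null(path)) path <- prune_path(grow_tree(data, formula, control))
  alphas <- vapply(path, `[[`, 0, "alpha")
  m <- length(alphas)
  # representative alpha for each interval [alpha_i, alpha_{i+1})
  rep_alpha <- c(if (m > 1) sqrt(alphas[-m] * alphas[-1]), Inf)

  fold <- run_with_seed(seed, {
    if (stratify) {
      f <- integer(n)
      for (cl in unique(mf$y)) {
        idx <- which(mf$y == cl)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })

  loss <- matrix(NA_real_, nrow = n, ncol = m)
  df <- as.data.frame(data)
  for (f in seq_len(k)) {
    test <- fold == f
    fit_f <- grow_tree(df[!test, , drop = FALSE], formula, control)
    path_f <- prune_path(fit_f)
    alphas_f <- vapply(path_f, `[[`, 0, "alpha")
    for (i in seq_len(m)) {
      # optimal fold subtree for penalty rep_alpha[i]
      pick <- max(which(alphas_f <= rep_alpha[i]))
      pred <- predict(path_f[[pick]]$tree, df[test, , drop = FALSE])
      loss[test, i] <- as.numeric(pred != as.character(mf$y[test]))
    }
  }
  out <- tibble::tibble(
    size = vapply(path, `[[`, 0L, "n_leaves"),
    alpha = alphas,
    resub_error = vapply(path, `[[`, 0, "resub_error"),
    cv_error = colMeans(loss),
    se = apply(loss, 2, sd) / sqrt(n))
  class(out) <- c("cv_table", class(out))
  attr(out, "path") <- path
  attr(out, "k") <- k
  out
}

#' Fit, prune, cross-validate and select a classification tree
#'
#' Convenience wrapper running the full model-selection protocol: grow a
#' maximal tree, compute its cost-complexity pruning path, cross-validate
#' the path with `k` folds, and keep the smallest subtree within one
#' standard error of the minimum cross-validation error.
#'
#' @inheritParams cross_validate
#' @return A list with `tree` (the selected `cart_tree`), `cv` (the
#'   `cv_table`) and `path` (the `prune_path`).
#' @export
fit_pruned_tree <- function(data, formula, k = 10, seed = 1,
                            control = tree_control(), stratify = FALSE) {
  cv <- cross_validate(data, formula, k = k, seed = seed, control = control,
                       stratify = stratify)
  path <- attr(cv, "path")
  list(tree = select_one_sd(path, cv), cv = cv, path = path)
}
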