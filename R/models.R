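# The three model configurations used in the oystercatcher study design:
#   S3   speed only, 3 behaviour classes
#   SA3  speed + all acceleration predictors, 3 classes
#   SA8  speed + all acceleration predictors, 8 classes
# All individuals are pooled, each observation weighted equally. S3 drops
# records without a speed measurement; the acceleration models keep them
# (missing speed follows the majority branch if a split ever uses it).

#' Specification of a behaviour classification model
#'
#' @param name `"S3"`, `"SA3"` or `"SA8"`.
#' @param control A [tree_control()] for the maximal tree.
#' @param k Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return A `model_spec` list with the predictor set and class scheme.
#' @export
model_spec <- function(name = c("S3", "SA3", "SA8"),
                       control = tree_control(), k = 10, seed = 1) {
  name <- match.arg(name)
  predictors <- if (name == "S3") "speed" else feature_names()
  scheme <- if (name == "SA8") "8-class" else "3-class"
  structure(list(name = name, predictors = predictors,
                 class_scheme = scheme, control = control, k = k,
                 seed = seed),
            class = "model_spec")
}

#' Fit a behaviour classification model
#'
#' Reclassifies the labeled records into the model's class scheme, pools
#' all individuals, grows a maximal classification tree on the model's
#' predictor set, prunes it, runs k-fold cross-validation and keeps the
#' smallest subtree within one standard error of the minimum
#' cross-validation error. Both resubstitution and cross-validation-pooled
#' confusion matrices are reported, since printed per-class counts can
#' come from either.
#'
#' @param records A tibble of labeled feature vectors: the 16 predictor
#'   columns (see [extract_features()]) plus `sub_behaviour` (and
#'   `behaviour`).
#' @param spec A [model_spec()], or a model name passed to it.
#' @param ... Passed to [model_spec()] when `spec` is a name.
#' @return A `behaviour_model` with elements `spec`, `tree`, `cv`
#'   (`cv_table`), `path`, `cv_error`, `se`, `confusion_resub`,
#'   `confusion_cv`, `n_used`, `data` (the modelling frame).
#' @export
#' @examples
#' \donttest{
#' st <- simulate_study(study_config(n_birds = 1, n_days = 2,
#'                                   fix_interval_s = 300), seed = 1)
#' recs <- filter_records(label_records(st$fixes, st$segments,
#'                                      st$observations))
#' feats <- extract_features(recs)
#' fit <- fit_behaviour_model(feats, "SA3")
#' glance(fit)
#' }
fit_behaviour_model <- function(records, spec = model_spec(), ...) {
  if (is.character(spec)) spec <- model_spec(spec, ...)
  stopifnot(inherits(spec, "model_spec"))
  if (!"sub_behaviour" %in% names(records))
    stop("records must carry a sub_behaviour column", call. = FALSE)
  cls <- reclassify_behaviour(records$sub_behaviour, spec$class_scheme)
  preds <- intersect(spec$predictors, names(records))
  if (length(preds) == 0) stop("no model predictors found in records",
                               call. = FALSE)
  df <- as.data.frame(records)[preds]
  df$.class <- cls
  if (spec$name == "S3") df <- df[!is.na(df$speed), , drop = FALSE]
  if (length(unique(df$.class)) < 2)
    stop("need at least two classes after reclassification", call. = FALSE)
  formula <- stats::as.formula(paste(
    ".class ~", paste(preds, collapse = " + ")))
  cv <- cross_validate(df, formula, k = spec$k, seed = spec$seed,
                       control = spec$control)
  path <- attr(cv, "path")
  tree <- select_one_sd(path, cv)
  pick <- which(vapply(path, function(el)
    identical(el$tree$node, tree$node), logical(1)))[1]
  cv_error <- cv$cv_error[pick]

  resub_pred <- predict(tree, df)
  conf_resub <- confusion_matrix(df$.class, resub_pred)
  conf_cv <- cv_pooled_confusion(df, formula, path[[pick]]$alpha, spec)

  structure(list(spec = spec, tree = tree, cv = cv, path = path,
                 cv_error = cv_error, se = cv$se[pick],
                 confusion_resub = conf_resub, confusion_cv = conf_cv,
                 n_used = nrow(df), data = tibble::as_tibble(df)),
            class = "behaviour_model")
}

# confusion of held-out predictions pooled over folds, at the selected
# complexity
cv_pooled_confusion <- function(df, formula, alpha, spec) {
  n <- nrow(df)
  fold <- run_with_seed(spec$seed, sample(rep_len(seq_len(spec$k), n)))
  pred <- character(n)
  for (f in seq_len(spec$k)) {
    test <- fold == f
    path_f <- prune_path(grow_tree(df[!test, , drop = FALSE], formula,
                                   spec$control))
    alphas_f <- vapply(path_f, `[[`, 0, "alpha")
    pick <- max(which(alphas_f <= max(alpha, 0) + 1e-12), 1)
    pred[test] <- predict(path_f[[pick]]$tree, df[test, , drop = FALSE])
  }
  confusion_matrix(df$.class, pred)
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat("<behaviour_model ", x$spec$name, "> ", x$spec$class_scheme,
      ", n = ", x$n_used, ", CV error = ", round(x$cv_error, 3),
      " (SE ", round(x$se, 3), ")\n", sep = "")
  cat(tree_rules(x$tree), sep = "\n")
  invisible(x)
}

#' @export
predict.behaviour_model <- function(object, newdata, ...) {
  predict(object$tree, newdata, ...)
}

#' Tidy a fitted behaviour model
#'
#' One row per node of the selected tree, in the broom convention.
#'
#' @param x A `behaviour_model`.
#' @param ... Unused.
#' @return Tibble with `node`, `depth`, `leaf`, `split_var`, `threshold`,
#'   `predicted`, `n`.
#' @export
tidy.behaviour_model <- function(x, ...) {
  rows <- list()
  walk <- function(node, depth) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      depth = depth, leaf = node$leaf,
      split_var = if (node$leaf) NA_character_ else node$split_var,
      threshold = if (node$leaf) NA_real_ else node$threshold,
      predicted = node$predicted, n = as.integer(node$n))
    if (!node$leaf) {
      walk(node$left, depth + 1)
      walk(node$right, depth + 1)
    }
  }
  walk(x$tree$node, 0)
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, node = dplyr::row_number(), .before = 1)
}

#' Glance at a fitted behaviour model
#'
#' @param x A `behaviour_model`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `classes`, `n_used`, `n_leaves`,
#'   `cv_error`, `se`, `resub_error`.
#' @export
glance.behaviour_model <- function(x, ...) {
  tibble::tibble(model = x$spec$name,
                 classes = length(x$tree$classes),
                 n_used = x$n_used,
                 n_leaves = n_leaves(x$tree$node),
                 cv_error = x$cv_error, se = x$se,
                 resub_error = x$confusion_resub$error)
}

#' Variables used by a fitted model's tree
#' @param x A `behaviour_model` or `cart_tree`.
#' @return Character vector of split variables actually used.
#' @export
tree_variables <- function(x) {
  node <- if (inherits(x, "behaviour_model")) x$tree$node else x$node
  collect_vars(node)
}

#' Write model reports to a directory
#'
#' Writes the selected tree as JSON, the cross-validation table and both
#' confusion matrices as CSV, and the decision rules as text.
#'
#' @param bundle A `behaviour_model`.
#' @param out_dir Output directory, created on demand.
#' @return Invisibly, the paths written.
#' @export
report_model <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "behaviour_model"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(out_dir, tolower(bundle$spec$name))
  tree_to_json(bundle$tree, paste0(pre, "_tree.json"))
  cvt <- bundle$cv
  write.csv(as.data.frame(cvt)[c("size", "alpha", "cv_error", "se")],
            paste0(pre, "_cv.csv"), row.names = FALSE)
  write.csv(as.data.frame.matrix(bundle$confusion_resub$matrix),
            paste0(pre, "_confusion_resub.csv"))
  write.csv(as.data.frame.matrix(bundle$confusion_cv$matrix),
            paste0(pre, "_confusion_cv.csv"))
  write_lines_csv(paste0(pre, "_rules.txt"), tree_rules(bundle$tree))
  invisible(paste0(pre, c("_tree.json", "_cv.csv", "_confusion_resub.csv",
                          "_confusion_cv.csv", "_rules.txt")))
}

#' Published oystercatcher reference trees
#'
#' Hand-built trees carrying the field-calibrated decision rules for
#' oystercatcher behaviour. `reference_speed_tree()` is the speed-only
#' 3-class model: speed below 0.18 m/s is no locomotion, speed of at
#' least 3.4 m/s is flight, intermediate speeds are terrestrial
#' locomotion. `reference_accel_tree()` is the acceleration 3-class
#' model: surge ODBA below 0.09 g is no locomotion; otherwise a dominant
#' heave power spectral density of at least 5.1 g^2/Hz separates flight
#' from terrestrial locomotion.
#'
#' @return A `cart_tree` that can be used with [predict.cart_tree()].
#' @export
#' @examples
#' predict(reference_speed_tree(),
#'         data.frame(speed = c(0.1, 1, 5)))
reference_speed_tree <- function() {
  manual_tree(split_node(
    "speed", 0.18,
    leaf_node("No locomotion"),
    split_node("speed", 3.4,
               leaf_node("Terrestrial locomotion"),
               leaf_node("Fly"))))
}

#' @rdname reference_speed_tree
#' @export
reference_accel_tree <- function() {
  manual_tree(split_node(
    "odbaX", 0.09,
    leaf_node("No locomotion"),
    split_node("dpsZ", 5.1,
               leaf_node("Terrestrial locomotion"),
               leaf_node("Fly"))))
}
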