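# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force or closed form, without touching the code
# paths they check.

# exhaustive best first split: minimal weighted Gini over every predictor
# and every midpoint threshold; ties -> earlier predictor, lower threshold
brute_force_split <- function(X, y) {
  gini <- function(labels) {
    if (length(labels) == 0) return(0)
    p <- table(labels) / length(labels)
    1 - sum(p^2)
  }
  n <- nrow(X)
  best <- NULL
  for (j in seq_along(X)) {
    v <- X[[j]]
    u <- sort(unique(v[!is.na(v)]))
    if (length(u) < 2) next
    thrs <- (u[-1] + u[-length(u)]) / 2
    for (thr in thrs) {
      obs <- !is.na(v)
      l <- obs & v < thr
      r <- obs & !(v < thr)
      imp <- (sum(l) * gini(y[l]) + sum(r) * gini(y[r])) / sum(obs)
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(var = names(X)[j], threshold = thr, impurity = imp)
      }
    }
  }
  best
}

# all pruned subtrees of a node (each internal node either kept with all
# pruned variants of its children, or collapsed to a leaf)
all_subtrees <- function(node) {
  as_leaf <- list(leaf = TRUE, predicted = node$predicted,
                  class_counts = node$class_counts, n = node$n)
  if (node$leaf) return(list(as_leaf))
  out <- list(as_leaf)
  for (l in all_subtrees(node$left)) {
    for (r in all_subtrees(node$right)) {
      keep <- node
      keep$left <- l
      keep$right <- r
      out[[length(out) + 1]] <- keep
    }
  }
  out
}

oracle_leaves <- function(node) {
  if (node$leaf) 1L else oracle_leaves(node$left) + oracle_leaves(node$right)
}

oracle_errors <- function(node) {
  if (node$leaf) sum(node$class_counts) - max(node$class_counts)
  else oracle_errors(node$left) + oracle_errors(node$right)
}

# smallest subtree minimizing R(T) + alpha * |leaves(T)|
oracle_best_subtree <- function(root, alpha, n_total) {
  subs <- all_subtrees(root)
  cost <- vapply(subs, function(s)
    oracle_errors(s) / n_total + alpha * oracle_leaves(s), numeric(1))
  sizes <- vapply(subs, oracle_leaves, integer(1))
  at_min <- which(cost <= min(cost) + 1e-12)
  subs[[at_min[which.min(sizes[at_min])]]]
}

# small well-separated two-class training frame
separable_frame <- function() {
  data.frame(
    x = c(0.1, 0.15, 0.2, 0.25, 0.3, 2.0, 2.05, 2.1, 2.2, 2.3),
    class = rep(c("a", "b"), each = 5))
}

make_deployment_records <- function(seg_tbl, start = "2009-07-01T00:00:00Z",
                                    interval_s = 600) {
  n <- nrow(seg_tbl)
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  times <- t0 + (seq_len(n) - 1) * interval_s
  list(
    fixes = tibble::tibble(bird_id = "b1", time = times, lat = 53.48,
                           lon = 6.2, alt_m = 1, speed_ms = seg_tbl$speed_ms),
    segments = tibble::tibble(bird_id = "b1", start_time = times, rate = 20,
                              duration = 3, x = seg_tbl$x, y = seg_tbl$y,
                              z = seg_tbl$z))
}

n_leaves_of <- function(tree) oracle_leaves(tree$node)
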