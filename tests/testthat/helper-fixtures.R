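# Fixtures and independent oracles used across the test files. Oracles are
# deliberately naive (path enumeration, pair loops) and share no code with
# the implementation they check.

chain_h <- function() {
  label_hierarchy(list(`1` = character(), `1.2` = "1", `1.2.3` = "1.2"),
                  kind = "tree")
}

flat_h <- function(labels) {
  label_hierarchy(stats::setNames(rep(list(character()), length(labels)),
                                  labels), kind = "dag")
}

# random DAG parent map built independently of generate_hierarchy():
# labels in creation order, each non-root draws 1..3 parents among earlier
random_dag_parents <- function(n, seed, p_extra_root = 0.1) {
  set.seed(seed)
  labs <- sprintf("N%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), labs)
  parents[[1L]] <- character(0)
  for (i in 2:n) {
    if (stats::runif(1) < p_extra_root) {
      parents[[i]] <- character(0)
    } else {
      k <- sample(1:min(3L, i - 1L), 1L)
      parents[[i]] <- labs[sample.int(i - 1L, k)]
    }
  }
  parents
}

# all root-to-label paths by recursive enumeration over parent links
oracle_paths <- function(parents, label) {
  ps <- parents[[label]]
  if (length(ps) == 0L) return(list(label))
  out <- list()
  for (p in ps)
    for (path in oracle_paths(parents, p))
      out[[length(out) + 1L]] <- c(path, label)
  out
}

oracle_ancestors <- function(parents, label) {
  setdiff(unique(unlist(oracle_paths(parents, label))), label)
}

oracle_level <- function(parents, label) {
  max(lengths(oracle_paths(parents, label)))
}

# brute-force pooled precision/recall: explicit loop over every pair
oracle_pooled_pr <- function(values, truth01, t) {
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      pos <- values[i, j] >= t
      if (pos && truth01[i, j] == 1) tp <- tp + 1L
      if (pos && truth01[i, j] == 0) fp <- fp + 1L
      if (!pos && truth01[i, j] == 1) fn <- fn + 1L
    }
  }
  c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = tp / (tp + fn))
}

# brute-force pooled AUPRC using the documented integration convention
oracle_auprc <- function(values, truth01, grid = seq(0, 1, by = 0.02)) {
  pts <- t(vapply(grid, function(t) oracle_pooled_pr(values, truth01, t),
                  c(precision = 0, recall = 0)))
  any_pred <- vapply(grid, function(t) any(values >= t), TRUE)
  pts <- pts[any_pred, , drop = FALSE]
  ord <- order(pts[, "recall"], -pts[, "precision"])
  r <- c(0, pts[ord, "recall"])
  p <- c(pts[ord, "precision"][1L], pts[ord, "precision"])
  sum(diff(r) * (head(p, -1L) + tail(p, -1L)) / 2)
}

# dataset over a flat (all-roots) hierarchy from an explicit label list
flat_dataset <- function(labels_per_instance, all_labels, split = "test",
                         n_features = 2L, seed = 99L) {
  set.seed(seed)
  n <- length(labels_per_instance)
  X <- matrix(stats::rnorm(n * n_features), n)
  hmc_dataset(flat_h(all_labels), sprintf("i%03d", seq_len(n)), X,
              labels_per_instance, split = split)
}

# predictions object from a plain named matrix
pred_from_matrix <- function(m, ids = rownames(m), labels = colnames(m)) {
  hmc_predictions(ids, labels, m)
}

small_gen_cfg <- function(seed, kind = "tree", ...) {
  generator_config(seed = seed, n_labels = 15L, hierarchy_kind = kind,
                   n_train = 40L, n_valid = 20L, n_test = 30L,
                   n_features = 10L, missing_rate = 0.05, ...)
}

walk_leaves <- function(node, fn) {
  if (node$type == "leaf") fn(node) else {
    walk_leaves(node$left, fn)
    walk_leaves(node$right, fn)
  }
}

hierarchies_equal <- function(a, b) {
  setequal(a$labels, b$labels) && identical(a$kind, b$kind) &&
    all(vapply(a$labels, function(l)
      setequal(a$parents[[l]], b$parents[[l]]), TRUE))
}

# engineered dataset in which one leaf of a min_leaf=5 tree holds exactly
# one positive instance for a label: two feature clusters of five, the low
# cluster with a single positive
min_positive_dataset <- function(seed = 1L) {
  set.seed(seed)
  x <- c(stats::rnorm(5, 0, 0.1), stats::rnorm(5, 5, 0.1))
  labels <- c(list("A"), rep(list(character(0)), 4L),
              rep(list("A"), 5L))
  hmc_dataset(flat_h("A"), sprintf("m%02d", 1:10),
              cbind(x1 = x), labels, split = "train")
}
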