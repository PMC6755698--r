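#' Depth-decaying label weights for the variance heuristic
#'
#' The intra-cluster variance minimized during tree induction weighs each
#' label by `w0^(level - 1)`, so deeper (more specific) labels contribute
#' less. Levels are by deepest path, also for DAG hierarchies.
#'
#' @param h a [label_hierarchy()].
#' @param w0 depth-weight base in (0, 1].
#' @return named numeric vector of strictly positive weights, one per label
#'   in hierarchy order.
#' @export
label_weights <- function(h, w0 = 0.75) {
  if (!(w0 > 0 && w0 <= 1)) stop("w0 must be in (0, 1]")
  w0^(h$level - 1)
}

#' Weighted variance of a set of label vectors
#'
#' The clustering heuristic of predictive clustering trees:
#' `(1/n) * sum_i sum_c w_c (v_ic - vbar_c)^2` over binarized,
#' ancestor-closed label vectors.
#'
#' @param label_vectors numeric matrix (instances x labels) with entries in
#'   \{0, 1\}.
#' @param weights positive per-label weights.
#' @return nonnegative scalar.
#' @export
hmc_variance <- function(label_vectors, weights) {
  label_vectors <- as.matrix(label_vectors)
  if (nrow(label_vectors) == 0L) stop("empty set of label vectors")
  ctr <- sweep(label_vectors, 2L, colMeans(label_vectors))
  sum(sweep(ctr^2, 2L, weights, `*`)) / nrow(label_vectors)
}

#' Binary label matrix of a dataset
#'
#' @param ds an [hmc_dataset()].
#' @return numeric 0/1 matrix, instances x hierarchy labels (in hierarchy
#'   order), with instance ids as row names.
#' @export
label_matrix <- function(ds) {
  labs <- ds$hierarchy$labels
  Y <- matrix(0, length(ds$ids), length(labs),
              dimnames = list(ds$ids, labs))
  for (i in seq_along(ds$ids)) Y[i, ds$labels[[i]]] <- 1
  Y
}

#' Configuration for predictive clustering tree induction
#'
#' @param min_leaf minimum number of instances per leaf (default 5, the
#'   benchmark setting; it also fixes the smallest strictly positive leaf
#'   probability at `1/min_leaf`).
#' @param ftest_level significance level of the F-test stopping criterion;
#'   for forests, `NULL` requests selection from `ftest_grid` on the
#'   validation split.
#' @param w0 depth-weight base, see [label_weights()].
#' @param features_per_split number of features sampled at each node;
#'   `NULL` means all features for a single tree and
#'   `ceiling(sqrt(n_features))` inside a forest.
#' @param max_depth depth limit (root = depth 0); `Inf` by default.
#' @param seed integer seed, or `NULL` to use the current RNG state (as the
#'   forest trainer does).
#' @return a `pct_config` list.
#' @export
pct_config <- function(min_leaf = 5L, ftest_level = 0.05, w0 = 0.75,
                       features_per_split = NULL, max_depth = Inf,
                       seed = 1L) {
  structure(list(min_leaf = as.integer(min_leaf),
                 ftest_level = ftest_level, w0 = w0,
                 features_per_split = features_per_split,
                 max_depth = max_depth, seed = seed),
            class = "pct_config")
}

# Weighted sum-of-squared-errors of a 0/1 column-sum vector: since v^2 = v
# for binary entries, SSE_w = sum_c w_c (S_c - S_c^2 / n).
sse_from_sums <- function(S, n, w) sum(w * S) - sum(w * S^2) / n

# Exhaustive best split for one feature over a node's rows; returns NULL or
# list(threshold, missing_left, sse). Missing values go to whichever side
# minimizes the resulting variance, and that direction is recorded.
best_split_feature <- function(x, Y, w, min_leaf) {
  miss <- is.na(x)
  xs <- x[!miss]
  if (length(xs) < 2L || length(unique(xs)) < 2L) return(NULL)
  ord <- order(xs)
  xs_o <- xs[ord]
  Yo <- Y[!miss, , drop = FALSE][ord, , drop = FALSE]
  n_nm <- nrow(Yo); nm <- sum(miss); n <- n_nm + nm
  CS <- apply(Yo, 2L, cumsum)
  if (n_nm == 1L) CS <- matrix(CS, 1L)
  Tot <- colSums(Y)                       # node totals incl. missing rows
  Sm <- if (nm) colSums(Y[miss, , drop = FALSE]) else numeric(ncol(Y))
  a  <- as.vector(CS %*% w)               # sum_c w S_L
  b  <- as.vector((CS * CS) %*% w)        # sum_c w S_L^2
  cM <- as.vector(CS %*% (w * Sm))        # sum_c w S_L Sm
  cT <- as.vector(CS %*% (w * Tot))       # sum_c w S_L T
  aM <- sum(w * Sm); bM <- sum(w * Sm^2)
  bT <- sum(w * Tot^2); aT <- sum(w * Tot)
  wTSm <- sum(w * Tot * Sm)
  cut_ok <- xs_o[-n_nm] < xs_o[-1L]       # split between distinct values
  k <- seq_len(n_nm - 1L)
  eval_side <- function(miss_left) {
    nL <- k + if (miss_left) nm else 0L
    nR <- n - nL
    linL <- a[k] + if (miss_left) aM else 0
    quadL <- b[k] + if (miss_left) 2 * cM[k] + bM else 0
    crossT <- cT[k] + if (miss_left) wTSm else 0
    quadR <- bT - 2 * crossT + quadL
    linR <- aT - linL
    sse <- (linL - quadL / nL) + (linR - quadR / nR)
    sse[!cut_ok | nL < min_leaf | nR < min_leaf] <- Inf
    sse
  }
  sse_l <- eval_side(TRUE)
  sse_r <- if (nm) eval_side(FALSE) else sse_l
  best <- which.min(pmin(sse_l, sse_r))
  val <- min(sse_l[best], sse_r[best])
  if (!is.finite(val)) return(NULL)
  list(threshold = (xs_o[best] + xs_o[best + 1L]) / 2,
       missing_left = !nm || sse_l[best] <= sse_r[best],
       sse = val)
}

grow_pct <- function(X, Y, w, cfg, rows, depth) {
  n <- length(rows)
  leaf <- function() list(type = "leaf",
                          prototype = colMeans(Y[rows, , drop = FALSE]),
                          n = n)
  if (n < 2L * cfg$min_leaf || depth >= cfg$max_depth) return(leaf())
  S <- colSums(Y[rows, , drop = FALSE])
  sse_parent <- sse_from_sums(S, n, w)
  if (sse_parent <= 0) return(leaf())
  p <- ncol(X)
  fps <- cfg$features_per_split
  feats <- if (is.null(fps) || fps >= p) seq_len(p)
           else sample.int(p, fps)
  best <- NULL
  for (f in feats) {
    cand <- best_split_feature(X[rows, f], Y[rows, , drop = FALSE], w,
                               cfg$min_leaf)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse)) {
      cand$feature <- f
      best <- cand
    }
  }
  if (is.null(best) || best$sse >= sse_parent) return(leaf())
  # one-way F-test on the weighted variance reduction, k = 2 children
  var_p <- sse_parent / n
  var_w <- best$sse / n
  p_val <- if (var_w <= 0) 0
           else stats::pf((var_p - var_w) / (var_w / (n - 2L)), 1L, n - 2L,
                          lower.tail = FALSE)
  if (p_val > cfg$ftest_level) return(leaf())
  x <- X[rows, best$feature]
  go_left <- ifelse(is.na(x), best$missing_left, x <= best$threshold)
  list(type = "split", feature = best$feature,
       feature_name = colnames(X)[best$feature],
       threshold = best$threshold, missing_left = best$missing_left,
       left = grow_pct(X, Y, w, cfg, rows[go_left], depth + 1L),
       right = grow_pct(X, Y, w, cfg, rows[!go_left], depth + 1L))
}

#' Train a single predictive clustering tree
#'
#' Greedy top-down induction: at each node, over a (possibly random) subset
#' of features, the (feature, threshold) pair maximizing the weighted
#' variance reduction is chosen subject to both children holding at least
#' `min_leaf` instances; the node becomes a leaf when no candidate passes
#' the F-test at `ftest_level` (or limits are hit). Leaf prototypes are the
#' mean label vector of the leaf's training instances, hence
#' hierarchy-monotone on ancestor-closed data, with `1/min_leaf` the
#' smallest attainable strictly positive entry.
#'
#' @param train an [hmc_dataset()] with at least `min_leaf` instances.
#' @param config a [pct_config()].
#' @return an object of class `pct_tree` (root node, label order, weights,
#'   config).
#' @export
train_pct <- function(train, config = pct_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  Y <- label_matrix(train)
  w <- label_weights(train$hierarchy, config$w0)
  if (nrow(Y) < config$min_leaf)
    stop("need at least min_leaf = ", config$min_leaf, " instances")
  root <- grow_pct(train$features, Y, w, config, seq_len(nrow(Y)), 0L)
  structure(list(root = root, label_order = colnames(Y),
                 feature_names = train$feature_names,
                 config = config, hierarchy = train$hierarchy),
            class = "pct_tree")
}

route_tree <- function(node, X, rows, out) {
  if (node$type == "leaf") {
    out[rows, ] <- matrix(node$prototype, length(rows), length(node$prototype),
                          byrow = TRUE)
    return(out)
  }
  x <- X[rows, node$feature]
  go_left <- ifelse(is.na(x), node$missing_left, x <= node$threshold)
  if (any(go_left)) out <- route_tree(node$left, X, rows[go_left], out)
  if (any(!go_left)) out <- route_tree(node$right, X, rows[!go_left], out)
  out
}

predict_tree_matrix <- function(tree, X) {
  out <- matrix(NA_real_, nrow(X), length(tree$label_order),
                dimnames = list(rownames(X), tree$label_order))
  route_tree(tree$root, X, seq_len(nrow(X)), out)
}

#' @export
predict.pct_tree <- function(object, newdata, ...) {
  check_feature_arity(object, newdata)
  vals <- predict_tree_matrix(object, newdata$features)
  hmc_predictions(newdata$ids, object$label_order, vals)
}

check_feature_arity <- function(model, ds) {
  fn <- model$feature_names
  if (!is.null(fn) && !identical(as.character(fn),
                                 as.character(ds$feature_names)))
    stop("feature arity/name mismatch between model and dataset")
  invisible(TRUE)
}

#' Configuration for a forest of predictive clustering trees
#'
#' Defaults follow the benchmark setting: 50 trees, at least 5 instances
#' per leaf, F-test level selected from
#' \{0.001, 0.005, 0.01, 0.05, 0.1, 0.125\} on the validation split.
#'
#' @inheritParams pct_config
#' @param n_trees number of trees.
#' @param bootstrap draw a bootstrap resample per tree.
#' @param ftest_grid candidate F-test levels for validation selection.
#' @param n_trees_select number of trees in the smaller forests used during
#'   grid selection.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 50L, min_leaf = 5L, ftest_level = NULL,
                          w0 = 0.75, features_per_split = NULL,
                          bootstrap = TRUE, max_depth = Inf, seed = 1L,
                          ftest_grid = c(0.001, 0.005, 0.01, 0.05, 0.1,
                                         0.125),
                          n_trees_select = 10L) {
  structure(list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 ftest_level = ftest_level, w0 = w0,
                 features_per_split = features_per_split,
                 bootstrap = bootstrap, max_depth = max_depth,
                 seed = as.integer(seed), ftest_grid = ftest_grid,
                 n_trees_select = as.integer(n_trees_select)),
            class = "forest_config")
}

train_forest_fixed <- function(train, cfg, ftest_level, n_trees, seed) {
  set.seed(seed)
  p <- ncol(train$features)
  fps <- if (is.null(cfg$features_per_split)) ceiling(sqrt(p))
         else cfg$features_per_split
  tcfg <- pct_config(min_leaf = cfg$min_leaf, ftest_level = ftest_level,
                     w0 = cfg$w0, features_per_split = fps,
                     max_depth = cfg$max_depth, seed = NULL)
  n <- length(train$ids)
  trees <- lapply(seq_len(n_trees), function(i) {
    rows <- if (cfg$bootstrap) sample.int(n, n, replace = TRUE)
            else seq_len(n)
    boot <- list(hierarchy = train$hierarchy, ids = sprintf("b%06d", seq_len(n)),
                 features = train$features[rows, , drop = FALSE],
                 labels = train$labels[rows], split = train$split,
                 feature_names = train$feature_names)
    class(boot) <- "hmc_dataset"
    train_pct(boot, tcfg)
  })
  structure(list(trees = trees, n_trees = n_trees,
                 label_order = trees[[1L]]$label_order,
                 feature_names = train$feature_names,
                 config = c(cfg, list(ftest_level_used = ftest_level,
                                      seed_used = seed))),
            class = "pct_forest")
}

#' Train a random forest of predictive clustering trees
#'
#' Trees are grown on bootstrap resamples with per-node random feature
#' subsets (both toggleable via [forest_config()]). When
#' `config$ftest_level` is `NULL`, the F-test level is selected from
#' `config$ftest_grid` by maximizing pooled AUPRC of a smaller
#' (`n_trees_select`-tree) forest on the validation split, and the final
#' forest is then retrained with all `n_trees` trees at the winning level.
#'
#' @param train training [hmc_dataset()].
#' @param valid validation [hmc_dataset()]; required when `ftest_level` is
#'   to be selected.
#' @param config a [forest_config()].
#' @return an object of class `pct_forest`; `$config$ftest_level_used`
#'   records the level in effect.
#' @export
train_forest <- function(train, valid = NULL, config = forest_config()) {
  level <- config$ftest_level
  selection <- NULL
  if (is.null(level)) {
    if (is.null(valid))
      stop("a validation split is required to select ftest_level")
    scores <- vapply(seq_along(config$ftest_grid), function(g) {
      fr <- train_forest_fixed(train, config, config$ftest_grid[g],
                               config$n_trees_select,
                               seed = config$seed + g)
      pooled_auprc(predict(fr, valid), valid)$auprc
    }, 0)
    level <- config$ftest_grid[which.max(scores)]
    selection <- data.frame(ftest_level = config$ftest_grid,
                            valid_auprc = scores)
  }
  forest <- train_forest_fixed(train, config, level, config$n_trees,
                               seed = config$seed)
  forest$selection <- selection
  forest
}

#' @export
print.pct_forest <- function(x, ...) {
  cat(sprintf("pct_forest: %d trees, %d labels, ftest level %g\n",
              x$n_trees, length(x$label_order),
              x$config$ftest_level_used))
  invisible(x)
}

#' @export
predict.pct_forest <- function(object, newdata, ...) {
  check_feature_arity(object, newdata)
  acc <- matrix(0, length(newdata$ids), length(object$label_order),
                dimnames = list(newdata$ids, object$label_order))
  for (tr in object$trees)
    acc <- acc + predict_tree_matrix(tr, newdata$features)
  hmc_predictions(newdata$ids, object$label_order, acc / object$n_trees)
}

#' Mean-rule prediction: the training set's label frequencies
#'
#' The fallback used by rule-based learners for uncovered instances, and
#' the natural no-information baseline: every instance receives the
#' per-label relative frequency observed in training. On ancestor-closed
#' data the frequencies are hierarchy-monotone.
#'
#' @param train training [hmc_dataset()].
#' @return named numeric vector of per-label frequencies in [0, 1].
#' @export
mean_rule_fallback <- function(train) {
  colMeans(label_matrix(train))
}

#' @rdname mean_rule_fallback
#' @param ds dataset whose instances receive the constant mean-rule row.
#' @return `mean_rule_predictions` returns an [hmc_predictions()] matrix.
#' @export
mean_rule_predictions <- function(train, ds) {
  f <- mean_rule_fallback(train)
  vals <- matrix(f, length(ds$ids), length(f), byrow = TRUE,
                 dimnames = list(ds$ids, names(f)))
  hmc_predictions(ds$ids, names(f), vals)
}

## ---------------------------------------------------------------------------
## Prediction matrices

#' Instance-by-label prediction probability matrix
#'
#' @param instance_ids character vector of instance ids.
#' @param label_order character vector fixing the label columns.
#' @param values numeric matrix of probabilities in [0, 1], dimensions
#'   `length(instance_ids)` x `length(label_order)`.
#' @return an object of class `hmc_predictions`.
#' @export
hmc_predictions <- function(instance_ids, label_order, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(instance_ids) ||
      ncol(values) != length(label_order))
    stop("prediction matrix dimensions inconsistent with ids/labels")
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("prediction values must lie in [0, 1]")
  dimnames(values) <- list(instance_ids, label_order)
  structure(list(instance_ids = as.character(instance_ids),
                 label_order = as.character(label_order),
                 values = values),
            class = "hmc_predictions")
}

#' Load externally produced predictions
#'
#' Plug-in point for methods not implemented in this package: a
#' tab-separated file of `instance_id<TAB>label<TAB>probability` rows (no
#' header; `#` comments allowed) is aligned to a dataset. Unlisted pairs
#' default to probability 0.
#'
#' @param path TSV file path.
#' @param ds the [hmc_dataset()] the predictions refer to.
#' @return an [hmc_predictions()] over `ds`'s instances and hierarchy
#'   labels.
#' @export
load_external_predictions <- function(path, ds) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  labs <- ds$hierarchy$labels
  vals <- matrix(0, length(ds$ids), length(labs),
                 dimnames = list(ds$ids, labs))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) stop("malformed prediction row: ", lines[bad][1L])
    id <- vapply(parts, `[[`, "", 1L)
    lab <- vapply(parts, `[[`, "", 2L)
    p <- as.numeric(vapply(parts, `[[`, "", 3L))
    if (any(!id %in% ds$ids))
      stop("unknown instance id(s): ",
           paste(unique(setdiff(id, ds$ids)), collapse = ", "))
    if (any(!lab %in% labs))
      stop("unknown label(s): ",
           paste(unique(setdiff(lab, labs)), collapse = ", "))
    if (anyNA(p) || any(p < 0 | p > 1))
      stop("prediction probabilities must lie in [0, 1]")
    key <- paste(id, lab)
    if (anyDuplicated(key))
      stop("duplicate (instance, label) pair: ", key[duplicated(key)][1L])
    vals[cbind(match(id, ds$ids), match(lab, labs))] <- p
  }
  hmc_predictions(ds$ids, labs, vals)
}

#' Write / read predictions as TSV
#'
#' The on-disk form matches [load_external_predictions()]:
#' `instance_id<TAB>label<TAB>probability`, one pair per row; zero entries
#' are omitted.
#'
#' @param pred an [hmc_predictions()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(pred, path) {
  nz <- which(pred$values != 0, arr.ind = TRUE)
  rows <- sprintf("%s\t%s\t%.12g",
                  pred$instance_ids[nz[, 1L]],
                  pred$label_order[nz[, 2L]],
                  pred$values[nz])
  writeLines(rows, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Model persistence

#' Save / load a PCT forest as structured JSON
#'
#' A versioned dump of every split (feature, threshold, missing direction)
#' and leaf prototype plus the training configuration, sufficient to
#' reproduce predictions exactly.
#'
#' @param forest a `pct_forest`.
#' @param path file path.
#' @return `write_pct_forest` returns `path` invisibly; `read_pct_forest`
#'   returns the restored `pct_forest`.
#' @export
write_pct_forest <- function(forest, path) {
  dump <- list(format = "hmcdrift_pct_forest", version = 1L,
               label_order = forest$label_order,
               feature_names = forest$feature_names,
               n_trees = forest$n_trees,
               config = forest$config[c("min_leaf", "w0", "bootstrap",
                                        "ftest_level_used", "seed_used")],
               trees = lapply(forest$trees, function(t) t$root))
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pct_forest
#' @export
read_pct_forest <- function(path) {
  dump <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (!identical(dump$format, "hmcdrift_pct_forest"))
    stop("not a pct_forest dump: ", path)
  fix_node <- function(nd) {
    if (identical(nd$type, "leaf")) {
      nd$prototype <- stats::setNames(unlist(nd$prototype),
                                      unlist(dump$label_order))
      nd
    } else {
      nd$left <- fix_node(nd$left); nd$right <- fix_node(nd$right)
      nd
    }
  }
  label_order <- unlist(dump$label_order)
  trees <- lapply(dump$trees, function(r)
    structure(list(root = fix_node(r), label_order = label_order,
                   config = dump$config), class = "pct_tree"))
  structure(list(trees = trees, n_trees = dump$n_trees,
                 label_order = label_order,
                 feature_names = unlist(dump$feature_names),
                 config = dump$config),
            class = "pct_forest")
}
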