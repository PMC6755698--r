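#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the structure of the yeast function-annotation
#' benchmarks: a tree- or DAG-shaped label hierarchy, sparse ancestor-closed
#' label sets that thin out with depth, feature vectors carrying label
#' signal (one Gaussian prototype direction per label), missing feature
#' values, and disjoint train/valid/test splits.
#'
#' Defaults define the package's study conditions: 1000 training instances
#' with 400/600 validation/test, 60 labels in a tree with at most 4 children
#' per node, keep-probability 0.75 at the root decaying by 0.5 per level,
#' 60 features, prototype separation of 3 noise standard deviations, and a
#' 2\% missing rate.
#'
#' @param seed integer seed; all generator output is deterministic given it.
#' @param n_labels number of labels in the hierarchy.
#' @param hierarchy_kind `"tree"` or `"dag"`.
#' @param max_children maximum children attached per node during
#'   breadth-first growth.
#' @param dag_extra_parent_prob for DAG hierarchies, probability that each
#'   earlier node becomes an additional parent of a non-root label.
#' @param depth_decay multiplicative decay in (0, 1] of the label
#'   keep-probability per level; values below 1 make annotations thin out
#'   with depth.
#' @param root_label_prob probability that a root label is assigned.
#' @param n_train,n_valid,n_test split sizes.
#' @param n_features feature-vector length.
#' @param signal_strength class-prototype separation in units of the noise
#'   standard deviation; 0 gives label-free features.
#' @param feature_noise_sd standard deviation of the additive Gaussian
#'   feature noise.
#' @param missing_rate probability that a feature entry is masked missing.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_labels = 60L,
                             hierarchy_kind = c("tree", "dag"),
                             max_children = 4L,
                             dag_extra_parent_prob = 0.1,
                             depth_decay = 0.5, root_label_prob = 0.75,
                             n_train = 1000L, n_valid = 400L, n_test = 600L,
                             n_features = 60L, signal_strength = 3,
                             feature_noise_sd = 1, missing_rate = 0.02) {
  hierarchy_kind <- match.arg(hierarchy_kind)
  cfg <- list(seed = as.integer(seed), n_labels = as.integer(n_labels),
              hierarchy_kind = hierarchy_kind,
              max_children = as.integer(max_children),
              dag_extra_parent_prob = dag_extra_parent_prob,
              depth_decay = depth_decay, root_label_prob = root_label_prob,
              n_train = as.integer(n_train), n_valid = as.integer(n_valid),
              n_test = as.integer(n_test), n_features = as.integer(n_features),
              signal_strength = signal_strength,
              feature_noise_sd = feature_noise_sd,
              missing_rate = missing_rate)
  probs <- c(cfg$dag_extra_parent_prob, cfg$root_label_prob,
             cfg$missing_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$depth_decay > 0, cfg$depth_decay <= 1,
            cfg$n_labels >= 1L, cfg$n_train > 0L, cfg$n_valid > 0L,
            cfg$n_test > 0L, cfg$n_features > 0L,
            cfg$signal_strength >= 0, cfg$feature_noise_sd > 0)
  structure(cfg, class = "generator_config")
}

#' Configuration of controlled annotation drift
#'
#' Drift produces a second dataset "version": annotation pairs flip from
#' negative to positive (discoveries) and from positive to negative
#' (corrections), and optionally brand-new labels appear that exist only in
#' the new version.
#'
#' @param seed integer seed.
#' @param p_add probability that an eligible negative (instance, label) pair
#'   (all parents positive) flips positive.
#' @param p_remove probability that a maximal positive label of an instance
#'   flips negative (taking its positive descendants with it).
#' @param n_new_labels number of new-version-only leaf labels grafted onto
#'   the hierarchy.
#' @return an object of class `drift_config`.
#' @export
drift_config <- function(seed = 1L, p_add = 0.05, p_remove = 0.02,
                         n_new_labels = 3L) {
  stopifnot(p_add >= 0, p_add <= 1, p_remove >= 0, p_remove <= 1,
            n_new_labels >= 0L)
  structure(list(seed = as.integer(seed), p_add = p_add,
                 p_remove = p_remove,
                 n_new_labels = as.integer(n_new_labels)),
            class = "drift_config")
}

#' Generate a random label hierarchy
#'
#' Grows a single-root hierarchy breadth-first: each dequeued node receives
#' between 1 and `max_children` children while the label budget lasts, so
#' creation order is a topological order. For DAG hierarchies, each non-root
#' label additionally gains each earlier-created node as an extra parent
#' with probability `dag_extra_parent_prob` (acyclic by construction). Tree
#' labels carry FunCat-style dotted codes; DAG labels generic `G`-codes.
#'
#' @param cfg a [generator_config()].
#' @return a [label_hierarchy()].
#' @export
generate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_labels
  parent_idx <- rep(NA_integer_, n)
  queue <- 1L
  next_id <- 2L
  while (next_id <= n) {
    v <- queue[1L]; queue <- queue[-1L]
    k <- min(sample.int(cfg$max_children, 1L), n - next_id + 1L)
    kids <- seq.int(next_id, length.out = k)
    parent_idx[kids] <- v
    queue <- c(queue, kids)
    next_id <- next_id + k
  }
  extra <- vector("list", n)
  if (cfg$hierarchy_kind == "dag" && cfg$dag_extra_parent_prob > 0) {
    for (i in seq_len(n)[-1L]) {
      eligible <- setdiff(seq_len(i - 1L), parent_idx[i])
      take <- eligible[stats::runif(length(eligible)) <
                         cfg$dag_extra_parent_prob]
      extra[[i]] <- take
    }
  }
  labs <- if (cfg$hierarchy_kind == "tree") {
    codes <- character(n); codes[1L] <- "1"; kid_count <- integer(n)
    for (i in seq_len(n)[-1L]) {
      p <- parent_idx[i]
      kid_count[p] <- kid_count[p] + 1L
      codes[i] <- paste0(codes[p], ".", kid_count[p])
    }
    codes
  } else sprintf("G%04d", seq_len(n))
  parents <- stats::setNames(lapply(seq_len(n), function(i) {
    idx <- c(parent_idx[i], extra[[i]])
    labs[idx[!is.na(idx)]]
  }), labs)
  label_hierarchy(parents, kind = cfg$hierarchy_kind)
}

sample_label_sets <- function(h, n, root_label_prob, depth_decay) {
  keep_prob <- root_label_prob * depth_decay^(h$level - 1)
  lapply(seq_len(n), function(i) {
    pos <- character(0)
    for (lab in h$labels) {  # topological order: parents decided first
      ps <- h$parents[[lab]]
      eligible <- length(ps) == 0L || any(ps %in% pos)
      if (eligible && stats::runif(1L) < keep_prob[[lab]])
        pos <- c(pos, lab)
    }
    close_under_ancestors(h, pos)
  })
}

#' Generate a synthetic hierarchical multi-label dataset
#'
#' Label sets are sampled top-down: a root is kept with probability
#' `root_label_prob`; a child is considered only if at least one parent is
#' positive and kept with probability `root_label_prob * depth_decay^(level-1)`;
#' the result is closed under ancestors. Each label owns a random unit
#' prototype direction in feature space; an instance's features are the sum
#' of `signal_strength * prototype` over its positive labels plus Gaussian
#' noise, with entries masked missing at `missing_rate`.
#'
#' @param cfg a [generator_config()].
#' @param h a [label_hierarchy()], typically from [generate_hierarchy()].
#' @return list with elements `train`, `valid`, `test` (each an
#'   [hmc_dataset()] over disjoint instances) and `prototypes` (the label
#'   prototype matrix, labels x features).
#' @export
generate_dataset <- function(cfg, h) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(h, "label_hierarchy"))
  set.seed(cfg$seed + 1L)
  n_all <- cfg$n_train + cfg$n_valid + cfg$n_test
  labsets <- sample_label_sets(h, n_all, cfg$root_label_prob,
                               cfg$depth_decay)
  proto <- matrix(stats::rnorm(length(h$labels) * cfg$n_features),
                  nrow = length(h$labels),
                  dimnames = list(h$labels, NULL))
  proto <- proto / sqrt(rowSums(proto^2))
  X <- matrix(stats::rnorm(n_all * cfg$n_features,
                           sd = cfg$feature_noise_sd),
              nrow = n_all)
  for (i in seq_len(n_all)) {
    s <- labsets[[i]]
    if (length(s))
      X[i, ] <- X[i, ] + cfg$signal_strength *
        colSums(proto[s, , drop = FALSE])
  }
  if (cfg$missing_rate > 0)
    X[matrix(stats::runif(length(X)) < cfg$missing_rate, nrow = n_all)] <- NA
  colnames(X) <- sprintf("f%d", seq_len(cfg$n_features))
  ids <- sprintf("inst%05d", seq_len(n_all))
  idx <- list(train = seq_len(cfg$n_train),
              valid = cfg$n_train + seq_len(cfg$n_valid),
              test = cfg$n_train + cfg$n_valid + seq_len(cfg$n_test))
  out <- lapply(names(idx), function(sp) {
    i <- idx[[sp]]
    hmc_dataset(h, ids[i], X[i, , drop = FALSE], labsets[i], split = sp)
  })
  names(out) <- names(idx)
  out$prototypes <- proto
  out
}

#' Apply controlled annotation drift to a dataset
#'
#' Produces a new dataset version plus the exact ground-truth partition of
#' (instance, label) pairs. First, `n_new_labels` new leaf labels are
#' grafted under random existing nodes, extending the hierarchy (these
#' exist only in the new version and are excluded from the truth
#' partition). Then, per instance: every negative label all of whose
#' parents are positive flips positive with `p_add` (frontier additions, so
#' closure is preserved); afterwards, every maximal positive label flips
#' negative with `p_remove`, removing it and any positive descendants.
#' Features and split tags are unchanged.
#'
#' @param ds an [hmc_dataset()].
#' @param dcfg a [drift_config()].
#' @return list with `new_ds` (the drifted [hmc_dataset()], over the
#'   extended hierarchy), `truth` (a `change_pair_partition`, see
#'   [identify_changed_pairs()]), and `hierarchy` (the extended hierarchy).
#' @export
apply_drift <- function(ds, dcfg) {
  stopifnot(inherits(dcfg, "drift_config"))
  set.seed(dcfg$seed)
  h_old <- ds$hierarchy
  parents <- h_old$parents
  if (dcfg$n_new_labels > 0L) {
    hosts <- sample(h_old$labels, dcfg$n_new_labels, replace = TRUE)
    for (k in seq_len(dcfg$n_new_labels))
      parents[[sprintf("NEW%03d", k)]] <- hosts[[k]]
  }
  h_new <- label_hierarchy(parents, kind = h_old$kind)
  added_log <- removed_log <- list()
  new_sets <- vector("list", length(ds$ids))
  for (i in seq_along(ds$ids)) {
    pos <- ds$labels[[i]]
    # frontier additions: negative labels with all parents positive; the
    # topological sweep lets a fresh addition enable deeper ones, and
    # closure is preserved by construction
    added_i <- character(0)
    for (lab in h_new$labels) {
      ps <- h_new$parents[[lab]]
      if (!(lab %in% pos) && (length(ps) == 0L || all(ps %in% pos)) &&
          stats::runif(1L) < dcfg$p_add) {
        pos <- c(pos, lab)
        added_i <- c(added_i, lab)
      }
    }
    # removals: a maximal positive label has no positive descendant, so
    # dropping it alone keeps the set closed
    for (lab in maximal_labels(h_new, pos)) {
      if (stats::runif(1L) < dcfg$p_remove) {
        pos <- setdiff(pos, lab)
        if (lab %in% added_i)       # added then removed: net unchanged
          added_i <- setdiff(added_i, lab)
        else if (lab %in% h_old$labels)
          removed_log[[length(removed_log) + 1L]] <- c(ds$ids[i], lab)
      }
    }
    for (lab in intersect(added_i, h_old$labels))
      added_log[[length(added_log) + 1L]] <- c(ds$ids[i], lab)
    new_sets[[i]] <- pos
  }
  new_ds <- hmc_dataset(h_new, ds$ids, ds$features, new_sets,
                        split = ds$split, feature_names = ds$feature_names)
  inter <- intersect(h_old$labels, h_new$labels)
  truth <- partition_from_logs(ds$ids, inter, ds$labels,
                               pair_df(added_log), pair_df(removed_log))
  list(new_ds = new_ds, truth = truth, hierarchy = h_new)
}

pair_df <- function(log) {
  if (length(log) == 0L)
    return(data.frame(instance_id = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, log)
  data.frame(instance_id = m[, 1L], label = m[, 2L],
             stringsAsFactors = FALSE)
}

# Assemble the exact truth partition from the drift event log: this is an
# independent construction from identify_changed_pairs(), which re-derives
# the partition by comparing the two label matrices.
partition_from_logs <- function(ids, inter, old_sets, added, removed) {
  all_pairs <- data.frame(
    instance_id = rep(ids, each = length(inter)),
    label = rep(inter, times = length(ids)),
    stringsAsFactors = FALSE)
  key <- function(df) paste(df$instance_id, df$label, sep = "\r")
  old_pos <- unlist(lapply(seq_along(ids), function(i)
    paste(ids[i], intersect(old_sets[[i]], inter), sep = "\r")),
    use.names = FALSE)
  k_all <- key(all_pairs); k_add <- key(added); k_rem <- key(removed)
  group <- ifelse(k_all %in% k_add, "added",
           ifelse(k_all %in% k_rem, "removed",
           ifelse(k_all %in% old_pos, "unchanged_pos", "unchanged_neg")))
  new_change_pair_partition(
    label_intersection = inter,
    added = all_pairs[group == "added", , drop = FALSE],
    removed = all_pairs[group == "removed", , drop = FALSE],
    unchanged_neg = all_pairs[group == "unchanged_neg", , drop = FALSE],
    unchanged_pos = all_pairs[group == "unchanged_pos", , drop = FALSE])
}
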