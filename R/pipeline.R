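#' Configuration for an end-to-end experiment
#'
#' Bundles the generator, drift, and model configurations with the
#' evaluation grid, the number of dataset replicates (the "datasets" axis
#' of the rank tests), and the number of runs over which stochastic methods
#' are averaged. All stage seeds are derived deterministically from the
#' global seed.
#'
#' @param seed global integer seed.
#' @param n_replicates number of independent synthetic dataset replicates.
#' @param generator a [generator_config()]; its seed field is overridden by
#'   a derived seed per replicate.
#' @param drift a [drift_config()]; seed likewise derived.
#' @param forest a [forest_config()] for the PCT-forest learner.
#' @param grid threshold grid for pooled AUPRC.
#' @param n_stochastic_runs runs to average for stochastic external
#'   methods (default 5).
#' @param external named list of external methods; each entry is
#'   `function(train, valid, test, seed)` returning an
#'   [hmc_predictions()] for `test` (use [load_external_predictions()]
#'   inside to plug in file-based predictions).
#' @param outdir optional directory; when given, score tables and reports
#'   are written there as TSV.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L, n_replicates = 5L,
                              generator = generator_config(),
                              drift = drift_config(),
                              forest = forest_config(),
                              grid = seq(0, 1, by = 0.02),
                              n_stochastic_runs = 5L,
                              external = list(), outdir = NULL) {
  stopifnot(n_stochastic_runs >= 1L, n_replicates >= 1L)
  cfg <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
              generator = generator, drift = drift, forest = forest,
              grid = grid, n_stochastic_runs = as.integer(n_stochastic_runs),
              external = external, outdir = outdir)
  cfg$stamp <- config_stamp(cfg)
  structure(cfg, class = "experiment_config")
}

# Polynomial rolling hash of the serialized configuration: a lightweight
# stamp that changes whenever any configuration field does.
config_stamp <- function(cfg) {
  raw <- serialize(cfg[setdiff(names(cfg), c("stamp", "external", "outdir"))],
                   NULL, version = 2L)
  h <- 0
  for (b in as.integer(raw))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x-seed%d", h, cfg$seed)
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

replicate_data <- function(cfg, rep_seed) {
  gen <- cfg$generator
  gen$seed <- rep_seed
  h <- generate_hierarchy(gen)
  generate_dataset(gen, h)
}

method_predictions <- function(cfg, name, train, valid, test, seeds) {
  if (name == "clus_forest") {
    fcfg <- cfg$forest
    fcfg$seed <- seeds[1L]
    forest <- train_forest(train, valid, fcfg)
    predict(forest, test)
  } else if (name == "mean_rule") {
    mean_rule_predictions(train, test)
  } else {
    fn <- cfg$external[[name]]
    runs <- lapply(seq_len(cfg$n_stochastic_runs), function(r)
      fn(train, valid, test, seeds[r]))
    aggregate_stochastic_runs(runs)$mean
  }
}

experiment_methods <- function(cfg) {
  c("clus_forest", "mean_rule", names(cfg$external))
}

#' Standard evaluation: pooled AUPRC per method and dataset replicate
#'
#' For each synthetic dataset replicate, every method is trained on the
#' train split (model selection on the validation split), evaluated by
#' pooled AUPRC on the test split, and — if at least two methods and two
#' replicates are available — compared by the Friedman-Nemenyi rank test.
#' The mean-rule baseline row is always present; stochastic external
#' methods are averaged over `n_stochastic_runs` runs.
#'
#' @param cfg an [experiment_config()].
#' @return list with `scores` (methods x replicates matrix of pooled
#'   AUPRC), `friedman` (a [friedman_nemenyi()] result or `NULL`), and
#'   `stamp`.
#' @export
run_standard_eval <- function(cfg) {
  methods <- experiment_methods(cfg)
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_replicates)
  scores <- matrix(NA_real_, length(methods), cfg$n_replicates,
                   dimnames = list(methods,
                                   sprintf("replicate%d", seq_len(cfg$n_replicates))))
  for (r in seq_len(cfg$n_replicates)) {
    d <- replicate_data(cfg, rep_seeds[r])
    run_seeds <- derive_seeds(rep_seeds[r] %% 1000000L + 7L,
                              cfg$n_stochastic_runs)
    for (m in methods) {
      pred <- method_predictions(cfg, m, d$train, d$valid, d$test, run_seeds)
      scores[m, r] <- pooled_auprc(pred, d$test, grid = cfg$grid)$auprc
    }
  }
  fn <- if (length(methods) >= 2L && cfg$n_replicates >= 2L)
    friedman_nemenyi(scores) else NULL
  report <- list(scores = scores, friedman = fn, stamp = cfg$stamp)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scores,
                       file.path(cfg$outdir, "standard_eval_scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  report
}

#' Cross-version evaluation: can old models flag annotation drift?
#'
#' For each replicate, a dataset is generated and its test split receives
#' controlled annotation drift (the "new version"). Every method is trained
#' on the OLD train split only — so it never sees new-version-only labels —
#' and its predictions on the test instances are summarized over the four
#' change groups of [identify_changed_pairs()] (whose output is verified
#' against the drift generator's exact ground truth). The median-difference
#' statistics for added and removed annotations feed two Friedman-Nemenyi
#' analyses.
#'
#' @param cfg an [experiment_config()].
#' @return list with `median_diff_added` and `median_diff_removed`
#'   (methods x replicates matrices), `friedman_added`, `friedman_removed`,
#'   `group_summaries` (per replicate, per method), `no_changed_pairs`
#'   (logical per replicate), and `stamp`.
#' @export
run_cross_version_eval <- function(cfg) {
  methods <- experiment_methods(cfg)
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_replicates)
  md_add <- md_rem <- matrix(NA_real_, length(methods), cfg$n_replicates,
                             dimnames = list(methods,
                                             sprintf("replicate%d",
                                                     seq_len(cfg$n_replicates))))
  summaries <- vector("list", cfg$n_replicates)
  no_changed <- logical(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    d <- replicate_data(cfg, rep_seeds[r])
    dcfg <- cfg$drift
    dcfg$seed <- rep_seeds[r] + 1L
    drift <- apply_drift(d$test, dcfg)
    part <- identify_changed_pairs(d$test, drift$new_ds)
    stopifnot(partitions_equal(part, drift$truth))
    no_changed[r] <- nrow(part$added) == 0L && nrow(part$removed) == 0L
    run_seeds <- derive_seeds(rep_seeds[r] %% 1000000L + 13L,
                              cfg$n_stochastic_runs)
    summaries[[r]] <- list()
    for (m in methods) {
      pred <- method_predictions(cfg, m, d$train, d$valid, d$test, run_seeds)
      summaries[[r]][[m]] <- group_summary(pred, part)
      if (!no_changed[r]) {
        if (nrow(part$added) > 0L)
          md_add[m, r] <- median_difference(pred, part, "added")
        if (nrow(part$removed) > 0L)
          md_rem[m, r] <- median_difference(pred, part, "removed")
      }
    }
  }
  fn_of <- function(mat) {
    cols <- colSums(is.na(mat)) == 0L
    if (length(methods) >= 2L && sum(cols) >= 2L)
      friedman_nemenyi(mat[, cols, drop = FALSE]) else NULL
  }
  report <- list(median_diff_added = md_add, median_diff_removed = md_rem,
                 friedman_added = fn_of(md_add),
                 friedman_removed = fn_of(md_rem),
                 group_summaries = summaries,
                 no_changed_pairs = no_changed, stamp = cfg$stamp)
  if (all(no_changed))
    message("no changed pairs in any replicate; ",
            "median-difference statistics are undefined")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(md_add,
                       file.path(cfg$outdir, "median_diff_added.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(md_rem,
                       file.path(cfg$outdir, "median_diff_removed.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  report
}

partitions_equal <- function(a, b) {
  key <- function(df) sort(paste(df$instance_id, df$label, sep = "\r"))
  setequal(a$label_intersection, b$label_intersection) &&
    identical(key(a$added), key(b$added)) &&
    identical(key(a$removed), key(b$removed)) &&
    identical(key(a$unchanged_neg), key(b$unchanged_neg)) &&
    identical(key(a$unchanged_pos), key(b$unchanged_pos))
}
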