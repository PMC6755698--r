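toy_tree_path <- system.file("extdata", "toy_tree.arff",
                             package = "hmcdrift")
toy_dag_path <- system.file("extdata", "toy_dag.arff", package = "hmcdrift")

test_that("the tree-dialect toy file parses with closure and missing marks", {
  ds <- read_arff_hmc(toy_tree_path)
  expect_s3_class(ds, "hmc_dataset")
  expect_identical(ds$hierarchy$kind, "tree")
  expect_setequal(ds$hierarchy$labels, c("1", "1.2", "1.2.3", "2", "2.1"))
  # row labeled 1.2.3 parses to its full ancestor chain
  expect_setequal(ds$labels[[1L]], c("1", "1.2", "1.2.3"))
  expect_setequal(ds$labels[[2L]], c("2", "2.1", "1", "1.2"))
  expect_identical(ds$labels[[3L]], character(0))
  # '?' becomes a missing marker, not 0
  expect_true(is.na(ds$features[2L, 2L]))
  expect_true(is.na(ds$features[3L, 1L]))
  expect_identical(ds$features[1L, ], c(f1 = 0.5, f2 = 1.25))
})

test_that("ARFF read/write is a semantic fixed point for both dialects", {
  for (p in c(toy_tree_path, toy_dag_path)) {
    ds <- read_arff_hmc(p)
    out <- tempfile(fileext = ".arff")
    write_arff_hmc(ds, out)
    ds2 <- read_arff_hmc(out)
    expect_true(hierarchies_equal(ds$hierarchy, ds2$hierarchy))
    expect_identical(lapply(ds$labels, sort), lapply(ds2$labels, sort))
    expect_equal(unname(ds$features), unname(ds2$features))
    expect_identical(ds$feature_names, ds2$feature_names)
    # idempotence: a second round trip is byte-compatible semantically
    out2 <- tempfile(fileext = ".arff")
    write_arff_hmc(ds2, out2)
    expect_identical(readLines(out), readLines(out2))
  }
})

test_that("the DAG dialect keeps multiple parents and the empty marker", {
  ds <- read_arff_hmc(toy_dag_path)
  expect_identical(ds$hierarchy$kind, "dag")
  expect_setequal(ds$hierarchy$parents[["GO:C"]], c("GO:A", "GO:B"))
  expect_setequal(ds$labels[[1L]], c("GO:D", "GO:C", "GO:A", "GO:B"))
  expect_identical(ds$labels[[4L]], character(0))
  out <- tempfile(fileext = ".arff")
  write_arff_hmc(ds, out)
  # empty label set writes the dialect's empty marker
  expect_match(grep("^2,2,2", readLines(out), value = TRUE), ",\\?$")
})

test_that("malformed ARFF input is rejected with the offending line", {
  base <- readLines(toy_tree_path)
  bad_label <- sub("1.2.3$", "9.9", base)
  f <- tempfile(); writeLines(bad_label, f)
  expect_error(read_arff_hmc(f), "line 8")
  expect_error(read_arff_hmc(f), "9.9")

  bad_arity <- c(base, "1,2,3,4,1.2")
  f <- tempfile(); writeLines(bad_arity, f)
  expect_error(read_arff_hmc(f), "arity")

  no_class <- base[!grepl("hierarchical", base)]
  f <- tempfile(); writeLines(no_class, f)
  expect_error(read_arff_hmc(f), "hierarchical")

  bad_value <- sub("^0.5", "abc", base)
  f <- tempfile(); writeLines(bad_value, f)
  expect_error(read_arff_hmc(f), "abc")
})

test_that("update_annotations merges alternates, drops obsoletes, closes", {
  h_new <- funcat_hierarchy(c("1.2.3", "2.1", "3.1"))
  ds <- read_arff_hmc(toy_tree_path)
  spec <- annotation_update_spec(
    new_annotations = list(row00001 = c("B", "3.1"),
                          row00002 = c("2.1", "X"),
                          row00003 = "1.2.3"),
    alternate_ids = c(B = "2.1"),
    obsolete = "X")
  upd <- update_annotations(ds, spec, h_new)
  # secondary ID B merged into canonical 2.1, then closed
  expect_setequal(upd$labels[[1L]], c("2", "2.1", "3", "3.1"))
  # obsolete X removed before closure
  expect_setequal(upd$labels[[2L]], c("2", "2.1"))
  expect_setequal(upd$labels[[3L]], c("1", "1.2", "1.2.3"))
  # features and split survive untouched
  expect_identical(upd$features, ds$features)
  expect_identical(upd$split, ds$split)
  # the hierarchy is the induced subset of the new one
  expect_setequal(upd$hierarchy$labels,
                  c("1", "1.2", "1.2.3", "2", "2.1", "3", "3.1"))

  # verbatim replacement (plus closure) with empty maps
  spec0 <- annotation_update_spec(list(row00001 = "1.2", row00002 = "2",
                                       row00003 = character(0)))
  upd0 <- update_annotations(ds, spec0, h_new)
  expect_setequal(upd0$labels[[1L]], c("1", "1.2"))
  expect_identical(upd0$labels[[3L]], character(0))

  # a missing instance is logged and gets the empty set
  spec_miss <- annotation_update_spec(list(row00001 = "1.2",
                                           row00002 = "2"))
  expect_message(upd_m <- update_annotations(ds, spec_miss, h_new),
                 "row00003")
  expect_identical(upd_m$labels[[3L]], character(0))

  # canonical label absent from the new hierarchy names instance and label
  spec_bad <- annotation_update_spec(list(row00001 = "7.7",
                                          row00002 = "2",
                                          row00003 = character(0)))
  expect_error(update_annotations(ds, spec_bad, h_new), "row00001.*7\\.7")
})

test_that("alternate-ID chains resolve to a fixed point, cycles refused", {
  expect_identical(
    hmcdrift:::canonical_label("A", c(A = "B", B = "C")), "C")
  expect_error(annotation_update_spec(list(), c(A = "B", B = "A")),
               "cycle")
  expect_error(annotation_update_spec(list(), c(A = "B"), obsolete = "B"),
               "obsolete")
})

test_that("hierarchy subsets keep exactly the closure of used labels", {
  h <- chain_h()
  sub <- build_hierarchy_subset(h, "1.2.3")
  expect_setequal(sub$labels, c("1", "1.2", "1.2.3"))
  expect_true(hierarchies_equal(build_hierarchy_subset(h, h$labels), h))

  parents <- random_dag_parents(25L, 13L)
  hd <- label_hierarchy(parents, kind = "dag")
  set.seed(5)
  used <- sample(hd$labels, 6L)
  sub <- build_hierarchy_subset(hd, used)
  for (lab in sub$labels)   # membership oracle: used or ancestor of used
    expect_true(lab %in% used ||
                  any(vapply(used, function(u)
                    lab %in% oracle_ancestors(parents, u), TRUE)))
  expect_true(validate_hierarchy(sub)$ok)
})

test_that("per-level statistics match hand counts and conserve totals", {
  h <- chain_h()
  ds <- hmc_dataset(h, c("a", "b"), matrix(0, 2, 1),
                    list(c("1", "1.2"), c("1", "1.2")), split = "train")
  st <- per_level_stats(ds)
  expect_identical(st$n_labels, c(1L, 1L, 1L))
  expect_identical(st$n_annotated_instances, c(2L, 2L, 0L))
  expect_identical(st$n_annotations, c(2L, 2L, 0L))

  empty <- hmc_dataset(h, character(0), matrix(0, 0, 1), list(),
                       split = "test")
  st0 <- per_level_stats(empty)
  expect_identical(st0$level, 1:3)           # table spans hierarchy levels
  expect_true(all(st0$n_annotated_instances == 0L))
  expect_true(all(st0$n_annotations == 0L))

  cfg <- small_gen_cfg(21L)
  d <- generate_dataset(cfg, generate_hierarchy(cfg))
  st <- per_level_stats(d$train)
  expect_identical(sum(st$n_annotations),
                   sum(lengths(d$train$labels)))   # conservation
  expect_identical(per_level_stats(d$train, drop_level1 = TRUE)$level,
                   st$level[-1L])
})

test_that("added/removed per level equals a brute-force pair diff", {
  h <- chain_h()
  ds <- hmc_dataset(h, c("a", "b"), matrix(0, 2, 1),
                    list("1", c("1", "1.2")), split = "test")
  expect_true(all(diff_annotation_stats(ds, ds)[, -1L] == 0L))

  gained <- hmc_dataset(h, c("a", "b"), matrix(0, 2, 1),
                        list(c("1", "1.2"), c("1", "1.2")), split = "test")
  st <- diff_annotation_stats(ds, gained)
  expect_identical(st$n_added, c(0L, 1L, 0L))
  expect_identical(st$n_removed, c(0L, 0L, 0L))

  # random drift: per-level counts equal an independent set-difference loop
  cfg <- small_gen_cfg(31L)
  d <- generate_dataset(cfg, generate_hierarchy(cfg))
  dr <- apply_drift(d$test, drift_config(seed = 8L, n_new_labels = 0L))
  st <- diff_annotation_stats(d$test, dr$new_ds)
  lev <- d$test$hierarchy$level
  add_ref <- rem_ref <- integer(nrow(st))
  for (i in seq_along(d$test$ids)) {
    for (lab in setdiff(dr$new_ds$labels[[i]], d$test$labels[[i]]))
      add_ref[lev[[lab]]] <- add_ref[lev[[lab]]] + 1L
    for (lab in setdiff(d$test$labels[[i]], dr$new_ds$labels[[i]]))
      rem_ref[lev[[lab]]] <- rem_ref[lev[[lab]]] + 1L
  }
  expect_identical(st$n_added, add_ref)
  expect_identical(st$n_removed, rem_ref)

  ds_other <- hmc_dataset(h, c("a", "zz"), matrix(0, 2, 1),
                          list("1", "1"), split = "test")
  expect_error(diff_annotation_stats(ds, ds_other), "zz")
})

test_that("duplicate feature vectors are grouped, conflicts flagged", {
  h <- flat_h(c("A", "B"))
  X <- rbind(c(1, 2), c(1, 2), c(3, NA), c(3, NA), c(5, 6))
  ds <- hmc_dataset(h, sprintf("i%d", 1:5), X,
                    list("A", "B", "A", "A", "B"), split = "train")
  rep <- duplicate_feature_report(ds)
  expect_identical(rep$n_unique, 3L)
  expect_identical(rep$n_duplicated, 2L)                # conservation
  expect_length(rep$conflicting_groups, 1L)             # rows 1,2 disagree
  expect_setequal(rep$conflicting_groups[[1L]], c("i1", "i2"))

  distinct <- hmc_dataset(h, c("x", "y"), rbind(c(1, 1), c(2, 2)),
                          list("A", "A"), split = "train")
  expect_identical(duplicate_feature_report(distinct)$n_duplicated, 0L)
})

test_that("annotation maps load from two-column TSV", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "p1\tGO:A", "p1\tGO:B", "p2\tGO:A"), f)
  m <- read_annotation_map_tsv(f)
  expect_identical(m, list(p1 = c("GO:A", "GO:B"), p2 = "GO:A"))
})
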