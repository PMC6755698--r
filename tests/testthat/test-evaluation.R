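test_that("pooled precision/recall at a threshold counts pairs micro", {
  truth <- flat_dataset(list("A", c("A", "B")), c("A", "B"))
  pred <- pred_from_matrix(
    matrix(c(0.9, 0.4, 0.8, 0.1), 2,
           dimnames = list(c("i001", "i002"), c("A", "B"))))
  # predicted positive: (1,A),(1,B); tp=1, fp=1, fn=2
  pr <- pooled_pr_at_threshold(pred, truth, 0.5)
  expect_equal(unname(pr["precision"]), 1 / 2)
  expect_equal(unname(pr["recall"]), 1 / 3)

  exact <- pred_from_matrix(label_matrix(truth))
  expect_equal(unname(pooled_pr_at_threshold(exact, truth, 0.5)),
               c(1, 1))

  # threshold 0: everything predicted, recall 1, precision = prevalence
  pr0 <- pooled_pr_at_threshold(pred, truth, 0)
  expect_equal(unname(pr0["recall"]), 1)
  expect_equal(unname(pr0["precision"]), 3 / 4)
})

test_that("pooled AUPRC hits the analytic endpoints", {
  truth <- flat_dataset(list("A", c("A", "B"), character(0)),
                        c("A", "B"))
  perfect <- pred_from_matrix(label_matrix(truth))
  expect_equal(pooled_auprc(perfect, truth)$auprc, 1)

  # constant 0.5 everywhere: single PR point at (1, prevalence)
  const <- pred_from_matrix(matrix(0.5, 3, 2,
                                   dimnames = list(truth$ids, c("A", "B"))))
  expect_equal(pooled_auprc(const, truth)$auprc, 3 / 6)

  none <- flat_dataset(list(character(0)), c("A", "B"))
  expect_error(pooled_auprc(pred_from_matrix(
    matrix(0.2, 1, 2, dimnames = list("i001", c("A", "B")))), none),
    "no positive pair")
})

test_that("pooled curves match the brute-force pair oracle exactly", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 15L; L <- 6L
    labs <- sprintf("c%d", seq_len(L))
    truth01 <- matrix(rbinom(n * L, 1, 0.3), n)
    sets <- lapply(seq_len(n), function(i) labs[truth01[i, ] == 1])
    truth <- flat_dataset(sets, labs, seed = rep)
    vals <- matrix(round(runif(n * L), 3), n,
                   dimnames = list(truth$ids, labs))
    pred <- pred_from_matrix(vals)
    tm <- label_matrix(truth)
    if (sum(tm) == 0) next
    curve <- pooled_auprc(pred, truth)
    for (t in curve$thresholds) {
      o <- oracle_pooled_pr(vals, tm, t)
      row <- curve$points[curve$points$threshold == t, ]
      expect_equal(row$precision, unname(o["precision"]))
      expect_equal(row$recall, unname(o["recall"]))
    }
    expect_equal(curve$auprc, oracle_auprc(vals, tm))
    # recall is non-increasing in the threshold
    expect_true(all(diff(curve$points$recall) <= 1e-12))
  }
})

test_that("refining the threshold grid barely moves the area", {
  set.seed(202)
  for (rep in 1:3) {
    n <- 50L; L <- 20L
    labs <- sprintf("c%d", seq_len(L))
    truth01 <- matrix(rbinom(n * L, 1, 0.2), n)
    truth <- flat_dataset(lapply(seq_len(n), function(i)
      labs[truth01[i, ] == 1]), labs, seed = 300 + rep)
    pred <- pred_from_matrix(matrix(runif(n * L), n,
                                    dimnames = list(truth$ids, labs)))
    a_coarse <- pooled_auprc(pred, truth)$auprc
    a_fine <- pooled_auprc(pred, truth,
                           grid = seq(0, 1, by = 0.001))$auprc
    expect_lt(abs(a_coarse - a_fine), 0.02)
  }
})

test_that("changed pairs partition the instance x intersection grid", {
  old <- flat_dataset(list("A", c("A", "B"), character(0)),
                      c("A", "B"))
  expect_identical(nrow(identify_changed_pairs(old, old)$added), 0L)
  expect_identical(nrow(identify_changed_pairs(old, old)$removed), 0L)

  # label C exists only in the new version: excluded everywhere
  h_new <- flat_h(c("A", "B", "C"))
  new <- hmc_dataset(h_new, old$ids, old$features,
                     list(c("A", "C"), "A", "B"), split = "test")
  part <- identify_changed_pairs(old, new)
  expect_setequal(part$label_intersection, c("A", "B"))
  all_labs <- unlist(lapply(c("added", "removed", "unchanged_neg",
                              "unchanged_pos"),
                            function(g) part[[g]]$label))
  expect_false("C" %in% all_labs)
  expect_identical(part$added$label, "B")          # i003 gained B
  expect_identical(part$added$instance_id, "i003")
  expect_identical(part$removed$label, "B")        # i002 lost B
  n_pairs <- sum(nrow(part$added), nrow(part$removed),
                 nrow(part$unchanged_neg), nrow(part$unchanged_pos))
  expect_identical(n_pairs, 3L * 2L)               # conservation

  bad <- hmc_dataset(h_new, c("i001", "i002", "zz"), old$features,
                     list("A", "A", "B"), split = "test")
  expect_error(identify_changed_pairs(old, bad), "zz")
})

test_that("group summaries report boxplot statistics per group", {
  old <- flat_dataset(list(character(0), character(0), character(0),
                           "A"), c("A", "B"))
  new <- hmc_dataset(old$hierarchy, old$ids, old$features,
                     list("A", "A", "A", "A"), split = "test")
  part <- identify_changed_pairs(old, new)
  vals <- matrix(c(0.1, 0.2, 0.3, 0.9,   # A column
                   0, 0, 0, 0), 4,       # B column
                 dimnames = list(old$ids, c("A", "B")))
  gs <- group_summary(pred_from_matrix(vals), part)
  expect_identical(gs$group,
                   c("added", "removed", "unchanged_neg", "unchanged_pos"))
  expect_identical(gs$n[gs$group == "added"], 3L)
  expect_equal(gs$median[gs$group == "added"], 0.2)
  expect_identical(gs$n[gs$group == "removed"], 0L)
  expect_true(is.na(gs$median[gs$group == "removed"]))

  # constant predictions: every nonempty median equals the constant
  gc <- group_summary(pred_from_matrix(
    matrix(0.4, 4, 2, dimnames = list(old$ids, c("A", "B")))), part)
  expect_true(all(gc$median[gc$n > 0] == 0.4))

  # medians agree with a sort-based oracle on random values
  set.seed(7)
  vr <- matrix(runif(8), 4, dimnames = list(old$ids, c("A", "B")))
  gr <- group_summary(pred_from_matrix(vr), part)
  med_oracle <- function(v) {
    s <- sort(unname(v)); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  }
  expect_equal(gr$median[gr$group == "added"],
               med_oracle(vr[1:3, "A"]))
})

test_that("median differences are signed so larger means better", {
  old <- flat_dataset(list(character(0), character(0), "A", "A"),
                      c("A", "B"))
  new <- hmc_dataset(old$hierarchy, old$ids, old$features,
                     list("A", character(0), "A", character(0)),
                     split = "test")
  part <- identify_changed_pairs(old, new)   # added (1,A); removed (4,A)

  perfect <- matrix(0, 4, 2, dimnames = list(old$ids, c("A", "B")))
  perfect["i001", "A"] <- 1                  # detects the addition
  perfect["i003", "A"] <- 1                  # keeps the true positive
  p <- pred_from_matrix(perfect)
  expect_equal(median_difference(p, part, "added"), 1)
  expect_equal(median_difference(p, part, "removed"), 1)

  const <- pred_from_matrix(matrix(0.3, 4, 2,
                                   dimnames = list(old$ids, c("A", "B"))))
  expect_equal(median_difference(const, part, "added"), 0)
  expect_equal(median_difference(const, part, "removed"), 0)

  # a random predictor sits near zero when the groups are large
  labs <- sprintf("L%02d", 1:8)
  set.seed(17)
  sets_old <- lapply(1:150, function(i) sample(labs, 3))
  old_big <- flat_dataset(sets_old, labs, seed = 31)
  sets_new <- lapply(sets_old, function(s) {
    s <- if (runif(1) < 0.5) union(s, sample(setdiff(labs, s), 1)) else s
    if (runif(1) < 0.5) setdiff(s, sample(s, 1)) else s
  })
  new_big <- hmc_dataset(old_big$hierarchy, old_big$ids, old_big$features,
                         sets_new, split = "test")
  part_big <- identify_changed_pairs(old_big, new_big)
  rnd <- pred_from_matrix(matrix(runif(150 * 8), 150,
                                 dimnames = list(old_big$ids, labs)))
  expect_lt(abs(median_difference(rnd, part_big, "added")), 0.15)
  expect_lt(abs(median_difference(rnd, part_big, "removed")), 0.15)

  empty_part <- identify_changed_pairs(old, old)
  expect_error(median_difference(const, empty_part, "added"), "empty")
})

test_that("identical scores rank uniformly with no significant pairs", {
  scores <- matrix(0.4, 3, 6,
                   dimnames = list(c("m1", "m2", "m3"), NULL))
  fr <- friedman_nemenyi(scores)
  expect_equal(unname(fr$avg_ranks), rep(2, 3))    # (k+1)/2
  expect_equal(fr$friedman_stat, 0)
  expect_equal(fr$p_value, 1)
  expect_identical(nrow(fr$significant_pairs), 0L)
})

test_that("rank statistics are invariant to monotone score transforms", {
  set.seed(41)
  for (rep in 1:100) {
    scores <- matrix(runif(4 * 6), 4,
                     dimnames = list(sprintf("m%d", 1:4), NULL))
    fr <- friedman_nemenyi(scores)
    # any within-dataset strictly monotone transform preserves ranks
    tr <- apply(scores, 2L, function(s) exp(3 * s) + rep(runif(1), 4))
    rownames(tr) <- rownames(scores)
    fr2 <- friedman_nemenyi(tr)
    expect_equal(fr$avg_ranks, fr2$avg_ranks)
    expect_equal(fr$friedman_stat, fr2$friedman_stat)
    expect_equal(fr$critical_distance, fr2$critical_distance)
  }
})

test_that("the Friedman statistic matches stats::friedman.test", {
  set.seed(43)
  scores <- matrix(rnorm(5 * 8), 5, dimnames = list(sprintf("m%d", 1:5),
                                                    NULL))
  fr <- friedman_nemenyi(scores)
  ref <- stats::friedman.test(t(scores))   # blocks in rows there
  expect_equal(fr$friedman_stat, unname(ref$statistic))
  expect_equal(fr$p_value, unname(ref$p.value))
})

test_that("the critical distance follows the studentized-range formula", {
  set.seed(47)
  scores <- matrix(runif(40), 4, 10,
                   dimnames = list(sprintf("m%d", 1:4), NULL))
  fr <- friedman_nemenyi(scores, alpha = 0.05)
  q4 <- qtukey(0.95, 4, Inf) / sqrt(2)
  expect_equal(fr$critical_distance, q4 * sqrt(4 * 5 / 60))
  expect_equal(q4, 2.569, tolerance = 1e-3)  # published table value

  # permuting methods or datasets only relabels the output
  perm_m <- sample(4); perm_d <- sample(10)
  fr2 <- friedman_nemenyi(scores[perm_m, perm_d])
  expect_equal(fr2$avg_ranks[rownames(scores)], fr$avg_ranks)
  expect_equal(fr2$friedman_stat, fr$friedman_stat)

  expect_error(friedman_nemenyi(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(friedman_nemenyi(scores[1, , drop = FALSE]), "at least 2")
})

test_that("stochastic runs aggregate to mean and sample sd", {
  ids <- c("a", "b"); labs <- c("A", "B")
  m1 <- pred_from_matrix(matrix(c(0.2, 0.4, 0.6, 0.8), 2,
                                dimnames = list(ids, labs)))
  m2 <- pred_from_matrix(matrix(c(0.4, 0.4, 0.2, 0.8), 2,
                                dimnames = list(ids, labs)))
  agg <- aggregate_stochastic_runs(list(m1, m2))
  expect_equal(agg$mean$values[1, 1], 0.3)
  expect_equal(agg$sd[1, 1], sd(c(0.2, 0.4)))
  expect_true(all(agg$mean$values >= pmin(m1$values, m2$values) &
                    agg$mean$values <= pmax(m1$values, m2$values)))

  same <- aggregate_stochastic_runs(list(m1, m1, m1))
  expect_true(all(same$sd == 0))
  expect_equal(same$mean$values, m1$values)

  single <- aggregate_stochastic_runs(list(m1))
  expect_equal(single$mean$values, m1$values)
  expect_true(all(is.na(single$sd)))

  m3 <- pred_from_matrix(matrix(0.5, 2, 2,
                                dimnames = list(rev(ids), labs)))
  expect_error(aggregate_stochastic_runs(list(m1, m3)), "misaligned")
})
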