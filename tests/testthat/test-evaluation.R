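test_that("binary precision/recall/F1 match hand-counted confusion cells", {
  perfect <- binary_prf(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$support, 2L)
  silent <- binary_prf(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(silent$recall, 0)
  expect_equal(silent$f1, 0)
  half <- binary_prf(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 0.5)
  expect_error(binary_prf(c(1, 0), c(1)), "equal length")
})

test_that("binary and one-vs-rest metrics agree with the caret oracle", {
  skip_if_not_installed("caret")
  total <- 0L
  for (i in 1:25) {
    n <- 40
    truth <- withr::with_seed(i, sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3)))
    pred <- withr::with_seed(i + 500, ifelse(stats::runif(n) < 0.75, truth, 1 - truth))
    ours <- binary_prf(truth, pred)
    ref <- factor(truth, levels = c(1, 0))
    est <- factor(pred, levels = c(1, 0))
    if (sum(pred == 1) > 0 && sum(truth == 1) > 0) {
      expect_equal(ours$precision, unname(caret::precision(est, ref)))
      expect_equal(ours$recall, unname(caret::recall(est, ref)))
      expect_equal(ours$f1, unname(caret::F_meas(est, ref)))
    }
    total <- total + n
  }
  # one-vs-rest per level, 1,000 instances
  n <- 1000
  truth <- withr::with_seed(1, sample(0:3, n, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)))
  pred <- withr::with_seed(2, ifelse(stats::runif(n) < 0.7, truth, sample(0:3, n, replace = TRUE)))
  hm <- hierarchical_macro_f1(truth, pred, levels = 0:3)
  for (lv in 0:3) {
    ref <- factor(as.integer(truth == lv), levels = c(1, 0))
    est <- factor(as.integer(pred == lv), levels = c(1, 0))
    row <- hm$per_level[hm$per_level$level == lv, ]
    expect_equal(row$precision, unname(caret::precision(est, ref)))
    expect_equal(row$recall, unname(caret::recall(est, ref)))
    expect_equal(row$f1, unname(caret::F_meas(est, ref)))
  }
  expect_equal(hm$macro_f1, mean(hm$per_level$f1))
})

test_that("hierarchical macro F1 averages one-vs-rest scores over levels", {
  hm <- hierarchical_macro_f1(c(0, 0, 1, 2), c(0, 1, 1, 2), levels = 0:2)
  expect_equal(hm$per_level$f1, c(2 / 3, 2 / 3, 1))
  expect_equal(hm$macro_f1, 7 / 9)
  perfect <- hierarchical_macro_f1(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$macro_f1, 1)
  # a supported level that is never predicted contributes an F1 of 0
  missed <- hierarchical_macro_f1(c(0, 0, 0, 4), c(0, 0, 0, 0), levels = 0:4)
  row4 <- missed$per_level[missed$per_level$level == 4, ]
  expect_equal(row4$f1, 0)
  expect_equal(row4$support, 1L)
  expect_equal(missed$macro_f1, mean(c(missed$per_level$f1[1], 0)))
  expect_error(hierarchical_macro_f1(integer(0), integer(0)), "empty")
})

test_that("Edwards-corrected McNemar matches its closed form and the chi-square law", {
  blank <- mcnemar_edwards(tibble::tibble(a = 5, b = 0, c = 0, d = 2))
  expect_true(blank$blank)
  expect_true(is.na(blank$statistic))
  expect_equal(format_p_value(blank$p_value), "")

  ten <- mcnemar_edwards(tibble::tibble(a = 0, b = 10, c = 0, d = 0))
  expect_equal(ten$statistic, 8.1)
  expect_equal(ten$p_value, 0.004426525857919834, tolerance = 1e-12)

  for (b in 1:10) {
    sym <- mcnemar_edwards(tibble::tibble(a = 1, b = b, c = b, d = 1))
    expect_equal(sym$statistic, 1 / (2 * b))
    expect_gt(sym$p_value, 0.3)
  }
  expect_error(mcnemar_edwards(tibble::tibble(a = 1, b = -1, c = 0, d = 0)), "non-negative")
})

test_that("McNemar agrees with the base-R continuity-corrected oracle on random tables", {
  for (i in 1:100) {
    cells <- withr::with_seed(i, stats::rpois(4, lambda = c(20, 4, 4, 6)))
    tab <- tibble::tibble(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    ours <- mcnemar_edwards(tab)
    if (tab$b + tab$c == 0) {
      expect_true(ours$blank)
      next
    }
    if (tab$b != tab$c) {
      # base R applies the continuity correction only for b != c; the
      # b == c corner is covered by the closed-form checks above
      m <- matrix(cells, 2, 2, byrow = TRUE)
      oracle <- stats::mcnemar.test(m, correct = TRUE)
      expect_equal(ours$statistic, unname(oracle$statistic))
      expect_equal(ours$p_value, oracle$p.value)
    } else {
      expect_equal(ours$statistic, 1 / (tab$b + tab$c))
    }
    # symmetric in (b, c), invariant to (a, d)
    swapped <- mcnemar_edwards(tibble::tibble(a = 99, b = tab$c, c = tab$b, d = 0))
    expect_equal(swapped$statistic, ours$statistic)
  }
})

test_that("contingency tables combine cellwise", {
  t1 <- tibble::tibble(a = 1, b = 2, c = 3, d = 4)
  t2 <- tibble::tibble(a = 10, b = 0, c = 1, d = 5)
  expect_equal(combine_tables(list(t1)), t1)
  both <- combine_tables(list(t1, t2))
  expect_equal(both, tibble::tibble(a = 11, b = 2, c = 4, d = 9))
  expect_equal(
    mcnemar_edwards(both),
    mcnemar_edwards(tibble::tibble(a = 11, b = 2, c = 4, d = 9))
  )
  expect_error(combine_tables(list()), "at least one")
})

test_that("Fleiss kappa matches a frozen hand computation and its bounds", {
  # fixed 6-item x 4-rater x 3-category table, worked through the
  # definition by hand: P_bar = 2/3, Pe_bar = 11/32, kappa = 31/63
  tab <- rbind(
    c(0, 0, 0, 0),
    c(0, 0, 1, 1),
    c(1, 1, 1, 2),
    c(2, 2, 2, 2),
    c(0, 1, 2, 2),
    c(1, 1, 1, 1)
  )
  expect_equal(fleiss_kappa(tab), 31 / 63, tolerance = 1e-12)

  agree <- cbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(fleiss_kappa(agree), 1)
  expect_true(is.na(fleiss_kappa(matrix(1, 4, 3))))
  expect_error(fleiss_kappa(matrix(0, 1, 3)), "at least 2")

  for (i in 1:50) {
    r <- withr::with_seed(i, matrix(sample(0:2, 30, replace = TRUE), 10, 3))
    k <- fleiss_kappa(r)
    expect_gte(k, -1)
    expect_lte(k, 1)
    all_agree <- all(apply(r, 1, function(v) length(unique(v)) == 1))
    expect_equal(isTRUE(all.equal(k, 1)), all_agree && length(unique(as.vector(r))) > 1)
  }
})

test_that("merged rater combinations behave like pseudo-raters", {
  # noise-free: kappa 1 at every merge size
  clean <- matrix(rep(c(0, 1, 2, 0, 1), each = 6), ncol = 6, byrow = TRUE)
  for (m in c(1, 3, 5)) {
    expect_equal(merged_rater_kappa(clean, m), 1)
  }
  expect_error(merged_rater_kappa(clean[, 1:5], 3), "exactly 6")
  expect_error(merged_rater_kappa(clean, 2), "1, 3 or 5")
  # majority merge: one dissenting rater disappears at m = 3
  one_off <- clean
  one_off[, 6] <- c(1, 2, 0, 1, 2)
  expect_lt(merged_rater_kappa(one_off, 1), 1)
  expect_equal(merged_rater_kappa(one_off, 5), 1)
  # the mean-over-combinations reading is available behind a flag
  expect_lte(merged_rater_kappa(one_off, 3, method = "mean"), 1)
})

test_that("vote merging uses majority with median tie-break", {
  expect_equal(surgal:::merge_votes(c(1L, 1L, 0L)), 1L)
  expect_equal(surgal:::merge_votes(c(0L, 2L, 4L)), 2L)
  expect_equal(surgal:::merge_votes(c(0L, 0L, 1L, 1L, 2L)), 1L)
})

test_that("group macro rows equal unweighted means of member features", {
  schema <- default_schema()
  n <- 60
  truth <- withr::with_seed(5, tibble::tibble(
    blood = sample(0:4, n, replace = TRUE),
    smoke = sample(0:3, n, replace = TRUE),
    azygos_vein = sample(0:1, n, replace = TRUE),
    gastric_tube = sample(0:1, n, replace = TRUE)
  ))
  pred <- withr::with_seed(6, dplyr::mutate(
    truth,
    blood = ifelse(stats::runif(n) < 0.7, blood, sample(0:4, n, TRUE)),
    azygos_vein = ifelse(stats::runif(n) < 0.8, azygos_vein, 1 - azygos_vein)
  ))
  sub <- schema[schema$name %in% names(truth), ]
  m <- feature_metrics(truth, pred, sub)
  feat_rows <- m[m$scope == "feature", ]
  grp <- m[m$feature == "anatomy (macro)", ]
  expect_equal(
    grp$f1,
    mean(feat_rows$f1[feat_rows$feature %in% c("azygos_vein", "gastric_tube")])
  )
  all_row <- m[m$feature == "all features (macro)", ]
  expect_equal(all_row$f1, mean(feat_rows$f1))
})
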