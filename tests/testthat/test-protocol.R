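schema <- default_schema()
toy_cfg <- training_config(
  epochs = 8L, hidden = 8L, max_learning_rate = 0.02,
  n_inferences_selection = 5L, n_inferences_eval = 10L
)
toy_cohort <- tiny_cohort(n = 7, duration = 300, fps = 0.5, seed = 21)
ledger <- suppressWarnings(run_protocol(toy_cohort,
  config = toy_cfg, n_cycles = 3,
  interval_s = 60, test_interval_s = 30, seed = 5
))

test_that("the ledger keeps matched budgets and growing pools", {
  expect_equal(ledger$n_cycles, 3)
  counts <- ledger$selections |>
    dplyr::count(cycle, arm, group)
  for (cyc in 1:3) {
    budget <- ledger$cycles$budget[ledger$cycles$cycle == cyc]
    sel <- counts[counts$cycle == cyc, ]
    expect_true(all(sel$n == budget)) # AL batch size equals the EQS budget
  }
  # cumulative labeled sets grow strictly
  for (arm in c("EQS", "AL")) {
    for (g in names(model_groups(schema))) {
      sizes <- vapply(0:3, function(cyc) nrow(cumulative_labels(ledger, arm, g, cyc)), numeric(1))
      expect_true(all(diff(sizes) > 0))
    }
  }
})

test_that("selection respects pool membership rules", {
  truth <- purrr::list_rbind(lapply(toy_cohort, function(p) p$truth))
  sel <- dplyr::left_join(ledger$selections, truth,
    by = c("video_id", "frame_index"),
    suffix = c("", ".truth")
  )
  # white (out-of-body) frames are never selected
  expect_true(all(!sel$outside_body))
  # EQS draws only from the cycle's newly added video
  for (cyc in 1:3) {
    eqs <- sel[sel$arm == "EQS" & sel$cycle == cyc, ]
    expect_equal(unique(eqs$video_id), ledger$cycles$video_id[cyc])
  }
  # no frame is selected twice within the same arm/group
  per <- ledger$selections |>
    dplyr::count(arm, group, video_id, frame_index)
  expect_true(all(per$n == 1))
  # test frames never appear in any labeled set
  test_keys <- paste(ledger$test$frames$video_id, ledger$test$frames$frame_index)
  for (arm in c("EQS", "AL")) {
    for (g in names(model_groups(schema))) {
      lab <- ledger$labels[[arm]][[g]]
      expect_equal(length(intersect(paste(lab$video_id, lab$frame_index), test_keys)), 0)
    }
  }
  # test videos themselves are never drawn from
  test_videos <- ledger$video_roles$video_id[ledger$video_roles$role == "test"]
  expect_false(any(ledger$selections$video_id %in% test_videos))
})

test_that("the protocol is exactly reproducible from its master seed", {
  again <- suppressWarnings(run_protocol(toy_cohort,
    config = toy_cfg, n_cycles = 3,
    interval_s = 60, test_interval_s = 30, seed = 5
  ))
  expect_identical(ledger$selections, again$selections)
  expect_identical(ledger$labels, again$labels)
  expect_identical(ledger$test$reference, again$test$reference)
})

test_that("the protocol refuses a cohort with too few videos", {
  expect_error(
    run_protocol(toy_cohort, config = toy_cfg, n_cycles = 10, seed = 1),
    "needed"
  )
})

test_that("post-hoc validation shares cycle-0 models and builds the union baseline", {
  val <- posthoc_validation(ledger,
    cycles = c(0, 3), groups = "anatomy",
    upper_baseline = TRUE, seed = 2
  )
  m0 <- val$metrics[val$metrics$cycle == 0 & val$metrics$scope == "feature", ]
  eqs0 <- m0[m0$arm == "EQS", c("feature", "f1", "precision", "recall")]
  al0 <- m0[m0$arm == "AL", c("feature", "f1", "precision", "recall")]
  expect_equal(eqs0, al0) # identical start set, identical seed
  # upper baseline trains on the distinct union of both arms' frames
  eqs <- cumulative_labels(ledger, "EQS", "anatomy", 3)
  al <- cumulative_labels(ledger, "AL", "anatomy", 3)
  overlap <- nrow(dplyr::semi_join(eqs, al, by = c("video_id", "frame_index")))
  ub <- val$train_sizes[val$train_sizes$arm == "EQS+AL", ]
  expect_equal(ub$n_train, nrow(eqs) + nrow(al) - overlap)
  expect_true(all(ub$n_train >= nrow(eqs)) && all(ub$n_train >= nrow(al)))
  # per-cycle McNemar inputs cover the whole test set
  mc <- mcnemar_cycles(val)
  per <- mc[mc$scope == "feature_cycle", ]
  expect_true(all(per$a + per$b + per$c + per$d == nrow(ledger$test$frames)))
})

test_that("well-trained evaluation models recognise common binary features", {
  cohort <- tiny_cohort(n = 7, duration = 400, fps = 0.5, seed = 33)
  cfg <- training_config(
    epochs = 30L, max_learning_rate = 0.02,
    n_inferences_selection = 5L, n_inferences_eval = 20L
  )
  led <- suppressWarnings(run_protocol(cohort,
    config = cfg, n_cycles = 3,
    interval_s = 25, test_interval_s = 20, seed = 8
  ))
  val <- posthoc_validation(led,
    cycles = 3, groups = "instruments",
    upper_baseline = FALSE, seed = 3
  )
  # high-prevalence instruments without the deliberate center-style
  # confound (the suction motif swaps color between centers by design)
  common <- c("vessel_sealer", "cautery_hook")
  rows <- val$metrics[val$metrics$feature %in% common & val$metrics$scope == "feature", ]
  expect_true(all(rows$f1 >= 0.9))
})

test_that("ledger summaries expose the experiment bookkeeping", {
  td <- tidy(ledger)
  expect_equal(td$cycle, 1:3)
  gl <- glance(ledger)
  expect_equal(gl$n_cycles, 3)
  expect_equal(gl$eqs_frames, sum(ledger$cycles$budget))
  expect_s3_class(autoplot(posthoc_validation(ledger,
    cycles = 3, groups = "anatomy",
    upper_baseline = FALSE, seed = 2
  )), "ggplot")
})
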