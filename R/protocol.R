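all_truth_frames <- function(videos) {
  list_rbind(lapply(videos, function(p) p$truth))
}

# Simulated consensus annotation of a batch of frames: three raters drawn
# from the annotator group tag every frame/feature independently; majority
# vote with oracle adjudication of three-way ordinal splits yields the label.
annotate_batch <- function(truth, frames, features, schema, profiles, seed,
                           n_raters = 3L, adjudication = "oracle") {
  sub <- seed_stream(seed, 2)
  batch_truth <- truth |>
    semi_join(frames, by = c("video_id", "frame_index")) |>
    select(dplyr::all_of(c("video_id", "frame_index", "timestamp_s", features)))
  picked <- with_seed_local(sub[1], sample(profiles, n_raters))
  tags <- simulate_raters(batch_truth, schema, picked, seed = sub[2])
  consensus <- consensus_labels(tags, schema,
    truth = batch_truth, adjudication = adjudication
  )
  labels <- consensus |>
    select("video_id", "frame_index", "feature", "level") |>
    pivot_wider(names_from = "feature", values_from = "level") |>
    left_join(
      batch_truth[, c("video_id", "frame_index", "timestamp_s")],
      by = c("video_id", "frame_index")
    ) |>
    select(dplyr::all_of(c("video_id", "frame_index", "timestamp_s", features)))
  list(labels = labels, tags = tags, consensus = consensus)
}

#' Build the held-out test set
#'
#' Selects frames equidistantly from the test videos and fills in frames from
#' ground truth until every feature level has at least `min_per_level`
#' examples. All six raters tag every test frame; the reference label is the
#' majority consensus of the first three raters (by rater id), while the full
#' six-rater table is retained for agreement analysis.
#'
#' @param videos Held-out test `surgal_procedure`s.
#' @param schema A feature schema.
#' @param interval_s Equidistant interval in seconds.
#' @param min_per_level Minimum examples per feature level.
#' @param profiles The six rater profiles.
#' @param seed Seed.
#' @return List with `frames`, `reference` (consensus labels, wide),
#'   `ratings` (long six-rater table), `truth` (ground truth, wide) and
#'   `n_manual` (frames added beyond the equidistant selection).
#' @export
build_test_set <- function(videos, schema, interval_s = 15, min_per_level = 3,
                           profiles = default_rater_profiles(6), seed = 1L) {
  sub <- seed_stream(seed, 2)
  frames <- list_rbind(lapply(videos, select_equidistant, interval_s = interval_s))
  truth_all <- list_rbind(lapply(videos, function(p) p$truth[!p$truth$outside_body, ]))
  sel_truth <- semi_join(truth_all, frames, by = c("video_id", "frame_index"))
  n_equidistant <- nrow(frames)
  for (f in schema$name) {
    for (lv in feature_levels(schema, f)) {
      have <- sum(sel_truth[[f]] == lv)
      if (have >= min_per_level) next
      cand <- truth_all[truth_all[[f]] == lv, ]
      cand <- anti_join(cand, frames, by = c("video_id", "frame_index"))
      take <- utils::head(cand, min_per_level - have)
      if (nrow(take) < min_per_level - have) {
        warn(paste0(
          "test set has fewer than ", min_per_level, " examples of ",
          f, " level ", lv
        ))
      }
      if (nrow(take) > 0) {
        frames <- bind_rows(frames, take[, c("video_id", "frame_index", "timestamp_s")])
        sel_truth <- bind_rows(sel_truth, take)
      }
    }
  }
  frames <- arrange(frames, .data$video_id, .data$frame_index)
  sel_truth <- arrange(sel_truth, .data$video_id, .data$frame_index)
  tags <- simulate_raters(sel_truth, schema, profiles, seed = sub[1])
  consensus <- consensus_labels(tags, schema, truth = sel_truth)
  reference <- consensus |>
    select("video_id", "frame_index", "feature", "level") |>
    pivot_wider(names_from = "feature", values_from = "level") |>
    arrange(.data$video_id, .data$frame_index)
  list(
    frames = frames, reference = reference, ratings = tags,
    truth = sel_truth, n_manual = nrow(frames) - n_equidistant
  )
}

#' Run the prospective annotation protocol
#'
#' Executes the multi-cycle comparison of equidistant sampling (EQS) and
#' uncertainty-driven active learning (AL) at matched budgets. Both arms
#' start from the same start set (equidistant frames from the first video of
#' each center, with missing feature levels filled in). Per cycle: (1) the
#' next video is added in chronological order; (2) the EQS arm selects frames
#' every `interval_s` seconds from the new video only; (3) each AL group
#' model scores all of its unlabeled pool frames (the pool spans every
#' available video) with Monte-Carlo-dropout uncertainty and selects as many
#' frames as EQS did this cycle; (4) both arms' batches receive simulated
#' three-rater consensus annotation; (5) all six models (three groups, two
#' arms) are retrained from scratch on their cumulative sets. No evaluation
#' happens between cycles; see [posthoc_validation()].
#'
#' @param cohort A `surgal_cohort`; the last `n_test_videos` videos are held
#'   out as the test set and never enter any pool.
#' @param config A [training_config()].
#' @param n_cycles Number of annotation cycles.
#' @param interval_s EQS interval in seconds (default: every two minutes).
#' @param test_interval_s Equidistant interval for the test set.
#' @param n_start_videos Videos in the start set (first of each center).
#' @param n_test_videos Held-out test videos.
#' @param rater_profiles The simulated annotator group.
#' @param uncertainty Frame-score aggregation, `"mean"` or `"max"` over
#'   per-class standard deviations.
#' @param checkpoint_dir Optional directory for per-cycle model checkpoints.
#' @param seed Master seed; every random draw derives from it.
#' @return A `surgal_ledger`.
#' @export
run_protocol <- function(cohort, config = training_config(),
                         n_cycles = 10L, interval_s = 120,
                         test_interval_s = 15,
                         n_start_videos = 2L, n_test_videos = 2L,
                         rater_profiles = default_rater_profiles(6),
                         uncertainty = c("mean", "max"),
                         checkpoint_dir = NULL,
                         seed = 1L) {
  uncertainty <- match.arg(uncertainty)
  schema <- attr(cohort, "schema")
  n_needed <- n_start_videos + n_cycles + n_test_videos
  if (length(cohort) < n_needed) {
    abort(paste0(
      "cohort has ", length(cohort), " videos but ", n_needed,
      " are needed (", n_start_videos, " start + ", n_cycles,
      " cycles + ", n_test_videos, " test)"
    ))
  }
  groups <- names(model_groups(schema))
  s <- seed_stream(seed, 5)
  cache <- new.env(parent = emptyenv())
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }

  start_videos <- cohort[seq_len(n_start_videos)]
  test_videos <- cohort[(length(cohort) - n_test_videos + 1L):length(cohort)]
  cycle_videos <- cohort[n_start_videos + seq_len(n_cycles)]
  train_scope <- cohort[seq_len(n_start_videos + n_cycles)]
  truth_scope <- all_truth_frames(train_scope)

  # --- start set (shared by both arms) -----------------------------------
  start <- build_start_set(start_videos, schema, interval_s = interval_s)
  start_union <- distinct(
    list_rbind(start$sets)[, c("video_id", "frame_index", "timestamp_s")]
  )
  start_ann <- annotate_batch(
    truth_scope, start_union, schema$name, schema,
    rater_profiles, s[1]
  )
  labels <- list()
  for (arm in c("EQS", "AL")) {
    labels[[arm]] <- list()
    for (g in groups) {
      gl <- start_ann$labels |>
        semi_join(start$sets[[g]], by = c("video_id", "frame_index")) |>
        select(dplyr::all_of(c(
          "video_id", "frame_index", "timestamp_s",
          model_groups(schema)[[g]]
        ))) |>
        mutate(cycle = 0L, .before = 1)
      labels[[arm]][[g]] <- gl
    }
  }

  # --- test set ------------------------------------------------------------
  test <- build_test_set(test_videos, schema,
    interval_s = test_interval_s,
    profiles = rater_profiles, seed = s[2]
  )

  # --- initial selection models (AL needs a pretrained model) -------------
  model_seeds0 <- seed_stream(s[5], length(groups))
  current_model <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    x <- frame_matrix(cohort, labels$AL[[g]],
      resolution = config$proxy_resolution, cache = cache
    )
    current_model[[g]] <- train_group_model(
      x, labels$AL[[g]], g, schema,
      config = config, seed = model_seeds0[gi]
    )
  }

  cycle_seeds <- seed_stream(s[3], n_cycles)
  selections <- list()
  cycles <- list()
  checkpoints <- list()
  consensus_records <- list(start = start_ann$consensus)

  for (cyc in seq_len(n_cycles)) {
    ks <- seed_stream(cycle_seeds[cyc], 4 + 3 * length(groups))
    new_video <- cycle_videos[[cyc]]
    available <- cohort[seq_len(n_start_videos + cyc)]

    # (2) EQS: equidistant frames from the newly added video only
    eqs_batch <- select_equidistant(new_video, interval_s = interval_s)
    budget <- nrow(eqs_batch)
    eqs_ann <- annotate_batch(
      truth_scope, eqs_batch, schema$name, schema,
      rater_profiles, ks[1]
    )
    consensus_records[[paste0("eqs_", cyc)]] <- eqs_ann$consensus
    for (g in groups) {
      gl <- eqs_ann$labels |>
        select(dplyr::all_of(c(
          "video_id", "frame_index", "timestamp_s",
          model_groups(schema)[[g]]
        ))) |>
        mutate(cycle = cyc, .before = 1)
      labels$EQS[[g]] <- bind_rows(labels$EQS[[g]], gl)
    }
    selections[[length(selections) + 1L]] <- eqs_batch |>
      mutate(cycle = cyc, arm = "EQS", group = "all", uncertainty = NA_real_)

    # (3) AL: score the whole unlabeled pool per group, take the EQS budget
    pool_all <- truth_scope |>
      filter(
        .data$video_id %in% vapply(available, function(p) p$video_id, character(1)),
        !.data$outside_body
      ) |>
      select("video_id", "frame_index", "timestamp_s")
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      pool <- anti_join(pool_all, labels$AL[[g]],
        by = c("video_id", "frame_index")
      )
      pool$video_order <- match(pool$video_id, unique(pool_all$video_id))
      xp <- frame_matrix(cohort, pool,
        resolution = config$proxy_resolution, cache = cache
      )
      pred <- predict_mc(current_model[[g]], xp,
        T = config$n_inferences_selection, seed = ks[1 + gi]
      )
      scores <- frame_uncertainty(pred, method = uncertainty)
      al_batch <- select_most_uncertain(pool, budget, scores = scores)
      al_ann <- annotate_batch(
        truth_scope, al_batch, model_groups(schema)[[g]], schema,
        rater_profiles, ks[1 + length(groups) + gi]
      )
      consensus_records[[paste0("al_", g, "_", cyc)]] <- al_ann$consensus
      labels$AL[[g]] <- bind_rows(
        labels$AL[[g]],
        mutate(al_ann$labels, cycle = cyc, .before = 1)
      )
      selections[[length(selections) + 1L]] <- al_batch |>
        mutate(cycle = cyc, arm = "AL", group = g)
    }

    # (5) retrain all six models on the cumulative sets
    model_seeds <- seed_stream(ks[2 + 2 * length(groups)], 2 * length(groups))
    mi <- 0L
    for (arm in c("EQS", "AL")) {
      for (g in groups) {
        mi <- mi + 1L
        x <- frame_matrix(cohort, labels[[arm]][[g]],
          resolution = config$proxy_resolution, cache = cache
        )
        mdl <- suppressWarnings(train_group_model(
          x, labels[[arm]][[g]], g, schema,
          config = config, seed = model_seeds[mi]
        ))
        if (arm == "AL") {
          current_model[[g]] <- mdl
        }
        if (!is.null(checkpoint_dir)) {
          path <- file.path(checkpoint_dir, sprintf("cycle%02d_%s_%s.rds", cyc, arm, g))
          save_model(mdl, path)
          checkpoints[[length(checkpoints) + 1L]] <- tibble(
            cycle = cyc, arm = arm, group = g, path = path
          )
        }
      }
    }
    cycles[[cyc]] <- tibble(
      cycle = cyc, video_id = new_video$video_id, budget = budget,
      pool_size = nrow(pool_all),
      eqs_cumulative = nrow(labels$EQS[[groups[1]]]),
      al_cumulative = nrow(labels$AL[[groups[1]]])
    )
  }

  structure(
    list(
      schema = schema, config = config, seed = seed,
      interval_s = interval_s, n_cycles = n_cycles,
      cohort = cohort,
      video_roles = tibble(
        video_id = vapply(cohort, function(p) p$video_id, character(1)),
        center = vapply(cohort, function(p) p$center, character(1)),
        role = c(
          rep("start", n_start_videos), rep("cycle", n_cycles),
          rep(
            "unused",
            length(cohort) - n_start_videos - n_cycles - n_test_videos
          ),
          rep("test", n_test_videos)
        )
      ),
      start = start, labels = labels, test = test,
      selections = list_rbind(selections),
      cycles = list_rbind(cycles),
      consensus = consensus_records,
      models = current_model,
      checkpoints = if (length(checkpoints)) list_rbind(checkpoints) else NULL,
      rater_profiles = rater_profiles,
      cache = cache
    ),
    class = "surgal_ledger"
  )
}

#' @export
print.surgal_ledger <- function(x, ...) {
  cat(
    "<surgal_ledger> ", x$n_cycles, " cycles, ",
    sum(x$cycles$budget), " frames per arm+group beyond the start set, ",
    nrow(x$test$frames), " test frames\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy surgal_ledger
#' @export
tidy.surgal_ledger <- function(x, ...) {
  x$cycles
}

#' @method glance surgal_ledger
#' @export
glance.surgal_ledger <- function(x, ...) {
  groups <- names(model_groups(x$schema))
  tibble(
    n_cycles = x$n_cycles,
    n_videos = length(x$cohort),
    start_frames = nrow(x$start$sets[[groups[1]]]),
    eqs_frames = sum(x$cycles$budget),
    al_frames = sum(x$cycles$budget) * length(groups),
    test_frames = nrow(x$test$frames),
    seed = x$seed
  )
}

#' Cumulative labeled set of one arm/group after a cycle
#'
#' @param ledger A `surgal_ledger`.
#' @param arm `"EQS"` or `"AL"`.
#' @param group Model group.
#' @param cycle Cycle index (0 = start set only).
#' @return Tibble of labeled frames with level columns.
#' @export
cumulative_labels <- function(ledger, arm, group, cycle) {
  filter(ledger$labels[[arm]][[group]], .data$cycle <= !!cycle)
}

#' Post-hoc validation of both arms on the held-out test set
#'
#' For each requested cycle and arm, an evaluation model (larger input
#' resolution, augmentation on) is trained on that cycle's cumulative labeled
#' set and scored on the test set with `n_inferences_eval` Monte-Carlo
#' inferences. Optionally an upper baseline is trained on the union of both
#' arms' data after the final cycle.
#'
#' @param ledger A `surgal_ledger`.
#' @param cycles Cycle indices (0 = start set only; default all).
#' @param groups Model groups to evaluate (default all).
#' @param arms Arms to evaluate.
#' @param upper_baseline Also train the combined EQS+AL model after the last
#'   cycle.
#' @param config Training configuration (defaults to the ledger's, with
#'   augmentation enabled).
#' @param seed Seed.
#' @return A `surgal_validation` list: `metrics` (per cycle/arm feature
#'   metrics), `predictions` (per-frame hard labels with reference),
#'   `uncertainty` (mean/max frame uncertainty per cycle/arm/group) and
#'   `train_sizes`.
#' @export
posthoc_validation <- function(ledger, cycles = NULL, groups = NULL,
                               arms = c("EQS", "AL"), upper_baseline = TRUE,
                               config = NULL, seed = 1L) {
  schema <- ledger$schema
  groups <- groups %||% names(model_groups(schema))
  cycles <- cycles %||% seq(0L, ledger$n_cycles)
  if (is.null(config)) {
    config <- ledger$config
    config$augmentation <- TRUE
  }
  test_x <- frame_matrix(ledger$cohort, ledger$test$frames,
    resolution = config$eval_resolution, cache = ledger$cache
  )
  reference <- ledger$test$reference
  # one seed per (cycle, group): both arms share it, so the cycle-0 models,
  # trained on the identical start set, coincide exactly across arms
  all_groups <- names(model_groups(schema))
  seed_key <- function(cyc, g, arm) {
    base <- if (arm == "EQS+AL") ledger$n_cycles + 1L else cyc
    base * length(all_groups) + match(g, all_groups)
  }
  seeds <- seed_stream(seed, (ledger$n_cycles + 2L) * length(all_groups) +
    length(all_groups))
  metrics <- list()
  predictions <- list()
  unc <- list()
  sizes <- list()

  eval_one <- function(train_labels, g, arm, cyc) {
    si <- seed_key(cyc, g, arm)
    x <- frame_matrix(ledger$cohort, train_labels,
      resolution = config$eval_resolution, cache = ledger$cache
    )
    mdl <- suppressWarnings(train_group_model(
      x, train_labels, g, schema,
      config = config, input_hw = config$eval_resolution,
      seed = seeds[si]
    ))
    pred <- predict_mc(mdl, test_x, T = config$n_inferences_eval, seed = seeds[si])
    hard <- decode_predictions(pred)
    feats <- model_groups(schema)[[g]]
    m <- feature_metrics(
      reference[, c("video_id", "frame_index", feats)],
      hard, schema[schema$name %in% feats, ]
    )
    metrics[[length(metrics) + 1L]] <<- mutate(m, cycle = cyc, arm = arm, group = g, .before = 1)
    pl <- list_rbind(lapply(feats, function(f) {
      tibble(
        cycle = cyc, arm = arm, group = g, feature = f,
        video_id = reference$video_id, frame_index = reference$frame_index,
        pred = hard[[f]], ref = reference[[f]],
        correct = hard[[f]] == reference[[f]]
      )
    }))
    predictions[[length(predictions) + 1L]] <<- pl
    fu <- frame_uncertainty(pred)
    unc[[length(unc) + 1L]] <<- tibble(
      cycle = cyc, arm = arm, group = g,
      mean_uncertainty = mean(fu), max_uncertainty = max(fu)
    )
    sizes[[length(sizes) + 1L]] <<- tibble(
      cycle = cyc, arm = arm, group = g, n_train = nrow(train_labels)
    )
  }

  for (cyc in cycles) {
    for (arm in arms) {
      for (g in groups) {
        eval_one(cumulative_labels(ledger, arm, g, cyc), g, arm, cyc)
      }
    }
  }
  if (upper_baseline) {
    for (g in groups) {
      feats <- model_groups(schema)[[g]]
      eqs <- cumulative_labels(ledger, "EQS", g, ledger$n_cycles)
      al <- cumulative_labels(ledger, "AL", g, ledger$n_cycles)
      union <- bind_rows(eqs, al) |>
        distinct(.data$video_id, .data$frame_index, .keep_all = TRUE)
      eval_one(union, g, "EQS+AL", ledger$n_cycles)
    }
  }
  structure(
    list(
      metrics = list_rbind(metrics),
      predictions = list_rbind(predictions),
      uncertainty = list_rbind(unc),
      train_sizes = list_rbind(sizes),
      schema = schema
    ),
    class = "surgal_validation"
  )
}

#' Edwards-corrected McNemar tests per feature and cycle
#'
#' Compares the correctness of the two arms' classifiers on the shared test
#' set for every feature and cycle, plus combined tests per model group and
#' over all features obtained by summing the contingency tables across cycles
#' and member features.
#'
#' @param validation A `surgal_validation` (needs both EQS and AL arms).
#' @return Tibble with the contingency cells, statistic, p-value, display
#'   string, and `blank` marker; combined rows have `cycle = NA`.
#' @export
mcnemar_cycles <- function(validation) {
  preds <- validation$predictions |>
    filter(.data$arm %in% c("EQS", "AL"), .data$cycle > 0)
  wide <- preds |>
    select("cycle", "group", "feature", "video_id", "frame_index", "arm", "correct") |>
    pivot_wider(names_from = "arm", values_from = "correct")
  if (!all(c("EQS", "AL") %in% names(wide))) {
    abort("mcnemar_cycles needs predictions for both the EQS and AL arms")
  }
  cells <- wide |>
    group_by(.data$feature, .data$group, .data$cycle) |>
    summarise(
      a = sum(.data$EQS & .data$AL), b = sum(.data$EQS & !.data$AL),
      c = sum(!.data$EQS & .data$AL), d = sum(!.data$EQS & !.data$AL),
      .groups = "drop"
    )
  run_tests <- function(tbl) {
    res <- purrr::pmap(
      list(tbl$a, tbl$b, tbl$c, tbl$d),
      function(a, b, c, d) mcnemar_edwards(tibble(a = a, b = b, c = c, d = d))
    )
    bind_cols(tbl, list_rbind(res))
  }
  per_feature <- run_tests(cells) |>
    mutate(scope = "feature_cycle")
  combined_groups <- cells |>
    group_by(feature = paste0(.data$group, " (combined)"), group = .data$group) |>
    summarise(
      a = sum(.data$a), b = sum(.data$b), c = sum(.data$c), d = sum(.data$d),
      .groups = "drop"
    ) |>
    mutate(cycle = NA_integer_)
  combined_all <- cells |>
    summarise(a = sum(.data$a), b = sum(.data$b), c = sum(.data$c), d = sum(.data$d)) |>
    mutate(
      feature = "all features (combined)", group = "all",
      cycle = NA_integer_
    )
  combined <- run_tests(bind_rows(combined_groups, combined_all)) |>
    mutate(scope = "combined")
  bind_rows(per_feature, combined) |>
    mutate(p_display = format_p_value(.data$p_value))
}

#' @method autoplot surgal_validation
#' @export
autoplot.surgal_validation <- function(object, metric = "f1", ...) {
  dat <- object$metrics |>
    filter(.data$scope == "feature", .data$cycle >= 0)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$cycle, y = .data[[metric]],
      colour = .data$arm, group = .data$arm
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature)) +
    ggplot2::labs(
      x = "annotation cycle", y = metric,
      colour = "frame selection"
    ) +
    ggplot2::theme_minimal()
}

#' Desk-scale annotation-efficiency experiment
#'
#' One end-to-end run of the prospective comparison under the package's
#' reference study conditions: a 14-video synthetic cohort (two start videos,
#' ten cycle videos, two held-out test videos) of 20-minute procedures
#' sampled at one frame per four seconds, equidistant selection every 30
#' seconds, and a rare instrument at 1% prevalence. Reports how many
#' positive frames of the rare instrument each arm accumulated and, when
#' `posthoc` is set, both arms' final-cycle test-set F1 for that instrument.
#'
#' @param seed Master seed for cohort, protocol and validation.
#' @param rare_feature The rare instrument under study.
#' @param n_videos,duration,fps,n_cycles,interval_s Cohort and protocol size.
#' @param config Training configuration (desk-scale default: 40 epochs at
#'   peak learning rate 0.02 with a 96-unit hidden layer; the wider layer
#'   makes one-shot generalisation from a single rare-instrument start frame
#'   reliable, which the active-learning bootstrap depends on).
#' @param posthoc Also run final-cycle post-hoc validation for the rare
#'   instrument's model group.
#' @param keep_ledger Return the full ledger as well.
#' @return List with `summary` (one-row tibble) and optionally `ledger` and
#'   `validation`.
#' @export
annotation_efficiency_experiment <- function(seed,
                                             rare_feature = "large_clip_applier",
                                             n_videos = 14L, duration = 1200,
                                             fps = 0.25, n_cycles = 10L,
                                             interval_s = 30,
                                             config = training_config(
                                               epochs = 40L,
                                               max_learning_rate = 0.02,
                                               hidden = 96L
                                             ),
                                             posthoc = TRUE,
                                             keep_ledger = FALSE) {
  s <- seed_stream(seed, 3)
  cohort <- generate_cohort(n_videos,
    duration = duration, fps = fps,
    seed = s[1]
  )
  ledger <- suppressWarnings(run_protocol(cohort,
    config = config,
    n_cycles = n_cycles, interval_s = interval_s, seed = s[2]
  ))
  schema <- ledger$schema
  g <- schema$model_group[match(rare_feature, schema$name)]
  al <- ledger$labels$AL[[g]]
  eqs <- ledger$labels$EQS[[g]]
  out <- tibble(
    seed = seed,
    rare_feature = rare_feature,
    start_rare_positives = sum(al[[rare_feature]][al$cycle == 0]),
    al_rare_positives = sum(al[[rare_feature]][al$cycle > 0]),
    eqs_rare_positives = sum(eqs[[rare_feature]][eqs$cycle > 0]),
    budget_total = sum(ledger$cycles$budget)
  )
  validation <- NULL
  if (posthoc) {
    validation <- posthoc_validation(ledger,
      cycles = n_cycles, groups = g,
      upper_baseline = FALSE, seed = s[3]
    )
    mx <- validation$metrics |>
      filter(.data$feature == rare_feature, .data$scope == "feature")
    out$al_rare_f1 <- mx$f1[mx$arm == "AL"]
    out$eqs_rare_f1 <- mx$f1[mx$arm == "EQS"]
  }
  res <- list(summary = out)
  if (keep_ledger) {
    res$ledger <- ledger
    res$validation <- validation
  }
  res
}
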