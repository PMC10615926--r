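schema <- default_schema()

test_that("cohort alternates centers and respects prevalence edge cases", {
  cohort <- tiny_cohort(n = 4)
  expect_equal(vapply(cohort, function(p) p$center, character(1)), c("A", "B", "A", "B"))
  prev <- default_prevalences(schema)
  prev$prevalence[prev$feature == "suction"] <- 0
  zero <- generate_cohort(2, duration = 300, fps = 0.5, prevalences = prev, seed = 1)
  expect_true(all(zero[[1]]$truth$suction == 0L))
  prev$prevalence[prev$feature == "suction"] <- 1.2
  expect_error(
    generate_cohort(2, duration = 300, fps = 0.5, prevalences = prev, seed = 1),
    "prevalence"
  )
})

test_that("rare binary tracks hit their stationary prevalence within sampling error", {
  # 20 videos x 30 min at a 1% target: empirical positive fraction within
  # +/- 50% relative (binomial error over dwell episodes)
  cohort <- generate_cohort(20, duration = 1800, fps = 0.25, seed = 123)
  frac <- mean(unlist(lapply(cohort, function(p) p$truth$large_clip_applier)))
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.015)
})

test_that("ordinal tracks match their target occupancancy (chi-square, 5 seeds)", {
  occupancy <- c(0.60, 0.24, 0.10, 0.052, 0.008)
  for (seed in 1:5) {
    x <- surgal:::ordinal_track(50000, occupancy, move_prob = 0.2, seed = seed)
    thinned <- x[seq(1, length(x), by = 50)] # break autocorrelation
    obs <- tabulate(thinned + 1L, nbins = 5)
    p <- suppressWarnings(stats::chisq.test(obs, p = occupancy)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("rendering is deterministic, white outside the body, monotone in blood and smoke", {
  p <- clean_procedure()
  fr1 <- render_frame(p, 10)
  fr2 <- render_frame(p, 10)
  expect_identical(fr1$pixels, fr2$pixels)
  expect_equal(fr1$timestamp_s, 10 / p$fps)
  expect_error(render_frame(p, p$n_frames), "frame_index")

  # out-of-body frames are completely white and duration is conserved
  cohort <- tiny_cohort(n = 2, seed = 7)
  q <- cohort[[1]]
  expect_equal(q$n_frames, q$duration * q$fps)
  oi <- which(q$truth$outside_body)
  expect_true(length(oi) > 0)
  white <- render_frame(q, oi[1] - 1L)
  expect_true(white$outside_body)
  expect_true(all(white$pixels == 1))

  # force levels and check monotone effects on a fixed frame
  red_mass <- vapply(0:4, function(lv) {
    p$truth$blood[6] <- lv
    p$truth$smoke[6] <- 0L
    px <- render_frame(p, 5)$pixels
    sum(px[, , 1] - (px[, , 2] + px[, , 3]) / 2)
  }, numeric(1))
  expect_true(all(diff(red_mass) > 0))
  brightness <- vapply(0:3, function(lv) {
    p$truth$smoke[6] <- lv
    p$truth$blood[6] <- 0L
    mean(render_frame(p, 5)$pixels)
  }, numeric(1))
  expect_true(all(diff(brightness) > 0))
})

test_that("simulated raters follow their error model exactly at the limits", {
  p <- clean_procedure()
  truth <- utils::head(p$truth, 40)
  clean <- simulate_rater(truth, schema, perfect_raters(1)[[1]], seed = 1)
  wide <- tidyr::pivot_wider(clean[, -4], names_from = "feature", values_from = "level")
  for (f in schema$name) {
    expect_equal(wide[[f]], truth[[f]])
  }
  flipper <- rater_profile("r", binary_flip_prob = 1, ordinal_noise = c("0" = 1))
  flipped <- simulate_rater(truth, schema, flipper, seed = 1)
  fw <- tidyr::pivot_wider(flipped[, -4], names_from = "feature", values_from = "level")
  expect_equal(fw$suction, 1L - truth$suction)
  expect_equal(fw$blood, truth$blood)
  # offsets are clipped to the level set
  shover <- rater_profile("r", binary_flip_prob = 0, ordinal_noise = c("2" = 1))
  shoved <- simulate_rater(truth, schema, shover, seed = 1)
  sw <- tidyr::pivot_wider(shoved[, -4], names_from = "feature", values_from = "level")
  expect_equal(sw$blood, pmin(truth$blood + 2L, 4L))
  expect_true(all(sw$smoke <= 3L))
})

test_that("default rater group agrees far more on binary than on ordinal features", {
  ks <- list()
  for (seed in 1:3) {
    cohort <- generate_cohort(2,
      duration = 1200, fps = 0.5,
      outside_rate = 0, seed = seed
    )
    truth <- utils::head(cohort[[1]]$truth, 500)
    tags <- simulate_raters(truth, schema, default_rater_profiles(6), seed = seed * 7)
    k1 <- function(f) {
      w <- tags |>
        dplyr::filter(feature == f) |>
        tidyr::pivot_wider(names_from = "rater_id", values_from = "level")
      fleiss_kappa(as.matrix(w[, -(1:3)]), categories = feature_levels(schema, f))
    }
    k_bin <- mean(vapply(
      c("suction", "cautery_hook", "azygos_vein", "gastric_tube"),
      k1, numeric(1)
    ))
    k_ord <- mean(vapply(c("blood", "smoke"), k1, numeric(1)))
    expect_gt(k_bin, k_ord)
  }
})

test_that("adjudication resolves only genuine three-way splits", {
  expect_equal(adjudicate(c(2L, 3L, 4L), truth = 3L, mode = "oracle"), 3L)
  expect_equal(adjudicate(c(1L, 2L, 4L), mode = "median"), 2L)
  expect_error(adjudicate(c(0L, 0L, 1L), mode = "median"), "majority")
  expect_error(adjudicate(c(0L, 1L), mode = "median"), "3 votes")
  expect_error(adjudicate(c(0L, 1L, 2L), mode = "oracle"), "ground-truth")
})

test_that("cohorts export to PNG frames plus manifests", {
  cohort <- tiny_cohort(n = 1, duration = 60, fps = 0.1, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  vdir <- file.path(dir, "video_01")
  manifest <- utils::read.csv(file.path(vdir, "manifest.csv"))
  expect_equal(nrow(manifest), cohort[[1]]$n_frames)
  expect_true(all(schema$name %in% names(manifest)))
  pngs <- list.files(vdir, pattern = "\\.png$")
  expect_equal(length(pngs), cohort[[1]]$n_frames)
  px <- png::readPNG(file.path(vdir, pngs[1]))
  expect_equal(dim(px), c(60, 80, 3))
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  expect_equal(meta$videos[[1]]$video_id, "video_01")
})
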