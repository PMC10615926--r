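schema <- default_schema()

test_that("videogram concatenates one center column per minute", {
  p <- clean_procedure(duration = 600, fps = 0.5) # 10 minutes
  vg <- make_videogram(p)
  expect_equal(dim(vg), c(60, 11, 3))
  # column k is the center column of the frame at minute k
  for (k in c(1, 5, 11)) {
    idx <- min(as.integer((k - 1) * 60 * p$fps), p$n_frames - 1L)
    fr <- render_frame(p, idx)
    expect_equal(vg[, k, ], fr$pixels[, 40, ])
  }
  # an all-outside video gives an all-white strip
  w <- p
  w$truth$outside_body <- TRUE
  expect_true(all(make_videogram(w) == 1))
  short <- clean_procedure(duration = 45, fps = 1)
  expect_error(make_videogram(short), "one minute")
})

test_that("barcode compression preserves the stream mean exactly", {
  v800 <- withr::with_seed(1, stats::runif(800))
  bc <- compress_barcode(v800)
  expect_equal(nrow(bc), 800)
  expect_equal(bc$value, v800) # identity binning
  v1600 <- withr::with_seed(2, stats::runif(1600))
  bc2 <- compress_barcode(v1600)
  expect_equal(bc2$value, colMeans(matrix(v1600, nrow = 2)))
  v1000 <- withr::with_seed(3, stats::runif(1000))
  bc3 <- compress_barcode(v1000)
  expect_equal(sum(bc3$n == 2), 200)
  expect_equal(sum(bc3$n == 1), 600)
  expect_equal(sum(bc3$value * bc3$n) / sum(bc3$n), mean(v1000), tolerance = 1e-12)
  # conservation holds for arbitrary lengths
  for (n in c(5, 801, 2341, 7919)) {
    v <- withr::with_seed(n, stats::runif(n))
    b <- compress_barcode(v)
    expect_equal(nrow(b), min(800, n))
    expect_true(all(abs(diff(range(b$n))) <= 1))
    expect_equal(sum(b$value * b$n) / sum(b$n), mean(v), tolerance = 1e-12)
  }
  expect_error(compress_barcode(numeric(0)), "empty")
  expect_error(compress_barcode(c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("feature summaries report durations, per-mille presence and certainty", {
  all_zero <- summarize_feature(rep(0L, 10), schema = schema, feature = "suction")
  expect_equal(all_zero$relevant_duration_s, 0)
  expect_equal(all_zero$per_mille, 0)
  blood <- summarize_feature(c(0L, 3L, 4L, 2L),
    certainties = c(0.9, 0.8, 0.7, 1),
    schema = schema, feature = "blood", timebase = 1
  )
  expect_equal(blood$relevant_duration_s, 2) # levels 3 and 4 exceed 2
  expect_equal(blood$mean_certainty, mean(c(0.9, 0.8, 0.7, 1)))
  expect_equal(blood$max_certainty, 1)
  expect_equal(blood$min_certainty, 0.7)
  stream <- withr::with_seed(4, sample(0:1, 300, replace = TRUE, prob = c(0.9, 0.1)))
  s <- summarize_feature(stream, schema = schema, feature = "scissors", timebase = 2)
  expect_equal(s$per_mille, 1000 * sum(stream == 1) / 300)
  expect_equal(s$relevant_duration_s, 2 * sum(stream == 1))
  expect_error(
    summarize_feature(c(0L, 9L), schema = schema, feature = "suction"),
    "level set"
  )
})

test_that("report assembly ties barcodes and summaries to the same stream", {
  p <- clean_procedure(duration = 300, fps = 0.5, seed = 15)
  preds <- tidyr::crossing(
    frame_index = p$truth$frame_index,
    feature = c("blood", "suction")
  )
  lv <- withr::with_seed(
    7,
    ifelse(preds$feature == "blood", sample(0:4, nrow(preds), TRUE), sample(0:1, nrow(preds), TRUE))
  )
  preds$level <- as.integer(lv)
  preds$certainty <- withr::with_seed(8, stats::runif(nrow(preds)))
  rep <- surgomic_report(preds, p, schema, n_bins = 50)
  expect_named(rep$barcodes, c("blood", "suction"))
  expect_equal(nrow(rep$barcodes$blood), 50)
  # summaries are computed from the raw stream, not the bins
  rep2 <- surgomic_report(preds, p, schema, n_bins = 10)
  expect_equal(rep$summaries, rep2$summaries)
  blood_stream <- preds[preds$feature == "blood", ]
  expect_equal(
    rep$summaries$relevant_duration_s[rep$summaries$feature == "blood"],
    sum(blood_stream$level > 2) / p$fps
  )
  # barcode mean equals raw indicator mean (weighted)
  bc <- rep$barcodes$suction
  raw <- as.numeric(preds$level[preds$feature == "suction"] == 1)
  expect_equal(sum(bc$value * bc$n) / sum(bc$n), mean(raw), tolerance = 1e-12)
})

test_that("rendered reports are byte-stable and JSON summaries round-trip", {
  p <- clean_procedure(duration = 300, fps = 0.5, seed = 16)
  preds <- tidyr::crossing(
    frame_index = p$truth$frame_index,
    feature = schema$name
  ) |>
    dplyr::left_join(
      tidyr::pivot_longer(p$truth, -c("video_id", "frame_index", "timestamp_s", "outside_body"),
        names_to = "feature", values_to = "level"
      ),
      by = c("frame_index", "feature")
    )
  preds$certainty <- withr::with_seed(9, stats::runif(nrow(preds)))
  rep <- surgomic_report(preds, p, schema, n_bins = 100)
  d <- withr::local_tempdir()
  out1 <- render_report(rep, file.path(d, "a.png"))
  out2 <- render_report(rep, file.path(d, "b.png"))
  expect_identical(
    readBin(out1$png, "raw", file.size(out1$png)),
    readBin(out2$png, "raw", file.size(out2$png))
  )
  js <- jsonlite::read_json(out1$json, simplifyVector = TRUE)
  expect_equal(js$video_id, p$video_id)
  expect_equal(js$features$relevant_duration_s, rep$summaries$relevant_duration_s)
  expect_equal(js$features$per_mille, rep$summaries$per_mille)
  # an all-absent feature renders an all-light barcode
  empty <- preds
  empty$level <- 0L
  rep0 <- surgomic_report(empty[empty$feature == "suction", ], p, schema)
  expect_true(all(rep0$barcodes$suction$value == 0))
})
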