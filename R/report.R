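#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Videogram: temporal overview strip of a procedure
#'
#' Concatenates the center pixel column of one frame per minute of the video
#' into a horizontal strip: `floor(duration / 60) + 1` columns, one per whole
#' minute from 0 onwards, each as tall as a frame.
#'
#' @param procedure A `surgal_procedure` of at least one minute.
#' @param resolution Frame rendering resolution.
#' @return H x minutes x 3 numeric array.
#' @export
make_videogram <- function(procedure, resolution = c(60, 80)) {
  if (procedure$duration < 60) {
    abort("videogram needs at least one minute of video")
  }
  minutes <- seq(0, floor(procedure$duration / 60))
  h <- resolution[1]
  strip <- array(0, dim = c(h, length(minutes), 3))
  mid <- ceiling(resolution[2] / 2)
  for (k in seq_along(minutes)) {
    idx <- as.integer(floor(minutes[k] * 60 * procedure$fps + 1e-9))
    idx <- min(idx, procedure$n_frames - 1L)
    fr <- render_frame(procedure, idx, resolution = resolution)
    strip[, k, ] <- fr$pixels[, mid, ]
  }
  strip
}

#' Compress a prediction stream into a barcode
#'
#' Partitions the per-frame value stream into at most `n_bins` contiguous
#' chunks whose sizes differ by at most one and represents each chunk by its
#' mean (and mean certainty). The bin means conserve the overall mean
#' exactly: the chunk-size-weighted mean of the bins equals the mean of the
#' raw stream. With `n_bins` or fewer values the binning is the identity.
#'
#' @param values Numeric stream in \[0, 1\] (binary presence or a
#'   relevant-level indicator for ordinal features).
#' @param certainties Optional aligned certainty stream.
#' @param n_bins Maximum number of bins (display width of the barcode).
#' @param timebase Seconds per prediction; sets the per-bin duration.
#' @return A `surgal_barcode` tibble: `bin`, `value`, `certainty`, `n`
#'   (values per bin), `bin_duration_s`.
#' @export
compress_barcode <- function(values, certainties = NULL, n_bins = 800,
                             timebase = 1) {
  n <- length(values)
  if (n == 0) {
    abort("empty prediction stream")
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    abort("barcode values must lie in [0, 1]")
  }
  if (!is.null(certainties) && length(certainties) != n) {
    abort("certainties must align with values")
  }
  k <- min(n_bins, n)
  # chunk sizes differ by at most 1 and partition the stream contiguously
  bin_of <- ceiling(seq_len(n) * k / n)
  value <- as.numeric(tapply(values, bin_of, mean))
  cert <- if (is.null(certainties)) {
    rep(NA_real_, k)
  } else {
    as.numeric(tapply(certainties, bin_of, mean))
  }
  size <- as.integer(tabulate(bin_of, nbins = k))
  out <- tibble(
    bin = seq_len(k), value = value, certainty = cert,
    n = size, bin_duration_s = size * timebase
  )
  class(out) <- c("surgal_barcode", class(out))
  out
}

#' Per-feature duration summary of a prediction stream
#'
#' Binary features report the total positive duration and the per-mille
#' presence; ordinal features report the duration spent above the feature's
#' relevant-level threshold (above 2 for blood, above 1 for smoke). All
#' features report mean, maximum and minimum certainty.
#'
#' @param predictions Integer level/presence stream.
#' @param certainties Optional aligned certainty stream.
#' @param schema A feature schema.
#' @param feature Feature name.
#' @param timebase Seconds per prediction.
#' @return One-row tibble.
#' @export
summarize_feature <- function(predictions, certainties = NULL, schema, feature,
                              timebase = 1) {
  row <- schema_row(schema, feature)
  lv <- feature_levels(schema, feature)
  if (!all(predictions %in% lv)) {
    abort(paste0("predictions outside the level set of '", feature, "'"))
  }
  positive <- if (row$kind == "binary") {
    predictions == 1L
  } else {
    predictions > relevant_level_threshold(schema, feature)
  }
  cert <- certainties %||% rep(NA_real_, length(predictions))
  tibble(
    feature = feature,
    kind = row$kind,
    n_predictions = length(predictions),
    total_duration_s = length(predictions) * timebase,
    relevant_duration_s = sum(positive) * timebase,
    per_mille = 1000 * sum(positive) / length(predictions),
    mean_certainty = mean(cert),
    max_certainty = if (all(is.na(cert))) NA_real_ else max(cert, na.rm = TRUE),
    min_certainty = if (all(is.na(cert))) NA_real_ else min(cert, na.rm = TRUE)
  )
}

#' Assemble a surgomic report
#'
#' Combines a videogram, one barcode per feature (relevant-level indicator
#' for ordinal features, presence for binary features) with a certainty
#' overlay, and per-feature duration summaries, all computed from the same
#' prediction stream.
#'
#' @param predictions Long tibble: `frame_index`, `feature`, `level`,
#'   optionally `certainty` in \[0, 1\].
#' @param procedure The `surgal_procedure` the predictions refer to (used for
#'   the videogram and the timebase).
#' @param schema A feature schema.
#' @param n_bins Barcode width.
#' @return A `surgal_report` list with `videogram`, `barcodes` (named list),
#'   `summaries` (tibble) and `timebase_s`.
#' @export
surgomic_report <- function(predictions, procedure, schema, n_bins = 800) {
  timebase <- 1 / procedure$fps
  feats <- intersect(schema$name, unique(predictions$feature))
  barcodes <- list()
  summaries <- list()
  for (f in feats) {
    dat <- predictions |>
      filter(.data$feature == f) |>
      arrange(.data$frame_index)
    row <- schema_row(schema, f)
    indicator <- if (row$kind == "binary") {
      as.numeric(dat$level == 1L)
    } else {
      as.numeric(dat$level > relevant_level_threshold(schema, f))
    }
    cert <- if ("certainty" %in% names(dat)) dat$certainty else NULL
    barcodes[[f]] <- compress_barcode(indicator, cert,
      n_bins = n_bins, timebase = timebase
    )
    summaries[[f]] <- summarize_feature(dat$level, cert, schema, f,
      timebase = timebase
    )
  }
  structure(
    list(
      video_id = procedure$video_id,
      videogram = make_videogram(procedure),
      barcodes = barcodes,
      summaries = list_rbind(summaries),
      timebase_s = timebase
    ),
    class = "surgal_report"
  )
}

#' Certainty scores from Monte-Carlo uncertainty
#'
#' Maps per-frame uncertainty (mean across-inference standard deviation) to a
#' display certainty in \[0, 1\] as `1 - u / max(u)`; constant streams map
#' to 1.
#'
#' @param uncertainty Non-negative per-frame scores.
#' @return Certainty values in \[0, 1\].
#' @export
certainty_from_uncertainty <- function(uncertainty) {
  top <- max(uncertainty)
  if (top <= 0) {
    return(rep(1, length(uncertainty)))
  }
  1 - uncertainty / top
}

#' Render a surgomic report to a PNG page plus JSON summary
#'
#' Draws the videogram on top and one barcode row per feature below it
#' (darker bars mean more positive predictions in the interval), with an
#' optional red certainty overlay, and writes a machine-readable JSON file
#' with the per-feature summaries. Rendering is deterministic: the same
#' report produces byte-identical files.
#'
#' @param report A `surgal_report`.
#' @param path Output PNG path (the JSON summary is written next to it).
#' @param with_certainty Overlay mean certainty per bin.
#' @param row_height Pixel height of one barcode row.
#' @return Invisibly, a list with the written `png` and `json` paths.
#' @export
render_report <- function(report, path, with_certainty = TRUE, row_height = 14) {
  feats <- names(report$barcodes)
  width <- max(vapply(report$barcodes, nrow, integer(1)))
  vg <- report$videogram
  vg_h <- dim(vg)[1]
  gap <- 4L
  height <- vg_h + gap + length(feats) * (row_height + gap)
  page <- array(1, dim = c(height, width, 3))
  # videogram, horizontally stretched to the page width
  vg_cols <- dim(vg)[2]
  col_map <- pmin(vg_cols, pmax(1L, ceiling(seq_len(width) * vg_cols / width)))
  page[seq_len(vg_h), , ] <- vg[, col_map, ]
  y <- vg_h + gap
  for (f in feats) {
    bc <- report$barcodes[[f]]
    shade <- 1 - bc$value # darker = more positive predictions
    rows <- y + seq_len(row_height)
    for (ch in 1:3) {
      page[rows, seq_len(nrow(bc)), ch] <- matrix(shade,
        nrow = row_height, ncol = nrow(bc), byrow = TRUE
      )
    }
    if (with_certainty && !all(is.na(bc$certainty))) {
      # certainty as a red dot row: vertical position encodes certainty
      dot_row <- y + 1L + as.integer(round((1 - bc$certainty) * (row_height - 2L)))
      idx_ok <- which(!is.na(bc$certainty))
      page[cbind(dot_row[idx_ok], idx_ok, 1L)] <- 1
      page[cbind(dot_row[idx_ok], idx_ok, 2L)] <- 0
      page[cbind(dot_row[idx_ok], idx_ok, 3L)] <- 0
    }
    y <- y + row_height + gap
  }
  png::writePNG(page, path)
  json_path <- sub("\\.png$", ".json", path)
  if (identical(json_path, path)) {
    json_path <- paste0(path, ".json")
  }
  jsonlite::write_json(
    list(
      video_id = report$video_id,
      timebase_s = report$timebase_s,
      features = report$summaries
    ),
    json_path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(list(png = path, json = json_path))
}

#' @export
print.surgal_report <- function(x, ...) {
  cat(
    "<surgal_report> ", x$video_id, ": ", length(x$barcodes),
    " feature barcodes, videogram ", dim(x$videogram)[2], " columns\n",
    sep = ""
  )
  invisible(x)
}

#' @method autoplot surgal_report
#' @export
autoplot.surgal_report <- function(object, ...) {
  dat <- list_rbind(imap(object$barcodes, function(bc, f) {
    mutate(bc, feature = f)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = 1, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$feature), switch = "y") +
    ggplot2::scale_fill_gradient(low = "white", high = "black", limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      strip.text.y.left = ggplot2::element_text(angle = 0)
    ) +
    ggplot2::labs(
      x = "interval", y = NULL, fill = "positive fraction",
      title = paste("feature barcodes:", object$video_id)
    )
}
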