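#' Majority-vote consensus for one frame/feature
#'
#' Merges exactly three independent tag annotations: three identical tags are
#' `unanimous`, a 2-vs-1 split is resolved by `majority`, and three distinct
#' ordinal levels yield an adjudication request (`level` is `NA` and
#' `provenance` is `"adjudication_required"`), to be resolved by
#' [adjudicate()]. Binary features always have a majority.
#'
#' @param tags Tibble with exactly 3 rows and columns `rater_id` and `level`
#'   (additional columns such as `video_id`, `frame_index`, `feature` are
#'   carried through).
#' @return One-row tibble with `level` and `provenance`.
#' @export
merge_majority <- function(tags) {
  if (nrow(tags) != 3) {
    abort("merge_majority expects exactly 3 tags")
  }
  if (anyDuplicated(tags$rater_id) > 0) {
    abort("tags must come from 3 distinct raters")
  }
  lv <- sort(tags$level)
  carried <- tags[1, intersect(c("video_id", "frame_index", "feature"), names(tags)), drop = FALSE]
  if (lv[1] == lv[3]) {
    out <- tibble(level = lv[2], provenance = "unanimous")
  } else if (lv[1] == lv[2] || lv[2] == lv[3]) {
    # the majority value of a 2-vs-1 split is the median of the sorted votes
    out <- tibble(level = lv[2], provenance = "majority")
  } else {
    out <- tibble(level = NA_integer_, provenance = "adjudication_required")
  }
  dplyr::bind_cols(carried, out)
}

#' Consensus labels for a table of per-rater tags
#'
#' Applies 3-rater majority voting per frame and feature. When more than
#' three raters are present the first three by `rater_id` are used (test-set
#' frames carry six raters for agreement analysis, but the reference label is
#' built from the first three for pipeline symmetry). Three-way ordinal
#' disagreements are adjudicated with [adjudicate()].
#'
#' @param tags Long tibble: `video_id`, `frame_index`, `feature`, `rater_id`,
#'   `level`.
#' @param schema A feature schema.
#' @param truth Optional ground-truth tibble (wide, one column per feature)
#'   required for oracle adjudication.
#' @param adjudication `"oracle"` (a discussion panel recovers the true
#'   level) or `"median"`.
#' @return Tibble `video_id`, `frame_index`, `feature`, `level`,
#'   `provenance` (one of `unanimous`, `majority`, `adjudicated`).
#' @export
consensus_labels <- function(tags, schema, truth = NULL,
                             adjudication = c("oracle", "median")) {
  adjudication <- match.arg(adjudication)
  picked <- tags |>
    arrange(.data$video_id, .data$frame_index, .data$feature, .data$rater_id) |>
    group_by(.data$video_id, .data$frame_index, .data$feature) |>
    slice_head(n = 3) |>
    summarise(
      n_tags = dplyr::n(),
      v1 = min(.data$level),
      v3 = max(.data$level),
      v2 = sort(.data$level)[2],
      .groups = "drop"
    )
  if (any(picked$n_tags != 3)) {
    abort("every frame/feature needs at least 3 rater tags")
  }
  picked <- picked |>
    mutate(
      provenance = dplyr::case_when(
        .data$v1 == .data$v3 ~ "unanimous",
        .data$v1 == .data$v2 | .data$v2 == .data$v3 ~ "majority",
        TRUE ~ "adjudication_required"
      ),
      level = .data$v2
    )
  need <- picked$provenance == "adjudication_required"
  if (any(need)) {
    if (adjudication == "oracle") {
      if (is.null(truth)) {
        abort("oracle adjudication requires the ground-truth table")
      }
      truth_long <- pivot_longer(
        truth[, c("video_id", "frame_index", intersect(schema$name, names(truth)))],
        -c("video_id", "frame_index"),
        names_to = "feature", values_to = "truth_level"
      )
      picked <- left_join(picked, truth_long,
        by = c("video_id", "frame_index", "feature")
      )
      if (any(need & is.na(picked$truth_level))) {
        abort("ground truth missing for a frame requiring adjudication")
      }
      picked$level[need] <- picked$truth_level[need]
      picked$truth_level <- NULL
    }
    # median adjudication: with three distinct votes the median is v2,
    # already stored in `level`
    picked$provenance[need] <- "adjudicated"
  }
  picked |>
    mutate(level = as.integer(.data$level)) |>
    select("video_id", "frame_index", "feature", "level", "provenance") |>
    arrange(.data$video_id, .data$frame_index, .data$feature)
}

#' Breakdown of consensus provenance
#'
#' Fractions of consensus labels that were unanimous, decided by majority
#' vote, or adjudicated after a three-way disagreement. The fractions sum
#' to 1.
#'
#' @param consensus Output of [consensus_labels()].
#' @return Tibble with columns `provenance`, `n`, `fraction`.
#' @export
agreement_breakdown <- function(consensus) {
  if (is.null(consensus) || nrow(consensus) == 0) {
    abort("consensus set is empty")
  }
  out <- tibble(provenance = c("unanimous", "majority", "adjudicated")) |>
    left_join(count(consensus, .data$provenance), by = "provenance") |>
    mutate(
      n = ifelse(is.na(.data$n), 0L, .data$n),
      fraction = .data$n / sum(.data$n)
    )
  out
}
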