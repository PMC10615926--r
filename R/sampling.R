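#' Equidistant frame selection from one video
#'
#' Selects the frames at timestamps `origin_s`, `origin_s + interval_s`, ...
#' strictly below the video duration. Frames falling inside out-of-body
#' (white-frame) intervals are skipped without substitution, so the retained
#' frames stay strictly equidistant.
#'
#' @param procedure A `surgal_procedure`.
#' @param interval_s Sampling interval in seconds (default: one frame every
#'   two minutes).
#' @param origin_s Timestamp of the first frame.
#' @return Tibble `video_id`, `frame_index`, `timestamp_s` in chronological
#'   order.
#' @export
select_equidistant <- function(procedure, interval_s = 120, origin_s = 0) {
  if (!is.numeric(interval_s) || interval_s <= 0) {
    abort("interval_s must be > 0")
  }
  ts <- seq(origin_s, procedure$duration - 1e-9, by = interval_s)
  idx <- as.integer(floor(ts * procedure$fps + 1e-9))
  idx <- idx[idx < procedure$n_frames]
  sel <- procedure$truth[idx + 1L, c("video_id", "frame_index", "timestamp_s", "outside_body")]
  sel <- sel[!sel$outside_body, c("video_id", "frame_index", "timestamp_s")]
  as_tibble(sel)
}

#' Select the most uncertain frames from a pool
#'
#' Returns the `budget` frames with the highest uncertainty score. Ties are
#' broken deterministically by video chronology and then frame index; the
#' selected frames are returned in chronological order, mirroring the
#' annotation workflow where chronological order is maintained.
#'
#' @param pool Tibble with columns `video_id`, `frame_index`, `timestamp_s`
#'   and either an `uncertainty` column or a separate `scores` vector. An
#'   optional `video_order` column fixes video chronology (defaults to order
#'   of first appearance).
#' @param budget Number of frames to select.
#' @param scores Optional numeric vector aligned with `pool` rows.
#' @return Tibble of selected frames with their `uncertainty`, in
#'   chronological order.
#' @export
select_most_uncertain <- function(pool, budget, scores = NULL) {
  if (!is_count(budget)) {
    abort("budget must be a non-negative count")
  }
  pool <- as_tibble(pool)
  if (!is.null(scores)) {
    if (length(scores) != nrow(pool)) {
      abort("scores must align with pool rows")
    }
    pool$uncertainty <- scores
  }
  if (!"uncertainty" %in% names(pool) || anyNA(pool$uncertainty)) {
    abort("every pool member needs an uncertainty score")
  }
  if (!"video_order" %in% names(pool)) {
    pool$video_order <- match(pool$video_id, unique(pool$video_id))
  }
  if (budget > nrow(pool)) {
    warn(paste0(
      "budget (", budget, ") exceeds pool size (", nrow(pool),
      "); returning the entire pool"
    ))
    budget <- nrow(pool)
  }
  pool |>
    arrange(desc(.data$uncertainty), .data$video_order, .data$frame_index) |>
    slice_head(n = budget) |>
    arrange(.data$video_order, .data$frame_index) |>
    select(-"video_order")
}

#' Build the start set from the first video of each center
#'
#' Selects frames equidistantly from the given videos and, when
#' `oracle_fill` is set, searches the same videos' ground truth for one frame
#' of every feature level that the equidistant selection missed, appending it
#' to the affected model group's start set only. This mirrors start-set
#' construction where a missing rare level (e.g. the highest blood level) is
#' filled in by manual selection so every feature and feature level is
#' represented.
#'
#' @param videos List of `surgal_procedure` (at least one per center).
#' @param schema A feature schema.
#' @param interval_s Equidistant interval in seconds.
#' @param oracle_fill Whether to fill in missing feature levels from ground
#'   truth.
#' @return List with `sets` (named list per model group of frame tibbles with
#'   a `source` column `equidistant`/`fill`), `fills` (tibble of fill
#'   frames) and `missing` (tibble of levels that no available frame
#'   exhibits; reported with a warning).
#' @export
build_start_set <- function(videos, schema, interval_s = 120,
                            oracle_fill = TRUE) {
  base <- list_rbind(lapply(videos, select_equidistant, interval_s = interval_s))
  base$source <- "equidistant"
  truth_all <- list_rbind(lapply(videos, function(p) p$truth[!p$truth$outside_body, ]))
  groups <- model_groups(schema)
  fills <- tibble(
    video_id = character(0), frame_index = integer(0),
    timestamp_s = numeric(0), group = character(0),
    feature = character(0), level = integer(0)
  )
  missing <- tibble(group = character(0), feature = character(0), level = integer(0))
  sets <- list()
  base_truth <- semi_join(truth_all, base, by = c("video_id", "frame_index"))
  for (g in names(groups)) {
    set <- base
    if (oracle_fill) {
      for (f in groups[[g]]) {
        present <- unique(c(base_truth[[f]], fills$level[fills$group == g & fills$feature == f]))
        for (lv in feature_levels(schema, f)) {
          if (lv %in% present) next
          cand <- truth_all[truth_all[[f]] == lv, ]
          cand <- anti_join(cand, set, by = c("video_id", "frame_index"))
          if (nrow(cand) == 0) {
            warn(paste0(
              "no available frame exhibits ", f, " level ", lv,
              "; start set for group '", g, "' remains incomplete"
            ))
            missing <- bind_rows(missing, tibble(group = g, feature = f, level = lv))
            next
          }
          pick <- cand[1, c("video_id", "frame_index", "timestamp_s")]
          pick$source <- "fill"
          set <- bind_rows(set, pick)
          fills <- bind_rows(fills, tibble(
            video_id = pick$video_id, frame_index = pick$frame_index,
            timestamp_s = pick$timestamp_s, group = g, feature = f, level = lv
          ))
        }
      }
    }
    sets[[g]] <- arrange(set, .data$video_id, .data$frame_index)
  }
  list(sets = sets, fills = fills, missing = missing)
}

#' Frame accounting across start set, sampling arms and test set
#'
#' Computes the per-group annotated-frame totals (start + equidistant +
#' active-learning + test) and the grand total of distinct annotated frames.
#' Per-group start counts are assumed to share one equidistant base plus
#' group-specific fill frames, so the number of distinct start frames is the
#' smallest group count plus the total excess (the fills); `n_fill` can
#' override that default.
#'
#' @param start_per_group Named vector of start-set sizes per model group.
#' @param eqs_total Total frames selected equidistantly over all cycles.
#' @param al_per_group Named vector of active-learning frame counts per
#'   model group.
#' @param test_total Test-set size.
#' @param n_fill Number of fill frames in the start sets (default: total
#'   excess of the group counts over their minimum).
#' @return A `surgal_frame_accounting` list with `per_group` (tibble) and
#'   `grand_total`.
#' @examples
#' frame_accounting(
#'   start_per_group = c(blood_smoke = 344, anatomy = 343, instruments = 343),
#'   eqs_total = 3264,
#'   al_per_group = c(blood_smoke = 3264, anatomy = 3264, instruments = 3264),
#'   test_total = 604
#' )
#' @export
frame_accounting <- function(start_per_group, eqs_total, al_per_group,
                             test_total, n_fill = NULL) {
  stopifnot(
    all(start_per_group >= 0), eqs_total >= 0,
    all(al_per_group >= 0), test_total >= 0
  )
  groups <- names(start_per_group) %||% paste0("group_", seq_along(start_per_group))
  al <- al_per_group[groups]
  per_group <- tibble(
    group = groups,
    start = as.numeric(start_per_group),
    eqs = as.numeric(eqs_total),
    al = as.numeric(al),
    test = as.numeric(test_total),
    total = as.numeric(start_per_group) + eqs_total + as.numeric(al) + test_total
  )
  if (is.null(n_fill)) {
    n_fill <- sum(start_per_group - min(start_per_group))
  }
  grand_total <- min(start_per_group) + n_fill + eqs_total +
    sum(al_per_group) + test_total
  structure(
    list(per_group = per_group, grand_total = grand_total, n_fill = n_fill),
    class = "surgal_frame_accounting"
  )
}

#' @export
print.surgal_frame_accounting <- function(x, ...) {
  cat("Annotated-frame accounting\n")
  print(x$per_group)
  cat("Distinct annotated frames:", format(x$grand_total, big.mark = ","), "\n")
  invisible(x)
}
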