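#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' One-class precision, recall and F1
#'
#' Standard positive-class metrics for binary vectors. Divisions by zero
#' (no predicted positives, no true positives) yield 0, so a class that is
#' never predicted scores 0 rather than `NaN`.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return One-row tibble: `precision`, `recall`, `f1`, `support` (number of
#'   positive truth instances).
#' @export
binary_prf <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length")
  }
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1, support = sum(truth == 1))
}

#' Hierarchical macro F1 for an ordinal feature
#'
#' Each level is scored one-vs-rest over all images (first aggregation over
#' images), then the per-level F1 scores are averaged without weighting
#' (second aggregation over levels), yielding the macro F1. Levels with zero
#' support in both truth and predictions are dropped; a level that occurs but
#' is never predicted contributes an F1 of 0 to the mean.
#'
#' @param truth,pred Integer level vectors of equal length.
#' @param levels Level set (defaults to the union of observed values).
#' @return List with `per_level` (tibble `level`, `precision`, `recall`,
#'   `f1`, `support`) and scalars `macro_f1`, `macro_precision`,
#'   `macro_recall`.
#' @export
hierarchical_macro_f1 <- function(truth, pred, levels = NULL) {
  if (length(truth) == 0) {
    abort("empty input")
  }
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length")
  }
  levels <- sort(unique(levels %||% union(truth, pred)))
  per_level <- list_rbind(lapply(levels, function(lv) {
    bind_cols(
      tibble(level = as.integer(lv)),
      binary_prf(as.integer(truth == lv), as.integer(pred == lv))
    )
  }))
  used <- per_level$support > 0 | vapply(per_level$level, function(lv) any(pred == lv), logical(1))
  scored <- per_level[used, ]
  list(
    per_level = per_level,
    macro_f1 = mean(scored$f1),
    macro_precision = mean(scored$precision),
    macro_recall = mean(scored$recall)
  )
}

#' Paired correctness table for two classifiers
#'
#' @param truth Reference labels.
#' @param pred1,pred2 Predictions of the two classifiers on the same test
#'   instances.
#' @return One-row tibble with cells `a` (both correct), `b` (only the first
#'   correct), `c` (only the second correct), `d` (both wrong).
#' @export
paired_correctness <- function(truth, pred1, pred2) {
  c1 <- pred1 == truth
  c2 <- pred2 == truth
  tibble(
    a = sum(c1 & c2), b = sum(c1 & !c2),
    c = sum(!c1 & c2), d = sum(!c1 & !c2)
  )
}

#' McNemar test with Edwards continuity correction
#'
#' Statistic `(|b - c| - 1)^2 / (b + c)` on the discordant cells of a paired
#' correctness table, compared against a chi-square distribution with one
#' degree of freedom. When both classifiers produce the exact same
#' classifications (`b + c = 0`) the result is left blank (`blank = TRUE`,
#' `NA` statistic and p-value).
#'
#' @param table One-row data frame (or list) with counts `a`, `b`, `c`, `d`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `blank`,
#'   `significant` (p < 0.05).
#' @export
mcnemar_edwards <- function(table) {
  b <- table$b
  cc <- table$c
  if (any(c(table$a, b, cc, table$d) < 0)) {
    abort("table counts must be non-negative")
  }
  if (b + cc == 0) {
    return(tibble(
      statistic = NA_real_, df = 1L, p_value = NA_real_,
      blank = TRUE, significant = NA
    ))
  }
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(statistic = stat, df = 1L, p_value = p, blank = FALSE, significant = p < 0.05)
}

#' Combine paired correctness tables cellwise
#'
#' Contingency tables of several features and/or cycles are combined by
#' summing their cells before testing, so group-level tests pool the
#' discordant counts.
#'
#' @param tables A data frame of tables (one per row) or a list of one-row
#'   tables with columns `a`, `b`, `c`, `d`.
#' @return One-row tibble with summed cells.
#' @export
combine_tables <- function(tables) {
  if (is.data.frame(tables)) {
    if (nrow(tables) < 1) abort("need at least one table")
    tbl <- tables
  } else {
    if (length(tables) < 1) abort("need at least one table")
    tbl <- list_rbind(lapply(tables, as_tibble))
  }
  tibble(a = sum(tbl$a), b = sum(tbl$b), c = sum(tbl$c), d = sum(tbl$d))
}

#' Format p-values for display
#'
#' Three decimals with values below 0.001 floored to `"<0.001"`; blank
#' markers render as an empty string.
#'
#' @param p Numeric p-values (NA = blank).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Fleiss kappa
#'
#' Chance-corrected agreement for a fixed number of raters over many items:
#' `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)` with the usual observed and
#' expected agreement terms. When every rating falls in a single category the
#' expected agreement is 1 and kappa is undefined (`NA`).
#'
#' @param ratings Items x raters matrix (or data frame) of category codes.
#' @param categories Optional category set (defaults to observed values).
#' @return Scalar kappa, or `NA` when undefined.
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2 || ncol(ratings) < 2) {
    abort("need at least 2 items and 2 raters")
  }
  if (anyNA(ratings)) {
    abort("ratings table must be complete (no missing entries)")
  }
  categories <- categories %||% sort(unique(as.vector(ratings)))
  n_raters <- ncol(ratings)
  counts <- vapply(
    categories,
    function(k) rowSums(ratings == k),
    numeric(nrow(ratings))
  )
  counts <- matrix(counts, nrow = nrow(ratings))
  p_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (nrow(ratings) * n_raters)
  pe_bar <- sum(p_j^2)
  if (abs(1 - pe_bar) < 1e-12) {
    return(NA_real_)
  }
  (p_bar - pe_bar) / (1 - pe_bar)
}

# Merge one item's votes from m raters into a single pseudo-rating:
# majority value when unique, otherwise the median (deterministic,
# order-respecting tie-break for ordinal scales).
merge_votes <- function(v) {
  tab <- table(v)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) {
    as.integer(top)
  } else {
    as.integer(stats::median(v))
  }
}

#' Agreement of merged rater combinations
#'
#' With six raters per item, `m = 1` scores the raw six-rater table; for
#' `m` of 3 or 5, every one of the `choose(6, m)` rater combinations is
#' merged per item by majority vote (ordinal three-way ties resolved by the
#' median), producing `choose(6, m)` pseudo-raters whose table is scored with
#' [fleiss_kappa()] (default, `method = "pooled"`). The alternative reading,
#' `method = "mean"`, averages the Fleiss kappa computed within each raw
#' m-rater combination instead.
#'
#' @param ratings Items x 6 matrix of category codes.
#' @param m Merge size: 1, 3 or 5.
#' @param method `"pooled"` (default) or `"mean"`, see Details.
#' @param categories Optional category set.
#' @return Scalar kappa.
#' @export
merged_rater_kappa <- function(ratings, m, method = c("pooled", "mean"),
                               categories = NULL) {
  method <- match.arg(method)
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 6) {
    abort("merged_rater_kappa expects exactly 6 raters")
  }
  if (!m %in% c(1L, 3L, 5L)) {
    abort("merge size m must be 1, 3 or 5")
  }
  if (m == 1) {
    return(fleiss_kappa(ratings, categories = categories))
  }
  combos <- utils::combn(6L, m)
  if (method == "pooled") {
    pseudo <- apply(combos, 2, function(cols) {
      apply(ratings[, cols, drop = FALSE], 1, merge_votes)
    })
    fleiss_kappa(pseudo, categories = categories)
  } else {
    mean(apply(combos, 2, function(cols) {
      fleiss_kappa(ratings[, cols, drop = FALSE], categories = categories)
    }), na.rm = TRUE)
  }
}

#' Per-feature metrics table
#'
#' Computes the performance table for a set of features: binary features get
#' one positive-class row; ordinal features get one one-vs-rest row per level
#' plus a `(macro)` row with the hierarchical macro scores. Additional macro
#' rows aggregate each model group and all features as unweighted means of
#' the member features' scores.
#'
#' @param truth,pred Wide tibbles with one level column per feature, aligned
#'   rows (test instances).
#' @param schema A feature schema.
#' @return Tibble: `feature`, `level` (`NA` for whole-feature rows),
#'   `precision`, `recall`, `f1`, `support`, `scope` (`"level"`, `"feature"`
#'   or `"group"`).
#' @export
feature_metrics <- function(truth, pred, schema) {
  feats <- intersect(schema$name, names(truth))
  rows <- list()
  feature_scores <- list()
  for (f in feats) {
    kind <- schema$kind[match(f, schema$name)]
    if (kind == "binary") {
      r <- binary_prf(truth[[f]], pred[[f]])
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(feature = f, level = NA_integer_),
        r,
        tibble(scope = "feature")
      )
      feature_scores[[f]] <- r
    } else {
      hm <- hierarchical_macro_f1(truth[[f]], pred[[f]],
        levels = feature_levels(schema, f)
      )
      rows[[length(rows) + 1L]] <- hm$per_level |>
        mutate(feature = f, scope = "level") |>
        select("feature", "level", "precision", "recall", "f1", "support", "scope")
      rows[[length(rows) + 1L]] <- tibble(
        feature = f, level = NA_integer_,
        precision = hm$macro_precision, recall = hm$macro_recall,
        f1 = hm$macro_f1, support = NA_integer_, scope = "feature"
      )
      feature_scores[[f]] <- tibble(
        precision = hm$macro_precision,
        recall = hm$macro_recall, f1 = hm$macro_f1
      )
    }
  }
  fs <- list_rbind(lapply(names(feature_scores), function(f) {
    mutate(feature_scores[[f]][, c("precision", "recall", "f1")], feature = f)
  }))
  fs <- left_join(fs, schema[, c("name", "model_group")], by = c(feature = "name"))
  group_rows <- fs |>
    group_by(feature = paste0(.data$model_group, " (macro)")) |>
    summarise(
      precision = mean(.data$precision), recall = mean(.data$recall),
      f1 = mean(.data$f1), .groups = "drop"
    ) |>
    mutate(level = NA_integer_, support = NA_integer_, scope = "group")
  all_row <- tibble(
    feature = "all features (macro)", level = NA_integer_,
    precision = mean(fs$precision), recall = mean(fs$recall),
    f1 = mean(fs$f1), support = NA_integer_, scope = "group"
  )
  bind_rows(list_rbind(rows), group_rows, all_row)
}
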