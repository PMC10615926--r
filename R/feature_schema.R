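#' Feature taxonomy for tag annotation of procedure videos
#'
#' A feature schema is a tibble with one row per video-derived feature. Each
#' feature belongs to one of three categories (`surgical_field`, `anatomy`,
#' `instrument`), is either `ordinal` (graded 0-based integer scale) or
#' `binary` (absent/present), and is assigned to one of three model groups
#' (`blood_smoke`, `anatomy`, `instruments`) that are classified by separate
#' networks.
#'
#' @param features A data frame with columns `name`, `label`, `group`,
#'   `kind`, `levels` (list column of integer vectors) and
#'   `relevant_threshold` (integer, `NA` for binary features).
#'
#' @return A `surgal_schema` tibble.
#' @seealso [default_schema()]
#' @export
surgal_schema <- function(features) {
  schema <- as_tibble(features)
  required <- c("name", "label", "group", "kind", "levels", "relevant_threshold")
  missing <- setdiff(required, names(schema))
  if (length(missing) > 0) {
    abort(paste0("schema is missing columns: ", paste(missing, collapse = ", ")))
  }
  schema$levels <- lapply(schema$levels, function(l) as.integer(sort(l)))
  schema$relevant_threshold <- as.integer(schema$relevant_threshold)
  schema$model_group <- model_group_of(schema$group)
  schema <- schema[, c(
    "name", "label", "group", "kind", "model_group",
    "levels", "relevant_threshold"
  )]
  validate_schema(schema)
  class(schema) <- c("surgal_schema", class(tibble()))
  schema
}

model_group_of <- function(group) {
  c(
    surgical_field = "blood_smoke",
    anatomy = "anatomy",
    instrument = "instruments"
  )[group]
}

validate_schema <- function(schema) {
  if (anyDuplicated(schema$name) > 0) {
    abort("feature names must be unique")
  }
  bad_group <- setdiff(schema$group, c("surgical_field", "anatomy", "instrument"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown feature group: ", paste(bad_group, collapse = ", ")))
  }
  bad_kind <- setdiff(schema$kind, c("ordinal", "binary"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown feature kind: ", paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(schema))) {
    lv <- schema$levels[[i]]
    if (schema$kind[i] == "binary") {
      if (!identical(lv, 0:1)) {
        abort(paste0("binary feature '", schema$name[i], "' must have levels {0, 1}"))
      }
    } else {
      if (length(lv) < 2 || !identical(lv, seq(0L, length(lv) - 1L))) {
        abort(paste0(
          "ordinal feature '", schema$name[i],
          "' must have >= 2 contiguous levels starting at 0"
        ))
      }
    }
  }
  invisible(schema)
}

#' The default ten-feature schema
#'
#' Ten features in three model groups: the ordinal surgical-field features
#' blood (levels 0 "no blood" to 4 "blood amount requiring immediate
#' intervention") and smoke (levels 0 "no smoke" to 3 "smoke amount leading
#' to no visibility"); the binary anatomic structures azygos vein and gastric
#' tube; and six binary instruments (vessel sealer, permanent cautery hook,
#' suction, scissors, large clip applier, metal clip applier).
#'
#' @return A `surgal_schema` tibble with 10 rows.
#' @examples
#' default_schema()
#' @export
default_schema <- function() {
  surgal_schema(tibble(
    name = c(
      "blood", "smoke", "azygos_vein", "gastric_tube",
      "vessel_sealer", "cautery_hook", "suction", "scissors",
      "large_clip_applier", "metal_clip_applier"
    ),
    label = c(
      "blood in the surgical field", "smoke in the surgical field",
      "azygos vein", "gastric tube",
      "vessel sealer", "permanent cautery hook", "suction", "scissors",
      "large clip applier", "metal clip applier"
    ),
    group = c(
      "surgical_field", "surgical_field", "anatomy", "anatomy",
      rep("instrument", 6)
    ),
    kind = c("ordinal", "ordinal", rep("binary", 8)),
    levels = c(list(0:4, 0:3), rep(list(0:1), 8)),
    relevant_threshold = c(2L, 1L, rep(NA_integer_, 8))
  ))
}

#' Clinically relevant level threshold of an ordinal feature
#'
#' Levels strictly above the threshold count as "relevant" in duration
#' summaries: above 2 for blood, above 1 for smoke.
#'
#' @param schema A feature schema.
#' @param feature Feature name.
#' @return Integer threshold level.
#' @export
relevant_level_threshold <- function(schema, feature) {
  row <- schema_row(schema, feature)
  if (row$kind != "ordinal") {
    abort(paste0(
      "feature '", feature, "' is ", row$kind,
      "; only ordinal features have a relevant-level threshold"
    ))
  }
  if (is.na(row$relevant_threshold)) {
    abort(paste0("feature '", feature, "' has no relevant-level threshold configured"))
  }
  row$relevant_threshold
}

schema_row <- function(schema, feature) {
  i <- match(feature, schema$name)
  if (is.na(i)) {
    abort(paste0("unknown feature '", feature, "'"))
  }
  schema[i, ]
}

#' Feature levels
#' @param schema A feature schema.
#' @param feature Feature name.
#' @return Integer vector of levels.
#' @export
feature_levels <- function(schema, feature) {
  schema_row(schema, feature)$levels[[1]]
}

#' Model groups of a schema
#'
#' @param schema A feature schema.
#' @return Named list mapping model group to member feature names.
#' @export
model_groups <- function(schema) {
  split(schema$name, factor(schema$model_group, levels = unique(schema$model_group)))
}

#' Read and write feature schemas as JSON
#'
#' The JSON form lists features with name, label, group, kind, levels and
#' relevant threshold; reading a written schema yields an identical object.
#'
#' @param schema A feature schema.
#' @param path File path.
#' @return `read_schema()` returns a `surgal_schema`; `write_schema()` its
#'   path, invisibly.
#' @export
write_schema <- function(schema, path) {
  features <- lapply(seq_len(nrow(schema)), function(i) {
    list(
      name = schema$name[i],
      label = schema$label[i],
      group = schema$group[i],
      kind = schema$kind[i],
      levels = schema$levels[[i]],
      relevant_threshold = if (is.na(schema$relevant_threshold[i])) {
        NULL
      } else {
        schema$relevant_threshold[i]
      }
    )
  })
  jsonlite::write_json(list(features = features), path,
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path)
  features <- purrr::map(doc$features, function(f) {
    tibble(
      name = f$name,
      label = f$label,
      group = f$group,
      kind = f$kind,
      levels = list(as.integer(unlist(f$levels))),
      relevant_threshold = if (is.null(f$relevant_threshold)) {
        NA_integer_
      } else {
        as.integer(f$relevant_threshold)
      }
    )
  })
  surgal_schema(list_rbind(features))
}
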