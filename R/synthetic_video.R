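#' Default per-feature ground-truth track parameters
#'
#' One row per feature. Binary features are modelled as two-state Markov
#' chains parameterised by their stationary positive prevalence and mean
#' positive dwell time; ordinal features as bounded birth-death chains
#' parameterised by a target level-occupancy distribution and a per-frame
#' move probability. Defaults emulate a procedure mix with common and rare
#' instruments (down to 1% prevalence for the large clip applier) and
#' strongly decreasing occupancy of high blood/smoke levels (top levels
#' below 1% of frames).
#'
#' @param schema A feature schema.
#' @return A tibble with columns `feature`, `prevalence`, `dwell_s`,
#'   `occupancy` (list column), `move_prob`.
#' @export
default_prevalences <- function(schema) {
  defaults <- tibble(
    feature = c(
      "blood", "smoke", "azygos_vein", "gastric_tube",
      "vessel_sealer", "cautery_hook", "suction", "scissors",
      "large_clip_applier", "metal_clip_applier"
    ),
    prevalence = c(
      NA, NA, 0.25, 0.20,
      0.15, 0.30, 0.35, 0.05, 0.01, 0.03
    ),
    dwell_s = c(
      NA, NA, 60, 60,
      30, 40, 30, 15, 10, 10
    ),
    occupancy = list(
      c(0.60, 0.24, 0.10, 0.052, 0.008),
      c(0.70, 0.20, 0.092, 0.008),
      NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL
    ),
    move_prob = c(0.2, 0.2, rep(NA, 8))
  )
  out <- defaults[match(schema$name, defaults$feature), ]
  out$feature <- schema$name
  # features unknown to the default table get neutral parameters
  for (i in seq_len(nrow(out))) {
    kind <- schema$kind[i]
    if (kind == "binary" && is.na(out$prevalence[i])) {
      out$prevalence[i] <- 0.1
      out$dwell_s[i] <- 30
    }
    if (kind == "ordinal" && is.null(out$occupancy[[i]])) {
      k <- length(schema$levels[[i]])
      occ <- 0.35^(seq_len(k) - 1)
      out$occupancy[[i]] <- occ / sum(occ)
      out$move_prob[i] <- 0.2
    }
  }
  out
}

# Two-state Markov chain with stationary positive rate `p` and mean positive
# dwell of `dwell` frames. p = 0 or 1 gives a constant track.
binary_track <- function(n, p, dwell, seed = NULL) {
  if (p < 0 || p >= 1) {
    abort("binary prevalence must lie in [0, 1)")
  }
  with_seed_local(seed, {
    if (p == 0) {
      return(integer(n))
    }
    p10 <- min(1, 1 / max(dwell, 1))
    p01 <- min(1, p * p10 / (1 - p))
    x <- integer(n)
    x[1] <- stats::rbinom(1, 1, p)
    u <- stats::runif(n)
    for (i in seq_len(n - 1L)) {
      x[i + 1L] <- if (x[i] == 1L) {
        if (u[i] < p10) 0L else 1L
      } else {
        if (u[i] < p01) 1L else 0L
      }
    }
    x
  })
}

# Bounded birth-death (Metropolis) chain over levels 0..K-1 with exact
# stationary distribution `occupancy`; `move_prob` is the per-frame proposal
# rate and controls dwell times.
ordinal_track <- function(n, occupancy, move_prob = 0.2, seed = NULL) {
  if (any(occupancy < 0) || abs(sum(occupancy) - 1) > 1e-8) {
    abort("occupancy must be a probability distribution over levels")
  }
  k <- length(occupancy)
  with_seed_local(seed, {
    x <- integer(n)
    x[1] <- sample.int(k, 1, prob = occupancy) - 1L
    u_move <- stats::runif(n)
    u_dir <- stats::runif(n)
    u_acc <- stats::runif(n)
    for (i in seq_len(n - 1L)) {
      cur <- x[i]
      nxt <- cur
      if (u_move[i] < move_prob) {
        prop <- cur + (if (u_dir[i] < 0.5) -1L else 1L)
        if (prop >= 0L && prop < k) {
          ratio <- occupancy[prop + 1L] / occupancy[cur + 1L]
          if (u_acc[i] < ratio) nxt <- prop
        }
      }
      x[i + 1L] <- nxt
    }
    x
  })
}

sample_outside_intervals <- function(duration, seed = NULL, rate = 1.5,
                                     min_len = 20, max_len = 60) {
  with_seed_local(seed, {
    n <- stats::rpois(1, rate)
    if (n == 0) {
      return(tibble(start = numeric(0), end = numeric(0)))
    }
    start <- sort(stats::runif(n, 0, duration))
    end <- pmin(start + stats::runif(n, min_len, max_len), duration)
    # merge overlaps so intervals are disjoint
    keep_start <- start[1]
    keep_end <- end[1]
    out_s <- numeric(0)
    out_e <- numeric(0)
    if (n > 1) {
      for (i in 2:n) {
        if (start[i] <= keep_end) {
          keep_end <- max(keep_end, end[i])
        } else {
          out_s <- c(out_s, keep_start)
          out_e <- c(out_e, keep_end)
          keep_start <- start[i]
          keep_end <- end[i]
        }
      }
    }
    tibble(start = c(out_s, keep_start), end = c(out_e, keep_end))
  })
}

#' Generate a cohort of synthetic procedure videos
#'
#' Produces seeded synthetic procedures with per-frame ground-truth feature
#' tracks, out-of-body intervals (rendered as completely white frames and
#' excluded from annotation), and alternating center assignment. The two
#' centers differ in rendering style; notably the suction motif is silver in
#' center A and black in center B, emulating a center-specific instrument
#' appearance confound.
#'
#' @param n_videos Number of procedures.
#' @param duration Video duration in seconds.
#' @param fps Frames per second of the sampled frame grid (fractional rates
#'   mean one frame every `1/fps` seconds).
#' @param schema A feature schema.
#' @param prevalences Track parameters, see [default_prevalences()].
#' @param render_resolution Height and width in pixels at which frames are
#'   rendered.
#' @param outside_rate Expected number of out-of-body intervals per video.
#' @param seed Master seed; all per-video randomness derives from it.
#' @return A `surgal_cohort`: list of `surgal_procedure` objects with the
#'   schema, seed and rendering parameters attached as attributes.
#' @examples
#' cohort <- generate_cohort(2, duration = 120, fps = 0.5, seed = 1)
#' cohort[[1]]$truth
#' @export
generate_cohort <- function(n_videos, duration = 1200, fps = 0.25,
                            schema = default_schema(),
                            prevalences = default_prevalences(schema),
                            render_resolution = c(60, 80),
                            outside_rate = 1.5,
                            seed = 1L) {
  if (!is_count(n_videos) || n_videos < 1) {
    abort("n_videos must be a positive count")
  }
  bad <- prevalences$feature[!is.na(prevalences$prevalence) &
    (prevalences$prevalence < 0 | prevalences$prevalence >= 1)]
  if (length(bad) > 0) {
    abort(paste0(
      "prevalence outside [0, 1) for feature(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  seeds <- seed_stream(seed, n_videos)
  videos <- lapply(seq_len(n_videos), function(v) {
    make_procedure(
      video_id = sprintf("video_%02d", v),
      center = if (v %% 2 == 1) "A" else "B",
      duration = duration, fps = fps, schema = schema,
      prevalences = prevalences, outside_rate = outside_rate,
      seed = seeds[v]
    )
  })
  structure(
    videos,
    class = "surgal_cohort",
    schema = schema,
    seed = seed,
    prevalences = prevalences,
    render_resolution = as.integer(render_resolution)
  )
}

make_procedure <- function(video_id, center, duration, fps, schema,
                           prevalences, outside_rate, seed) {
  n_frames <- as.integer(floor(duration * fps + 1e-9))
  sub <- seed_stream(seed, nrow(schema) + 1L)
  outside <- sample_outside_intervals(duration, seed = sub[1], rate = outside_rate)
  timestamp <- (seq_len(n_frames) - 1L) / fps
  outside_body <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(outside))) {
    outside_body <- outside_body |
      (timestamp >= outside$start[i] & timestamp < outside$end[i])
  }
  truth <- tibble(
    video_id = video_id,
    frame_index = seq_len(n_frames) - 1L,
    timestamp_s = timestamp,
    outside_body = outside_body
  )
  for (i in seq_len(nrow(schema))) {
    f <- schema$name[i]
    prow <- prevalences[match(f, prevalences$feature), ]
    track <- if (schema$kind[i] == "binary") {
      binary_track(
        n_frames, prow$prevalence,
        dwell = prow$dwell_s * fps, seed = sub[i + 1L]
      )
    } else {
      ordinal_track(n_frames, prow$occupancy[[1]],
        move_prob = prow$move_prob, seed = sub[i + 1L]
      )
    }
    truth[[f]] <- as.integer(track)
  }
  structure(
    list(
      video_id = video_id, center = center, duration = duration, fps = fps,
      n_frames = n_frames, outside_intervals = outside, truth = truth,
      style = center_style(center), seed = seed
    ),
    class = "surgal_procedure"
  )
}

center_style <- function(center) {
  if (center == "A") {
    list(
      background = c(0.55, 0.36, 0.36),
      suction_color = c(0.82, 0.82, 0.86) # silver
    )
  } else {
    list(
      background = c(0.46, 0.34, 0.40),
      suction_color = c(0.07, 0.07, 0.07) # black
    )
  }
}

#' @export
print.surgal_cohort <- function(x, ...) {
  cat(
    "<surgal_cohort> ", length(x), " videos, ",
    x[[1]]$duration, " s @ ", x[[1]]$fps, " fps, seed ",
    attr(x, "seed"), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.surgal_procedure <- function(x, ...) {
  cat(
    "<surgal_procedure> ", x$video_id, " (center ", x$center, "): ",
    x$n_frames, " frames, ", nrow(x$outside_intervals),
    " out-of-body interval(s)\n",
    sep = ""
  )
  invisible(x)
}

# ---- frame rendering ---------------------------------------------------

# Relative-coordinate motif geometry: each binary feature stamps a distinct
# shape at a fixed anchor; colors may depend on the center style.
motif_table <- function(style) {
  list(
    azygos_vein = list(shape = "rect", u = c(0.04, 0.16), v = c(0.20, 0.80), col = c(0.20, 0.20, 0.58)),
    gastric_tube = list(shape = "rect", u = c(0.22, 0.82), v = c(0.06, 0.20), col = c(0.88, 0.78, 0.55)),
    vessel_sealer = list(shape = "rect", u = c(0.24, 0.44), v = c(0.30, 0.50), col = c(0.92, 0.90, 0.20)),
    cautery_hook = list(shape = "rect", u = c(0.54, 0.76), v = c(0.28, 0.42), col = c(0.15, 0.80, 0.80)),
    suction = list(shape = "disc", c_u = 0.32, c_v = 0.72, r = 0.10, col = style$suction_color),
    scissors = list(shape = "disc", c_u = 0.72, c_v = 0.72, r = 0.09, col = c(0.90, 0.35, 0.90)),
    large_clip_applier = list(shape = "rect", u = c(0.44, 0.60), v = c(0.58, 0.80), col = c(1.00, 0.60, 0.08)),
    metal_clip_applier = list(shape = "rect", u = c(0.80, 0.96), v = c(0.52, 0.76), col = c(0.55, 0.95, 0.35))
  )
}

#' Render one synthetic frame
#'
#' Deterministic given the procedure's seed and the frame index: the same
#' (video, index) pair always renders to identical pixels. Out-of-body frames
#' are completely white. Each present binary feature stamps its geometric
#' motif; the blood level controls the area of a red region monotonically and
#' the smoke level adds a white haze of monotonically increasing opacity.
#'
#' @param procedure A `surgal_procedure`.
#' @param frame_index 0-based frame index.
#' @param resolution Height and width in pixels.
#' @return A `surgal_frame`: list with `video_id`, `frame_index`,
#'   `timestamp_s`, `pixels` (H x W x 3 array in \[0, 1\]), `outside_body`
#'   and the hidden ground-truth levels in `truth`.
#' @export
render_frame <- function(procedure, frame_index, resolution = c(60, 80)) {
  if (!is_count(frame_index) || frame_index >= procedure$n_frames) {
    abort(paste0(
      "frame_index must be in [0, ", procedure$n_frames - 1L,
      "] for ", procedure$video_id
    ))
  }
  h <- as.integer(resolution[1])
  w <- as.integer(resolution[2])
  row <- procedure$truth[frame_index + 1L, ]
  truth <- row[, setdiff(
    names(row),
    c("video_id", "frame_index", "timestamp_s", "outside_body")
  )]
  truth <- vapply(truth, identity, integer(1))
  if (row$outside_body) {
    px <- array(1, dim = c(h, w, 3))
  } else {
    px <- render_inside(procedure, frame_index, truth, h, w)
  }
  structure(
    list(
      video_id = procedure$video_id,
      frame_index = as.integer(frame_index),
      timestamp_s = row$timestamp_s,
      pixels = px,
      outside_body = row$outside_body,
      truth = truth
    ),
    class = "surgal_frame"
  )
}

render_inside <- function(procedure, frame_index, truth, h, w) {
  style <- procedure$style
  # coordinate grids in [0, 1]
  v <- matrix((seq_len(h) - 0.5) / h, nrow = h, ncol = w)
  u <- matrix((seq_len(w) - 0.5) / w, nrow = h, ncol = w, byrow = TRUE)
  fseed <- frame_seed(procedure$seed, frame_index)
  rnd <- with_seed_local(fseed, list(
    jitter = stats::runif(2, -0.02, 0.02),
    phase = stats::runif(1, 0, 2 * pi),
    noise = matrix(stats::rnorm(h * w, 0, 0.035), nrow = h)
  ))
  base <- style$background
  tex <- 0.05 * sin(2 * pi * (2.0 * u + 1.3 * v) + rnd$phase) +
    0.04 * sin(2 * pi * (0.7 * u - 2.1 * v) + 0.31 * frame_index)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- base[ch] + tex
  # binary motifs
  motifs <- motif_table(style)
  du <- rnd$jitter[1]
  dv <- rnd$jitter[2]
  for (f in names(motifs)) {
    if (!is.null(truth[f]) && !is.na(truth[f]) && truth[f] > 0L) {
      m <- motifs[[f]]
      mask <- if (m$shape == "rect") {
        u >= m$u[1] + du & u <= m$u[2] + du & v >= m$v[1] + dv & v <= m$v[2] + dv
      } else {
        (u - m$c_u - du)^2 + (v - m$c_v - dv)^2 <= m$r^2
      }
      for (ch in 1:3) {
        slab <- px[, , ch]
        slab[mask] <- m$col[ch]
        px[, , ch] <- slab
      }
    }
  }
  # blood: red region growing monotonically with level from the bottom edge
  if (!is.na(truth["blood"]) && truth["blood"] > 0L) {
    lv <- truth["blood"]
    k_levels <- 4
    frac <- 0.45 * lv / k_levels
    mask <- v >= (1 - frac)
    blood_col <- c(0.75, 0.03, 0.03)
    for (ch in 1:3) {
      slab <- px[, , ch]
      slab[mask] <- 0.1 * slab[mask] + 0.9 * blood_col[ch]
      px[, , ch] <- slab
    }
  }
  # smoke: additive white haze with monotone opacity
  if (!is.na(truth["smoke"]) && truth["smoke"] > 0L) {
    alpha <- 0.16 * truth["smoke"]
    px <- px * (1 - alpha) + alpha
  }
  for (ch in 1:3) px[, , ch] <- px[, , ch] + rnd$noise
  px[px < 0] <- 0
  px[px > 1] <- 1
  px
}

# Flattened block-mean-pooled representation of one frame (channels
# concatenated), the input of the classifiers.
frame_vector <- function(procedure, frame_index, input_hw,
                         render_hw = c(60, 80)) {
  fr <- render_frame(procedure, frame_index, resolution = render_hw)
  fr_h <- dim(fr$pixels)[1]
  fr_w <- dim(fr$pixels)[2]
  fac_r <- fr_h %/% input_hw[1]
  fac_c <- fr_w %/% input_hw[2]
  unlist(lapply(1:3, function(ch) {
    as.vector(block_mean(fr$pixels[, , ch], fac_r, fac_c))
  }), use.names = FALSE)
}

#' Build the model input matrix for a set of frames
#'
#' Renders each referenced frame and reduces it to the requested input
#' resolution by block-mean pooling, returning one row per frame. A cache
#' environment can be supplied to avoid re-rendering frames across cycles.
#'
#' @param cohort A `surgal_cohort`.
#' @param frames Tibble with columns `video_id` and `frame_index`.
#' @param resolution Input height and width after pooling; must divide the
#'   cohort's render resolution.
#' @param cache Optional environment used as a memo table.
#' @return Numeric matrix with `nrow(frames)` rows.
#' @export
frame_matrix <- function(cohort, frames, resolution = c(15, 20), cache = NULL) {
  render_hw <- attr(cohort, "render_resolution") %||% c(60L, 80L)
  ids <- vapply(cohort, function(p) p$video_id, character(1))
  d <- 3L * resolution[1] * resolution[2]
  out <- matrix(0, nrow = nrow(frames), ncol = d)
  for (i in seq_len(nrow(frames))) {
    key <- paste0(frames$video_id[i], "#", frames$frame_index[i], "#", resolution[1], "x", resolution[2])
    vec <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      p <- cohort[[match(frames$video_id[i], ids)]]
      v <- frame_vector(p, frames$frame_index[i], resolution, render_hw)
      if (!is.null(cache)) cache[[key]] <- v
      v
    }
    out[i, ] <- vec
  }
  out
}

# ---- simulated raters ---------------------------------------------------

#' Simulated annotator profiles
#'
#' A rater profile fixes the per-feature error model of one simulated
#' annotator: binary tags are flipped with probability `binary_flip_prob`;
#' ordinal tags receive an additive offset drawn from `ordinal_noise` (a
#' named probability vector over offsets), clipped to the feature's level
#' set. The default group of six is calibrated so that agreement is much
#' higher on binary presence features than on the graded blood/smoke scales.
#'
#' @param rater_id Identifier.
#' @param binary_flip_prob Flip probability for binary features.
#' @param ordinal_noise Named numeric vector: names are integer offsets,
#'   values their probabilities (must sum to 1).
#' @return A `surgal_rater` list.
#' @export
rater_profile <- function(rater_id,
                          binary_flip_prob = 0.03,
                          ordinal_noise = c(
                            "-2" = 0.02, "-1" = 0.16, "0" = 0.64,
                            "1" = 0.16, "2" = 0.02
                          )) {
  if (binary_flip_prob < 0 || binary_flip_prob > 1) {
    abort("binary_flip_prob must lie in [0, 1]")
  }
  if (any(ordinal_noise < 0) || abs(sum(ordinal_noise) - 1) > 1e-8) {
    abort("ordinal_noise must be a probability distribution over offsets")
  }
  structure(
    list(
      rater_id = rater_id,
      binary_flip_prob = binary_flip_prob,
      ordinal_noise = ordinal_noise
    ),
    class = "surgal_rater"
  )
}

#' @rdname rater_profile
#' @param n Number of raters.
#' @export
default_rater_profiles <- function(n = 6) {
  flips <- c(0.002, 0.003, 0.004, 0.002, 0.003, 0.004)
  zero <- c(0.76, 0.78, 0.80, 0.76, 0.78, 0.80)
  lapply(seq_len(n), function(i) {
    z <- zero[((i - 1) %% 6) + 1]
    side <- (1 - z)
    rater_profile(
      rater_id = sprintf("rater_%d", i),
      binary_flip_prob = flips[((i - 1) %% 6) + 1],
      ordinal_noise = c(
        "-2" = side * 0.1, "-1" = side * 0.4, "0" = z,
        "1" = side * 0.4, "2" = side * 0.1
      )
    )
  })
}

#' Simulate one noisy rater over ground-truth labels
#'
#' @param truth Tibble with `video_id`, `frame_index` and one column per
#'   feature holding ground-truth levels.
#' @param schema A feature schema.
#' @param profile A [rater_profile()].
#' @param seed Seed.
#' @return Long tibble: `video_id`, `frame_index`, `feature`, `rater_id`,
#'   `level`.
#' @export
simulate_rater <- function(truth, schema, profile, seed = NULL) {
  n <- nrow(truth)
  feats <- intersect(schema$name, names(truth))
  sub <- seed_stream(seed %||% 1L, length(feats))
  cols <- lapply(seq_along(feats), function(j) {
    f <- feats[j]
    lv <- truth[[f]]
    kind <- schema$kind[match(f, schema$name)]
    with_seed_local(sub[j], {
      if (kind == "binary") {
        flip <- stats::rbinom(n, 1, profile$binary_flip_prob)
        as.integer(ifelse(flip == 1, 1L - lv, lv))
      } else {
        offsets <- as.integer(names(profile$ordinal_noise))
        draw <- offsets[sample.int(length(offsets), n,
          replace = TRUE, prob = profile$ordinal_noise
        )]
        rng <- range(feature_levels(schema, f))
        as.integer(pmin(pmax(lv + draw, rng[1]), rng[2]))
      }
    })
  })
  names(cols) <- feats
  out <- tibble(
    video_id = truth$video_id,
    frame_index = truth$frame_index,
    !!!cols
  )
  out <- pivot_longer(out, -c("video_id", "frame_index"),
    names_to = "feature", values_to = "level"
  )
  out$rater_id <- profile$rater_id
  out[, c("video_id", "frame_index", "feature", "rater_id", "level")]
}

#' @rdname simulate_rater
#' @param profiles List of rater profiles.
#' @export
simulate_raters <- function(truth, schema, profiles, seed = NULL) {
  sub <- seed_stream(seed %||% 1L, length(profiles))
  list_rbind(lapply(seq_along(profiles), function(i) {
    simulate_rater(truth, schema, profiles[[i]], seed = sub[i])
  }))
}

#' Adjudicate a three-way ordinal disagreement
#'
#' Called only when all three submitted levels differ so no majority exists.
#' `mode = "oracle"` emulates a consensus discussion that recovers the
#' ground-truth level; `mode = "median"` takes the median of the three votes.
#'
#' @param votes Integer vector of exactly 3 distinct levels.
#' @param truth Ground-truth level (required for `mode = "oracle"`).
#' @param mode Adjudication mode.
#' @return Integer level.
#' @export
adjudicate <- function(votes, truth = NULL, mode = c("oracle", "median")) {
  mode <- match.arg(mode)
  if (length(votes) != 3) {
    abort("adjudication expects exactly 3 votes")
  }
  if (max(table(votes)) >= 2) {
    abort("a majority exists; adjudication must not be called")
  }
  if (mode == "oracle") {
    if (is.null(truth)) {
      abort("oracle adjudication requires the ground-truth level")
    }
    as.integer(truth)
  } else {
    as.integer(stats::median(votes))
  }
}

# ---- cohort export -------------------------------------------------------

#' Write a cohort to disk as PNG frames plus manifests
#'
#' Writes one directory per video containing PNG frames, a per-video
#' manifest CSV (`video_id`, `frame_index`, `timestamp_s`, `outside_body`,
#' one ground-truth column per feature) and a cohort-level JSON file with
#' seeds and style parameters.
#'
#' @param cohort A `surgal_cohort`.
#' @param dir Output directory.
#' @param frames Optional tibble (`video_id`, `frame_index`) restricting
#'   which frames are written as PNGs; manifests always cover all frames.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, frames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  render_hw <- attr(cohort, "render_resolution") %||% c(60L, 80L)
  meta <- list(
    seed = attr(cohort, "seed"),
    render_resolution = render_hw,
    videos = lapply(cohort, function(p) {
      list(
        video_id = p$video_id, center = p$center, seed = p$seed,
        duration = p$duration, fps = p$fps, style = p$style
      )
    })
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (p in cohort) {
    vdir <- file.path(dir, p$video_id)
    dir.create(vdir, showWarnings = FALSE)
    utils::write.csv(p$truth, file.path(vdir, "manifest.csv"), row.names = FALSE)
    idx <- if (is.null(frames)) {
      p$truth$frame_index
    } else {
      frames$frame_index[frames$video_id == p$video_id]
    }
    for (i in idx) {
      fr <- render_frame(p, i, resolution = render_hw)
      png::writePNG(fr$pixels, file.path(vdir, sprintf("frame_%06d.png", i)))
    }
  }
  invisible(dir)
}
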