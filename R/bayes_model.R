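#' Training configuration
#'
#' Hyperparameters of the per-group Bayesian classifiers. Defaults: 100
#' epochs of SGD under a one-cycle learning-rate schedule with maximum
#' learning rate 3e-3, batch size 16, and 100 stochastic inferences for
#' final-evaluation uncertainty; desk-scale choices elsewhere: classifiers consume frames block-mean pooled to
#' `proxy_resolution` during the annotation cycles and to the larger
#' `eval_resolution` for post-hoc evaluation, where augmentation is enabled.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param max_learning_rate Peak learning rate of the one-cycle schedule.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty.
#' @param proxy_resolution Input height/width during selection cycles.
#' @param eval_resolution Input height/width for post-hoc evaluation models.
#' @param hidden Hidden-layer width.
#' @param dropout_rate Dropout probability; the dropout layer stays
#'   stochastic at inference (Monte-Carlo dropout).
#' @param augmentation Enable brightness/color jitter and pixel shifts.
#' @param n_inferences_selection Stochastic forward passes per frame when
#'   scoring the unlabeled pool.
#' @param n_inferences_eval Stochastic forward passes for post-hoc
#'   evaluation.
#' @param seed Default training seed.
#' @return A `surgal_training_config` list.
#' @export
training_config <- function(epochs = 100L,
                            batch_size = 16L,
                            max_learning_rate = 3e-3,
                            momentum = 0.9,
                            weight_decay = 1e-4,
                            proxy_resolution = c(15L, 20L),
                            eval_resolution = c(30L, 40L),
                            hidden = 24L,
                            dropout_rate = 0.3,
                            augmentation = FALSE,
                            n_inferences_selection = 20L,
                            n_inferences_eval = 100L,
                            seed = NULL) {
  stopifnot(
    is_count(epochs) && epochs >= 1,
    is_count(batch_size) && batch_size >= 1,
    max_learning_rate > 0,
    dropout_rate >= 0 && dropout_rate < 1,
    all(proxy_resolution >= 1), all(eval_resolution >= 1),
    is_count(hidden) && hidden >= 1,
    is_count(n_inferences_selection) && n_inferences_selection >= 2,
    is_count(n_inferences_eval) && n_inferences_eval >= 2
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      max_learning_rate = max_learning_rate, momentum = momentum,
      weight_decay = weight_decay,
      proxy_resolution = as.integer(proxy_resolution),
      eval_resolution = as.integer(eval_resolution),
      hidden = as.integer(hidden), dropout_rate = dropout_rate,
      augmentation = isTRUE(augmentation),
      n_inferences_selection = as.integer(n_inferences_selection),
      n_inferences_eval = as.integer(n_inferences_eval),
      seed = seed
    ),
    class = "surgal_training_config"
  )
}

# Head layout of a model group: ordinal features get one softmax head each
# (levels are mutually exclusive within a feature), binary features share a
# multi-label sigmoid head with one output column per feature.
group_heads <- function(schema, group) {
  feats <- schema[schema$model_group == group, ]
  if (nrow(feats) == 0) {
    abort(paste0("unknown model group '", group, "'"))
  }
  heads <- list()
  col <- 0L
  for (i in seq_len(nrow(feats))) {
    if (feats$kind[i] == "ordinal") {
      k <- length(feats$levels[[i]])
      heads[[length(heads) + 1L]] <- list(
        feature = feats$name[i], type = "softmax",
        cols = col + seq_len(k), levels = feats$levels[[i]]
      )
      col <- col + k
    } else {
      heads[[length(heads) + 1L]] <- list(
        feature = feats$name[i], type = "sigmoid",
        cols = col + 1L, levels = 0:1
      )
      col <- col + 1L
    }
  }
  list(heads = heads, n_out = col, features = feats$name)
}

labels_to_targets <- function(labels, heads) {
  n <- nrow(labels)
  y <- matrix(0, nrow = n, ncol = heads$n_out)
  for (h in heads$heads) {
    lv <- labels[[h$feature]]
    if (is.null(lv) || anyNA(lv)) {
      abort(paste0("labels are missing levels for feature '", h$feature, "'"))
    }
    if (!all(lv %in% h$levels)) {
      abort(paste0("labels outside the level set of '", h$feature, "'"))
    }
    if (h$type == "softmax") {
      y[cbind(seq_len(n), h$cols[1] + lv)] <- 1
    } else {
      y[, h$cols] <- lv
    }
  }
  y
}

# column-wise add without sweep()'s aperm overhead; exact same arithmetic
add_cols <- function(x, v) {
  x + rep(v, each = nrow(x))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

head_probs <- function(z, heads) {
  p <- z
  for (h in heads$heads) {
    if (h$type == "softmax") {
      p[, h$cols] <- softmax_rows(z[, h$cols, drop = FALSE])
    } else {
      p[, h$cols] <- stats::plogis(z[, h$cols])
    }
  }
  p
}

head_loss <- function(p, y, heads) {
  eps <- 1e-12
  total <- 0
  for (h in heads$heads) {
    if (h$type == "softmax") {
      total <- total - mean(rowSums(y[, h$cols, drop = FALSE] *
        log(p[, h$cols, drop = FALSE] + eps)))
    } else {
      pc <- p[, h$cols]
      yc <- y[, h$cols]
      total <- total - mean(yc * log(pc + eps) + (1 - yc) * log(1 - pc + eps))
    }
  }
  total
}

one_cycle_lr <- function(step, total_steps, max_lr, warmup_frac = 0.3) {
  warm <- max(1, ceiling(warmup_frac * total_steps))
  min_lr <- max_lr / 100
  if (step <= warm) {
    min_lr + (max_lr - min_lr) * step / warm
  } else {
    min_lr + (max_lr - min_lr) * 0.5 *
      (1 + cos(pi * (step - warm) / max(1, total_steps - warm)))
  }
}

# Lightweight augmentation on the pooled representation: integer pixel
# shifts (geometric jitter), additive brightness and per-channel color scale.
augment_batch <- function(x, input_hw) {
  h <- input_hw[1]
  w <- input_hw[2]
  n <- nrow(x)
  npx <- h * w
  base_r <- rep(seq_len(h), times = w)
  base_c <- rep(seq_len(w), each = h)
  out <- x
  dr <- sample(-1:1, n, replace = TRUE)
  dc <- sample(-1:1, n, replace = TRUE)
  bright <- stats::runif(n, -0.08, 0.08)
  cscale <- matrix(stats::runif(3 * n, 0.9, 1.1), nrow = n)
  for (s in unique(paste(dr, dc))[unique(paste(dr, dc)) != "0 0"]) {
    rows <- which(paste(dr, dc) == s)
    src_r <- pmin(pmax(base_r - dr[rows[1]], 1L), h)
    src_c <- pmin(pmax(base_c - dc[rows[1]], 1L), w)
    map <- (src_c - 1L) * h + src_r
    idx <- c(map, map + npx, map + 2L * npx)
    out[rows, ] <- out[rows, idx, drop = FALSE]
  }
  out <- out * cscale[, rep(1:3, each = npx)] + bright
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Train a Bayesian group classifier
#'
#' Fits a small feed-forward network (one ReLU hidden layer behind a fixed
#' average-pooling stem, dropout on the hidden layer) with stochastic
#' gradient descent under a one-cycle learning-rate schedule. The dropout
#' layer is kept stochastic at inference, turning the network into a
#' Monte-Carlo-dropout Bayesian model whose predictive spread encodes
#' uncertainty. Ordinal features are classified by per-feature softmax heads,
#' binary features by a multi-label sigmoid head.
#'
#' @param x Input matrix, one pooled frame per row (see [frame_matrix()]).
#' @param labels Data frame with one ground/consensus level column per
#'   feature of the group, aligned with the rows of `x`.
#' @param group Model group name (`blood_smoke`, `anatomy`, `instruments`).
#' @param schema A feature schema.
#' @param config A [training_config()].
#' @param input_hw Height/width of the pooled input (defaults to the
#'   config's proxy resolution); required for augmentation geometry.
#' @param seed Training seed (defaults to the config seed); fixing it makes
#'   the loss trajectory exactly reproducible.
#' @return A `surgal_model`.
#' @export
train_group_model <- function(x, labels, group, schema,
                              config = training_config(),
                              input_hw = config$proxy_resolution,
                              seed = config$seed) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    abort("training set is empty")
  }
  heads <- group_heads(schema, group)
  y <- labels_to_targets(labels, heads)
  for (h in heads$heads) {
    observed <- unique(labels[[h$feature]])
    absent <- setdiff(h$levels, observed)
    if (length(absent) > 0) {
      warn(paste0(
        "feature '", h$feature, "': level(s) ",
        paste(absent, collapse = ", "),
        " absent from the training set; the model may never predict them"
      ))
    }
  }
  d <- ncol(x)
  hdim <- config$hidden
  k <- heads$n_out
  n <- nrow(x)
  # center inputs on the training-set pixel means; augmentation operates on
  # raw [0, 1] intensities, so centering is applied after it
  center <- colMeans(x)
  with_seed_local(seed, {
    w1 <- matrix(stats::rnorm(d * hdim, 0, sqrt(2 / d)), nrow = d)
    b1 <- numeric(hdim)
    w2 <- matrix(stats::rnorm(hdim * k, 0, sqrt(2 / hdim)), nrow = hdim)
    b2 <- numeric(k)
    v_w1 <- matrix(0, d, hdim)
    v_b1 <- numeric(hdim)
    v_w2 <- matrix(0, hdim, k)
    v_b2 <- numeric(k)
    n_batches <- max(1L, ceiling(n / config$batch_size))
    total_steps <- config$epochs * n_batches
    step <- 0L
    keep <- 1 - config$dropout_rate
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (b in seq_len(n_batches)) {
        step <- step + 1L
        idx <- ord[(((b - 1L) * config$batch_size) + 1L):min(b * config$batch_size, n)]
        xb <- x[idx, , drop = FALSE]
        if (config$augmentation) {
          xb <- augment_batch(xb, input_hw)
        }
        xb <- add_cols(xb, -center)
        yb <- y[idx, , drop = FALSE]
        m <- length(idx)
        a1 <- relu(add_cols(xb %*% w1, b1))
        mask <- if (config$dropout_rate > 0) {
          dropout_mask(m, hdim, keep)
        } else {
          1
        }
        a1d <- a1 * mask
        z <- add_cols(a1d %*% w2, b2)
        p <- head_probs(z, heads)
        epoch_loss <- epoch_loss + head_loss(p, yb, heads)
        # gradient of cross-entropy w.r.t. logits is (p - y) for both the
        # softmax and the sigmoid heads
        dz <- (p - yb) / m
        g_w2 <- crossprod(a1d, dz) + config$weight_decay * w2
        g_b2 <- colSums(dz)
        da <- (dz %*% t(w2)) * mask
        da[a1 <= 0] <- 0
        g_w1 <- crossprod(xb, da) + config$weight_decay * w1
        g_b1 <- colSums(da)
        lr <- one_cycle_lr(step, total_steps, config$max_learning_rate)
        sgd_step_inplace(w1, v_w1, g_w1, lr, config$momentum, 0)
        sgd_step_inplace_vec(b1, v_b1, g_b1, lr, config$momentum)
        sgd_step_inplace(w2, v_w2, g_w2, lr, config$momentum, 0)
        sgd_step_inplace_vec(b2, v_b2, g_b2, lr, config$momentum)
      }
      history[epoch] <- epoch_loss / n_batches
    }
    structure(
      list(
        group = group, heads = heads, input_hw = as.integer(input_hw),
        center = center,
        w1 = w1, b1 = b1, w2 = w2, b2 = b2,
        dropout_rate = config$dropout_rate,
        n_train = n, seed = seed, config = config,
        history = tibble(epoch = seq_len(config$epochs), loss = history)
      ),
      class = "surgal_model"
    )
  })
}

#' @export
print.surgal_model <- function(x, ...) {
  cat(
    "<surgal_model> group '", x$group, "': ",
    nrow(x$w1), " inputs -> ", ncol(x$w1), " hidden -> ",
    ncol(x$w2), " outputs; dropout ", x$dropout_rate,
    "; trained on ", x$n_train, " frames\n",
    sep = ""
  )
  invisible(x)
}

#' Monte-Carlo-dropout predictive distribution
#'
#' Runs `T` stochastic forward passes with the dropout layer active and
#' returns the per-class mean probability and the across-inference standard
#' deviation. With dropout rate 0 every pass is identical and all standard
#' deviations are 0.
#'
#' @param model A `surgal_model`.
#' @param x Input matrix (rows aligned with frames).
#' @param T Number of stochastic inferences (>= 2).
#' @param seed Seed for the dropout draws.
#' @return A `surgal_prediction`: list with matrices `mean` and `std`
#'   (frames x classes), the head layout and `T`.
#' @export
predict_mc <- function(model, x, T = 100L, seed = NULL) {
  if (!is_count(T) || T < 2) {
    abort("T must be >= 2 (the across-inference standard deviation is undefined otherwise)")
  }
  x <- add_cols(as.matrix(x), -model$center)
  n <- nrow(x)
  hdim <- ncol(model$w1)
  keep <- 1 - model$dropout_rate
  a1 <- relu(add_cols(x %*% model$w1, model$b1))
  if (model$dropout_rate == 0) {
    # every pass is identical: one deterministic forward pass, zero spread
    p <- head_probs(add_cols(a1 %*% model$w2, model$b2), model$heads)
    return(structure(
      list(
        mean = p, std = matrix(0, n, ncol(model$w2)),
        T = as.integer(T), heads = model$heads
      ),
      class = "surgal_prediction"
    ))
  }
  s1 <- matrix(0, n, ncol(model$w2))
  s2 <- matrix(0, n, ncol(model$w2))
  with_seed_local(seed, {
    for (t in seq_len(T)) {
      a1d <- a1 * dropout_mask(n, hdim, keep)
      z <- add_cols(a1d %*% model$w2, model$b2)
      p <- head_probs(z, model$heads)
      s1 <- s1 + p
      s2 <- s2 + p * p
    }
  })
  mean_p <- s1 / T
  var_p <- (s2 - T * mean_p^2) / (T - 1)
  var_p[var_p < 0] <- 0
  structure(
    list(mean = mean_p, std = sqrt(var_p), T = as.integer(T), heads = model$heads),
    class = "surgal_prediction"
  )
}

#' Tidy a predictive distribution
#'
#' @param pred A `surgal_prediction`.
#' @param frames Optional tibble (`video_id`, `frame_index`) aligned with the
#'   prediction rows.
#' @return Long tibble: frame reference, `feature`, `class` (level), `mean`,
#'   `std`.
#' @export
tidy_predictions <- function(pred, frames = NULL) {
  n <- nrow(pred$mean)
  ref <- if (is.null(frames)) {
    tibble(row = seq_len(n))
  } else {
    as_tibble(frames[, c("video_id", "frame_index")])
  }
  rows <- lapply(pred$heads$heads, function(h) {
    part <- lapply(seq_along(h$cols), function(j) {
      lvl <- if (h$type == "softmax") h$levels[j] else 1L
      bind_cols(ref, tibble(
        feature = h$feature, class = as.integer(lvl),
        mean = pred$mean[, h$cols[j]], std = pred$std[, h$cols[j]]
      ))
    })
    list_rbind(part)
  })
  list_rbind(rows)
}

#' Decode hard labels from a predictive distribution
#'
#' Softmax heads take the level with the highest mean probability; sigmoid
#' heads threshold the mean probability at 0.5.
#'
#' @param pred A `surgal_prediction`.
#' @return Tibble with one level column per feature of the group.
#' @export
decode_predictions <- function(pred) {
  out <- list()
  for (h in pred$heads$heads) {
    out[[h$feature]] <- if (h$type == "softmax") {
      as.integer(h$levels[max.col(pred$mean[, h$cols, drop = FALSE], ties.method = "first")])
    } else {
      as.integer(pred$mean[, h$cols] > 0.5)
    }
  }
  as_tibble(out)
}

#' Per-frame uncertainty score
#'
#' Aggregates the per-class across-inference standard deviations of a
#' predictive distribution to one score per frame: the mean over all classes
#' of the group's heads (default) or the maximum.
#'
#' @param pred A `surgal_prediction`.
#' @param method `"mean"` or `"max"`.
#' @return Numeric vector, one non-negative score per frame.
#' @export
frame_uncertainty <- function(pred, method = c("mean", "max")) {
  method <- match.arg(method)
  if (method == "mean") {
    rowMeans(pred$std)
  } else {
    apply(pred$std, 1, max)
  }
}

#' Save or load a model checkpoint
#'
#' @param model A `surgal_model`.
#' @param path Checkpoint path.
#' @return `read_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
read_model <- function(path) {
  readRDS(path)
}

#' @method glance surgal_model
#' @export
glance.surgal_model <- function(x, ...) {
  tibble(
    group = x$group,
    n_train = x$n_train,
    n_inputs = nrow(x$w1),
    n_hidden = ncol(x$w1),
    n_outputs = ncol(x$w2),
    n_params = length(x$w1) + length(x$b1) + length(x$w2) + length(x$b2),
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    dropout_rate = x$dropout_rate
  )
}

#' @method tidy surgal_model
#' @export
tidy.surgal_model <- function(x, ...) {
  list_rbind(lapply(x$heads$heads, function(h) {
    tibble(feature = h$feature, head = h$type, n_classes = length(h$cols))
  }))
}
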