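#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl imap pmap list_rbind
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed_local <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive `n` reproducible sub-seeds from one master seed. Every source of
# randomness in the package draws its seed from such a stream, so one integer
# reruns an entire experiment exactly.
seed_stream <- function(seed, n) {
  with_seed_local(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Deterministic per-frame seed: mixes a procedure seed with a frame index
# without consuming RNG state.
frame_seed <- function(seed, frame_index) {
  as.integer((as.double(seed) * 2654435761 + as.double(frame_index) * 97561) %%
    (.Machine$integer.max - 1)) + 1L
}

# Mean over non-overlapping fr x fc pixel blocks; used as the fixed
# average-pooling stem in front of the classifier.
block_mean <- function(mat, fr, fc) {
  h <- nrow(mat)
  w <- ncol(mat)
  stopifnot(h %% fr == 0, w %% fc == 0)
  if (fr == 1 && fc == 1) {
    return(mat)
  }
  # collapse rows, then columns
  m <- matrix(colMeans(matrix(mat, nrow = fr)), nrow = h %/% fr)
  t(matrix(colMeans(matrix(t(m), nrow = fc)), nrow = w %/% fc))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == round(x)
}
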