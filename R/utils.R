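# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators are pure functions of (spec, seed) through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-item sub-seed derived from a base seed.
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647
}

# Frames are H x W x 3 numeric arrays in [0, 1]; masks are logical matrices.
assert_frame <- function(frame) {
  if (is.null(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L ||
      any(dim(frame)[1:2] < 1L)) {
    stop("frame must be a height x width x 3 numeric array", call. = FALSE)
  }
  invisible(frame)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop(what, " must be a logical matrix", call. = FALSE)
  }
  invisible(mask)
}

assert_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(what[1], " and ", what[2], " have different shapes", call. = FALSE)
  }
  invisible(NULL)
}

# Rec. 601 luma of an RGB frame.
luminance <- function(frame) {
  assert_frame(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Per-pixel hue/saturation/value matrices for an RGB frame. Hue in [0, 1).
frame_hsv <- function(frame) {
  assert_frame(frame)
  d <- dim(frame)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(frame[, , 1]),
    g = as.vector(frame[, , 2]),
    b = as.vector(frame[, , 3]),
    maxColorValue = 1
  )
  list(
    h = matrix(hsv["h", ], d[1], d[2]),
    s = matrix(hsv["s", ], d[1], d[2]),
    v = matrix(hsv["v", ], d[1], d[2])
  )
}

# Round half away from zero, the convention of printed clinical tables
# (base round() is half-to-even: 1.25% would print as 1.2, not 1.3).
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

# TRUE where hue lies in [lo, hi] (wrapping around 1 when lo > hi).
hue_in_band <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}
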