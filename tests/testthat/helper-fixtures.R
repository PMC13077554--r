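# Fixture builders shared across the suite; everything is generated in
# code, nothing is stored on disk.

# Small logical mask with the first `k` pixels set (column-major).
mask_of <- function(nrow, ncol, k) {
  m <- matrix(FALSE, nrow, ncol)
  if (k > 0) m[seq_len(k)] <- TRUE
  m
}

# Minimal hand-built phantom for streaming tests: truth masks with a known
# CMEA and a ground-truth label, no pixels rendered. Valid input for the
# oracle QC backend and truth-mask accumulation.
fake_phantom <- function(cmea_value, label = "qualified", side = 4L) {
  view <- matrix(TRUE, side, side)
  k <- round(cmea_value * side * side)
  structure(
    list(frame = array(0.5, c(side, side, 3)),
         view_truth = view,
         exposure_truth = mask_of(side, side, k),
         artifacts = list(), label = label,
         cmea_truth = k / (side * side)),
    class = "ccmea_phantom"
  )
}

small_spec <- function(seed = 1L, ...) {
  frame_phantom_spec(height = 64, width = 64, seed = seed, ...)
}

# Random small mask for metric fuzzing.
random_mask <- function(nrow = 12, ncol = 12, p = 0.4) {
  matrix(runif(nrow * ncol) < p, nrow, ncol)
}

# Reference Dice/IoU by explicit pixel enumeration, independent of the
# package implementation.
brute_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    sa <- sa + as.integer(a[[i]]); sb <- sb + as.integer(b[[i]])
    inter <- inter + as.integer(a[[i]] && b[[i]])
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}
brute_iou <- function(a, b) {
  inter <- 0; un <- 0
  for (i in seq_along(a)) {
    inter <- inter + as.integer(a[[i]] && b[[i]])
    un <- un + as.integer(a[[i]] || b[[i]])
  }
  if (un == 0) 1 else inter / un
}
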