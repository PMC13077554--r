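#' Per-frame colorectal mucosal exposure area (CMEA)
#'
#' The ratio of clearly exposed mucosa to the endoscopic view in one
#' frame: `CMEA = area(exposure ∩ view) / area(view)`. Dimensionless and
#' in `[0, 1]`; the pixel scale cancels.
#'
#' @param exposure Logical matrix; clearly exposed mucosa (expected to be
#'   a subset of `view`).
#' @param view Logical matrix; endoscopic field of view (non-empty).
#' @return A single number in `[0, 1]`.
#' @export
cmea <- function(exposure, view) {
  assert_mask(exposure, "exposure"); assert_mask(view, "view")
  assert_same_shape(exposure, view, c("exposure", "view"))
  va <- sum(view)
  if (va == 0) {
    stop("view mask is empty: frame should have been filtered out upstream",
         call. = FALSE)
  }
  sum(exposure & view) / va
}

new_procedure_record <- function(patient_id, ccmea, n_total, n_qualified,
                                 n_chromo, n_other, threshold, sampling_rate,
                                 log = NULL) {
  structure(
    list(patient_id = patient_id, ccmea = ccmea,
         n_frames_total = n_total, n_qualified = n_qualified,
         n_chromo = n_chromo, n_other_unqualified = n_other,
         threshold = threshold, sampling_rate = sampling_rate,
         qualified_flag = ccmea >= threshold, log = log),
    class = "procedure_record"
  )
}

#' @export
print.procedure_record <- function(x, ...) {
  cat(sprintf(
    "Procedure %s: CCMEA %.2f over %d frames (%d qualified, %d chromoendoscopy, %d other unqualified) at %g fps\n",
    as.character(x$patient_id), x$ccmea, x$n_frames_total, x$n_qualified,
    x$n_chromo, x$n_other_unqualified, x$sampling_rate))
  cat(sprintf("qualified colonoscopy (CCMEA >= %g): %s\n", x$threshold,
              x$qualified_flag))
  invisible(x)
}

#' Accumulate per-frame CMEA into a procedure CCMEA
#'
#' Runs the scoring pipeline over an ordered withdrawal frame stream:
#' classify each frame, and for qualified frames add
#' `CMEA = exposure/view` to the running total. Chromoendoscopy frames
#' suspend accumulation (they contribute exactly 0, as do all other
#' unqualified frames). The accumulation state is constant-size; only the
#' optional per-frame log grows with the stream.
#'
#' A procedure is a *qualified colonoscopy* when its CCMEA is greater than
#' or equal to `threshold` (ties count as qualified). Because CCMEA is a
#' sum over frames, its magnitude — and any threshold — is specific to the
#' frame rate at which frames were sampled; `sampling_rate` is therefore
#' recorded in every result.
#'
#' @param frames Ordered list of RGB arrays and/or `ccmea_phantom`
#'   objects. May be empty (gives CCMEA 0, not an error).
#' @param qc A [qc_config()]; with `backend = "oracle"` the generator's
#'   ground-truth labels are used.
#' @param seg A [seg_config()].
#' @param threshold Qualified-colonoscopy CCMEA threshold (>= 0).
#' @param masks `"baseline"` to segment view/exposure from pixels, or
#'   `"truth"` to use the generator's ground-truth masks (phantom input
#'   only; for pipeline validation).
#' @param sampling_rate Frames per second the stream was sampled at;
#'   bookkeeping only.
#' @param patient_id Identifier stored in the record.
#' @param keep_log Keep the per-frame `(frame_index, class, cmea)` log.
#' @return A `procedure_record`: `ccmea`, frame counts by class
#'   (`n_qualified`, `n_chromo`, `n_other_unqualified`, summing to
#'   `n_frames_total`), `threshold`, `sampling_rate`, `qualified_flag`,
#'   and the log.
#' @export
accumulate <- function(frames, qc = qc_config(), seg = seg_config(),
                       threshold = 2000, masks = c("baseline", "truth"),
                       sampling_rate = 25, patient_id = "procedure",
                       keep_log = TRUE) {
  masks <- match.arg(masks)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  total <- 0
  n_q <- 0L; n_chromo <- 0L; n_other <- 0L
  n <- length(frames)
  log <- if (keep_log) {
    data.frame(frame_index = seq_len(n), class = character(n),
               cmea = rep(NA_real_, n), stringsAsFactors = FALSE)
  } else {
    NULL
  }
  for (i in seq_len(n)) {
    f <- frames[[i]]
    cl <- classify_frame(f, qc)
    label <- cl$label
    value <- NA_real_
    if (label == "qualified") {
      value <- tryCatch({
        if (masks == "truth") {
          if (!inherits(f, "ccmea_phantom")) {
            stop("masks = \"truth\" requires phantom frames", call. = FALSE)
          }
          cmea(f$exposure_truth, f$view_truth)
        } else {
          view <- segment_view(f, seg)
          cmea(segment_exposure(f, view, seg), view)
        }
      }, error = function(e) {
        if (grepl("requires phantom frames", conditionMessage(e))) stop(e)
        NA_real_
      })
      if (is.na(value)) label <- "in_vitro"  # empty view: treat as unqualified
    }
    if (label == "qualified") {
      total <- total + value
      n_q <- n_q + 1L
    } else if (label == "chromoendoscopy") {
      n_chromo <- n_chromo + 1L
    } else {
      n_other <- n_other + 1L
    }
    if (keep_log) {
      log$class[i] <- label
      log$cmea[i] <- value
    }
  }
  new_procedure_record(patient_id, total, n, n_q, n_chromo, n_other,
                       threshold, sampling_rate, log)
}

# Read one PNG as an H x W x 3 array in [0, 1].
read_frame_png <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot decode frame file: ", path, call. = FALSE)
  })
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a frame (or phantom) to a PNG file
#'
#' @param frame RGB array or `ccmea_phantom`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(as_rgb_frame(frame), path)
  invisible(path)
}

#' Score a directory of frame images
#'
#' Scores an image-directory representation of a withdrawal video: PNG
#' files are read in lexicographic order as the frame stream and passed
#' through [accumulate()]. Given identical input and configuration the
#' result, including the per-frame log, is bit-for-bit reproducible.
#'
#' @param path Directory containing the frames as `.png` files.
#' @param log_csv Optional path; when set, the per-frame
#'   `(frame_index, class, cmea)` log is written there as CSV.
#' @param ... Passed to [accumulate()] (`qc`, `seg`, `threshold`,
#'   `sampling_rate`, `patient_id`, ...).
#' @return A `procedure_record`.
#' @export
score_frame_dir <- function(path, log_csv = NULL, ...) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no decodable frames found in ", path, call. = FALSE)
  }
  frames <- lapply(files, read_frame_png)
  rec <- accumulate(frames, ...)
  if (!is.null(log_csv)) {
    utils::write.csv(rec$log, log_csv, row.names = FALSE)
  }
  rec
}
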