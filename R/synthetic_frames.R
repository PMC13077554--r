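#' Specification for a synthetic endoscopy phantom frame
#'
#' Describes one synthetic colonoscopy frame: a bright textured disk (the
#' endoscopic field of view over mucosa) on a near-black background, with
#' optional artifact patches drawn from the unqualified-region taxonomy
#' (specular reflections, fecal material, dark regions, instrument), global
#' Gaussian blur, and a chromoendoscopy blue tint. Every rendered frame
#' carries exact ground-truth masks, so phantoms double as segmentation and
#' scoring fixtures.
#'
#' @param height,width Frame dimensions in pixels (positive integers).
#' @param view_shape `"circle"` or `"rounded-rectangle"`; shape of the
#'   endoscopic field of view.
#' @param view_fraction Fraction of the frame area inside the field of view,
#'   in `[0.4, 0.95]`.
#' @param specular,fecal,dark,instrument Per-class artifact area budgets as
#'   fractions of the view area, each in `[0, 1]`; their sum must not
#'   exceed 1. Rendered artifact patches are always inside the view, and
#'   the ground-truth exposure mask is the view minus their union.
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0),
#'   applied to the whole rendered frame.
#' @param chromo Logical; render the frame with a chromoendoscopy-style
#'   blue tint.
#' @param blur_label_min Blur sigma at or above which the ground-truth
#'   frame label becomes `"blurred"`.
#' @param seed Integer seed; rendering is a pure function of the spec, so a
#'   fixed seed reproduces the frame bit for bit.
#'
#' @return An object of class `frame_phantom_spec`.
#' @seealso [generate_frame()], [generate_procedure()]
#' @export
frame_phantom_spec <- function(height = 128, width = 128,
                               view_shape = c("circle", "rounded-rectangle"),
                               view_fraction = 0.6,
                               specular = 0, fecal = 0, dark = 0,
                               instrument = 0,
                               blur_sigma = 0, chromo = FALSE,
                               blur_label_min = 2,
                               seed = 1L) {
  view_shape <- match.arg(view_shape)
  if (height < 1 || width < 1) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  if (view_fraction < 0.4 || view_fraction > 0.95) {
    stop("view_fraction must lie in [0.4, 0.95]", call. = FALSE)
  }
  budget <- c(specular = specular, fecal = fecal, dark = dark,
              instrument = instrument)
  if (any(budget < 0) || any(budget > 1)) {
    stop("artifact budgets must each lie in [0, 1]", call. = FALSE)
  }
  if (sum(budget) > 1) {
    stop("artifact budgets must not sum above 1", call. = FALSE)
  }
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         view_shape = view_shape, view_fraction = view_fraction,
         budget = budget, blur_sigma = blur_sigma, chromo = isTRUE(chromo),
         blur_label_min = blur_label_min, seed = seed),
    class = "frame_phantom_spec"
  )
}

# Reference colors of the phantom renderer. Chosen so that the baseline
# color rules separate the classes: mucosa pink (hue near 0/1), specular
# bright and unsaturated, fecal brown (hue ~0.09), dark below the exposure
# luminance floor but above the view near-black floor.
.phantom_colors <- list(
  mucosa     = c(0.78, 0.46, 0.42),
  background = c(0.012, 0.010, 0.010),
  specular   = c(0.97, 0.965, 0.955),
  fecal      = c(0.45, 0.28, 0.10),
  dark       = c(0.060, 0.052, 0.050),
  instrument = c(0.58, 0.62, 0.66),
  chromo     = c(0.25, 0.45, 0.85)
)

view_mask_for <- function(spec) {
  h <- spec$height; w <- spec$width
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  if (spec$view_shape == "circle") {
    r <- sqrt(spec$view_fraction * h * w / pi)
    (row - cy)^2 + (col - cx)^2 <= r^2
  } else {
    # Rounded rectangle: half-sides scaled to the target area, corner
    # radius 20% of the smaller half-side; area is matched approximately
    # (corner rounding removes ~1% of the target).
    a <- sqrt(spec$view_fraction) * h / 2
    b <- sqrt(spec$view_fraction) * w / 2
    rc <- 0.2 * min(a, b)
    dy <- pmax(abs(row - cy) - (a - rc), 0)
    dx <- pmax(abs(col - cx) - (b - rc), 0)
    dy^2 + dx^2 <= rc^2
  }
}

blur_channel <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

# Low-frequency multiplicative texture field in [1 - amp, 1 + amp].
texture_field <- function(h, w, amp = 0.12, sigma = 6) {
  f <- blur_channel(matrix(runif(h * w), h, w), sigma)
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(matrix(1, h, w))
  1 + amp * (2 * (f - rng[1]) / diff(rng) - 1)
}

# Fill a per-class artifact mask with random disks inside `view` until the
# target area fraction of the view is covered (over all already-placed
# artifact pixels the new class may not re-claim).
place_artifact <- function(view, occupied, frac, min_r, max_r) {
  h <- nrow(view); w <- ncol(view)
  target <- frac * sum(view)
  mask <- matrix(FALSE, h, w)
  if (target < 1) return(mask)
  idx <- which(view & !occupied)
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  tries <- 0L
  while (sum(mask) < target && tries < 400L) {
    tries <- tries + 1L
    free <- idx[!mask[idx]]
    if (length(free) == 0L) break
    ctr <- free[sample.int(length(free), 1L)]
    cy <- (ctr - 1L) %% h + 1L
    cx <- (ctr - 1L) %/% h + 1L
    r <- runif(1, min_r, max_r)
    disk <- (row - cy)^2 + (col - cx)^2 <= r^2
    add <- disk & view & !occupied & !mask
    need <- target - sum(mask)
    if (sum(add) > need * 1.6 && r > min_r) {
      # shrink the last disk so the realized area lands near the budget
      r <- max(min_r, r * sqrt(need / sum(add)))
      disk <- (row - cy)^2 + (col - cx)^2 <= r^2
      add <- disk & view & !occupied & !mask
    }
    mask <- mask | add
  }
  mask
}

paint <- function(frame, mask, color, field = NULL) {
  for (k in 1:3) {
    ch <- frame[, , k]
    val <- color[k]
    ch[mask] <- if (is.null(field)) val else val * field[mask]
    frame[, , k] <- ch
  }
  frame
}

#' Render one synthetic endoscopy frame with ground truth
#'
#' Renders the phantom described by a [frame_phantom_spec()]: textured pink
#' mucosa inside the field of view, artifact patches (specular, fecal,
#' dark, instrument) inside the view, optional chromoendoscopy tint and
#' Gaussian blur. Ground-truth masks are recorded before blurring, so they
#' are exact pixel sets.
#'
#' @param spec A [frame_phantom_spec()].
#' @return A list of class `ccmea_phantom` with elements
#'   \describe{
#'     \item{frame}{numeric `height x width x 3` RGB array in `[0, 1]`}
#'     \item{view_truth}{logical matrix; endoscopic field of view}
#'     \item{exposure_truth}{logical matrix; clearly exposed mucosa =
#'       view minus all artifact patches (subset of `view_truth`)}
#'     \item{artifacts}{named list of per-class logical masks}
#'     \item{label}{ground-truth frame class: `"chromoendoscopy"` if the
#'       tint is on, else `"blurred"` if `blur_sigma >= blur_label_min`,
#'       else `"qualified"`}
#'     \item{cmea_truth}{exposure area / view area}
#'   }
#' @export
generate_frame <- function(spec) {
  stopifnot(inherits(spec, "frame_phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    view <- view_mask_for(spec)
    frame <- array(0, c(h, w, 3))
    bgnoise <- matrix(runif(h * w, 0.6, 1.4), h, w)
    frame <- paint(frame, !view, .phantom_colors$background, bgnoise)
    field <- texture_field(h, w)
    frame <- paint(frame, view, .phantom_colors$mucosa, field)

    min_r <- max(2, 0.04 * min(h, w)); max_r <- max(3, 0.11 * min(h, w))
    occupied <- matrix(FALSE, h, w)
    artifacts <- list()
    for (cls in names(spec$budget)) {
      m <- place_artifact(view, occupied, spec$budget[[cls]], min_r, max_r)
      occupied <- occupied | m
      artifacts[[cls]] <- m
      if (any(m)) frame <- paint(frame, m, .phantom_colors[[cls]])
    }

    if (spec$chromo) {
      mix <- 0.62
      for (k in 1:3) {
        ch <- frame[, , k]
        ch[view] <- (1 - mix) * ch[view] + mix * .phantom_colors$chromo[k]
        frame[, , k] <- ch
      }
    }
    if (spec$blur_sigma > 0) {
      for (k in 1:3) frame[, , k] <- blur_channel(frame[, , k], spec$blur_sigma)
    }
    frame[frame < 0] <- 0
    frame[frame > 1] <- 1

    exposure <- view & !occupied
    label <- if (spec$chromo) {
      "chromoendoscopy"
    } else if (spec$blur_sigma >= spec$blur_label_min) {
      "blurred"
    } else {
      "qualified"
    }
    structure(
      list(frame = frame, view_truth = view, exposure_truth = exposure,
           artifacts = artifacts, label = label,
           cmea_truth = sum(exposure) / sum(view), spec = spec),
      class = "ccmea_phantom"
    )
  })
}

# An in-vitro phantom: the scope is outside the patient, frame is dark
# noise with no field of view and no exposure truth.
render_in_vitro <- function(spec) {
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    frame <- array(runif(h * w * 3, 0, 0.035), c(h, w, 3))
    structure(
      list(frame = frame,
           view_truth = matrix(FALSE, h, w),
           exposure_truth = matrix(FALSE, h, w),
           artifacts = list(), label = "in_vitro", cmea_truth = NA_real_,
           spec = spec),
      class = "ccmea_phantom"
    )
  })
}

#' Generate a synthetic withdrawal procedure
#'
#' Builds an ordered sequence of phantom frames following a phase plan
#' (run-lengths of frame classes), emulating a colonoscopy withdrawal
#' recording. Ground-truth per-frame CMEA values are recorded alongside so
#' the analytic CCMEA of the procedure is known exactly: it is the sum of
#' `cmea_truth` over frames whose ground-truth label is `"qualified"`
#' (blurred, chromoendoscopy and in-vitro frames carry no exposure
#' contribution).
#'
#' @param n_frames Total number of frames; must equal the sum of plan
#'   run-lengths.
#' @param phase_plan A data frame with columns `class` (one of
#'   `"qualified"`, `"blurred"`, `"chromoendoscopy"`, `"in_vitro"`) and
#'   `n` (run length), or a list of `list(class=, n=)` entries.
#' @param spec_defaults A [frame_phantom_spec()] used for every frame;
#'   per-frame seeds are derived deterministically from its `seed`, and
#'   blur/chromo settings are overridden per the plan.
#' @param jitter_artifacts Logical; if `TRUE`, each qualified frame's
#'   artifact budgets are independently scaled by a random factor in
#'   `[0, 1]`, giving a varying ground-truth CMEA series.
#'
#' @return A list of class `ccmea_procedure` with elements `frames`
#'   (list of `ccmea_phantom`), `truth` (data frame: `frame_index`,
#'   `class`, `cmea_truth`), and `ccmea_truth` (analytic CCMEA).
#' @export
generate_procedure <- function(n_frames, phase_plan, spec_defaults,
                               jitter_artifacts = FALSE) {
  stopifnot(inherits(spec_defaults, "frame_phantom_spec"))
  if (is.data.frame(phase_plan)) {
    phase_plan <- lapply(seq_len(nrow(phase_plan)), function(i) {
      list(class = phase_plan$class[i], n = phase_plan$n[i])
    })
  }
  if (length(phase_plan) == 0L) stop("phase_plan must be non-empty", call. = FALSE)
  classes <- unlist(lapply(phase_plan, function(p) rep(p$class, p$n)))
  if (length(classes) != n_frames) {
    stop("phase plan run-lengths must sum to n_frames", call. = FALSE)
  }
  known <- c("qualified", "blurred", "chromoendoscopy", "in_vitro")
  if (!all(classes %in% known)) {
    stop("unknown frame class in phase_plan", call. = FALSE)
  }
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    cls <- classes[i]
    sp <- spec_defaults
    sp$seed <- derive_seed(spec_defaults$seed, i)
    if (cls == "in_vitro") {
      frames[[i]] <- render_in_vitro(sp)
      next
    }
    sp$chromo <- cls == "chromoendoscopy"
    sp$blur_sigma <- if (cls == "blurred") {
      max(spec_defaults$blur_label_min, 3)
    } else {
      0
    }
    if (jitter_artifacts && cls == "qualified") {
      sp$budget <- sp$budget * with_seed(sp$seed + 1, runif(4))
    }
    frames[[i]] <- generate_frame(sp)
  }
  truth <- data.frame(
    frame_index = seq_len(n_frames),
    class = classes,
    cmea_truth = vapply(
      seq_len(n_frames),
      function(i) if (classes[i] == "qualified") frames[[i]]$cmea_truth else NA_real_,
      numeric(1)
    ),
    stringsAsFactors = FALSE
  )
  # sequential double-precision addition, matching the order and arithmetic
  # of streaming accumulation so oracle equivalence is exact, not approximate
  ccmea_truth <- Reduce(`+`, truth$cmea_truth[!is.na(truth$cmea_truth)], 0)
  structure(
    list(frames = frames, truth = truth, ccmea_truth = ccmea_truth),
    class = "ccmea_procedure"
  )
}

#' @export
print.ccmea_procedure <- function(x, ...) {
  cat("Synthetic withdrawal procedure:", nrow(x$truth), "frames\n")
  print(table(x$truth$class))
  cat("analytic CCMEA:", format(x$ccmea_truth, digits = 6), "\n")
  invisible(x)
}
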