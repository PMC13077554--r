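test_that("baseline view segmentation recovers the phantom field of view", {
  ph <- generate_frame(frame_phantom_spec(height = 96, width = 96,
                                          view_fraction = 0.6, seed = 8))
  v <- segment_view(ph)
  expect_gte(dice(v, ph$view_truth), 0.99)
})

test_that("a uniformly bright frame yields a full-frame view", {
  bright <- array(0.8, c(40, 40, 3))
  expect_true(all(segment_view(bright)))
})

test_that("view segmentation is mirror-equivariant", {
  ph <- generate_frame(small_spec(seed = 15, specular = 0.1))
  mirrored <- ph$frame[, ncol(ph$frame):1, , drop = FALSE]
  v <- segment_view(ph$frame)
  vm <- segment_view(mirrored)
  expect_identical(vm, v[, ncol(v):1])
})

test_that("near-black frames raise an empty-view error", {
  expect_error(segment_view(array(0.005, c(40, 40, 3))), "view")
})

test_that("exposure segmentation stays inside the view and handles darkness", {
  for (s in 1:6) {
    budgets <- ccmea:::with_seed(100 + s, runif(3, 0, 0.15))
    ph <- generate_frame(small_spec(seed = s, specular = budgets[1],
                                    fecal = budgets[2], dark = budgets[3]))
    v <- segment_view(ph)
    e <- segment_exposure(ph, v)
    expect_true(all(v[e]))
  }
  # fully dark interior: view from truth, exposure empty
  ph <- generate_frame(small_spec(seed = 50, dark = 1.0))
  e <- segment_exposure(ph, ph$view_truth)
  expect_equal(sum(e), 0)
  expect_error(segment_exposure(ph, matrix(TRUE, 3, 3)), "shapes")
})

test_that("specular artifacts are excluded at close to their true area", {
  ph <- generate_frame(small_spec(seed = 11, specular = 0.2))
  v <- segment_view(ph)
  e <- segment_exposure(ph, v)
  expect_equal(sum(e) / sum(ph$exposure_truth), 1, tolerance = 0.1)
})

test_that("dice matches brute-force pixel counting on constructed masks", {
  a <- mask_of(10, 10, 100); b <- mask_of(10, 10, 100)
  expect_equal(dice(a, b), 1)
  expect_equal(dice(mask_of(10, 10, 30),
                    matrix(rev(mask_of(10, 10, 30)), 10, 10)), 0)
  a <- mask_of(20, 10, 100)
  b <- matrix(FALSE, 20, 10); b[51:150] <- TRUE  # |A|=|B|=100, overlap 50
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), brute_dice(a, b))
  expect_message(val <- dice(mask_of(4, 4, 0), mask_of(4, 4, 0)), "empty")
  expect_equal(val, 1)
  expect_error(dice(mask_of(4, 4, 2), mask_of(5, 4, 2)), "shapes")
})

test_that("miou follows the image-mean convention", {
  a <- mask_of(10, 10, 40)
  expect_equal(miou(list(list(a, a))), 1)
  x <- mask_of(20, 10, 100)
  y <- matrix(FALSE, 20, 10); y[51:150] <- TRUE  # IoU = 50/150
  expect_equal(miou(list(list(x, y))), 1 / 3, tolerance = 1e-12)
  # two pairs with IoU 0.2 and 0.8 average to 0.5
  p1 <- list(mask_of(10, 10, 20), mask_of(10, 10, 100))  # 20/100
  p2 <- list(mask_of(10, 10, 80), mask_of(10, 10, 100))  # 80/100
  expect_equal(miou(list(p1, p2)), 0.5)
  expect_error(miou(list()), "at least one")
})

test_that("dice-IoU identity and metric invariances hold under fuzzing", {
  ccmea:::with_seed(77, {
    for (i in 1:200) {
      a <- random_mask(); b <- random_mask()
      d <- suppressMessages(dice(a, b))
      iou <- brute_iou(a, b)
      expect_equal(d, 2 * iou / (1 + iou), tolerance = 1e-12)
      expect_equal(d, suppressMessages(dice(b, a)))
      expect_equal(d, brute_dice(a, b), tolerance = 1e-12)
    }
  })
  # simultaneous translation leaves the metrics unchanged
  a <- matrix(FALSE, 12, 12); a[3:6, 3:6] <- TRUE
  b <- matrix(FALSE, 12, 12); b[4:7, 3:6] <- TRUE
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(dice(a, b), dice(shift(a, 3, 2), shift(b, 3, 2)))
  expect_equal(miou(list(list(a, b))),
               miou(list(list(shift(a, 3, 2), shift(b, 3, 2)))))
})

test_that("seg_evaluate aggregates per-image records", {
  preds <- list(mask_of(8, 8, 20), mask_of(8, 8, 30))
  truths <- list(mask_of(8, 8, 20), mask_of(8, 8, 40))
  rep <- seg_evaluate(preds, truths)
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(rep$dice, mean(rep$per_image$dice))
  expect_equal(rep$per_image$dice[1], 1)
  expect_equal(rep$per_image$iou[2], 30 / 40)
})

test_that("class-averaged mIoU switch includes the background class", {
  cfg <- seg_config(miou_average = "class")
  x <- mask_of(10, 10, 40); y <- mask_of(10, 10, 40)
  expect_equal(miou(list(list(x, y)), cfg), 1)
  y2 <- mask_of(10, 10, 20)
  fg <- 20 / 40
  bg <- 60 / 80
  expect_equal(miou(list(list(x, y2)), cfg), (fg + bg) / 2)
})
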