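test_that("cmea is the exposure-to-view area ratio", {
  v <- matrix(TRUE, 100, 100)
  expect_equal(cmea(v, v), 1)
  expect_equal(cmea(matrix(FALSE, 100, 100), v), 0)
  expect_equal(cmea(mask_of(100, 100, 5000), v), 0.5)
  expect_error(cmea(v, matrix(FALSE, 100, 100)), "empty")
  expect_error(cmea(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("accumulation sums CMEA over qualified frames only", {
  cfg <- qc_config(backend = "oracle")
  frames <- replicate(4000, fake_phantom(0.5), simplify = FALSE)
  rec <- accumulate(frames, qc = cfg, masks = "truth", threshold = 2000,
                    keep_log = FALSE)
  expect_equal(rec$ccmea, 2000)
  expect_true(rec$qualified_flag)  # tie at the threshold counts as qualified
  # chromoendoscopy suspends accumulation
  mixed <- c(replicate(10, fake_phantom(0.5), simplify = FALSE),
             replicate(5, fake_phantom(0.5, label = "chromoendoscopy"),
                       simplify = FALSE))
  rec2 <- accumulate(mixed, qc = cfg, masks = "truth")
  expect_equal(rec2$ccmea, 5)
  expect_equal(rec2$n_qualified, 10)
  expect_equal(rec2$n_chromo, 5)
  expect_equal(rec2$n_qualified + rec2$n_chromo + rec2$n_other_unqualified,
               rec2$n_frames_total)
})

test_that("empty streams give a zero, unqualified record", {
  rec <- accumulate(list())
  expect_equal(rec$ccmea, 0)
  expect_false(rec$qualified_flag)
  expect_equal(rec$n_frames_total, 0)
})

test_that("ccmea is additive, bounded and monotone in the stream", {
  cfg <- qc_config(backend = "oracle")
  ccmea:::with_seed(5, {
    a <- lapply(runif(8), fake_phantom)
    b <- lapply(runif(6), fake_phantom)
  })
  ra <- accumulate(a, qc = cfg, masks = "truth")
  rb <- accumulate(b, qc = cfg, masks = "truth")
  rab <- accumulate(c(a, b), qc = cfg, masks = "truth")
  expect_equal(rab$ccmea, ra$ccmea + rb$ccmea)
  expect_lte(rab$ccmea, rab$n_qualified)
  expect_gte(rab$ccmea, 0)
  # adding a qualified frame never decreases; unqualified never changes
  more <- accumulate(c(a, list(fake_phantom(0.3))), qc = cfg, masks = "truth")
  expect_gte(more$ccmea, ra$ccmea)
  pad <- accumulate(c(a, list(fake_phantom(0.9, label = "blurred"))),
                    qc = cfg, masks = "truth")
  expect_equal(pad$ccmea, ra$ccmea)
})

test_that("oracle pipeline equals the generator analytic CCMEA exactly", {
  plan <- data.frame(class = c("qualified", "chromoendoscopy", "qualified"),
                     n = c(8, 4, 8))
  proc <- generate_procedure(20, plan, small_spec(seed = 21, specular = 0.1))
  rec <- accumulate(proc$frames, qc = qc_config(backend = "oracle"),
                    masks = "truth")
  expect_identical(rec$ccmea, proc$ccmea_truth)
})

test_that("frame directories are scored reproducibly", {
  dir <- withr::local_tempdir()
  proc <- generate_procedure(
    20, data.frame(class = c("qualified", "chromoendoscopy"), n = c(15, 5)),
    small_spec(seed = 33, specular = 0.05)
  )
  for (i in seq_along(proc$frames)) {
    write_frame_png(proc$frames[[i]], file.path(dir, sprintf("f%03d.png", i)))
  }
  log1 <- file.path(dir, "log1.csv"); log2 <- file.path(dir, "log2.csv")
  rec1 <- score_frame_dir(dir, log_csv = log1)
  rec2 <- score_frame_dir(dir, log_csv = log2)
  expect_equal(rec1$n_frames_total, 20)
  expect_identical(readBin(log1, "raw", file.size(log1)),
                   readBin(log2, "raw", file.size(log2)))
  expect_identical(rec1$ccmea, rec2$ccmea)
  expect_error(score_frame_dir(file.path(dir, "missing")), "no such directory")
  empty <- file.path(dir, "empty"); dir.create(empty)
  expect_error(score_frame_dir(empty), "no decodable frames")
})

test_that("temporal downsampling scales CCMEA linearly", {
  cfg <- qc_config(backend = "oracle")
  frames <- replicate(40, fake_phantom(0.5), simplify = FALSE)
  full <- accumulate(frames, qc = cfg, masks = "truth", sampling_rate = 25)
  half <- accumulate(frames[seq(1, 40, by = 2)], qc = cfg, masks = "truth",
                     sampling_rate = 12.5)
  expect_equal(half$ccmea, full$ccmea / 2, tolerance = 1 / 40)
  expect_equal(half$sampling_rate, 12.5)
})
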