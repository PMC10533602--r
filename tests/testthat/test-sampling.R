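test_that("cubic kernel satisfies node conditions and printed values", {
  expect_equal(cubic_kernel(0), 1)
  expect_equal(cubic_kernel(1), 0)
  expect_equal(cubic_kernel(2), 0)
  expect_equal(cubic_kernel(-1), 0)
  expect_equal(cubic_kernel(0.5), 0.5625)
  expect_equal(cubic_kernel(1.5), -0.0625)
  expect_equal(cubic_kernel(3), 0)
  # agrees with the scalar piecewise oracle on a dense grid
  xs <- seq(-2.5, 2.5, by = 0.01)
  expect_equal(cubic_kernel(xs), vapply(xs, oracle_keys, numeric(1)))
})

test_that("kernel weights form a partition of unity at every offset", {
  for (a in c(-0.5, -0.75, -1)) {
    xs <- seq(0.001, 0.999, by = 0.001)
    # offsets of the 4 support samples around fractional position x
    sums <- vapply(xs, function(x) sum(cubic_kernel(x - (-1:2), a)), numeric(1))
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("beamline decimation keeps exactly the probe's line grid", {
  img <- random_test_image(8, 5, seed = 42)
  d2 <- downsample_beamlines(img, sampling_scheme(2))
  expect_equal(n_lines(d2), 4)
  expect_identical(d2$pixels, img$pixels[c(1, 3, 5, 7), ])
  d4 <- downsample_beamlines(img, sampling_scheme(4))
  expect_equal(n_lines(d4), 2)
  expect_identical(d4$pixels, img$pixels[c(1, 5), ])
  # phase shifts the acquired grid
  d2p <- downsample_beamlines(img, sampling_scheme(2, phase = 1))
  expect_identical(d2p$pixels, img$pixels[c(2, 4, 6, 8), ])
  # identity factor
  d1 <- downsample_beamlines(img, sampling_scheme(1))
  expect_identical(d1$pixels, img$pixels)
  # depth axis untouched, all lines flagged acquired
  expect_equal(n_depth(d4), 5)
  expect_true(all(d2$acquired_mask))
})

test_that("decimation refuses images too narrow to carry the grid", {
  img <- random_test_image(6, 4, seed = 1)
  expect_error(downsample_beamlines(img, sampling_scheme(4)), "too narrow")
})

test_that("non-divisible line counts are trailing-cropped before pairing", {
  img <- random_test_image(65, 8, seed = 3)
  pair <- make_training_pair(img, sampling_scheme(2))
  expect_equal(n_lines(pair$target), 64)
  expect_identical(pair$target$pixels, img$pixels[1:64, ])
  expect_equal(dim(pair$input), dim(pair$target))
})

test_that("2X interpolation uses the (-1/16, 9/16, 9/16, -1/16) weights", {
  w <- cubic_kernel(c(1.5, 0.5, 0.5, 1.5))
  expect_equal(w, c(-1, 9, 9, -1) / 16)
  # interior interpolated line of an upsampled image matches the stencil
  img <- random_test_image(16, 6, seed = 9)
  low <- downsample_beamlines(img, sampling_scheme(2))
  up <- upsample_beamlines(low, sampling_scheme(2))
  lowpx <- low$pixels
  # output line 5 (0-based) sits between low-res lines 2 and 3 (0-based)
  manual <- -1 / 16 * lowpx[2, ] + 9 / 16 * lowpx[3, ] +
    9 / 16 * lowpx[4, ] - 1 / 16 * lowpx[5, ]
  expect_equal(up$pixels[6, ], manual, tolerance = 1e-14)
})

test_that("4X quarter-offset weights match kernel evaluations and sum to 1", {
  w <- cubic_kernel(c(1.25, 0.25, 0.75, 1.75))
  expect_equal(w, c(-0.0703125, 0.8671875, 0.2265625, -0.0234375))
  expect_equal(sum(w), 1)
})

test_that("constant images are reproduced exactly by interpolation", {
  for (s in c(2, 4)) {
    img <- us_image(matrix(0.37, 32, 7), "unit")
    pair <- make_training_pair(img, sampling_scheme(s))
    expect_equal(max(abs(pair$input$pixels - 0.37)), 0, tolerance = 1e-13)
  }
})

test_that("lateral linear ramps are reconstructed exactly on all lines", {
  # quadratic-precision property of the a = -0.5 kernel, including borders
  # thanks to the quadratic boundary extension
  ramp <- matrix(seq(0, 1, length.out = 32), 32, 5)
  for (s in c(2, 4)) {
    pair <- make_training_pair(us_image(ramp, "unit"), sampling_scheme(s))
    expect_equal(pair$input$pixels, pair$target$pixels, tolerance = 1e-12)
  }
})

test_that("acquired lines pass through interpolation bit-identically", {
  for (s in c(2, 4)) {
    img <- random_test_image(24, 9, seed = 100 + s)
    pair <- make_training_pair(img, sampling_scheme(s))
    acq <- pair$input$acquired_mask
    expect_equal(sum(acq), 24 / s)
    expect_identical(pair$input$pixels[acq, ], pair$target$pixels[acq, ])
  }
})

test_that("vectorised up-sampling matches the brute-force kernel loop", {
  for (s in c(2, 4)) {
    for (seed in 1:5) {
      img <- random_test_image(32, 12, seed = 200 + seed)
      low <- downsample_beamlines(img, sampling_scheme(s))
      up <- upsample_beamlines(low, sampling_scheme(s))
      expect_lt(max(abs(up$pixels - oracle_upsample(low$pixels, s))), 1e-10)
    }
  }
  # nonzero phase follows the same stencil
  img <- random_test_image(32, 4, seed = 300)
  low <- downsample_beamlines(img, sampling_scheme(2, phase = 1))
  up <- upsample_beamlines(low, sampling_scheme(2, phase = 1))
  expect_lt(max(abs(up$pixels - oracle_upsample(low$pixels, 2, phase = 1))),
            1e-10)
})

test_that("up-sampling validates its support and target size", {
  low <- random_test_image(4, 4, seed = 1)
  expect_error(upsample_beamlines(low, sampling_scheme(2), target_lines = 10),
               "target_lines")
  tiny <- downsample_beamlines(random_test_image(8, 4, seed = 2),
                               sampling_scheme(4))
  expect_error(upsample_beamlines(tiny, sampling_scheme(4)),
               "insufficient support")
})

test_that("sampling scheme validates its fields", {
  expect_error(sampling_scheme(3), "factor")
  expect_error(sampling_scheme(2, phase = 2), "phase")
  expect_error(sampling_scheme(2, kernel_a = 0.5), "kernel_a")
})
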