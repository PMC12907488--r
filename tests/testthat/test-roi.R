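test_that("box enlargement scales about the center, capped at slice bounds", {
  # (w, h) = (40, 30) at factor 3 -> (120, 90), same center
  b <- enlarge_box(c(100, 110, 140, 140), factor = 3, bounds = 256)
  expect_equal(unname(b[3] - b[1]), 120)
  expect_equal(unname(b[4] - b[2]), 90)
  expect_equal(unname(b[1] + b[3]) / 2, (100 + 140) / 2)
  expect_equal(unname(b[2] + b[4]) / 2, (110 + 140) / 2)

  expect_equal(unname(enlarge_box(c(10, 20, 30, 40), 1)), c(10, 20, 30, 40))
  expect_error(enlarge_box(c(0, 0, 10, 10), 5), "factor")
  expect_error(enlarge_box(c(10, 10, 10, 20), 2), "empty")

  # corner boxes: clipped result stays in bounds and contains the original
  set.seed(61)
  for (i in 1:1000) {
    x0 <- sample(0:250, 1); y0 <- sample(0:250, 1)
    x1 <- min(256, x0 + sample(1:40, 1)); y1 <- min(256, y0 + sample(1:40, 1))
    eb <- enlarge_box(c(x0, y0, x1, y1), 3, 256)
    expect_true(eb[1] >= 0 && eb[2] >= 0 && eb[3] <= 256 && eb[4] <= 256)
    expect_true(eb[1] <= x0 && eb[2] <= y0 && eb[3] >= x1 && eb[4] >= y1)
  }
})

test_that("crop geometry follows the pad/resize mode contract", {
  sl <- matrix(runif(256^2), 256, 256)
  # non-square 120 x 90 -> padded to 120 square, resized x(256/120)
  cr <- crop_pad_resize(sl, c(60, 60, 180, 150), target = 256)
  expect_equal(cr$transform$square, 120L)
  expect_equal(cr$transform$resize_factor, 256 / 120)
  expect_equal(dim(cr$patch), c(256L, 256L))

  # already-square 200 x 200 within target -> pad-only, 28-pixel borders
  cr2 <- crop_pad_resize(sl, c(20, 20, 220, 220), target = 256)
  expect_equal(cr2$transform$resize_factor, 1)
  expect_equal(unname(cr2$transform$pad["left"]), 28L)
  expect_true(all(cr2$patch[1:28, ] == 0))
  expect_equal(cr2$patch[29:228, 29:228], sl[21:220, 21:220])

  expect_error(crop_pad_resize(sl, c(10, 10, 10, 30)), "empty box")
  # identical inputs give identical transforms
  expect_identical(crop_pad_resize(sl, c(60, 60, 180, 150))$transform,
                   crop_pad_resize(sl, c(60, 60, 180, 150))$transform)
})

test_that("pad-only crop/invert round trip is bit-exact on random masks", {
  set.seed(62)
  for (i in 1:60) {
    n <- 256L
    x0 <- sample(0:200, 1); y0 <- sample(0:200, 1)
    w <- sample(5:50, 1); h <- sample(5:50, 1)
    m <- matrix(0, n, n)
    m[(x0 + 1):(x0 + w), (y0 + 1):(y0 + h)] <- matrix(rbinom(w * h, 1, 0.5), w, h)
    cr <- crop_pad_resize(m, c(x0, y0, x0 + w, y0 + h), target = 256,
                          mode = "pad", interp = "nearest")
    back <- invert_crop(cr$patch, cr$transform)
    ref <- matrix(0, n, n)
    ref[(x0 + 1):(x0 + w), (y0 + 1):(y0 + h)] <- m[(x0 + 1):(x0 + w), (y0 + 1):(y0 + h)]
    expect_identical(back, ref)
  }
})

test_that("resize-mode round trip keeps disk masks at Dice >= 0.98", {
  set.seed(63)
  worst <- 1
  for (i in 1:40) {
    r <- sample(20:45, 1)
    cx <- sample(70:180, 1); cy <- sample(70:180, 1)
    m <- disk_mask(256, cx, cy, r)
    box <- enlarge_box(c(cx - r - 2, cy - r - 2, cx + r + 1, cy + r + 1), 1.5, 256)
    # target below the square size forces a genuine down/up resize cycle
    cr <- crop_pad_resize(m, box, target = 128, mode = "resize", interp = "nearest")
    back <- invert_crop(cr$patch, cr$transform)
    worst <- min(worst, as.numeric(dice(back, m)))
  }
  expect_gte(worst, 0.98)
})

test_that("inverting an all-zero patch yields an all-zero slice", {
  sl <- matrix(runif(256^2), 256, 256)
  cr <- crop_pad_resize(sl, c(60, 60, 180, 150), target = 256)
  out <- invert_crop(matrix(0, 256, 256), cr$transform)
  expect_true(all(out == 0))
  expect_error(invert_crop(matrix(0, 256, 256), cr$transform, out_size = 100),
               "inconsistent")
})
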