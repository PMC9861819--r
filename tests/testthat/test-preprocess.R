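test_that("standardization z-scores the brain and leaves background at zero", {
  img <- array(0, dim = c(1, 4, 4, 4))
  img[1, 1:2, 1, 1] <- c(1, 3)
  out <- normalize_volume(img)
  expect_equal(out[1, 1:2, 1, 1], c(-1, 1))  # two-point set z-scores to +/-1
  expect_true(all(out[1, 3:4, , ] == 0))

  # constant brain region -> zeros (guarded zero variance)
  cimg <- array(0, dim = c(1, 4, 4, 4))
  cimg[1, 1:3, 1:3, 1:3] <- 5
  expect_true(all(normalize_volume(cimg) == 0))

  # all-zero modality warns and passes through
  expect_warning(normalize_volume(array(0, dim = c(1, 2, 2, 2))), "all zero")

  # idempotent up to floating tolerance
  set.seed(40)
  r <- array(0, dim = c(2, 6, 6, 6))
  r[, 2:5, 2:5, 2:5] <- rnorm(2 * 64, mean = 3)
  once <- normalize_volume(r)
  twice <- normalize_volume(once)
  expect_equal(twice, once, tolerance = 1e-10)
})

test_that("sample statistics match over the brain mask per channel", {
  set.seed(41)
  img <- array(0, dim = c(4, 8, 8, 8))
  mask <- array(runif(512) > 0.4, dim = c(8, 8, 8))
  for (c in 1:4) {
    v <- array(0, dim = c(8, 8, 8))
    v[mask] <- rnorm(sum(mask), mean = c, sd = c)
    img[c, , , ] <- v
  }
  out <- normalize_volume(img)
  for (c in 1:4) {
    vals <- out[c, , , ][mask]
    expect_equal(mean(vals), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(vals^2)), 1, tolerance = 1e-10)
  }
})

test_that("augmentation is identity without flips and rotation", {
  set.seed(42)
  s <- list(image = rand_volume(2, 8), label = array(
    sample(c(0L, 1L, 2L, 4L), 512, replace = TRUE), dim = c(8, 8, 8)))
  out <- augment_sample(s, p_flip = 0, rot_range = 0)
  expect_identical(out$image, s$image)
  expect_identical(out$label, s$label)
})

test_that("pure flips preserve voxel histograms and are involutions", {
  set.seed(43)
  s <- list(image = rand_volume(2, 8), label = array(
    sample(c(0L, 1L, 2L, 4L), 512, replace = TRUE), dim = c(8, 8, 8)))
  out <- augment_sample(s, p_flip = 1, rot_range = 0)  # flip all three axes
  expect_equal(sort(as.vector(out$image)), sort(as.vector(s$image)))
  expect_identical(table(out$label), table(s$label))
  back <- augment_sample(out, p_flip = 1, rot_range = 0)
  expect_identical(back$image, s$image)
  expect_identical(back$label, s$label)
})

test_that("rotation keeps labels inside the label set and images finite", {
  set.seed(44)
  lab <- array(0L, dim = c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 2L
  lab[4:5, 4:5, 4:5] <- 4L
  s <- list(image = rand_volume(4, 8), label = lab)
  for (i in 1:10) {
    out <- augment_sample(s, p_flip = 0.5, rot_range = 10)
    expect_true(all(out$label %in% c(0L, 1L, 2L, 4L)))
    expect_true(all(is.finite(out$image)))
    expect_equal(dim(out$image), dim(s$image))
  }
})

test_that("crop records an exact inverse mapping", {
  set.seed(45)
  img <- array(rnorm(4 * 20 * 20 * 12), dim = c(4, 20, 20, 12))
  lab <- array(sample(c(0L, 2L), 20 * 20 * 12, replace = TRUE), dim = c(20, 20, 12))
  s <- list(image = img, label = lab)
  cs <- crop_to_patch(s, extent = 16, mode = "center")
  expect_equal(dim(cs$image), c(4, 16, 16, 16))
  expect_equal(cs$crop$native, c(20, 20, 12))
  # paste-back of an all-zero prediction gives an all-zero native volume
  zero <- paste_back(array(0L, dim = c(16, 16, 16)), cs$crop)
  expect_equal(dim(zero), c(20, 20, 12))
  expect_true(all(zero == 0))
  # the label round-trips losslessly inside the window
  back <- paste_back(cs$label, cs$crop)
  ix <- lapply(1:3, function(a) cs$crop$offset[a] + seq_len(16))
  inside <- lapply(1:3, function(a) ix[[a]][ix[[a]] <= dim(lab)[a]])
  expect_identical(back[inside[[1]], inside[[2]], inside[[3]]],
                   lab[inside[[1]], inside[[2]], inside[[3]]])
})

test_that("the 155-slice axis pads to 160 before cropping", {
  img <- array(1, dim = c(4, 240, 240, 155))
  s <- crop_to_patch(list(image = img), extent = 128, mode = "center")
  expect_equal(s$crop$padded, c(240, 240, 160))
  expect_equal(dim(s$image), c(4, 128, 128, 128))
  expect_equal(s$crop$offset, c(56, 56, 16))
})

test_that("tumor-biased cropping keeps a lone tumor voxel inside the patch", {
  set.seed(46)
  for (i in 1:50) {
    lab <- array(0L, dim = c(24, 24, 24))
    pos <- sample(24, 3, replace = TRUE)
    lab[pos[1], pos[2], pos[3]] <- 4L
    s <- list(image = array(rnorm(4 * 24^3), dim = c(4, 24, 24, 24)), label = lab)
    cs <- crop_to_patch(s, extent = 16, mode = "random")
    expect_equal(sum(cs$label == 4L), 1)
  }
})
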