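test_that("channel_split halves the channels and round-trips", {
  set.seed(1)
  x <- rand_volume(32, 8)
  h <- channel_split(x)
  expect_equal(dim(h$main), c(16, 8, 8, 8))
  expect_equal(dim(h$identity), c(16, 8, 8, 8))

  x2 <- rand_volume(2, 4)
  h2 <- channel_split(x2)
  expect_equal(h2$main[1, , , ], x2[1, , , ])
  expect_equal(h2$identity[1, , , ], x2[2, , , ])

  for (C in seq(2, 64, by = 2)) {
    xr <- rand_volume(C, 2)
    hr <- channel_split(xr)
    rejoined <- array(0, dim = dim(xr))
    rejoined[seq_len(C / 2), , , ] <- hr$main
    rejoined[C / 2 + seq_len(C / 2), , , ] <- hr$identity
    expect_identical(rejoined, xr)
  }
  expect_error(channel_split(rand_volume(3, 4)), "even")
})

test_that("channel_shuffle matches the reshape-transpose oracle and is a bijection", {
  set.seed(2)
  x <- rand_volume(4, 4)
  expect_identical(channel_shuffle(x, 1L), x)

  y <- channel_shuffle(x, 2L)
  expect_identical(y, x[c(1, 3, 2, 4), , , , drop = FALSE])
  expect_identical(channel_shuffle(y, 2L), x)  # self-inverse for C = 4, g = 2

  for (C in c(4, 6, 8, 12, 16)) {
    for (g in Filter(function(g) C %% g == 0, 2:C)) {
      xr <- rand_volume(C, 2)
      got <- channel_shuffle(xr, g)
      expect_identical(got, xr[oracle_shuffle_perm(C, g), , , , drop = FALSE],
                       label = sprintf("C=%d g=%d", C, g))
      # shuffling with g then with C/g restores the original order
      expect_identical(channel_shuffle(got, C %/% g), xr,
                       label = sprintf("inverse C=%d g=%d", C, g))
    }
  }
  expect_error(channel_shuffle(rand_volume(4, 2), 3L), "divisible")
})

test_that("adaptive kernel size follows the channel-attention rule", {
  expect_identical(cwu_kernel_size(16), 3L)
  expect_identical(cwu_kernel_size(256), 5L)
  expect_identical(cwu_kernel_size(2), 1L)
  expect_error(cwu_kernel_size(0), ">= 1")
  ks <- vapply(1:1024, cwu_kernel_size, integer(1))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(ks >= 1))
  expect_true(all(diff(ks) >= 0))
})

test_that("cross-resolution weighting pools, weights and rescales correctly", {
  set.seed(3)
  # stage-2 geometry: own half 16 ch at 64-grid scale, other branch 64 ch at
  # half that; exercised at reduced extents with identical channel counts
  own <- rand_volume(16, 8)
  other <- rand_volume(64, 4)
  out <- cwu_forward(own, list(other))
  expect_equal(dim(out), dim(own))
  expect_identical(cwu_kernel_size(16 + 64), 3L)

  # zero 1-D kernel -> sigmoid(0) = 0.5 everywhere
  expect_equal(out, own * 0.5, tolerance = 1e-12)

  # constant inputs stay constant through adaptive pooling at every scale;
  # weights then equal sigmoid(k-sum * constant) per channel slice
  cown <- array(1, dim = c(2, 8, 8, 8))
  cother <- array(2, dim = c(6, 4, 4, 4))
  kern <- c(0.3, -0.2, 0.1)
  expect_identical(cwu_kernel_size(8), 3L)
  got <- cwu_forward(cown, list(cother), kernel = kern)
  # concatenated pooled channel vector is c(1, 1, 2, ..., 2); correlate
  # with the kernel centred at each channel, first two channels are ours
  vec <- c(1, 1, rep(2, 6))
  padded <- c(0, vec, 0)
  lin <- vapply(1:2, function(c) sum(kern * padded[c:(c + 2)]), numeric(1))
  wref <- 1 / (1 + exp(-lin))
  expect_equal(got[1, , , ], cown[1, , , ] * wref[1], tolerance = 1e-12)
  expect_equal(got[2, , , ], cown[2, , , ] * wref[2], tolerance = 1e-12)

  # degenerate first-stage case: no other branches
  solo <- cwu_forward(own)
  expect_equal(solo, own * 0.5, tolerance = 1e-12)
})

test_that("spatial weighting squeezes space into bounded channel weights", {
  set.seed(4)
  x <- rand_volume(16, 6)
  out <- swu_forward(x)
  expect_equal(dim(out), dim(x))
  expect_equal(out, x / 2, tolerance = 1e-12)  # zero weights -> 0.5

  # random weights: output is x scaled channel-wise by values in (0, 1)
  w1 <- matrix(rnorm(16 * 16, sd = 0.5), 16, 16)
  w2 <- matrix(rnorm(16 * 16, sd = 0.5), 16, 16)
  out2 <- swu_forward(x, w1, w2)
  ratio <- out2 / x
  per_channel <- apply(ratio, 1, function(v) diff(range(v)))
  expect_true(all(per_channel < 1e-9))   # homogeneous per channel
  wts <- ratio[, 1, 1, 1]
  expect_true(all(wts > 0 & wts < 1))    # sigmoid range
})

test_that("LCC block preserves shape and routes the identity half through the shuffle", {
  set.seed(5)
  maps <- list(rand_volume(32, 8), rand_volume(64, 4))
  out <- lcc_forward(maps, 1L)
  expect_equal(dim(out), dim(maps[[1]]))

  # frozen block: zero weighting units (-> 0.5 factors) and identity
  # depthwise kernel; the identity half must appear untouched at the
  # shuffled positions
  block <- hmnet:::new_lcc(c(32L, 64L), 1L, 2L, init = "zero")
  dwk <- array(0, dim = c(16, 3, 3, 3))
  dwk[, 2, 2, 2] <- 1
  block$dw$w$value <- dwk
  got <- lcc_forward(maps, 1L, block = block)
  perm <- oracle_shuffle_perm(32, 2)
  identity_positions <- which(perm > 16)
  for (j in identity_positions) {
    expect_equal(got[j, , , ], maps[[1]][perm[j], , , ],
                 tolerance = 1e-12)
  }
  # main half: x * 0.5 (CWU) convolved with identity kernel, * 0.5 (SWU)
  main_positions <- which(perm <= 16)
  for (j in main_positions[1:3]) {
    expect_equal(got[j, , , ], maps[[1]][perm[j], , , ] * 0.25,
                 tolerance = 1e-12)
  }
  # weighting keeps the main half bounded by the input
  expect_true(max(abs(got)) <= max(abs(maps[[1]])) + 1e-12)
})

test_that("ghost reduction produces the requested channel count", {
  set.seed(6)
  x <- rand_volume(64, 4)
  out <- ghost_reduce(x, 32L)
  expect_equal(dim(out), c(32, 4, 4, 4))
  expect_equal(dim(ghost_reduce(x, 2L)), c(2, 4, 4, 4))
  expect_equal(dim(ghost_reduce(rand_volume(8, 4), 32L))[1], 32)
  expect_error(ghost_reduce(x, 5L), "even")
})

test_that("fusion downsampling halves extents and doubles channels per hop", {
  set.seed(7)
  x <- rand_volume(64, 8)
  expect_equal(dim(lmrf_downsample(x, 1L)), c(128, 4, 4, 4))
  x2 <- rand_volume(32, 8)
  expect_equal(dim(lmrf_downsample(x2, 2L)), c(128, 2, 2, 2))
  expect_equal(dim(lmrf_downsample(rand_volume(4, 2), 1L)), c(8, 1, 1, 1))
  expect_error(lmrf_downsample(rand_volume(4, 6), 2L), "divisible")
  expect_error(lmrf_downsample(x, 0L), ">= 1")
})

test_that("multi-resolution fusion conserves shapes and zero laterals are identity", {
  set.seed(8)
  maps <- list(rand_volume(32, 8), rand_volume(64, 4))
  out <- lmrf_fuse(maps)
  expect_equal(lapply(out, dim), lapply(maps, dim))

  fusion0 <- hmnet:::new_lmrf(c(32L, 64L), 2L, add_branch = FALSE, init = "zero")
  out0 <- lmrf_fuse(maps, fusion0)
  expect_equal(out0[[1]], maps[[1]], tolerance = 1e-14)
  expect_equal(out0[[2]], maps[[2]], tolerance = 1e-14)

  # three-branch stage: branch 3 receives a 2-hop downsample of branch 1,
  # and the added branch 4 doubles branch 3's channels at half its extent
  maps3 <- list(rand_volume(32, 8), rand_volume(64, 4), rand_volume(128, 2))
  fusion3 <- hmnet:::new_lmrf(c(32L, 64L, 128L, 256L), 3L, add_branch = TRUE)
  out3 <- lmrf_fuse(maps3, fusion3)
  expect_length(out3, 4)
  expect_equal(lapply(out3[1:3], dim), lapply(maps3, dim))
  expect_equal(dim(out3[[4]]), c(256, 1, 1, 1))
  expect_equal(dim(fusion3$paths[["1>3"]]$forward(hmnet:::ag_leaf(maps3[[1]]))$value),
               c(128, 2, 2, 2))
  expect_error(lmrf_fuse(list(rand_volume(32, 8), rand_volume(100, 4))),
               "channel plan")
})

test_that("all blocks respect the stage shape plan across the four stages", {
  set.seed(9)
  chans <- c(8L, 16L, 32L, 64L)
  base <- 16L
  for (stage in 1:4) {
    n_active <- min(stage, 4L)
    maps <- lapply(seq_len(n_active), function(b)
      rand_volume(chans[b], base / 2L^(b - 1L)))
    for (b in seq_len(n_active)) {
      blk <- hmnet:::new_lcc(chans, b, n_active)
      out <- lcc_forward(maps, b, block = blk)
      expect_equal(dim(out), dim(maps[[b]]),
                   label = sprintf("stage %d branch %d", stage, b))
    }
    fusion <- hmnet:::new_lmrf(chans, n_active, add_branch = n_active < 4L)
    fused <- lmrf_fuse(maps, fusion)
    for (b in seq_len(n_active))
      expect_equal(dim(fused[[b]]), dim(maps[[b]]))
    if (n_active < 4L)
      expect_equal(dim(fused[[n_active + 1L]]),
                   c(chans[n_active + 1L], rep(base / 2L^n_active, 3L)))
  }
})
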