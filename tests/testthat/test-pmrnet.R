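test_that("configuration invariants are enforced", {
  expect_s3_class(hmnet_config(), "hmnet_config")
  expect_error(hmnet_config(branch_channels = c(32, 64, 128, 200)), "twice")
  expect_error(hmnet_config(input_size = 100), "divisible by 16")
  expect_error(hmnet_config(branch_channels = c(32, 64, 128)), "four branches")
  expect_error(hmnet_config(lcc_blocks_per_stage = 0), ">= 1")
})

test_that("the built model follows the branch resolution/channel plan", {
  model <- hmnet_build(hmnet_config(), seed = 1)
  expect_equal(model$concat_channels, 480L)
  expect_equal(model$stage2_concat_channels, 80L)

  # analytic extents at the default 128 input: 64/32/16/8 at 32/64/128/256
  lt <- tidy(model_complexity(model, input_size = 128))
  lcc_rows <- dplyr::filter(lt, grepl("stage4.*lcc\\.dw$", .data$layer))
  expect_equal(lcc_rows$extent, c(64, 32, 16, 8))
  expect_equal(lcc_rows$cin, c(16, 32, 64, 128))  # split halves of 32/64/128/256

  # the same plan scales to a 32-voxel input
  m32 <- hmnet_build(hmnet_config(input_size = 32), seed = 1)
  lt32 <- tidy(model_complexity(m32, input_size = 32))
  expect_equal(dplyr::filter(lt32, grepl("stage4.*lcc\\.dw$", .data$layer))$extent,
               c(16, 8, 4, 2))
})

test_that("forward maps 4-channel volumes to 3-channel outputs at stage-plan shapes", {
  set.seed(10)
  model <- hmnet_build(hmnet_config(input_size = 32), seed = 3)
  x <- rand_volume(4, 32)
  out <- hmnet_forward(model, x, collect_stages = TRUE)
  expect_equal(dim(out), c(3, 32, 32, 32))
  sd_ <- attr(out, "stage_dims")
  expect_length(sd_, 4)
  for (s in 1:4) {
    nb <- length(sd_[[s]])
    expect_equal(nb, if (s >= 3) 4L else s + 1L)
    for (b in seq_len(nb)) {
      expect_equal(sd_[[s]][[b]],
                   c(c(32, 64, 128, 256)[b], rep(32 / 2^b, 3)),
                   label = sprintf("stage %d branch %d", s, b))
    }
  }
  expect_error(hmnet_forward(model, rand_volume(3, 32)), "array")
  expect_error(hmnet_forward(model, rand_volume(4, 24)), "divisible")
})

test_that("evaluation forward passes are deterministic", {
  set.seed(11)
  model <- hmnet_build(tiny_config(), seed = 4)
  x <- rand_volume(4, 16)
  o1 <- hmnet_forward(model, x)
  o2 <- hmnet_forward(model, x)
  expect_identical(unclass(o1), unclass(o2))
})

test_that("every parameter receives gradient from a generic input (no dead branches)", {
  set.seed(12)
  model <- hmnet_build(tiny_config(), seed = 5)
  x <- rand_volume(4, 16)
  tgt <- array(as.numeric(runif(3 * 16^3) > 0.7), dim = c(3, 16, 16, 16))
  out <- hmnet:::hmnet_forward_node(model, hmnet:::ag_leaf(x))
  loss <- hmnet:::op_dice_bce_loss(out, tgt)
  hmnet:::ag_backward(loss)
  gnorm <- vapply(model$params, function(p)
    if (is.null(p$grad)) 0 else sum(abs(p$grad)), numeric(1))
  expect_true(all(gnorm > 0),
              info = paste("dead:", paste(names(gnorm)[gnorm == 0], collapse = ", ")))
})

test_that("label prediction composes the nested regions hierarchically", {
  low <- array(-10, dim = c(3, 4, 4, 4))
  out <- structure(low, head_mode = "region")
  expect_true(all(predict_labels(out) == 0L))

  high <- structure(array(10, dim = c(3, 4, 4, 4)), head_mode = "region")
  expect_true(all(predict_labels(high) == 4L))

  set.seed(13)
  for (i in 1:20) {
    sc <- structure(array(rnorm(3 * 8^3, sd = 3), dim = c(3, 8, 8, 8)),
                    head_mode = "region")
    lab <- predict_labels(sc)
    expect_true(all(lab %in% c(0L, 1L, 2L, 4L)))
    m <- region_masks(lab)
    expect_true(all(m$ET <= m$TC))
    expect_true(all(m$TC <= m$WT))
  }
})

test_that("the label head decodes argmax classes against a background threshold", {
  sc <- array(-10, dim = c(3, 2, 2, 2))
  sc[2, 1, 1, 1] <- 10                      # class 2 wins at one voxel
  out <- structure(sc, head_mode = "label")
  lab <- predict_labels(out)
  expect_equal(lab[1, 1, 1], 2L)
  expect_true(all(lab[-1] == 0L))           # everything else below threshold
})
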