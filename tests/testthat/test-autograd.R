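# Backward passes checked against central-difference gradients on small
# tensors; these guard the hand-written convolution/normalization kernels.

expect_gradmatch <- function(analytic, f, x, tol = 1e-6, eps = 1e-5) {
  num <- numeric_grad(f, x, eps)
  expect_lt(max(abs(analytic - num)) / max(1, max(abs(num))), tol)
}

scalar_probe <- function(out) {
  seed <- array(rnorm(length(out$value)), dim = dim(out$value))
  loss <- hmnet:::ag_node(sum(out$value * seed), list(out),
                          function(dy) list(dy * seed))
  hmnet:::ag_backward(loss)
  seed
}

test_that("dense 3D convolution gradients match central differences", {
  set.seed(60)
  x <- rand_volume(3, 5)
  w <- matrix(rnorm(3 * 27 * 4, sd = 0.3), 3 * 27, 4)
  b <- rnorm(4)
  for (stride in 1:2) {
    nx <- hmnet:::ag_leaf(x); nw <- hmnet:::ag_leaf(w); nb <- hmnet:::ag_leaf(b)
    out <- hmnet:::op_conv3d(nx, nw, 3L, 4L, stride = stride, bias = nb)
    seed <- scalar_probe(out)
    f <- function(xx, ww = w, bb = b) {
      o <- hmnet:::with_no_grad(hmnet:::op_conv3d(
        hmnet:::ag_leaf(xx), hmnet:::ag_leaf(ww), 3L, 4L, stride = stride,
        bias = hmnet:::ag_leaf(bb)))
      sum(o$value * seed)
    }
    expect_gradmatch(nx$grad, f, x)
    expect_gradmatch(nw$grad, function(z) f(x, matrix(z, nrow(w))), w)
    expect_gradmatch(nb$grad, function(z) f(x, w, z), b)
  }
})

test_that("depthwise convolution gradients match central differences", {
  set.seed(61)
  x <- rand_volume(3, 5)
  w <- array(rnorm(3 * 27, sd = 0.3), dim = c(3, 3, 3, 3))
  for (stride in 1:2) {
    nx <- hmnet:::ag_leaf(x); nw <- hmnet:::ag_leaf(w)
    out <- hmnet:::op_dwconv3d(nx, nw, 3L, stride = stride)
    seed <- scalar_probe(out)
    f <- function(xx, ww = w) {
      o <- hmnet:::with_no_grad(hmnet:::op_dwconv3d(
        hmnet:::ag_leaf(xx), hmnet:::ag_leaf(ww), 3L, stride = stride))
      sum(o$value * seed)
    }
    expect_gradmatch(nx$grad, f, x)
    expect_gradmatch(nw$grad, function(z) f(x, array(z, dim(w))), w)
  }
})

test_that("group normalization gradients match central differences", {
  set.seed(62)
  x <- rand_volume(4, 4)
  ga <- rnorm(4, 1, 0.2); be <- rnorm(4, 0, 0.2)
  nx <- hmnet:::ag_leaf(x); ng <- hmnet:::ag_leaf(ga); nb <- hmnet:::ag_leaf(be)
  out <- hmnet:::op_groupnorm(nx, ng, nb, 2L)
  seed <- scalar_probe(out)
  f <- function(xx, gg = ga, bb = be) {
    o <- hmnet:::with_no_grad(hmnet:::op_groupnorm(
      hmnet:::ag_leaf(array(xx, dim(x))), hmnet:::ag_leaf(gg),
      hmnet:::ag_leaf(bb), 2L))
    sum(o$value * seed)
  }
  expect_gradmatch(nx$grad, f, x, tol = 5e-5)
  expect_gradmatch(ng$grad, function(z) f(x, z), ga)
  expect_gradmatch(nb$grad, function(z) f(x, ga, z), be)
})

test_that("channel 1-D convolution, pooling and upsampling backprop exactly", {
  set.seed(63)
  x <- rand_volume(6, 4)
  w <- rnorm(3)
  nx <- hmnet:::ag_leaf(x); nw <- hmnet:::ag_leaf(w)
  out <- hmnet:::op_conv1d_channels(nx, nw, 3L)
  seed <- scalar_probe(out)
  f <- function(xx, ww = w) {
    o <- hmnet:::with_no_grad(hmnet:::op_conv1d_channels(
      hmnet:::ag_leaf(array(xx, dim(x))), hmnet:::ag_leaf(ww), 3L))
    sum(o$value * seed)
  }
  expect_gradmatch(nx$grad, f, x)
  expect_gradmatch(nw$grad, function(z) f(x, z), w)

  # mean pooling backward spreads gradient uniformly
  nx <- hmnet:::ag_leaf(x)
  out <- hmnet:::op_pool_mean(nx, 2L)
  seed <- scalar_probe(out)
  fp <- function(xx) {
    o <- hmnet:::with_no_grad(hmnet:::op_pool_mean(
      hmnet:::ag_leaf(array(xx, dim(x))), 2L))
    sum(o$value * seed)
  }
  expect_gradmatch(nx$grad, fp, x)

  # nearest upsampling backward sums gradient blocks
  nx <- hmnet:::ag_leaf(x)
  out <- hmnet:::op_upsample_nearest(nx, 2L)
  seed <- scalar_probe(out)
  fu <- function(xx) {
    o <- hmnet:::with_no_grad(hmnet:::op_upsample_nearest(
      hmnet:::ag_leaf(array(xx, dim(x))), 2L))
    sum(o$value * seed)
  }
  expect_gradmatch(nx$grad, fu, x)
})

test_that("the region Dice+BCE loss gradient matches central differences", {
  set.seed(64)
  logits <- array(rnorm(3 * 4^3), dim = c(3, 4, 4, 4))
  tgt <- array(as.numeric(runif(3 * 4^3) > 0.6), dim = c(3, 4, 4, 4))
  nl <- hmnet:::ag_leaf(logits)
  loss <- hmnet:::op_dice_bce_loss(nl, tgt)
  hmnet:::ag_backward(loss)
  f <- function(z) hmnet:::with_no_grad(
    hmnet:::op_dice_bce_loss(hmnet:::ag_leaf(array(z, dim(logits))), tgt))$value
  expect_gradmatch(nl$grad, f, logits, tol = 1e-5)

  # loss is ~zero for confident, correct predictions
  perfect <- hmnet:::ag_leaf(array(ifelse(tgt > 0.5, 15, -15), dim = dim(tgt)))
  expect_lt(hmnet:::op_dice_bce_loss(perfect, tgt)$value, 1e-4)
})

test_that("randomly probed end-to-end model gradients match central differences", {
  set.seed(65)
  model <- hmnet_build(tiny_config(), seed = 6)
  x <- rand_volume(4, 16)
  tgt <- array(as.numeric(runif(3 * 16^3) > 0.7), dim = c(3, 16, 16, 16))
  lossf <- function() {
    out <- hmnet:::hmnet_forward_node(model, hmnet:::ag_leaf(x))
    hmnet:::op_dice_bce_loss(out, tgt)
  }
  l <- lossf()
  hmnet:::ag_backward(l)
  sel <- sample(names(model$params), 8)
  for (nm in sel) {
    p <- model$params[[nm]]
    i <- sample(length(p$value), 1)
    g_an <- p$grad[i]
    eps <- 1e-4
    old <- p$value[i]
    p$value[i] <- old + eps
    lp <- hmnet:::with_no_grad(lossf())$value
    p$value[i] <- old - eps
    lm <- hmnet:::with_no_grad(lossf())$value
    p$value[i] <- old
    g_num <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_an - g_num), 1e-6 + 1e-3 * abs(g_num), label = nm)
  }
})
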