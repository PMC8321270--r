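# Architecture contracts: shapes, ranges, determinism, locality.

test_that("input downsampling is 2x2x2 average pooling with ceil shapes", {
  const <- array(0.42, c(8, 8, 8))
  expect_equal(downsample_input(const), array(0.42, c(4, 4, 4)))

  blk <- array((0:7) / 7, c(2, 2, 2))
  expect_equal(downsample_input(blk)[1, 1, 1], 0.5)

  odd <- array(runif(65 * 64 * 64), c(65, 64, 64))
  out <- downsample_input(odd)
  expect_equal(dim(out), c(33, 32, 32))
  # replicated edge: the last output plane averages the last input plane
  # duplicated along x
  expect_equal(out[33, 1, 1],
               mean(odd[65, 1:2, 1:2]))
  expect_error(downsample_input(odd, factor = 4), "exactly 2")
})

test_that("stage-1 output obeys the x8 shape contract on random shapes", {
  net <- tiny_net()
  params <- init_network(net, stages = 1, seed = 3)
  p64 <- stage1_forward(params, array(runif(64^3), c(64, 64, 64)))
  expect_equal(dim(p64$prob), c(8, 8, 8))

  set.seed(42)
  for (i in 1:4) {
    d <- sample(16:56, 3, replace = TRUE)
    x <- array(runif(prod(d)), d)
    out <- stage1_forward(params, x)
    expect_equal(dim(out$prob), as.integer(ceiling(d / 8)))
    expect_true(all(out$prob > 0 & out$prob < 1))      # sigmoid range
    expect_equal(dim(out$pyramid$f2)[1:3], as.integer(ceiling(d / 8)) * 4L)
    expect_equal(dim(out$pyramid$f4)[1:3], as.integer(ceiling(d / 8)) * 2L)
  }
  expect_error(stage1_forward(params, array(0, c(8, 20, 20))), ">= 16")
})

test_that("evaluation-mode forward passes are deterministic", {
  params <- init_network(tiny_net(), stages = 1, seed = 5)
  x <- array(runif(32^3), c(32, 32, 32))
  expect_identical(stage1_forward(params, x)$prob,
                   stage1_forward(params, x)$prob)
})

test_that("the detailed stage has more parameters than the localization stage", {
  for (bw in c(4L, 8L, 16L)) {
    p <- init_network(net_config(base_width = bw), stages = c(1, 2), seed = 1)
    np <- count_params(p)
    expect_lt(np["stage1"], np["stage2"])
  }
})

test_that("stage-2 output covers exactly the 8x-upsampled box extent", {
  net <- tiny_net()
  params <- init_network(net, stages = c(1, 2), seed = 7)
  x <- array(runif(64^3), c(64, 64, 64))
  s1 <- stage1_forward(params, x)
  box <- bbox3(c(1, 2, 3), c(3, 5, 7), "lowres")   # extent (2, 3, 4)
  out <- stage2_forward(params, s1$pyramid, box, image = x)
  expect_equal(dim(out), c(16, 24, 32))
  expect_true(all(out > 0 & out < 1))
  expect_error(stage2_forward(params, s1$pyramid,
                              bbox3(c(0, 0, 0), c(9, 1, 1), "lowres"), x),
               "exceeds")
})

test_that("nested boxes agree away from the decoder's receptive field", {
  # fully-convolutional locality: predictions for an inner box match the
  # outer box's prediction once the rf_margin border is eroded
  net <- net_config(base_width = 4, resblocks_per_scale = 0)
  params <- init_network(net, stages = c(1, 2), seed = 9)
  x <- array(runif(64^3), c(64, 64, 64))
  s1 <- stage1_forward(params, x)
  outer <- bbox3(c(0, 0, 0), c(8, 8, 8), "lowres")
  inner <- bbox3(c(1, 1, 1), c(7, 7, 7), "lowres")
  po <- stage2_forward(params, s1$pyramid, outer, image = x)
  pi_ <- stage2_forward(params, s1$pyramid, inner, image = x)
  m <- net$rf_margin          # 15 full-res voxels without ResBlocks
  # inner box spans [8,56) in full-res; erode by m on each side
  keep <- (8 + m + 1):(56 - m)
  expect_lt(max(abs(po[keep, keep, keep] -
                      pi_[keep - 8, keep - 8, keep - 8])), 1e-8)
})

test_that("stage-1 training steps produce gradients for every parameter", {
  net <- tiny_net()
  params <- init_network(net, stages = 1, seed = 11)
  set.seed(12)
  xs <- lapply(1:2, function(i) array(runif(16^3), c(16, 16, 16)))
  ts <- lapply(1:2, function(i) array(rbinom(8, 1, 0.5), c(2, 2, 2)))
  step <- adaptseg:::cpp_stage1_batch(params, xs, ts, 5, TRUE, TRUE, 0.1)
  trainable <- names(params)[!grepl("_rm|_rv", names(params))]
  expect_setequal(names(step$grads), trainable)
  gnorm <- vapply(step$grads, function(g) sum(abs(g)), numeric(1))
  expect_true(all(gnorm > 0))
})
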