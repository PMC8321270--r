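# Adaptive inference: thresholding, components, boxes, assembly, tiling.

test_that("binarization uses the >= convention", {
  z <- array(0, c(4, 4, 4))
  expect_true(all(!binarize(z)))
  m <- array(c(0.4999, 0.5, 0.5001, 0), c(1, 2, 2))
  b <- binarize(m, 0.5)
  expect_identical(as.vector(b), c(FALSE, TRUE, TRUE, FALSE))
  set.seed(31)
  r <- array(runif(10^3), c(10, 10, 10))
  expect_equal(sum(binarize(r, 0.5)), sum(r >= 0.5))   # loop-free oracle
})

test_that("corner voxels are separate components even at 26-connectivity", {
  b <- array(FALSE, c(3, 3, 3))
  expect_equal(connected_components(b)$n_components, 0)
  b[1, 1, 1] <- TRUE; b[3, 3, 3] <- TRUE
  expect_equal(connected_components(b, 26L)$n_components, 2)
  # and a touching diagonal pair merges at 26 but not at 6
  b2 <- array(FALSE, c(3, 3, 3)); b2[1, 1, 1] <- TRUE; b2[2, 2, 2] <- TRUE
  expect_equal(connected_components(b2, 26L)$n_components, 1)
  expect_equal(connected_components(b2, 6L)$n_components, 2)
})

test_that("component labelling matches a BFS flood-fill oracle", {
  set.seed(32)
  for (i in 1:15) {
    b <- array(rbinom(8^3, 1, runif(1, 0.1, 0.6)) > 0, c(8, 8, 8))
    for (conn in c(6L, 26L)) {
      lab <- connected_components(b, conn)$labels
      expect_true(same_partition(lab, oracle_flood_fill(b, conn)))
    }
  }
})

test_that("margined boxes expand tight boxes and clamp at bounds", {
  b <- array(FALSE, c(10, 10, 10)); b[5, 5, 5] <- TRUE   # voxel (4,4,4) 0-based
  cs <- connected_components(b)
  bx <- boxes_with_margin(cs, margin = 1)[[1]]
  expect_equal(bx$start, c(3L, 3L, 3L))
  expect_equal(bx$stop, c(6L, 6L, 6L))

  bx0 <- boxes_with_margin(cs, margin = 0)[[1]]
  expect_equal(bx0$start, c(4L, 4L, 4L))
  expect_equal(bx0$stop, c(5L, 5L, 5L))

  corner <- array(FALSE, c(10, 10, 10)); corner[1, 1, 10] <- TRUE
  bc <- boxes_with_margin(connected_components(corner), margin = 1)[[1]]
  expect_equal(bc$start, c(0L, 0L, 8L))
  expect_equal(bc$stop, c(2L, 2L, 10L))

  expect_equal(length(boxes_with_margin(connected_components(
    array(FALSE, c(4, 4, 4))))), 0)
})

test_that("low-resolution boxes scale by 8 and clamp to the volume", {
  b <- bbox3(c(3, 3, 3), c(6, 6, 6), "lowres")
  f <- box_to_fullres(b, 8L, c(80, 80, 80))
  expect_equal(f$start, c(24L, 24L, 24L))
  expect_equal(f$stop, c(48L, 48L, 48L))
  expect_equal(f$space, "fullres")

  f0 <- box_to_fullres(bbox3(c(0, 0, 0), c(1, 1, 1), "lowres"), 8L,
                       c(80, 80, 80))
  expect_equal(f0$stop, c(8L, 8L, 8L))

  # a padded coarse grid may overhang the true shape
  fo <- box_to_fullres(bbox3(c(11, 0, 0), c(12, 1, 1), "lowres"), 8L,
                       c(90, 90, 90))
  expect_equal(fo$stop[1], 90L)
  expect_error(box_to_fullres(f, 8L, c(80, 80, 80)), "low-resolution")
})

test_that("fraction_processed counts the box union once", {
  shp <- c(20, 20, 20)
  expect_equal(fraction_processed(list(), shp), 0)
  whole <- bbox3(c(0, 0, 0), c(20, 20, 20), "fullres")
  expect_equal(fraction_processed(list(whole), shp), 1)

  b1 <- bbox3(c(0, 0, 0), c(10, 10, 10), "fullres")
  b2 <- bbox3(c(5, 5, 5), c(15, 15, 15), "fullres")
  # dense boolean union oracle
  u <- array(FALSE, shp)
  u[1:10, 1:10, 1:10] <- TRUE
  u[6:15, 6:15, 6:15] <- TRUE
  expect_equal(fraction_processed(list(b1, b2), shp), mean(u))

  # monotone in the margin
  b <- array(FALSE, c(10, 10, 10)); b[5, 5, 5] <- TRUE; b[2, 8, 3] <- TRUE
  cs <- connected_components(b)
  fr <- vapply(0:3, function(m) {
    boxes <- lapply(boxes_with_margin(cs, margin = m),
                    box_to_fullres, factor = 8L, full_shape = c(80, 80, 80))
    fraction_processed(boxes, c(80, 80, 80))
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("tiled stage-1 prediction equals the direct forward pass", {
  params <- init_network(tiny_net(), stages = 1, seed = 41)
  x <- array(runif(64^3), c(64, 64, 64))
  direct <- stage1_forward(params, x)
  # single tile: identical
  one <- grid_predict(x, params, tiny_net(),
                      inference_config(grid_patch = c(64, 64, 64)))
  expect_equal(one$prob, direct$prob, tolerance = 1e-12)
  # forced 8-tile partition: equal within floating tolerance
  tiled <- grid_predict(x, params, tiny_net(),
                        inference_config(grid_patch = c(32, 32, 32)))
  expect_lt(max(abs(tiled$prob - direct$prob)), 1e-5)
  expect_lt(max(abs(tiled$pyramid$f4 - direct$pyramid$f4)), 1e-5)
  expect_equal(dim(tiled$prob), c(8, 8, 8))
})

test_that("adaptive predictions are exactly zero outside all boxes", {
  model <- fixture_model()
  cases <- make_cases(2, tiny_phantom_config(seed = 55), seed = 201)
  for (cs in cases) {
    pr <- adaptive_predict(cs$vol, model)
    outside <- array(TRUE, dim(cs$vol))
    for (b in pr$boxes) {
      if (any(b$start >= b$stop)) next
      outside[(b$start[1] + 1):b$stop[1], (b$start[2] + 1):b$stop[2],
              (b$start[3] + 1):b$stop[3]] <- FALSE
    }
    expect_true(all(pr$prob$data[outside] == 0))
    expect_true(pr$fraction_processed >= 0 && pr$fraction_processed <= 1)
  }
})

test_that("volumes not divisible by 8 predict cleanly, including boxes in
           the padding margin", {
  model <- fixture_model()
  set.seed(88)
  x <- array(runif(50 * 44 * 58, 0, 0.3), c(50, 44, 58))
  probs <- array(0, c(7, 6, 8))
  probs[3, 3, 3] <- 1       # interior proposal
  probs[7, 6, 8] <- 1       # proposal at the padded corner
  pr <- adaptive_predict(x, model, stage1_probs = probs)
  expect_equal(dim(pr$prob$data), dim(x))
  for (b in pr$boxes) expect_true(all(b$stop <= dim(x)))
  expect_true(pr$fraction_processed > 0 && pr$fraction_processed < 1)
})

test_that("a silent first stage yields a valid all-zero prediction", {
  model <- fixture_model()
  x <- array(runif(48^3, 0, 0.2), c(48, 48, 48))
  pr <- adaptive_predict(x, model, stage1_probs = array(0.1, c(6, 6, 6)))
  expect_equal(pr$n_boxes, 0)
  expect_true(all(pr$prob$data == 0))
  expect_equal(nrow(pr$components), 0)
  expect_equal(pr$fraction_processed, 0)
})

test_that("oracle localization covers every foreground voxel with margin 1", {
  model <- fixture_model()
  cases <- make_cases(3, tiny_phantom_config(seed = 66), seed = 301)
  for (cs in cases) {
    gt_lr <- maxpool_gt(cs$mask)
    pr <- adaptive_predict(cs$vol, model, stage1_probs = gt_lr)
    covered <- array(FALSE, dim(cs$mask))
    for (b in pr$boxes)
      covered[(b$start[1] + 1):b$stop[1], (b$start[2] + 1):b$stop[2],
              (b$start[3] + 1):b$stop[3]] <- TRUE
    expect_true(all(covered[cs$mask == 1]))
  }
})

test_that("overlap policy 'max' keeps the larger probability", {
  model <- fixture_model()
  cs <- make_cases(1, tiny_phantom_config(seed = 77), seed = 401)[[1]]
  # two adjacent positive cells force overlapping margined boxes
  probs <- array(0, ceiling(dim(cs$vol) / 8))
  probs[2, 2, 2] <- 1; probs[4, 2, 2] <- 1
  pr_last <- adaptive_predict(cs$vol, model, stage1_probs = probs,
                              cfg = inference_config(overlap = "last"))
  pr_max <- adaptive_predict(cs$vol, model, stage1_probs = probs,
                             cfg = inference_config(overlap = "max"))
  expect_equal(pr_max$n_boxes, 2)
  expect_true(all(pr_max$prob$data >= pr_last$prob$data - 1e-12))
})
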