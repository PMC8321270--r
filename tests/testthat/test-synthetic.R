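# Lesion-phantom generator: distributions, geometry, determinism.

test_that("lesion count follows the configured Poisson regime", {
  cfg0 <- phantom_config(lesion_count_mean = 0)
  expect_equal(nrow(sample_lesions(cfg0, seed = 1)), 0)  # Poisson(0)

  cfg <- tiny_phantom_config()
  n <- vapply(1:30, function(i) nrow(sample_lesions(cfg, seed = i)),
              numeric(1))
  expect_true(all(n >= 1 & n <= 3))   # truncation bounds respected
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- tiny_phantom_config()
  expect_identical(sample_lesions(cfg, seed = 42),
                   sample_lesions(cfg, seed = 42))
})

test_that("sampled diameters have the configured lognormal median", {
  # ~1e4 diameters; lognormal median is exp(meanlog)
  cfg <- phantom_config(shape = c(160, 160, 160), lesion_count_mean = 30,
                        lesion_count_min = 30, lesion_count_max = 30,
                        diameter_log_mean = log(8), diameter_log_sd = 0.25)
  set.seed(99)
  d <- unlist(lapply(1:334, function(i) sample_lesions(cfg)$diameter_mm))
  expect_gt(length(d), 9000)
  expect_lt(abs(median(d) - 8) / 8, 0.05)
})

test_that("presets centre diameters at the clinical small-lesion thresholds", {
  lung <- phantom_preset("lung_like")
  expect_equal(exp(lung$diameter_log_mean), 10)
  expect_equal(lung$spacing, c(0.7, 0.7, 1.25))
  brain <- phantom_preset("brain_like", shape = c(64, 64, 64))
  expect_equal(exp(brain$diameter_log_mean), 5)
  expect_equal(brain$shape, c(64L, 64L, 64L))   # overrides pass through
})

test_that("rendered mask equals the brute-force sphere voxelisation", {
  cfg <- phantom_config(shape = c(32, 32, 32), spacing = c(1, 1, 1),
                        edge_sigma = 0.5)
  lesions <- data.frame(cx = 15.3, cy = 16.1, cz = 14.8, diameter_mm = 8,
                        contrast = 0.5)
  ph <- render_phantom(cfg, lesions, seed = 1)
  # exhaustive distance check over every voxel centre
  idx <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
  dist <- sqrt((idx[, 1] - 15.3)^2 + (idx[, 2] - 16.1)^2 +
                 (idx[, 3] - 14.8)^2)
  expect_equal(sum(ph$mask$data), sum(dist <= 4))
  expect_identical(which(ph$mask$data == 1),
                   which(array(dist <= 4, c(32, 32, 32))))
})

test_that("anisotropic spacing measures lesion radii in millimetres", {
  cfg <- phantom_config(shape = c(32, 32, 32), spacing = c(0.7, 0.7, 1.25))
  lesions <- data.frame(cx = 16, cy = 16, cz = 16, diameter_mm = 8,
                        contrast = 0.5)
  ph <- render_phantom(cfg, lesions, seed = 1)
  idx <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
  dist <- sqrt((0.7 * (idx[, 1] - 16))^2 + (0.7 * (idx[, 2] - 16))^2 +
                 (1.25 * (idx[, 3] - 16))^2)
  expect_equal(sum(ph$mask$data), sum(dist <= 4))
})

test_that("each lesion renders as exactly one connected component", {
  cfg <- tiny_phantom_config()
  for (s in 1:5) {
    set.seed(s)
    les <- sample_lesions(cfg)
    ph <- render_phantom(cfg, les)
    cs <- connected_components(ph$mask$data > 0, 26L)
    expect_equal(cs$n_components, nrow(les))
  }
})

test_that("volumes stay in [0,1] and lesions are brighter than background", {
  cfg <- tiny_phantom_config()
  set.seed(7)
  les <- sample_lesions(cfg)
  ph <- render_phantom(cfg, les)
  expect_true(all(ph$volume$data >= 0 & ph$volume$data <= 1))
  fg <- ph$mask$data == 1
  expect_gt(mean(ph$volume$data[fg]), mean(ph$volume$data[!fg]) + 0.2)
})

test_that("dataset generation writes a coherent, reproducible manifest", {
  cfg <- tiny_phantom_config(shape = c(32, 32, 32))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(cfg, 3, d1)
  expect_equal(nrow(m1), 3)
  expect_equal(length(list.files(d1, pattern = "\\.nii\\.gz$")), 6)
  man <- read_manifest(file.path(d1, "manifest.csv"))
  for (i in 1:3) {
    les_i <- as.numeric(strsplit(man$diameters_mm[i], ";")[[1]])
    expect_equal(length(les_i), man$n_lesions[i])
    set.seed(cfg$seed + i)
    expect_equal(les_i, sample_lesions(cfg)$diameter_mm, tolerance = 1e-4)
  }
  generate_dataset(cfg, 3, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("default-config foreground fraction sits in the sparse regime", {
  # the method's operating regime: foreground fraction around 1e-2..1e-3
  cfg <- phantom_config()   # 96^3, ~2 lesions of ~8 mm
  fracs <- vapply(1:12, function(s) {
    set.seed(1000 + s)
    les <- sample_lesions(cfg)
    ph <- render_phantom(cfg, les)
    mean(ph$mask$data)
  }, numeric(1))
  expect_gt(mean(fracs), 1e-4)
  expect_lt(mean(fracs), 1e-2)
})
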