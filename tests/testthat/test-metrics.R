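# Object-wise Dice and FROC analysis.

# small helper: component sets from explicit voxel assignments
cs_from <- function(arr, connectivity = 26L) {
  connected_components(arr > 0, connectivity)
}

test_that("component scores follow the max / mean rules", {
  p <- array(0.9, c(4, 4, 4))
  cs <- cs_from(array(1, c(4, 4, 4)))
  expect_equal(component_score(p, cs, 1), 0.9)
  p2 <- array(0, c(2, 2, 2)); p2[1, 1, 1] <- 0.2; p2[2, 1, 1] <- 0.7
  vox <- c(1L, 2L)
  expect_equal(component_score(p2, vox), 0.7)
  expect_equal(component_score(p2, vox, rule = "mean"), 0.45)
  expect_error(component_score(p2, integer(0)), "empty")
})

test_that("object matching uses voxel overlap, allowing many-to-many hits", {
  m <- array(0, c(6, 6, 6)); m[2:3, 2:3, 2:3] <- 1; m[5, 5, 5] <- 1
  gt <- cs_from(m)
  mm <- match_objects(gt, gt)
  expect_true(all(mm$gt_hit))
  expect_false(any(mm$pred_fp))

  empty <- cs_from(array(0, c(6, 6, 6)))
  mm0 <- match_objects(empty, gt)
  expect_false(any(mm0$gt_hit))
  expect_equal(sum(mm0$pred_fp), 0)

  # one prediction straddling two ground-truth objects: both hit, no FP
  g <- array(0, c(8, 8, 8)); g[2, 2, 2] <- 1; g[6, 2, 2] <- 1
  p <- array(0, c(8, 8, 8)); p[2:6, 2, 2] <- 1
  mm2 <- match_objects(cs_from(p), cs_from(g))
  expect_equal(cs_from(g)$n_components, 2)
  expect_equal(cs_from(p)$n_components, 1)
  expect_true(all(mm2$gt_hit))
  expect_false(any(mm2$pred_fp))
  expect_equal(nrow(mm2$pairs), 2)

  # a minimum-overlap fraction can demote marginal hits
  mm3 <- match_objects(cs_from(p), cs_from(g), min_overlap_frac = 2)
  expect_false(any(mm3$gt_hit))
})

test_that("object Dice follows the per-object formula", {
  g <- array(0, c(12, 12, 12)); g[2:11, 2, 2] <- 1   # one 10-voxel object
  gt <- cs_from(g)
  expect_equal(object_dice(g, gt)$mean, 1)
  expect_equal(object_dice(array(0, dim(g)), gt)$mean, 0)
  p <- array(0, dim(g)); p[2:7, 2, 2] <- 1           # 6 of 10 covered
  expect_equal(object_dice(p, gt)$mean, 0.75)        # 2*6 / (6 + 10)
  # invariant to ground-truth label order
  g2 <- array(0, c(12, 12, 12)); g2[2:11, 2, 2] <- 1; g2[2:11, 10, 10] <- 1
  p2 <- array(0, dim(g2)); p2[2:7, 2, 2] <- 1; p2[2:11, 10, 10] <- 1
  gt2 <- cs_from(g2)
  rev_lab <- gt2
  rev_lab$labels[gt2$labels > 0] <- 3L - gt2$labels[gt2$labels > 0]
  rev_lab$sizes <- rev(gt2$sizes)
  expect_equal(object_dice(p2, gt2)$mean, object_dice(p2, rev_lab)$mean)
  expect_warning(od <- object_dice(p, cs_from(array(0, dim(g)))), "undefined")
  expect_true(is.na(od$mean))
})

test_that("distant false positives do not depress object Dice", {
  g <- array(0, c(40, 12, 12)); g[2:5, 2:5, 2:5] <- 1
  p <- g
  p[35:39, 2:5, 2:5] <- 1   # FP far outside the dilated context box
  expect_equal(object_dice(p, cs_from(g), context_margin = 8L)$mean, 1)
})

test_that("the FROC sweep reproduces the hand-computed example", {
  # 2 images, 3 GT objects; detections: hit(0.9), FP(0.8), hit(0.7)
  det <- data.frame(case_id = c("a", "a", "b"), det_id = c(1L, 2L, 1L),
                    score = c(0.9, 0.8, 0.7))
  mat <- data.frame(case_id = c("a", "b"), det_id = c(1L, 1L),
                    gt_id = c(1L, 1L))
  cv <- froc_curve(det, mat, n_images = 2, n_gt = 3)
  expect_equal(cv$points$avg_fp_per_image, c(0, 0.5, 0.5))
  expect_equal(cv$points$recall, c(1/3, 1/3, 2/3))
  # recall is non-decreasing along the sweep
  expect_true(all(diff(cv$points$recall) >= -1e-12))
})

test_that("average recall integrates the step function over the FP grid", {
  perfect <- froc_curve(data.frame(case_id = "a", det_id = 1L, score = 1),
                        data.frame(case_id = "a", det_id = 1L, gt_id = 1L),
                        n_images = 1, n_gt = 1)
  expect_equal(average_recall(perfect), 1)
  expect_equal(luna_average_recall(perfect), 1)

  none <- froc_curve(data.frame(case_id = character(0), det_id = integer(0),
                                score = numeric(0)),
                     data.frame(case_id = character(0), det_id = integer(0),
                                gt_id = integer(0)),
                     n_images = 1, n_gt = 2)
  expect_equal(average_recall(none), 0)
  expect_equal(nrow(none$points), 1)

  # curve {(0, 0.25), (1, 0.75)} on the 0..5/0.01 grid: the 100 grid points
  # below 1.0 take 0.25, the 401 points from 1.0 on take 0.75
  det <- data.frame(case_id = "a", det_id = 1:4,
                    score = c(0.9, 0.5, 0.5, 0.5))
  mat <- data.frame(case_id = "a", det_id = c(1L, 3L, 4L), gt_id = 1:3)
  cv <- froc_curve(det, mat, n_images = 1, n_gt = 4)
  expect_equal(cv$points$avg_fp_per_image, c(0, 1))
  expect_equal(cv$points$recall, c(0.25, 0.75))
  expect_equal(average_recall(cv), (100 * 0.25 + 401 * 0.75) / 501)

  # curve {(0, 0.5), (2, 1.0)} at the 7 classic FP rates
  det2 <- data.frame(case_id = "a", det_id = 1:4,
                     score = c(0.9, 0.4, 0.4, 0.4))
  mat2 <- data.frame(case_id = "a", det_id = c(1L, 2L), gt_id = 1:2)
  cv2 <- froc_curve(det2, mat2, n_images = 1, n_gt = 2)
  expect_equal(cv2$points$avg_fp_per_image, c(0, 2))
  expect_equal(cv2$points$recall, c(0.5, 1))
  expect_equal(luna_average_recall(cv2), (4 * 0.5 + 3 * 1) / 7)
})

test_that("the sweep matches a brute-force re-evaluation on random cases", {
  set.seed(61)
  for (rep in 1:15) {
    n_img <- sample(1:3, 1)
    n_gt_per <- sample(0:3, n_img, replace = TRUE)
    if (sum(n_gt_per) == 0) n_gt_per[1] <- 1
    det <- data.frame(case_id = character(0), det_id = integer(0),
                      score = numeric(0))
    mat <- data.frame(case_id = character(0), det_id = integer(0),
                      gt_id = integer(0))
    for (i in seq_len(n_img)) {
      nd <- sample(0:4, 1)
      if (nd == 0) next
      det <- rbind(det, data.frame(case_id = paste0("c", i), det_id = 1:nd,
                                   score = round(runif(nd), 2)))
      for (d in 1:nd) {
        if (n_gt_per[i] > 0 && runif(1) < 0.5) {
          hits <- sample(seq_len(n_gt_per[i]), sample(1:n_gt_per[i], 1))
          mat <- rbind(mat, data.frame(case_id = paste0("c", i), det_id = d,
                                       gt_id = hits))
        }
      }
    }
    cv <- froc_curve(det, mat, n_images = n_img, n_gt = sum(n_gt_per))
    # oracle: re-evaluate hits and FPs independently at each threshold
    for (th in unique(det$score)) {
      act <- det[det$score >= th, ]
      fp <- 0; hit_keys <- character(0)
      for (r in seq_len(nrow(act))) {
        mk <- mat[mat$case_id == act$case_id[r] & mat$det_id == act$det_id[r], ]
        if (nrow(mk) == 0) fp <- fp + 1
        else hit_keys <- union(hit_keys,
                               paste(mk$case_id, mk$gt_id))
      }
      i <- which(abs(cv$points$threshold - th) < 1e-12)
      expect_equal(cv$points$avg_fp_per_image[i], fp / n_img)
      expect_equal(cv$points$recall[i], length(hit_keys) / sum(n_gt_per))
    }
    expect_true(all(cv$points$recall >= 0 & cv$points$recall <= 1))
    ar <- average_recall(cv)
    expect_true(ar >= 0 && ar <= 1)
  }
})

test_that("end-to-end evaluation scores a perfect prediction as perfect", {
  set.seed(62)
  gts <- lapply(1:2, function(i) {
    g <- array(0, c(24, 24, 24))
    g[(2:5) + 6 * i, 3:6, 3:6] <- 1
    g[15:18, 15:18, 15:18] <- 1
    g
  })
  preds <- lapply(gts, function(g)
    list(prob = g * 0.99, binary = g,
         components = NULL, component_set = NULL))
  ev <- evaluate_cases(preds, gts)
  expect_equal(ev$metrics$avg_recall_0to5, 1)
  expect_equal(ev$metrics$luna_avg_recall, 1)
  expect_equal(ev$metrics$mean_object_dice, 1)
  expect_equal(ev$metrics$n_gt, 4)
  expect_equal(ev$metrics$n_fp_at_no_threshold, 0)

  empty <- lapply(gts, function(g)
    list(prob = g * 0, binary = g * 0,
         components = NULL, component_set = NULL))
  ev0 <- evaluate_cases(empty, gts)
  expect_equal(ev0$metrics$avg_recall_0to5, 0)
  expect_equal(ev0$metrics$mean_object_dice, 0)
})
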