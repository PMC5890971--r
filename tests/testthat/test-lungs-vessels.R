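# Lung field segmentation and vessel objects with lobar assignment.

test_that("lung segmentation recovers the phantom lungs", {
  run <- phantom_run(1, "insp")
  lungs <- run$result$lungs
  t <- run$phantom$truth
  expect_gte(dice(lungs$left | lungs$right,
                  t$lung_mask_left | t$lung_mask_right), 0.98)
  expect_gte(dice(lungs$left, t$lung_mask_left), 0.97)
  expect_gte(dice(lungs$right, t$lung_mask_right), 0.97)
  expect_false(any(lungs$left & lungs$right))
  # airway lumen excluded
  expect_false(any((lungs$left | lungs$right) & run$result$airway_mask))
})

test_that("low-contrast expiratory lungs still segment acceptably", {
  run <- phantom_run(1, "exp", degrade = 0.5)
  lungs <- run$result$lungs
  t <- run$phantom$truth
  expect_gte(dice(lungs$left | lungs$right,
                  t$lung_mask_left | t$lung_mask_right), 0.90)
})

test_that("a featureless volume is a segmentation failure", {
  ct <- ct_volume(array(40L, c(24, 24, 24)), c(1.5, 1, 1))
  aw <- array(FALSE, c(24, 24, 24))
  expect_error(segment_lungs(ct, aw), class = "pulmolobe_segmentation_failure")
  cte <- ct_volume(array(40L, c(24, 24, 24)), c(1.5, 1, 1), phase = "exp")
  expect_error(segment_lungs(cte, aw),
               class = "pulmolobe_segmentation_failure")
})

test_that("joined lungs are split by erosion into two plausible halves", {
  # two spheres bridged by a thin neck
  d <- c(24, 24, 48)
  Z <- slice.index(array(0L, d), 1); Y <- slice.index(array(0L, d), 2)
  X <- slice.index(array(0L, d), 3)
  m <- ((Z - 12)^2 + (Y - 12)^2 + (X - 12)^2 <= 81) |
       ((Z - 12)^2 + (Y - 12)^2 + (X - 36)^2 <= 81) |
       (abs(Z - 12) <= 1 & abs(Y - 12) <= 1 & X > 12 & X < 36)
  halves <- pulmolobe:::split_joined_lungs(m, c(1, 1, 1))
  expect_identical(sum(halves[[1]]) + sum(halves[[2]]), sum(m))
  expect_gt(sum(halves[[1]]), 0.3 * sum(m))
  expect_gt(sum(halves[[2]]), 0.3 * sum(m))
})

test_that("vessel threshold adapts per CT and captures the phantom vessels", {
  run <- phantom_run(1, "insp")
  vx <- run$result$vessels
  truth_vessels <- run$phantom$truth$vessel_mask
  # the adjusted threshold must sit above parenchyma
  expect_gt(vx$threshold_hu, -500 - 1e-9)
  # segmented vessel voxels lie almost entirely on designed vessels
  seg <- vx$labels > 0L
  expect_gte(sum(seg & truth_vessels) / sum(seg), 0.9)
})

test_that("vessel segmentation degenerates gracefully and is shift-invariant", {
  d <- c(16, 16, 16)
  lung <- array(TRUE, d)
  attr(lung, "spacing") <- c(1, 1, 1)
  ct0 <- ct_volume(array(-300L, d), c(1, 1, 1))
  v0 <- segment_vessels(ct0, lung)
  expect_identical(nrow(v0$table), 0L)       # constant: nothing above

  set.seed(31)
  base <- array(as.integer(round(rnorm(prod(d), -300, 50))), d)
  base[8:9, 8:9, 3:14] <- 150L               # one bright tube
  ct1 <- ct_volume(base, c(1, 1, 1))
  ct2 <- ct_volume(base + 200L, c(1, 1, 1))
  v1 <- segment_vessels(ct1, lung)
  v2 <- segment_vessels(ct2, lung)
  expect_identical(v1$labels, v2$labels)
  empty <- array(FALSE, d)
  expect_error(segment_vessels(ct1, empty), class = "pulmolobe_empty_input")
})

test_that("vessel objects inside one hull are assigned in round one", {
  run <- phantom_run(1, "insp")
  res <- run$result
  tab <- res$vessels$table
  expect_true(all(tab$code %in% 0:6))
  # per-voxel codes agree with the truth lobes for the vast majority
  va <- res$vessels$voxel_codes
  tm <- run$phantom$truth$lobe_map$labels
  agree <- va > 0L & tm > 0L
  expect_gte(mean(va[agree] == tm[agree]), 0.9)
})

test_that("a dumbbell component splits and its ends go to different lobes", {
  d <- c(16, 16, 40)
  sp <- c(1, 1, 1)
  # two 'hulls' (anchor blocks) at the ends
  hulls <- replicate(6, array(FALSE, d), simplify = FALSE)
  hulls[[1]][6:11, 6:11, 3:6] <- TRUE
  hulls[[2]][6:11, 6:11, 35:38] <- TRUE
  graph <- structure(list(edges = data.frame(code = integer(0)),
                          chains = list(), spacing = sp),
                     class = "airway_graph")
  # dumbbell vessel object: blobs at both ends joined by a 1-voxel wire
  labels <- array(0L, d)
  labels[7:10, 7:10, 8:11] <- 1L
  labels[7:10, 7:10, 30:33] <- 1L
  labels[8, 8, 12:29] <- 1L
  vx <- structure(list(labels = labels,
                       table = data.frame(component = 1L,
                                          voxels = sum(labels > 0),
                                          cz = 0, cy = 0, cx = 0, code = 0L),
                       spacing = sp, threshold_hu = 0), class = "vessel_objects")
  out <- assign_vessels_to_lobes(vx, graph, hulls)
  vc <- out$voxel_codes
  expect_true(all(vc[7:10, 7:10, 8:11] %in% c(0L, 1L)))
  expect_true(any(vc[7:10, 7:10, 8:11] == 1L))
  expect_true(any(vc[7:10, 7:10, 30:33] == 2L))
  expect_false(any(vc == 2L & labels == 1L &
                     slice.index(labels, 3) < 20))
})

test_that("an equidistant component that erodes away stays unassigned", {
  d <- c(10, 10, 21)
  sp <- c(1, 1, 1)
  hulls <- replicate(6, array(FALSE, d), simplify = FALSE)
  hulls[[1]][4:6, 4:6, 1:2] <- TRUE
  hulls[[2]][4:6, 4:6, 20:21] <- TRUE
  graph <- structure(list(edges = data.frame(code = integer(0)),
                          chains = list(), spacing = sp),
                     class = "airway_graph")
  labels <- array(0L, d)
  labels[5, 5, 10:12] <- 1L      # thin, exactly in the middle
  vx <- structure(list(labels = labels,
                       table = data.frame(component = 1L, voxels = 3L,
                                          cz = 0, cy = 0, cx = 0, code = 0L),
                       spacing = sp, threshold_hu = 0), class = "vessel_objects")
  out <- assign_vessels_to_lobes(vx, graph, hulls)
  expect_identical(out$table$code, 0L)
  expect_true(all(out$voxel_codes == 0L))
})
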