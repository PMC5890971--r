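# Bronchial hulls, fissure enhancement, initial masks, watershed, and the
# five-lobe merge.

test_that("hulls handle degenerate and full-rank centerline sets", {
  dims <- c(32L, 32L, 32L)
  mk_graph <- function(chains_codes) {
    edges <- data.frame(code = vapply(chains_codes, `[[`, integer(1), "code"))
    edges$label <- ifelse(edges$code > 0, "lobar", "unlabeled")
    structure(list(edges = edges,
                   chains = lapply(chains_codes, `[[`, "chain"),
                   spacing = c(1, 1, 1)), class = "airway_graph")
  }
  # collinear chain -> 1-voxel-wide segment
  seg <- cbind(5, 5:15, 5)
  g <- mk_graph(list(list(code = 1L, chain = seg)))
  h <- lobar_hulls(g, dims)
  expect_identical(sum(h[[1]]), nrow(unique(seg)))
  expect_identical(sum(h[[2]]), 0L)   # absent code -> empty mask

  # L-shaped chain: voxelized hull must match the barycentric oracle
  Lchain <- rbind(cbind(4, 4:14, 4), cbind(4:14, 14, 4), cbind(4, 4, 4:14))
  g2 <- mk_graph(list(list(code = 3L, chain = Lchain)))
  h2 <- lobar_hulls(g2, dims)
  pts <- unique(Lchain)
  in_hull_oracle <- function(q, S) {
    cmb <- utils::combn(nrow(S), 4)
    for (i in seq_len(ncol(cmb))) {
      A <- t(S[cmb[, i], ])
      M <- cbind(A[, 2] - A[, 1], A[, 3] - A[, 1], A[, 4] - A[, 1])
      if (abs(det(M)) < 1e-9) next
      lam <- solve(M, q - A[, 1])
      if (all(lam >= -1e-9) && sum(lam) <= 1 + 1e-9) return(TRUE)
    }
    FALSE
  }
  # subsample the oracle grid to keep the O(n^4) check affordable
  set.seed(51)
  probe <- cbind(sample(0:20, 150, TRUE), sample(0:20, 150, TRUE),
                 sample(0:20, 150, TRUE))
  sub <- pts[round(seq(1, nrow(pts), length.out = 12)), ]
  g3 <- mk_graph(list(list(code = 3L, chain = sub)))
  h3 <- lobar_hulls(g3, dims)
  for (i in seq_len(nrow(probe))) {
    q <- probe[i, ]
    expect_identical(unname(h3[[3]][q[1] + 1, q[2] + 1, q[3] + 1]),
                     in_hull_oracle(q, sub))
  }

  g0 <- mk_graph(list(list(code = 0L, chain = seg)))
  expect_error(lobar_hulls(g0, dims), class = "pulmolobe_labeling_required")
})

test_that("the plate filter lights up bright planes, not blobs", {
  d <- c(32, 32, 32)
  lung <- array(TRUE, d)
  base <- array(-800L, d)
  plane <- base; plane[16, , ] <- -650L
  ctp <- ct_volume(plane, c(1, 1, 1))
  sc <- enhance_fissures(ctp, lung, scales_mm = c(1, 2),
                         boundary_voxels = 0L)
  on <- sc[16, 5:28, 5:28]
  off <- sc[c(8, 24), 5:28, 5:28]
  expect_gte(mean(on), 5 * mean(off))

  # blob of radius 5: weaker plate response than the plane
  Z <- slice.index(base, 1); Y <- slice.index(base, 2); X <- slice.index(base, 3)
  blob <- base
  blob[(Z - 16)^2 + (Y - 16)^2 + (X - 16)^2 <= 25] <- -650L
  ctb <- ct_volume(blob, c(1, 1, 1))
  scb <- enhance_fissures(ctb, lung, scales_mm = c(1, 2),
                          boundary_voxels = 0L)
  expect_lt(mean(scb[(Z - 16)^2 + (Y - 16)^2 + (X - 16)^2 <= 25]), mean(on))

  # uniform volume: zero dynamic range handled, all scores 0
  ctu <- ct_volume(base, c(1, 1, 1))
  expect_true(all(enhance_fissures(ctu, lung, c(1, 2)) == 0))
  expect_error(enhance_fissures(ctu, array(FALSE, d), c(1, 2)),
               class = "pulmolobe_empty_input")
  expect_error(enhance_fissures(ctu, lung, numeric(0)),
               class = "pulmolobe_validation_error")
})

test_that("fissure scores vanish outside the lung mask", {
  run <- phantom_run(1, "insp")
  lung <- run$result$lungs$left | run$result$lungs$right
  expect_true(all(run$result$fissures[!lung] == 0))
  expect_true(all(run$result$fissures >= 0 & run$result$fissures <= 1))
})

test_that("initial masks respect hull containment and the side constraint", {
  run <- phantom_run(1, "insp")
  res <- run$result
  ini <- res$initial
  # voxels inside exactly one hull carry that hull's code
  for (k in c(1L, 6L)) {
    only <- res$hulls[[k]]
    for (j in setdiff(1:6, k)) only <- only & !res$hulls[[j]]
    only <- only & (if (k <= 3) res$lungs$right else res$lungs$left)
    if (sum(only) > 0)
      expect_true(all(ini$labels[only] == k))
  }
  # side constraint: right lung only right codes, left only left codes
  expect_true(all(ini$labels[res$lungs$right] %in% 1:3))
  expect_true(all(ini$labels[res$lungs$left] %in% 4:6))
  # distance-only masks already overlap the truth decently
  dd <- per_lobe_dice(ini, run$phantom$truth$lobe_map)
  expect_true(all(dd >= 0.6, na.rm = TRUE))
})

test_that("initial masks fail loudly when a side has no structures", {
  d <- c(10, 10, 10)
  left <- array(FALSE, d); right <- array(FALSE, d)
  right[3:8, 3:8, 2:4] <- TRUE; left[3:8, 3:8, 7:9] <- TRUE
  attr(left, "spacing") <- attr(right, "spacing") <- c(1, 1, 1)
  hulls <- replicate(6, array(FALSE, d), simplify = FALSE)
  hulls[[1]][5, 5, 3] <- TRUE   # right side has an anchor, left has none
  graph <- structure(list(edges = data.frame(code = 1L, label = "RUL"),
                          chains = list(cbind(4, 4, 2)), spacing = c(1, 1, 1)),
                     class = "airway_graph")
  expect_error(initial_lobe_masks(left, right, graph, hulls),
               class = "pulmolobe_assignment_error")
})

test_that("a flat fissure map reduces the watershed to nearest markers", {
  d <- c(12, 12, 24)
  lungmask <- array(FALSE, d); lungmask[2:11, 2:11, 2:23] <- TRUE
  right <- lungmask & slice.index(lungmask, 3) <= 12
  left <- lungmask & !right
  attr(left, "spacing") <- attr(right, "spacing") <- c(1, 1, 1)
  lab <- array(0L, d)
  lab[right & slice.index(lungmask, 1) <= 6] <- 1L
  lab[right & slice.index(lungmask, 1) > 6] <- 2L
  lab[left & slice.index(lungmask, 1) <= 6] <- 4L
  lab[left & slice.index(lungmask, 1) > 6] <- 6L
  ini <- lobe_map(lab, c(1, 1, 1))
  flat <- array(0, d)
  out <- finalize_lobes(ini, flat, left, right, erosion_layers = 2)
  # with no topography the boundary must fall where marker distances tie,
  # i.e. the initial partition is reproduced exactly
  expect_identical(out$labels, ini$labels)
})

test_that("finalize output partitions the lung and preserves markers", {
  run <- phantom_run(1, "insp")
  res <- run$result
  lung <- res$lungs$left | res$lungs$right
  out <- res$lobe_map
  expect_identical(out$labels > 0L, lung)
  expect_true(all(out$labels[res$lungs$right] %in% 1:3))
  expect_true(all(out$labels[res$lungs$left] %in% 4:6))
})

test_that("a lobe eroded to extinction falls back with a warning", {
  d <- c(10, 10, 10)
  lungmask <- array(FALSE, d); lungmask[2:9, 2:9, 2:9] <- TRUE
  right <- lungmask; left <- array(FALSE, d)
  attr(left, "spacing") <- attr(right, "spacing") <- c(1, 1, 1)
  lab <- array(0L, d)
  lab[lungmask] <- 1L
  lab[5, 5, 5] <- 2L                      # single-voxel lobe
  ini <- lobe_map(lab, c(1, 1, 1))
  w <- capture_warnings(
    out <- finalize_lobes(ini, array(0, d), left, right, erosion_layers = 2))
  expect_true(any(grepl("extinction", w)))
  expect_true(any(out$labels == 2L))
})

test_that("merging the lingula conserves voxels and modes", {
  run <- phantom_run(1, "insp")
  m6 <- run$result$lobe_map
  n5 <- sum(m6$labels == 5L)
  m5 <- merge_lingula(m6)
  expect_identical(m5$mode, "five_lobe")
  expect_identical(sum(m5$labels > 0L), sum(m6$labels > 0L))
  expect_identical(sum(m5$labels == 4L), sum(m6$labels == 4L) + n5)
  expect_identical(sum(m5$labels == 5L), 0L)
  expect_warning(merge_lingula(m5), "already")

  no_lli <- lobe_map(array(ifelse(m6$labels == 5L, 4L, m6$labels),
                           dim(m6$labels)), m6$spacing)
  merged <- merge_lingula(no_lli)
  expect_identical(merged$labels, no_lli$labels)
})
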