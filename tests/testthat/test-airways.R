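# Airway stages: region growing with leak guard, topology-preserving
# thinning, graph construction, and lobar labeling.

test_that("region growing recovers the phantom airway tree without leaking", {
  ph <- default_phantom(1)
  mask <- segment_airway_tree(ph$insp)
  cc <- pulmolobe:::label_components(mask, 26L)
  expect_identical(cc$n, 1L)

  # coverage: nearly all truth centerline voxels inside the mask
  d <- dim(mask)
  tree_vox <- do.call(rbind, lapply(ph$truth$centerline_tree, `[[`, "voxels"))
  idx <- pulmolobe:::voxel_index(tree_vox, d)
  expect_gte(mean(mask[idx]), 0.95)

  # specificity: few mask voxels outside the dilated truth tree
  truth_tube <- array(FALSE, d)
  truth_tube[idx] <- TRUE
  # dilate by the largest designed radius (4 mm) plus 2 voxels guard
  truth_tube <- array(pulmolobe:::.bin_dilate(truth_tube, 26L, 6L), d)
  expect_lte(sum(mask & !truth_tube) / sum(mask), 0.02)
})

test_that("region growing refuses a volume without a tracheal air column", {
  ct <- ct_volume(array(40L, c(24, 24, 24)), c(1.5, 1, 1))
  expect_error(segment_airway_tree(ct), class = "pulmolobe_seed_error")
})

test_that("the explosion guard caps growth through a drilled wall hole", {
  ph <- default_phantom(2)
  base <- segment_airway_tree(ph$insp)

  holed <- ph$insp
  # drill a 1-voxel channel from the bronchus intermedius lumen straight
  # into the surrounding parenchyma
  nm <- vapply(ph$truth$centerline_tree, `[[`, character(1), "name")
  bi <- ph$truth$centerline_tree[[which(nm == "bronchus_intermedius")]]$voxels
  mid <- bi[nrow(bi) %/% 2, ]
  vox <- holed$voxels
  z <- mid[1] + 1
  for (dx in 0:8) vox[z, mid[2] + 1, mid[3] + 1 - dx] <- -1000L
  holed <- ct_volume(vox, holed$spacing, holed$origin, holed$phase,
                     holed$kernel)
  grown <- segment_airway_tree(holed)
  expect_lt(sum(grown), 1.5 * sum(base))
})

test_that("skeletonization thins a cylinder to its axis and is idempotent", {
  d <- c(13, 40, 13)
  cyl <- cylinder_mask(d, radius = 5, axis_z = 7, axis_x = 7, y_range = c(4, 37))
  sk <- skeletonize(cyl)
  expect_true(all(sk[cyl == FALSE] == FALSE))     # subset of the input
  co <- pulmolobe:::which_voxels(sk)
  expect_true(all(co[, 1] == 6))                   # on the axis (0-based)
  expect_true(all(co[, 3] == 6))
  # endpoint retraction stays within the tube radius
  expect_lte(min(co[, 2]) - 3, 5)
  expect_gte(max(co[, 2]) + 5, 36)
  # one voxel thick: no voxel has a full 3x3x3 neighborhood inside
  nc <- pulmolobe:::.neighbor_count26(sk)
  expect_lte(max(nc[sk]), 2)
  expect_identical(skeletonize(sk), sk)            # idempotence

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_identical(skeletonize(single), single)
  expect_error(skeletonize(array(FALSE, c(4, 4, 4))),
               class = "pulmolobe_empty_input")
})

test_that("skeletonization preserves the component count", {
  set.seed(21)
  d <- c(20, 20, 20)
  m <- array(FALSE, d)
  m[3:8, 3:8, 3:8] <- TRUE
  m[12:18, 12:18, 4:9] <- TRUE
  m[14:17, 2:6, 12:18] <- TRUE
  sk <- skeletonize(m)
  n0 <- pulmolobe:::label_components(m, 26L)$n
  n1 <- pulmolobe:::label_components(sk, 26L)$n
  expect_identical(n0, n1)
})

y_tube <- function() {
  d <- c(40, 30, 30)
  m <- array(FALSE, d)
  paint <- function(from, to, r) {
    idx <- pulmolobe:::tube_indices(from, to, r, d, c(1, 1, 1))
    m[idx] <<- TRUE
  }
  paint(c(3, 15, 15), c(20, 15, 15), 3)
  paint(c(20, 15, 15), c(35, 8, 15), 2.5)
  paint(c(20, 15, 15), c(35, 22, 15), 2.5)
  m
}

test_that("a Y-shaped tube yields 3 endpoints, 1 bifurcation, 3 edges", {
  m <- y_tube()
  sk <- skeletonize(m)
  g <- build_airway_graph(sk, m, c(1, 1, 1))
  expect_identical(nrow(g$edges), 3L)
  expect_identical(sum(g$nodes$type == "endpoint") +
                     sum(g$nodes$type == "root"), 3L)
  expect_identical(sum(g$nodes$type == "bifurcation"), 1L)
  expect_identical(sort(g$edges$generation), c(0L, 1L, 1L))
  # graph is a tree
  expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
})

test_that("short spurs are pruned and straight chains give one edge", {
  d <- c(30, 20, 20)
  m <- array(FALSE, d)
  m[cbind(5:25, 10, 10)] <- TRUE
  m[cbind(15, 11:12, 10)] <- TRUE   # 2 mm spur off the chain
  g <- build_airway_graph(m, array(pulmolobe:::.bin_dilate(m, 26L, 2L), d),
                          c(1, 1, 1))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$generation, 0L)
  expect_identical(nrow(g$nodes), 2L)
})

test_that("airway graphs from phantoms are connected and acyclic", {
  for (seed in c(1, 2)) {
    run <- phantom_run(seed, "insp")
    g <- run$result$graph
    expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
    # one root, generations increase from it
    expect_identical(sum(g$nodes$type == "root"), 1L)
    expect_identical(sort(unique(g$edges$generation))[1], 0L)
  }
})

test_that("lobar labeling places all six codes on the phantom tree", {
  run <- phantom_run(1, "insp")
  g <- run$result$graph
  expect_setequal(unique(g$edges$code[g$edges$code > 0]), 1:6)
  expect_true("trachea" %in% g$edges$label)
  expect_true(all(c("main_L", "main_R", "bronchus_intermedius") %in%
                    g$edges$label))

  # each labeled chain must follow the designed centerline of the same
  # code: for every auto centerline voxel, the nearest truth branch (among
  # the lobar branches) should carry the matching code, by majority vote
  ph <- run$phantom
  truth_sets <- lapply(1:6, function(k) {
    do.call(rbind, lapply(Filter(function(e) e$code == k,
                                 ph$truth$centerline_tree), `[[`, "voxels"))
  })
  sp <- ph$insp$spacing
  for (k in 1:6) {
    cv <- pulmolobe:::graph_code_voxels(g, k)
    nearest <- vapply(seq_len(nrow(cv)), function(i) {
      p <- cv[i, ] * sp
      dists <- vapply(1:6, function(j) {
        tj <- sweep(truth_sets[[j]], 2, sp, `*`)
        min(sqrt(rowSums(sweep(tj, 2, p)^2)))
      }, numeric(1))
      which.min(dists)
    }, integer(1))
    expect_identical(as.integer(names(which.max(table(nearest)))), k)
  }
})

test_that("mirroring the volume swaps the main bronchi", {
  run <- phantom_run(1, "insp")
  g <- run$result$graph
  mL <- g$edges[g$edges$label == "main_L", ]
  node_x <- g$nodes$x[match(mL$to, g$nodes$id)]
  expect_gt(node_x, median(g$nodes$x))   # left main heads to high x

  ph <- run$phantom
  d <- dim(ph$insp$voxels)
  flipped <- ct_volume(ph$insp$voxels[, , d[3]:1], ph$insp$spacing)
  mask <- segment_airway_tree(flipped)
  sk <- skeletonize(mask)
  gf <- label_lobar_bronchi(build_airway_graph(sk, mask, flipped$spacing))
  mLf <- gf$edges[gf$edges$label == "main_L", ]
  xLf <- gf$nodes$x[match(mLf$to, gf$nodes$id)]
  expect_gt(xLf, median(gf$nodes$x))     # still by the +x rule after the flip
})

test_that("a missing lobar branch is tolerated, not fatal", {
  run <- phantom_run(1, "insp")
  g <- run$result$graph
  # remove the RUL subtree and relabel from scratch
  drop <- g$edges$code == 1L
  g2 <- g
  g2$edges <- g$edges[!drop, ]
  g2$chains <- g$chains[!drop]
  g2$edges$label <- "unlabeled"; g2$edges$code <- 0L
  relab <- label_lobar_bronchi(g2)
  expect_setequal(unique(relab$edges$code[relab$edges$code > 0]), 2:6)
})

test_that("labeling an underdeveloped graph is a labeling error", {
  d <- c(30, 20, 20)
  m <- array(FALSE, d)
  m[cbind(5:25, 10, 10)] <- TRUE
  g <- build_airway_graph(m, array(pulmolobe:::.bin_dilate(m, 26L, 2L), d),
                          c(1, 1, 1))
  expect_error(label_lobar_bronchi(g), class = "pulmolobe_labeling_error")
})
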