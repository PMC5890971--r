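# Agreement statistics against independent brute-force oracles.

brute_dice <- function(a, m) {
  inter <- 0; na <- 0; nm <- 0
  for (i in seq_along(a)) {
    if (a[i] && m[i]) inter <- inter + 1
    if (a[i]) na <- na + 1
    if (m[i]) nm <- nm + 1
  }
  2 * inter / (na + nm)
}

brute_jaccard <- function(a, m) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] && m[i]) inter <- inter + 1
    if (a[i] || m[i]) uni <- uni + 1
  }
  inter / uni
}

test_that("dice and jaccard match hand counts and brute force", {
  # constructed 4x4x1 fixture: |A| = 8, |M| = 6, |A n M| = 4
  a <- array(FALSE, c(4, 4, 1)); m <- array(FALSE, c(4, 4, 1))
  a[1:8] <- TRUE
  m[5:10] <- TRUE
  expect_identical(sum(a), 8L); expect_identical(sum(m), 6L)
  expect_identical(sum(a & m), 4L)
  expect_equal(dice(a, m), 8 / 14)
  expect_equal(jaccard(a, m), 4 / 10)

  full <- array(TRUE, c(3, 3, 3))
  expect_equal(dice(full, full), 1.0)
  expect_equal(jaccard(full, full), 1.0)
  disj <- array(FALSE, c(3, 3, 3)); disj[1] <- TRUE
  disj2 <- array(FALSE, c(3, 3, 3)); disj2[2] <- TRUE
  expect_equal(dice(disj, disj2), 0.0)

  set.seed(41)
  for (i in 1:60) {
    a <- random_mask(c(5, 4, 3), runif(1, 0.1, 0.9))
    m <- random_mask(c(5, 4, 3), runif(1, 0.1, 0.9))
    if (!any(a) && !any(m)) next
    expect_identical(dice(a, m), brute_dice(a, m))
    if (any(a | m)) expect_identical(jaccard(a, m), brute_jaccard(a, m))
  }
})

test_that("overlap indices are symmetric and error on empty input", {
  set.seed(42)
  a <- random_mask(c(4, 4, 4)); m <- random_mask(c(4, 4, 4))
  expect_identical(dice(a, m), dice(m, a))
  expect_identical(jaccard(a, m), jaccard(m, a))
  e <- array(FALSE, c(4, 4, 4))
  expect_error(dice(e, e), class = "pulmolobe_metric_error")
  expect_error(jaccard(e, e), class = "pulmolobe_metric_error")
})

test_that("jaccard satisfies J = D / (2 - D) to 1e-12", {
  set.seed(43)
  for (i in 1:100) {
    a <- random_mask(c(6, 5, 4), runif(1, 0.05, 0.95))
    m <- random_mask(c(6, 5, 4), runif(1, 0.05, 0.95))
    if (!any(a | m)) next
    d <- dice(a, m)
    expect_equal(jaccard(a, m), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("multi-region dice pools per-lobe overlap by voxel-count weights", {
  # two-lobe toy: lobe 1 perfect (10, 10), lobe 2 dice 0.5 (8, 8, overlap 4)
  au <- array(0L, c(4, 4, 4)); rf <- array(0L, c(4, 4, 4))
  au[1:10] <- 1L; rf[1:10] <- 1L
  au[21:28] <- 2L; rf[25:32] <- 2L
  am <- lobe_map(au, c(1, 1, 1)); rm <- lobe_map(rf, c(1, 1, 1))
  expect_equal(multi_region_dice(am, rm), (20 + 8) / (20 + 16))
  expect_equal(multi_region_dice(am, am), 1.0)

  set.seed(44)
  for (i in 1:100) {
    a <- random_lobe_map(); r <- random_lobe_map()
    codes <- sort(unique(c(a$labels[a$labels > 0], r$labels[r$labels > 0])))
    w <- num <- 0
    for (k in codes) {
      ak <- a$labels == k; rk <- r$labels == k
      wk <- sum(ak) + sum(rk)
      if (wk == 0) next
      num <- num + wk * brute_dice(ak, rk)
      w <- w + wk
    }
    expect_equal(multi_region_dice(a, r), num / w, tolerance = 1e-12)
  }
})

test_that("multi-region dice rejects mode mismatch", {
  a <- lobe_map(array(1L, c(2, 2, 2)), c(1, 1, 1), mode = "six_lobe")
  b <- lobe_map(array(1L, c(2, 2, 2)), c(1, 1, 1), mode = "five_lobe")
  expect_error(multi_region_dice(a, b), class = "pulmolobe_mode_error")
})

brute_assd <- function(a, m, spacing) {
  surf <- function(msk) {
    d <- dim(msk)
    out <- array(FALSE, d)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (!msk[z, y, x]) next
      nb <- c(
        z == 1 || !msk[z - 1, y, x], z == d[1] || !msk[z + 1, y, x],
        y == 1 || !msk[z, y - 1, x], y == d[2] || !msk[z, y + 1, x],
        x == 1 || !msk[z, y, x - 1], x == d[3] || !msk[z, y, x + 1])
      out[z, y, x] <- any(nb)
    }
    out
  }
  pa <- which(surf(a), arr.ind = TRUE)
  pm <- which(surf(m), arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, `*`); pm <- sweep(pm, 2, spacing, `*`)
  d1 <- apply(pa, 1, function(p) min(sqrt(colSums((t(pm) - p)^2))))
  d2 <- apply(pm, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  (sum(d1) + sum(d2)) / (length(d1) + length(d2))
}

test_that("average surface distance matches the all-pairs oracle", {
  a <- array(FALSE, c(9, 3, 3)); a[2, 2, 2] <- TRUE
  m <- array(FALSE, c(9, 3, 3)); m[5, 2, 2] <- TRUE
  expect_equal(avg_surface_distance(a, m, c(1, 1, 1)), 3.0)
  expect_equal(avg_surface_distance(a, a, c(1, 1, 1)), 0.0)
  expect_error(avg_surface_distance(a, array(FALSE, c(9, 3, 3)), c(1, 1, 1)),
               class = "pulmolobe_metric_error")

  set.seed(45)
  for (i in 1:30) {
    sp <- c(1.5, 1, runif(1, 0.5, 2))
    a <- random_mask(c(12, 12, 12), 0.2)
    m <- random_mask(c(12, 12, 12), 0.2)
    if (!any(a) || !any(m)) next
    expect_equal(avg_surface_distance(a, m, sp), brute_assd(a, m, sp),
                 tolerance = 1e-9)
    expect_equal(avg_surface_distance(a, m, sp),
                 avg_surface_distance(m, a, sp), tolerance = 1e-12)
  }
})

test_that("Bland-Altman agrees with direct arithmetic and translates exactly", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(z$mean_delta, z$loa_low, z$loa_high), c(0, 0, 0))

  auto <- c(1, 4, 0, 7); ref <- c(3, 4, 3, 5)  # d = (-2, 0, -3, 2)
  d <- auto - ref
  b <- bland_altman(auto, ref)
  expect_equal(b$mean_delta, mean(d), tolerance = 1e-12)
  expect_equal(b$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(b$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(b$mean_delta, -0.75)
  expect_equal(b$sd_delta, 2.217356, tolerance = 1e-6)

  set.seed(46)
  for (i in 1:50) {
    x <- rnorm(8); y <- rnorm(8); cc <- rnorm(1)
    b0 <- bland_altman(x, y)
    b1 <- bland_altman(x + cc, y)
    expect_equal(b1$mean_delta, b0$mean_delta + cc, tolerance = 1e-12)
    expect_equal(b1$loa_low, b0$loa_low + cc, tolerance = 1e-12)
    expect_equal(b1$loa_high, b0$loa_high + cc, tolerance = 1e-12)
  }
  expect_error(bland_altman(1, 1), class = "pulmolobe_insufficient_data")
})

test_that("pearson matches the covariance formula and flags bad input", {
  x <- c(1, 2, 5, 7)
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  set.seed(47)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson(x, y), direct, tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "pulmolobe_metric_error")
  expect_error(pearson(1:2, 1:2), class = "pulmolobe_metric_error")
})

test_that("validation report covers present lobes and detects erosion bias", {
  ph <- default_phantom(1)
  tm <- ph$truth$lobe_map
  rep0 <- validation_report(tm, tm)
  expect_s3_class(rep0, "agreement_report")
  expect_true(all(rep0$per_lobe$dice == 1))
  expect_true(all(rep0$per_lobe$volume_delta_cm3 == 0))
  expect_equal(rep0$pooled_dice, 1.0)
  expect_equal(nrow(rep0$per_lobe),
               length(setdiff(unique(as.vector(tm$labels)), 0L)))

  # erode the truth by one voxel per lobe: volumes must shrink and the
  # surface distance stay within one voxel diagonal
  er <- array(0L, dim(tm$labels))
  for (k in 1:6) {
    m <- tm$labels == k
    er[pulmolobe:::.bin_erode(m, 6L, 1L)] <- k
  }
  erm <- lobe_map(er, tm$spacing)
  rep1 <- validation_report(erm, tm)
  expect_true(all(rep1$per_lobe$volume_delta_cm3 < 0))
  expect_true(all(rep1$per_lobe$assd_mm <= sqrt(sum(tm$spacing^2))))
})
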