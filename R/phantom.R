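# Synthetic paired inspiratory/expiratory thorax phantom with exact ground
# truth: two quasi-ellipsoidal lungs (left smaller, with a cardiac notch),
# six truth lobes delimited by oblique/horizontal planes, a branching airway
# tree with labeled lobar bronchi, per-lobe vessel trees, thin bright
# fissures (optionally incomplete; none between lingula and LUL), planted
# air-trapping regions that keep inspiratory-like attenuation on expiration,
# and soft/sharp reconstruction-kernel texture.

#' Phantom specification
#'
#' All tunables of the synthetic thorax generator with their defaults. The
#' defaults emulate a pediatric chest: inspiratory parenchyma around
#' -820 HU (children's lungs are denser than adults'), expiratory parenchyma
#' around -560 HU so that the designed whole-lung E/I MLA falls in the range
#' reported for spirometer-controlled pediatric acquisitions (~0.6-0.75),
#' fissures +150 HU above parenchyma, soft tissue and vessels +40 HU,
#' airway walls -200 HU, airway lumen at air density.
#'
#' @param shape Grid dimensions (z, y, x). Default 96 x 128 x 128.
#' @param spacing Voxel size in mm (z, y, x). Default (1.5, 1, 1).
#' @param seed Integer seed; the phantom is fully deterministic given the
#'   spec (including this seed).
#' @param completeness Fraction of each designed fissure plane that is
#'   actually painted (fissures are frequently incomplete; the watershed has
#'   to bridge the gaps). Default 0.85.
#' @param fissure_thickness Fissure plane thickness in voxels. Default 2
#'   (a sub-millimetre fissure appears as a 1-2 voxel sheet on CT through
#'   partial-volume averaging).
#' @param densities Named list of HU constants: `air`, `soft`, `insp_mean`,
#'   `insp_sd`, `exp_mean`, `exp_sd`, `fissure_offset`, `fissure_offset_exp`,
#'   `vessel`, `airway_wall`.
#' @param air_trap_regions List of `list(lobe =, frac =, hu =)` entries:
#'   regions covering `frac` of the lobe volume that keep `hu` (inspiratory
#'   attenuation) on the expiratory scan.
#' @param vessels_per_lobe Number of vessel segments planted per lobe.
#' @param noise_sigma Global Gaussian image noise (HU).
#' @param kernel `"soft"` (Gaussian blur sigma 0.7 voxel, the B30f regime) or
#'   `"sharp"` (same blur plus high-frequency noise of 1.5 x `noise_sigma`,
#'   the B60f regime).
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(shape = c(96L, 128L, 128L),
                         spacing = c(1.5, 1.0, 1.0),
                         seed = 1L,
                         completeness = 0.85,
                         fissure_thickness = 2,
                         densities = list(),
                         air_trap_regions = list(
                           list(lobe = 3L, frac = 0.25, hu = -820),
                           list(lobe = 6L, frac = 0.35, hu = -820)),
                         vessels_per_lobe = 16L,
                         noise_sigma = 10,
                         kernel = c("soft", "sharp")) {
  kernel <- match.arg(kernel)
  dens <- utils::modifyList(list(
    air = -1000, soft = 40,
    insp_mean = -820, insp_sd = 30,
    exp_mean = -560, exp_sd = 40,
    fissure_offset = 150, fissure_offset_exp = 150,
    vessel = 40, airway_wall = -200), densities)
  if (completeness < 0 || completeness > 1)
    stop_pulmo("completeness must lie in [0, 1]", "validation_error")
  if (dens$exp_mean <= dens$insp_mean)
    stop_pulmo("expiratory parenchyma must be denser than inspiratory",
               "validation_error")
  fr <- vapply(air_trap_regions, function(r) r$frac, numeric(1))
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    stop_pulmo("air-trap fractions must lie in [0, 1]", "validation_error")
  lb <- vapply(air_trap_regions, function(r) as.integer(r$lobe), integer(1))
  if (length(lb)) {
    s <- tapply(fr, lb, sum)
    if (any(s > 1))
      stop_pulmo("air-trap fractions of a lobe must not sum above 1",
                 "validation_error")
    if (!all(lb %in% 1:6))
      stop_pulmo("air-trap lobe codes must be in 1..6", "validation_error")
  }
  structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    seed = as.integer(seed), completeness = completeness,
    fissure_thickness = fissure_thickness, densities = dens,
    air_trap_regions = air_trap_regions,
    vessels_per_lobe = as.integer(vessels_per_lobe),
    noise_sigma = noise_sigma, kernel = kernel,
    blur_sigma_vox = 0.7
  ), class = "phantom_spec")
}

#' Lower the expiratory parenchyma contrast of a phantom spec
#'
#' Reproduces the regime that makes expiratory scans hard to segment: deep
#' expiration raises parenchymal density toward soft tissue and washes out
#' the fissures. `level = 0` returns the spec unchanged; `level = 1` moves
#' the expiratory parenchyma mean all the way to `soft - 150` HU (floor) and
#' removes the expiratory fissure contrast.
#'
#' @param spec A [phantom_spec()].
#' @param level Degradation level in \[0, 1\].
#' @return A modified `phantom_spec`.
#' @export
degrade_expiratory_contrast <- function(spec, level) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (level < 0 || level > 1)
    stop_pulmo("level must lie in [0, 1]", "validation_error")
  d <- spec$densities
  floor_hu <- d$soft - 150
  d$exp_mean <- d$exp_mean + level * (floor_hu - d$exp_mean)
  d$fissure_offset_exp <- d$fissure_offset_exp * (1 - level)
  spec$densities <- d
  spec
}

# ---- geometry --------------------------------------------------------------

# fractional (z, y, x) coordinates and radii (mm) of the airway tree; lobar
# bronchi and their two sub-branches carry the lobe code
phantom_tree_table <- function() {
  e <- function(name, code, from, to, r)
    list(name = name, code = code, from = from, to = to, radius = r)
  carina <- c(0.354, 0.469, 0.500)
  hr <- c(0.438, 0.484, 0.359)
  hl <- c(0.458, 0.484, 0.625)
  bi <- c(0.542, 0.500, 0.328)
  rul <- c(0.313, 0.453, 0.266)
  rml <- c(0.604, 0.344, 0.281)
  rll <- c(0.729, 0.563, 0.313)
  lul <- c(0.354, 0.453, 0.688)
  lli <- c(0.550, 0.300, 0.700)
  lll <- c(0.667, 0.547, 0.656)
  list(
    e("trachea", 0L, c(0.042, 0.469, 0.500), carina, 4.0),
    e("main_R", 0L, carina, hr, 3.0),
    e("main_L", 0L, carina, hl, 3.0),
    e("RUL", 1L, hr, rul, 2.0),
    e("RUL_a", 1L, rul, c(0.229, 0.391, 0.219), 1.5),
    e("RUL_b", 1L, rul, c(0.250, 0.516, 0.203), 1.5),
    e("bronchus_intermedius", 0L, hr, bi, 2.5),
    e("RML", 2L, bi, rml, 2.0),
    e("RML_a", 2L, rml, c(0.625, 0.281, 0.250), 1.5),
    e("RML_b", 2L, rml, c(0.583, 0.250, 0.313), 1.5),
    e("RLL", 3L, bi, rll, 2.0),
    e("RLL_a", 3L, rll, c(0.833, 0.609, 0.266), 1.5),
    e("RLL_b", 3L, rll, c(0.792, 0.656, 0.375), 1.5),
    e("LUL", 4L, hl, lul, 2.0),
    e("LUL_a", 4L, lul, c(0.250, 0.406, 0.719), 1.5),
    e("LUL_b", 4L, lul, c(0.292, 0.516, 0.750), 1.5),
    e("LLi", 5L, lul, lli, 2.0),
    e("LLi_a", 5L, lli, c(0.560, 0.260, 0.680), 1.5),
    e("LLi_b", 5L, lli, c(0.550, 0.300, 0.750), 1.5),
    e("LLL", 6L, hl, lll, 2.0),
    e("LLL_a", 6L, lll, c(0.771, 0.594, 0.625), 1.5),
    e("LLL_b", 6L, lll, c(0.750, 0.641, 0.719), 1.5)
  )
}

# rasterize a segment given 0-based endpoint voxel coordinates
rasterize_segment <- function(from, to) {
  n <- max(2L, ceiling(max(abs(to - from))) + 1L)
  pts <- cbind(seq(from[1], to[1], length.out = n),
               seq(from[2], to[2], length.out = n),
               seq(from[3], to[3], length.out = n))
  pts <- round(pts)
  pts[!duplicated(pts), , drop = FALSE]
}

# voxel indices (1-based linear) within physical distance r_mm of segment
# from->to (0-based voxel coords)
tube_indices <- function(from, to, r_mm, d, spacing) {
  lo <- pmax(0, floor(pmin(from, to) - r_mm / spacing - 1))
  hi <- pmin(d - 1, ceiling(pmax(from, to) + r_mm / spacing + 1))
  if (any(lo > hi)) return(integer(0))
  z <- lo[1]:hi[1]; y <- lo[2]:hi[2]; x <- lo[3]:hi[3]
  g <- expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE)
  p <- cbind(g$z * spacing[1], g$y * spacing[2], g$x * spacing[3])
  a <- from * spacing
  b <- to * spacing
  u <- b - a
  len2 <- sum(u^2)
  t <- if (len2 == 0) rep(0, nrow(p)) else
    pmin(1, pmax(0, ((p[, 1] - a[1]) * u[1] + (p[, 2] - a[2]) * u[2] +
                     (p[, 3] - a[3]) * u[3]) / len2))
  dz <- p[, 1] - (a[1] + t * u[1])
  dy <- p[, 2] - (a[2] + t * u[2])
  dx <- p[, 3] - (a[3] + t * u[3])
  keep <- (dz * dz + dy * dy + dx * dx) <= r_mm^2
  gi <- g[keep, , drop = FALSE]
  1L + gi$z + d[1] * (gi$y + d[2] * gi$x)
}

phantom_geometry <- function(spec, tree = NULL) {
  d <- spec$shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  Z <- slice.index(array(0L, d), 1) - 1
  Y <- slice.index(array(0L, d), 2) - 1
  X <- slice.index(array(0L, d), 3) - 1

  ell <- function(cz, cy, cx, az, ay, ax)
    ((Z - cz * nz) / (az * nz))^2 + ((Y - cy * ny) / (ay * ny))^2 +
    ((X - cx * nx) / (ax * nx))^2 <= 1
  right <- ell(0.52, 0.52, 0.30, 0.40, 0.30, 0.155)
  left <- ell(0.53, 0.52, 0.71, 0.38, 0.28, 0.145) &
          !ell(0.45, 0.30, 0.58, 0.18, 0.12, 0.07)   # cardiac notch

  yc <- 0.52 * ny
  m <- 0.6 * spec$spacing[2] / spec$spacing[1]  # oblique slope, index units
  # plane levels are tied to the airway geometry: the horizontal fissure
  # sits at the bronchus-intermedius level (below the RUL origin, above the
  # RML origin), the oblique planes pass just above the lower-lobe origins
  ro_bound <- 0.530 * nz - m * (Y - yc)          # right oblique plane
  lo_bound <- 0.470 * nz - m * (Y - yc)          # left oblique plane
  zh <- 0.45 * nz                                # right horizontal plane
  rll <- right & (Z > ro_bound)
  rml <- right & !rll & (Z > zh)
  rul <- right & !rll & !rml
  lll <- left & (Z > lo_bound)
  # the lingula has no fissure: its boundary is the bronchial territory of
  # the lingular bronchus within the non-LLL left lung
  if (!is.null(tree)) {
    codes <- vapply(tree, function(e) e$code, integer(1))
    feat_of <- function(code) {
      f <- array(FALSE, d)
      vx <- do.call(rbind, lapply(tree[codes == code], function(e) e$voxels))
      ok <- vx[, 1] >= 0 & vx[, 1] < d[1] & vx[, 2] >= 0 & vx[, 2] < d[2] &
        vx[, 3] >= 0 & vx[, 3] < d[3]
      f[1L + vx[ok, 1] + d[1] * (vx[ok, 2] + d[2] * vx[ok, 3])] <- TRUE
      f
    }
    d_lli <- .edt_sq(feat_of(5L), spec$spacing)
    d_lul <- .edt_sq(feat_of(4L), spec$spacing)
    lli <- left & !lll & (d_lli < d_lul)
  } else {
    lli <- left & !lll & (Z > 0.50 * nz) & (Y < yc)
  }
  lul <- left & !lll & !lli

  th <- spec$fissure_thickness / 2
  fiss_ro <- right & (abs(Z - ro_bound) <= th)
  fiss_lo <- left & (abs(Z - lo_bound) <= th)
  fiss_h <- right & !rll & (abs(Z - zh) <= th)
  # no fissure between lingula and LUL: that boundary is airway/vessel-driven

  list(right = right, left = left,
       lobes = list(`1` = rul, `2` = rml, `3` = rll,
                    `4` = lul, `5` = lli, `6` = lll),
       fissures = list(fiss_ro, fiss_h, fiss_lo),
       hila = list(c(0.438, 0.484, 0.359) * (d - 1),   # right
                   c(0.438, 0.484, 0.359) * (d - 1),
                   c(0.458, 0.484, 0.625) * (d - 1)))  # left
}

# drop the (1 - completeness) fraction of a fissure plane nearest the hilum:
# fissure incompleteness is predominantly medial/para-hilar, while the
# peripheral fissure is usually well formed
apply_completeness <- function(fissure, completeness, d, hilum) {
  if (completeness >= 1) return(fissure)
  co <- which_voxels(fissure)
  if (nrow(co) == 0) return(fissure)
  dist <- sqrt(rowSums(sweep(co, 2, hilum)^2))
  keep <- dist >= stats::quantile(dist, 1 - completeness)
  out <- array(FALSE, d)
  out[voxel_index(co[keep, , drop = FALSE], d)] <- TRUE
  out
}

# ---- generation ------------------------------------------------------------

#' Generate a paired inspiratory/expiratory thorax phantom
#'
#' Deterministic for a fixed spec (seed included). Returns both CT volumes on
#' one grid plus the exact ground truth: the six-lobe label map, left/right
#' lung masks, the labeled airway centerline tree, the planted vessel and
#' air-trap masks, and the designed per-lobe mean lung attenuation for both
#' phases (computed on the blurred, noise-free phantom, so the designed
#' E/I MLA ratios are closed-form references for the quantification module).
#'
#' @param spec A [phantom_spec()].
#' @return `list(insp = ct_volume, exp = ct_volume, truth = list(...))`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  d <- spec$shape

  # airway tree in voxel coordinates
  tree <- lapply(phantom_tree_table(), function(e) {
    from <- e$from * (d - 1)
    to <- e$to * (d - 1)
    e$from_vox <- from; e$to_vox <- to
    e$voxels <- rasterize_segment(from, to)
    e
  })

  geo <- phantom_geometry(spec, tree)
  lung <- geo$right | geo$left

  lumen <- array(FALSE, d)
  wall <- array(FALSE, d)
  for (e in tree) {
    wall[tube_indices(e$from_vox, e$to_vox, e$radius + 1.5, d,
                      spec$spacing)] <- TRUE
  }
  for (e in tree) {
    lumen[tube_indices(e$from_vox, e$to_vox, e$radius, d,
                       spec$spacing)] <- TRUE
  }
  wall <- wall & !lumen

  # truth lobes and lung masks exclude the airway lumen
  lobes <- lapply(geo$lobes, function(mk) mk & !lumen)
  lung_right <- geo$right & !lumen
  lung_left <- geo$left & !lumen

  labels <- array(0L, d)
  for (k in 1:6) labels[lobes[[k]]] <- k

  # fissures at designed completeness
  fissure <- array(FALSE, d)
  for (i in seq_along(geo$fissures))
    fissure <- fissure | apply_completeness(geo$fissures[[i]] & !lumen & !wall,
                                            spec$completeness, d,
                                            geo$hila[[i]])

  # vessels: per lobe, a fan of segments accompanying the bronchi -- origins
  # spread along the lobar centerlines, endpoints across the lobe, calibers
  # in the segmental-artery range so that vessels remain resolvable objects
  vessel <- array(FALSE, d)
  tree_names <- vapply(tree, function(e) e$name, character(1))
  tree_codes <- vapply(tree, function(e) e$code, integer(1))
  lobe_sizes <- vapply(lobes, sum, numeric(1))
  for (k in 1:6) {
    chains <- do.call(rbind, lapply(tree[tree_codes == k],
                                    function(e) e$voxels))
    # vessels respect the perifissural/subpleural avascular zone: endpoints
    # are drawn from the lobe interior, not from its boundary layer
    core <- array(.bin_erode(lobes[[k]], 26L, 3L), d)
    if (!any(core)) core <- lobes[[k]]
    cand <- which_voxels(core)
    if (nrow(cand) == 0 || is.null(chains)) next
    # vessel density is roughly uniform across lung tissue, so the segment
    # count scales with the lobe's share of the lung volume
    n_v <- max(4L, round(6 * spec$vessels_per_lobe *
                           lobe_sizes[k] / sum(lobe_sizes)))
    n_v <- min(n_v, nrow(cand))
    pick <- cand[sample.int(nrow(cand), n_v), , drop = FALSE]
    if (k %in% 4:5) {
      # no fissure separates lingula and LUL, and pulmonary veins run
      # intersegmentally: a third of their vessels roam the combined
      # territory instead of respecting the designed boundary
      union_core <- array(.bin_erode(lobes[[4]] | lobes[[5]], 26L, 3L), d)
      uc <- which_voxels(if (any(union_core)) union_core else
                           lobes[[4]] | lobes[[5]])
      n_mix <- floor(n_v / 3)
      if (n_mix > 0 && nrow(uc) > 0)
        pick[seq_len(n_mix), ] <- uc[sample.int(nrow(uc), n_mix), ,
                                     drop = FALSE]
    }
    orig <- chains[sample.int(nrow(chains), n_v, replace = TRUE), ,
                   drop = FALSE]
    radii <- stats::runif(n_v, 1.4, 2.4)
    for (i in seq_len(n_v))
      vessel[tube_indices(orig[i, ], pick[i, ], radii[i], d,
                          spec$spacing)] <- TRUE
  }
  vessel <- vessel & lung & !lumen & !wall

  # air-trap regions: the frac*N lobe voxels nearest a seeded center
  traps <- vector("list", length(spec$air_trap_regions))
  for (i in seq_along(spec$air_trap_regions)) {
    r <- spec$air_trap_regions[[i]]
    co <- which_voxels(lobes[[r$lobe]])
    n_take <- round(r$frac * nrow(co))
    msk <- array(FALSE, d)
    if (n_take > 0) {
      ctr <- colMeans(co) + stats::rnorm(3, 0, 1)
      dist <- sqrt(rowSums(sweep(sweep(co, 2, ctr), 2, spec$spacing, `*`)^2))
      msk[voxel_index(co[order(dist)[seq_len(n_take)], , drop = FALSE], d)] <- TRUE
    }
    traps[[i]] <- list(lobe = r$lobe, hu = r$hu, mask = msk)
  }

  paint <- function(phase, textured) {
    dens <- spec$densities
    hu <- array(dens$soft, d)
    if (phase == "insp") {
      mu <- dens$insp_mean; sdv <- dens$insp_sd; off <- dens$fissure_offset
    } else {
      mu <- dens$exp_mean; sdv <- dens$exp_sd; off <- dens$fissure_offset_exp
    }
    nlung <- sum(lung)
    hu[lung] <- if (textured) stats::rnorm(nlung, mu, sdv) else mu
    if (phase == "exp") {
      for (tr in traps) {
        ntr <- sum(tr$mask)
        if (ntr > 0)
          hu[tr$mask] <- if (textured)
            stats::rnorm(ntr, tr$hu, spec$densities$insp_sd) else tr$hu
      }
    }
    hu[fissure] <- hu[fissure] + off
    hu[vessel] <- dens$vessel
    hu[wall] <- dens$airway_wall
    hu[lumen] <- dens$air
    hu
  }

  finish <- function(hu, add_noise) {
    sig <- spec$blur_sigma_vox
    # quantum noise enters before the reconstruction kernel, so it is
    # band-limited by the blur; the sharp kernel restores high frequencies,
    # emulated as extra white noise added after the blur
    if (add_noise && spec$noise_sigma > 0)
      hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sigma)
    hu <- gaussian_blur(hu, c(sig, sig, sig))
    if (add_noise && spec$kernel == "sharp")
      hu <- hu + stats::rnorm(length(hu), 0, 1.5 * spec$noise_sigma)
    array(as.integer(round(pmin(3071, pmax(-1024, hu)))), d)
  }

  # designed (noise-free) attenuation references, blurred like the output
  clean_insp <- finish(paint("insp", textured = FALSE), add_noise = FALSE)
  clean_exp <- finish(paint("exp", textured = FALSE), add_noise = FALSE)
  designed_mla <- data.frame(
    lobe = names(lobe_codes()), code = as.integer(lobe_codes()),
    mla_insp = vapply(1:6, function(k) mean(clean_insp[lobes[[k]]]), numeric(1)),
    mla_exp = vapply(1:6, function(k) mean(clean_exp[lobes[[k]]]), numeric(1)))
  designed_mla$ei_mla <- designed_mla$mla_exp / designed_mla$mla_insp
  wl <- data.frame(
    lobe = "whole_lung", code = 0L,
    mla_insp = mean(clean_insp[labels > 0L]),
    mla_exp = mean(clean_exp[labels > 0L]))
  wl$ei_mla <- wl$mla_exp / wl$mla_insp
  designed_mla <- rbind(designed_mla, wl)

  insp <- ct_volume(finish(paint("insp", TRUE), TRUE), spec$spacing,
                    phase = "insp", kernel = spec$kernel)
  expv <- ct_volume(finish(paint("exp", TRUE), TRUE), spec$spacing,
                    phase = "exp", kernel = spec$kernel)

  centerline_tree <- lapply(tree, function(e)
    list(name = e$name, code = e$code, voxels = e$voxels))

  truth <- list(
    lobe_map = lobe_map(labels, spec$spacing, mode = "six_lobe"),
    lung_mask_left = lung_left, lung_mask_right = lung_right,
    centerline_tree = centerline_tree,
    designed_mla = designed_mla,
    vessel_mask = vessel, fissure_mask = fissure,
    airway_lumen = lumen, traps = traps, spec = spec)
  list(insp = insp, exp = expv, truth = truth)
}
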