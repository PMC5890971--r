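# Final stages: bronchial convex hulls, Hessian-eigenvalue fissure
# enhancement, distance-based initial lobe masks, and the erosion +
# marker-watershed that produces the final lobe map.

#' Convex hulls of the labeled bronchi, per lobe
#'
#' For each lobar code the 3-D convex hull of all centerline voxels carrying
#' that code is voxelized on the CT grid (degenerate point sets yield a
#' voxel, a 1-voxel-wide segment, or a thin polygon). Lobes whose code is
#' absent from the graph yield an empty mask. Very long centerline sets are
#' evenly subsampled to `max_points` before hull construction.
#'
#' @param graph A labeled `airway_graph`.
#' @param dims Grid dimensions (z, y, x).
#' @param max_points Subsampling cap for hull construction.
#' @return List of six logical arrays, one per lobar code.
#' @export
lobar_hulls <- function(graph, dims, max_points = 80L) {
  stopifnot(inherits(graph, "airway_graph"))
  if (all(graph$edges$code == 0L))
    stop_pulmo("graph carries no lobar labels; run label_lobar_bronchi first",
               "labeling_required")
  out <- vector("list", 6)
  for (k in 1:6) {
    pts <- graph_code_voxels(graph, k)
    if (nrow(pts) == 0) {
      out[[k]] <- array(FALSE, dims)
      next
    }
    if (nrow(pts) > max_points)
      pts <- pts[round(seq(1, nrow(pts), length.out = max_points)), ,
                 drop = FALSE]
    out[[k]] <- array(.hull_voxelize(as.matrix(pts), as.integer(dims)), dims)
  }
  names(out) <- names(lobe_codes())
  out
}

#' Enhance pulmonary fissures by Hessian eigenvalue analysis
#'
#' Multi-scale plate filter: at each scale the image is convolved with
#' Gaussian derivative kernels (scale-normalized by sigma^2) to obtain the
#' Hessian; with eigenvalues ordered |l1| >= |l2| >= |l3|, the
#' plate-likeness (|l1| - |l2|) / (|l1| + |l2| + eps) is kept only where
#' l1 < 0 (a fissure is a thin sheet DENSER than its surroundings, so the
#' second derivative across the sheet is strongly negative). The final map
#' is the maximum over scales, min-max normalized to \[0, 1\] inside the
#' lung; voxels outside the lung are 0.
#'
#' The strongest plate responses in a chest CT are not fissures but the
#' lung boundary (a massive density step) and vessel walls; scores within
#' `boundary_voxels` of the lung border and on (dilated) `exclude` voxels
#' (typically the segmented vessels) are therefore zeroed before
#' normalization.
#'
#' @param ct A [ct_volume()].
#' @param lung Logical lung mask.
#' @param scales_mm Gaussian scales in mm.
#' @param exclude Optional mask of voxels (e.g. segmented vessels) whose
#'   neighborhood is suppressed.
#' @param boundary_voxels Width of the suppressed lung-border shell.
#' @return Numeric 3-D array of plate scores in \[0, 1\].
#' @export
enhance_fissures <- function(ct, lung, scales_mm = c(1.0, 2.0),
                             exclude = NULL, boundary_voxels = 2L) {
  stopifnot(inherits(ct, "ct_volume"))
  assert_same_grid(ct, lung)
  if (length(scales_mm) == 0)
    stop_pulmo("scales_mm must be non-empty", "validation_error")
  if (!any(lung)) stop_pulmo("empty lung mask", "empty_input")
  d <- dim(ct$voxels)
  sp <- ct$spacing
  vol <- array(as.numeric(ct$voxels), d)

  domain <- lung
  if (boundary_voxels > 0)
    domain <- array(.bin_erode(lung, 26L, as.integer(boundary_voxels)), d)
  if (!is.null(exclude))
    domain <- domain & !array(.bin_dilate(exclude, 26L, 1L), d)
  if (!any(domain)) domain <- lung

  best <- array(0, d)
  for (sigma in scales_mm) {
    sig_vox <- sigma / sp
    deriv <- function(orders) {    # orders = c(oz, oy, ox)
      v <- vol
      for (axis in 1:3)
        v <- .convolve_axis(v, gaussian_kernel(sig_vox[axis], orders[axis]),
                            axis - 1L)
      # voxel-unit derivatives -> mm, plus sigma^2 scale normalization
      v * sigma^2 / prod(sp^orders)
    }
    hzz <- deriv(c(2L, 0L, 0L)); hyy <- deriv(c(0L, 2L, 0L))
    hxx <- deriv(c(0L, 0L, 2L)); hzy <- deriv(c(1L, 1L, 0L))
    hzx <- deriv(c(1L, 0L, 1L)); hyx <- deriv(c(0L, 1L, 1L))
    # structureness reference: a multiple of the median Hessian magnitude in
    # the lung (the noise floor), so weak noise plates are suppressed while
    # fissures, an order of magnitude above it, keep full weight
    s2 <- (hzz^2 + hyy^2 + hxx^2 + 2 * (hzy^2 + hzx^2 + hyx^2))[domain]
    cstr <- 3 * sqrt(stats::median(s2))
    sc <- array(.plate_score(hzz, hyy, hxx, hzy, hzx, hyx, domain, cstr), d)
    best <- pmax(best, sc)
  }
  rng <- range(best[domain])
  if (diff(rng) <= .Machine$double.eps) {
    best[] <- 0
    return(best)
  }
  out <- (best - rng[1]) / diff(rng)
  out[!domain] <- 0
  # close pinholes in the fissure sheet: a voxel surrounded by strong plate
  # responses inherits their support, while isolated noise is diluted
  out <- gaussian_blur(array(out, d), c(0.7, 0.7, 0.7))
  out[!lung] <- 0
  # seal the holes that excluded structures (vessels, airway walls, the
  # boundary shell) punch through fissure sheets: a suppressed voxel close
  # to a large connected supra-threshold sheet inherits the local maximum
  # score. Suppressed voxels away from fissures stay zero, so vessels and
  # airways running through lobe interiors never become barriers.
  gap <- lung & !domain
  strong <- array(out > 0.08, d)
  if (any(gap) && any(strong)) {
    cc <- label_components(strong, 26L)
    strong <- array(cc$labels %in% which(cc$sizes >= 200L), d)
    seal <- gap & array(.bin_dilate(strong, 26L, 4L), d)
    if (any(seal)) {
      fat <- max_filter3(array(out, d), 4L)
      out[seal] <- pmax(out[seal], fat[seal])
    }
  }
  array(out, d)
}

#' Initial lobe masks by distance to labeled structures
#'
#' Every lung voxel receives the code of its nearest labeled structure,
#' where the candidates are the bronchial hulls (their distance weighted by
#' `hull_weight`, so hulls dominate near the hilum), the labeled bronchial
#' centerlines, and the lobe-assigned vessel voxels. Right-lung voxels may
#' only take right-side codes (1-3), left-lung voxels left-side codes (4-6).
#'
#' @param left,right Lung masks from [segment_lungs()].
#' @param graph A labeled `airway_graph`.
#' @param hulls From [lobar_hulls()].
#' @param vessels Assigned `vessel_objects` (or NULL to use bronchi/hulls only).
#' @param hull_weight Multiplier on hull distances.
#' @return A six-lobe [lobe_map()].
#' @export
initial_lobe_masks <- function(left, right, graph, hulls, vessels = NULL,
                               hull_weight = 0.5) {
  d <- dim(left)
  assert_same_grid(left, right)
  sp <- attr(left, "spacing") %||% graph$spacing
  dist_k <- vector("list", 6)
  for (k in 1:6) {
    hb <- hulls[[k]]
    cv <- graph_code_voxels(graph, k)
    if (nrow(cv) > 0) {
      cvr <- round(cv)
      ok <- cvr[, 1] >= 0 & cvr[, 1] < d[1] & cvr[, 2] >= 0 &
        cvr[, 2] < d[2] & cvr[, 3] >= 0 & cvr[, 3] < d[3]
      hb[voxel_index(cvr[ok, , drop = FALSE], d)] <- TRUE
    }
    dk <- if (any(hb)) hull_weight * sqrt(.edt_sq(hb, sp)) else NULL
    if (!is.null(vessels) && !is.null(vessels$voxel_codes)) {
      vm <- vessels$voxel_codes == k & vessels$labels > 0L
      if (any(vm)) {
        dv <- sqrt(.edt_sq(array(vm, d), sp))
        dk <- if (is.null(dk)) dv else pmin(dk, dv)
      }
    }
    dist_k[[k]] <- dk
  }

  labels <- array(0L, d)
  for (side in list(list(mask = right, codes = 1:3),
                    list(mask = left, codes = 4:6))) {
    have <- side$codes[!vapply(dist_k[side$codes], is.null, logical(1))]
    if (length(have) == 0)
      stop_pulmo("a lung side has no labeled structures to assign from",
                 "assignment_error")
    best <- array(Inf, d)
    bestk <- array(0L, d)
    for (k in have) {
      better <- side$mask & (dist_k[[k]] < best)
      best[better] <- dist_k[[k]][better]
      bestk[better] <- k
    }
    labels[side$mask] <- bestk[side$mask]
  }
  lobe_map(labels, sp, mode = "six_lobe")
}

#' Finalize lobe masks by erosion and marker-based watershed
#'
#' Each initial lobe mask is eroded by `erosion_layers` voxel layers (a lobe
#' eroded to extinction falls back to the largest component of its uneroded
#' mask, with a warning); the eroded masks are markers for a watershed on
#' the fissure score image (high score = barrier), flooded per lung side so
#' right codes stay in the right lung. The output exactly partitions
#' left-union-right; marker voxels keep their labels. Lung voxels in pockets
#' disconnected from every marker are assigned to the nearest marker.
#'
#' Markers additionally keep clear of the fissure zone: marker voxels within
#' `marker_clearance_mm` of any voxel whose fissure score exceeds
#' `marker_cut` are removed, and only the largest connected component of
#' each cleaned mask is kept. A mislabeled patch that the initial distance
#' assignment placed on the far side of a fissure is thereby released for
#' re-flooding (where the flood has to climb the fissure barrier) instead of
#' being locked in by its marker; boundaries without fissures keep their
#' shallow distance-derived markers.
#'
#' @param initial A six-lobe [lobe_map()] from [initial_lobe_masks()].
#' @param fissures Fissure score array from [enhance_fissures()].
#' @param left,right Lung masks.
#' @param erosion_layers Number of erosion layers (default 2; the
#'   fissure-zone clearance below does the work an extra layer would).
#' @param marker_cut Fissure score above which a voxel counts as fissure
#'   zone for the marker clearance.
#' @param marker_clearance_mm Clearance distance around the fissure zone.
#' @return A six-lobe [lobe_map()].
#' @export
finalize_lobes <- function(initial, fissures, left, right,
                           erosion_layers = 2L, marker_cut = 0.05,
                           marker_clearance_mm = 3,
                           use_fissures = c("auto", "on", "off")) {
  use_fissures <- match.arg(use_fissures)
  stopifnot(inherits(initial, "lobe_map"))
  if (erosion_layers < 1)
    stop_pulmo("erosion_layers must be >= 1", "validation_error")
  d <- dim(initial$labels)
  assert_same_grid(initial, left)
  assert_same_grid(left, right)

  markers <- array(0L, d)
  lung <- left | right
  topo <- array(as.numeric(fissures), d)

  # confidence gate: useful fissure information forms sparse coherent
  # sheets. When supra-threshold voxels are diffuse (low-contrast
  # expiratory scans wash the fissures out), the score map carries no
  # boundary signal; the watershed then degrades gracefully to the
  # nearest-marker partition of the distance-derived masks.
  informative <- switch(use_fissures,
                        on = TRUE, off = FALSE,
                        auto = mean(topo[lung] > 0.2) < 0.10)
  if (!informative) topo[] <- 0

  # fissure zone = large connected sheets of supra-threshold score; small
  # supra-threshold blobs (vessel remnants, noise) must not eat markers
  strong <- array(informative & topo > marker_cut, d)
  if (any(strong)) {
    cc <- label_components(strong, 26L)
    keep <- which(cc$sizes >= 200L)
    strong <- array(cc$labels %in% keep, d)
  }
  clear <- if (any(strong)) {
    sqrt(.edt_sq(strong, initial$spacing)) > marker_clearance_mm
  } else array(TRUE, d)
  for (k in 1:6) {
    m <- initial$labels == k
    if (!any(m)) next
    er <- array(.bin_erode(m, 26L, as.integer(erosion_layers)), d) & clear
    if (any(er)) {
      er <- largest_component(array(er, d))
    } else {
      warning(sprintf(
        "lobe %s eroded to extinction; using its largest component as marker",
        names(lobe_codes())[k]))
      er <- largest_component(array(m, d))
    }
    markers[er] <- k
  }

  out <- array(0L, d)
  for (side in list(right, left)) {
    ws <- .watershed3d(topo, markers * (markers != 0L & side), side,
                       initial$spacing)
    out[side] <- ws[side]
  }

  # pockets unreachable from any marker: nearest-marker assignment
  missing <- (left | right) & out == 0L
  if (any(missing)) {
    best <- array(Inf, d)
    for (k in 1:6) {
      mk <- out == k | markers == k
      if (!any(mk)) next
      dk <- .edt_sq(array(mk, d), initial$spacing)
      better <- missing & (dk < best)
      best[better] <- dk[better]
      out[better] <- k
    }
  }
  lobe_map(out, initial$spacing, initial$origin, mode = "six_lobe")
}

#' Merge the lingula into the left upper lobe
#'
#' Relabels all code-5 voxels to 4 and switches the map to five-lobe mode;
#' all other labels are untouched. Already-five-lobe maps are returned
#' unchanged with a warning.
#'
#' @param map A [lobe_map()].
#' @return A five-lobe [lobe_map()].
#' @export
merge_lingula <- function(map) {
  stopifnot(inherits(map, "lobe_map"))
  if (map$mode == "five_lobe") {
    warning("map is already in five-lobe mode; nothing to merge")
    return(map)
  }
  labels <- map$labels
  labels[labels == 5L] <- 4L
  lobe_map(labels, map$spacing, map$origin, mode = "five_lobe")
}
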