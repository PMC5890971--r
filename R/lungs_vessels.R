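# Lung field segmentation (left/right masks) and vessel segmentation with
# iterative lobar assignment of 3-D connected vessel objects.

#' Segment the left and right lung
#'
#' Inspiratory scans are thresholded at a fixed -400 HU; expiratory scans,
#' where parenchyma approaches soft-tissue density, use a global Otsu
#' threshold computed over the body (padding/air below -990 HU excluded).
#' The airway tree (dilated by one voxel to remove partial-volume fringes)
#' is subtracted before connected-component analysis. The two largest
#' lung-sized components are kept; when the lungs come out as a single
#' component they are split by repeated erosion until two cores emerge,
#' each half recovered by nearest-core assignment within the original mask.
#' Holes are closed by morphological closing (radius 2) and the airway
#' lumen is removed again at the end. Left and right are decided by the
#' x centroid.
#'
#' @param ct A [ct_volume()].
#' @param airways Airway lumen mask from [segment_airway_tree()].
#' @param insp_threshold_hu Fixed threshold for inspiratory scans.
#' @param min_frac Minimum lung-component size as a fraction of the grid.
#' @return `list(left =, right =)` logical arrays with `spacing` attributes.
#' @export
segment_lungs <- function(ct, airways, insp_threshold_hu = -400,
                          min_frac = 0.02) {
  stopifnot(inherits(ct, "ct_volume"))
  assert_same_grid(ct, airways)
  d <- dim(ct$voxels)
  hu <- ct$voxels

  thr <- if (ct$phase == "insp") {
    insp_threshold_hu
  } else {
    body <- hu[hu > -990]
    ot <- tryCatch(otsu_threshold(as.numeric(body)),
                   pulmolobe_validation_error = function(e) NA_real_)
    if (is.na(ot))
      stop_pulmo("no lung/soft-tissue contrast for expiratory thresholding",
                 "segmentation_failure")
    ot
  }

  aw <- array(.bin_dilate(airways, 26L, 1L), d)
  cand <- (hu < thr) & !aw
  cc <- label_components(cand, 26L)
  if (cc$n == 0)
    stop_pulmo("no lung-sized component found", "segmentation_failure")

  # drop components touching the lateral grid boundary (outside-patient air)
  border <- array(FALSE, d)
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  touching <- unique(cc$labels[border & cand])
  sizes <- cc$sizes
  sizes[touching[touching > 0]] <- 0L

  min_vox <- min_frac * prod(d)
  big <- which(sizes >= min_vox)
  if (length(big) == 0)
    stop_pulmo("no lung-sized component found", "segmentation_failure")

  if (length(big) >= 2) {
    big <- big[order(sizes[big], decreasing = TRUE)][1:2]
    m1 <- array(cc$labels == big[1], d)
    m2 <- array(cc$labels == big[2], d)
  } else {
    halves <- split_joined_lungs(array(cc$labels == big[1], d), ct$spacing)
    m1 <- halves[[1]]; m2 <- halves[[2]]
  }

  close_mask <- function(m)
    array(.bin_erode(.bin_dilate(m, 26L, 2L), 26L, 2L), d)
  m1 <- close_mask(m1) & !airways
  m2 <- close_mask(m2) & !airways
  # closing may re-merge the masks near the mediastinum; keep them disjoint
  both <- m1 & m2
  if (any(both)) m2 <- m2 & !m1

  cx <- function(m) mean(which_voxels(m)[, 3])
  if (cx(m1) > cx(m2)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  attr(m1, "spacing") <- ct$spacing
  attr(m2, "spacing") <- ct$spacing
  list(right = m1, left = m2)   # right lung sits at low x
}

# split a single joined lung component by repeated erosion; halves are
# recovered by nearest-core distance within the original component
split_joined_lungs <- function(mask, spacing, max_iter = 10L) {
  d <- dim(mask)
  core <- mask
  for (i in seq_len(max_iter)) {
    core <- array(.bin_erode(core, 26L, 1L), d)
    cc <- label_components(core, 26L)
    big <- which(cc$sizes >= 0.001 * prod(d))
    if (length(big) >= 2) {
      big <- big[order(cc$sizes[big], decreasing = TRUE)][1:2]
      d1 <- .edt_sq(array(cc$labels == big[1], d), as.numeric(spacing))
      d2 <- .edt_sq(array(cc$labels == big[2], d), as.numeric(spacing))
      return(list(mask & (d1 <= d2), mask & (d1 > d2)))
    }
  }
  stop_pulmo("could not separate left and right lung by erosion",
             "segmentation_failure")
}

#' Segment pulmonary vessels
#'
#' Per-CT adjusted threshold: the 97.5th percentile of HU inside the lung,
#' floored at -500 HU; 26-connected components of at least `min_voxels`
#' voxels become vessel objects, initially unassigned.
#'
#' @param ct A [ct_volume()].
#' @param lung Logical lung mask (left and right combined).
#' @param percentile Percentile of within-lung HU defining the threshold.
#' @param floor_hu Lower bound for the adjusted threshold.
#' @param min_voxels Minimum component size.
#' @return A `vessel_objects` list: `labels` (integer array), `table`
#'   (data.frame: component, voxels, centroid mm, assigned code).
#' @export
segment_vessels <- function(ct, lung, percentile = 0.975, floor_hu = -500,
                            min_voxels = 5L) {
  stopifnot(inherits(ct, "ct_volume"))
  assert_same_grid(ct, lung)
  if (!any(lung)) stop_pulmo("empty lung mask", "empty_input")
  d <- dim(ct$voxels)
  vals <- as.numeric(ct$voxels[lung])
  thr <- max(stats::quantile(vals, percentile, names = FALSE), floor_hu)
  cand <- lung & (ct$voxels > thr)
  cc <- label_components(cand, 26L)
  keep <- which(cc$sizes >= min_voxels)
  labels <- array(0L, d)
  tab <- data.frame(component = integer(0), voxels = integer(0),
                    cz = numeric(0), cy = numeric(0), cx = numeric(0),
                    code = integer(0))
  sp <- attr(lung, "spacing") %||% ct$spacing
  for (i in seq_along(keep)) {
    sel <- cc$labels == keep[i]
    labels[sel] <- i
    co <- which_voxels(array(sel, d))
    ctr <- colMeans(co) * sp
    tab <- rbind(tab, data.frame(component = i, voxels = sum(sel),
                                 cz = ctr[1], cy = ctr[2], cx = ctr[3],
                                 code = 0L))
  }
  structure(list(labels = labels, table = tab, spacing = sp,
                 threshold_hu = thr),
            class = "vessel_objects")
}

#' @export
print.vessel_objects <- function(x, ...) {
  cat(sprintf("<vessel_objects> %d components, threshold %.1f HU, %d assigned\n",
              nrow(x$table), x$threshold_hu, sum(x$table$code > 0)))
  invisible(x)
}

#' Iteratively assign vessel objects to lobes
#'
#' For every unassigned component the distance (mm) to each lobe's
#' hull-plus-bronchi voxel set is measured; the component is assigned to the
#' nearest lobe when the assignment is unambiguous (nearest distance at most
#' `ambiguity` times the second-nearest). Ambiguous components are eroded by
#' one voxel, split into their connected parts, and reconsidered in the next
#' round (up to `max_rounds`); whatever remains stays unassigned, which is a
#' valid terminal state. Voxel losses to erosion are recorded in the result.
#'
#' @param vessels A `vessel_objects` from [segment_vessels()].
#' @param graph A labeled `airway_graph`.
#' @param hulls Per-lobe hull masks from [lobar_hulls()].
#' @param ambiguity Distance-ratio threshold for an unambiguous assignment.
#' @param max_rounds Erosion/split iteration cap.
#' @return The `vessel_objects` with codes filled in; attribute
#'   `eroded_voxels` counts voxels lost while splitting.
#' @export
assign_vessels_to_lobes <- function(vessels, graph, hulls, ambiguity = 0.5,
                                    max_rounds = 5L) {
  stopifnot(inherits(vessels, "vessel_objects"))
  d <- dim(vessels$labels)
  sp <- vessels$spacing

  # distance fields to each lobe's hull + labeled bronchial centerlines
  dist_k <- vector("list", 6)
  for (k in 1:6) {
    feat <- hulls[[k]]
    cv <- graph_code_voxels(graph, k)
    if (nrow(cv) > 0) {
      cvr <- round(cv)
      ok <- cvr[, 1] >= 0 & cvr[, 1] < d[1] & cvr[, 2] >= 0 &
        cvr[, 2] < d[2] & cvr[, 3] >= 0 & cvr[, 3] < d[3]
      feat[voxel_index(cvr[ok, , drop = FALSE], d)] <- TRUE
    }
    dist_k[[k]] <- if (any(feat)) sqrt(.edt_sq(feat, sp)) else NULL
  }
  present <- which(!vapply(dist_k, is.null, logical(1)))

  out <- array(0L, d)                      # final per-voxel lobe code
  eroded_lost <- 0L
  active <- vessels$labels                 # integer component labels
  nact <- max(active)

  for (round in seq_len(max_rounds)) {
    if (nact == 0) break
    # min distance of each active component to each lobe
    dmat <- matrix(Inf, nrow = nact, ncol = 6)
    for (k in present)
      dmat[, k] <- .min_by_component(dist_k[[k]], active, nact)
    alive <- tabulate(active[active > 0L], nbins = nact) > 0L
    assign_code <- rep(0L, nact)
    ambiguous <- rep(FALSE, nact)
    for (ci in which(alive)) {
      o <- order(dmat[ci, ])
      dmin <- dmat[ci, o[1]]; dsec <- dmat[ci, o[2]]
      if (!is.finite(dmin)) next
      if (!is.finite(dsec) || (dsec > 0 && dmin / dsec <= ambiguity))
        assign_code[ci] <- o[1]
      else ambiguous[ci] <- TRUE   # includes touching several lobes (0/0)
    }
    for (ci in which(assign_code > 0L)) {
      out[active == ci] <- assign_code[ci]
    }
    if (!any(ambiguous) || round == max_rounds) {
      active[] <- 0L
      break
    }
    # erode ambiguous components, split, requeue
    amb_mask <- array(active > 0L & ambiguous[pmax(active, 1L)], d)
    before <- sum(amb_mask)
    # face-connected erosion: thin vessels survive one splitting round
    er <- array(.bin_erode(amb_mask, 6L, 1L), d)
    eroded_lost <- eroded_lost + (before - sum(er))
    cc <- label_components(er, 26L)
    active <- cc$labels
    nact <- cc$n
  }

  # write back per-component codes on the ORIGINAL components: a component
  # may now be split across lobes; record the per-voxel map and the modal
  # code per original component
  tab <- vessels$table
  for (i in seq_len(nrow(tab))) {
    codes <- out[vessels$labels == tab$component[i]]
    codes <- codes[codes > 0L]
    tab$code[i] <- if (length(codes)) as.integer(names(which.max(table(codes))))
                   else 0L
  }
  vessels$table <- tab
  vessels$voxel_codes <- out
  attr(vessels, "eroded_voxels") <- eroded_lost
  vessels
}
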