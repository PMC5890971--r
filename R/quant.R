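# Lobe-based quantification: volumes, mean lung attenuation, and the
# air-trapping index E/I MLA (expiratory-to-inspiratory ratio of the mean
# lung attenuation, computed on each phase's own lobe masks -- the paired
# scans are never registered to each other).

#' Lobar volumes in cm3
#'
#' @param map A [lobe_map()].
#' @return Named numeric vector (lobe name -> cm3) including absent codes
#'   (0) and a `whole_lung` total.
#' @export
lobe_volumes <- function(map) {
  stopifnot(inherits(map, "lobe_map"))
  vv <- voxel_volume_mm3(map$spacing) / 1000
  counts <- tabulate(map$labels[map$labels > 0L], nbins = 6L)
  out <- counts * vv
  names(out) <- names(lobe_codes())
  c(out, whole_lung = sum(out))
}

#' Mean lung attenuation over a mask
#'
#' Arithmetic mean of HU over the mask voxels (vessels included; airway
#' lumen is excluded only when an airway mask is supplied).
#'
#' @param ct A [ct_volume()].
#' @param mask Non-empty logical array on the CT grid.
#' @param airways Optional airway lumen mask to exclude.
#' @return Mean HU.
#' @export
mean_lung_attenuation <- function(ct, mask, airways = NULL) {
  stopifnot(inherits(ct, "ct_volume"))
  assert_same_grid(ct, mask)
  if (!is.null(airways)) {
    assert_same_grid(ct, airways)
    mask <- mask & !airways
  }
  if (!any(mask))
    stop_pulmo("mean attenuation undefined for an empty mask", "metric_error")
  mean(ct$voxels[mask])
}

#' Lobar air trapping: E/I MLA
#'
#' Per lobe (and whole lung): the ratio of the expiratory to the inspiratory
#' mean lung attenuation, each computed on that phase's own lobe mask.
#' Values closer to 1 indicate more trapped air.
#'
#' @param ct_insp,ct_exp Inspiratory and expiratory [ct_volume()]s.
#' @param map_insp,map_exp The lobe maps segmented on each phase.
#' @param airways_insp,airways_exp Optional airway lumen masks to exclude
#'   from the attenuation means.
#' @return data.frame: lobe, code, `mla_insp`, `mla_exp`, `ei_mla`; the last
#'   row is the whole lung. Attribute `airways_excluded` records whether
#'   lumen voxels were excluded.
#' @export
ei_mla <- function(ct_insp, map_insp, ct_exp, map_exp,
                   airways_insp = NULL, airways_exp = NULL) {
  stopifnot(inherits(ct_insp, "ct_volume"), inherits(ct_exp, "ct_volume"),
            inherits(map_insp, "lobe_map"), inherits(map_exp, "lobe_map"))
  assert_same_grid(ct_insp, map_insp)
  assert_same_grid(ct_exp, map_exp)
  codes <- sort(intersect(unique(map_insp$labels[map_insp$labels > 0L]),
                          unique(map_exp$labels[map_exp$labels > 0L])))
  one <- function(k) {
    mi <- if (k == 0) map_insp$labels > 0L else map_insp$labels == k
    me <- if (k == 0) map_exp$labels > 0L else map_exp$labels == k
    mla_i <- mean_lung_attenuation(ct_insp, array(mi, dim(mi)), airways_insp)
    mla_e <- mean_lung_attenuation(ct_exp, array(me, dim(me)), airways_exp)
    if (mla_i >= 0)
      stop_pulmo(sprintf(
        "non-physical inspiratory attenuation (%.1f HU >= 0) for lobe %d",
        mla_i, k), "undefined_ratio")
    data.frame(lobe = if (k == 0) "whole_lung" else names(lobe_codes())[k],
               code = k, mla_insp = mla_i, mla_exp = mla_e,
               ei_mla = mla_e / mla_i)
  }
  out <- do.call(rbind, c(lapply(codes, one), list(one(0L))))
  attr(out, "airways_excluded") <- !is.null(airways_insp) ||
    !is.null(airways_exp)
  out
}

#' Lobe quantification table for a paired acquisition
#'
#' Volumes and MLA per phase plus E/I MLA, per lobe and for the whole lung.
#'
#' @inheritParams ei_mla
#' @return data.frame with one row per lobe plus whole lung.
#' @export
lobe_quant_table <- function(ct_insp, map_insp, ct_exp, map_exp,
                             airways_insp = NULL, airways_exp = NULL) {
  ei <- ei_mla(ct_insp, map_insp, ct_exp, map_exp, airways_insp, airways_exp)
  vi <- lobe_volumes(map_insp)
  ve <- lobe_volumes(map_exp)
  key <- ifelse(ei$code == 0, "whole_lung", names(lobe_codes())[pmax(ei$code, 1)])
  ei$volume_insp_cm3 <- unname(vi[key])
  ei$volume_exp_cm3 <- unname(ve[key])
  ei
}
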