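# Segmentation agreement statistics: overlap indices, surface distance,
# Bland-Altman limits of agreement, Pearson correlation, and the per-lobe
# validation report.

#' Dice overlap index
#'
#' `D = 2|A n M| / (|A| + |M|)`, computed on integer voxel counts
#' (1 = perfect overlap, 0 = none).
#'
#' @param a,m Logical arrays on the same grid, not both empty.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(a, m) {
  assert_same_grid(a, m)
  na <- sum(a); nm <- sum(m)
  if (na + nm == 0)
    stop_pulmo("dice undefined for two empty masks", "metric_error")
  2 * sum(a & m) / (na + nm)
}

#' Jaccard overlap index
#'
#' `J = |A n M| / |A u M|`; satisfies `J = D / (2 - D)` identically.
#'
#' @inheritParams dice
#' @return Jaccard score in \[0, 1\].
#' @export
jaccard <- function(a, m) {
  assert_same_grid(a, m)
  u <- sum(a | m)
  if (u == 0)
    stop_pulmo("jaccard undefined for two empty masks", "metric_error")
  sum(a & m) / u
}

#' Pooled multi-region Dice over lobe maps
#'
#' `2 * sum_i |A_i n M_i| / sum_i (|A_i| + |M_i|)` over the lobe codes
#' present in either map: the voxel-count-weighted mean of the per-lobe
#' Dice values.
#'
#' @param auto,ref [lobe_map()]s on the same grid with the same mode.
#' @return Pooled Dice in \[0, 1\].
#' @export
multi_region_dice <- function(auto, ref) {
  stopifnot(inherits(auto, "lobe_map"), inherits(ref, "lobe_map"))
  assert_same_grid(auto, ref)
  if (!identical(auto$mode, ref$mode))
    stop_pulmo(sprintf("mode mismatch: %s vs %s", auto$mode, ref$mode),
               "mode_error")
  codes <- sort(unique(c(auto$labels[auto$labels > 0L],
                         ref$labels[ref$labels > 0L])))
  num <- 0; den <- 0
  for (k in codes) {
    ak <- auto$labels == k
    mk <- ref$labels == k
    num <- num + sum(ak & mk)
    den <- den + sum(ak) + sum(mk)
  }
  if (den == 0)
    stop_pulmo("multi-region dice undefined for empty maps", "metric_error")
  2 * num / den
}

#' Mean absolute (average symmetric) surface distance
#'
#' Surface voxels are mask voxels with at least one face-adjacent background
#' neighbor (the grid boundary counts as background). The metric is the
#' mean, over both surface voxel sets pooled, of the Euclidean
#' nearest-neighbor distance (mm) to the other surface.
#'
#' @param a,m Non-empty logical arrays on the same grid.
#' @param spacing Voxel spacing in mm (z, y, x).
#' @return Distance in mm, `>= 0`.
#' @export
avg_surface_distance <- function(a, m, spacing) {
  assert_same_grid(a, m)
  if (!any(a) || !any(m))
    stop_pulmo("surface distance undefined for an empty mask", "metric_error")
  sa <- surface_voxels(a)
  sm <- surface_voxels(m)
  da <- sqrt(.edt_sq(sm, as.numeric(spacing)))[sa]   # a-surface -> m-surface
  dm <- sqrt(.edt_sq(sa, as.numeric(spacing)))[sm]
  (sum(da) + sum(dm)) / (length(da) + length(dm))
}

#' Bland-Altman mean difference and limits of agreement
#'
#' Differences `d = auto - ref`; mean difference and
#' `LoA = mean(d) +/- 1.96 sd(d)` with the sample (n-1) standard deviation.
#'
#' @param auto_values,ref_values Equal-length numeric vectors, n >= 2.
#' @return `list(mean_delta, loa_low, loa_high, sd_delta, n)`.
#' @export
bland_altman <- function(auto_values, ref_values) {
  if (length(auto_values) != length(ref_values))
    stop_pulmo("paired vectors must have equal length", "metric_error")
  if (length(auto_values) < 2)
    stop_pulmo("Bland-Altman needs at least 2 pairs", "insufficient_data")
  d <- auto_values - ref_values
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_delta = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_delta = s, n = length(d))
}

#' Pearson correlation coefficient
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_pulmo("pearson needs equal-length vectors with n >= 3",
               "metric_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_pulmo("pearson undefined for constant input", "metric_error")
  stats::cor(x, y)
}

#' Per-lobe validation report
#'
#' Compares an automatically generated lobe map against a reference map:
#' per-lobe Dice, Jaccard, average surface distance, volumes and volume
#' difference, plus a pooled multi-region row. When paired CT volumes are
#' supplied (inspiratory and expiratory with their own maps for each
#' method), per-lobe E/I MLA is computed for both maps and the air-trapping
#' difference is reported. Study-level Bland-Altman and Pearson statistics
#' are computed across the per-lobe volumes.
#'
#' @param auto,ref [lobe_map()]s on one grid, same mode.
#' @param ct_pair Optional `list(insp =, exp =, auto_exp =, ref_exp =)`:
#'   inspiratory/expiratory [ct_volume()]s plus the expiratory-phase maps
#'   for both methods (`auto`/`ref` are then the inspiratory-phase maps).
#' @return An `agreement_report`: `per_lobe` data.frame, `pooled_dice`,
#'   `bland_altman`, `pearson_r`.
#' @export
validation_report <- function(auto, ref, ct_pair = NULL) {
  stopifnot(inherits(auto, "lobe_map"), inherits(ref, "lobe_map"))
  assert_same_grid(auto, ref)
  if (!identical(auto$mode, ref$mode))
    stop_pulmo(sprintf("mode mismatch: %s vs %s", auto$mode, ref$mode),
               "mode_error")
  codes <- sort(unique(c(auto$labels[auto$labels > 0L],
                         ref$labels[ref$labels > 0L])))
  vv <- voxel_volume_mm3(auto$spacing) / 1000   # cm3 per voxel

  ei_auto <- ei_ref <- NULL
  if (!is.null(ct_pair)) {
    ei_auto <- ei_mla(ct_pair$insp, auto, ct_pair$exp, ct_pair$auto_exp)
    ei_ref <- ei_mla(ct_pair$insp, ref, ct_pair$exp, ct_pair$ref_exp)
  }

  rows <- lapply(codes, function(k) {
    ak <- array(auto$labels == k, dim(auto$labels))
    mk <- array(ref$labels == k, dim(ref$labels))
    both_empty <- !any(ak) && !any(mk)
    data.frame(
      lobe = names(lobe_codes())[k], code = k,
      dice = if (both_empty) NA_real_ else dice(ak, mk),
      jaccard = if (both_empty) NA_real_ else jaccard(ak, mk),
      assd_mm = if (!any(ak) || !any(mk)) NA_real_ else
        avg_surface_distance(ak, mk, auto$spacing),
      volume_auto_cm3 = sum(ak) * vv,
      volume_ref_cm3 = sum(mk) * vv,
      volume_delta_cm3 = (sum(ak) - sum(mk)) * vv,
      ei_auto = if (is.null(ei_auto)) NA_real_ else
        ei_auto$ei_mla[match(k, ei_auto$code)],
      ei_ref = if (is.null(ei_ref)) NA_real_ else
        ei_ref$ei_mla[match(k, ei_ref$code)],
      ei_delta = if (is.null(ei_auto)) NA_real_ else
        ei_auto$ei_mla[match(k, ei_auto$code)] -
          ei_ref$ei_mla[match(k, ei_ref$code)])
  })
  per_lobe <- do.call(rbind, rows)

  ba <- pr <- NULL
  if (nrow(per_lobe) >= 2) {
    ba <- bland_altman(per_lobe$volume_auto_cm3, per_lobe$volume_ref_cm3)
    if (nrow(per_lobe) >= 3 &&
        stats::sd(per_lobe$volume_auto_cm3) > 0 &&
        stats::sd(per_lobe$volume_ref_cm3) > 0)
      pr <- pearson(per_lobe$volume_auto_cm3, per_lobe$volume_ref_cm3)
  }

  structure(list(
    per_lobe = per_lobe,
    pooled_dice = multi_region_dice(auto, ref),
    bland_altman = ba,
    pearson_r = pr,
    mode = auto$mode), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> (%s) pooled Dice %.4f\n",
              x$mode, x$pooled_dice))
  print(x$per_lobe[, c("lobe", "dice", "jaccard", "assd_mm",
                       "volume_delta_cm3")], row.names = FALSE, digits = 4)
  if (!is.null(x$bland_altman))
    cat(sprintf("  volume Bland-Altman: mean %.2f cm3, LoA [%.2f, %.2f]\n",
                x$bland_altman$mean_delta, x$bland_altman$loa_low,
                x$bland_altman$loa_high))
  invisible(x)
}

#' Serialize an agreement report
#'
#' @param report An `agreement_report`.
#' @param json_path,csv_path Output paths (either may be NULL).
#' @return Invisibly the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(per_lobe = report$per_lobe, pooled_dice = report$pooled_dice,
                bland_altman = report$bland_altman,
                pearson_r = report$pearson_r, mode = report$mode)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = 10,
                         na = "null")
  }
  if (!is.null(csv_path))
    utils::write.csv(report$per_lobe, csv_path, row.names = FALSE)
  invisible(report)
}
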