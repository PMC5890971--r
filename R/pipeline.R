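# End-to-end lobe segmentation: wires the airway, lung/vessel, fissure and
# watershed stages together.

#' Fully automatic lobe segmentation
#'
#' Runs the complete pipeline on one CT volume: airway region growing,
#' skeletonization and graph construction, lobar labeling, lung and vessel
#' segmentation, bronchial convex hulls, iterative vessel-to-lobe
#' assignment, Hessian fissure enhancement, distance-based initial lobe
#' masks, and the final erosion + marker-watershed. Per-stage wall times are
#' recorded in the result.
#'
#' @param ct A [ct_volume()].
#' @param lobes 6 (lingula separate) or 5 (lingula merged into LUL).
#' @param erosion_layers Marker erosion depth for the watershed stage.
#' @param scales_mm Fissure-filter scales.
#' @param verbose Log stage progress via `message()`.
#' @return A list with `lobe_map` plus all intermediates (`airway_mask`,
#'   `graph`, `lungs`, `vessels`, `hulls`, `fissures`, `initial`, `timings`).
#' @export
segment_lobes <- function(ct, lobes = 6, erosion_layers = 2L,
                          scales_mm = c(1.0, 2.0), verbose = FALSE) {
  stopifnot(inherits(ct, "ct_volume"), lobes %in% c(5, 6))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop_pulmo(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 "stage_failure")
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.1fs", name, timings[[name]]))
    res
  }

  airway <- stage("airways", segment_airway_tree(ct))
  skel <- stage("skeleton", skeletonize(airway))
  graph <- stage("graph", build_airway_graph(skel, airway, ct$spacing))
  graph <- stage("labeling", label_lobar_bronchi(graph))
  lungs <- stage("lungs", segment_lungs(ct, airway))
  lung_all <- lungs$left | lungs$right
  attr(lung_all, "spacing") <- ct$spacing
  vessels <- stage("vessels", segment_vessels(ct, lung_all))
  hulls <- stage("hulls", lobar_hulls(graph, dim(ct$voxels)))
  vessels <- stage("vessel_assignment",
                   assign_vessels_to_lobes(vessels, graph, hulls))
  # vessel objects and airway walls are the strongest non-fissure plates;
  # both are excluded from the fissure-score domain
  not_fissure <- vessels$labels > 0L |
    array(.bin_dilate(airway, 26L, 2L), dim(ct$voxels))
  fiss <- stage("fissures",
                enhance_fissures(ct, lung_all, scales_mm,
                                 exclude = not_fissure))
  initial <- stage("initial_masks",
                   initial_lobe_masks(lungs$left, lungs$right, graph, hulls,
                                      vessels))
  map <- stage("watershed",
               finalize_lobes(initial, fiss, lungs$left, lungs$right,
                              erosion_layers))
  if (lobes == 5) map <- merge_lingula(map)

  list(lobe_map = map, airway_mask = airway, skeleton = skel, graph = graph,
       lungs = lungs, vessels = vessels, hulls = hulls, fissures = fiss,
       initial = initial, timings = unlist(timings))
}
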