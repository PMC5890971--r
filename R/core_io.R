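# Shared containers and I/O.
#
# Conventions used throughout the package:
#   * voxel arrays have dim = (nz, ny, nx), i.e. axis order (z, y, x) with
#     z the slowest anatomical axis (cranial at low z index);
#   * voxel indices are 0-based wherever they are exchanged with the C++
#     kernels, 1-based inside plain R code (standard R subscripting);
#   * physical position of voxel (i, j, k) (0-based) = origin + index * spacing,
#     in mm, per axis in the same (z, y, x) order.

#' Construct a CT volume
#'
#' A `ct_volume` is a 3-D integer grid of Hounsfield units (HU) with physical
#' voxel spacing and origin (mm, axis order z, y, x), tagged with the
#' respiratory phase (`"insp"` or `"exp"`) and the reconstruction kernel
#' (`"soft"` or `"sharp"`, the B30f/B60f regimes).
#'
#' HU values outside the valid CT range \[-1024, 3071\] are clamped with a
#' message reporting the count (CT dialects differ in their padding values).
#'
#' @param voxels 3-D numeric array of HU values, axis order (z, y, x).
#' @param spacing Numeric length-3, voxel size in mm per axis (z, y, x).
#' @param origin Numeric length-3, physical offset in mm.
#' @param phase `"insp"` or `"exp"`.
#' @param kernel `"soft"` or `"sharp"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      phase = c("insp", "exp"), kernel = c("soft", "sharp")) {
  phase <- match.arg(phase)
  kernel <- match.arg(kernel)
  if (length(dim(voxels)) != 3L)
    stop_pulmo("ct_volume requires a 3-D array", "dim_error")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_pulmo("spacing must be 3 positive values (mm)", "validation_error")
  n_low <- sum(voxels < -1024)
  n_high <- sum(voxels > 3071)
  if (n_low + n_high > 0) {
    message(sprintf("ct_volume: clamped %d HU value(s) to [-1024, 3071]",
                    n_low + n_high))
    voxels[voxels < -1024] <- -1024
    voxels[voxels > 3071] <- 3071
  }
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), phase = phase, kernel = kernel),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d (z,y,x), spacing %s mm, phase=%s, kernel=%s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              x$phase, x$kernel))
  cat(sprintf("  HU range [%d, %d]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a lobe label map
#'
#' Integer label volume on a CT grid. Codes: 0 background, 1 RUL, 2 RML,
#' 3 RLL, 4 LUL, 5 LLi, 6 LLL (see [lobe_codes()]). In `five_lobe` mode the
#' lingula is merged into the left upper lobe, so code 5 must not occur.
#'
#' @param labels 3-D integer array, axis order (z, y, x).
#' @param spacing,origin Grid geometry in mm, as for [ct_volume()].
#' @param mode `"six_lobe"` or `"five_lobe"`.
#' @return An object of class `lobe_map`.
#' @export
lobe_map <- function(labels, spacing, origin = c(0, 0, 0),
                     mode = c("six_lobe", "five_lobe")) {
  mode <- match.arg(mode)
  if (length(dim(labels)) != 3L)
    stop_pulmo("lobe_map requires a 3-D array", "dim_error")
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:6))
    stop_pulmo(sprintf("invalid lobe codes: %s (allowed 0..6)",
                       paste(setdiff(u, 0:6), collapse = ", ")),
               "validation_error")
  if (mode == "five_lobe" && 5L %in% u)
    stop_pulmo("five_lobe mode must not contain code 5 (lingula)",
               "validation_error")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_pulmo("spacing must be 3 positive values (mm)", "validation_error")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), mode = mode),
    class = "lobe_map"
  )
}

#' @export
print.lobe_map <- function(x, ...) {
  d <- dim(x$labels)
  present <- sort(setdiff(unique(as.vector(x$labels)), 0L))
  nm <- names(lobe_codes())[match(present, lobe_codes())]
  cat(sprintf("<lobe_map> %dx%dx%d (z,y,x), mode=%s, lobes: %s\n",
              d[1], d[2], d[3], x$mode,
              if (length(nm)) paste(nm, collapse = ", ") else "none"))
  invisible(x)
}

# ---- grid compatibility ----------------------------------------------------

grid_info <- function(x) {
  if (inherits(x, "ct_volume")) {
    list(shape = dim(x$voxels), spacing = x$spacing, what = "ct_volume")
  } else if (inherits(x, "lobe_map")) {
    list(shape = dim(x$labels), spacing = x$spacing, what = "lobe_map")
  } else if (is.array(x) && length(dim(x)) == 3L) {
    list(shape = dim(x), spacing = attr(x, "spacing"), what = "array")
  } else {
    stop_pulmo("object carries no 3-D grid", "grid_error")
  }
}

#' Assert that two gridded objects live on the same voxel grid
#'
#' Shapes must be identical and spacings must agree within a relative
#' tolerance of 1e-6. Every operation consuming two gridded inputs calls this
#' first; a mismatch is a hard error naming both grids.
#'
#' @param a,b `ct_volume`, `lobe_map`, or a 3-D array (optionally carrying a
#'   `spacing` attribute).
#' @return Invisibly `TRUE` on success.
#' @export
assert_same_grid <- function(a, b) {
  ga <- grid_info(a)
  gb <- grid_info(b)
  if (!identical(as.integer(ga$shape), as.integer(gb$shape)))
    stop_pulmo(sprintf(
      "grid mismatch: %s %s vs %s %s",
      ga$what, paste(ga$shape, collapse = "x"),
      gb$what, paste(gb$shape, collapse = "x")), "grid_error")
  if (!is.null(ga$spacing) && !is.null(gb$spacing)) {
    rel <- abs(ga$spacing - gb$spacing) / pmax(abs(ga$spacing), abs(gb$spacing))
    if (any(rel > 1e-6))
      stop_pulmo(sprintf(
        "grid mismatch: spacing (%s) vs (%s) mm",
        paste(format(ga$spacing), collapse = ", "),
        paste(format(gb$spacing), collapse = ", ")), "grid_error")
  }
  invisible(TRUE)
}

voxel_volume_mm3 <- function(spacing) prod(spacing)

# ---- file formats ----------------------------------------------------------

sidecar_path <- function(path) {
  base <- sub("\\.nii\\.gz$", "", path)
  base <- sub("\\.(nii|mha|mhd)$", "", base)
  paste0(base, ".meta.json")
}

detect_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(mha|mhd)$", path)) "metaimage"
  else stop_pulmo(sprintf("unsupported file format: %s", path), "format_error")
}

#' Read a volumetric CT image
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd`) into a
#' [ct_volume()]. Phase and kernel tags are taken from a JSON sidecar file
#' (same basename, extension `.meta.json`) when present; otherwise the
#' defaults `"insp"`/`"soft"` are used and a message is logged (neither
#' standard format reserves fields for these tags).
#'
#' @param path Path to the image file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  raw <- read_raw_volume(path)
  meta <- read_sidecar(path)
  ct_volume(raw$voxels, raw$spacing, raw$origin,
            phase = meta$phase, kernel = meta$kernel)
}

#' Write a volumetric CT image
#'
#' Counterpart of [read_volume()]; also writes the phase/kernel JSON sidecar.
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return Invisibly `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_raw_volume(vol$voxels, vol$spacing, vol$origin, path)
  jsonlite::write_json(list(phase = vol$phase, kernel = vol$kernel),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a lobe label map
#'
#' @param path Path to a NIfTI or MetaImage label volume; the mode
#'   (`six_lobe`/`five_lobe`) is restored from the JSON sidecar when present.
#' @return A [lobe_map()].
#' @export
read_labelmap <- function(path) {
  raw <- read_raw_volume(path)
  meta <- read_sidecar(path, label = TRUE)
  lobe_map(raw$voxels, raw$spacing, raw$origin, mode = meta$mode)
}

#' Write a lobe label map
#'
#' Validates the map invariants (codes in 0..6, no code 5 in five-lobe mode)
#' before writing; round-trips voxel-identically through [read_labelmap()].
#'
#' @param map A [lobe_map()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_labelmap <- function(map, path) {
  stopifnot(inherits(map, "lobe_map"))
  # revalidate: the array may have been modified since construction
  map <- lobe_map(map$labels, map$spacing, map$origin, mode = map$mode)
  write_raw_volume(map$labels, map$spacing, map$origin, path)
  jsonlite::write_json(list(mode = map$mode), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

read_sidecar <- function(path, label = FALSE) {
  sp <- sidecar_path(path)
  defaults <- if (label) list(mode = "six_lobe")
              else list(phase = "insp", kernel = "soft")
  if (!file.exists(sp)) {
    message(sprintf("no sidecar %s: using defaults (%s)", basename(sp),
                    paste(unlist(defaults), collapse = "/")))
    return(defaults)
  }
  got <- jsonlite::read_json(sp, simplifyVector = TRUE)
  utils::modifyList(defaults, got[names(got) %in% names(defaults)])
}

# internal: format dispatch, returning list(voxels, spacing, origin),
# voxels already in (z, y, x) axis order
read_raw_volume <- function(path) {
  if (!file.exists(path))
    stop_pulmo(sprintf("file not found: %s", path), "format_error")
  switch(detect_format(path),
         nifti = read_nifti_raw(path),
         metaimage = read_metaimage_raw(path))
}

write_raw_volume <- function(voxels, spacing, origin, path) {
  switch(detect_format(path),
         nifti = write_nifti_raw(voxels, spacing, origin, path),
         metaimage = write_metaimage_raw(voxels, spacing, origin, path))
}

# ---- NIfTI (via RNifti); files store x fastest, we store z fastest ---------

read_nifti_raw <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_pulmo(sprintf("unreadable NIfTI file %s: %s",
                                       path, conditionMessage(e)),
                               "format_error"))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop_pulmo(sprintf("expected a 3-D image, got %d-D", length(dim(a))),
               "dim_error")
  pd <- RNifti::pixdim(img)        # (x, y, z); stored as float32 on disk
  orig <- RNifti::xform(img)[1:3, 4]
  list(voxels = aperm(a, c(3, 2, 1)),
       spacing = signif(rev(pd[1:3]), 7),
       origin = signif(rev(as.numeric(orig)), 7))
}

write_nifti_raw <- function(voxels, spacing, origin, path) {
  a <- aperm(voxels, c(3, 2, 1))   # back to (x, y, z)
  img <- RNifti::asNifti(a)
  img <- RNifti::`pixdim<-`(img, rev(spacing))
  xf <- diag(c(rev(spacing), 1))
  xf[1:3, 4] <- rev(origin)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
}

# ---- MetaImage (hand-rolled; uncompressed only) ----------------------------

metaimage_types <- c(MET_CHAR = "integer", MET_UCHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_CHAR = 1, MET_UCHAR = 1, MET_SHORT = 2,
                     MET_USHORT = 2, MET_INT = 4, MET_UINT = 4,
                     MET_FLOAT = 4, MET_DOUBLE = 8)

read_metaimage_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0)
      stop_pulmo("truncated MetaImage header", "format_error")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3)
      stop_pulmo(sprintf("malformed MetaImage header line: %s", line),
                 "format_error")
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3"))
    stop_pulmo(sprintf("expected a 3-D image, got NDims=%s",
                       hdr$NDims %||% "?"), "dim_error")
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop_pulmo("compressed MetaImage not supported", "format_error")
  if (identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE"))
    stop_pulmo("big-endian MetaImage not supported", "format_error")
  type <- hdr$ElementType %||% "MET_SHORT"
  if (!type %in% names(metaimage_types))
    stop_pulmo(sprintf("unsupported ElementType %s", type), "format_error")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])   # (x, y, z)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    vals <- read_metaimage_data(con, type, n)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop_pulmo(sprintf("MetaImage data file not found: %s", rawpath),
                 "format_error")
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- read_metaimage_data(con2, type, n)
  }
  if (length(vals) != n)
    stop_pulmo("MetaImage data shorter than DimSize promises", "format_error")
  a <- array(vals, dim = dims)                              # x fastest
  list(voxels = aperm(a, c(3, 2, 1)),
       spacing = rev(spacing), origin = rev(origin))
}

read_metaimage_data <- function(con, type, n) {
  readBin(con, what = metaimage_types[[type]], n = n,
          size = metaimage_sizes[[type]], endian = "little",
          signed = !(type %in% c("MET_UCHAR", "MET_USHORT")))
}

write_metaimage_raw <- function(voxels, spacing, origin, path) {
  a <- aperm(voxels, c(3, 2, 1))    # (x, y, z), x fastest in file
  is_mhd <- grepl("\\.mhd$", path)
  type <- if (is.integer(a)) "MET_SHORT" else "MET_DOUBLE"
  if (is.integer(a) && (min(a) < -32768 || max(a) > 32767)) type <- "MET_INT"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(a), collapse = " ")),
    paste("ElementSpacing =", paste(format(rev(spacing), trim = TRUE),
                                    collapse = " ")),
    paste("Offset =", paste(format(rev(origin), trim = TRUE), collapse = " ")),
    paste("ElementType =", type)
  )
  if (is_mhd) {
    rawname <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
  } else {
    con <- file(path, "wb")
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
  }
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(a), con,
           size = metaimage_sizes[[type]], endian = "little")
  invisible(path)
}
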