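#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar array indexed `(z, y, x)` together with the
#' physical metadata needed to relate voxel indices to world (scanner)
#' coordinates: per-axis spacing in millimetres and the world position of the
#' first voxel centre. Intensities are either Hounsfield units (`"HU"`) or
#' normalised units (`"normalized"`, after [normalize_volume()]).
#'
#' @param voxels numeric 3D array with `dim = c(nz, ny, nx)`.
#' @param spacing numeric length-3, mm per voxel along `(z, y, x)`; all > 0.
#' @param origin numeric length-3, world-mm coordinate of voxel `(0,0,0)`
#'   along `(z, y, x)`.
#' @param intensity_domain `"HU"` or `"normalized"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      intensity_domain = c("HU", "normalized")) {
  intensity_domain <- match.arg(intensity_domain)
  if (length(dim(voxels)) != 3L)
    stop("ct_volume: `voxels` must be a 3D array, got ",
         length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: `spacing` must be 3 positive finite values (z, y, x)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: `origin` must be 3 finite values (z, y, x)")
  if (any(!is.finite(voxels)))
    stop("ct_volume: voxel values must be finite")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         intensity_domain = intensity_domain),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g mm, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$intensity_domain))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Nodule annotation record
#'
#' One nodule in the LUNA16 `annotations.csv` dialect: a series identifier,
#' a world-coordinate centre in mm (given as `(x, y, z)`, the CSV column
#' order) and an equivalent diameter in mm.
#'
#' @param series_id character scalar.
#' @param center_world numeric length-3 `(x, y, z)` world mm.
#' @param diameter_mm positive diameter in mm.
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(series_id, center_world, diameter_mm) {
  if (!is.character(series_id) || length(series_id) != 1L)
    stop("nodule_annotation: `series_id` must be a character scalar")
  center_world <- as.numeric(center_world)
  if (length(center_world) != 3L || any(!is.finite(center_world)))
    stop("nodule_annotation: `center_world` must be 3 finite values (x, y, z)")
  diameter_mm <- as.numeric(diameter_mm)
  if (length(diameter_mm) != 1L || !is.finite(diameter_mm) || diameter_mm <= 0)
    stop("nodule_annotation: `diameter_mm` must be a positive number")
  structure(list(series_id = series_id, center_world = center_world,
                 diameter_mm = diameter_mm),
            class = "nodule_annotation")
}

# Reference diameter range of the LUNA16 nodule set; used for a soft
# dataset-level plausibility check, not a hard error.
LUNA16_DIAMETER_RANGE <- c(3.170, 27.442)

#' Nodule-centred region-of-interest sample
#'
#' The network's unit of input: an 11-slice stack of 64 x 64 normalised image
#' patches with a matching binary mask, both indexed `(z, y, x)`.
#'
#' @param image numeric array `11 x 64 x 64` (or `size`), normalised units.
#' @param mask binary array of identical shape.
#' @param source_id character id of the originating series.
#' @param center_voxel integer `(z, y, x)` 0-based voxel index of the ROI
#'   centre in the source (resampled) volume.
#' @param size integer length-3 expected shape, default `c(11, 64, 64)`.
#' @return An object of class `roi_sample`.
#' @export
roi_sample <- function(image, mask, source_id = "", center_voxel = c(0L, 0L, 0L),
                       size = c(11L, 64L, 64L)) {
  if (!identical(dim(image), as.integer(size)))
    stop("roi_sample: image must be ", paste(size, collapse = "x"))
  if (!identical(dim(image), dim(mask)))
    stop("roi_sample: image and mask shapes differ")
  if (!all(mask %in% c(0, 1)))
    stop("roi_sample: mask values must be 0/1")
  structure(list(image = image, mask = mask, source_id = source_id,
                 center_voxel = as.integer(center_voxel)),
            class = "roi_sample")
}
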