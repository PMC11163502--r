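#' Clip a CT volume to a Hounsfield window
#'
#' Restricts intensities to `[lo, hi]` HU. The default window of
#' \eqn{[-1000, 600]} keeps the full lung parenchyma and soft tissue range
#' while discarding dense bone and scanner padding values.
#'
#' @param vol [ct_volume()] in HU.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return Clipped [ct_volume()]; shape and metadata unchanged.
#' @export
clip_hu <- function(vol, lo = -1000, hi = 600) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_domain != "HU")
    stop("clip_hu: volume is not in HU")
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("clip_hu: need lo < hi, got [", lo, ", ", hi, "]")
  vol$voxels <- pmin(pmax(vol$voxels, lo), hi)
  vol
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

binary_dilate <- function(mask, radius = 1) {
  storage.mode(mask) <- "logical"
  cpp_binary_morph(mask, dim(mask), ball_offsets(radius), 1L)
}

binary_erode <- function(mask, radius = 1) {
  storage.mode(mask) <- "logical"
  cpp_binary_morph(mask, dim(mask), ball_offsets(radius), 0L)
}

fill_holes_3d <- function(mask) {
  storage.mode(mask) <- "logical"
  lab <- cpp_label_components(!mask, dim(mask))
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

#' Extract a lung parenchyma mask
#'
#' Segments the aerated lung region from a HU-clipped chest volume by
#' air thresholding, removal of background air connected to the volume
#' border, retention of the (up to) two largest interior air components,
#' hole filling and morphological closing. This is a conventional
#' parenchyma extraction; the downstream ROIs are nodule-centred, so the
#' exact recipe mainly serves to suppress non-lung structures.
#'
#' If no interior air component is found (e.g. a cropped slab with no body
#' outline) the function fails open: it warns and returns an all-`TRUE`
#' mask so the rest of the pipeline can proceed.
#'
#' @param vol HU [ct_volume()] (ideally after [clip_hu()]).
#' @param air_threshold HU below which a voxel counts as air (default -320).
#' @param closing_radius radius (voxels) of the ball used for closing.
#' @return logical array, same shape as `vol$voxels`.
#' @export
extract_lung_mask <- function(vol, air_threshold = -320, closing_radius = 2) {
  stopifnot(inherits(vol, "ct_volume"))
  air <- vol$voxels < air_threshold
  storage.mode(air) <- "logical"
  d <- dim(air)
  lab <- cpp_label_components(air, d)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border_labels <- border_labels[border_labels > 0]
  interior <- lab
  interior[interior %in% border_labels] <- 0L
  sizes <- tabulate(interior)
  if (!length(sizes) || all(sizes == 0)) {
    warning("extract_lung_mask: no interior air component found; ",
            "returning all-true mask")
    return(array(TRUE, dim = d))
  }
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, sum(sizes > 0)))]
  mask <- array(interior %in% keep, dim = d)
  mask <- fill_holes_3d(mask)
  # morphological closing: dilate then erode with a ball
  mask <- binary_erode(binary_dilate(mask, closing_radius), closing_radius)
  array(as.logical(mask), dim = d)
}

#' Apply a lung mask to a volume
#'
#' Sets all voxels outside the mask to `fill` (defaults to the lower HU
#' window bound, i.e. air).
#'
#' @param vol [ct_volume()].
#' @param mask logical array of identical shape.
#' @param fill replacement value for non-lung voxels.
#' @return masked [ct_volume()].
#' @export
apply_lung_mask <- function(vol, mask, fill = -1000) {
  stopifnot(inherits(vol, "ct_volume"), identical(dim(vol$voxels), dim(mask)))
  vol$voxels[!mask] <- fill
  vol
}

#' Resample a volume to isotropic spacing
#'
#' Resamples onto a grid with `target_spacing` mm voxels (default 1 mm in
#' all three directions). The output shape is
#' `round(input_shape * input_spacing / target_spacing)` and voxel-centre
#' world positions are preserved (the origin carries over unchanged).
#' Images are interpolated trilinearly; pass `nearest = TRUE` for label
#' masks.
#'
#' @param vol [ct_volume()] or plain `(z,y,x)` array (then `spacing`/`origin`
#'   are taken from `ref`).
#' @param target_spacing scalar or length-3 mm spacing, > 0.
#' @param nearest use nearest-neighbour interpolation (for masks).
#' @return resampled [ct_volume()].
#' @export
resample_isotropic <- function(vol, target_spacing = 1.0, nearest = FALSE) {
  stopifnot(inherits(vol, "ct_volume"))
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("resample_isotropic: target_spacing must be > 0")
  d_in <- dim(vol$voxels)
  d_out <- pmax(1L, as.integer(round(d_in * vol$spacing / target_spacing)))
  out <- cpp_resample3d(vol$voxels, d_out, vol$spacing, vol$origin,
                        target_spacing, vol$origin, nearest)
  ct_volume(out, spacing = target_spacing, origin = vol$origin,
            intensity_domain = vol$intensity_domain)
}

#' Normalise and de-average a HU volume
#'
#' Maps the retained HU window \eqn{[-1000, 600]} linearly onto `[0, 1]`,
#' then subtracts the volume mean so the input to the network is zero-mean.
#' Refuses to run twice (the map is only meaningful on HU data).
#'
#' @param vol HU [ct_volume()], ideally clipped to the window first.
#' @param window HU window mapped to `[0, 1]`.
#' @return [ct_volume()] with `intensity_domain = "normalized"` and mean 0.
#' @export
normalize_volume <- function(vol, window = c(-1000, 600)) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_domain == "normalized")
    stop("normalize_volume: volume is already normalized")
  v <- (vol$voxels - window[1]) / (window[2] - window[1])
  v <- v - mean(v)
  ct_volume(v, spacing = vol$spacing, origin = vol$origin,
            intensity_domain = "normalized")
}

#' Convert a world-coordinate annotation centre to a voxel index
#'
#' LUNA16 annotations are world mm in `(x, y, z)` order; volumes are indexed
#' `(z, y, x)`. The voxel index is `round((world - origin) / spacing)` per
#' axis, returned 0-based in `(z, y, x)` order.
#'
#' @param ann [nodule_annotation()].
#' @param vol [ct_volume()].
#' @return integer length-3 `(z, y, x)`, 0-based.
#' @export
world_to_voxel <- function(ann, vol) {
  stopifnot(inherits(ann, "nodule_annotation"), inherits(vol, "ct_volume"))
  world_zyx <- rev(ann$center_world)
  idx <- as.integer(round((world_zyx - vol$origin) / vol$spacing))
  d <- dim(vol$voxels)
  if (any(idx < 0L) || any(idx >= d))
    stop("world_to_voxel: annotation '", ann$series_id,
         "' maps to voxel (", paste(idx, collapse = ", "),
         ") outside the volume of shape (", paste(d, collapse = ", "), ")")
  idx
}

#' Crop a nodule-centred ROI
#'
#' Extracts a patch of `size` (default 11 x 64 x 64) centred on `center`
#' (0-based `(z,y,x)`; the centre lands at 0-based patch index
#' `(5, 32, 32)`). Windows that extend past the volume are zero-padded so
#' the nodule stays centred; a warning is raised when more than half the
#' patch is padding.
#'
#' @param vol normalised [ct_volume()] (resampled to 1 mm).
#' @param mask binary ground-truth array of the same geometry (or `NULL`).
#' @param center integer `(z, y, x)`, 0-based.
#' @param size patch shape `(z, y, x)`.
#' @param source_id id stored on the sample.
#' @return A [roi_sample()] (mask all-zero if `mask` is `NULL`).
#' @export
crop_roi <- function(vol, mask, center, size = c(11L, 64L, 64L),
                     source_id = "") {
  stopifnot(inherits(vol, "ct_volume"))
  size <- as.integer(size)
  center <- as.integer(center)
  d <- dim(vol$voxels)
  lo <- center - size %/% 2L          # 0-based inclusive start
  hi <- lo + size - 1L                # inclusive end
  take <- function(arr, fill = 0) {
    out <- array(fill, dim = size)
    src_lo <- pmax(lo, 0L)
    src_hi <- pmin(hi, d - 1L)
    if (any(src_lo > src_hi)) return(out)
    dst_lo <- src_lo - lo
    out[(dst_lo[1] + 1L):(dst_lo[1] + src_hi[1] - src_lo[1] + 1L),
        (dst_lo[2] + 1L):(dst_lo[2] + src_hi[2] - src_lo[2] + 1L),
        (dst_lo[3] + 1L):(dst_lo[3] + src_hi[3] - src_lo[3] + 1L)] <-
      arr[(src_lo[1] + 1L):(src_hi[1] + 1L),
          (src_lo[2] + 1L):(src_hi[2] + 1L),
          (src_lo[3] + 1L):(src_hi[3] + 1L)]
    out
  }
  img <- take(vol$voxels)
  n_pad <- prod(size) - prod(pmax(0L, pmin(hi, d - 1L) - pmax(lo, 0L) + 1L))
  if (n_pad > prod(size) / 2)
    warning("crop_roi: more than half of the patch is zero padding")
  msk <- if (is.null(mask)) array(0, dim = size) else take(mask * 1)
  roi_sample(img, msk, source_id = source_id, center_voxel = center,
             size = size)
}

#' Spherical proxy mask from an annotation
#'
#' LUNA16 annotations carry a centre and diameter but no contour, so a
#' sphere of the annotated diameter serves as proxy ground truth: all voxels
#' whose centre lies within `diameter_mm / 2` (world distance) of the
#' annotated centre are set to 1. The centre voxel is always included so the
#' mask is never empty.
#'
#' @param ann [nodule_annotation()].
#' @param vol [ct_volume()] (ideally at 1 mm isotropic spacing).
#' @return binary integer array shaped like `vol$voxels`.
#' @export
sphere_mask_from_annotation <- function(ann, vol) {
  stopifnot(inherits(ann, "nodule_annotation"), inherits(vol, "ct_volume"))
  if (ann$diameter_mm <= 0) stop("sphere_mask_from_annotation: diameter must be > 0")
  d <- dim(vol$voxels)
  r <- ann$diameter_mm / 2
  wz <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  wy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  wx <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  c_xyz <- ann$center_world
  dz2 <- (wz - c_xyz[3])^2
  dy2 <- (wy - c_xyz[2])^2
  dx2 <- (wx - c_xyz[1])^2
  mask <- array(0L, dim = d)
  mask[outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2] <- 1L
  cv <- world_to_voxel(ann, vol)
  mask[cv[1] + 1L, cv[2] + 1L, cv[3] + 1L] <- 1L
  mask
}

#' Full preprocessing chain for one case
#'
#' Applies, in order: HU clipping, lung-mask restriction, 1 mm isotropic
#' resampling, normalisation/de-averaging, and nodule-centred ROI cropping
#' (one ROI per annotation). Ground-truth masks are resampled with
#' nearest-neighbour interpolation; when no mask volume is supplied the
#' spherical proxy from the annotated diameter is used.
#'
#' @param vol HU [ct_volume()].
#' @param annotations list of [nodule_annotation()] for this series.
#' @param gt_mask optional binary `(z,y,x)` array in the input geometry.
#' @param hu_window HU clip window.
#' @param target_spacing isotropic spacing in mm.
#' @param roi_size patch shape `(z, y, x)`.
#' @param lung_mask apply parenchyma masking (default TRUE).
#' @return list of [roi_sample()].
#' @export
preprocess_case <- function(vol, annotations, gt_mask = NULL,
                            hu_window = c(-1000, 600), target_spacing = 1.0,
                            roi_size = c(11L, 64L, 64L), lung_mask = TRUE) {
  stopifnot(inherits(vol, "ct_volume"))
  if (inherits(annotations, "nodule_annotation")) annotations <- list(annotations)
  v <- clip_hu(vol, hu_window[1], hu_window[2])
  if (lung_mask) {
    lm <- extract_lung_mask(v)
    # The air-threshold mask excludes dense nodules; enclosed ones are
    # recovered by hole filling, but wall- and vessel-adherent nodules can
    # remain attached to excluded structures. The annotated neighbourhood
    # (1.25x the annotated diameter) is therefore always retained, so the
    # masking step can never erase a nodule it is meant to preserve.
    for (ann in annotations) {
      keep <- nodule_annotation(ann$series_id, ann$center_world,
                                ann$diameter_mm * 1.25)
      lm <- lm | (sphere_mask_from_annotation(keep, v) > 0)
    }
    v <- apply_lung_mask(v, lm, fill = hu_window[1])
  }
  v_iso <- resample_isotropic(v, target_spacing)
  v_norm <- normalize_volume(v_iso, window = hu_window)
  lapply(annotations, function(ann) {
    m_src <- if (is.null(gt_mask)) sphere_mask_from_annotation(ann, vol) else gt_mask * 1
    m_vol <- ct_volume(m_src, spacing = vol$spacing, origin = vol$origin)
    m_iso <- resample_isotropic(m_vol, target_spacing, nearest = TRUE)
    cv <- world_to_voxel(ann, v_norm)
    smp <- crop_roi(v_norm, m_iso$voxels, cv, size = roi_size,
                    source_id = ann$series_id)
    if (sum(smp$mask) == 0)
      warning("preprocess_case: empty ROI mask for '", ann$series_id, "'")
    smp
  })
}
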