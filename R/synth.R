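#' Phantom specification
#'
#' Describes one synthetic chest-CT phantom: an elliptical soft-tissue body
#' containing two air-filled lung fields, plus one nodule of a given
#' archetype. The four archetypes cover the classical presentation classes:
#' `solid_isolated` (dense nodule free in the parenchyma), `wall_adherent`
#' (nodule touching the chest wall), `ggo` (ground-glass opacity: faint,
#' soft-edged) and `vessel_adherent` (a soft-tissue vessel tube passing
#' through the nodule surface).
#'
#' HU palette defaults: lung -850, soft tissue +40, solid nodule +20,
#' GGO -550, with sparse bone (+1200) and air (-1024) speckles so the HU
#' clipping stage has work to do. Nodule diameters are kept inside the
#' 3.17--27.44 mm range spanned by the LUNA16 nodule set.
#'
#' @param archetype one of `"solid_isolated"`, `"wall_adherent"`, `"ggo"`,
#'   `"vessel_adherent"`.
#' @param extent_mm world extent `(z, y, x)` of the volume in mm.
#' @param spacing mm per voxel `(z, y, x)`.
#' @param radii_mm nodule semi-axes `(rz, ry, rx)` in mm.
#' @param nodule_hu,lung_hu,body_hu,ggo_hu HU palette.
#' @param noise_sd Gaussian noise SD in HU.
#' @param vessel_radius_mm radius of the vessel tube (vessel archetype).
#' @param seed per-case RNG seed.
#' @param series_id series identifier used in filenames/annotations.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(archetype = c("solid_isolated", "wall_adherent",
                                       "ggo", "vessel_adherent"),
                         extent_mm = c(48, 120, 120), spacing = c(1, 1, 1),
                         radii_mm = c(5, 5, 5), nodule_hu = 20,
                         lung_hu = -850, body_hu = 40, ggo_hu = -550,
                         noise_sd = 20, vessel_radius_mm = 1.5, seed = 1L,
                         series_id = NULL) {
  archetype <- match.arg(archetype)
  if (any(spacing <= 0)) stop("phantom_spec: spacing must be positive")
  d <- 2 * max(radii_mm)
  if (d < LUNA16_DIAMETER_RANGE[1] || d > LUNA16_DIAMETER_RANGE[2])
    warning("phantom_spec: nodule diameter ", d, " mm outside [",
            LUNA16_DIAMETER_RANGE[1], ", ", LUNA16_DIAMETER_RANGE[2], "] mm")
  if (is.null(series_id))
    series_id <- sprintf("synth.%s.%04d", archetype, seed %% 10000L)
  structure(list(archetype = archetype, extent_mm = extent_mm,
                 spacing = spacing, radii_mm = radii_mm,
                 nodule_hu = nodule_hu, lung_hu = lung_hu, body_hu = body_hu,
                 ggo_hu = ggo_hu, noise_sd = noise_sd,
                 vessel_radius_mm = vessel_radius_mm, seed = as.integer(seed),
                 series_id = series_id),
            class = "phantom_spec")
}

#' Generate one synthetic phantom case
#'
#' Renders the body/lung geometry, one nodule of the requested archetype,
#' Gaussian noise, and sparse out-of-window speckles. The ground-truth mask
#' is the exact (noise-free) nodule ellipsoid support; the annotation
#' carries the world-mm centre and `2 * max(radii)` as diameter, mimicking
#' the LUNA16 annotation dialect.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([ct_volume()]), `mask` (binary array),
#'   `lung_label` (logical array of the noise-free lung support),
#'   `annotation` ([nodule_annotation()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- pmax(4L, as.integer(round(spec$extent_mm / spec$spacing)))
  wz <- (seq_len(d[1]) - 1) * spec$spacing[1]
  wy <- (seq_len(d[2]) - 1) * spec$spacing[2]
  wx <- (seq_len(d[3]) - 1) * spec$spacing[3]
  cz <- max(wz) / 2; cy <- max(wy) / 2; cx <- max(wx) / 2
  Z <- array(wz, dim = d)
  Y <- aperm(array(wy, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(wx, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  # body: elliptical cylinder along z
  body_ry <- max(wy) * 0.45; body_rx <- max(wx) * 0.45
  body <- ((Y - cy) / body_ry)^2 + ((X - cx) / body_rx)^2 <= 1
  # two lung fields: ellipsoids off-centre in x
  lung_r <- c(0.42 * max(wz), 0.30 * max(wy), 0.18 * max(wx))
  lungs <- (((Z - cz) / lung_r[1])^2 + ((Y - cy) / lung_r[2])^2 +
              ((X - (cx - 0.22 * max(wx))) / lung_r[3])^2 <= 1) |
           (((Z - cz) / lung_r[1])^2 + ((Y - cy) / lung_r[2])^2 +
              ((X - (cx + 0.22 * max(wx))) / lung_r[3])^2 <= 1)
  lungs <- lungs & body
  # nodule centre in the right lung field
  lx <- cx + 0.22 * max(wx)
  centre <- c(cz, cy, lx)
  if (spec$archetype == "wall_adherent") {
    # push the nodule to the lung boundary (towards +x)
    centre[3] <- lx + lung_r[3] - max(spec$radii_mm) * 0.6
  }
  nod <- ((Z - centre[1]) / spec$radii_mm[1])^2 +
    ((Y - centre[2]) / spec$radii_mm[2])^2 +
    ((X - centre[3]) / spec$radii_mm[3])^2 <= 1
  nod <- nod & body
  if (!any(nod & lungs))
    stop("generate_phantom: nodule does not intersect the lung region")
  vox <- array(-1000, dim = d)          # background air
  vox[body] <- spec$body_hu
  vox[lungs] <- spec$lung_hu
  hu_nod <- if (spec$archetype == "ggo") spec$ggo_hu else spec$nodule_hu
  if (spec$archetype == "ggo") {
    # soft edge: blend towards lung HU over ~1.5 mm outside the core
    soft <- ((Z - centre[1]) / (spec$radii_mm[1] + 1.5))^2 +
      ((Y - centre[2]) / (spec$radii_mm[2] + 1.5))^2 +
      ((X - centre[3]) / (spec$radii_mm[3] + 1.5))^2 <= 1
    vox[soft & lungs & !nod] <- (hu_nod + spec$lung_hu) / 2
  }
  vox[nod] <- hu_nod
  if (spec$archetype == "vessel_adherent") {
    vessel <- sqrt((Z - centre[1])^2 + (Y - centre[2])^2) <= spec$vessel_radius_mm
    vessel <- vessel & lungs & !nod
    vox[vessel] <- spec$body_hu
  }
  # sparse out-of-window speckles exercise the HU clipping stage
  n_speck <- max(10L, round(prod(d) * 2e-4))
  ii <- sample.int(prod(d), 2L * n_speck)
  vox[ii[seq_len(n_speck)]] <- 1200
  vox[ii[n_speck + seq_len(n_speck)]] <- -1024
  vox <- vox + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
  vol <- ct_volume(vox, spacing = spec$spacing, origin = c(0, 0, 0))
  ann <- nodule_annotation(spec$series_id,
                           center_world = c(centre[3], centre[2], centre[1]),
                           diameter_mm = 2 * max(spec$radii_mm))
  list(volume = vol, mask = nod * 1L, lung_label = lungs, annotation = ann,
       spec = spec)
}

#' Write a phantom case in LUNA16 layout
#'
#' Writes the volume and mask as MetaImage pairs and appends the annotation
#' row to `annotations.csv` in `out_dir`.
#'
#' @param case result of [generate_phantom()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of the written paths.
#' @export
write_case <- function(case, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sid <- case$annotation$series_id
  vol_path <- file.path(out_dir, paste0(sid, ".mhd"))
  write_mhd(case$volume, vol_path)
  mask_dir <- file.path(out_dir, "masks")
  if (!dir.exists(mask_dir)) dir.create(mask_dir)
  mask_path <- file.path(mask_dir, paste0(sid, ".mhd"))
  write_mhd(ct_volume(case$mask, spacing = case$volume$spacing,
                      origin = case$volume$origin),
            mask_path, element_type = "MET_UCHAR")
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(case$annotation, ann_path)
  invisible(list(volume = vol_path, mask = mask_path, annotations = ann_path))
}

#' Generate a phantom dataset
#'
#' Draws `n` cases with archetypes allocated deterministically in
#' proportion to `mix`. With `anisotropic = TRUE` the slice spacing of each
#' case is sampled uniformly from 0.45--3.0 mm (the slice-interval range of
#' the LUNA16 scans) so the isotropic resampling stage is exercised; the
#' in-plane spacing is sampled from 0.46--0.98 mm likewise. A master seed
#' fans out per-case seeds reproducibly.
#'
#' @param n number of cases.
#' @param seed master seed.
#' @param mix named archetype proportions (must sum to 1).
#' @param anisotropic sample anisotropic spacings.
#' @param out_dir optional directory: when given, each case is written via
#'   [write_case()].
#' @param diameter_range_mm sampled nodule diameters (mm).
#' @return list of cases (as from [generate_phantom()]), invisibly when
#'   `out_dir` is given.
#' @export
generate_dataset <- function(n, seed = 1L,
                             mix = c(solid_isolated = 0.25, wall_adherent = 0.25,
                                     ggo = 0.25, vessel_adherent = 0.25),
                             anisotropic = FALSE, out_dir = NULL,
                             diameter_range_mm = c(6, 16)) {
  if (n < 1L) stop("generate_dataset: n must be >= 1")
  if (abs(sum(mix) - 1) > 1e-8)
    stop("generate_dataset: mix proportions must sum to 1")
  counts <- floor(mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  archetypes <- rep(names(counts), counts)
  set.seed(seed)
  case_seeds <- sample.int(1e7, n)
  spacings <- lapply(seq_len(n), function(i) {
    if (anisotropic) c(runif(1, 0.45, 3.0), rep(runif(1, 0.46, 0.98), 2))
    else c(1, 1, 1)
  })
  diams <- runif(n, diameter_range_mm[1], diameter_range_mm[2])
  cases <- lapply(seq_len(n), function(i) {
    r <- diams[i] / 2
    sp <- phantom_spec(archetype = archetypes[i], spacing = spacings[[i]],
                       radii_mm = c(r, r, r), seed = case_seeds[i],
                       series_id = sprintf("synth.%02d.%s", i, archetypes[i]))
    generate_phantom(sp)
  })
  if (!is.null(out_dir)) {
    for (case in cases) write_case(case, out_dir)
    return(invisible(cases))
  }
  cases
}

#' Preprocess phantom cases into ROI samples
#'
#' Runs the full preprocessing chain on generated cases, using each case's
#' exact generator mask as ground truth.
#'
#' @param cases list from [generate_dataset()].
#' @param ... passed to [preprocess_case()].
#' @return list of [roi_sample()].
#' @export
phantoms_to_rois <- function(cases, ...) {
  unlist(lapply(cases, function(case) {
    preprocess_case(case$volume, case$annotation, gt_mask = case$mask, ...)
  }), recursive = FALSE)
}
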