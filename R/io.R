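#' Read a CT volume from MetaImage or NIfTI
#'
#' Reads a 3D scalar volume plus its physical metadata. MetaImage
#' (`.mhd` + raw data file) is the format LUNA16 ships; NIfTI
#' (`.nii`/`.nii.gz`) is read through the RNifti package. The returned array
#' is re-ordered to the package's `(z, y, x)` convention regardless of the
#' on-disk layout (both formats store x fastest).
#'
#' @param path path to a `.mhd`, `.nii` or `.nii.gz` file.
#' @return A [ct_volume()] in Hounsfield units.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "mhd") {
    read_mhd(path)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("load_volume: expected a 3D volume, got ", length(d),
           " dimensions in ", path)
    sp <- RNifti::pixdim(img)  # (x, y, z)
    if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
      stop("load_volume: missing or invalid spacing metadata in ", path)
    xf <- try(RNifti::xform(img), silent = TRUE)
    org_xyz <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
    ct_volume(aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1)),
              spacing = rev(sp[1:3]), origin = rev(org_xyz))
  } else {
    stop("load_volume: unsupported format '.", ext, "' (use .mhd or .nii[.gz])")
  }
}

mhd_type_info <- function(type) {
  switch(type,
    MET_UCHAR  = list(size = 1L, what = "integer", signed = FALSE),
    MET_CHAR   = list(size = 1L, what = "integer", signed = TRUE),
    MET_SHORT  = list(size = 2L, what = "integer", signed = TRUE),
    MET_USHORT = list(size = 2L, what = "integer", signed = FALSE),
    MET_INT    = list(size = 4L, what = "integer", signed = TRUE),
    MET_FLOAT  = list(size = 4L, what = "numeric", signed = TRUE),
    MET_DOUBLE = list(size = 8L, what = "numeric", signed = TRUE),
    stop("read_mhd: unsupported ElementType ", type)
  )
}

#' Read a MetaImage (.mhd) volume
#'
#' Minimal MetaImage reader covering the uncompressed single-file dialect
#' used by LUNA16: an ASCII `key = value` header next to a raw voxel file.
#'
#' @param path path to the `.mhd` header.
#' @return A [ct_volume()].
#' @export
read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop("read_mhd: header of ", path, " is missing required field ", key)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L))
    stop("read_mhd: expected a 3D volume, ", path, " declares NDims = ", ndims)
  dimsize <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])  # (x, y, z)
  if (length(dimsize) != 3L || any(is.na(dimsize)) || any(dimsize < 1))
    stop("read_mhd: corrupt DimSize in ", path)
  sp_raw <- kv[["ElementSpacing"]] %||% kv[["ElementSize"]]
  if (is.null(sp_raw))
    stop("read_mhd: ", path, " has no ElementSpacing metadata")
  spacing_xyz <- as.numeric(strsplit(sp_raw, "\\s+")[[1]])
  if (length(spacing_xyz) != 3L || any(is.na(spacing_xyz)) || any(spacing_xyz <= 0))
    stop("read_mhd: invalid ElementSpacing in ", path)
  off_raw <- kv[["Offset"]] %||% kv[["Position"]] %||% kv[["Origin"]] %||% "0 0 0"
  origin_xyz <- as.numeric(strsplit(off_raw, "\\s+")[[1]])
  if (!is.null(kv[["CompressedData"]]) && toupper(kv[["CompressedData"]]) == "TRUE")
    stop("read_mhd: compressed MetaImage not supported: ", path)
  info <- mhd_type_info(need("ElementType"))
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop("read_mhd: inline (LOCAL) data not supported: ", path)
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath))
    stop("read_mhd: raw data file not found: ", datapath)
  n <- prod(dimsize)
  msb <- toupper(kv[["ElementByteOrderMSB"]] %||% kv[["BinaryDataByteOrderMSB"]] %||% "FALSE")
  endian <- if (msb == "TRUE") "big" else "little"
  con <- file(datapath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = info$what, n = n, size = info$size,
                  signed = info$signed, endian = endian)
  if (length(vals) != n)
    stop("read_mhd: raw file ", datapath, " holds ", length(vals),
         " voxels, header promises ", n)
  arr <- array(as.numeric(vals), dim = dimsize)  # (x, y, z)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(spacing_xyz),
            origin = rev(origin_xyz))
}

#' Write a MetaImage (.mhd + .raw) volume
#'
#' @param vol a [ct_volume()] (or a plain 3D `(z,y,x)` array).
#' @param path output `.mhd` path; the raw file is written alongside.
#' @param element_type MetaImage element type; `MET_DOUBLE` (default)
#'   round-trips values exactly, `MET_UCHAR` suits binary masks.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(vol, path, element_type = "MET_DOUBLE") {
  if (!inherits(vol, "ct_volume")) vol <- ct_volume(vol)
  info <- mhd_type_info(element_type)
  d <- dim(vol$voxels)  # (z, y, x)
  rawpath <- sub("\\.mhd$", ".raw", path)
  if (identical(rawpath, path)) rawpath <- paste0(path, ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", d[3], d[2], d[1]),
    paste("ElementSpacing =", vol$spacing[3], vol$spacing[2], vol$spacing[1]),
    paste("Offset =", vol$origin[3], vol$origin[2], vol$origin[1]),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", basename(rawpath))
  )
  writeLines(hdr, path)
  vals <- as.vector(aperm(vol$voxels, c(3, 2, 1)))  # x fastest on disk
  con <- file(rawpath, "wb")
  on.exit(close(con))
  if (info$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = info$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = info$size, endian = "little")
  }
  invisible(path)
}

ANNOTATION_COLUMNS <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")

#' Read LUNA16-style nodule annotations
#'
#' Parses a CSV with header `seriesuid,coordX,coordY,coordZ,diameter_mm`
#' (world coordinates in mm) into a list of [nodule_annotation()] records.
#' Diameters outside the reference range 3.170--27.442 mm trigger a warning
#' (the range spans the LUNA16 nodule set); non-positive diameters are an
#' error.
#'
#' @param path CSV file path.
#' @return list of `nodule_annotation`.
#' @export
load_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("load_annotations: missing column(s) ",
         paste(missing_cols, collapse = ", "),
         "; expected header: ", paste(ANNOTATION_COLUMNS, collapse = ","))
  if (nrow(df) == 0L) return(list())
  bad <- which(!is.finite(df$diameter_mm) | df$diameter_mm <= 0)
  if (length(bad))
    stop("load_annotations: non-positive diameter_mm at row ", bad[1])
  out_of_range <- df$diameter_mm < LUNA16_DIAMETER_RANGE[1] |
    df$diameter_mm > LUNA16_DIAMETER_RANGE[2]
  if (any(out_of_range))
    warning(sum(out_of_range), " annotation(s) with diameter outside [",
            LUNA16_DIAMETER_RANGE[1], ", ", LUNA16_DIAMETER_RANGE[2], "] mm")
  lapply(seq_len(nrow(df)), function(i) {
    nodule_annotation(as.character(df$seriesuid[i]),
                      c(df$coordX[i], df$coordY[i], df$coordZ[i]),
                      df$diameter_mm[i])
  })
}

#' Append annotations to a LUNA16-style CSV
#'
#' @param annotations list of [nodule_annotation()].
#' @param path CSV path; created with a header if absent.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "nodule_annotation")) annotations <- list(annotations)
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(seriesuid = a$series_id, coordX = a$center_world[1],
               coordY = a$center_world[2], coordZ = a$center_world[3],
               diameter_mm = a$diameter_mm, stringsAsFactors = FALSE)
  }))
  if (file.exists(path)) {
    old <- read.csv(path, stringsAsFactors = FALSE)
    df <- rbind(old, df)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
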