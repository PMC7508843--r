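#' Construct a drusen scan bundle
#'
#' A bundle holds everything extracted from one segmented SD-OCT acquisition:
#' the 3-D instance-agnostic drusen mask, the topographic RPE-elevation map
#' above the Bruch's membrane (BM) estimate, the B-scan intensity volume, and
#' geometry metadata. Array axes are (fast-scan, slow-scan, axial); the axial
#' axis measures height above the BM plane. The en-face origin is the scan
#' corner; `fovea_center_mm` is given in en-face mm coordinates.
#'
#' @param drusen_mask 3-D logical (or 0/1) array.
#' @param elevation_map_mm 2-D non-negative array, en-face dimensions matching
#'   the mask.
#' @param intensity_volume 3-D numeric array, same dimensions as the mask.
#' @param voxel_size_mm positive length-3 numeric (fast, slow, axial) in mm.
#' @param fovea_center_mm length-2 numeric, en-face mm.
#' @param eye_id,session_date identifiers.
#' @return an object of class `drusen_scan_bundle`.
#' @export
drusen_scan_bundle <- function(drusen_mask, elevation_map_mm, intensity_volume,
                               voxel_size_mm, fovea_center_mm,
                               eye_id = "eye", session_date = "0000-00-00") {
  drusen_mask <- as_binary_mask(drusen_mask)
  assert_that(length(dim(drusen_mask)) == 3L, "drusen_mask must be a 3-D array")
  assert_that(
    identical(dim(drusen_mask), dim(intensity_volume)),
    "mask and intensity volume dimensions differ"
  )
  assert_that(
    identical(dim(drusen_mask)[1:2], dim(elevation_map_mm)),
    "elevation map en-face dimensions differ from the mask"
  )
  assert_that(all(elevation_map_mm >= 0), "elevation must be non-negative")
  assert_that(
    is.numeric(voxel_size_mm) && length(voxel_size_mm) == 3L &&
      all(voxel_size_mm > 0),
    "voxel_size_mm must be 3 positive reals"
  )
  assert_that(
    is.numeric(fovea_center_mm) && length(fovea_center_mm) == 2L,
    "fovea_center_mm must be 2 reals"
  )
  structure(
    list(
      drusen_mask = drusen_mask,
      elevation_map_mm = elevation_map_mm,
      intensity_volume = intensity_volume,
      voxel_size_mm = as.numeric(voxel_size_mm),
      fovea_center_mm = as.numeric(fovea_center_mm),
      eye_id = eye_id,
      session_date = session_date
    ),
    class = "drusen_scan_bundle"
  )
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    stop_drusenseq("mask must be binary (0/1 or logical)", "drusenseq_invalid")
  }
  array(mask != 0, dim = dim(mask))
}

#' @export
print.drusen_scan_bundle <- function(x, ...) {
  d <- dim(x$drusen_mask)
  cat(sprintf(
    "<drusen_scan_bundle> eye %s @ %s | grid %d x %d x %d | voxel %.4g x %.4g x %.4g mm | %d drusen voxels\n",
    x$eye_id, x$session_date, d[1], d[2], d[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    sum(x$drusen_mask)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 single-file (.nii) I/O, float32 little-endian.
# No NIfTI reader/writer ships with the supported environment, so the small
# subset needed for phantom-bundle interchange is implemented here and
# round-trip tested. Only 3-D float volumes written by this package are
# supported on read.

write_nifti1 <- function(vol, path) {
  d <- dim(vol)
  assert_that(length(d) %in% c(2L, 3L), "only 2-D/3-D volumes supported")
  if (length(d) == 2L) d <- c(d, 1L)
  pix <- attr(vol, "pixdim") %||% c(1, 1, 1)
  pad_chr <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    if (length(b)) r[seq_along(b)] <- b
    r
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                        # [0]   sizeof_hdr
  writeBin(raw(36), con)                            # [4]   legacy fields
  w(as.integer(c(3, d, 1, 1, 1, 1)), 2)             # [40]  dim[8]
  w(numeric(3), 4)                                  # [56]  intent_p1..p3
  w(c(0L, 16L, 32L, 0L), 2)                         # [68]  intent_code, datatype=FLOAT32, bitpix, slice_start
  w(c(0, pix, 1, 1, 1, 1), 4)                       # [76]  pixdim[8]
  w(352, 4)                                         # [108] vox_offset
  w(c(1, 0), 4)                                     # [112] scl_slope, scl_inter
  w(0L, 2)                                          # [120] slice_end
  writeBin(as.raw(c(0, 2)), con)                    # [122] slice_code, xyzt_units=mm
  w(numeric(4), 4)                                  # [124] cal_max/min, slice_dur, toffset
  w(c(0L, 0L), 4)                                   # [140] glmax, glmin
  writeBin(pad_chr("drusenseq", 80), con)           # [148] descrip
  writeBin(raw(24), con)                            # [228] aux_file
  w(c(0L, 0L), 2)                                   # [252] qform_code, sform_code
  w(numeric(18), 4)                                 # [256] quaternions, offsets, srows
  writeBin(raw(16), con)                            # [328] intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)     # [344] magic
  writeBin(raw(4), con)                             # [348] extension flag
  w(as.numeric(vol), 4)                             # [352] data
  invisible(path)
}

read_nifti1 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  at <- function(off, what, n, size) {
    readBin(hdr[(off + 1):length(hdr)], what, n, size = size,
            endian = "little")
  }
  assert_that(at(0, "integer", 1, 4) == 348L, "not a NIfTI-1 file",
              "drusenseq_io")
  magic <- rawToChar(hdr[345:347])
  assert_that(magic == "n+1", "unsupported NIfTI flavour", "drusenseq_io")
  dimv <- at(40, "integer", 8, 2)
  datatype <- at(70, "integer", 1, 2)
  assert_that(datatype == 16L, "only FLOAT32 NIfTI supported", "drusenseq_io")
  pixdim <- at(76, "numeric", 8, 4)
  vox_offset <- at(108, "numeric", 1, 4)
  d <- dimv[2:(1 + dimv[1])]
  seek(con, vox_offset)
  vol <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  out <- array(vol, dim = d)
  attr(out, "pixdim") <- pixdim[2:4]
  out
}

#' Write a drusen scan bundle to disk
#'
#' Writes three NIfTI-1 volumes (`<prefix>_mask.nii`, `<prefix>_elevation.nii`,
#' `<prefix>_intensity.nii`) plus a JSON sidecar `<prefix>.json` carrying
#' `voxel_size_mm`, `fovea_center_mm`, `eye_id`, `session_date` and
#' `laterality`.
#'
#' @param bundle a [drusen_scan_bundle].
#' @param prefix output path prefix (directories must exist).
#' @param laterality "OD", "OS" or "unknown"; metadata only.
#' @return the sidecar path, invisibly.
#' @export
write_bundle <- function(bundle, prefix, laterality = "unknown") {
  stopifnot(inherits(bundle, "drusen_scan_bundle"))
  pd <- bundle$voxel_size_mm
  m <- bundle$drusen_mask * 1; attr(m, "pixdim") <- pd
  e <- bundle$elevation_map_mm; attr(e, "pixdim") <- c(pd[1:2], 1)
  v <- bundle$intensity_volume; attr(v, "pixdim") <- pd
  write_nifti1(m, paste0(prefix, "_mask.nii"))
  write_nifti1(e, paste0(prefix, "_elevation.nii"))
  write_nifti1(v, paste0(prefix, "_intensity.nii"))
  sidecar <- list(
    voxel_size_mm = bundle$voxel_size_mm,
    fovea_center_mm = bundle$fovea_center_mm,
    eye_id = bundle$eye_id,
    session_date = bundle$session_date,
    laterality = laterality
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a drusen scan bundle written by [write_bundle()]
#'
#' @param prefix path prefix used at write time (or the sidecar path).
#' @return a [drusen_scan_bundle].
#' @export
read_bundle <- function(prefix) {
  prefix <- sub("\\.json$", "", prefix)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- read_nifti1(paste0(prefix, "_mask.nii"))
  elev <- read_nifti1(paste0(prefix, "_elevation.nii"))
  if (length(dim(elev)) == 3L && dim(elev)[3] == 1L) {
    elev <- array(elev, dim = dim(elev)[1:2])
  }
  vol <- read_nifti1(paste0(prefix, "_intensity.nii"))
  attr(vol, "pixdim") <- NULL
  attr(elev, "pixdim") <- NULL
  # float32 round-trip can leave tiny negative dust on an all-zero map
  elev[elev < 0 & elev > -1e-6] <- 0
  drusen_scan_bundle(
    drusen_mask = mask != 0,
    elevation_map_mm = elev,
    intensity_volume = vol,
    voxel_size_mm = side$voxel_size_mm,
    fovea_center_mm = side$fovea_center_mm,
    eye_id = side$eye_id,
    session_date = side$session_date
  )
}
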