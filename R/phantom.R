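#' Specify a parametric drusen phantom
#'
#' A phantom is a synthetic SD-OCT acquisition in which every druse is a
#' spherical cap sitting on a flat Bruch's membrane plane. Spherical caps are
#' used because their footprint area (`pi * a^2`) and volume
#' (`pi * h * (3 a^2 + h^2) / 6`, with base radius `a` and peak height `h`)
#' have closed forms, giving analytic oracles for the feature extractor.
#'
#' The default grid is a reduced 128 x 128 x 128 test geometry over the usual
#' 6 x 6 x 2 mm scan field; the two clinical Cirrus macular protocols
#' (512 x 128 x 1024 at 11.7 x 47.2 x 2.0 um and 200 x 200 x 1024 at
#' 30 x 30 x 2 um) are also accepted.
#'
#' @param grid_shape integer length-3 (fast-scan, slow-scan, axial).
#' @param voxel_size_mm positive length-3 numeric; defaults to the 6 x 6 x 2 mm
#'   field divided by `grid_shape`.
#' @param druse_list list of drusen, each `list(center_xy_mm =, radius_mm =,
#'   peak_height_mm =)`.
#' @param background_intensity,druse_intensity_mean in `[0, 1]`.
#' @param druse_intensity_sd,noise_sd non-negative.
#' @param fovea_center_mm length-2, defaults to the field centre.
#' @param seed integer seed for the intensity noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size_mm = c(6, 6, 2) / grid_shape,
                         druse_list = list(),
                         background_intensity = 0.25,
                         druse_intensity_mean = 0.75,
                         druse_intensity_sd = 0.05,
                         noise_sd = 0.02,
                         fovea_center_mm = grid_shape[1:2] * voxel_size_mm[1:2] / 2,
                         seed = 1L) {
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 2),
              "grid_shape must be 3 integers >= 2")
  grid_shape <- as.integer(grid_shape)
  assert_that(length(voxel_size_mm) == 3L && all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive reals")
  field <- grid_shape[1:2] * voxel_size_mm[1:2]
  for (d in druse_list) {
    assert_that(
      is.numeric(d$radius_mm) && d$radius_mm > 0 &&
        is.numeric(d$peak_height_mm) && d$peak_height_mm > 0,
      "druse radius and peak height must be positive"
    )
    assert_that(length(d$center_xy_mm) == 2L &&
                  all(d$center_xy_mm >= 0 & d$center_xy_mm <= field),
                "druse center outside the scan field")
    if (any(d$center_xy_mm - d$radius_mm < 0) ||
        any(d$center_xy_mm + d$radius_mm > field) ||
        d$peak_height_mm > grid_shape[3] * voxel_size_mm[3]) {
      stop_drusenseq("druse extends outside the scan grid",
                     "drusenseq_invalid")
    }
  }
  assert_that(background_intensity >= 0 && background_intensity <= 1 &&
                druse_intensity_mean >= 0 && druse_intensity_mean <= 1,
              "intensities must lie in [0, 1]")
  assert_that(druse_intensity_sd >= 0 && noise_sd >= 0,
              "intensity sds must be non-negative")
  structure(
    list(
      grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
      druse_list = druse_list,
      background_intensity = background_intensity,
      druse_intensity_mean = druse_intensity_mean,
      druse_intensity_sd = druse_intensity_sd, noise_sd = noise_sd,
      fovea_center_mm = as.numeric(fovea_center_mm), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

cap_elevation <- function(dist_mm, radius_mm, peak_height_mm) {
  # height of a spherical cap (base radius a, peak h) above its base plane at
  # en-face distance d from the cap axis; 0 outside the footprint
  a <- radius_mm
  h <- peak_height_mm
  R <- (a^2 + h^2) / (2 * h)      # radius of the generating sphere
  e <- numeric(length(dist_mm))
  inside <- dist_mm < a
  e[inside] <- sqrt(pmax(R^2 - dist_mm[inside]^2, 0)) - (R - h)
  pmax(e, 0)
}

cap_volume <- function(radius_mm, peak_height_mm) {
  pi * peak_height_mm * (3 * radius_mm^2 + peak_height_mm^2) / 6
}

#' Generate a spherical-cap drusen phantom
#'
#' Builds a [drusen_scan_bundle] from a [phantom_spec]: the elevation map is
#' the pointwise maximum of all cap surfaces, the mask contains every voxel
#' whose axial centre lies below the local elevation, and the intensity volume
#' is background plus druse-region intensity plus white Gaussian noise.
#' Overlapping drusen are allowed; the union geometry is generated and the
#' overlap is flagged in the ground truth. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a [phantom_spec].
#' @param eye_id,session_date identifiers stamped on the bundle.
#' @return a [drusen_scan_bundle] with an extra `ground_truth` element: a list
#'   with per-druse `analytic_area_mm2`, `analytic_volume_mm3`, their totals,
#'   and `overlap` (logical).
#' @export
generate_phantom <- function(spec, eye_id = "phantom",
                             session_date = "2020-01-01") {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  dx <- spec$voxel_size_mm[1]; dy <- spec$voxel_size_mm[2]
  dz <- spec$voxel_size_mm[3]
  xc <- (seq_len(nx) - 0.5) * dx        # pixel-centre coordinates
  yc <- (seq_len(ny) - 0.5) * dy
  zc <- (seq_len(nz) - 0.5) * dz        # axial height above the BM plane

  elev <- matrix(0, nx, ny)
  for (d in spec$druse_list) {
    dist <- sqrt(outer((xc - d$center_xy_mm[1])^2,
                       (yc - d$center_xy_mm[2])^2, `+`))
    elev <- pmax(elev, matrix(
      cap_elevation(dist, d$radius_mm, d$peak_height_mm), nx, ny
    ))
  }

  # voxel (i,j,k) is druse iff its axial centre sits below elev(i,j)
  mask <- array(
    rep(as.vector(elev), times = nz) > rep(zc, each = nx * ny),
    dim = c(nx, ny, nz)
  )

  set.seed(spec$seed)
  vol <- array(
    spec$background_intensity + stats::rnorm(nx * ny * nz, 0, spec$noise_sd),
    dim = c(nx, ny, nz)
  )
  n_in <- sum(mask)
  if (n_in > 0) {
    vol[mask] <- stats::rnorm(n_in, spec$druse_intensity_mean,
                              spec$druse_intensity_sd) +
      stats::rnorm(n_in, 0, spec$noise_sd)
  }

  areas <- vapply(spec$druse_list, function(d) pi * d$radius_mm^2, 0)
  vols <- vapply(spec$druse_list,
                 function(d) cap_volume(d$radius_mm, d$peak_height_mm), 0)
  overlap <- FALSE
  dl <- spec$druse_list
  if (length(dl) >= 2) {
    for (i in seq_len(length(dl) - 1)) {
      for (j in (i + 1):length(dl)) {
        gap <- sqrt(sum((dl[[i]]$center_xy_mm - dl[[j]]$center_xy_mm)^2))
        if (gap < dl[[i]]$radius_mm + dl[[j]]$radius_mm) overlap <- TRUE
      }
    }
  }
  if (overlap) {
    warning("overlapping drusen: union geometry generated, analytic totals ",
            "ignore the overlap", call. = FALSE)
  }

  bundle <- drusen_scan_bundle(
    drusen_mask = mask, elevation_map_mm = elev, intensity_volume = vol,
    voxel_size_mm = spec$voxel_size_mm, fovea_center_mm = spec$fovea_center_mm,
    eye_id = eye_id, session_date = session_date
  )
  bundle$ground_truth <- list(
    analytic_area_mm2 = areas,
    analytic_volume_mm3 = vols,
    total_area_mm2 = sum(areas),
    total_volume_mm3 = sum(vols),
    overlap = overlap
  )
  bundle
}
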