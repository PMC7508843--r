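#' Names of the drusen imaging biomarkers
#'
#' The 15 internally computed features plus the 6 optional device-reported
#' ("Cirrus") pass-through counterparts. Units: areas mm^2, volumes mm^3,
#' heights mm, slope dimensionless (mm/mm), reflectivity in normalized 0-1
#' units, density dimensionless.
#'
#' @return character vector of 15 (or 21 with `cirrus = TRUE`) feature names.
#' @param cirrus include the 6 pass-through columns.
#' @export
feature_names <- function(cirrus = TRUE) {
  base <- c(
    "n_drusen", "mean_volume", "total_volume", "mean_area", "total_area",
    "extent_area", "density", "max_height", "avg_slope",
    "mean_reflectivity", "std_reflectivity",
    "area_3mm", "area_5mm", "volume_3mm", "volume_5mm"
  )
  if (!cirrus) return(base)
  c(base, paste0(c("total_area", "area_3mm", "area_5mm",
                   "total_volume", "volume_3mm", "volume_5mm"), "_cirrus"))
}

#' Label individually separated drusen
#'
#' Connected-component labelling of the 3-D binary drusen mask. Default
#' 26-connectivity (voxels sharing a face, edge or corner belong to the same
#' druse); 6-connectivity available for sensitivity analyses.
#'
#' @param mask 3-D binary array.
#' @param connectivity 26 or 6.
#' @return list with `labels` (integer array, 0 = background) and `count`.
#' @export
label_instances <- function(mask, connectivity = 26) {
  mask <- as_binary_mask(mask)
  assert_that(length(dim(mask)) == 3L, "mask must be 3-D")
  assert_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, dim = d)
  if (length(idx) == 0L) return(list(labels = labels, count = 0L))

  co <- arrayInd(idx, d)
  offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  # keep one of each +/- pair (forward offsets); drop the zero offset
  offsets <- offsets[offsets[, 3] > 0 |
                       (offsets[, 3] == 0 & offsets[, 2] > 0) |
                       (offsets[, 3] == 0 & offsets[, 2] == 0 &
                          offsets[, 1] > 0), , drop = FALSE]
  if (connectivity == 6) {
    offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  }

  pos <- seq_along(idx)           # vertex id of each foreground voxel
  edges <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    ni <- co[, 1] + offsets[r, 1]
    nj <- co[, 2] + offsets[r, 2]
    nk <- co[, 3] + offsets[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nlin <- ni[ok] + (nj[ok] - 1) * d[1] + (nk[ok] - 1) * d[1] * d[2]
    m <- match(nlin, idx)
    hit <- !is.na(m)
    edges[[r]] <- cbind(pos[ok][hit], m[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, count = as.integer(comp$no))
}

#' Per-druse and total size features
#'
#' Per-druse volume is voxel count times voxel volume; per-druse area is the
#' en-face footprint pixel count times pixel area. Means are over druse
#' instances, totals over the union.
#'
#' @param bundle a [drusen_scan_bundle].
#' @param labels result of [label_instances()] on the bundle's mask.
#' @return list `n_drusen`, `mean_volume`, `total_volume`, `mean_area`,
#'   `total_area`.
#' @export
compute_size_features <- function(bundle, labels) {
  vox_vol <- prod(bundle$voxel_size_mm)
  pix_area <- prod(bundle$voxel_size_mm[1:2])
  n <- labels$count
  if (n == 0L) {
    return(list(n_drusen = 0L, mean_volume = 0, total_volume = 0,
                mean_area = 0, total_area = 0))
  }
  lab <- labels$labels
  vox_counts <- tabulate(lab[lab > 0L], nbins = n)
  # per-druse footprint: pixels where that label appears in any axial slice;
  # the axial axis is collapsed by reshaping to (en-face pixel) x (slice),
  # which is orders of magnitude faster than apply() on clinical-size grids
  d <- dim(lab)
  flat <- matrix(lab, d[1] * d[2], d[3])
  pix_counts <- vapply(seq_len(n), function(k) {
    sum(rowSums(flat == k) > 0)
  }, 0L)
  vols <- vox_counts * vox_vol
  areas <- pix_counts * pix_area
  list(
    n_drusen = as.integer(n),
    mean_volume = mean(vols), total_volume = sum(vols),
    mean_area = mean(areas),
    total_area = sum(rowSums(flat != 0L) > 0) * pix_area
  )
}

polygon_area <- function(x, y) {
  # shoelace formula
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

footprint_of <- function(labels) {
  d <- dim(labels$labels)
  matrix(rowSums(matrix(labels$labels, d[1] * d[2], d[3]) != 0L) > 0,
         d[1], d[2])
}

#' Drusen extent and density
#'
#' Extent is the area of the 2-D convex hull of the union en-face footprint
#' (pixel centres in mm coordinates); density is total footprint area divided
#' by extent. Because the hull of pixel centres can undershoot the pixelised
#' footprint by a half-pixel rim (and collapses to zero for collinear
#' footprints), extent is floored at the total footprint area, which keeps
#' density in (0, 1] and makes a single convex druse report density 1.
#'
#' @inheritParams compute_size_features
#' @return list `extent_area`, `density`.
#' @export
compute_extent_density <- function(bundle, labels) {
  pix_area <- prod(bundle$voxel_size_mm[1:2])
  foot <- footprint_of(labels)
  npix <- sum(foot)
  if (npix == 0L) return(list(extent_area = 0, density = 0))
  total_area <- npix * pix_area
  dx <- bundle$voxel_size_mm[1]; dy <- bundle$voxel_size_mm[2]
  ij <- which(foot, arr.ind = TRUE)
  pts <- cbind((ij[, 1] - 0.5) * dx, (ij[, 2] - 0.5) * dy)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  extent <- max(polygon_area(pts[hull, 1], pts[hull, 2]), total_area)
  list(extent_area = extent, density = total_area / extent)
}

#' Maximum druse height and average slope
#'
#' Height is the maximum of the RPE-elevation map over the drusen footprint.
#' Slope is the mean finite-difference gradient magnitude of the elevation map
#' over the footprint, with physical spacing on both en-face axes (central
#' differences in the interior, one-sided at the borders).
#'
#' @inheritParams compute_size_features
#' @return list `max_height`, `avg_slope`.
#' @export
compute_height_slope <- function(bundle, labels) {
  foot <- footprint_of(labels)
  if (!any(foot)) return(list(max_height = 0, avg_slope = 0))
  e <- bundle$elevation_map_mm
  dx <- bundle$voxel_size_mm[1]; dy <- bundle$voxel_size_mm[2]
  gx <- e; gy <- e
  nx <- nrow(e); ny <- ncol(e)
  gx[2:(nx - 1), ] <- (e[3:nx, ] - e[1:(nx - 2), ]) / (2 * dx)
  gx[1, ] <- (e[2, ] - e[1, ]) / dx
  gx[nx, ] <- (e[nx, ] - e[nx - 1, ]) / dx
  gy[, 2:(ny - 1)] <- (e[, 3:ny] - e[, 1:(ny - 2)]) / (2 * dy)
  gy[, 1] <- (e[, 2] - e[, 1]) / dy
  gy[, ny] <- (e[, ny] - e[, ny - 1]) / dy
  gmag <- sqrt(gx^2 + gy^2)
  list(max_height = max(e[foot]), avg_slope = mean(gmag[foot]))
}

#' Percentile-normalise B-scan reflectivity
#'
#' Linear normalisation of the whole volume so that its 5th percentile maps to
#' 0 and its 95th percentile to 1. Values outside `[0, 1]` are legal (no
#' clipping): the percentiles anchor the scale, they do not bound it.
#'
#' @param intensity_volume numeric array.
#' @return normalised array of the same shape.
#' @export
normalize_reflectivity <- function(intensity_volume) {
  q <- stats::quantile(intensity_volume, c(0.05, 0.95), names = FALSE)
  if (q[2] <= q[1]) {
    stop_drusenseq("degenerate intensity range (p95 == p5)",
                   "drusenseq_degenerate")
  }
  (intensity_volume - q[1]) / (q[2] - q[1])
}

#' Reflectivity statistics inside drusen
#'
#' Mean and population standard deviation (divisor N, not N-1) of the
#' normalised intensity over masked voxels.
#'
#' @param normalized_volume output of [normalize_reflectivity()].
#' @param mask 3-D binary mask.
#' @return list `mean_reflectivity`, `std_reflectivity`, `undefined` (TRUE
#'   when the mask is empty, in which case both statistics are 0).
#' @export
compute_reflectivity_stats <- function(normalized_volume, mask) {
  mask <- as_binary_mask(mask)
  v <- normalized_volume[mask]
  if (length(v) == 0L) {
    return(list(mean_reflectivity = 0, std_reflectivity = 0, undefined = TRUE))
  }
  m <- mean(v)
  list(
    mean_reflectivity = m,
    std_reflectivity = sqrt(mean((v - m)^2)),
    undefined = FALSE
  )
}

#' Regional (foveal) drusen area and volume
#'
#' Restricts the footprint and mask to en-face Euclidean distance at most
#' `radius_mm` from the fovea centre and recomputes total area and volume
#' there. `radius_mm` is a radius, not an ETDRS-style diameter; pass 1.5/2.5
#' if a diameter convention is wanted.
#'
#' @inheritParams compute_size_features
#' @param radius_mm region radius in mm (the standard features use 3 and 5).
#' @return list `area`, `volume`.
#' @export
compute_regional <- function(bundle, labels, radius_mm) {
  assert_that(is_scalar_num(radius_mm) && radius_mm > 0,
              "radius_mm must be a positive scalar")
  pix_area <- prod(bundle$voxel_size_mm[1:2])
  vox_vol <- prod(bundle$voxel_size_mm)
  foot <- footprint_of(labels)
  if (!any(foot)) return(list(area = 0, volume = 0))
  nx <- nrow(foot); ny <- ncol(foot)
  xc <- (seq_len(nx) - 0.5) * bundle$voxel_size_mm[1]
  yc <- (seq_len(ny) - 0.5) * bundle$voxel_size_mm[2]
  dist2 <- outer((xc - bundle$fovea_center_mm[1])^2,
                 (yc - bundle$fovea_center_mm[2])^2, `+`)
  inside <- dist2 <= radius_mm^2
  d <- dim(labels$labels)
  col_counts <- matrix(                                 # voxels per column
    rowSums(matrix(labels$labels, d[1] * d[2], d[3]) != 0L), d[1], d[2]
  )
  list(
    area = sum(foot & inside) * pix_area,
    volume = sum(col_counts[inside]) * vox_vol
  )
}

#' Assemble the full imaging feature vector for one scan
#'
#' Orchestrates instance labelling, size, extent/density, height/slope,
#' reflectivity and regional features into the 21-column feature vector.
#' Device-reported ("Cirrus") fields are copied from `cirrus` when provided;
#' otherwise they mirror the internally computed counterparts and the result
#' carries attribute `cirrus_mirrored = TRUE`.
#'
#' @param bundle a [drusen_scan_bundle].
#' @param cirrus optional named list/vector with any of the 6
#'   `*_cirrus` fields.
#' @param connectivity passed to [label_instances()].
#' @param region_radii_mm the two foveal region radii (mm).
#' @return a named numeric vector over [feature_names()], with attributes
#'   `eye_id`, `session_date`, `undefined` (no-drusen flag) and
#'   `cirrus_mirrored`.
#' @export
assemble_features <- function(bundle, cirrus = NULL, connectivity = 26,
                              region_radii_mm = c(3, 5)) {
  stopifnot(inherits(bundle, "drusen_scan_bundle"))
  labels <- label_instances(bundle$drusen_mask, connectivity)
  sz <- compute_size_features(bundle, labels)
  ed <- compute_extent_density(bundle, labels)
  hs <- compute_height_slope(bundle, labels)
  refl <- if (labels$count > 0L) {
    compute_reflectivity_stats(normalize_reflectivity(bundle$intensity_volume),
                               bundle$drusen_mask)
  } else {
    list(mean_reflectivity = 0, std_reflectivity = 0, undefined = TRUE)
  }
  r3 <- compute_regional(bundle, labels, region_radii_mm[1])
  r5 <- compute_regional(bundle, labels, region_radii_mm[2])
  out <- c(
    n_drusen = as.numeric(sz$n_drusen),
    mean_volume = sz$mean_volume, total_volume = sz$total_volume,
    mean_area = sz$mean_area, total_area = sz$total_area,
    extent_area = ed$extent_area, density = ed$density,
    max_height = hs$max_height, avg_slope = hs$avg_slope,
    mean_reflectivity = refl$mean_reflectivity,
    std_reflectivity = refl$std_reflectivity,
    area_3mm = r3$area, area_5mm = r5$area,
    volume_3mm = r3$volume, volume_5mm = r5$volume
  )
  cirrus_cols <- setdiff(feature_names(TRUE), feature_names(FALSE))
  mirrored <- FALSE
  for (cc in cirrus_cols) {
    if (!is.null(cirrus) && !is.null(cirrus[[cc]]) && !is.na(cirrus[[cc]])) {
      out[cc] <- as.numeric(cirrus[[cc]])
    } else {
      out[cc] <- out[[sub("_cirrus$", "", cc)]]
      mirrored <- TRUE
    }
  }
  attr(out, "eye_id") <- bundle$eye_id
  attr(out, "session_date") <- bundle$session_date
  attr(out, "undefined") <- isTRUE(refl$undefined)
  attr(out, "cirrus_mirrored") <- mirrored
  out
}

#' Average feature vectors from one imaging session
#'
#' Scans acquired for the same eye on the same date are reduced to a single
#' observation by the element-wise arithmetic mean of all 21 features.
#'
#' @param vectors list of feature vectors from [assemble_features()] (or named
#'   numeric vectors over [feature_names()]), all for the same eye and date.
#' @return a single averaged named numeric vector.
#' @export
average_session <- function(vectors) {
  assert_that(length(vectors) >= 1L, "need at least one feature vector")
  eyes <- unique(vapply(vectors, function(v) {
    as.character(attr(v, "eye_id") %||% "eye")
  }, ""))
  dates <- unique(vapply(vectors, function(v) {
    as.character(attr(v, "session_date") %||% "date")
  }, ""))
  if (length(eyes) > 1L || length(dates) > 1L) {
    stop_drusenseq("session averaging requires a single eye and date",
                   "drusenseq_invalid")
  }
  nm <- feature_names(TRUE)
  mat <- do.call(rbind, lapply(vectors, function(v) as.numeric(v[nm])))
  out <- colMeans(mat)
  names(out) <- nm
  attr(out, "eye_id") <- eyes
  attr(out, "session_date") <- dates
  out
}
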