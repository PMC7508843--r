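make_bundle <- function(mask, elev = NULL, vol = NULL,
                        voxel = c(0.03, 0.03, 0.002), fovea = NULL) {
  d <- dim(mask)
  drusen_scan_bundle(
    drusen_mask = mask,
    elevation_map_mm = elev %||% matrix(0, d[1], d[2]),
    intensity_volume = vol %||% array(seq_len(prod(d)) / prod(d), d),
    voxel_size_mm = voxel,
    fovea_center_mm = fovea %||% (d[1:2] * voxel[1:2] / 2)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("label_instances matches the flood-fill oracle on random masks", {
  expect_error(label_instances(array(2, c(2, 2, 2))), "binary")
  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(label_instances(empty)$count, 0L)

  # two voxels sharing only a corner: one component at 26, two at 6
  corner <- array(FALSE, c(4, 4, 4))
  corner[2, 2, 2] <- TRUE; corner[3, 3, 3] <- TRUE
  expect_equal(label_instances(corner, 26)$count, 1L)
  expect_equal(label_instances(corner, 6)$count, 2L)

  # blobs separated by >= 2 empty voxels stay apart
  blobs <- array(FALSE, c(8, 4, 4))
  blobs[1:2, 1:2, 1:2] <- TRUE; blobs[6:7, 1:2, 1:2] <- TRUE
  expect_equal(label_instances(blobs)$count, 2L)

  set.seed(11)
  for (i in 1:8) {
    m <- array(runif(6 * 6 * 6) < 0.25, c(6, 6, 6))
    for (conn in c(26, 6)) {
      got <- label_instances(m, conn)
      want <- oracle_components(m, conn)
      expect_equal(got$count, want$count)
      if (got$count > 0) {
        # same partition up to label permutation
        expect_equal(length(unique(paste(got$labels[m], want$labels[m]))),
                     got$count)
      }
    }
  }
})

test_that("size features follow voxel arithmetic", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:5, 1:5, 1:4] <- TRUE           # 100 voxels, footprint 25 pixels
  b <- make_bundle(m)
  sz <- compute_size_features(b, label_instances(m))
  expect_equal(sz$n_drusen, 1L)
  expect_equal(sz$total_volume, 100 * 0.03 * 0.03 * 0.002)
  expect_equal(sz$total_area, 25 * 0.03^2)
  expect_equal(sz$mean_volume, sz$total_volume)

  # two identical drusen: mean = total / 2
  m[7:8, 7:8, 1:2] <- FALSE
  m2 <- array(FALSE, c(12, 12, 6))
  m2[1:2, 1:2, 1:2] <- TRUE
  m2[8:9, 8:9, 1:2] <- TRUE
  sz2 <- compute_size_features(make_bundle(m2), label_instances(m2))
  expect_equal(sz2$n_drusen, 2L)
  expect_equal(sz2$mean_volume, sz2$total_volume / 2)
  expect_equal(sz2$mean_area, sz2$total_area / 2)
})

test_that("extent and density: filled square, two far squares (hull oracle)", {
  # single filled square footprint: extent = area, density = 1
  m <- array(FALSE, c(10, 10, 4)); m[3:6, 3:6, 1] <- TRUE
  b <- make_bundle(m)
  ed <- compute_extent_density(b, label_instances(m))
  expect_equal(ed$extent_area, 16 * 0.03^2)
  expect_equal(ed$density, 1)

  # two unit-pixel squares at opposite corners
  m2 <- array(FALSE, c(20, 20, 2))
  m2[1:2, 1:2, 1] <- TRUE; m2[19:20, 19:20, 1] <- TRUE
  b2 <- make_bundle(m2)
  ed2 <- compute_extent_density(b2, label_instances(m2))
  ij <- which(apply(m2, c(1, 2), any), arr.ind = TRUE)
  want <- oracle_hull_area((ij[, 1] - 0.5) * 0.03, (ij[, 2] - 0.5) * 0.03,
                           20 * 0.03, 20 * 0.03, step = 0.003)
  expect_equal(ed2$extent_area, want, tolerance = 0.03)
  expect_equal(ed2$density, 8 * 0.03^2 / ed2$extent_area)

  # no drusen
  ed0 <- compute_extent_density(make_bundle(array(FALSE, c(4, 4, 2))),
                                label_instances(array(FALSE, c(4, 4, 2))))
  expect_equal(ed0$extent_area, 0)
  expect_equal(ed0$density, 0)
})

test_that("height and slope: planar ramp recovers its gradient", {
  nx <- 20; ny <- 20
  m <- array(FALSE, c(nx, ny, 4)); m[, , 1] <- TRUE
  s <- 0.8                                     # mm per mm along x
  dx <- 0.03
  elev <- matrix(rep((seq_len(nx) - 0.5) * dx * s, ny), nx, ny)
  b <- make_bundle(m, elev = elev)
  hs <- compute_height_slope(b, label_instances(m))
  expect_equal(hs$avg_slope, s, tolerance = 1e-9)
  expect_equal(hs$max_height, max(elev))

  flat <- compute_height_slope(make_bundle(m), label_instances(m))
  expect_equal(flat$avg_slope, 0)
  expect_equal(flat$max_height, 0)

  none <- compute_height_slope(make_bundle(array(FALSE, c(4, 4, 2))),
                               label_instances(array(FALSE, c(4, 4, 2))))
  expect_equal(unlist(none), c(max_height = 0, avg_slope = 0))
})

test_that("reflectivity normalization: percentiles, affine invariance", {
  set.seed(3)
  v <- array(runif(8000, 0, 100), c(20, 20, 20))
  nv <- normalize_reflectivity(v)
  q <- quantile(nv, c(0.05, 0.95), names = FALSE)
  expect_equal(q[1], 0, tolerance = 1e-6)
  expect_equal(q[2], 1, tolerance = 1e-6)
  expect_equal(normalize_reflectivity(3.7 * v + 11), nv, tolerance = 1e-12)
  expect_error(normalize_reflectivity(array(5, c(3, 3, 3))), "degenerate")
  # value mid-way between the percentiles maps near 0.5 for uniform data
  expect_equal(mean(nv[abs(v - 50) < 0.5]), 0.5, tolerance = 0.02)
})

test_that("reflectivity stats equal the direct formula", {
  vals <- c(0.2, 0.4, 0.9, 0.1, 0.65)
  v <- array(0, c(5, 1, 1)); v[, 1, 1] <- vals
  m <- array(TRUE, c(5, 1, 1))
  rs <- compute_reflectivity_stats(v, m)
  expect_equal(rs$mean_reflectivity, mean(vals))
  expect_equal(rs$std_reflectivity, sqrt(mean((vals - mean(vals))^2)))
  expect_false(rs$undefined)

  same <- compute_reflectivity_stats(array(0.3, c(2, 2, 2)),
                                     array(TRUE, c(2, 2, 2)))
  expect_equal(same$std_reflectivity, 0)

  none <- compute_reflectivity_stats(v, array(FALSE, c(5, 1, 1)))
  expect_true(none$undefined)
  expect_equal(none$mean_reflectivity, 0)
})

test_that("regional features: radius semantics and per-pixel oracle", {
  ps <- phantom_spec(druse_list = list(list(center_xy_mm = c(3, 3),
                                            radius_mm = 0.2,
                                            peak_height_mm = 0.15)))
  b <- generate_phantom(ps)           # fovea at (3, 3): fully inside 3 mm
  lab <- label_instances(b$drusen_mask)
  fv <- assemble_features(b)
  expect_equal(fv[["area_3mm"]], fv[["total_area"]])
  expect_equal(fv[["volume_5mm"]], fv[["total_volume"]])

  # druse centred 4 mm from the fovea: outside 3 mm, inside 5 mm
  ps2 <- phantom_spec(druse_list = list(list(center_xy_mm = c(1, 3),
                                             radius_mm = 0.2,
                                             peak_height_mm = 0.15)),
                      fovea_center_mm = c(5, 3))
  fv2 <- assemble_features(generate_phantom(ps2))
  expect_equal(fv2[["area_3mm"]], 0)
  expect_equal(fv2[["area_5mm"]], fv2[["total_area"]])

  # druse straddling the 3 mm circle: compare against per-pixel counting
  ps3 <- phantom_spec(druse_list = list(list(center_xy_mm = c(3, 3),
                                             radius_mm = 0.4,
                                             peak_height_mm = 0.2)),
                      fovea_center_mm = c(3 - 2.8, 3))
  b3 <- generate_phantom(ps3)
  lab3 <- label_instances(b3$drusen_mask)
  r3 <- compute_regional(b3, lab3, 3)
  foot <- apply(b3$drusen_mask, c(1, 2), any)
  ij <- which(foot, arr.ind = TRUE)
  dd <- sqrt(((ij[, 1] - 0.5) * b3$voxel_size_mm[1] - b3$fovea_center_mm[1])^2 +
               ((ij[, 2] - 0.5) * b3$voxel_size_mm[2] - b3$fovea_center_mm[2])^2)
  expect_equal(r3$area, sum(dd <= 3) * prod(b3$voxel_size_mm[1:2]))
  total3 <- sum(foot) * prod(b3$voxel_size_mm[1:2])
  expect_true(r3$area > 0 && r3$area < total3)   # genuinely straddles
})

test_that("assemble_features: invariants on phantoms and fuzzed masks", {
  check_inv <- function(fv) {
    sizes <- c("mean_volume", "total_volume", "mean_area", "total_area",
               "extent_area", "area_3mm", "area_5mm", "volume_3mm",
               "volume_5mm")
    expect_true(all(fv[sizes] >= 0))
    expect_lte(fv[["area_3mm"]], fv[["area_5mm"]] + 1e-12)
    expect_lte(fv[["area_5mm"]], fv[["total_area"]] + 1e-12)
    expect_lte(fv[["volume_3mm"]], fv[["volume_5mm"]] + 1e-12)
    expect_lte(fv[["volume_5mm"]], fv[["total_volume"]] + 1e-12)
    if (fv[["n_drusen"]] > 0) {
      expect_lte(fv[["total_area"]], fv[["extent_area"]] + 1e-12)
      expect_gt(fv[["density"]], 0)
      expect_lte(fv[["density"]], 1)
    } else {
      expect_true(all(fv == 0))
    }
  }
  set.seed(5)
  for (i in 1:6) {
    m <- array(runif(8 * 8 * 6) < 0.2, c(8, 8, 6))
    elev <- matrix(runif(64, 0, 0.3), 8, 8)
    elev[!apply(m, c(1, 2), any)] <- 0
    b <- make_bundle(m, elev = elev)
    check_inv(assemble_features(b))
  }
  ps <- phantom_spec(druse_list = list(
    list(center_xy_mm = c(2, 2), radius_mm = 0.25, peak_height_mm = 0.2),
    list(center_xy_mm = c(4, 4), radius_mm = 0.35, peak_height_mm = 0.15)
  ))
  check_inv(assemble_features(generate_phantom(ps)))
})

test_that("assemble_features: empty mask, cirrus pass-through, monotonicity", {
  b0 <- make_bundle(array(FALSE, c(6, 6, 4)))
  fv0 <- assemble_features(b0)
  expect_equal(unname(fv0[feature_names(FALSE)]), rep(0, 15))
  expect_true(attr(fv0, "undefined"))

  ps <- phantom_spec(druse_list = list(list(center_xy_mm = c(3, 3),
                                            radius_mm = 0.3,
                                            peak_height_mm = 0.2)))
  b <- generate_phantom(ps)
  fv <- assemble_features(b, cirrus = list(total_volume_cirrus = 0.123))
  expect_equal(fv[["total_volume_cirrus"]], 0.123)       # passed through
  expect_equal(fv[["total_area_cirrus"]], fv[["total_area"]])  # mirrored

  # adding voxels never decreases the totals
  b2 <- b
  b2$drusen_mask[1:3, 1:3, 1:2] <- TRUE
  fv2 <- assemble_features(b2)
  expect_gte(fv2[["total_volume"]], fv[["total_volume"]])
  expect_gte(fv2[["total_area"]], fv[["total_area"]])
  expect_gte(fv2[["extent_area"]], fv[["extent_area"]])

  # determinism: no RNG involved
  expect_identical(assemble_features(b), assemble_features(b))
})

test_that("feature values are stable under en-face voxel-size doubling", {
  fv <- lapply(c(128L, 64L), function(g) {
    ps <- phantom_spec(grid_shape = c(g, g, 96L),
                       druse_list = list(list(center_xy_mm = c(3, 3),
                                              radius_mm = 0.4,
                                              peak_height_mm = 0.25)))
    assemble_features(generate_phantom(ps))
  })
  for (f in c("total_volume", "total_area", "max_height")) {
    expect_equal(fv[[1]][[f]], fv[[2]][[f]], tolerance = 0.1)
  }
})

test_that("average_session is the element-wise mean and validates identity", {
  ps <- phantom_spec(druse_list = list(list(center_xy_mm = c(3, 3),
                                            radius_mm = 0.3,
                                            peak_height_mm = 0.2)))
  v1 <- assemble_features(generate_phantom(ps, eye_id = "E", session_date = "d"))
  expect_equal(as.numeric(average_session(list(v1))),
               as.numeric(v1[feature_names(TRUE)]))

  v2 <- v1; v2[] <- as.numeric(v1) * 3
  attr(v2, "eye_id") <- "E"; attr(v2, "session_date") <- "d"
  avg <- average_session(list(v1, v2))
  expect_equal(as.numeric(avg), as.numeric(v1[feature_names(TRUE)]) * 2)

  # three hand-listed vectors vs the arithmetic oracle
  mk <- function(x) {
    v <- stats::setNames(rep(x, 21), feature_names(TRUE))
    attr(v, "eye_id") <- "E"; attr(v, "session_date") <- "d"
    v
  }
  expect_equal(as.numeric(average_session(list(mk(1), mk(2), mk(6)))),
               rep(3, 21))

  v3 <- v1; attr(v3, "session_date") <- "other"
  expect_error(average_session(list(v1, v3)), "single eye and date")
})
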