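mini_vol <- function(vals, spacing = 0.5) {
  hu_volume(array(vals, dim = c(length(vals), 1, 1)), spacing)
}

test_that("HU threshold window is inclusive on both bounds", {
  v <- mini_vol(c(-1000, -430, -429, 0, -1001, -700))
  m <- threshold_airway(v)
  expect_identical(as.vector(m$mask), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_error(threshold_airway(mini_vol(c(0, 100, 50))), "no air")
  expect_error(threshold_airway(mini_vol(c(-500)), lo = -430, hi = -1000),
               "below")
})

test_that("noise-free phantom thresholds to the exact ground-truth airway", {
  ph <- generate_phantom(phantom_params(noise_sd = 0))
  m <- threshold_airway(ph$volume)
  expect_identical(m$mask, ph$truth$airway)
})

test_that("isolated-region removal keeps only inlet-to-outlet components", {
  ph <- generate_phantom(phantom_params(sinus_pocket = TRUE))
  lm <- ph$truth$landmarks
  m <- threshold_airway(ph$volume)
  m2 <- remove_isolated_regions(m, lm$nostril_plane, lm$nasopharynx_plane)
  # pocket removed, airway kept exactly
  expect_identical(m2$mask, ph$truth$airway)
  expect_gt(m2$provenance$isolated_removed$voxels, 0)
  # a single spanning component passes through unchanged
  m3 <- remove_isolated_regions(m2, lm$nostril_plane, lm$nasopharynx_plane)
  expect_identical(m3$mask, m2$mask)
  # no spanning component -> occlusion error
  blocked <- m2
  blocked$mask[, 40, ] <- FALSE
  expect_error(remove_isolated_regions(blocked, lm$nostril_plane,
                                       lm$nasopharynx_plane), "occluded")
})

test_that("segmentation chain is idempotent", {
  ph <- generate_phantom(phantom_params(sinus_pocket = TRUE, seed = 11))
  lm <- ph$truth$landmarks
  run <- function(m) {
    m <- remove_isolated_regions(m, lm$nostril_plane, lm$nasopharynx_plane)
    crop_domain(m, lm$nostril_plane, lm$nasopharynx_plane, 10)
  }
  once <- run(threshold_airway(ph$volume))
  # re-running the cleanup on the already clean, cropped mask changes nothing
  # (the cropped mask keeps the original coordinate frame)
  twice <- remove_isolated_regions(once, lm$nostril_plane,
                                   lm$nasopharynx_plane + 10)
  expect_identical(twice$mask, once$mask)
})

test_that("domain cropping appends the extruded outlet duct", {
  ph <- generate_phantom(phantom_params(noise_sd = 0))
  lm <- ph$truth$landmarks
  m <- threshold_airway(ph$volume)
  c0 <- crop_domain(m, lm$nostril_plane, lm$nasopharynx_plane, 0)
  expect_equal(dim(c0$mask)[2], round(ph$params$length / ph$params$spacing))
  c50 <- crop_domain(m, lm$nostril_plane, lm$nasopharynx_plane, 50)
  expect_equal(dim(c50$mask)[2], dim(c0$mask)[2] + round(50 / m$spacing))
  # extruded cross-section area equals the nasopharynx-plane airway area
  np_slice <- sum(c0$mask[, dim(c0$mask)[2], ])
  ext_counts <- apply(c50$mask[, (dim(c0$mask)[2] + 1):dim(c50$mask)[2], ,
                               drop = FALSE], 2, sum)
  expect_true(all(ext_counts == np_slice))
  expect_error(crop_domain(m, 55, 0), "anterior")
})

test_that("volumetry is exact, additive and axis-permutation invariant", {
  one <- rhinoflow:::airway_mask(array(TRUE, c(1, 1, 1)), 0.2)
  expect_equal(measure_volume(one), 8e-6)
  blk <- rhinoflow:::airway_mask(array(TRUE, c(10, 10, 10)), 1)
  expect_equal(measure_volume(blk), 1)
  ph <- generate_phantom(phantom_params())
  m <- rhinoflow:::airway_mask(ph$truth$airway, ph$params$spacing)
  tot <- measure_volume(m)
  expect_equal(measure_volume(m, y_range = c(0, 30)) +
                 measure_volume(m, y_range = c(30 + 1e-9, 100)), tot)
  mp <- rhinoflow:::airway_mask(aperm(ph$truth$airway, c(3, 2, 1)),
                                ph$params$spacing)
  expect_equal(measure_volume(mp), tot)
})

test_that("ROI-band volume grows with surgical reduction", {
  p <- phantom_params(noise_sd = 0)
  band <- p$turbinate_peak + c(5, 20)
  v <- sapply(c(0, 0.5, 1), function(r) {
    ph <- generate_phantom(p, reduction = r)
    measure_volume(rhinoflow:::airway_mask(ph$truth$airway, p$spacing),
                   y_range = band)
  })
  expect_true(all(diff(v) > 0))
})

test_that("surface extraction is closed, correctly sized and STL round-trips", {
  one <- rhinoflow:::airway_mask(array(TRUE, c(1, 1, 1)), 0.7)
  s <- extract_surface(one)
  expect_equal(sum(s$area), 6 * 0.7^2)
  expect_equal(nrow(s$triangles), 12)
  # watertight: every undirected edge shared by exactly two triangles
  edge_counts <- function(s) {
    e <- rbind(s$triangles[, c(1, 2)], s$triangles[, c(2, 3)],
               s$triangles[, c(3, 1)])
    table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_true(all(edge_counts(s) == 2))
  ph <- generate_phantom(phantom_params(seed = 2))
  sm <- extract_surface(rhinoflow:::airway_mask(ph$truth$airway,
                                                ph$params$spacing))
  expect_true(all(edge_counts(sm) == 2))
  # STL round trip, both flavours
  for (bin in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".stl")
    write_stl(s, f, binary = bin)
    back <- read_stl(f)
    expect_equal(nrow(back$triangles), nrow(s$triangles))
    expect_equal(sum(back$area), sum(s$area), tolerance = 1e-6)
    unlink(f)
  }
  expect_error(extract_surface(rhinoflow:::airway_mask(
    array(FALSE, c(2, 2, 2)), 1)), "empty")
})

test_that("voxel isosurface area bounds the smooth surface from above", {
  # stair-step bound checked on spheres of several radii
  for (r_mm in c(3, 5, 8)) {
    n <- ceiling(2 * r_mm / 0.5) + 4
    cc <- (n / 2 + 0.5) * 0.5
    ax <- (seq_len(n) - 0.5) * 0.5
    dist2 <- outer(outer((ax - cc)^2, (ax - cc)^2, "+"), (ax - cc)^2, "+")
    sph <- rhinoflow:::airway_mask(dist2 < r_mm^2, 0.5)
    s <- extract_surface(sph)
    expect_gte(sum(s$area), 4 * pi * r_mm^2)
  }
})

test_that("volumes survive a NIfTI write-read round trip", {
  ph <- generate_phantom(phantom_params(seed = 9))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  back <- read_volume(f)
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-6)
  expect_equal(back$values, ph$volume$values, tolerance = 1e-4,
               ignore_attr = TRUE)
  unlink(f)
})
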