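test_that("phantom generation is deterministic and validates parameters", {
  p <- phantom_params(noise_sd = 30, seed = 7)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$airway, b$truth$airway)
  expect_error(phantom_params(turbinate_amplitude = 6), "occlude")
  expect_error(phantom_params(spacing = 0), "spacing")
  expect_error(generate_phantom(p, reduction = 1.2), "\\[0, 1\\]")
})

test_that("noise-free unobstructed phantom has the analytic channel volume", {
  p <- phantom_params(noise_sd = 0, turbinate_amplitude = c(0, 0))
  ph <- generate_phantom(p)
  vol <- measure_volume(rhinoflow:::airway_mask(ph$truth$airway, p$spacing))
  # two channels plus the merged posterior segment where the septum is absent
  main <- 2 * p$channel_width * p$channel_height *
    (p$length - p$merge_length)
  merged <- (2 * p$channel_width + p$septum) * p$channel_height *
    p$merge_length
  expect_equal(vol, (main + merged) / 1000, tolerance = 1e-12)
})

test_that("sinus pocket stays disjoint from the main airway", {
  ph <- generate_phantom(phantom_params(sinus_pocket = TRUE, noise_sd = 0))
  expect_gt(sum(ph$truth$pocket), 0)
  expect_false(any(ph$truth$pocket & ph$truth$airway))
  # connected-component oracle: pocket and airway never share a label
  both <- ph$truth$pocket | ph$truth$airway
  lab <- rhinoflow:::.cc_label6(as.vector(both), dim(both))
  lab <- array(lab, dim(both))
  expect_length(intersect(unique(lab[ph$truth$pocket]),
                          unique(lab[ph$truth$airway])), 0)
})

test_that("virtual surgery scales the bump only inside the operated band", {
  p <- phantom_params(seed = 3)
  pre <- generate_phantom(p)
  expect_identical(apply_surgery(pre, 0)$volume$values, pre$volume$values)
  post <- apply_surgery(pre, 0.7)
  diffmask <- post$volume$values != pre$volume$values
  yc <- (seq_len(dim(diffmask)[2]) - 0.5) * p$spacing
  band <- p$turbinate_peak + c(5, 20)
  changed_slices <- which(apply(diffmask, 2, any))
  expect_true(all(yc[changed_slices] >= band[1] & yc[changed_slices] <= band[2]))
  expect_error(apply_surgery(pre, -0.1), "\\[0, 1\\]")
})

test_that("airway volume is monotone non-decreasing in the reduction fraction", {
  p <- phantom_params(noise_sd = 0)
  vols <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(r)
    sum(generate_phantom(p, reduction = r)$truth$airway))
  expect_true(all(diff(vols) >= 0))
  expect_gt(vols[5], vols[1])
})

test_that("full reduction restores the unobstructed band volume", {
  p <- phantom_params(noise_sd = 0)
  ph <- generate_phantom(p, reduction = 1)
  band <- p$turbinate_peak + c(5, 20)
  vol <- measure_volume(rhinoflow:::airway_mask(ph$truth$airway, p$spacing),
                        y_range = band)
  analytic <- 2 * p$channel_width * p$channel_height *
    (band[2] - band[1]) / 1000
  # half-voxel skin at most at the analytic boundaries
  expect_equal(vol, analytic, tolerance = 0.02)
})

test_that("cohort generation is reproducible and respects its contracts", {
  co1 <- generate_cohort(10, seed = 5)
  co2 <- generate_cohort(10, seed = 5)
  expect_identical(co1$subjects, co2$subjects)
  expect_error(generate_cohort(2), "at least 3")
  s <- co1$subjects
  expect_true(all(s$vas >= 0 & s$vas <= 10))
  expect_true(all(s$ghsi >= 0 & s$ghsi <= 100))
  expect_true(all(s$reduction >= 0 & s$reduction <= 1))
  expect_true(all(table(s$id) == 2))
})

test_that("uncoupled outcomes are uncorrelated with the geometric change", {
  n <- 400
  co <- generate_cohort(n, coupling_params(target_rho = 0), seed = 8)
  ch <- change_scores(co$subjects[, c("id", "timepoint", "vas",
                                      "force_surrogate")])
  rho <- spearman_cor(ch$vas, ch$force_surrogate)$rho
  expect_lt(abs(rho), 2 / sqrt(n))
})

test_that("the generator recovers a strong target coupling across seeds", {
  rhos <- sapply(1:50, function(s) {
    co <- generate_cohort(200, coupling_params(target_rho = 0.9), seed = s)
    ch <- change_scores(co$subjects[, c("id", "timepoint", "vas",
                                        "force_surrogate")])
    spearman_cor(ch$vas, ch$force_surrogate)$rho
  })
  expect_lt(abs(mean(rhos) - 0.9), 0.1)
})

test_that("the shear-force surrogate falls with surgical reduction", {
  p <- phantom_params()
  f <- sapply(c(0, 0.3, 0.6, 0.9), function(r)
    wall_force_surrogate(p, r = r, Q = 2.9e-4))
  expect_true(all(diff(f) < 0))
})
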