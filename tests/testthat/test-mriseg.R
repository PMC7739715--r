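test_that("body mask keeps the largest component and fills holes", {
  sl <- matrix(0, 60, 60)
  xg <- row(sl) - 30; yg <- col(sl) - 30
  disc <- xg^2 + yg^2 <= 20^2
  hole <- xg^2 + yg^2 <= 5^2
  img <- ifelse(disc & !hole, 800, 0)
  img[5, 5] <- 800                          # detached speck
  vol <- image_volume(img + matrix(rnorm(3600, 0, 5), 60, 60),
                      spacing_mm = c(1, 1, 1), modality = "MRI")
  bm <- body_mask(vol)$voxels[, , 1]
  expect_false(bm[5, 5] > 0)                # speck excluded
  expect_true(all(bm[hole] > 0))            # hole filled
  expect_true(all(bm[disc] > 0))
})

test_that("bias correction is near-identity on bias-free input and recovers a known field", {
  ph <- annulus_phantom(n_slices = 1)
  out <- correct_bias(ph$mri)
  fg <- ph$truth$labels$voxels > 0
  rms <- sqrt(mean((out$voxels[fg] - ph$mri$voxels[fg])^2)) /
    mean(ph$mri$voxels[fg])
  expect_lt(rms, 0.005)

  # multiply a known degree-2 field onto the phantom: corrected/truth ratio
  # should be nearly constant over the foreground
  d <- dim(ph$mri$voxels)
  u <- (row(matrix(0, d[1], d[2])) - d[1] / 2) / d[1]
  v <- (col(matrix(0, d[1], d[2])) - d[2] / 2) / d[2]
  field <- 1 + 0.3 * (u + 0.5 * v + u * v - u^2)
  biased <- ph$mri
  biased$voxels[, , 1] <- ph$mri$voxels[, , 1] * field
  corr <- correct_bias(biased)
  ratio <- corr$voxels[fg] / ph$mri$voxels[fg]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})

test_that("bias correction preserves a constant foreground and rejects empty input", {
  const <- image_volume(matrix(500, 40, 40), spacing_mm = c(1, 1, 1),
                        modality = "MRI")
  fg <- image_volume(matrix(1L, 40, 40), spacing_mm = c(1, 1, 1),
                     modality = "LABEL")
  out <- correct_bias(const, foreground = fg)
  expect_equal(mean(out$voxels), 500, tolerance = 1e-8)
  empty <- image_volume(matrix(0L, 40, 40), spacing_mm = c(1, 1, 1),
                        modality = "LABEL")
  expect_error(correct_bias(const, foreground = empty), "empty foreground")
})

test_that("unrolling a rotationally symmetric image gives identical angle columns", {
  # smooth radial profile (Gaussian ring) so the only column-to-column
  # variation is interpolation error
  n <- 161
  ctr <- (n + 1) / 2
  x <- (seq_len(n) - ctr)
  r <- sqrt(outer(x^2, x^2, `+`))
  img <- 1000 * exp(-((r - 40) / 8)^2)
  pol <- unroll_slice(img, c(ctr, ctr), spacing_mm = c(1, 1))
  s <- pol$samples
  ref <- colMeans(s)
  col_rms <- sqrt(rowMeans(sweep(s, 2, ref)^2))
  expect_lt(max(col_rms), 0.01 * max(s))
})

test_that("unroll/re-roll roundtrip preserves a binary annulus", {
  ph <- annulus_phantom()
  truth_sat <- ph$truth$labels$voxels[, , 1] == 1
  up <- unroll_phantom_slice(ph)
  b <- detect_sat_boundaries(up$pol, up$pol_mask, delta = 2)
  rerolled <- sat_mask_from_boundaries(b$outer, b$inner, up$pol)
  expect_gte(dice(rerolled, truth_sat), 0.98)
})

test_that("boundary radii are stable when the angular resolution doubles", {
  ph <- annulus_phantom()
  up1 <- unroll_phantom_slice(ph, n_angles = 180)
  up2 <- unroll_phantom_slice(ph, n_angles = 360)
  b1 <- detect_sat_boundaries(up1$pol, up1$pol_mask, delta = 2)
  b2 <- detect_sat_boundaries(up2$pol, up2$pol_mask, delta = 2)
  r1 <- boundary_radius_mm(b1$inner)
  r2 <- boundary_radius_mm(b2$inner)[seq(1, 360, by = 2)]
  expect_lt(max(abs(r1 - r2)), 0.5 * up1$pol$radial_step_mm)
})

test_that("noiseless annulus boundaries localise to the true radii", {
  ph <- annulus_phantom(inner = 80, outer = 95)
  up <- unroll_phantom_slice(ph)
  b <- detect_sat_boundaries(up$pol, up$pol_mask, delta = 2)
  step <- up$pol$radial_step_mm
  expect_lt(max(abs(boundary_radius_mm(b$inner) - 80)), step + 1e-9)
  expect_lt(max(abs(boundary_radius_mm(b$outer) - 95)), step + 1e-9)
  # closure invariant holds by construction
  expect_lte(abs(b$inner$radius_idx[1] - b$inner$radius_idx[360]), 2)
  expect_lte(abs(b$outer$radius_idx[1] - b$outer$radius_idx[360]), 2)
})

test_that("delta = 0 on a symmetric annulus yields constant-radius curves", {
  ph <- annulus_phantom()
  up <- unroll_phantom_slice(ph)
  b <- detect_sat_boundaries(up$pol, up$pol_mask, delta = 0, refine = FALSE)
  expect_equal(length(unique(b$inner$radius_idx)), 1L)
  expect_equal(length(unique(b$outer$radius_idx)), 1L)
})

test_that("minimal circular path matches brute-force enumeration on small grids", {
  set.seed(42)
  for (delta in c(1L, 2L)) {
    for (rep in 1:5) {
      cost <- matrix(runif(8 * 6), 8, 6)
      dp <- min_circular_path(cost, delta)
      bf <- brute_force_circular_path(cost, delta)
      expect_equal(dp$cost, bf$cost, tolerance = 1e-12)
      expect_lte(abs(dp$radius_idx[1] - dp$radius_idx[8]), delta)
    }
  }
})

test_that("infeasible smoothness constraints are reported", {
  cost <- matrix(Inf, 6, 5)
  cost[, 3] <- c(1, Inf, 1, 1, 1, 1)
  expect_error(min_circular_path(cost, 0L), "delta")
})

test_that("sat mask geometry behaves for thin rings and rejects degenerate input", {
  ph <- annulus_phantom()
  up <- unroll_phantom_slice(ph)
  step <- up$pol$radial_step_mm
  n_a <- nrow(up$pol$samples)
  outer_c <- boundary_curve(rep(121L, n_a), step, 2)
  inner_c <- boundary_curve(rep(118L, n_a), step, 2)
  ring <- sat_mask_from_boundaries(outer_c, inner_c, up$pol)
  r_mid <- (119.5 - 1) * step
  expected_area <- 2 * pi * r_mid * (3 * step)
  got_area <- sum(ring) * prod(up$pol$spacing_mm)
  expect_lt(abs(got_area - expected_area) / expected_area, 0.1)
  # crossing curves rejected
  expect_error(sat_mask_from_boundaries(inner_c, outer_c, up$pol), "strictly inside")
})

test_that("k-means threshold rules behave as documented", {
  # k distinct values: each its own cluster; median centre is the middle value
  x <- rep(c(10, 20, 30, 40, 50), each = 100)
  expect_equal(kmeans_threshold(x, method = "median_center"), 30)
  # translation equivariance (default gap rule)
  set.seed(1)
  y <- c(rnorm(500, 100, 10), rnorm(200, 300, 15))
  t0 <- kmeans_threshold(y, seed = 5)
  t1 <- kmeans_threshold(y + 37, seed = 5)
  expect_equal(t1 - t0, 37, tolerance = 1e-8)
  expect_error(kmeans_threshold(rep(1, 100)), "distinct")
})

test_that("the threshold separates muscle from fat across seeded draws", {
  set.seed(11)
  hits <- replicate(100, {
    x <- c(rnorm(8000, 100, 10), rnorm(2000, 300, 15))
    th <- kmeans_threshold(x, seed = sample.int(1e6, 1))
    th > qnorm(0.99, 100, 10) && th < qnorm(0.01, 300, 15)
  })
  expect_gte(sum(hits), 95)
})

test_that("internal fat segmentation respects threshold and exclusions", {
  spec <- phantom_spec(n_slices = 2, internal_fat_fraction = 0.1,
                       organ_layout = list(), seed = 5)
  ph <- generate_phantom(spec, "abdomen")
  lab <- ph$truth$labels$voxels
  internal <- lab == 2 | lab == 3
  fat <- segment_internal_fat(ph$mri, internal, threshold = 700)
  expect_gte(dice(fat, lab == 3), 0.95)
  # threshold above the maximum -> empty depot
  none <- segment_internal_fat(ph$mri, internal,
                               threshold = max(ph$mri$voxels) + 1)
  expect_equal(sum(none), 0)
  # excluding the whole compartment -> empty depot
  none2 <- segment_internal_fat(ph$mri, internal, threshold = 700,
                                exclusion_masks = list(internal))
  expect_equal(sum(none2), 0)
  # SAT overlap is inconsistent input
  expect_error(segment_internal_fat(ph$mri, internal, 700,
                                    sat_mask = internal), "overlaps")
})

test_that("anatomical slice selection applies the delimiter rules", {
  rng <- select_slices(list(th11_th12_disc = 3, iliac_crest_first = 10),
                       "visceral")
  expect_equal(c(rng$first, rng$last), c(3, 9))
  expect_equal(rng$n_slices_analyzed, 7)
  expect_error(select_slices(list(th11_th12_disc = 9, iliac_crest_first = 3),
                             "visceral"), "below")
  expect_error(select_slices(list(th11_th12_disc = 3), "visceral"),
               "iliac_crest_first")
  fem <- select_slices(list(gluteal_lower = 2, patella_first = 12),
                       "femoral_sat", n_slices = 20)
  expect_equal(fem$n_slices_analyzed, 10)
})

test_that("mask-to-mass conversion follows the density and spacing exactly", {
  expect_equal(mask_to_mass(array(FALSE, c(4, 4, 2)), c(1, 1, 1))$mass_kg, 0)
  m <- array(FALSE, c(50, 50, 40))
  m[seq_len(100000)] <- TRUE
  dm <- mask_to_mass(m, c(1.1719, 1.1719, 7.2))
  expect_equal(dm$volume_L, 100000 * 1.1719^2 * 7.2 * 1e-6, tolerance = 1e-12)
  expect_equal(dm$mass_kg, dm$volume_L * 0.9, tolerance = 1e-12)
  expect_equal(round(dm$mass_kg, 4), 0.8899)
  # doubling the slice pitch doubles the mass
  dm2 <- mask_to_mass(m, c(1.1719, 1.1719, 14.4))
  expect_equal(dm2$mass_kg, 2 * dm$mass_kg)
})

test_that("segmentation is invariant to global intensity scaling and keeps depots disjoint", {
  spec <- phantom_spec(n_slices = 2, noise_sd = 50, bias_amplitude = 0.15,
                       internal_fat_fraction = 0.08, seed = 21)
  ph <- generate_phantom(spec, "abdomen")
  liver <- ph$truth$labels$voxels == 4
  seg1 <- segment_adipose_mri(ph$mri, exclusion_masks = list(liver = liver),
                              seed = 2)
  scaled <- ph$mri
  scaled$voxels <- scaled$voxels * 3.7
  seg2 <- segment_adipose_mri(scaled, exclusion_masks = list(liver = liver),
                              seed = 2)
  expect_equal(seg1$masses$sat$mass_kg, seg2$masses$sat$mass_kg,
               tolerance = 0.02)
  expect_equal(seg1$masses$internal_fat$mass_kg,
               seg2$masses$internal_fat$mass_kg, tolerance = 0.02)
  # depot masks disjoint
  expect_equal(sum(seg1$sat_mask & seg1$internal_fat_mask), 0)
})
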