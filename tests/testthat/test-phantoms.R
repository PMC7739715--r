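test_that("phantom geometry yields the exact SAT annulus and the mass identity", {
  ph <- annulus_phantom(n_slices = 10, inner = 80, outer = 95)
  labels <- ph$truth$labels$voxels
  sp <- ph$truth$labels$spacing_mm

  # SAT label is exactly the annulus between the two radii (pixel centres)
  d <- dim(labels)
  ctr <- (d[1] + 1) / 2
  x <- (seq_len(d[1]) - ctr) * sp[1]
  r <- sqrt(outer(x^2, x^2, `+`))
  expected_sat <- r > 80 & r <= 95
  expect_true(all((labels[, , 1] == 1) == expected_sat))

  # mass identity: count x voxel volume x 0.9 kg/L, exactly
  n_sat <- sum(labels == 1)
  vox_L <- prod(sp) * 1e-6
  expect_identical(ph$truth$depot_masses_kg[["sat"]], n_sat * vox_L * 0.9)

  # hand arithmetic on the voxel volume itself
  expect_equal(vox_L, 1.1719^2 * 7.2 * 1e-6)
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(n_slices = 2, noise_sd = 40, bias_amplitude = 0.2,
                       internal_fat_fraction = 0.1, seed = 123)
  a <- generate_phantom(spec, "abdomen")
  b <- generate_phantom(spec, "abdomen")
  expect_identical(a$mri$voxels, b$mri$voxels)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$truth$depot_masses_kg, b$truth$depot_masses_kg)
})

test_that("CT phantom puts fat in [-150, -50] HU and non-fat outside", {
  spec <- phantom_spec(n_slices = 2, internal_fat_fraction = 0.1, seed = 2)
  ph <- generate_phantom(spec, "abdomen")
  lab <- ph$truth$labels$voxels
  fat <- lab == 1 | lab == 3 | lab == 5
  expect_true(all(ph$ct$voxels[fat] >= -150 & ph$ct$voxels[fat] <= -50))
  expect_true(all(ph$ct$voxels[!fat] < -150 | ph$ct$voxels[!fat] > -50))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(body_radius_mm = -5), "positive")
  expect_error(phantom_spec(sat_thickness_mm = 200, body_radius_mm = 95),
               "smaller than the body radius")
  expect_error(phantom_spec(internal_fat_fraction = 1.3), "\\[0, 1\\]")
})

test_that("input function AUC matches fine-grid quadrature and closed forms", {
  inp <- default_input()
  tfine <- seq(0, 60, by = 0.01)
  quad <- pracma::trapz(tfine, input_function_at(inp, tfine))
  expect_lt(abs(input_function_auc(inp, 60) - quad) / quad, 0.001)

  # all coefficients zero -> zero curve, zero AUC
  z <- simulate_input_function(list(A = c(0, 0, 0), lambda = c(1, 1, 1)),
                               times_min = seq(0, 10, 1))
  expect_true(all(z$cp_kBq_per_ml == 0))
  expect_identical(input_function_auc(z, 10), 0)

  # constant-plasma mode: AUC(0, T) = c * T
  cinp <- simulate_input_function(list(value = 2.5), seq(0, 30, 1),
                                  family = "constant")
  expect_equal(input_function_auc(cinp, 30), 2.5 * 30)
})

test_that("input function has a single early peak followed by monotone decay", {
  inp <- default_input()
  t <- seq(0, 60, by = 0.05)
  cp <- input_function_at(inp, t)
  pk <- which.max(cp)
  expect_lt(t[pk], 2)                    # peak within the first 2 minutes
  late <- cp[t >= 5]
  expect_true(all(diff(late) <= 1e-9))   # monotone decay after washout
  expect_true(all(cp >= 0))
  expect_error(simulate_input_function(times_min = c(0, 2, 1)), "increasing")
})

test_that("simulated tissue curves reproduce the closed-form constant-input solution", {
  p <- kinetic_params(0.05, 0.25, 0.06, Vb = 0)
  cinp <- simulate_input_function(list(value = 1), seq(0, 60, 0.5), "constant")
  fc <- tissue_curve_2tcm(cinp, p, 60)
  cf <- tissue_curve_2tcm_constant_cp(p, 1, fc$t)
  idx <- fc$t >= 0.5
  expect_lt(max(abs(fc$ct[idx] - cf[idx]) / cf[idx]), 0.005)
})

test_that("degenerate kinetic parameter sets behave as the model dictates", {
  sched <- default_schedule()
  inp <- default_input()
  # K1 = 0, Vb = 0 -> all-zero tissue curve
  z <- simulate_tissue_tac(inp, kinetic_params(0, 0.2, 0.05, 0), sched)
  expect_true(all(z$activity_kBq_per_ml == 0))
  # k3 = 0 -> no trapping, Patlak slope ~ 0
  tc <- simulate_tissue_tac(inp, kinetic_params(0.05, 0.25, 0, 0), sched)
  pk <- patlak_ki(tc, inp, t_star_min = 30)
  expect_lt(abs(pk$ki), 1e-4)
  # negative rates rejected
  expect_error(kinetic_params(-0.1, 0.2, 0.05), "non-negative")
})

test_that("noiseless TAC simulation is deterministic and frame-averaged", {
  sched <- default_schedule()
  inp <- default_input()
  p <- kinetic_params(0.05, 0.25, 0.06, 0.03)
  a <- simulate_tissue_tac(inp, p, sched)
  b <- simulate_tissue_tac(inp, p, sched)
  expect_identical(a$activity_kBq_per_ml, b$activity_kBq_per_ml)
  # frame averages of the late, nearly linear segment sit between the
  # endpoint values of each frame
  fine <- tissue_curve_2tcm(inp, p, 60)
  i <- 26
  lo <- min(fine$ct[fine$t >= sched$start_s[i] / 60 &
                    fine$t <= (sched$start_s[i] + sched$duration_s[i]) / 60])
  hi <- max(fine$ct[fine$t >= sched$start_s[i] / 60 &
                    fine$t <= (sched$start_s[i] + sched$duration_s[i]) / 60])
  expect_gte(a$activity_kBq_per_ml[i], lo)
  expect_lte(a$activity_kBq_per_ml[i], hi)
})

test_that("cohort simulation honours exact effects when noise is off", {
  sp <- cohort_spec(n_per_group = 5, within_subject_cv = 0,
                    time_effect = c(SAT = 0.96, VAT = 0.94), seed = 3)
  tab <- simulate_cohort(sp)
  w <- reshape(tab[tab$outcome == "SAT", c("participant_id", "group", "time", "value")],
               idvar = c("participant_id", "group"), timevar = "time",
               direction = "wide")
  expect_equal(w$value.followup / w$value.baseline, rep(0.96, 10))
})

test_that("cohort follow-up/baseline ratio converges to the simulated time effect", {
  sp <- cohort_spec(n_per_group = 5000, seed = 9)
  tab <- simulate_cohort(sp)
  vat <- tab[tab$outcome == "VAT", c("participant_id", "group", "time", "value")]
  w <- reshape(vat, idvar = c("participant_id", "group"), timevar = "time",
               direction = "wide")
  ratio <- mean(w$value.followup / w$value.baseline)
  expect_lt(abs(ratio - 0.94) / 0.94, 0.005)
})

test_that("cohort simulation is seed-reproducible and rejects tiny groups", {
  expect_error(cohort_spec(n_per_group = 1), "at least 2")
  a <- simulate_cohort(cohort_spec(seed = 77))
  b <- simulate_cohort(cohort_spec(seed = 77))
  expect_identical(a, b)
})
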