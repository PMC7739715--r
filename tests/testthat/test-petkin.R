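test_that("frame schedules are contiguous and match the acquisition pattern", {
  s <- build_frame_schedule(list(c(12, 10), c(4, 120), c(10, 300)))
  expect_length(s$start_s, 26)
  expect_equal(sum(s$duration_s), 3600)
  expect_equal(s$start_s[-1], (s$start_s + s$duration_s)[-26])
  one <- build_frame_schedule(list(c(1, 60)))
  expect_equal(c(one$start_s, one$duration_s), c(0, 60))
  expect_error(build_frame_schedule(list()), "empty")
  expect_error(build_frame_schedule(list(c(0, 10))), "positive")
})

test_that("decay correction uses exp(lambda t_mid) and round-trips exactly", {
  # one frame centred at t = 0, one at one half-life
  sched <- build_frame_schedule(list(c(1, 2 * 109.77 * 60)))
  tc <- tac(sched, 1, "none")
  corrected <- decay_correct(tc, direction = "apply")
  expect_equal(corrected$activity_kBq_per_ml, 2, tolerance = 1e-9)

  s26 <- build_frame_schedule()
  raw <- tac(s26, runif(26, 0.5, 10), "none")
  back <- decay_correct(decay_correct(raw, direction = "apply"),
                        direction = "remove")
  expect_lt(max(abs(back$activity_kBq_per_ml - raw$activity_kBq_per_ml) /
                raw$activity_kBq_per_ml), 1e-12)
  expect_error(decay_correct(decay_correct(raw, direction = "apply"),
                             direction = "apply"), "already")
  expect_error(decay_correct(raw, direction = "remove"), "no decay correction")
})

test_that("IDIF extraction averages the VOI per frame", {
  sched <- build_frame_schedule(list(c(4, 60)))
  tm <- frame_mid_times_min(sched)
  cp <- c(10, 8, 6, 5)
  dims <- c(6, 6, 2)
  voi <- array(FALSE, dims); voi[2:3, 2:3, 1] <- TRUE
  frames <- lapply(seq_len(4), function(i) {
    v <- array(0, dims)
    v[voi] <- cp[i]
    image_volume(v, c(2, 2, 2), modality = "PET")
  })
  idif <- extract_idif(frames, voi, sched)
  expect_equal(idif$cp_kBq_per_ml, cp)
  expect_equal(idif$times_min, tm)
  # half the VOI on background halves the mean
  half <- voi; half[2, 2:3, 1] <- FALSE; half[5, 5, 1:2] <- TRUE
  idif2 <- extract_idif(frames, half, sched)
  expect_equal(idif2$cp_kBq_per_ml, cp / 2)
  # single-voxel VOI returns that voxel's TAC
  one <- array(FALSE, dims); one[2, 2, 1] <- TRUE
  expect_equal(extract_idif(frames, one, sched)$cp_kBq_per_ml, cp)
  expect_error(extract_idif(frames, array(FALSE, dims), sched), "empty")
})

test_that("connected-threshold CT segmentation respects HU window and connectivity", {
  vox <- array(50, c(14, 14, 4))
  vox[3:6, 3:6, 2:3] <- -100                # block A
  vox[10:12, 10:12, 2] <- -100              # block B, disconnected
  vox[7, 3, 2] <- -151                      # adjacent but out of range
  ct <- image_volume(vox, c(1, 1, 1), modality = "CT")
  voi <- segment_adipose_voi_ct(ct, c(4, 4, 2))
  expect_equal(sum(voi), 4 * 4 * 2)
  expect_false(any(voi[10:12, 10:12, ]))
  expect_false(voi[7, 3, 2])
  expect_error(segment_adipose_voi_ct(ct, c(1, 1, 1)), "outside adipose range")
})

test_that("two-pixel erosion shrinks a square by two on each side and is contained", {
  m <- matrix(0, 20, 20); m[6:15, 6:15] <- 1
  e <- erode_voi(m, 2)
  expect_equal(sum(e), 36)
  expect_equal(range(which(rowSums(e) > 0)), c(8, 13))
  expect_true(all(m[e == 1] == 1))
  # any mask: eroded subset of original
  set.seed(3)
  rnd <- matrix(runif(400) > 0.4, 20, 20)
  expect_true(all(!(erode_voi(rnd, 2) & !rnd)))
  # 3x3 square erodes away entirely
  m3 <- matrix(0, 9, 9); m3[4:6, 4:6] <- 1
  expect_equal(sum(erode_voi(m3, 2)), 0)
})

test_that("Patlak is exact in the constant-input linear limit", {
  sched <- build_frame_schedule(list(c(60, 60)))
  tm <- frame_mid_times_min(sched)
  inp <- input_function(c(0, tm), rep(1, length(tm) + 1), source = "simulated")
  y <- 0.01 * tm + 0.05
  tc <- tac(sched, y, "scan_start")
  fit <- patlak_ki(tc, inp, t_star_min = 20)
  expect_equal(fit$ki, 0.01, tolerance = 1e-9)
  expect_equal(fit$intercept_V0, 0.05, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("Patlak recovers Ki within 2 percent in the trapping-dominated regime", {
  sched <- default_schedule()
  inp <- default_input()
  for (K1 in c(0.02, 0.05, 0.1)) {
    for (k2 in c(0.1, 0.25, 0.5)) {
      for (k3 in c(0.06, 0.1)) {
        p <- kinetic_params(K1, k2, k3, 0)
        tc <- simulate_tissue_tac(inp, p, sched)
        fit <- patlak_ki(tc, inp, t_star_min = 20)
        expect_lt(abs(fit$ki - p$ki) / p$ki, 0.02)
      }
    }
  }
})

test_that("slow trapping (small k3) biases Patlak low, as the transient predicts", {
  # with k3 = 0.01 the equilibration term has not converged relative to the
  # tiny Ki by t* = 20 min on a 60-min scan, so the slope underestimates Ki;
  # verified against an ideal-sampling oracle (same sign and size)
  sched <- default_schedule()
  inp <- default_input()
  for (k2 in c(0.1, 0.25, 0.5)) {
    p <- kinetic_params(0.05, k2, 0.01, 0)
    tc <- simulate_tissue_tac(inp, p, sched)
    fit <- patlak_ki(tc, inp, t_star_min = 20)
    err <- (fit$ki - p$ki) / p$ki
    expect_lt(err, 0)        # systematic underestimate
    expect_gt(err, -0.10)    # but bounded
  }
})

test_that("compartmental fit recovers its own forward simulation", {
  sched <- default_schedule()
  inp <- default_input()
  p <- kinetic_params(0.05, 0.25, 0.06, 0.05)
  tc <- simulate_tissue_tac(inp, p, sched)
  fit <- fit_2tcm_irreversible(tc, inp, seed = 2)
  expect_lt(abs(fit$K1 - p$K1) / p$K1, 0.01)
  expect_lt(abs(fit$k2 - p$k2) / p$k2, 0.01)
  expect_lt(abs(fit$k3 - p$k3) / p$k3, 0.01)
  expect_lt(abs(fit$ki - p$ki) / p$ki, 0.005)
  expect_true(attr(fit, "converged"))
  # agreement with Patlak on noiseless data
  pat <- patlak_ki(tc, inp, 20)
  expect_lt(abs(fit$ki - pat$ki) / pat$ki, 0.03)
})

test_that("compartmental fit handles zero uptake and noisy replicates", {
  sched <- default_schedule()
  inp <- default_input()
  zero <- tac(sched, rep(0, 26), "scan_start")
  fit0 <- suppressWarnings(fit_2tcm_irreversible(zero, inp, seed = 1,
                                                 n_starts = 2))
  expect_lt(fit0$K1, 1e-4)
  # median Ki bias under 5% frame noise stays small
  p <- kinetic_params(0.05, 0.25, 0.06, 0.05)
  kis <- vapply(1:60, function(r) {
    tc <- simulate_tissue_tac(inp, p, sched, noise_sd = 0.05, seed = 1000 + r)
    fit <- tryCatch(fit_2tcm_irreversible(tc, inp, seed = r, n_starts = 2),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) NA_real_ else fit$ki
  }, numeric(1))
  expect_lt(abs(stats::median(kis, na.rm = TRUE) - p$ki) / p$ki, 0.03)
})

test_that("IDIF AUC extrapolation matches closed forms", {
  # constant curve: non-decaying tail falls back to constant extrapolation
  cinp <- input_function(seq(0, 60, 0.5), rep(2, 121), source = "simulated")
  expect_warning(a <- extrapolate_idif_auc(cinp, 70), "not decaying")
  expect_equal(a, 70 * 2, tolerance = 1e-9)
  # pure exponential matches the analytic integral
  lam <- 0.02
  t <- seq(0, 60, 0.25)
  einp <- input_function(t, 5 * exp(-lam * t), source = "simulated")
  auc <- extrapolate_idif_auc(einp, 70)
  expect_lt(abs(auc - 5 / lam * (1 - exp(-lam * 70))) /
            (5 / lam * (1 - exp(-lam * 70))), 0.005)
  # to_time at the last sample: plain trapezoid
  expect_equal(extrapolate_idif_auc(einp, 60),
               pracma::trapz(t, 5 * exp(-lam * t)), tolerance = 1e-12)
  expect_error(extrapolate_idif_auc(input_function(seq(0, 20, 1), rep(1, 21)), 70),
               "at least 30 min")
})

test_that("static estimated Ki is the activity/AUC ratio and bounds Patlak from above", {
  est <- estimated_ki_static(10, 1000)
  expect_equal(est$estimated_ki, 0.01)
  expect_equal(estimated_ki_static(0, 500)$estimated_ki, 0)
  expect_error(estimated_ki_static(10, 0), "positive")

  sched <- default_schedule()
  inp <- default_input(t_max = 60)
  for (vb in c(0, 0.03, 0.05)) {
    p <- kinetic_params(0.05, 0.25, 0.06, vb)
    tc <- simulate_tissue_tac(inp, p, sched)
    pat <- patlak_ki(tc, inp, 20)
    fine <- tissue_curve_2tcm(inp, p, 120)
    gaps <- vapply(c(70, 120), function(tmid) {
      act <- fine$ct[which.min(abs(fine$t - tmid))]
      est <- estimated_ki_static(act, extrapolate_idif_auc(inp, tmid), tmid)
      est$estimated_ki - pat$ki
    }, numeric(1))
    expect_true(all(gaps > 0))
    expect_lt(gaps[2], gaps[1])
  }
})

test_that("MRglucose follows the uptake equation exactly", {
  res <- mr_glucose(0.01, 5.0)
  expect_equal(res$mr_glucose, 1000 * 0.01 * 5 / (1.14 * 0.9), tolerance = 1e-12)
  expect_equal(round(res$mr_glucose, 2), 48.73)
  expect_equal(mr_glucose(0, 5)$mr_glucose, 0)
  expect_equal(mr_glucose(0.02, 5)$mr_glucose, 2 * res$mr_glucose,
               tolerance = 1e-12)
  expect_equal(mr_glucose(0.01, 10)$mr_glucose, 2 * res$mr_glucose,
               tolerance = 1e-12)
  expect_error(mr_glucose(-0.01, 5), "non-negative")
})
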