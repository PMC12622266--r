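test_that("log-normal calibration reproduces reported median/IQR summaries", {
  # mouse lysed T1: closed-form mu = log(723), sigma = log(782/667)/1.3489796
  d <- calibrate_lognormal(723, 667, 782)
  expect_equal(d$mu, 6.5834, tolerance = 1e-4)
  expect_equal(d$sigma, 0.1180, tolerance = 1e-3)
  # human lysed ADC on the reported 1e-3 mm^2/s scale
  d2 <- calibrate_lognormal(1.02, 0.96, 1.14)
  expect_equal(d2$mu, 0.0198, tolerance = 1e-3)
  expect_equal(d2$sigma, 0.1274, tolerance = 1e-3)
  # degenerate zero-spread case is a point mass
  d3 <- calibrate_lognormal(5, 5, 5)
  expect_identical(d3$sigma, 0)
  expect_equal(q_msti_lognormal(c(0.1, 0.9), d3), c(5, 5))
  expect_error(calibrate_lognormal(1, 2, 3), "q1 <= median")
  expect_error(calibrate_lognormal(1, -1, 2), "positive")
})

test_that("truncation-aware calibration matches the post-exclusion median exactly", {
  # human nonlysed ADC: a quarter of a naive log-normal sits above the 2.0
  # exclusion bound; calibration targets the truncated law instead
  d <- calibrate_lognormal(1.23, 0.69, 1.74, upper = 2)
  med <- q_msti_lognormal(0.5, d)
  expect_equal(med, 1.23, tolerance = 1e-6)
  expect_equal(q_msti_lognormal(1, d), 2, tolerance = 1e-9)
  # negligible truncation reduces to the closed form
  d2 <- calibrate_lognormal(1.02, 0.96, 1.14, upper = 2)
  expect_equal(q_msti_lognormal(0.5, d2), 1.02, tolerance = 1e-6)
})

test_that("sampled slice parameters match the calibrated marginals", {
  # large draw, one slice per subject, no jitter: sample median within 2 ms
  cc <- msti_cohort_config("mouse", n_subjects = 1e5, slices_per_thrombus = 1,
                           slice_jitter_cv = 0, stratify_subjects = FALSE,
                           seed = 1)
  sp <- msti:::.with_seed(7, sample_slice_parameters(cc, "lysed"))
  expect_equal(median(sp$t1_ms), 723, tolerance = 2 / 723)
  expect_equal(median(sp$adc_e3), 1.02, tolerance = 0.01)
  # with default slice jitter the (median-neutral) marginals still hold to 1%
  cc2 <- msti_cohort_config("human", n_subjects = 2e4, slices_per_thrombus = 2,
                            stratify_subjects = FALSE, seed = 1)
  sp2 <- msti:::.with_seed(8, sample_slice_parameters(cc2, "nonlysed"))
  expect_equal(median(sp2$t1_ms), 765, tolerance = 0.01)
  expect_equal(median(sp2$adc_e3), 1.23, tolerance = 0.01)
  expect_error(sample_slice_parameters(cc, "mice"), "unknown group")
})

test_that("latent coupling gives coherent slice-level structure", {
  cc <- msti_cohort_config("mouse", n_subjects = 500, slices_per_thrombus = 4,
                           seed = 3)
  sp <- msti:::.with_seed(3, sample_slice_parameters(cc, "lysed"))
  # organized thrombus: high T1; mouse ADC runs opposite to organization
  expect_gt(cor(sp$t1_ms, sp$organization, method = "spearman"), 0.9)
  expect_lt(cor(sp$t1_ms, sp$adc_e3, method = "spearman"), -0.9)
  # zero slice jitter: all slices of a subject identical given the draw
  cc0 <- msti_cohort_config("mouse", n_subjects = 5, slices_per_thrombus = 6,
                            slice_jitter_cv = 0, seed = 3)
  sp0 <- msti:::.with_seed(3, sample_slice_parameters(cc0, "lysed"))
  spread <- tapply(sp0$t1_ms, sp0$subject, function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # within-thrombus variability close to the configured cv
  cvs <- tapply(sp$t1_ms, sp$subject, function(v) sd(v) / mean(v))
  expect_equal(mean(cvs), 0.10, tolerance = 0.25)
})

test_that("phantom geometry and ground truth are consistent and seeded", {
  cc <- tiny_config(slices = 5)
  ph <- build_phantom(cc, protocol = msti_protocol())
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
  expect_equal(nrow(ph$truth_table), 5)
  expect_equal(length(unique(ph$truth_table$slice_index)), 5)
  # thrombus voxels contiguous inside the vessel, carrying slice truth
  z <- ph$truth_table$slice_z[1]
  idx <- which(ph$labels[, , z] == 3L)
  expect_gt(length(idx), 0)
  expect_equal(unique(ph$t1[, , z][idx]), ph$truth_table$t1_ms[1])
  expect_error(build_phantom(tiny_config(slices = 0)), "geometry error")
  bad <- tiny_config(); bad$geometry$thrombus_radius_mm <- 10
  expect_error(build_phantom(bad), "thrombus larger than vessel")
  # determinism: same config/seed gives bit-identical subjects
  s1 <- simulate_subject(cc, "lysed", 1)
  s2 <- simulate_subject(cc, "lysed", 1)
  expect_identical(s1$stack$ir$volumes, s2$stack$ir$volumes)
  expect_identical(s1$truth_table, s2$truth_table)
})

test_that("inversion-recovery signal model obeys its closed forms", {
  cc <- tiny_config(slices = 3)
  sp <- data.frame(subject = 1, slice_index = 0:2, label = "lysed",
                   organization = 0.5, t1_ms = 500, adc_e3 = 1, mtr_pct = 40)
  proto <- msti_protocol(inversion_times = c(500 * log(2), 1000, 8000),
                         snr = Inf)
  ph <- build_phantom(cc, slice_params = sp, protocol = proto)
  ir <- simulate_ir_series(ph, proto, noiseless = TRUE)
  vox <- which(ph$labels == 3L)[1]
  # ideal inversion nulls at TI = T1 * ln 2, and S -> A as TI -> infinity
  expect_equal(ir$volumes[[1]][vox], 0, tolerance = 1e-8)
  expect_equal(ir$volumes[[3]][vox], 1000, tolerance = 1)
  # imperfect inversion: B/A = 1.8, T1 = 480 -> T1* = 600, S(600) = 337.82
  proto2 <- msti_protocol(inversion_times = c(200, 600, 5000),
                          inversion_efficiency = 1.8, snr = Inf)
  sp2 <- sp; sp2$t1_ms <- 480
  ph2 <- build_phantom(cc, slice_params = sp2, protocol = proto2)
  ir2 <- simulate_ir_series(ph2, proto2, noiseless = TRUE)
  expect_equal(ir2$volumes[[2]][vox], 337.82, tolerance = 0.01)
  bad <- msti_protocol()
  bad$inversion_efficiency <- 0.9
  expect_error(simulate_ir_series(ph, bad), "invalid protocol")
})

test_that("MT pair and DWI signal models are exact before noise", {
  cc <- tiny_config(slices = 2)
  sp <- data.frame(subject = 1, slice_index = 0:1, label = "lysed",
                   organization = 0.5, t1_ms = 700, adc_e3 = 1.0,
                   mtr_pct = 40)
  proto <- msti_protocol(snr = Inf)
  ph <- build_phantom(cc, slice_params = sp, protocol = proto)
  vox <- which(ph$labels == 3L)[1]
  mt <- simulate_mt_pair(ph, proto, noiseless = TRUE)
  expect_equal(mt$ms[vox] / mt$m0[vox], 0.6)     # mt_fraction 0.40
  ph0 <- ph; ph0$mtf[] <- 0
  mt0 <- simulate_mt_pair(ph0, proto, noiseless = TRUE)
  expect_identical(mt0$ms, mt0$m0)               # zero MT fraction: identity
  dwi <- simulate_dwi(ph, proto, noiseless = TRUE)
  expect_equal(dwi$volumes[[2]][vox], 1000 * exp(-0.6), tolerance = 1e-9)
  expect_equal(dwi$volumes[[1]][vox], 1000)      # b = b0 unchanged
  phd0 <- ph; phd0$adc[] <- 0
  d0 <- simulate_dwi(phd0, proto, noiseless = TRUE)
  expect_identical(d0$volumes[[1]], d0$volumes[[2]])
  badp <- proto; badp$b_values <- c(-10, 600)
  expect_error(simulate_dwi(ph, badp), "negative b-value")
})

test_that("Rician noise has the right moments and degenerate behaviour", {
  x <- array(c(0, 100), dim = c(2, 1, 1))
  expect_identical(add_rician_noise(x, 0), x)
  set.seed(99)
  zeros <- array(0, dim = c(100, 100, 10))
  noisy <- add_rician_noise(zeros, 1)
  # Rayleigh mean sigma*sqrt(pi/2) = 1.2533 at v = 0
  expect_equal(mean(noisy), sqrt(pi / 2), tolerance = 0.01)
  big <- array(1000, dim = c(100, 100, 1))
  expect_equal(mean(add_rician_noise(big, 1)), 1000, tolerance = 0.001)
  expect_error(add_rician_noise(zeros, -1), ">= 0")
})

test_that("lysed and nonlysed generator groups separate as reported", {
  # mouse presets: lysed group stochastically lower T1 (200 slices, p < 0.01)
  cc <- msti_cohort_config("mouse", n_subjects = 20, slices_per_thrombus = 5,
                           seed = 17)
  ly <- msti:::.with_seed(17, sample_slice_parameters(cc, "lysed"))
  nl <- msti:::.with_seed(18, sample_slice_parameters(cc, "nonlysed"))
  mw <- mann_whitney_u(ly$t1_ms, nl$t1_ms)
  expect_lt(mw$p, 0.01)
  expect_lt(median(ly$t1_ms), median(nl$t1_ms))
  expect_gt(median(ly$adc_e3), median(nl$adc_e3))
})

test_that("cohort writer round-trips through NIfTI and is reproducible", {
  dir1 <- withr::local_tempdir()
  cc <- msti_cohort_config("mouse", n_subjects = 2, slices_per_thrombus = 4,
                           seed = 12)
  idx <- simulate_cohort(cc, msti_protocol(), dir1)
  expect_equal(nrow(idx), 4)  # 2 groups x 2 subjects
  expect_true(file.exists(file.path(dir1, "cohort_manifest.json")))
  sdir <- idx$subject_dir[1]
  expect_true(all(file.exists(file.path(sdir,
    c("mt_on.nii.gz", "mt_off.nii.gz", "mask_thrombus.nii.gz", "truth.csv")))))
  rt <- read_subject_stack(sdir)
  sub <- simulate_subject(cc, idx$group[1], idx$subject[1])
  expect_equal(rt$stack$ir$volumes[[1]], sub$stack$ir$volumes[[1]],
               tolerance = 1e-6)
  expect_identical(rt$mask_thrombus, sub$mask_thrombus)
})
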