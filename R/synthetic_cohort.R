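#' Cohort generator configuration
#'
#' Defines a two-group (lysed vs nonlysed) synthetic cohort: number of
#' subjects per group, thrombus extent in axial slices, within-thrombus
#' slice-level heterogeneity, and the latent-correlation switch that couples
#' T1/ADC/MTR through a single per-subject thrombus "organization" score.
#'
#' @param cohort `"mouse"` or `"human"`; selects group distributions
#'   ([msti_group_distributions()]) and phantom geometry.
#' @param n_subjects Subjects per group (>= 2).
#' @param slices_per_thrombus Contiguous axial slices occupied by the
#'   thrombus (>= 1).
#' @param slice_jitter_cv Coefficient of variation of the within-thrombus
#'   slice-level variation (default 0.10).
#' @param voxel_jitter_cv Optional voxel-level jitter inside a slice
#'   (default 0 so slice ground truth is exactly the slice summary).
#' @param latent_correlation Couple the three parameters through one latent
#'   organization score per subject/slice (default `TRUE`).
#' @param stratify_subjects Draw subject-level latent scores by stratified
#'   sampling so small groups are quantile-representative of the configured
#'   distribution (default `TRUE`; set `FALSE` for plain iid draws).
#' @param seed Root seed; all cohort randomness is derived from it.
#' @param group_distributions Override the preset group distributions.
#' @return An object of class `msti_cohort_config`.
#' @export
msti_cohort_config <- function(cohort = c("mouse", "human"),
                               n_subjects = 20,
                               slices_per_thrombus = 10,
                               slice_jitter_cv = 0.10,
                               voxel_jitter_cv = 0,
                               latent_correlation = TRUE,
                               stratify_subjects = TRUE,
                               seed = 1L,
                               group_distributions = NULL) {
  cohort <- match.arg(cohort)
  .assert(n_subjects >= 2, "n_subjects must be >= 2 per group")
  .assert(slices_per_thrombus >= 0, "slices_per_thrombus must be >= 0")
  .assert(slice_jitter_cv >= 0, "slice_jitter_cv must be >= 0")
  .assert(voxel_jitter_cv >= 0, "voxel_jitter_cv must be >= 0")
  if (is.null(group_distributions))
    group_distributions <- msti_group_distributions(cohort)
  geom <- if (cohort == "mouse") {
    list(grid = c(32L, 32L), voxel_size = c(0.25, 0.25, 0.5),
         vessel_radius_mm = 1.75, thrombus_radius_mm = 1.25)
  } else {
    list(grid = c(32L, 32L), voxel_size = c(1, 1, 2),
         vessel_radius_mm = 7, thrombus_radius_mm = 5)
  }
  structure(list(cohort = cohort, n_subjects = as.integer(n_subjects),
                 slices_per_thrombus = as.integer(slices_per_thrombus),
                 slice_jitter_cv = slice_jitter_cv,
                 voxel_jitter_cv = voxel_jitter_cv,
                 latent_correlation = isTRUE(latent_correlation),
                 stratify_subjects = isTRUE(stratify_subjects),
                 seed = as.integer(seed),
                 group_distributions = group_distributions,
                 geometry = geom, margin_slices = 2L),
            class = "msti_cohort_config")
}

#' Acquisition protocol for the simulated multi-contrast stack
#'
#' @param inversion_times Inversion times in ms (>= 3; default 8 log-spaced
#'   values 100--5000 ms, a generic inversion-recovery series exercising the
#'   same 3-parameter fit as a clinical MOLLI scheme).
#' @param ir_amplitude Equilibrium signal amplitude `A` (arbitrary units).
#' @param inversion_efficiency `B/A` ratio of the IR model (2 = ideal
#'   inversion, in which case the Look-Locker correction is the identity).
#' @param b_values Diffusion weightings in s/mm^2 (>= 2 values including the
#'   reference; default `c(0, 600)`, a conventional body-DWI choice).
#' @param snr Signal-to-noise ratio defining the Rician noise level
#'   `noise_sigma = ir_amplitude / snr`; `Inf` = noiseless.
#' @param noise_sigma Override the noise standard deviation directly.
#' @param tissue_defaults True T1 (ms), ADC (1e-3 mm^2/s) and MT fraction for
#'   the non-thrombus tissues (muscle, vessel lumen). Lumen diffusivity of
#'   3.0e-3 mm^2/s deliberately exceeds the 2.0 exclusion bound, mimicking
#'   flow-contaminated blood signal.
#' @return An object of class `msti_protocol`.
#' @export
msti_protocol <- function(inversion_times = exp(seq(log(100), log(5000),
                                                    length.out = 8)),
                          ir_amplitude = 1000,
                          inversion_efficiency = 2.0,
                          b_values = c(0, 600),
                          snr = 40,
                          noise_sigma = NULL,
                          tissue_defaults = list(
                            muscle = list(t1 = 1200, adc = 1.5, mtf = 0.30),
                            lumen  = list(t1 = 1800, adc = 3.0, mtf = 0.05))) {
  .assert(length(inversion_times) >= 3,
          "need >= 3 inversion times for a 3-parameter fit")
  .assert(length(unique(b_values)) >= 2, "need >= 2 distinct b-values")
  .assert(all(b_values >= 0), "b-values must be non-negative")
  .assert(inversion_efficiency > 1,
          "inversion_efficiency (B/A) must exceed 1 for a valid protocol")
  if (is.null(noise_sigma))
    noise_sigma <- if (is.infinite(snr)) 0 else ir_amplitude / snr
  .assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  structure(list(inversion_times = sort(inversion_times),
                 ir_amplitude = ir_amplitude,
                 inversion_efficiency = inversion_efficiency,
                 b_values = sort(unique(b_values)),
                 noise_sigma = noise_sigma,
                 tissue_defaults = tissue_defaults),
            class = "msti_protocol")
}

#' Sample per-slice ground-truth thrombus parameters for one group
#'
#' Each subject receives a latent organization score; the three parameters
#' are quantile transforms of it under the calibrated group marginals, with
#' the configured sign (so, e.g., mouse ADC falls as organization rises).
#' Slice-level heterogeneity multiplies the subject value by a median-neutral
#' log-normal jitter with coefficient of variation `slice_jitter_cv`, signed
#' consistently across parameters so within-thrombus variation also respects
#' the latent coupling. With `latent_correlation = FALSE` every parameter
#' draws an independent latent score and independent jitter.
#'
#' Randomness comes from the current RNG state; seed the caller (cohort-level
#' functions derive substream seeds from `config$seed`).
#'
#' @param config An [msti_cohort_config()].
#' @param group `"lysed"` or `"nonlysed"`.
#' @param n_subjects Optionally override `config$n_subjects`.
#' @return data.frame with columns `subject`, `slice_index` (0-based),
#'   `label`, `organization`, `t1_ms`, `adc_e3`, `mtr_pct`.
#' @export
sample_slice_parameters <- function(config, group,
                                    n_subjects = config$n_subjects) {
  .assert(inherits(config, "msti_cohort_config"), "config must be an msti_cohort_config")
  gd <- config$group_distributions[[group]]
  if (is.null(gd)) stop("unknown group label: ", group, call. = FALSE)
  n <- n_subjects
  S <- config$slices_per_thrombus
  sj <- sqrt(log(1 + config$slice_jitter_cv^2))  # log-sd of slice jitter

  draw_latent <- function() {
    if (config$stratify_subjects) sample((seq_len(n) - runif(n)) / n)
    else runif(n)
  }
  u_shared <- draw_latent()
  eps_shared <- matrix(rnorm(n * S), n, S)

  param <- function(name) {
    g <- gd[[name]]
    if (config$latent_correlation) {
      u <- u_shared; eps <- eps_shared
    } else {
      u <- draw_latent(); eps <- matrix(rnorm(n * S), n, S)
    }
    # slice jitter acts on the latent scale and maps through the (possibly
    # truncated) quantile function, so jittered values respect the support;
    # for an untruncated log-normal this is exactly a multiplicative
    # log-normal jitter with coefficient of variation slice_jitter_cv
    tau <- if (g$dist$sigma > 0) sj / g$dist$sigma else 0
    z <- matrix(qnorm(u), n, S) + tau * eps
    val <- q_msti_lognormal(pnorm(g$direction * z), g$dist)
    dim(val) <- c(n, S)
    list(val = as.vector(t(val)),       # slice-major within subject
         z = as.vector(t(z)))
  }
  t1 <- param("T1"); adc <- param("ADC"); mtr <- param("MTR")
  # per-slice latent organization score: the latent (T1-scaled) coordinate
  # all parameters are monotone transforms of when latent_correlation is on
  out <- data.frame(
    subject = rep(seq_len(n), each = S),
    slice_index = rep(seq_len(S) - 1L, times = n),
    label = group,
    organization = pnorm(t1$z),
    t1_ms = t1$val,
    adc_e3 = adc$val,
    mtr_pct = pmin(mtr$val, 99.9),
    stringsAsFactors = FALSE)
  out
}

#' Build the cylindrical vessel/thrombus phantom for one subject
#'
#' Geometry is deterministic given the config: a vessel running along the
#' slice (third) axis through a muscle block, with the thrombus occupying
#' `slices_per_thrombus` contiguous axial slices inside the lumen. Voxelwise
#' ground truth assigns every thrombus voxel its slice's sampled parameters
#' (times optional voxel-level jitter) and the protocol tissue defaults
#' elsewhere.
#'
#' @param config An [msti_cohort_config()].
#' @param slice_params One subject's rows from [sample_slice_parameters()]
#'   (default: sample a single lysed subject under `config$seed`).
#' @param protocol An [msti_protocol()] supplying tissue defaults.
#' @return List with `labels` (3D integer array; 0 background, 1 muscle,
#'   2 lumen, 3 thrombus), `voxel_size` (mm), per-voxel truth volumes
#'   `t1`, `adc`, `mtf`, and the per-slice `truth_table`.
#' @export
build_phantom <- function(config, slice_params = NULL,
                          protocol = msti_protocol()) {
  .assert(inherits(config, "msti_cohort_config"), "config must be an msti_cohort_config")
  S <- config$slices_per_thrombus
  if (S < 1) stop("geometry error: thrombus must occupy >= 1 slice", call. = FALSE)
  g <- config$geometry
  if (g$thrombus_radius_mm >= g$vessel_radius_mm)
    stop("geometry error: thrombus larger than vessel", call. = FALSE)
  if (is.null(slice_params))
    slice_params <- .with_seed(config$seed,
      sample_slice_parameters(config, "lysed", n_subjects = 2))[
        seq_len(S), , drop = FALSE]
  .assert(nrow(slice_params) == S,
          "slice_params must have one row per thrombus slice")

  nx <- g$grid[1]; ny <- g$grid[2]
  nz <- S + 2L * config$margin_slices
  dx <- g$voxel_size[1]; dy <- g$voxel_size[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r2 <- outer((seq_len(nx) - cx) * dx, rep(1, ny))^2 +
        outer(rep(1, nx), (seq_len(ny) - cy) * dy)^2
  lumen2d <- r2 <= g$vessel_radius_mm^2
  thromb2d <- r2 <= g$thrombus_radius_mm^2
  border <- 2L
  bg2d <- matrix(TRUE, nx, ny)
  bg2d[(border + 1):(nx - border), (border + 1):(ny - border)] <- FALSE

  labels <- array(1L, dim = c(nx, ny, nz))
  labels[rep(bg2d, nz)] <- 0L
  thrombus_z <- config$margin_slices + seq_len(S)
  for (z in seq_len(nz)) {
    sl <- labels[, , z]
    sl[lumen2d & sl == 1L] <- 2L
    if (z %in% thrombus_z) sl[thromb2d & sl == 2L] <- 3L
    labels[, , z] <- sl
  }

  td <- protocol$tissue_defaults
  t1 <- array(0, dim(labels)); adc <- array(0, dim(labels))
  mtf <- array(0, dim(labels))
  t1[labels == 1L] <- td$muscle$t1; adc[labels == 1L] <- td$muscle$adc
  mtf[labels == 1L] <- td$muscle$mtf
  t1[labels == 2L] <- td$lumen$t1; adc[labels == 2L] <- td$lumen$adc
  mtf[labels == 2L] <- td$lumen$mtf
  vj <- sqrt(log(1 + config$voxel_jitter_cv^2))
  for (i in seq_len(S)) {
    idx <- which(labels[, , thrombus_z[i]] == 3L)
    nvox <- length(idx)
    jit <- function() if (vj > 0) exp(vj * rnorm(nvox)) else 1
    zoff <- (thrombus_z[i] - 1L) * nx * ny
    t1[zoff + idx] <- slice_params$t1_ms[i] * jit()
    adc[zoff + idx] <- slice_params$adc_e3[i] * jit()
    mtf[zoff + idx] <- pmin(slice_params$mtr_pct[i] * jit(), 99.9) / 100
  }
  truth_table <- slice_params
  # slice_index convention everywhere: 0-based along the volume's third axis
  truth_table$slice_index <- thrombus_z - 1L
  truth_table$slice_z <- thrombus_z  # 1-based array index of the same slice
  list(labels = labels, voxel_size = g$voxel_size,
       t1 = t1, adc = adc, mtf = mtf, truth_table = truth_table)
}

#' Add Rician noise to a magnitude image volume
#'
#' Each voxel `v` becomes `sqrt((v + n1)^2 + n2^2)` with independent
#' `n1, n2 ~ N(0, sigma^2)`; `sigma = 0` returns the input unchanged.
#'
#' @param volume Numeric array.
#' @param sigma Noise standard deviation (>= 0).
#' @return Noisy volume of the same shape.
#' @export
add_rician_noise <- function(volume, sigma) {
  .assert(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(volume)
  n <- length(volume)
  out <- sqrt((volume + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(volume))) dim(out) <- dim(volume)
  out
}

#' Simulate the inversion-recovery series
#'
#' Noiseless magnitude signal per voxel
#' `S(TI) = |A - B exp(-TI / T1*)|` with `B = A * inversion_efficiency` and
#' apparent `T1* = T1 / (B/A - 1)` (Look-Locker convention); Rician noise is
#' then applied at the protocol noise level. With ideal inversion
#' (`B/A = 2`) `T1* = T1`.
#'
#' @param phantom Output of [build_phantom()].
#' @param protocol An [msti_protocol()].
#' @param noiseless Skip the noise stage (default `FALSE`).
#' @return List with `ti` (ms) and `volumes` (one per inversion time).
#' @export
simulate_ir_series <- function(phantom, protocol, noiseless = FALSE) {
  A <- protocol$ir_amplitude
  eff <- protocol$inversion_efficiency
  .assert(eff > 1, "invalid protocol: B/A - 1 must be positive")
  B <- A * eff
  t1star <- phantom$t1 / (eff - 1)
  amp <- (phantom$labels > 0L) * 1
  vols <- lapply(protocol$inversion_times, function(ti) {
    s <- abs(A - B * exp(-ti / pmax(t1star, 1e-9))) * amp
    dim(s) <- dim(phantom$labels)
    if (noiseless) s else add_rician_noise(s, protocol$noise_sigma)
  })
  list(ti = protocol$inversion_times, volumes = vols)
}

#' Simulate the magnetization-transfer image pair
#'
#' `Ms = M0 * (1 - mt_fraction)` before noise, so the noiseless MTR map
#' `(M0 - Ms)/M0 * 100` returns `100 * mt_fraction` exactly.
#'
#' @inheritParams simulate_ir_series
#' @return List with `m0` (no prepulse) and `ms` (with MT prepulse) volumes.
#' @export
simulate_mt_pair <- function(phantom, protocol, noiseless = FALSE) {
  .assert(all(phantom$mtf >= 0 & phantom$mtf < 1),
          "mt_fraction must lie in [0, 1)")
  m0 <- protocol$ir_amplitude * (phantom$labels > 0L)
  ms <- m0 * (1 - phantom$mtf)
  dim(m0) <- dim(ms) <- dim(phantom$labels)
  if (!noiseless) {
    m0 <- add_rician_noise(m0, protocol$noise_sigma)
    ms <- add_rician_noise(ms, protocol$noise_sigma)
  }
  list(m0 = m0, ms = ms)
}

#' Simulate the diffusion-weighted series
#'
#' Mono-exponential decay `S(b) = S(b0) * exp(-(b - b0) * D)` with `D` in
#' mm^2/s (`adc` volume is in 1e-3 mm^2/s), before Rician noise.
#'
#' @inheritParams simulate_ir_series
#' @return List with `b` (s/mm^2) and `volumes` (one per b-value).
#' @export
simulate_dwi <- function(phantom, protocol, noiseless = FALSE) {
  b <- protocol$b_values
  .assert(all(b >= 0), "negative b-value")
  b0 <- min(b)
  s0 <- protocol$ir_amplitude * (phantom$labels > 0L)
  vols <- lapply(b, function(bi) {
    s <- s0 * exp(-(bi - b0) * phantom$adc * 1e-3)
    dim(s) <- dim(phantom$labels)
    if (noiseless) s else add_rician_noise(s, protocol$noise_sigma)
  })
  list(b = b, volumes = vols)
}

#' Simulate the full multi-contrast stack for one subject
#'
#' Samples (or accepts) the subject's slice parameters, builds the phantom,
#' and acquires the IR, MT and DWI series with independent Rician noise,
#' all under a deterministic substream seed derived from `config$seed` and
#' the subject's position, so identical configs are bit-identical.
#'
#' @param config An [msti_cohort_config()].
#' @param group `"lysed"` or `"nonlysed"`.
#' @param subject Subject index within the group (1-based).
#' @param protocol An [msti_protocol()].
#' @param cohort_params Optional precomputed full-group parameter table from
#'   [sample_slice_parameters()]; sampled deterministically if missing.
#' @param noiseless Acquire without noise.
#' @return List with `stack` (class `msti_stack`), `phantom`, `truth_table`,
#'   and masks `mask_thrombus`, `mask_vessel`.
#' @export
simulate_subject <- function(config, group = "lysed", subject = 1L,
                             protocol = msti_protocol(),
                             cohort_params = NULL, noiseless = FALSE) {
  if (is.null(cohort_params)) {
    gi <- match(group, names(config$group_distributions))
    if (is.na(gi)) stop("unknown group label: ", group, call. = FALSE)
    cohort_params <- .with_seed(.substream_seed(config$seed, gi),
                                sample_slice_parameters(config, group))
  }
  sp <- cohort_params[cohort_params$subject == subject, , drop = FALSE]
  .assert(nrow(sp) == config$slices_per_thrombus,
          "subject not present in cohort parameter table")
  gi <- match(group, names(config$group_distributions))
  acq_seed <- .substream_seed(config$seed, 1000L * gi + subject)
  .with_seed(acq_seed, {
    phantom <- build_phantom(config, slice_params = sp, protocol = protocol)
    ir <- simulate_ir_series(phantom, protocol, noiseless = noiseless)
    mt <- simulate_mt_pair(phantom, protocol, noiseless = noiseless)
    dwi <- simulate_dwi(phantom, protocol, noiseless = noiseless)
    stack <- structure(list(ir = ir, mt = mt, dwi = dwi,
                            voxel_size = phantom$voxel_size,
                            noise_sigma = if (noiseless) 0 else protocol$noise_sigma),
                       class = "msti_stack")
    list(stack = stack, phantom = phantom, truth_table = phantom$truth_table,
         mask_thrombus = phantom$labels == 3L,
         mask_vessel = phantom$labels == 2L | phantom$labels == 3L)
  })
}

#' Simulate and write a full two-group cohort to disk
#'
#' Writes, per subject, NIfTI volumes `ir_<TI>.nii.gz`, `mt_off.nii.gz`,
#' `mt_on.nii.gz`, `dwi_b<b>.nii.gz`, `mask_thrombus.nii.gz`,
#' `mask_vessel.nii.gz`, a `truth.csv` slice table, and a subject manifest;
#' plus a cohort-level `cohort_manifest.json` echoing the config and seed.
#'
#' @param config An [msti_cohort_config()].
#' @param protocol An [msti_protocol()].
#' @param out_dir Output directory (created if needed).
#' @param noiseless Acquire without noise.
#' @return Invisibly, a data.frame of subject directories and labels.
#' @export
simulate_cohort <- function(config, protocol = msti_protocol(), out_dir,
                            noiseless = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- names(config$group_distributions)
  index <- list()
  for (gi in seq_along(groups)) {
    group <- groups[gi]
    params <- .with_seed(.substream_seed(config$seed, gi),
                         sample_slice_parameters(config, group))
    for (s in seq_len(config$n_subjects)) {
      sub <- simulate_subject(config, group, s, protocol,
                              cohort_params = params, noiseless = noiseless)
      sdir <- file.path(out_dir, sprintf("%s_%02d", group, s))
      dir.create(sdir, showWarnings = FALSE)
      .write_subject_nifti(sub, protocol, sdir)
      tt <- sub$truth_table
      write.csv(data.frame(slice_index = tt$slice_index, label = tt$label,
                           true_T1_ms = tt$t1_ms,
                           true_ADC_e3mm2s = tt$adc_e3,
                           true_MTR_pct = tt$mtr_pct),
                file.path(sdir, "truth.csv"), row.names = FALSE)
      index[[length(index) + 1L]] <- data.frame(
        subject_dir = sdir, group = group, subject = s,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- list(cohort = config$cohort, seed = config$seed,
                   n_subjects_per_group = config$n_subjects,
                   slices_per_thrombus = config$slices_per_thrombus,
                   slice_jitter_cv = config$slice_jitter_cv,
                   latent_correlation = config$latent_correlation,
                   noise_sigma = if (noiseless) 0 else protocol$noise_sigma,
                   inversion_times = protocol$inversion_times,
                   b_values = protocol$b_values,
                   voxel_size = config$geometry$voxel_size,
                   package_version = as.character(packageVersion("msti")))
  jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(do.call(rbind, index))
}

.subject_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  structure(a, dimnames = NULL)
}

.write_subject_nifti <- function(sub, protocol, sdir) {
  vs <- sub$stack$voxel_size
  wr <- function(vol, name) {
    img <- RNifti::asNifti(vol * 1, pixdim = vs)
    RNifti::writeNifti(img, file.path(sdir, name))
  }
  for (i in seq_along(sub$stack$ir$ti))
    wr(sub$stack$ir$volumes[[i]],
       sprintf("ir_%04.0f.nii.gz", sub$stack$ir$ti[i]))
  wr(sub$stack$mt$m0, "mt_off.nii.gz")
  wr(sub$stack$mt$ms, "mt_on.nii.gz")
  for (i in seq_along(sub$stack$dwi$b))
    wr(sub$stack$dwi$volumes[[i]],
       sprintf("dwi_b%04.0f.nii.gz", sub$stack$dwi$b[i]))
  wr(sub$mask_thrombus * 1L, "mask_thrombus.nii.gz")
  wr(sub$mask_vessel * 1L, "mask_vessel.nii.gz")
  jsonlite::write_json(
    list(inversion_times = sub$stack$ir$ti, b_values = sub$stack$dwi$b,
         noise_sigma = sub$stack$noise_sigma, voxel_size = vs),
    file.path(sdir, "subject_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a subject's multi-contrast stack back from disk
#'
#' Counterpart of [simulate_cohort()]'s per-subject output layout; acquisition
#' metadata are taken from `subject_manifest.json`.
#'
#' @param sdir Subject directory.
#' @return List with `stack` (class `msti_stack`), `mask_thrombus`,
#'   `mask_vessel`.
#' @export
read_subject_stack <- function(sdir) {
  man <- jsonlite::read_json(file.path(sdir, "subject_manifest.json"),
                             simplifyVector = TRUE)
  rd <- function(name) {
    v <- RNifti::readNifti(file.path(sdir, name))
    array(as.numeric(v), dim = dim(v))
  }
  ir <- list(ti = man$inversion_times,
             volumes = lapply(man$inversion_times,
                              function(ti) rd(sprintf("ir_%04.0f.nii.gz", ti))))
  dwi <- list(b = man$b_values,
              volumes = lapply(man$b_values,
                               function(b) rd(sprintf("dwi_b%04.0f.nii.gz", b))))
  stack <- structure(list(ir = ir,
                          mt = list(m0 = rd("mt_off.nii.gz"),
                                    ms = rd("mt_on.nii.gz")),
                          dwi = dwi,
                          voxel_size = man$voxel_size,
                          noise_sigma = man$noise_sigma),
                     class = "msti_stack")
  list(stack = stack,
       mask_thrombus = rd("mask_thrombus.nii.gz") > 0.5,
       mask_vessel = rd("mask_vessel.nii.gz") > 0.5)
}
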