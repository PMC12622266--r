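#' Fit the 3-parameter inversion-recovery model at one voxel
#'
#' Nonlinear least squares of `S(t) = A - B * exp(-t / T1*)` (signed form),
#' solved by variable projection: for fixed `T1*` the model is linear in
#' `(A, B)`, leaving a 1-D search over `T1*` (log-spaced grid plus
#' golden-section refinement), which finds the global minimiser without
#' starting-value sensitivity. For magnitude data, polarity restoration
#' refits with the sign of the earliest `k` samples flipped (`k = 0..n`) and
#' keeps the lowest-residual solution. The corrected relaxation time is the
#' Look-Locker expression `T1 = T1* (B/A - 1)`.
#'
#' A voxel is flagged invalid (not an error) when the fitted `B <= A` or
#' `T1* <= 0`, e.g. for constant or signal-free data.
#'
#' @param ti Inversion times in ms (>= 3 distinct values).
#' @param signal Measured signal at each `ti`.
#' @param magnitude_data Apply polarity restoration (default `TRUE`).
#' @param t1s_range Search range for `T1*` in ms.
#' @return List with `A`, `B`, `t1star`, `t1_ms`, `rss`, `valid`.
#' @export
fit_t1_voxel <- function(ti, signal, magnitude_data = TRUE,
                         t1s_range = c(5, 10000)) {
  .assert(length(ti) == length(signal), "ti and signal lengths differ")
  .assert(length(unique(ti)) >= 3, "insufficient data: need >= 3 distinct TIs")
  .assert(all(is.finite(ti)) && all(is.finite(signal)),
          "ti and signal must be finite")
  o <- order(ti)
  res <- .fit_t1_vp_cpp(matrix(signal[o], nrow = 1), ti[o],
                        isTRUE(magnitude_data),
                        t1s_range[1], t1s_range[2], 40L)
  .t1_from_fit(res)[1, ]
}

# Shared post-processing: Look-Locker correction + validity flags.
.t1_from_fit <- function(res) {
  A <- res[, "A"]; B <- res[, "B"]; t1s <- res[, "t1star"]
  valid <- is.finite(A) & is.finite(B) & A > 0 & B > A & t1s > 0
  t1 <- ifelse(valid, t1s * (B / A - 1), NA_real_)
  data.frame(A = A, B = B, t1star = t1s, t1_ms = t1,
             rss = res[, "rss"], valid = valid)
}

#' Fit the voxelwise T1 map inside a mask
#'
#' @param ir List with `ti` (ms) and `volumes` (one volume per TI), as
#'   produced by [simulate_ir_series()] or [read_subject_stack()].
#' @param mask Logical volume selecting voxels to fit (non-empty).
#' @param magnitude_data Apply polarity restoration voxelwise.
#' @return List of volumes `t1_ms`, `A`, `B`, `t1star`, logical `valid`, and
#'   the scalar `convergence_fraction` (fraction of masked voxels with a
#'   valid fit).
#' @export
fit_t1_map <- function(ir, mask, magnitude_data = TRUE) {
  .assert(is.array(mask) || is.matrix(mask), "mask must be an array")
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  .assert(all(vapply(ir$volumes, function(v) identical(dim(v), dim(mask)),
                     logical(1))), "mask grid does not match IR volumes")
  o <- order(ir$ti)
  sig <- vapply(ir$volumes[o], function(v) v[idx], numeric(length(idx)))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = length(idx))
  res <- .fit_t1_vp_cpp(sig, ir$ti[o], isTRUE(magnitude_data), 5, 10000, 40L)
  fit <- .t1_from_fit(res)
  blank <- array(NA_real_, dim(mask))
  out <- list(t1_ms = blank, A = blank, B = blank, t1star = blank,
              valid = array(FALSE, dim(mask)))
  out$t1_ms[idx] <- fit$t1_ms; out$A[idx] <- fit$A; out$B[idx] <- fit$B
  out$t1star[idx] <- fit$t1star; out$valid[idx] <- fit$valid
  out$convergence_fraction <- mean(fit$valid)
  out
}

#' Compute the magnetization-transfer-ratio map
#'
#' Voxelwise `%MTR = (M0 - Ms) / M0 * 100`; voxels with `M0 <= 0` are marked
#' invalid rather than raising an error.
#'
#' @param m0 Volume acquired without the MT prepulse.
#' @param ms Volume acquired with the MT prepulse.
#' @param mask Optional logical volume restricting computation.
#' @return List with `mtr_pct` volume and logical `valid`.
#' @export
compute_mtr_map <- function(m0, ms, mask = NULL) {
  .assert(identical(dim(m0), dim(ms)), "M0 and Ms grids do not match")
  if (is.null(mask)) mask <- array(TRUE, dim(m0))
  .assert(identical(dim(mask), dim(m0)), "mask grid does not match")
  valid <- mask & is.finite(m0) & is.finite(ms) & m0 > 0
  mtr <- array(NA_real_, dim(m0))
  mtr[valid] <- (m0[valid] - ms[valid]) / m0[valid] * 100
  list(mtr_pct = mtr, valid = valid)
}

#' Compute the apparent-diffusion-coefficient map
#'
#' Two b-values give the closed form `ADC = ln(S0/Si) / (bi - b0)`; with more
#' than two, the least-squares slope of `ln S` versus `b`. Voxels with
#' non-positive signal (or below `signal_floor`) at any b-value, or with a
#' negative estimate (`Si > S0`), are marked invalid.
#'
#' @param dwi List with `b` (s/mm^2) and `volumes` (one per b-value).
#' @param mask Optional logical volume restricting computation.
#' @param signal_floor Minimum usable signal; defaults to 3x the stack noise
#'   estimate when called via [compute_maps()], else 0.
#' @return List with `adc_e3` volume (1e-3 mm^2/s) and logical `valid`.
#' @export
compute_adc_map <- function(dwi, mask = NULL, signal_floor = 0) {
  b <- dwi$b
  .assert(length(b) >= 2, "need >= 2 b-values")
  if (length(unique(b)) < 2) stop("all b-values equal", call. = FALSE)
  dims <- dim(dwi$volumes[[1]])
  if (is.null(mask)) mask <- array(TRUE, dims)
  .assert(identical(dim(mask), dims), "mask grid does not match")
  idx <- which(mask)
  sig <- vapply(dwi$volumes, function(v) v[idx], numeric(length(idx)))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = length(idx))
  pos <- rowSums(sig <= pmax(signal_floor, 0) | !is.finite(sig)) == 0
  ls <- log(pmax(sig, .Machine$double.xmin))
  if (length(b) == 2) {
    o <- order(b)
    d <- (ls[, o[1]] - ls[, o[2]]) / (b[o[2]] - b[o[1]])  # mm^2/s
  } else {
    bc <- b - mean(b)
    d <- -as.vector(ls %*% bc) / sum(bc^2)
  }
  adc <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  adc[idx] <- d * 1e3
  valid[idx] <- pos & is.finite(d) & d >= 0
  list(adc_e3 = adc, valid = valid)
}

#' Apply the physiological ADC exclusion rule
#'
#' Voxels whose ADC exceeds the threshold (strictly: "exceeding" means
#' `> threshold`, so a voxel at exactly the threshold is retained) are marked
#' invalid; the count of newly excluded voxels is recorded as attribute
#' `n_excluded` and logged.
#'
#' @param adc_e3 ADC volume in 1e-3 mm^2/s.
#' @param valid Logical validity volume to update.
#' @param threshold Exclusion bound (default 2.0e-3 mm^2/s, written 2.0).
#' @return Updated logical `valid` with attribute `n_excluded`.
#' @export
apply_adc_exclusion <- function(adc_e3, valid = NULL, threshold = 2.0) {
  .assert(threshold > 0, "threshold must be > 0")
  if (is.null(valid)) valid <- is.finite(adc_e3)
  excl <- valid & is.finite(adc_e3) & adc_e3 > threshold
  out <- valid & !excl
  n <- sum(excl)
  if (n > 0)
    message(sprintf("ADC exclusion: %d voxel(s) above %.3g removed", n, threshold))
  attr(out, "n_excluded") <- n
  out
}

#' Compute all parametric maps from a multi-contrast stack
#'
#' Runs the T1 fit, MTR and ADC computations inside `mask`, applies the ADC
#' exclusion, and assembles the joint validity volume (a voxel invalid in
#' any map is dropped from joint statistics).
#'
#' @param stack An `msti_stack` ([simulate_subject()] or
#'   [read_subject_stack()]).
#' @param mask Logical volume (e.g. the thrombus ROI propagated from
#'   venography).
#' @param adc_max ADC exclusion threshold (1e-3 mm^2/s).
#' @param magnitude_data Polarity restoration for the T1 fit.
#' @param adc_signal_floor Minimum usable DWI signal; default 3x the stack's
#'   noise sigma.
#' @return An object of class `msti_maps`.
#' @export
compute_maps <- function(stack, mask, adc_max = 2.0, magnitude_data = TRUE,
                         adc_signal_floor = NULL) {
  .assert(inherits(stack, "msti_stack"), "stack must be an msti_stack")
  if (is.null(adc_signal_floor))
    adc_signal_floor <- 3 * (stack$noise_sigma %||% 0)
  t1 <- fit_t1_map(stack$ir, mask, magnitude_data = magnitude_data)
  mtr <- compute_mtr_map(stack$mt$m0, stack$mt$ms, mask)
  adc <- compute_adc_map(stack$dwi, mask, signal_floor = adc_signal_floor)
  adc_valid <- apply_adc_exclusion(adc$adc_e3, adc$valid, threshold = adc_max)
  structure(list(
    t1_ms = t1$t1_ms, t1_fit = t1[c("A", "B", "t1star")],
    mtr_pct = mtr$mtr_pct, adc_e3 = adc$adc_e3,
    valid_t1 = t1$valid, valid_mtr = mtr$valid,
    valid_adc = adc_valid,
    valid = t1$valid & mtr$valid & adc_valid,
    convergence_fraction = t1$convergence_fraction,
    n_adc_excluded = attr(adc_valid, "n_excluded"),
    voxel_size = stack$voxel_size), class = "msti_maps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write parametric maps as NIfTI volumes
#'
#' @param maps An `msti_maps` object.
#' @param out_dir Output directory; writes `t1_ms.nii.gz`, `mtr_pct.nii.gz`,
#'   `adc_e3.nii.gz` and per-map validity masks.
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- maps$voxel_size %||% c(1, 1, 1)
  wr <- function(vol, name) {
    v <- vol; v[!is.finite(v)] <- 0
    RNifti::writeNifti(RNifti::asNifti(v * 1, pixdim = vs),
                       file.path(out_dir, name))
    file.path(out_dir, name)
  }
  paths <- c(wr(maps$t1_ms, "t1_ms.nii.gz"),
             wr(maps$mtr_pct, "mtr_pct.nii.gz"),
             wr(maps$adc_e3, "adc_e3.nii.gz"),
             wr(maps$valid_t1, "valid_t1.nii.gz"),
             wr(maps$valid_mtr, "valid_mtr.nii.gz"),
             wr(maps$valid_adc * 1, "valid_adc.nii.gz"))
  invisible(paths)
}
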