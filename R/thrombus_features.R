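#' Propagate the thrombus ROI across parametric maps
#'
#' For each axial slice intersecting the mask, collects the in-mask voxels
#' that are valid in all three maps (T1, MTR, post-exclusion ADC). Slices in
#' which every voxel failed a validity rule are dropped with a warning, as is
#' an entirely empty mask.
#'
#' @param mask Logical thrombus ROI on the map grid.
#' @param maps An `msti_maps` object from [compute_maps()].
#' @return Named list (0-based slice index as name) of linear voxel indices.
#' @export
propagate_rois <- function(mask, maps) {
  .assert(inherits(maps, "msti_maps"), "maps must be an msti_maps")
  .assert(identical(dim(mask), dim(maps$valid)), "grid mismatch between mask and maps")
  nz <- dim(mask)[3]
  nxy <- prod(dim(mask)[1:2])
  out <- list()
  for (z in seq_len(nz)) {
    in_mask <- which(mask[, , z])
    if (length(in_mask) == 0) next
    ok <- in_mask[maps$valid[, , z][in_mask]]
    if (length(ok) == 0) {
      warning(sprintf("slice %d: all %d ROI voxels invalid; slice dropped",
                      z - 1L, length(in_mask)), call. = FALSE)
      next
    }
    out[[as.character(z - 1L)]] <- (z - 1L) * nxy + ok
  }
  if (length(out) == 0) warning("empty ROI: no valid thrombus voxels", call. = FALSE)
  out
}

#' Slice-wise summaries of the thrombus parameters
#'
#' Summarises T1, MTR and ADC over each slice's valid ROI voxels with the
#' configured statistic (mean by default; group-level reporting conventionally
#' uses medians, available via `statistic = "median"`). Deterministic and
#' invariant to voxel ordering.
#'
#' @param rois Output of [propagate_rois()].
#' @param maps An `msti_maps` object.
#' @param statistic `"mean"` or `"median"`.
#' @return data.frame with `slice_index` (0-based), `n_valid_voxels`,
#'   `t1_ms`, `mtr_pct`, `adc_e3`.
#' @export
slicewise_summary <- function(rois, maps, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else median
  rows <- lapply(names(rois), function(k) {
    idx <- rois[[k]]
    data.frame(slice_index = as.integer(k),
               n_valid_voxels = length(idx),
               t1_ms = fun(maps$t1_ms[idx]),
               mtr_pct = fun(maps$mtr_pct[idx]),
               adc_e3 = fun(maps$adc_e3[idx]))
  })
  if (length(rows) == 0)
    return(data.frame(slice_index = integer(), n_valid_voxels = integer(),
                      t1_ms = numeric(), mtr_pct = numeric(),
                      adc_e3 = numeric()))
  do.call(rbind, rows)
}

#' Thrombus volume from the ROI filling defect
#'
#' @param mask Logical thrombus mask.
#' @param voxel_size `(dx, dy, dz)` in mm.
#' @return List with `mm3` and `cm3`.
#' @export
thrombus_volume <- function(mask, voxel_size) {
  .assert(all(voxel_size > 0), "voxel_size must be positive")
  mm3 <- sum(mask) * prod(voxel_size)
  list(mm3 = mm3, cm3 = mm3 / 1000)
}

#' Volume-normalized MTR
#'
#' The combined-cutoff rule uses MTR normalized to thrombus volume, in
#' %/cm^3. The adopted definition is (mean MTR) / (thrombus volume in cm^3):
#' it reproduces the printed unit and the qualitative behaviour (small, fresh
#' thrombi score high; doubling the volume at fixed mean MTR halves the
#' score). The unit is dimensionally ambiguous as printed, so the 2800 %/cm^3
#' cutoff is treated as cohort configuration, not physics.
#'
#' @param mtr_mean Mean (or slice-summary) MTR in %.
#' @param volume_cm3 Thrombus volume in cm^3 (> 0).
#' @return Normalized MTR in %/cm^3.
#' @export
normalize_mtr <- function(mtr_mean, volume_cm3) {
  if (any(volume_cm3 <= 0)) stop("zero or negative thrombus volume", call. = FALSE)
  mtr_mean / volume_cm3
}

#' Extract the per-slice thrombus feature table
#'
#' Combines ROI propagation, slice summaries, thrombus volume and
#' volume-normalized MTR into the table the classifier and statistics
#' consume. Slices with fewer than `min_voxels` valid voxels are dropped as
#' noise-dominated.
#'
#' @param maps An `msti_maps` object.
#' @param mask Logical thrombus ROI.
#' @param statistic Slice summary statistic (`"mean"` or `"median"`).
#' @param min_voxels Minimum valid voxels per emitted slice (default 5).
#' @param subject_id Optional subject identifier column.
#' @param outcome_label Optional `"lysed"`/`"nonlysed"` outcome column.
#' @return data.frame with columns `subject_id`, `slice_index`,
#'   `n_valid_voxels`, `t1_ms`, `mtr_pct`, `adc_e3`, `mtr_per_cm3`,
#'   `thrombus_volume_mm3`, `outcome_label`.
#' @export
extract_slice_features <- function(maps, mask, statistic = "mean",
                                   min_voxels = 5, subject_id = NA_character_,
                                   outcome_label = NA_character_) {
  rois <- propagate_rois(mask, maps)
  summ <- slicewise_summary(rois, maps, statistic = statistic)
  summ <- summ[summ$n_valid_voxels >= min_voxels, , drop = FALSE]
  vol <- thrombus_volume(mask, maps$voxel_size %||% c(1, 1, 1))
  if (nrow(summ) > 0) {
    summ$mtr_per_cm3 <- normalize_mtr(summ$mtr_pct, vol$cm3)
    summ$thrombus_volume_mm3 <- vol$mm3
    summ <- cbind(data.frame(subject_id = subject_id), summ,
                  data.frame(outcome_label = outcome_label))
  } else {
    summ <- data.frame(subject_id = character(), slice_index = integer(),
                       n_valid_voxels = integer(), t1_ms = numeric(),
                       mtr_pct = numeric(), adc_e3 = numeric(),
                       mtr_per_cm3 = numeric(), thrombus_volume_mm3 = numeric(),
                       outcome_label = character())
  }
  rownames(summ) <- NULL
  summ
}
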