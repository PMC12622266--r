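#' Combined-cutoff classification rule
#'
#' A conjunction of strict per-parameter inequalities; a slice is called
#' lysable iff every inequality holds. Ties at a threshold go nonlysable
#' (conservative, matching the strict "<784" / ">0.88" wording).
#'
#' @param parameters Character vector of feature-column names.
#' @param thresholds Numeric thresholds, one per parameter.
#' @param directions `"below"` or `"above"` per parameter.
#' @return An object of class `msti_cutoff_rule`.
#' @export
msti_cutoff_rule <- function(parameters, thresholds, directions) {
  .assert(length(parameters) == length(thresholds) &&
            length(parameters) == length(directions),
          "parameters, thresholds, directions must have equal length")
  .assert(all(is.finite(thresholds)), "thresholds must be finite")
  .assert(all(directions %in% c("below", "above")),
          "directions must be 'below' or 'above'")
  structure(list(parameters = parameters, thresholds = thresholds,
                 directions = directions), class = "msti_cutoff_rule")
}

#' Mouse-cohort combined cutoff rule
#'
#' The ROC-derived operating point for the murine cohort: T1 < 784 ms,
#' volume-normalized MTR < 2800 %/cm^3, ADC > 0.88 (1e-3 mm^2/s), combined
#' as a conjunction.
#'
#' @return An `msti_cutoff_rule`.
#' @export
msti_mouse_rule <- function() {
  msti_cutoff_rule(parameters = c("t1_ms", "mtr_per_cm3", "adc_e3"),
                   thresholds = c(784, 2800, 0.88),
                   directions = c("below", "below", "above"))
}

#' Classify slices by the combined-cutoff rule
#'
#' @param features Slice feature table ([extract_slice_features()]).
#' @param rule An `msti_cutoff_rule` (default the mouse rule).
#' @return Factor-free character vector (`"lysable"`/`"nonlysable"`), `NA`
#'   where any rule parameter is missing (those slices are logged).
#' @export
classify_by_cutoffs <- function(features, rule = msti_mouse_rule()) {
  .assert(inherits(rule, "msti_cutoff_rule"), "rule must be an msti_cutoff_rule")
  missing_cols <- setdiff(rule$parameters, names(features))
  if (length(missing_cols) > 0)
    stop("unknown rule parameter(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pass <- rep(TRUE, nrow(features))
  defined <- rep(TRUE, nrow(features))
  for (i in seq_along(rule$parameters)) {
    v <- features[[rule$parameters[i]]]
    defined <- defined & is.finite(v)
    ok <- if (rule$directions[i] == "below") v < rule$thresholds[i]
          else v > rule$thresholds[i]
    pass <- pass & ok
  }
  out <- ifelse(pass, "lysable", "nonlysable")
  if (any(!defined)) {
    warning(sprintf("%d slice(s) with missing parameter values excluded",
                    sum(!defined)), call. = FALSE)
    out[!defined] <- NA_character_
  }
  out
}

#' Published logistic lysis-model coefficients
#'
#' Multivariate logistic coefficients for the human cohort: intercept
#' `beta0 = 5.37`, `beta1 = -0.006` per ms of T1, `beta2 = -0.448` per
#' 1e-3 mm^2/s of ADC (the scale on which all ADC values are reported).
#'
#' @param beta0,beta1,beta2 Override individual coefficients.
#' @return An object of class `msti_coefficients`.
#' @export
msti_human_coefficients <- function(beta0 = 5.37, beta1 = -0.006,
                                    beta2 = -0.448) {
  .assert(all(is.finite(c(beta0, beta1, beta2))), "coefficients must be finite")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2),
            class = "msti_coefficients")
}

#' Predicted probability of lysis for a thrombus slice
#'
#' The logistic lysis-probability model
#' `P = exp(eta) / (1 + exp(eta))` with
#' `eta = beta0 + beta1 * T1 + beta2 * ADC`, T1 in ms and ADC in
#' 1e-3 mm^2/s. Numerically stable for `|eta|` up to at least 1e3 and
#' clamped to the open interval (0, 1).
#'
#' @param t1_ms T1 relaxation time in ms.
#' @param adc_e3 ADC in 1e-3 mm^2/s.
#' @param coeffs An `msti_coefficients` (default the published values).
#' @return Probability of lysis in (0, 1), vectorised over inputs.
#' @export
lysis_probability <- function(t1_ms, adc_e3,
                              coeffs = msti_human_coefficients()) {
  .assert(all(is.finite(t1_ms)) && all(is.finite(adc_e3)),
          "non-finite input to lysis_probability")
  eta <- coeffs$beta0 + coeffs$beta1 * t1_ms + coeffs$beta2 * adc_e3
  p <- ifelse(eta >= 0, 1 / (1 + exp(-eta)), exp(eta) / (1 + exp(eta)))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Fit a binary logistic lysis model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`) of a binary lysis outcome on a subset of the
#' slice parameters, with Wald 95% confidence intervals, odds ratios, and
#' the training AUC of the fitted probabilities. Complete separation is
#' flagged (coefficients diverging / fitted probabilities numerically 0 or
#' 1), not silently accepted.
#'
#' @param features Slice feature table including the predictor columns.
#' @param outcome Binary outcome: logical/0-1 vector, or the name of a
#'   column in `features` (`"lysed"` is treated as the positive class).
#' @param predictors Predictor column names (default `c("t1_ms", "adc_e3")`).
#' @return List with `coefficients` (data.frame: estimate, SE, z, p,
#'   odds_ratio, CI bounds), `auc`, `separation`, `converged`, `model_id`,
#'   and the underlying `fit`.
#' @export
fit_logistic <- function(features, outcome,
                         predictors = c("t1_ms", "adc_e3")) {
  if (is.character(outcome) && length(outcome) == 1) {
    y <- features[[outcome]]
    if (is.character(y) || is.factor(y)) y <- as.character(y) == "lysed"
  } else y <- outcome
  y <- as.numeric(y)
  .assert(all(y %in% c(0, 1)), "outcome must be binary")
  .assert(length(unique(y)) == 2, "both outcome classes must be present")
  missing_cols <- setdiff(predictors, names(features))
  if (length(missing_cols) > 0)
    stop("unknown predictor(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  .assert(length(y) > length(predictors) + 1,
          "need n > number of predictors + 1")
  dat <- features[, predictors, drop = FALSE]
  dat$.y <- y
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit))) stop("singular design matrix", call. = FALSE)
  fv <- fitted(fit)
  if (all(fv[y == 1] > 1 - 1e-8) && all(fv[y == 0] < 1e-8))
    separation <- TRUE
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zc <- qnorm(0.975)
  ctab <- data.frame(term = names(est), estimate = unname(est),
                     se = unname(se), z = unname(est / se),
                     p = unname(2 * pnorm(-abs(est / se))),
                     odds_ratio = unname(exp(est)),
                     or_lo = unname(exp(est - zc * se)),
                     or_hi = unname(exp(est + zc * se)))
  auc <- roc_analysis(fitted(fit), y, positive_direction = "higher")$auc
  list(coefficients = ctab, auc = auc, separation = separation,
       converged = fit$converged,
       model_id = paste0("logistic[", paste(predictors, collapse = "+"), "]"),
       fit = fit)
}

#' Per-slice lysability predictions
#'
#' Applies the cohort-appropriate model to a slice feature table: the
#' combined-cutoff conjunction (`model = "mouse-cutoffs"`) or the logistic
#' probability model (`model = "human-logistic"`; binary call at
#' `prob_threshold`).
#'
#' @param features Slice feature table.
#' @param model `"mouse-cutoffs"`, `"human-logistic"`, an
#'   `msti_cutoff_rule`, or an `msti_coefficients`.
#' @param prob_threshold Probability cut for the binary call (default 0.5;
#'   no operating threshold is published for the logistic model).
#' @return data.frame `subject_id`, `slice_index`, `P`, `call`, `model_id`.
#' @export
predict_lysis <- function(features, model = "human-logistic",
                          prob_threshold = 0.5) {
  if (inherits(model, "msti_cutoff_rule") ||
      identical(model, "mouse-cutoffs")) {
    rule <- if (inherits(model, "msti_cutoff_rule")) model else msti_mouse_rule()
    call <- classify_by_cutoffs(features, rule)
    out <- data.frame(subject_id = features$subject_id %||% NA,
                      slice_index = features$slice_index,
                      P = NA_real_, call = call,
                      model_id = "mouse-cutoffs")
  } else {
    coeffs <- if (inherits(model, "msti_coefficients")) model
              else msti_human_coefficients()
    p <- lysis_probability(features$t1_ms, features$adc_e3, coeffs)
    out <- data.frame(subject_id = features$subject_id %||% NA,
                      slice_index = features$slice_index,
                      P = p,
                      call = ifelse(p > prob_threshold, "lysable", "nonlysable"),
                      model_id = "human-logistic")
  }
  out
}

#' Lysis-probability heat-map volume and montage
#'
#' Paints each thrombus voxel with its slice's lysis probability (red = 0,
#' unlysable, through yellow to green = 1, lysable) and produces both the
#' overlay volume (for NIfTI export) and an RGB axial montage.
#'
#' @param predictions data.frame with `slice_index` (0-based) and `P`, one
#'   row per mask slice.
#' @param mask Logical thrombus mask volume.
#' @param out_prefix Optional path prefix; writes `<prefix>_heatmap.nii.gz`,
#'   `<prefix>_montage.png` and `<prefix>_slices.csv`.
#' @param voxel_size Voxel dimensions for the NIfTI header.
#' @return List with `volume` (probability overlay, NA outside thrombus),
#'   `montage` (H x W x 3 RGB array in \[0,1\]), and `per_slice` table.
#' @export
probability_heatmap <- function(predictions, mask, out_prefix = NULL,
                                voxel_size = c(1, 1, 1)) {
  nz <- dim(mask)[3]
  mask_slices <- which(vapply(seq_len(nz), function(z) any(mask[, , z]),
                              logical(1))) - 1L
  .assert(setequal(predictions$slice_index, mask_slices),
          "slice count mismatch between predictions and mask")
  p_of <- setNames(predictions$P, as.character(predictions$slice_index))
  vol <- array(NA_real_, dim(mask))
  for (z in mask_slices) {
    sl <- vol[, , z + 1L]
    sl[mask[, , z + 1L]] <- p_of[[as.character(z)]]
    vol[, , z + 1L] <- sl
  }
  # red (P=0) -> yellow (P=0.5) -> green (P=1)
  rgb_of <- function(p) {
    r <- ifelse(p <= 0.5, 1, 2 * (1 - p))
    g <- ifelse(p <= 0.5, 2 * p, 1)
    cbind(r, g, 0)
  }
  nx <- dim(mask)[1]; ny <- dim(mask)[2]
  nslices <- length(mask_slices)
  montage <- array(0.15, dim = c(ny, nx * nslices, 3))  # grey background
  for (j in seq_along(mask_slices)) {
    z <- mask_slices[j] + 1L
    msl <- t(mask[, , z])[ny:1, , drop = FALSE]
    cols <- rgb_of(p_of[[as.character(mask_slices[j])]])
    for (ch in 1:3) {
      pane <- montage[, (j - 1) * nx + seq_len(nx), ch]
      pane[msl] <- cols[ch]
      montage[, (j - 1) * nx + seq_len(nx), ch] <- pane
    }
  }
  per_slice <- data.frame(slice_index = predictions$slice_index,
                          P = predictions$P,
                          call = predictions$call %||% NA)
  if (!is.null(out_prefix)) {
    v <- vol; v[is.na(v)] <- 0
    RNifti::writeNifti(RNifti::asNifti(v, pixdim = voxel_size),
                       paste0(out_prefix, "_heatmap.nii.gz"))
    png::writePNG(montage, paste0(out_prefix, "_montage.png"))
    write.csv(per_slice, paste0(out_prefix, "_slices.csv"), row.names = FALSE)
  }
  list(volume = vol, montage = montage, per_slice = per_slice)
}
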