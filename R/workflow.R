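#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run
#' (simulate -> maps -> features -> predict -> evaluate) plus the root seed
#' from which all stage randomness is derived.
#'
#' @param cohort `"mouse"` or `"human"`; also selects the default prediction
#'   model (combined cutoffs vs logistic probability).
#' @param out_dir Run directory.
#' @param n_subjects Subjects per group.
#' @param slices_per_thrombus Thrombus extent in slices.
#' @param seed Root seed.
#' @param snr Acquisition signal-to-noise ratio.
#' @param b_values DWI b-values (s/mm^2).
#' @param inversion_times IR inversion times (ms).
#' @param statistic Slice summary statistic.
#' @param model Prediction model (default by cohort).
#' @param prob_threshold Probability threshold for the logistic call.
#' @param adc_max ADC exclusion threshold (1e-3 mm^2/s).
#' @param stages Subset of stages to run, in order.
#' @return An object of class `msti_pipeline_config`.
#' @export
msti_pipeline_config <- function(cohort = c("mouse", "human"), out_dir,
                                 n_subjects = 10, slices_per_thrombus = 10,
                                 seed = 1L, snr = 40, b_values = c(0, 600),
                                 inversion_times = exp(seq(log(100), log(5000),
                                                           length.out = 8)),
                                 statistic = "mean",
                                 model = NULL, prob_threshold = 0.5,
                                 adc_max = 2.0,
                                 stages = c("simulate", "maps", "features",
                                            "predict", "evaluate")) {
  cohort <- match.arg(cohort)
  if (is.null(model))
    model <- if (cohort == "mouse") "mouse-cutoffs" else "human-logistic"
  structure(list(cohort = cohort, out_dir = out_dir,
                 n_subjects = n_subjects,
                 slices_per_thrombus = slices_per_thrombus,
                 seed = as.integer(seed), snr = snr, b_values = b_values,
                 inversion_times = inversion_times, statistic = statistic,
                 model = model, prob_threshold = prob_threshold,
                 adc_max = adc_max, stages = stages),
            class = "msti_pipeline_config")
}

.stage_manifest <- function(out_dir, stage, params, outputs) {
  man <- list(stage = stage,
              package_version = as.character(packageVersion("msti")),
              parameters = params,
              outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(man,
                       file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full MSTI pipeline
#'
#' Executes the configured stages in order, writing every stage's outputs
#' and a manifest (parameters, seed, output checksums) under the run
#' directory. A rerun with the same config is bit-identical for the
#' deterministic stages.
#'
#' @param config An [msti_pipeline_config()].
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "msti_pipeline_config"),
          "config must be an msti_pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out, "simulate")
  maps_dir <- file.path(out, "maps")
  cc <- msti_cohort_config(config$cohort, n_subjects = config$n_subjects,
                           slices_per_thrombus = config$slices_per_thrombus,
                           seed = config$seed)
  proto <- msti_protocol(inversion_times = config$inversion_times,
                         b_values = config$b_values, snr = config$snr)

  if ("simulate" %in% config$stages) {
    idx <- simulate_cohort(cc, proto, sim_dir)
    .stage_manifest(out, "simulate",
                    list(cohort = config$cohort, seed = config$seed,
                         n_subjects = config$n_subjects, snr = config$snr),
                    file.path(sim_dir, "cohort_manifest.json"))
  }
  subject_dirs <- list.dirs(sim_dir, recursive = FALSE)
  if (length(subject_dirs) == 0)
    stop("configuration error: no simulated subjects under ", sim_dir,
         call. = FALSE)

  if ("maps" %in% config$stages) {
    outs <- character()
    for (sdir in subject_dirs) {
      sub <- read_subject_stack(sdir)
      maps <- suppressMessages(
        compute_maps(sub$stack, sub$mask_vessel, adc_max = config$adc_max))
      outs <- c(outs, write_maps(maps, file.path(maps_dir, basename(sdir))))
    }
    .stage_manifest(out, "maps", list(adc_max = config$adc_max), outs)
  }

  feat_file <- file.path(out, "features.csv")
  if ("features" %in% config$stages) {
    feats <- lapply(subject_dirs, function(sdir) {
      sub <- read_subject_stack(sdir)
      maps <- suppressMessages(
        compute_maps(sub$stack, sub$mask_thrombus, adc_max = config$adc_max))
      truth <- read.csv(file.path(sdir, "truth.csv"))
      suppressWarnings(extract_slice_features(
        maps, sub$mask_thrombus, statistic = config$statistic,
        subject_id = basename(sdir), outcome_label = truth$label[1]))
    })
    feats <- do.call(rbind, feats)
    write.csv(feats, feat_file, row.names = FALSE)
    .stage_manifest(out, "features",
                    list(statistic = config$statistic), feat_file)
  }

  pred_file <- file.path(out, "predictions.csv")
  if ("predict" %in% config$stages) {
    if (!file.exists(feat_file))
      stop("configuration error: features.csv missing; run the features stage",
           call. = FALSE)
    feats <- read.csv(feat_file)
    preds <- predict_lysis(feats, model = config$model,
                           prob_threshold = config$prob_threshold)
    write.csv(preds, pred_file, row.names = FALSE)
    if (config$model == "human-logistic") {
      for (sdir in subject_dirs) {
        sid <- basename(sdir)
        sub_pred <- preds[preds$subject_id == sid, ]
        sub <- read_subject_stack(sdir)
        present <- which(apply(sub$mask_thrombus, 3, any)) - 1L
        sub_pred <- sub_pred[sub_pred$slice_index %in% present, ]
        if (setequal(sub_pred$slice_index, present))
          probability_heatmap(sub_pred, sub$mask_thrombus,
                              out_prefix = file.path(out, paste0("heatmap_", sid)),
                              voxel_size = sub$stack$voxel_size)
      }
    }
    .stage_manifest(out, "predict",
                    list(model = config$model,
                         prob_threshold = config$prob_threshold), pred_file)
  }

  if ("evaluate" %in% config$stages) {
    feats <- read.csv(feat_file)
    preds <- read.csv(pred_file)
    report_file <- file.path(out, "report.json")
    keep <- !is.na(preds$call)
    metrics <- diagnostic_metrics(preds$call[keep],
                                  ifelse(feats$outcome_label[keep] == "lysed",
                                         "lysable", "nonlysable"),
                                  positive = "lysable")
    y <- feats$outcome_label == "lysed"
    group_tests <- lapply(c(t1_ms = "t1_ms", mtr_pct = "mtr_pct",
                            adc_e3 = "adc_e3"), function(col) {
      mw <- mann_whitney_u(feats[[col]][y], feats[[col]][!y])
      list(median_lysed = median(feats[[col]][y]),
           median_nonlysed = median(feats[[col]][!y]),
           U = mw$U, p = mw$p)
    })
    roc <- if (!all(is.na(preds$P)))
      roc_analysis(preds$P[keep], y[keep], positive_direction = "higher")
    else NULL
    report <- list(schema_version = "1.0",
                   cohort = config$cohort, seed = config$seed,
                   n_slices = nrow(feats),
                   diagnostic = metrics[c("sensitivity", "specificity",
                                          "ppv", "npv")],
                   counts = as.list(metrics$counts),
                   group_tests = group_tests,
                   auc = if (!is.null(roc)) roc$auc else NA,
                   youden_threshold = if (!is.null(roc)) roc$youden_threshold
                                      else NA)
    jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    .stage_manifest(out, "evaluate", list(model = config$model), report_file)
  }
  invisible(out)
}

#' One-command demonstration run
#'
#' Runs the full mouse-preset pipeline on a small cohort and prints the
#' evaluation summary.
#'
#' @param out_dir Run directory (default a temporary directory).
#' @param n_subjects Subjects per group (default 10, i.e. 20 subjects).
#' @param seed Root seed.
#' @return Invisibly, the parsed `report.json`.
#' @export
msti_demo <- function(out_dir = file.path(tempdir(), "msti_demo"),
                      n_subjects = 10, seed = 7L) {
  cfg <- msti_pipeline_config("mouse", out_dir, n_subjects = n_subjects,
                              seed = seed)
  run_pipeline(cfg)
  report <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  cat(sprintf("mouse demo (%d subjects/group): sens %.2f spec %.2f on %d slices\n",
              n_subjects, report$diagnostic$sensitivity,
              report$diagnostic$specificity, report$n_slices))
  invisible(report)
}
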