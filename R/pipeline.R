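# End-to-end orchestration: simulate -> extract -> statistics -> classify,
# reproducibly from one configuration object.

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n_per_group cohort layout (default 50 healthy / 36 FFKC / 50 KC).
#' @param group_configs cohort distributions ([cohort_defaults()]).
#' @param airpuff an [airpuff_config()].
#' @param sim a [sim_config()].
#' @param window stiffness slope window, mm.
#' @param contrasts list of 2-vectors of group names for the ROC tables.
#' @param roc_params parameter columns entering the per-contrast ROC table.
#' @param classifier an [mlp_config()].
#' @param use_measured_rp use the measured first-applanation radius in the
#'   shell relation instead of the configured `rp`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_group = c(healthy = 50, FFKC = 36, KC = 50),
                            group_configs = cohort_defaults(),
                            airpuff = airpuff_config(),
                            sim = sim_config(),
                            window = c(0.2, 0.4),
                            contrasts = list(c("healthy", "KC"),
                                             c("healthy", "FFKC"),
                                             c("KC", "FFKC")),
                            roc_params = c("A1T", "A1V", "A2T", "A2V", "PD",
                                           "DA", "SP_A1", "ARTh", "S_TSC",
                                           "E"),
                            classifier = mlp_config(),
                            use_measured_rp = FALSE) {
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 group_configs = group_configs, airpuff = airpuff,
                 sim = sim, window = window, contrasts = contrasts,
                 roc_params = roc_params, classifier = classifier,
                 use_measured_rp = use_measured_rp),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Scalar overrides (`seed`, `n_per_group`, `window`, `use_measured_rp`,
#' and the fields of `airpuff`, `sim` and `classifier`) are merged into
#' the defaults of [pipeline_config()].
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (f in c("seed", "window", "use_measured_rp", "roc_params")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$n_per_group)) args$n_per_group <- unlist(raw$n_per_group)
  if (!is.null(raw$airpuff)) args$airpuff <- do.call(airpuff_config, raw$airpuff)
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$classifier)) args$classifier <- do.call(mlp_config, raw$classifier)
  do.call(pipeline_config, args)
}

#' Run the full simulated study
#'
#' Generates a cohort, simulates and extracts every examination, assembles
#' the group-comparison and ROC tables for every parameter and contrast,
#' trains the 12-5-1 classifier on the 70/30 split, and tabulates modulus
#' recovery (estimated versus true E).  Subjects whose extraction fails a
#' quality gate are excluded from statistics and counted, never silently
#' dropped.  Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress to stderr.
#' @return object of class `study_report`: list with `cohort`, `subjects`
#'   (per-subject extraction + truth), `group_tables`, `roc_tables`,
#'   `agreement_R`, `classifier`, `recovery`, `exclusions` and `timings`.
#' @export
run_study <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  timings <- list()

  t0 <- tic()
  cohort <- generate_cohort(config$n_per_group, config$group_configs,
                            seed = config$seed)
  timings$simulate_cohort <- as.numeric(tic() - t0, units = "secs")
  say("cohort: %d subjects in %d groups", nrow(cohort),
      nlevels(cohort$group))

  t0 <- tic()
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- cohort[i, ]
    row <- tryCatch({
      exam <- simulate_examination(sub, config$airpuff, config$sim)
      extract_subject(exam, config$airpuff, config$window,
                      use_measured_rp = config$use_measured_rp)
    }, error = function(e) {
      stop(sprintf("stage extract failed for subject %s: %s",
                   sub$subject_id, conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- row
  }
  subjects <- do.call(rbind, rows)
  subjects <- cbind(subjects,
                    cohort[, c("group", "E_true", "R", "CCT", "t", "bIOP",
                               "SP_A1", "ARTh", "B_Ele_Th", "Kmax",
                               "Pachymin")])
  timings$simulate_extract <- as.numeric(tic() - t0, units = "secs")

  ok <- is.finite(subjects$E) & is.finite(subjects$A1T) &
    subjects$quality_flags == ""
  exclusions <- subjects[!ok, c("subject_id", "quality_flags")]
  good <- subjects[ok, ]
  say("extraction: %d/%d subjects pass QC", nrow(good), nrow(subjects))

  t0 <- tic()
  stat_params <- intersect(c("A1T", "A1V", "A2T", "A2V", "HCT", "PD", "DA",
                             "SP_A1", "ARTh", "S_TSC", "E"), names(good))
  group_tables <- lapply(stat_params, function(p) {
    anova_lsd(split(good[[p]], good$group))
  })
  names(group_tables) <- stat_params

  roc_tables <- list()
  for (ct in config$contrasts) {
    key <- paste(ct[2], "vs", ct[1])
    sel <- good$group %in% ct
    lab <- droplevels(good$group[sel])
    tab <- do.call(rbind, lapply(config$roc_params, function(p) {
      r <- roc_curve(good[[p]][sel], lab == ct[2])
      data.frame(parameter = p, cutoff = r$cutoff,
                 specificity = r$specificity, sensitivity = r$sensitivity,
                 auc = r$auc, direction = r$direction)
    }))
    roc_tables[[key]] <- tab
  }
  agreement_R <- agreement_suite(good$R, good$R_fit)
  timings$statistics <- as.numeric(tic() - t0, units = "secs")

  t0 <- tic()
  feats <- good
  feats$E <- good$E                    # estimated modulus feeds the model
  cls_cfg <- config$classifier
  cls_cfg$seed <- derive_seed(config$seed, 999983)
  sp <- split_data(feats, cls_cfg$train_fraction, seed = cls_cfg$seed)
  model <- mlp_train(sp$train, cls_cfg)
  pred_val <- mlp_predict(model, sp$validation)
  pred_grp <- classify_values(pred_val, sp$validation$group)
  acc <- attr(pred_grp, "accuracy")
  # screening contrast on the verification set: FFKC vs healthy
  vsel <- sp$validation$group %in% c("healthy", "FFKC")
  pred_roc <- NULL
  comparisons <- NULL
  if (sum(vsel) >= 4 && length(unique(sp$validation$group[vsel])) == 2) {
    lab_v <- sp$validation$group[vsel] == "FFKC"
    pred_roc <- roc_curve(pred_val[vsel], lab_v)
    comparisons <- do.call(rbind, lapply(c("E", "A1T", "SP_A1"), function(p) {
      cmp <- roc_compare(pred_val[vsel], sp$validation[[p]][vsel], lab_v)
      data.frame(against = p, auc_model = cmp$auc1, auc_param = cmp$auc2,
                 z = cmp$z, p = cmp$p)
    }))
  }
  timings$classifier <- as.numeric(tic() - t0, units = "secs")
  say("classifier: validation accuracy %.1f%% (%d/%d rows)",
      100 * acc, length(pred_val), nrow(feats))

  rec_err <- (good$E - good$E_true) / good$E_true
  recovery <- list(
    table = data.frame(subject_id = good$subject_id, group = good$group,
                       E_true = good$E_true, E_hat = good$E,
                       rel_error = rec_err),
    bias = mean(rec_err), median_abs_rel_error = stats::median(abs(rec_err)),
    rmse_rel = sqrt(mean(rec_err^2)))

  structure(
    list(config = config, cohort = cohort, subjects = subjects,
         group_tables = group_tables, roc_tables = roc_tables,
         agreement_R = agreement_R,
         classifier = list(model = model, validation_accuracy = acc,
                           predicted = pred_val,
                           validation_groups = sp$validation$group,
                           pred_roc = pred_roc, comparisons = comparisons,
                           train_idx = sp$train_idx),
         recovery = recovery, exclusions = exclusions, timings = timings),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d subjects (%d excluded by QC)\n",
              nrow(x$subjects), nrow(x$exclusions)))
  cat(sprintf("  E recovery: bias %.2f%%, median |rel err| %.2f%%\n",
              100 * x$recovery$bias, 100 * x$recovery$median_abs_rel_error))
  for (k in names(x$roc_tables)) {
    e_row <- x$roc_tables[[k]][x$roc_tables[[k]]$parameter == "E", ]
    cat(sprintf("  AUC(E, %s) = %.3f\n", k, e_row$auc))
  }
  cat(sprintf("  classifier validation accuracy: %.1f%%\n",
              100 * x$classifier$validation_accuracy))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits tidy CSVs (cohort, per-subject results, ROC tables), the model
#' JSON, a machine-readable `report.json` and a human-readable
#' `report.md` with the group and ROC tables.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  roc_all <- do.call(rbind, lapply(names(report$roc_tables), function(k) {
    cbind(contrast = k, report$roc_tables[[k]])
  }))
  utils::write.csv(roc_all, file.path(dir, "roc_tables.csv"),
                   row.names = FALSE)
  write_mlp_json(report$classifier$model, file.path(dir, "classifier.json"))
  group_summ <- do.call(rbind, lapply(names(report$group_tables), function(p) {
    gt <- report$group_tables[[p]]
    cbind(parameter = p, gt$summary, F = gt$F, p_anova = gt$p)
  }))
  utils::write.csv(group_summ, file.path(dir, "group_tables.csv"),
                   row.names = FALSE)
  json <- list(
    n_subjects = nrow(report$subjects),
    n_excluded = nrow(report$exclusions),
    recovery = report$recovery[c("bias", "median_abs_rel_error", "rmse_rel")],
    auc_E = lapply(report$roc_tables, function(t) t$auc[t$parameter == "E"]),
    classifier_validation_accuracy = report$classifier$validation_accuracy,
    timings = report$timings)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Simulated air-puff study report", "",
          sprintf("- subjects: %d (%d excluded by QC)", nrow(report$subjects),
                  nrow(report$exclusions)),
          sprintf("- E recovery: bias %.2f%%, median |rel err| %.2f%%",
                  100 * report$recovery$bias,
                  100 * report$recovery$median_abs_rel_error),
          sprintf("- classifier validation accuracy: %.1f%%",
                  100 * report$classifier$validation_accuracy), "",
          "## AUC of E by contrast", "")
  for (k in names(report$roc_tables)) {
    e_row <- report$roc_tables[[k]][report$roc_tables[[k]]$parameter == "E", ]
    md <- c(md, sprintf("- %s: AUC %.3f (cutoff %.3g, sens %.3f, spec %.3f)",
                        k, e_row$auc, e_row$cutoff, e_row$sensitivity,
                        e_row$specificity))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Modulus recovery experiment
#'
#' For every combination of true modulus and noise level, simulates
#' `n_reps` examinations of a template subject, runs the extraction chain
#' and tabulates the bias, median absolute relative error and relative
#' RMSE of the recovered modulus.
#'
#' @param E_grid true moduli, MPa.
#' @param noise_levels elevation noise SDs, mm.
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param geometry template geometry (healthy-mean by default).
#' @param airpuff an [airpuff_config()].
#' @param sim base [sim_config()] (its `sigma_noise` is overridden per cell).
#' @param bIOP template bIOP, mmHg.
#' @return data frame with one row per `(E, noise)` cell: `bias`,
#'   `median_abs_rel_error`, `rmse_rel`, `n_ok`.
#' @export
recovery_experiment <- function(E_grid, noise_levels = 0.002, n_reps = 50,
                                seed = 1L,
                                geometry = cornea_geometry(7.75, 0.5345),
                                airpuff = airpuff_config(),
                                sim = sim_config(), bIOP = 15.3) {
  stopifnot(length(E_grid) >= 1)
  cells <- expand.grid(E = E_grid, noise = noise_levels)
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    E <- cells$E[ci]
    sim_i <- sim
    sim_i$sigma_noise <- cells$noise[ci]
    errs <- vapply(seq_len(n_reps), function(r) {
      sub <- list(subject_id = sprintf("cell%d_rep%d", ci, r),
                  E_true = E, R = geometry$R, t = geometry$t,
                  nu = geometry$nu, bIOP = bIOP,
                  seed = derive_seed(seed, ci * 100003 + r))
      exam <- simulate_examination(sub, airpuff, sim_i)
      row <- extract_subject(exam, airpuff)
      if (is.finite(row$E)) (row$E - E) / E else NA_real_
    }, numeric(1))
    ok <- errs[is.finite(errs)]
    data.frame(E_true = E, noise = cells$noise[ci],
               bias = mean(ok), median_abs_rel_error = stats::median(abs(ok)),
               rmse_rel = sqrt(mean(ok^2)), n_ok = length(ok))
  })
  do.call(rbind, out)
}
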