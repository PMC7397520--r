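#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the simulate -> quantify -> score -> evaluate
#' chain in one validated object. `"stats_only"` mode draws patient ratios
#' directly from the cohort distributions; `"phantom"` mode additionally
#' renders a voxel phantom per patient whose tissue rates realize the drawn
#' ratios, measures the ROIs on the rendered volumes, and carries the
#' measured ratios forward.
#'
#' @param mode `"stats_only"` or `"phantom"`.
#' @param seed Integer seed controlling every random draw of the run.
#' @param cohort Named list of [cohort_spec()] overrides (all but `seed`).
#' @param anatomy Named list of [anatomy_model()] overrides (phantom mode).
#' @param uptake Named list of [uptake_params()] overrides (phantom mode);
#'   the affected-head and acetabular rates are derived per patient from
#'   the drawn ratios.
#' @param roi Named list with `head_diameter` and `dome_diameter` (mm).
#' @param cutoffs Named list with classification cutoffs `head_to_head`
#'   and `head_to_acetabulum`.
#' @param alpha Significance level for all confidence intervals.
#' @param out_dir Optional output directory; when set, every intermediate
#'   artifact (manifest, scored cohorts, ROC tables, JSON and text report)
#'   is written there.
#' @param write_volumes Write per-patient NIfTI volumes in phantom mode.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("stats_only", "phantom"),
                       seed,
                       cohort = list(),
                       anatomy = list(),
                       uptake = list(),
                       roi = list(head_diameter = 30, dome_diameter = 10),
                       cutoffs = list(head_to_head = 0.5,
                                      head_to_acetabulum = 0.3),
                       alpha = 0.05,
                       out_dir = NULL,
                       write_volumes = FALSE) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory", call. = FALSE)
  if (is.null(roi$head_diameter)) roi$head_diameter <- 30
  if (is.null(roi$dome_diameter)) roi$dome_diameter <- 10
  if (roi$head_diameter <= 0 || roi$dome_diameter <= 0)
    stop("ROI diameters must be positive", call. = FALSE)
  if (is.null(cutoffs$head_to_head) || is.null(cutoffs$head_to_acetabulum))
    stop("`cutoffs` must name head_to_head and head_to_acetabulum",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  # validate module parameters eagerly so a bad config fails at build time
  do.call(cohort_spec, c(cohort, list(seed = as.integer(seed))))
  if (mode == "phantom") do.call(anatomy_model, anatomy)
  structure(
    list(mode = mode, seed = as.integer(seed), cohort = cohort,
         anatomy = anatomy, uptake = uptake, roi = roi, cutoffs = cutoffs,
         alpha = alpha, out_dir = out_dir, write_volumes = write_volumes),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' The YAML form round-trips losslessly through [run_config()].
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  for (nm in c("cohort", "anatomy", "uptake", "roi", "cutoffs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.list(raw[[nm]])
  do.call(run_config, raw)
}

# Derived per-patient RNG seed, kept inside 32-bit integer range.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131071 + i * 7919) %% 2147483629)
}

# Render one patient's phantom, quantify the three ROIs, and return the
# measured uptakes plus ratios.  The affected-head and dome rates realize
# the patient's drawn ratios against the fixed unaffected-head rate.
quantify_patient_phantom <- function(record, config, index = 1L) {
  anatomy <- do.call(anatomy_model, config$anatomy)
  up_over <- config$uptake
  base_unaffected <- up_over$cancellous_head_rate_unaffected %||% 201.3
  affected_rate <- record$head_to_head_ratio * base_unaffected
  dome_rate <- affected_rate / record$head_to_acetabulum_ratio
  up_args <- utils::modifyList(
    list(cancellous_head_rate_affected = affected_rate,
         cancellous_head_rate_unaffected = base_unaffected,
         acetabular_rate = dome_rate,
         noise_model = "none"),
    up_over[setdiff(names(up_over),
                    c("cancellous_head_rate_affected", "acetabular_rate",
                      "seed"))]
  )
  if (identical(up_args$noise_model, "poisson"))
    up_args$seed <- patient_seed(config$seed, index)
  uptake <- do.call(uptake_params, up_args)
  ph <- build_hip_phantom(anatomy, uptake, affected_side = record$affected_side)

  side_aff <- record$affected_side
  side_un <- if (side_aff == "left") "right" else "left"
  ctr_aff <- anatomy[[paste0("femoral_head_center_", side_aff)]]
  ctr_un <- anatomy[[paste0("femoral_head_center_", side_un)]]
  ctr_dome <- anatomy[[paste0("acetabular_dome_center_", side_aff)]]

  roi_aff <- make_head_roi(ph$counts, ph$labels, ctr_aff,
                           diameter = config$roi$head_diameter)
  roi_un <- make_head_roi(ph$counts, ph$labels, ctr_un,
                          diameter = config$roi$head_diameter)
  roi_dome <- make_acetabular_roi(ph$counts, ph$labels, ctr_dome,
                                  diameter = config$roi$dome_diameter)
  m_aff <- roi_mean_uptake(ph$counts, roi_aff, ph$labels)
  m_un <- roi_mean_uptake(ph$counts, roi_un, ph$labels)
  m_dome <- roi_mean_uptake(ph$counts, roi_dome, ph$labels)

  list(phantom = ph,
       landmarks = list(head_affected = ctr_aff, head_unaffected = ctr_un,
                        acetabulum_affected = ctr_dome),
       uptake_head_affected = m_aff$combined_mean,
       uptake_head_unaffected = m_un$combined_mean,
       uptake_acetabulum_affected = m_dome$combined_mean,
       measurements = list(head_affected = m_aff, head_unaffected = m_un,
                           acetabulum_affected = m_dome))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-group means and normal-theory confidence intervals
#'
#' Summarizes the cohort's measured uptakes (when present) and both uptake
#' ratios per outcome group, reporting the mean and the normal-approximation
#' interval `mean +/- z * sd / sqrt(n)`. Groups of fewer than 2 patients get
#' the mean with the CI omitted and flagged.
#'
#' @param records Cohort data frame with an `outcome` column.
#' @param alpha Significance level (CIs at level `1 - alpha`).
#' @return A data frame with columns `quantity`, `group`, `n`, `mean`,
#'   `ci_lower`, `ci_upper`, `ci_omitted`.
#' @export
table3_summary <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), "outcome" %in% names(records))
  z <- stats::qnorm(1 - alpha / 2)
  quantities <- intersect(
    c("uptake_head_affected", "uptake_head_unaffected",
      "uptake_acetabulum_affected",
      "head_to_head_ratio", "head_to_acetabulum_ratio"),
    names(records)
  )
  rows <- list()
  for (q in quantities) {
    for (g in c("onfh", "union")) {
      x <- records[[q]][records$outcome == g]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n == 0L) next
      m <- mean(x)
      if (n >= 2L) {
        half <- z * stats::sd(x) / sqrt(n)
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = q, group = g, n = n, mean = m,
          ci_lower = m - half, ci_upper = m + half, ci_omitted = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = q, group = g, n = n, mean = m,
          ci_lower = NA_real_, ci_upper = NA_real_, ci_omitted = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

evaluate_ratio <- function(records, ratio_col, cutoff, alpha) {
  scores <- records[[ratio_col]]
  pred <- classify_perfusion(scores, cutoff)
  tab <- contingency(records$outcome, pred)
  met <- accuracy_metrics(tab)
  lr <- tryCatch(likelihood_ratios(tab, alpha = alpha),
                 error = function(e) NULL)
  rc <- roc_curve(scores, records$outcome, orientation = "lower_is_positive")
  yc <- youden_cutoff(rc)
  list(ratio = ratio_col, cutoff = cutoff, table = tab, metrics = met,
       likelihood_ratios = lr, roc = rc, youden = yc)
}

#' Run the full analysis pipeline
#'
#' Simulates (or renders and quantifies) a cohort, scores both uptake
#' ratios at their configured cutoffs, evaluates diagnostic accuracy,
#' builds both ROC curves with Youden cutoffs, compares the two AUCs by
#' the paired DeLong test, and summarizes per-group ratio distributions.
#' The run is a pure function of its configuration: the same config (and
#' seed) reproduces the identical report and artifacts byte for byte.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: `config`, `records` (the
#'   scored cohort), `table3` (group summaries), `evaluations` (one per
#'   ratio: 2x2 table, metrics, likelihood ratios, ROC, Youden cutoff),
#'   `delong` (paired AUC comparison), and `artifact_paths` when an
#'   output directory was configured.
#' @export
#' @examples
#' rep <- run_pipeline(run_config(seed = 1))
#' rep$evaluations$head_to_head$metrics
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  records <- simulate_cohort(spec)

  quantification <- NULL
  if (config$mode == "phantom") {
    qrows <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      res <- tryCatch(
        quantify_patient_phantom(records[i, ], config, index = i),
        error = function(e)
          stop(sprintf("quantify stage failed for patient %s: %s",
                       records$patient_id[i], conditionMessage(e)),
               call. = FALSE)
      )
      records$uptake_head_affected[i] <- res$uptake_head_affected
      records$uptake_head_unaffected[i] <- res$uptake_head_unaffected
      records$uptake_acetabulum_affected[i] <- res$uptake_acetabulum_affected
      lm <- res$landmarks
      records[i, c("head_affected_x", "head_affected_y", "head_affected_z")] <-
        as.list(lm$head_affected)
      records[i, c("head_unaffected_x", "head_unaffected_y",
                   "head_unaffected_z")] <- as.list(lm$head_unaffected)
      records[i, c("acetabulum_affected_x", "acetabulum_affected_y",
                   "acetabulum_affected_z")] <- as.list(lm$acetabulum_affected)
      # measured ratios replace the drawn (latent) ones
      records$head_to_head_ratio[i] <- head_to_head_ratio(
        res$uptake_head_affected, res$uptake_head_unaffected)
      records$head_to_acetabulum_ratio[i] <- head_to_acetabulum_ratio(
        res$uptake_head_affected, res$uptake_acetabulum_affected)
      qrows[[i]] <- do.call(rbind, lapply(
        names(res$measurements), function(site) {
          mm <- res$measurements[[site]]
          data.frame(patient_id = records$patient_id[i], site = site,
                     coronal = mm$plane_means[["coronal"]],
                     axial = mm$plane_means[["axial"]],
                     sagittal = mm$plane_means[["sagittal"]],
                     combined_mean = mm$combined_mean,
                     n_voxels = sum(mm$n_voxels))
        }))
      if (!is.null(config$out_dir) && isTRUE(config$write_volumes)) {
        vdir <- file.path(config$out_dir, "volumes")
        dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
        cp <- file.path(vdir, paste0(records$patient_id[i], "_counts.nii.gz"))
        lp <- file.path(vdir, paste0(records$patient_id[i], "_labels.nii.gz"))
        write_volume_nifti(res$phantom$counts, cp)
        write_volume_nifti(res$phantom$labels, lp)
        records$counts_path[i] <- cp
        records$labels_path[i] <- lp
      }
    }
    quantification <- do.call(rbind, qrows)
  } else {
    records$uptake_head_affected <- NA_real_
    records$uptake_head_unaffected <- NA_real_
    records$uptake_acetabulum_affected <- NA_real_
  }

  evaluations <- list(
    head_to_head = evaluate_ratio(records, "head_to_head_ratio",
                                  config$cutoffs$head_to_head, config$alpha),
    head_to_acetabulum = evaluate_ratio(records, "head_to_acetabulum_ratio",
                                        config$cutoffs$head_to_acetabulum,
                                        config$alpha)
  )
  delong <- delong_test(records$head_to_head_ratio,
                        records$head_to_acetabulum_ratio,
                        records$outcome, orientation = "lower_is_positive",
                        paired = TRUE)
  scored <- score_cohort(records, config$cutoffs$head_to_head, ratio = "auto")
  report <- structure(
    list(config = config, records = scored,
         quantification = quantification,
         table3 = table3_summary(records, config$alpha),
         evaluations = evaluations, delong = delong),
    class = "run_report"
  )
  if (!is.null(config$out_dir))
    report$artifact_paths <- write_run_report(report, config$out_dir)
  report
}

roc_table <- function(rc) {
  data.frame(threshold = rc$thresholds, sensitivity = rc$sensitivity,
             specificity = rc$specificity,
             youden_j = rc$sensitivity + rc$specificity - 1)
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    manifest = file.path(out_dir, "cohort_manifest.csv"),
    scored = file.path(out_dir, "scored_cohort.csv"),
    table3 = file.path(out_dir, "group_summary.csv"),
    report_json = file.path(out_dir, "report.json"),
    report_txt = file.path(out_dir, "report.txt")
  )
  write_cohort_manifest(
    report$records[, intersect(names(report$records),
                               c(manifest_required_cols(),
                                 grep("_[xyz]$|_path$|^uptake_",
                                      names(report$records), value = TRUE)))],
    paths$manifest)
  utils::write.csv(report$records, paths$scored, row.names = FALSE)
  utils::write.csv(report$table3, paths$table3, row.names = FALSE)
  if (!is.null(report$quantification)) {
    paths$quantification <- file.path(out_dir, "quantification.csv")
    utils::write.csv(report$quantification, paths$quantification,
                     row.names = FALSE)
  }
  for (nm in names(report$evaluations)) {
    p <- file.path(out_dir, paste0("roc_", nm, ".csv"))
    utils::write.csv(roc_table(report$evaluations[[nm]]$roc), p,
                     row.names = FALSE)
    paths[[paste0("roc_", nm)]] <- p
  }
  json <- list(
    seed = report$config$seed,
    mode = report$config$mode,
    alpha = report$config$alpha,
    table3 = report$table3,
    evaluations = lapply(report$evaluations, function(ev) list(
      ratio = ev$ratio, cutoff = ev$cutoff,
      counts = unclass(ev$table), metrics = ev$metrics,
      likelihood_ratios = if (!is.null(ev$likelihood_ratios))
        unclass(ev$likelihood_ratios) else NULL,
      auc = ev$roc$auc, youden = ev$youden)),
    delong = unclass(report$delong)
  )
  jsonlite::write_json(json, paths$report_json, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  writeLines(utils::capture.output(print(report)), paths$report_txt)
  paths
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (mode = %s, seed = %d): %d patients, %d ONFH\n\n",
              x$config$mode, x$config$seed, nrow(x$records),
              sum(x$records$outcome == "onfh")))
  cat("Group summaries (mean, normal 95% CI):\n")
  t3 <- x$table3
  for (i in seq_len(nrow(t3)))
    cat(sprintf("  %-28s %-6s n=%2d  %.3f (%.3f-%.3f)%s\n",
                t3$quantity[i], t3$group[i], t3$n[i], t3$mean[i],
                t3$ci_lower[i], t3$ci_upper[i],
                if (t3$ci_omitted[i]) " [CI omitted: n < 2]" else ""))
  for (nm in names(x$evaluations)) {
    ev <- x$evaluations[[nm]]
    cat(sprintf("\n%s @ cutoff %.2f: tp=%d fp=%d fn=%d tn=%d\n",
                nm, ev$cutoff, ev$table$tp, ev$table$fp, ev$table$fn,
                ev$table$tn))
    cat(sprintf("  sens %.1f%%  spec %.1f%%  acc %.1f%%  AUC %.3f\n",
                100 * ev$metrics$sensitivity, 100 * ev$metrics$specificity,
                100 * ev$metrics$accuracy, ev$roc$auc))
    if (!is.null(ev$likelihood_ratios)) {
      lr <- ev$likelihood_ratios
      fmt_ci <- function(ci) if (is.null(ci)) "CI omitted"
        else sprintf("(%.2f-%.2f)", ci[1], ci[2])
      cat(sprintf("  LR+ %.2f %s  LR- %.2f %s\n", lr$lr_pos,
                  fmt_ci(lr$ci_lr_pos), lr$lr_neg, fmt_ci(lr$ci_lr_neg)))
    }
    cat(sprintf("  Youden cutoff %.3f (sens %.1f%%, spec %.1f%%)\n",
                ev$youden$cutoff, 100 * ev$youden$sensitivity,
                100 * ev$youden$specificity))
  }
  cat(sprintf("\nDeLong paired AUC comparison: %.3f vs %.3f, p = %.3f\n",
              x$delong$auc_a, x$delong$auc_b, x$delong$p_value))
  invisible(x)
}
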