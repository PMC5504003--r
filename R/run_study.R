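#' Run the complete observational study analysis
#'
#' Applies eligibility screening, derives ocular perfusion pressure, compares
#' the groups at baseline and analyses the longitudinal course of every
#' circulatory variable in the treated (POAG) group, producing output shaped
#' like a clinical paper's baseline-characteristics and longitudinal-change
#' tables.
#'
#' Eligibility: all subjects need best-corrected visual acuity of 20/40 or
#' better (logMAR <= 0.301); when visual-field tests are supplied, POAG
#' subjects additionally need a reliable, glaucomatous 24-2 field per
#' [classify_vf_glaucomatous()].
#'
#' @param cohort subject-visit data.frame (schema of [simulate_cohort()]).
#' @param vf_tests optional named list of \code{vf_test} objects keyed by
#'   POAG \code{subject_id}; subjects without a supplied test are retained.
#' @param config list of options: \code{variables} (longitudinal roster;
#'   default pBFV, MBR_T, RVD_A, RVD_V, IOP, OPP, sBP, dBP), \code{alpha}
#'   (default 0.05), \code{welch}, \code{sphericity_correction},
#'   \code{bcva_logmar_max} (default 0.301).
#' @return object of class \code{study_report}: \code{eligibility}
#'   (per-subject flags), \code{table1} (baseline [compare_groups()], or
#'   \code{NULL} when a group has fewer than 2 baseline records),
#'   \code{table2} (per variable: per-visit mean +/- SD, RM-ANOVA p, three
#'   Bonferroni-flagged post hoc p-values), \code{longitudinal} (full
#'   [longitudinal_analysis()] objects).
#' @export
run_study <- function(cohort, vf_tests = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(variables = c("pbfv_mm_s", "mbr_t_au", "rvd_a_um", "rvd_v_um",
                       "iop_mmHg", "opp_mmHg", "sbp_mmHg", "dbp_mmHg"),
         alpha = 0.05, welch = FALSE, sphericity_correction = "none",
         bcva_logmar_max = 0.301),
    config)
  need <- c("subject_id", "group", "visit", "bcva_logmar")
  if (!all(need %in% names(cohort)))
    stopf("cohort lacks required columns: %s",
          paste(setdiff(need, names(cohort)), collapse = ", "))

  cohort$opp_mmHg <- compute_opp(cohort$sbp_mmHg, cohort$dbp_mmHg,
                                 cohort$iop_mmHg)

  subj <- unique(cohort[, c("subject_id", "group")])
  base_bcva <- cohort[cohort$visit == "baseline",
                      c("subject_id", "bcva_logmar")]
  subj$bcva_ok <- base_bcva$bcva_logmar[match(subj$subject_id,
                                              base_bcva$subject_id)] <=
    cfg$bcva_logmar_max
  subj$vf_status <- NA_character_
  if (!is.null(vf_tests)) {
    for (i in which(subj$group == "POAG")) {
      vt <- vf_tests[[subj$subject_id[i]]]
      if (!is.null(vt))
        subj$vf_status[i] <- classify_vf_glaucomatous(vt)
    }
  }
  subj$eligible <- subj$bcva_ok &
    (subj$group == "healthy" | is.na(subj$vf_status) |
       subj$vf_status == "glaucomatous")
  keep_ids <- subj$subject_id[subj$eligible %in% TRUE]
  if (!length(keep_ids)) stopf("no eligible subjects remain")
  elig <- cohort[cohort$subject_id %in% keep_ids, ]
  if (!any(elig$group == "POAG") || !any(elig$group == "healthy"))
    stopf("an entire group was excluded by eligibility screening")

  # the baseline comparison needs two records per group; with fewer (e.g. a
  # single treated subject) it is refused but the longitudinal analysis of
  # whatever subjects remain still runs
  n_base <- table(factor(elig$group[elig$visit == "baseline"],
                         c("healthy", "POAG")))
  table1 <- if (all(n_base >= 2)) compare_groups(elig, welch = cfg$welch)
            else NULL

  longi <- lapply(cfg$variables, function(v)
    longitudinal_analysis(elig, v, alpha = cfg$alpha,
                          sphericity_correction = cfg$sphericity_correction))
  names(longi) <- cfg$variables

  table2 <- do.call(rbind, lapply(longi, function(lr) {
    vs <- lr$visit_stats
    cells <- sprintf("%.2f +/- %.2f", vs$mean, vs$sd)
    ph <- lr$post_hoc
    data.frame(variable = lr$variable,
               baseline = cells[1], wk1 = cells[2], wk4 = cells[3],
               wk12 = cells[4],
               rm_anova_p = if (isTRUE(lr$rm_anova$refused)) NA_real_
                            else lr$rm_anova$p,
               rm_anova_refused = isTRUE(lr$rm_anova$refused),
               p_wk1 = ph$p[1], p_wk4 = ph$p[2], p_wk12 = ph$p[3],
               sig_wk1 = ph$significant_bonferroni[1],
               sig_wk4 = ph$significant_bonferroni[2],
               sig_wk12 = ph$significant_bonferroni[3],
               pct_wk1 = vs$mean_pct_change[2],
               pct_wk4 = vs$mean_pct_change[3],
               pct_wk12 = vs$mean_pct_change[4])
  }))
  rownames(table2) <- NULL

  structure(list(eligibility = subj, table1 = table1, table2 = table2,
                 longitudinal = longi, config = cfg),
            class = "study_report")
}

#' Write a study report to disk
#'
#' Emits a machine-readable JSON report plus the two rendered CSV tables.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table1, file.path(dir, "table1_baseline.csv"),
            row.names = FALSE)
  write.csv(report$table2, file.path(dir, "table2_longitudinal.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(eligibility = report$eligibility, table1 = report$table1,
         table2 = report$table2),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
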