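#' Baseline comparison of healthy and POAG groups
#'
#' For each continuous variable, a two-sided unpaired t-test on the baseline
#' records (equal-variance by default, Welch behind a flag); for sex, a
#' chi-square test on the 2 x 2 contingency table.  A variable constant in
#' both groups has no defined test and is flagged with an \code{NA} p-value.
#'
#' @param cohort subject-visit data.frame (schema of [simulate_cohort()]).
#' @param variables continuous variables to compare; defaults to the full
#'   clinical roster present in the table.
#' @param welch use Welch's unequal-variance t-test instead of the
#'   equal-variance test.
#' @param include_sex add the chi-square comparison of sex.
#' @return data.frame of class \code{group_comparison}: one row per
#'   variable with group means, SDs, test statistic, p-value and test name.
#' @export
compare_groups <- function(cohort, variables = NULL, welch = FALSE,
                           include_sex = TRUE) {
  base <- cohort[cohort$visit == "baseline", ]
  g1 <- base[base$group == "healthy", ]
  g2 <- base[base$group == "POAG", ]
  if (nrow(g1) < 2 || nrow(g2) < 2)
    stopf("need >= 2 baseline records per group")
  if (is.null(variables)) {
    roster <- c("age", "axial_length_mm", "bcva_logmar", "sbp_mmHg",
                "dbp_mmHg", "iop_mmHg", "opp_mmHg", "pbfv_mm_s", "mbr_t_au",
                "rvd_a_um", "rvd_v_um")
    variables <- intersect(roster, names(base))
  }
  rows <- lapply(variables, function(v) {
    x <- g1[[v]]; y <- g2[[v]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2 ||
        (sd(c(x, y)) == 0)) {
      return(data.frame(variable = v, mean_healthy = mean(x), sd_healthy = sd(x),
                        mean_poag = mean(y), sd_poag = sd(y),
                        statistic = NA_real_, p_value = NA_real_,
                        test = "degenerate (constant or too few values)"))
    }
    tt <- t.test(x, y, var.equal = !welch)
    data.frame(variable = v, mean_healthy = mean(x), sd_healthy = sd(x),
               mean_poag = mean(y), sd_poag = sd(y),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               test = if (welch) "Welch t" else "unpaired t")
  })
  out <- do.call(rbind, rows)
  if (include_sex && "sex" %in% names(base)) {
    tab <- table(factor(base$group, c("healthy", "POAG")),
                 factor(base$sex, c("F", "M")))
    sex_row <- if (any(colSums(tab) == 0)) {
      data.frame(variable = "sex_male", mean_healthy = mean(g1$sex == "M"),
                 sd_healthy = NA_real_, mean_poag = mean(g2$sex == "M"),
                 sd_poag = NA_real_, statistic = NA_real_, p_value = NA_real_,
                 test = "degenerate (constant or too few values)")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(variable = "sex_male", mean_healthy = mean(g1$sex == "M"),
                 sd_healthy = NA_real_, mean_poag = mean(g2$sex == "M"),
                 sd_poag = NA_real_, statistic = unname(ct$statistic),
                 p_value = ct$p.value, test = "chi-square")
    }
    out <- rbind(out, sex_row)
  }
  class(out) <- c("group_comparison", class(out))
  out
}

# one-way within-subject ANOVA on a complete n x m matrix of measurements
# (rows = subjects, cols = occasions); returns F, dfs and p
rm_anova_within <- function(mat, eps = 1) {
  n <- nrow(mat); m <- ncol(mat)
  grand <- mean(mat)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- m * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- (m - 1) * eps
  df2 <- (n - 1) * (m - 1) * eps
  ms_time <- ss_time / (m - 1)
  ms_err <- ss_err / ((n - 1) * (m - 1))
  F <- if (ms_err > 0) ms_time / ms_err else if (ss_time == 0) 0 else Inf
  p <- if (is.finite(F)) pf(F, df1, df2, lower.tail = FALSE) else 0
  list(F = F, df1 = df1, df2 = df2, p = p, n = n, m = m)
}

# Greenhouse-Geisser nonsphericity estimate from the occasion covariance
gg_epsilon <- function(mat) {
  S <- stats::cov(mat)
  m <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  rowm <- rowMeans(S)
  num <- (m * (dbar - sbar))^2
  den <- (m - 1) * (sum(S^2) - 2 * m * sum(rowm^2) + m^2 * sbar^2)
  eps <- num / den
  min(max(eps, 1 / (m - 1)), 1)
}

#' Longitudinal analysis of one clinical variable in the POAG group
#'
#' One-way within-subject repeated-measures ANOVA across the four visits on
#' complete cases, followed by paired t-tests of baseline against each
#' follow-up visit on all available pairs, with Bonferroni-corrected
#' significance at \code{alpha / 3} (three contrasts).  Per-visit percent
#' change is computed per subject against that subject's baseline and then
#' averaged.  Subjects missing a visit are excluded from the ANOVA
#' complete-case set but retained in the paired tests of the visits they do
#' have.
#'
#' @param cohort subject-visit data.frame.
#' @param variable column name to analyse.
#' @param alpha significance level before correction (default 0.05).
#' @param sphericity_correction \code{"none"} (default; sphericity assumed)
#'   or \code{"greenhouse-geisser"}.
#' @return object of class \code{longitudinal_result}: \code{visit_stats}
#'   (per-visit n/mean/SD/mean percent change), \code{rm_anova} (F, dfs, p,
#'   n of complete cases, or a refusal flag when fewer than 3 complete
#'   cases), \code{post_hoc} (per follow-up visit: n pairs, t, p, Bonferroni
#'   significance flag), \code{alpha}, \code{n_contrasts}.
#' @export
longitudinal_analysis <- function(cohort, variable, alpha = 0.05,
                                  sphericity_correction = c("none",
                                                            "greenhouse-geisser")) {
  sphericity_correction <- match.arg(sphericity_correction)
  lv <- visit_levels()
  poag <- cohort[cohort$group == "POAG", c("subject_id", "visit", variable)]
  if (!nrow(poag)) stopf("no POAG records")
  wide <- matrix(NA_real_, length(unique(poag$subject_id)), length(lv),
                 dimnames = list(unique(poag$subject_id), lv))
  for (i in seq_len(nrow(poag)))
    wide[poag$subject_id[i], poag$visit[i]] <- poag[[variable]][i]
  if (all(is.na(wide[, -1]))) stopf("POAG subjects need >= 2 visits")

  visit_stats <- data.frame(
    visit = lv,
    n = colSums(!is.na(wide)),
    mean = colMeans(wide, na.rm = TRUE),
    sd = apply(wide, 2, sd, na.rm = TRUE), row.names = NULL)
  pc <- sapply(lv[-1], function(v) {
    ok <- !is.na(wide[, "baseline"]) & !is.na(wide[, v]) &
      wide[, "baseline"] != 0
    if (!any(ok)) return(NA_real_)
    mean(percent_change(wide[ok, "baseline"], wide[ok, v]))
  })
  visit_stats$mean_pct_change <- c(0, pc)

  complete <- wide[complete.cases(wide), , drop = FALSE]
  rm <- if (nrow(complete) < 3) {
    list(refused = TRUE, reason = "fewer than 3 complete cases",
         n = nrow(complete))
  } else {
    eps <- if (sphericity_correction == "greenhouse-geisser")
      gg_epsilon(complete) else 1
    c(rm_anova_within(complete, eps = eps), refused = FALSE,
      list(epsilon = eps))
  }

  post_hoc <- do.call(rbind, lapply(lv[-1], function(v) {
    ok <- !is.na(wide[, "baseline"]) & !is.na(wide[, v])
    if (sum(ok) < 2)
      return(data.frame(visit = v, n_pairs = sum(ok), t = NA_real_,
                        p = NA_real_, significant_bonferroni = NA))
    d <- wide[ok, v] - wide[ok, "baseline"]
    if (sd(d) == 0) {
      p <- if (all(d == 0)) 1 else 0
      return(data.frame(visit = v, n_pairs = sum(ok), t = 0, p = p,
                        significant_bonferroni = p < alpha / 3))
    }
    tt <- t.test(wide[ok, v], wide[ok, "baseline"], paired = TRUE)
    data.frame(visit = v, n_pairs = sum(ok), t = unname(tt$statistic),
               p = tt$p.value, significant_bonferroni = tt$p.value < alpha / 3)
  }))

  structure(list(variable = variable, visit_stats = visit_stats,
                 rm_anova = rm, post_hoc = post_hoc, alpha = alpha,
                 n_contrasts = 3L),
            class = "longitudinal_result")
}
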