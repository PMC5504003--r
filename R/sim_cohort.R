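#' Configuration for the synthetic clinical cohort generator
#'
#' Defaults reproduce the statistical structure of a two-group glaucoma
#' perfusion study: 11 healthy subjects examined at baseline only and 11
#' primary open-angle glaucoma (POAG) patients examined at baseline and 1, 4
#' and 12 weeks after starting topical prostaglandin treatment.  Per-group,
#' per-variable means and SDs default to summary statistics representative of
#' a treatment-naive POAG cohort and matched healthy controls; the POAG
#' longitudinal profile defaults to per-visit means typical of response to a
#' topical prostaglandin analogue (IOP falls ~20% under treatment, pBFV rises ~15-20%,
#' blood pressures and structural measures essentially unchanged).
#'
#' Time-varying variables follow a compound-symmetry model,
#' \deqn{X_{iv} = \mu_v + \sigma_v(\sqrt{\rho}\, z_i + \sqrt{1-\rho}\,
#'   e_{iv})}
#' with subject effect \eqn{z_i} and visit noise \eqn{e_{iv}} standard
#' normal, so each visit has exactly mean \eqn{\mu_v}, SD \eqn{\sigma_v} and
#' between-visit correlation \eqn{\rho}.  Subject-level variables (age,
#' axial length, acuity, visual-field mean deviation) are drawn once per
#' subject.  Variables are mutually independent except the systolic and
#' diastolic pressures, whose latents are coupled (see \code{bp_corr}); OPP
#' is never stored and is always derived downstream from pressures.
#'
#' @param n_healthy,n_poag subjects per group (each >= 2).
#' @param rho within-subject correlation across visits, in [0, 1).
#' @param longitudinal_effects if \code{FALSE}, the POAG baseline mean and
#'   SD are replicated at all visits (an exchangeable null, used for type-I
#'   error studies); if \code{TRUE} (default) the default per-visit
#'   treatment-effect profile is used.
#' @param missing_week12 number of POAG subjects whose week-12 visit is
#'   dropped entirely (default 1, mirroring a single study dropout).
#' @param p_male per-group probability of male sex (healthy, POAG).
#' @param bp_corr correlation between the systolic and diastolic latent
#'   draws (subject and visit level), in [0, 1).  Pressures are coupled so
#'   that the physiologically impossible sBP < dBP is vanishingly rare; any
#'   residual inversion is floored at sBP = dBP + 2 mmHg.
#' @param healthy,poag_means,poag_sds optional overrides: \code{healthy} a
#'   named list of \code{c(mean, sd)}; \code{poag_means}/\code{poag_sds}
#'   named lists of length-4 numeric vectors (baseline, wk1, wk4, wk12) for
#'   the time-varying variables, or length-1 for subject-level ones.
#' @return object of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n_healthy = 11L, n_poag = 11L, rho = 0.5,
                              longitudinal_effects = TRUE,
                              missing_week12 = 1L,
                              p_male = c(healthy = 6 / 11, poag = 7 / 11),
                              bp_corr = 0.6, healthy = NULL,
                              poag_means = NULL, poag_sds = NULL) {
  if (n_healthy < 2 || n_poag < 2) stopf("need at least 2 subjects per group")
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  if (missing_week12 < 0 || missing_week12 > n_poag)
    stopf("missing_week12 must lie in [0, n_poag]")

  h <- list(age = c(50.3, 11.8), axial_length_mm = c(23.98, 0.72),
            bcva_logmar = c(-0.18, 0.07), vf_md_db = c(NA, NA),
            sbp_mmHg = c(121.3, 10.6), dbp_mmHg = c(72.3, 6.8),
            iop_mmHg = c(13.3, 1.2), pbfv_mm_s = c(1.35, 0.33),
            mbr_t_au = c(14.5, 3.2), rvd_a_um = c(109.3, 7.4),
            rvd_v_um = c(149.9, 12.6))
  pm <- list(age = 54.9, axial_length_mm = 25.33, bcva_logmar = -0.16,
             vf_md_db = -5.23,
             sbp_mmHg = c(116.0, 111.0, 118.4, 120.9),
             dbp_mmHg = c(69.2, 67.2, 68.8, 71.1),
             iop_mmHg = c(17.1, 13.7, 14.0, 14.4),
             pbfv_mm_s = c(1.05, 1.21, 1.28, 1.19),
             mbr_t_au = c(11.8, 12.2, 12.3, 11.9),
             rvd_a_um = c(98.0, 98.5, 98.6, 93.7),
             rvd_v_um = c(131.9, 133.6, 135.7, 134.8))
  ps <- list(age = 8.4, axial_length_mm = 1.48, bcva_logmar = 0.04,
             vf_md_db = 4.41,
             sbp_mmHg = c(18.0, 19.5, 20.2, 18.9),
             dbp_mmHg = c(11.0, 12.1, 15.9, 13.0),
             iop_mmHg = c(2.3, 1.5, 2.0, 2.0),
             pbfv_mm_s = c(0.16, 0.26, 0.24, 0.21),
             mbr_t_au = c(2.7, 3.1, 3.3, 3.2),
             rvd_a_um = c(12.4, 13.1, 13.5, 11.6),
             rvd_v_um = c(11.7, 11.7, 15.3, 16.7))
  if (!is.null(healthy)) h[names(healthy)] <- healthy
  if (!is.null(poag_means)) pm[names(poag_means)] <- poag_means
  if (!is.null(poag_sds)) ps[names(poag_sds)] <- poag_sds
  if (!longitudinal_effects) {
    for (v in names(pm)) {
      pm[[v]] <- rep(pm[[v]][1], length(pm[[v]]))
      ps[[v]] <- rep(ps[[v]][1], length(ps[[v]]))
    }
  }
  sds <- unlist(ps)
  if (any(sds[!is.na(sds)] < 0)) stopf("SDs must be non-negative")
  structure(list(n_healthy = as.integer(n_healthy),
                 n_poag = as.integer(n_poag), rho = rho,
                 longitudinal_effects = longitudinal_effects,
                 missing_week12 = as.integer(missing_week12),
                 p_male = p_male, bp_corr = bp_corr, healthy = h,
                 poag_means = pm, poag_sds = ps),
            class = "cohort_sim_config")
}

#' Visit labels of the longitudinal design
#' @return character vector \code{c("baseline", "wk1", "wk4", "wk12")}.
#' @export
visit_levels <- function() c("baseline", "wk1", "wk4", "wk12")

# variables that carry a visit profile (everything else is subject-level)
time_varying_vars <- function() c("sbp_mmHg", "dbp_mmHg", "iop_mmHg",
                                  "pbfv_mm_s", "mbr_t_au", "rvd_a_um",
                                  "rvd_v_um")

#' Simulate a two-group longitudinal clinical cohort
#'
#' Draws one row per subject per visit (healthy subjects: baseline only;
#' POAG: baseline, 1, 4 and 12 weeks) from the compound-symmetry model of
#' [cohort_sim_config()].  OPP is deliberately never stored; it is derived
#' downstream from the stored pressures.
#'
#' @param cfg a [cohort_sim_config()].
#' @param seed RNG seed; same config and seed give identical tables.
#' @return data.frame of subject-visit records with columns
#'   \code{subject_id}, \code{group}, \code{visit}, \code{sex}, \code{age},
#'   \code{axial_length_mm}, \code{bcva_logmar}, \code{vf_md_db},
#'   \code{sbp_mmHg}, \code{dbp_mmHg}, \code{iop_mmHg}, \code{pbfv_mm_s},
#'   \code{mbr_t_au}, \code{rvd_a_um}, \code{rvd_v_um}.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(seed, {
    subj_vars <- setdiff(names(cfg$healthy), time_varying_vars())
    ## healthy: baseline only
    nh <- cfg$n_healthy
    healthy <- data.frame(
      subject_id = sprintf("H%02d", seq_len(nh)), group = "healthy",
      visit = "baseline",
      sex = ifelse(rbinom(nh, 1, cfg$p_male[["healthy"]]) == 1, "M", "F"),
      stringsAsFactors = FALSE)
    zh <- matrix(rnorm(nh * 2), nh, 2)   # coupled pressure draws
    zh[, 2] <- cfg$bp_corr * zh[, 1] + sqrt(1 - cfg$bp_corr^2) * zh[, 2]
    for (v in names(cfg$healthy)) {
      p <- cfg$healthy[[v]]
      healthy[[v]] <- if (anyNA(p)) NA_real_
      else if (v == "dbp_mmHg") p[1] + p[2] * zh[, 1]
      else if (v == "sbp_mmHg") p[1] + p[2] * zh[, 2]
      else rnorm(nh, p[1], p[2])
    }
    healthy$sbp_mmHg <- pmax(healthy$sbp_mmHg, healthy$dbp_mmHg + 2)
    ## POAG: 4 visits under compound symmetry
    np <- cfg$n_poag
    m <- length(visit_levels())
    poag <- data.frame(
      subject_id = rep(sprintf("P%02d", seq_len(np)), each = m),
      group = "POAG", visit = rep(visit_levels(), times = np),
      sex = rep(ifelse(rbinom(np, 1, cfg$p_male[["poag"]]) == 1, "M", "F"),
                each = m),
      stringsAsFactors = FALSE)
    zd <- rnorm(np); ed <- matrix(rnorm(np * m), np, m)  # dBP latents
    zs <- cfg$bp_corr * zd + sqrt(1 - cfg$bp_corr^2) * rnorm(np)
    es <- cfg$bp_corr * ed + sqrt(1 - cfg$bp_corr^2) *
      matrix(rnorm(np * m), np, m)
    for (v in names(cfg$poag_means)) {
      mu <- cfg$poag_means[[v]]; sg <- cfg$poag_sds[[v]]
      if (v %in% subj_vars) {
        poag[[v]] <- rep(rnorm(np, mu[1], sg[1]), each = m)
      } else {
        if (v == "dbp_mmHg") { z <- zd; e <- ed }
        else if (v == "sbp_mmHg") { z <- zs; e <- es }
        else { z <- rnorm(np); e <- matrix(rnorm(np * m), np, m) }
        x <- sweep(sweep(sqrt(cfg$rho) * z + sqrt(1 - cfg$rho) * e,
                         2, sg, "*"), 2, mu, "+")
        poag[[v]] <- as.vector(t(x))
      }
    }
    poag$sbp_mmHg <- pmax(poag$sbp_mmHg, poag$dbp_mmHg + 2)
    if (cfg$missing_week12 > 0) {
      drop_ids <- sample(unique(poag$subject_id), cfg$missing_week12)
      poag <- poag[!(poag$subject_id %in% drop_ids & poag$visit == "wk12"), ]
    }
    cohort <- rbind(healthy, poag)
    rownames(cohort) <- NULL
    cohort
  })
}

#' Write / read a cohort table as CSV
#'
#' The CSV schema is exactly the column set of [simulate_cohort()], one row
#' per subject-visit.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return \code{read_cohort_csv} returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
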