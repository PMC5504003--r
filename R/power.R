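#' Power of a one-group within-subject repeated-measures ANOVA F test
#'
#' Computes the power of the within-factor F test for a single group measured
#' on \code{m} occasions, using the conventional noncentral-F formulation
#' (as popularised by G*Power): noncentrality
#' \deqn{\lambda = \frac{n \, m \, f^2}{1 - \rho}}
#' with numerator degrees of freedom \eqn{(m-1)\varepsilon} and denominator
#' degrees of freedom \eqn{(n-1)(m-1)\varepsilon}, where \eqn{f} is Cohen's
#' effect size for ANOVA, \eqn{\rho} the correlation among repeated measures
#' and \eqn{\varepsilon} the nonsphericity correction (1 = sphericity
#' assumed).
#'
#' @param n number of subjects (>= 2).
#' @param spec a [power_spec()].
#' @return power in (0, 1), vectorised over \code{n}.
#' @seealso [required_sample_size()]
#' @export
rm_anova_power <- function(n, spec = power_spec()) {
  stopifnot(inherits(spec, "power_spec"))
  if (any(n < 2)) stopf("n must be >= 2")
  m <- spec$n_timepoints
  lambda <- n * m * spec$effect_size_f^2 / (1 - spec$corr_among_reps)
  df1 <- (m - 1) * spec$nonsphericity_eps
  df2 <- (n - 1) * (m - 1) * spec$nonsphericity_eps
  crit <- qf(1 - spec$alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Specification for a repeated-measures power analysis
#'
#' Defaults match a 4-occasion within-subject design powered for a medium-to-
#' large effect: \code{f = 0.4}, \code{alpha = 0.05}, \code{power = 0.8},
#' correlation among repeated measures 0.5 and sphericity assumed
#' (\code{nonsphericity_eps = 1}).
#'
#' @param effect_size_f Cohen's f (> 0): between-occasion SD of means divided
#'   by the within-cell SD.
#' @param alpha type-I error rate, in (0, 1).
#' @param power target power, in (0, 1).
#' @param n_timepoints number of measurement occasions m (>= 2).
#' @param corr_among_reps correlation among repeated measures, in [0, 1).
#' @param nonsphericity_eps nonsphericity correction epsilon, in
#'   [1/(m-1), 1].
#' @return an object of class \code{power_spec}.
#' @export
power_spec <- function(effect_size_f = 0.4, alpha = 0.05, power = 0.8,
                       n_timepoints = 4, corr_among_reps = 0.5,
                       nonsphericity_eps = 1) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stopf("alpha and power must lie in (0, 1)")
  if (effect_size_f < 0) stopf("effect_size_f must be non-negative")
  if (n_timepoints < 2) stopf("n_timepoints must be >= 2")
  if (corr_among_reps < 0 || corr_among_reps >= 1)
    stopf("corr_among_reps must lie in [0, 1)")
  if (nonsphericity_eps < 1 / (n_timepoints - 1) || nonsphericity_eps > 1)
    stopf("nonsphericity_eps must lie in [1/(m-1), 1]")
  structure(list(effect_size_f = effect_size_f, alpha = alpha, power = power,
                 n_timepoints = n_timepoints,
                 corr_among_reps = corr_among_reps,
                 nonsphericity_eps = nonsphericity_eps),
            class = "power_spec")
}

#' A-priori sample size for a within-subject repeated-measures ANOVA
#'
#' Returns the smallest number of subjects n such that
#' \code{rm_anova_power(n, spec) >= spec$power}.  Power is monotone
#' increasing in n for this design, so a linear search from n = 2 upward
#' terminates at the answer.
#'
#' @param spec a [power_spec()].
#' @param n_max search ceiling; exceeded means the requested power is
#'   unattainable at plausible sample sizes and is reported as an error.
#' @return required sample size (integer scalar).
#' @examples
#' required_sample_size(power_spec(effect_size_f = 0.4, alpha = 0.05,
#'                                 power = 0.8, n_timepoints = 4,
#'                                 corr_among_reps = 0.5))  # 10
#' @export
required_sample_size <- function(spec = power_spec(), n_max = 10000L) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$effect_size_f == 0)
    stopf("effect_size_f = 0: no finite sample size attains the power")
  for (n in 2:n_max) {
    if (rm_anova_power(n, spec) >= spec$power) return(as.integer(n))
  }
  stopf("required sample size exceeds n_max = %d", n_max)
}
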