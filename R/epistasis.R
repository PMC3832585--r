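#' Define a combined-knockdown (epistasis) plate design
#'
#' Each arm combines siRNA doses against one or more target genes plus a
#' non-targeting filler, with the total siRNA amount per well held constant
#' across arms (4 pmol in the screen design).
#'
#' @param arms named list; each element is a list with `doses` (named
#'   numeric vector of per-target pmol amounts, possibly empty for the
#'   non-targeting control arm) and `filler` (non-targeting pmol).
#' @param total_dose constant total siRNA amount per well in pmol.
#' @param n_wells wells per arm.
#' @return object of class `epistasis_design`.
#' @examples
#' des <- epistasis_design(list(
#'   control = list(doses = c(), filler = 4),
#'   EB2     = list(doses = c(Mapre2 = 2), filler = 2),
#'   EB1_EB2 = list(doses = c(Mapre1 = 2, Mapre2 = 2), filler = 0)))
#' validate_design(des)
#' @export
epistasis_design <- function(arms, total_dose = 4, n_wells = 6) {
  stopifnot(is.list(arms), length(arms) >= 1, !is.null(names(arms)))
  arms <- lapply(arms, function(a) {
    list(doses = if (is.null(a$doses)) numeric(0) else a$doses,
         filler = if (is.null(a$filler)) 0 else a$filler)
  })
  structure(list(arms = arms, total_dose = total_dose, n_wells = n_wells),
            class = "epistasis_design")
}

#' Validate the constant-total-dose rule of an epistasis design
#'
#' @param design an [epistasis_design()].
#' @return the design, invisibly, if every arm's target doses plus filler
#'   sum to the total dose; otherwise an error naming the offending arm(s).
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "epistasis_design"))
  tot <- vapply(design$arms, function(a) sum(a$doses) + a$filler, numeric(1))
  neg <- vapply(design$arms, function(a) any(c(a$doses, a$filler) < 0), logical(1))
  bad <- abs(tot - design$total_dose) > 1e-9 | neg
  if (any(bad))
    stop("validate_design(): arm(s) violating the constant total dose of ",
         design$total_dose, " pmol: ", paste(names(design$arms)[bad], collapse = ", "),
         call. = FALSE)
  invisible(design)
}

# density of S = sqrt(chi^2_df / df)
dscaled_chi <- function(s, df) 2 * df * s * stats::dchisq(df * s^2, df)

# P(max_i |T_i| <= q) for many-to-one comparisons against a shared control,
# via the one-factor representation T_i = (a_i Z_i - b_i Z0) / S and nested
# numerical integration over (Z0, S)
dunnett_prob <- function(q, n_treat, n_control, df) {
  a <- sqrt((1 / n_treat) / (1 / n_treat + 1 / n_control))
  b <- sqrt((1 / n_control) / (1 / n_treat + 1 / n_control))
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) {
        pr <- rep(1, length(z))
        for (i in seq_along(a)) {
          pr <- pr * (stats::pnorm((b[i] * z + q * si) / a[i]) -
                        stats::pnorm((b[i] * z - q * si) / a[i]))
        }
        pr * stats::dnorm(z)
      }
      stats::integrate(f, -9, 9, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  stats::integrate(function(s) inner(s) * dscaled_chi(s, df),
                   1e-8, Inf, rel.tol = 1e-8)$value
}

#' Two-sided Dunnett many-to-one critical value
#'
#' Critical value q such that the familywise probability of any |t|
#' statistic exceeding q under the null is `alpha`.
#'
#' @param alpha familywise error level.
#' @param n_treat vector of per-treatment-arm sample sizes.
#' @param n_control control-arm sample size.
#' @param df residual degrees of freedom.
#' @return critical value (scalar).
#' @export
dunnett_critical <- function(alpha, n_treat, n_control, df) {
  stats::uniroot(function(q) dunnett_prob(q, n_treat, n_control, df) - (1 - alpha),
                 c(0.5, 15), tol = 1e-7)$root
}

#' Compare epistasis arms against a control arm
#'
#' One-way ANOVA over the arms followed by Dunnett-type many-to-one
#' comparisons of every treatment arm against the designated control arm
#' (two-sided, familywise-adjusted p-values from the multivariate-t
#' distribution of the simultaneous t statistics, computed by numerical
#' integration).
#'
#' @param data data.frame with columns `arm` and `value` (e.g. well-level
#'   outgrowth scores).
#' @param control name of the control arm (e.g. non-targeting siRNA).
#' @return object of class `arm_comparison`: list with the ANOVA F test and
#'   a per-arm table of effects, t statistics, adjusted p-values and
#'   significance stars (0.05 / 0.01 / 0.001).
#' @export
compare_arms <- function(data, control) {
  stopifnot(is.data.frame(data), all(c("arm", "value") %in% names(data)))
  data$arm <- as.character(data$arm)
  arms <- unique(data$arm)
  if (!control %in% arms)
    stop("compare_arms(): control arm '", control, "' not present", call. = FALSE)
  if (length(arms) < 2L)
    stop("compare_arms(): need at least two arms", call. = FALSE)
  n <- table(data$arm)
  if (any(n < 2))
    stop("compare_arms(): arm(s) with fewer than 2 wells: ",
         paste(names(n)[n < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(value ~ arm, data = data)
  an <- stats::anova(fit)
  s2 <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  means <- tapply(data$value, data$arm, mean)
  treat <- setdiff(arms, control)
  n_t <- as.numeric(n[treat]); n_c <- as.numeric(n[control])
  diff <- means[treat] - means[control]
  se <- sqrt(s2 * (1 / n_t + 1 / n_c))
  tstat <- diff / se
  p_adj <- vapply(abs(tstat), function(tt)
    max(0, 1 - dunnett_prob(tt, n_t, n_c, df)), numeric(1))
  comp <- data.frame(arm = treat, n = n_t, mean = as.numeric(means[treat]),
                     diff = as.numeric(diff), se = se, t = as.numeric(tstat),
                     p_adj = p_adj, stars = p_stars(p_adj),
                     stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  structure(list(comparisons = comp, control = control,
                 control_mean = as.numeric(means[control]), n_control = n_c,
                 F = an["arm", "F value"], df1 = an["arm", "Df"], df2 = df,
                 p_F = an["arm", "Pr(>F)"], sigma = sqrt(s2)),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p_F))
  cat(sprintf("Dunnett many-to-one comparisons vs '%s' (n = %d):\n",
              x$control, x$n_control))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Permutation-based many-to-one comparison (validation fallback)
#'
#' Recomputes familywise-adjusted p-values for the same max-|t| statistic by
#' permuting arm labels; serves as a distribution-free check of
#' [compare_arms()].
#'
#' @param data data.frame with columns `arm` and `value`.
#' @param control control arm name.
#' @param n_perm number of permutations.
#' @param seed seed for the permutation draw.
#' @return data.frame of arms with permutation-adjusted p-values.
#' @export
compare_arms_permutation <- function(data, control, n_perm = 2000, seed = 1) {
  obs <- compare_arms(data, control)
  t_obs <- abs(obs$comparisons$t)
  with_seed(seed, {
    maxt <- vapply(seq_len(n_perm), function(i) {
      d <- data
      d$value <- sample(d$value)
      max(abs(compare_arms(d, control)$comparisons$t))
    }, numeric(1))
    data.frame(arm = obs$comparisons$arm,
               p_perm = vapply(t_obs, function(tt) mean(maxt >= tt), numeric(1)))
  })
}

#' Correlation between protein knockdown and phenotype strength
#'
#' Pearson correlation between the per-oligo knockdown level (protein
#' reduction measured externally, e.g. by western blot) and the phenotype
#' score, as used to relate EB2 or Dync1h1 depletion to neurite outgrowth.
#'
#' @param pairs data.frame with columns `knockdown` (protein remaining or
#'   reduction, fraction in [0, 1.5]) and `score` (phenotype score in SD
#'   units).
#' @return Pearson's r (scalar).
#' @export
knockdown_correlation <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("knockdown", "score") %in% names(pairs)))
  if (nrow(pairs) < 3L)
    stop("knockdown_correlation(): need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(pairs$knockdown)) || any(!is.finite(pairs$score)))
    stop("knockdown_correlation(): non-finite values", call. = FALSE)
  if (any(pairs$knockdown < 0 | pairs$knockdown > 1.5))
    stop("knockdown_correlation(): knockdown fractions must lie in [0, 1.5]", call. = FALSE)
  if (stats::var(pairs$knockdown) == 0 || stats::var(pairs$score) == 0)
    stop("knockdown_correlation(): zero variance on one axis", call. = FALSE)
  stats::cor(pairs$knockdown, pairs$score)
}

#' Two-sample comparison of masked mean intensities
#'
#' Equal-variance two-sided Student's t-test between two groups of
#' per-experiment masked mean intensities (e.g. EB1 signal within neurites
#' for control vs knockdown).
#'
#' @param group_a,group_b numeric vectors of per-experiment means (>= 2
#'   values each).
#' @return list with `t`, `df`, `p`, group means and the star annotation.
#' @export
compare_masked_intensity <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("compare_masked_intensity(): need >= 2 values per group", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    return(list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1,
                mean_a = mean(group_a), mean_b = mean(group_b), stars = ""))
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       stars = p_stars(tt$p.value))
}
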