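#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computes the exact two-sided binomial interval from Beta quantiles:
#' the lower bound is 0 when `x = 0` and otherwise the `(1 - level)/2`
#' quantile of `Beta(x, n - x + 1)`; the upper bound is 1 when `x = n` and
#' otherwise the `1 - (1 - level)/2` quantile of `Beta(x + 1, n - x)`.
#' Coverage is conservative (at least the nominal level).
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return A data frame with columns `lower` and `upper`; the level is kept
#'   in `attr(, "level")`.
#' @examples
#' clopper_pearson(1, 5040)$upper  # ~0.00109, prints as 0.11%
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(x < 0) || any(x > n)) stop("x must lie in [0, n]", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha, x + 1, n - x))
  structure(data.frame(lower = lower, upper = upper), level = level)
}

#' A population cohort with a disease-allele count
#'
#' @param label Population name.
#' @param n_individuals Number of sequenced (diploid) individuals, `N`.
#' @param disease_allele_count Number of disease alleles observed, `x`
#'   (at most `2N`).
#' @param scheme Classification scheme the count was derived under.
#' @return An object of class `cohort`.
#' @export
cohort <- function(label, n_individuals, disease_allele_count,
                   scheme = c("acmg", "clinvar", "hgmd")) {
  scheme <- match.arg(scheme)
  n_individuals <- as.integer(n_individuals)
  disease_allele_count <- as.integer(disease_allele_count)
  if (is.na(n_individuals) || n_individuals <= 0L)
    stop("n_individuals must be a positive integer", call. = FALSE)
  if (is.na(disease_allele_count) || disease_allele_count < 0L ||
      disease_allele_count > 2L * n_individuals)
    stop("disease_allele_count must lie in [0, 2N]", call. = FALSE)
  structure(list(label = label, n_individuals = n_individuals,
                 disease_allele_count = disease_allele_count,
                 scheme = scheme),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s [%s]: %d disease alleles in %s individuals\n",
              x$label, x$scheme, x$disease_allele_count,
              format(x$n_individuals, big.mark = ",")))
  invisible(x)
}

#' Pool cohorts into a combined cohort
#'
#' Sums disease-allele counts and sample sizes across cohorts genotyped
#' under the same scheme — e.g. combining gnomAD Korean with the KOVA and
#' KRGDB Korean reference cohorts.
#'
#' @param cohorts List of [cohort()] objects with distinct labels and a
#'   common scheme.
#' @param label Label of the pooled cohort.
#' @return A [cohort()].
#' @export
pool_cohorts <- function(cohorts, label = "pooled") {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1L,
            all(vapply(cohorts, inherits, NA, "cohort")))
  schemes <- unique(vapply(cohorts, `[[`, "", "scheme"))
  if (length(schemes) > 1L)
    stop("cannot pool cohorts with mixed schemes: ",
         paste(schemes, collapse = ", "), call. = FALSE)
  labels <- vapply(cohorts, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("cohort labels must be distinct", call. = FALSE)
  if (length(cohorts) == 1L) return(cohorts[[1L]])
  cohort(label,
         sum(vapply(cohorts, `[[`, 0L, "n_individuals")),
         sum(vapply(cohorts, `[[`, 0L, "disease_allele_count")),
         schemes)
}

#' Fit a carrier-frequency / incidence model to a cohort
#'
#' The estimator treats each observed disease allele as one carrier:
#' with `x` disease alleles among `N` individuals the carrier frequency is
#' `x/N` (equal to `2q` where `q = x/2N` is the disease allele frequency;
#' under Hardy-Weinberg the exact carrier proportion is `2q(1-q)`, and with
#' `p ~ 1` the two coincide at reporting precision). The 95% CI is the
#' exact binomial interval for `x` out of `N`. The expected incidence is
#' `q^2`, reported as a denominator `1/q^2`; its CI is derived on the
#' allele scale (`x` out of `2N`), squared and inverted, and reported with
#' the larger denominator first. A zero-count cohort has an undefined
#' (`NA`) incidence denominator but retains the upper-bound-derived
#' denominator.
#'
#' @param cohort A [cohort()], or a plain disease-allele count `x` if
#'   `n_individuals` is also given.
#' @param n_individuals Optional; builds the cohort from `x` and `N`.
#' @param level Confidence level for all intervals.
#' @param label,scheme Passed to [cohort()] when building from counts.
#' @return An object of class `carrier_estimate` with components `cohort`,
#'   `carrier_frequency`, `cf_ci`, `q`, `q_ci`, `incidence`,
#'   `incidence_denominator`, `incidence_denominator_ci` (ordered larger
#'   first) and `level`. Methods: `print`, `summary`, `coef`, `confint`.
#' @examples
#' fit <- carrier_fit(cohort("Finnish", 10824, 53))
#' coef(fit)
#' @export
carrier_fit <- function(cohort, n_individuals = NULL, level = 0.95,
                        label = "cohort", scheme = "acmg") {
  if (!inherits(cohort, "cohort")) {
    stopifnot(!is.null(n_individuals))
    cohort <- cohort(label, n_individuals, cohort, scheme)
  }
  x <- cohort$disease_allele_count
  N <- cohort$n_individuals

  cf <- x / N
  # x can exceed N only when homozygotes dominate (x close to 2N); the
  # carrier-count interval is then saturated
  cf_ci <- clopper_pearson(min(x, N), N, level)

  q <- x / (2 * N)
  q_ci <- clopper_pearson(x, 2 * N, level)
  incidence <- q^2
  denom <- if (x > 0) 1 / q^2 else NA_real_
  denom_from_lower <- if (q_ci$lower > 0) 1 / q_ci$lower^2 else NA_real_
  denom_from_upper <- 1 / q_ci$upper^2

  structure(list(cohort = cohort,
                 carrier_frequency = cf,
                 cf_ci = cf_ci,
                 q = q,
                 q_ci = q_ci,
                 incidence = incidence,
                 incidence_denominator = denom,
                 incidence_denominator_ci = c(denom_from_lower,
                                              denom_from_upper),
                 level = level),
            class = "carrier_estimate")
}

#' Carrier frequency of a cohort with its exact interval
#'
#' @param cohort A [cohort()].
#' @param level Confidence level.
#' @return List with `estimate` (the proportion `x/N`) and `ci`
#'   (a [clopper_pearson()] interval).
#' @export
carrier_frequency <- function(cohort, level = 0.95) {
  fit <- carrier_fit(cohort, level = level)
  list(estimate = fit$carrier_frequency, ci = fit$cf_ci)
}

#' Hardy-Weinberg expected incidence of a cohort
#'
#' @param cohort A [cohort()].
#' @param level Confidence level.
#' @return List with `denominator` (`1/q^2`, `NA` for zero counts) and
#'   `ci_denominators` (ordered pair, larger first).
#' @export
estimate_incidence <- function(cohort, level = 0.95) {
  fit <- carrier_fit(cohort, level = level)
  list(denominator = fit$incidence_denominator,
       ci_denominators = fit$incidence_denominator_ci)
}

#' @export
print.carrier_estimate <- function(x, ...) {
  co <- x$cohort
  cat(sprintf("Carrier-frequency fit: %s [%s]\n", co$label, co$scheme))
  cat(sprintf("  disease alleles: %d / %s individuals\n",
              co$disease_allele_count,
              format(co$n_individuals, big.mark = ",")))
  cat(sprintf("  carrier frequency: %s (%s)\n",
              fmt_percent(x$carrier_frequency),
              fmt_percent_ci(x$cf_ci)))
  cat(sprintf("  expected incidence: %s (%s)\n",
              fmt_denominator(x$incidence_denominator),
              fmt_denominator_ci(x$incidence_denominator_ci)))
  invisible(x)
}

#' @export
summary.carrier_estimate <- function(object, ...) {
  out <- c(coef(object),
           cf_lower = object$cf_ci$lower, cf_upper = object$cf_ci$upper,
           q_lower = object$q_ci$lower, q_upper = object$q_ci$upper,
           incidence_denominator = object$incidence_denominator,
           denominator_from_q_lower = object$incidence_denominator_ci[[1L]],
           denominator_from_q_upper = object$incidence_denominator_ci[[2L]])
  class(out) <- c("summary.carrier_estimate", class(out))
  out
}

#' @export
print.summary.carrier_estimate <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
coef.carrier_estimate <- function(object, ...) {
  c(carrier_frequency = object$carrier_frequency,
    q = object$q,
    incidence = object$incidence)
}

#' @export
confint.carrier_estimate <- function(object, parm = c("carrier_frequency", "q"),
                                     level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (!is.null(level) && level != object$level) {
    object <- carrier_fit(object$cohort, level = level)
  }
  m <- rbind(carrier_frequency = unlist(object$cf_ci),
             q = unlist(object$q_ci))
  colnames(m) <- c("lower", "upper")
  m[parm, , drop = FALSE]
}

#' Project carrier and case burden onto a census population
#'
#' Scales a carrier frequency and an incidence denominator to census
#' figures: total carriers (reported to the nearest thousand), expected
#' carriers among one year's newborns (nearest unit), and expected new
#' cases per year (`annual_births / incidence_denominator`, two decimals).
#' The carrier frequency is conventionally the reported (2-decimal percent)
#' figure rather than the raw ratio, matching how such projections are
#' quoted.
#'
#' @param carrier_frequency Proportion (not percent).
#' @param incidence_denominator The `n` of a `1/n` incidence; `NA` allowed
#'   when only carrier projections are wanted.
#' @param population_size,annual_births Census figures.
#' @return An object of class `burden_projection`: list with
#'   `carriers_total`, `carriers_newborn`, `expected_cases_per_year`.
#' @examples
#' project_burden(0.0004, 19963024, 51700000, 260562)
#' @export
project_burden <- function(carrier_frequency, incidence_denominator,
                           population_size, annual_births) {
  if (carrier_frequency < 0 || carrier_frequency > 1)
    stop("carrier_frequency must lie in [0, 1]", call. = FALSE)
  if (population_size <= 0 || annual_births <= 0)
    stop("population_size and annual_births must be positive", call. = FALSE)
  if (!is.na(incidence_denominator) && incidence_denominator <= 0)
    stop("incidence_denominator must be positive", call. = FALSE)
  carriers_total <- round_half_up(population_size * carrier_frequency / 1000) * 1000
  carriers_newborn <- round_half_up(annual_births * carrier_frequency)
  cases <- if (is.na(incidence_denominator)) NA_real_ else
    round(annual_births / incidence_denominator, 2)
  structure(list(carriers_total = carriers_total,
                 carriers_newborn = carriers_newborn,
                 expected_cases_per_year = cases),
            class = "burden_projection")
}

#' @export
print.burden_projection <- function(x, ...) {
  cat(sprintf("Burden projection: ~%s carriers in the population, %d among newborns/yr, %s expected cases/yr\n",
              format(x$carriers_total, big.mark = ","),
              x$carriers_newborn,
              ifelse(is.na(x$expected_cases_per_year), "NA",
                     format(x$expected_cases_per_year, nsmall = 2))))
  invisible(x)
}

# nearest integer, half away from zero (round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
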