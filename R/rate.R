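#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' Chi-square inversion of the Poisson count: the lower bound is
#' `qchisq(a/2, 2n) / 2` (0 when n = 0) and the upper bound
#' `qchisq(1 - a/2, 2n + 2) / 2`, both scaled by the exposure denominator.
#' Equivalent to inverting the Poisson tail probabilities exactly, and
#' guarantees at least nominal coverage.
#'
#' @param n Observed event count (non-negative integer).
#' @param denominator Exposure (e.g. diploid callable site-generations); > 0.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lo, hi)` on the rate scale.
#' @export
#' @examples
#' poisson_rate_ci(508, 508 / 1.27e-8)
poisson_rate_ci <- function(n, denominator, level = 0.95) {
  stopifnot(n >= 0, denominator > 0, level > 0, level < 1)
  a <- 1 - level
  lo <- if (n == 0) 0 else stats::qchisq(a / 2, 2 * n) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * n + 2) / 2
  c(lo = lo / denominator, hi = hi / denominator)
}

#' Estimate per-nucleotide per-generation mutation rates
#'
#' For each family the rate is the germline mutation count divided by the
#' effective diploid denominator `2 * (1 - alpha_site) * sum_x C_f(x)`, where
#' `sum_x C_f(x)` is the family's expected callable (haploid) site count and
#' `alpha_site` the expected site-filter loss. The pooled rate divides the
#' total count by the total denominator (it is not the mean of family rates);
#' per-family rates feed the paternal-age regression. Exact Poisson intervals
#' are attached to every estimate.
#'
#' @param n_mutations Named integer vector of germline mutation counts per
#'   family.
#' @param callable Named numeric vector of expected callable haploid sites
#'   per family (same names); all > 0.
#' @param alpha_site Expected site-filter loss (scalar in \[0, 1)), or a
#'   `site_filter_loss` object.
#' @param level Confidence level for the intervals.
#' @return An object of class `rate_estimate`: `per_family` data.frame
#'   (family_id, n, callable, denominator, rate, ci_lo, ci_hi) and `pooled`
#'   list (n, denominator, rate, ci_lo, ci_hi).
#' @export
estimate_rate <- function(n_mutations, callable, alpha_site = 0, level = 0.95) {
  if (inherits(alpha_site, "site_filter_loss")) alpha_site <- alpha_site$alpha_site
  stopifnot(alpha_site >= 0, alpha_site < 1)
  fams <- names(callable)
  if (is.null(fams)) stop("callable must be named by family")
  n <- n_mutations[fams]
  n[is.na(n)] <- 0
  if (any(callable <= 0)) stop("callable site count must be positive")
  denom <- 2 * (1 - alpha_site) * callable
  rate <- n / denom
  cis <- t(vapply(seq_along(n), function(i) poisson_rate_ci(n[i], denom[i], level),
                  numeric(2)))
  per_family <- data.frame(family_id = fams, n = as.numeric(n),
                           callable = as.numeric(callable),
                           denominator = as.numeric(denom),
                           rate = as.numeric(rate),
                           ci_lo = cis[, 1], ci_hi = cis[, 2],
                           stringsAsFactors = FALSE)
  rownames(per_family) <- NULL
  N <- sum(n); D <- sum(denom)
  pooled_ci <- poisson_rate_ci(N, D, level)
  structure(list(per_family = per_family,
                 pooled = list(n = N, denominator = D, rate = N / D,
                               ci_lo = unname(pooled_ci["lo"]),
                               ci_hi = unname(pooled_ci["hi"])),
                 alpha_site = alpha_site, level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("pooled mutation rate: %.3g per nt per generation (%d%% CI %.3g - %.3g)\n",
              p$rate, round(100 * x$level), p$ci_lo, p$ci_hi))
  cat(sprintf("  %d mutations over %.3g diploid site-generations (alpha_site = %g)\n",
              p$n, p$denominator, x$alpha_site))
  cat(sprintf("  %d families, per-family rates %.3g - %.3g\n",
              nrow(x$per_family), min(x$per_family$rate), max(x$per_family$rate)))
  invisible(x)
}

#' Paternal-age effect on the mutation rate
#'
#' Ordinary least-squares regression of per-family mutation rate on the
#' father's age at the child's birth. The slope is reported as extra
#' mutations per nucleotide per year. A weighted fit (weights proportional to
#' the family denominators, so families with more callable genome count more)
#' is available behind `weights`.
#'
#' @param rates Named numeric vector of per-family rates (or a
#'   `rate_estimate`, from which they are taken).
#' @param ages Named numeric vector of paternal ages (years), matched by
#'   family name where names are present.
#' @param weights Optional non-negative weights (e.g. family denominators).
#' @return An object of class `paternal_age_model`: `slope`, `intercept`,
#'   `slope_se`, `p_value` (NA with fewer than 3 families) and the `lm` fit.
#' @export
paternal_age_fit <- function(rates, ages, weights = NULL) {
  if (inherits(rates, "rate_estimate")) {
    r <- rates$per_family$rate
    names(r) <- rates$per_family$family_id
    rates <- r
  }
  if (!is.null(names(rates)) && !is.null(names(ages)))
    ages <- ages[names(rates)]
  ok <- is.finite(rates) & is.finite(ages)
  rates <- rates[ok]; ages <- ages[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(rates) < 2) stop("need at least 2 families to fit an age effect")
  if (length(unique(ages)) < 2)
    stop("paternal ages are all identical: slope unidentifiable")
  fit <- stats::lm(rates ~ ages, weights = weights)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  p_value <- if (length(rates) >= 3) co["ages", "Pr(>|t|)"] else NA_real_
  slope_se <- if (length(rates) >= 3) co["ages", "Std. Error"] else NA_real_
  structure(list(slope = unname(stats::coef(fit)["ages"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_se = slope_se, p_value = p_value,
                 n_families = length(rates), fit = fit),
            class = "paternal_age_model")
}

#' @export
print.paternal_age_model <- function(x, ...) {
  cat(sprintf("paternal-age effect: %.3g extra mutations per nt per year (SE %.3g, p = %.3g, %d families)\n",
              x$slope, x$slope_se, x$p_value, x$n_families))
  invisible(x)
}

#' Full de novo rate estimation pipeline for a cohort
#'
#' Convenience wrapper running candidate calling, callability calibration,
#' the per-family callable-genome summation and the pooled rate estimate,
#' plus the paternal-age regression when ages are available. SNVs and indels
#' are estimated against separately calibrated callability tables (the indel
#' calibration is restricted to indel sites and imposes no known-variants
#' requirement).
#'
#' @param cohort A `trio_cohort`.
#' @param depth_histograms Named list of `depth_histogram`s, one per family
#'   id.
#' @param config A [filter_config()].
#' @param variant_type `"SNV"` or `"indel"`.
#' @param calls Optional precomputed [call_denovo()] result to reuse.
#' @param weighted_age_fit Weight the age regression by family denominators.
#' @return A list of class `dnm_rate_result`: `rate` (a `rate_estimate`),
#'   `age_model` (or NULL), `calls`, `het_table`, `homref_table`,
#'   `alpha_site`.
#' @export
estimate_dnm_rate <- function(cohort, depth_histograms,
                              config = filter_config(),
                              variant_type = "SNV", calls = NULL,
                              weighted_age_fit = FALSE) {
  variant_type <- match.arg(variant_type, c("SNV", "indel"))
  if (is.null(calls)) calls <- call_denovo(cohort, config)
  germ <- calls[calls$classification == "germline" &
                  calls$variant_type == variant_type, , drop = FALSE]
  fams <- cohort$pedigrees$family_id
  n_mut <- table(factor(germ$family_id, levels = fams))
  n_mut <- stats::setNames(as.integer(n_mut), fams)
  het_tab <- calibrate_het_callability(cohort, config, variant_type)
  hom_tab <- calibrate_homref_callability(cohort, config, variant_type)
  missing_hist <- setdiff(fams, names(depth_histograms))
  if (length(missing_hist))
    stop("no depth histogram for family: ", paste(missing_hist, collapse = ", "))
  callable <- vapply(fams, function(f)
    expected_callable_sites(depth_histograms[[f]], het_tab, hom_tab),
    numeric(1))
  loss <- alpha_site_from_config(config$site_test_alphas)
  rate <- estimate_rate(n_mut, callable, loss, level = 0.95)
  age_model <- NULL
  ages <- stats::setNames(cohort$pedigrees$father_age, fams)
  if (sum(is.finite(ages)) >= 2 && length(unique(ages[is.finite(ages)])) >= 2) {
    w <- if (weighted_age_fit) stats::setNames(rate$per_family$denominator, fams)
    age_model <- paternal_age_fit(rate, ages, weights = w)
  }
  structure(list(rate = rate, age_model = age_model, calls = calls,
                 het_table = het_tab, homref_table = hom_tab,
                 alpha_site = loss$alpha_site, variant_type = variant_type),
            class = "dnm_rate_result")
}

#' @export
print.dnm_rate_result <- function(x, ...) {
  cat(sprintf("de novo %s rate estimate\n", x$variant_type))
  print(x$rate)
  if (!is.null(x$age_model)) print(x$age_model)
  invisible(x)
}
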