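.pool_counts <- function(successes, trials, min_trials) {
  # outward expansion around each depth bin until min_trials is reached;
  # ties between sides broken toward lower depth
  D <- length(trials)
  est <- numeric(D)
  for (i in seq_len(D)) {
    lo <- i; hi <- i
    s <- successes[i]; t <- trials[i]
    while (t < min_trials && (lo > 1 || hi < D)) {
      grow_left <- lo > 1 && (hi >= D || (i - (lo - 1)) <= ((hi + 1) - i))
      if (grow_left) {
        lo <- lo - 1; s <- s + successes[lo]; t <- t + trials[lo]
      } else {
        hi <- hi + 1; s <- s + successes[hi]; t <- t + trials[hi]
      }
    }
    est[i] <- if (t > 0) s / t else NA_real_
  }
  est
}

new_callability_table <- function(depth, successes, trials, role, min_trials) {
  stopifnot(length(depth) == length(successes),
            length(depth) == length(trials))
  estimate <- .pool_counts(successes, trials, min_trials)
  if (all(is.na(estimate))) stop("callability calibration impossible: no trials")
  out <- data.frame(depth = depth, successes = successes, trials = trials,
                    estimate = estimate)
  structure(out, role = role, min_trials = min_trials,
            class = c("callability_table", "data.frame"))
}

#' @export
print.callability_table <- function(x, ...) {
  cat(sprintf("callability table (role %s): depths %d..%d, %g trials total, %d per-bin minimum\n",
              attr(x, "role"), min(x$depth), max(x$depth), sum(x$trials),
              attr(x, "min_trials")))
  invisible(x)
}

#' Look up callability at given depths
#'
#' Depths outside the calibrated range are clamped to the nearest calibrated
#' bin (which is itself pooled to the configured minimum trial count).
#'
#' @param table A `callability_table`.
#' @param d Integer depth(s).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
callability_at <- function(table, d) {
  d <- pmin(pmax(round(d), min(table$depth)), max(table$depth))
  table$estimate[match(d, table$depth)]
}

.calibration_counts <- function(depths, success) {
  depths <- as.integer(round(depths))
  dmax <- max(depths)
  trials <- tabulate(depths + 1L, nbins = dmax + 1L)
  succ <- tabulate((depths + 1L)[success], nbins = dmax + 1L)
  list(depth = 0:dmax, successes = succ, trials = trials)
}

#' Calibrate heterozygote callability against depth
#'
#' Estimates, per child depth d, the probability that a true heterozygote is
#' called Het and survives the heterozygote filter. Calibration sites are
#' those passing the site filter where one parent is confidently homozygous
#' reference and the other confidently homozygous alternative (genotype
#' quality at least `gq_min` for both): at such sites the child must be a
#' heterozygote barring de novo events, so every qualifying child observation
#' is a Bernoulli trial of the Het calling machinery. Depth bins with fewer
#' than `min_trials` observations are pooled outward with neighbouring bins.
#'
#' @param cohort A `trio_cohort`.
#' @param config A [filter_config()].
#' @param variant_type Calibrate on `"SNV"` (default) or `"indel"` sites.
#' @return A `callability_table` with role `het_child`.
#' @export
calibrate_het_callability <- function(cohort, config = filter_config(),
                                      variant_type = "SNV") {
  sp <- site_filter(cohort, config)$pass
  type_ok <- cohort$sites$variant_type == variant_type
  depths <- integer(0); succ <- logical(0)
  for (k in seq_len(nrow(cohort$pedigrees))) {
    fam <- cohort$pedigrees[k, ]
    fa_gt <- cohort$gt[, fam$father_id]; mo_gt <- cohort$gt[, fam$mother_id]
    fa_gq <- cohort$gq[, fam$father_id]; mo_gq <- cohort$gq[, fam$mother_id]
    opp <- ((fa_gt == 0L & mo_gt == 2L) | (fa_gt == 2L & mo_gt == 0L)) &
      fa_gq >= config$gq_min & mo_gq >= config$gq_min
    opp[is.na(opp)] <- FALSE
    qual <- which(sp & type_ok & opp)
    if (!length(qual)) next
    d <- cohort$dp[qual, fam$child_id]
    d[is.na(d)] <- 0
    s <- heterozygote_filter(cohort$gt[qual, fam$child_id],
                             cohort$gq[qual, fam$child_id],
                             cohort$dp[qual, fam$child_id], config)
    depths <- c(depths, d); succ <- c(succ, s)
  }
  if (!length(depths))
    stop("no qualifying heterozygote calibration observations")
  cc <- .calibration_counts(depths, succ)
  new_callability_table(cc$depth, cc$successes, cc$trials,
                        role = "het_child", min_trials = config$min_trials)
}

#' Calibrate homozygote-reference callability against depth
#'
#' Estimates, per depth d, the probability that a truly homozygous-reference
#' individual is called HomRef and survives the homozygote filter.
#' Calibration sites are those passing the site filter where both parents of
#' the family are confidently HomRef (genotype quality at least `gq_min`),
#' the variant is carried by at least one sample in another family, and - for
#' SNVs - the site is in the known-variants list (dbSNP stand-in), so that
#' the site is a real polymorphism and the child is truly HomRef barring de
#' novo events. The children of such families supply the Bernoulli trials.
#'
#' @inheritParams calibrate_het_callability
#' @return A `callability_table` with role `homref_parent` (calibrated on
#'   children, applied to parents).
#' @export
calibrate_homref_callability <- function(cohort, config = filter_config(),
                                         variant_type = "SNV") {
  sp <- site_filter(cohort, config)$pass
  type_ok <- cohort$sites$variant_type == variant_type
  known_ok <- if (variant_type == "SNV") cohort$sites$known else TRUE
  depths <- integer(0); succ <- logical(0)
  for (k in seq_len(nrow(cohort$pedigrees))) {
    fam <- cohort$pedigrees[k, ]
    fa_gt <- cohort$gt[, fam$father_id]; mo_gt <- cohort$gt[, fam$mother_id]
    fa_gq <- cohort$gq[, fam$father_id]; mo_gq <- cohort$gq[, fam$mother_id]
    both_ref <- fa_gt == 0L & mo_gt == 0L &
      fa_gq >= config$gq_min & mo_gq >= config$gq_min
    both_ref[is.na(both_ref)] <- FALSE
    others <- setdiff(cohort$samples,
                      c(fam$child_id, fam$father_id, fam$mother_id))
    carrier <- if (length(others))
      rowSums(cohort$gt[, others, drop = FALSE] != 0L, na.rm = TRUE) > 0
    else rep(FALSE, nrow(cohort$sites))
    qual <- which(sp & type_ok & known_ok & both_ref & carrier)
    if (!length(qual)) next
    d <- cohort$dp[qual, fam$child_id]
    d[is.na(d)] <- 0
    s <- homozygote_filter(cohort$gt[qual, fam$child_id],
                           cohort$gq[qual, fam$child_id],
                           cohort$dp[qual, fam$child_id],
                           cohort$ad_alt[qual, fam$child_id], config)
    depths <- c(depths, d); succ <- c(succ, s)
  }
  if (!length(depths))
    stop("no qualifying homozygote calibration observations")
  cc <- .calibration_counts(depths, succ)
  new_callability_table(cc$depth, cc$successes, cc$trials,
                        role = "homref_parent", min_trials = config$min_trials)
}

#' Callability of one site in one family
#'
#' Under independence of the three calling events, the probability that a
#' true de novo mutation would be called and survive all individual filters
#' is the product of calling the child Het and each parent HomRef correctly.
#'
#' @param c_het Child Het-callability at the child's depth.
#' @param c_hom_father,c_hom_mother Parental HomRef-callabilities at their
#'   depths.
#' @return The product, a probability.
#' @export
family_site_callability <- function(c_het, c_hom_father, c_hom_mother) {
  p <- c(c_het, c_hom_father, c_hom_mother)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("callability factors must be probabilities in [0, 1]")
  c_het * c_hom_father * c_hom_mother
}

#' Expected number of callable sites for a family
#'
#' Sums the per-site callability over the genome using the family's joint
#' depth histogram: for each (child, father, mother) depth cell the product
#' of the calibrated Het and HomRef callabilities, weighted by the number of
#' positions in the cell. Depths outside a table's calibrated range clamp to
#' the nearest bin.
#'
#' @param depth_histogram A `depth_histogram` for the family.
#' @param het_table `callability_table` for the child Het call.
#' @param homref_table `callability_table` for the parental HomRef calls.
#' @return The expected callable site count (haploid positions, real-valued).
#' @export
expected_callable_sites <- function(depth_histogram, het_table, homref_table) {
  if (!nrow(depth_histogram)) return(0)
  sum(depth_histogram$count *
        callability_at(het_table, depth_histogram$d_child) *
        callability_at(homref_table, depth_histogram$d_father) *
        callability_at(homref_table, depth_histogram$d_mother))
}

#' Expected site-filter loss under the null
#'
#' The site filter rejects a genuinely good site when any of its tests falls
#' below its alpha; assuming the tests are independent with uniform null
#' p-values, the expected loss is `1 - prod(1 - alpha_k)`.
#'
#' @param site_test_alphas Numeric vector of per-test alphas in \[0, 1).
#' @return A list of class `site_filter_loss`: `alpha_site` and the per-test
#'   `alphas`.
#' @export
alpha_site_from_config <- function(site_test_alphas) {
  if (length(site_test_alphas) &&
      any(site_test_alphas < 0 | site_test_alphas >= 1))
    stop("alphas must lie in [0, 1)")
  a <- 1 - prod(1 - site_test_alphas)
  structure(list(alpha_site = a, alphas = site_test_alphas),
            class = "site_filter_loss")
}

#' @export
print.site_filter_loss <- function(x, ...) {
  cat(sprintf("expected site-filter loss alpha_site = %g\n", x$alpha_site))
  invisible(x)
}
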