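#' Exact strand-bias test p-value
#'
#' Two-sided exact conditional test (hypergeometric / Fisher) on the 2x2 table
#' of reference/alternative reads by forward/reverse strand, aggregated over
#' the cohort. Degenerate tables (missing counts, empty margins) return 1 so
#' that sites without strand information are never rejected.
#'
#' @param srf,srr Reference-supporting reads on the forward/reverse strand.
#' @param saf,sar Alternative-supporting reads on the forward/reverse strand.
#' @return The p-value.
#' @export
strand_bias_p <- function(srf, srr, saf, sar) {
  x <- c(srf, srr, saf, sar)
  if (any(is.na(x))) return(1)
  if ((srf + srr) == 0 || (saf + sar) == 0 ||
      (srf + saf) == 0 || (srr + sar) == 0) return(1)
  stats::fisher.test(matrix(x, nrow = 2, byrow = TRUE))$p.value
}

#' Read-position rank test p-value
#'
#' Two-sided Wilcoxon rank-sum test comparing the within-read positions of
#' reference- and alternative-supporting observations; systematic clustering
#' of the alternative allele near read ends is the alignment-artifact signal
#' being screened. Returns 1 when either group is empty or the statistic is
#' undefined.
#'
#' @param rp_ref,rp_alt Numeric vectors of within-read positions, or
#'   comma-separated strings as stored in VCF INFO.
#' @return The p-value.
#' @export
read_position_p <- function(rp_ref, rp_alt) {
  parse <- function(x) {
    if (is.character(x)) x <- suppressWarnings(as.numeric(strsplit(x, ",")[[1]]))
    x[!is.na(x)]
  }
  a <- parse(rp_ref); b <- parse(rp_alt)
  if (!length(a) || !length(b)) return(1)
  if (length(unique(c(a, b))) == 1L) return(1)
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  if (!is.finite(p)) 1 else p
}

#' Cohort-level site filter
#'
#' Applies the configured site tests to every site of a cohort. A site passes
#' when each configured test's p-value is at least its alpha; because the
#' tests have known null distributions, the expected fraction of good sites
#' lost to this filter is [alpha_site_from_config()] of the same alphas and is
#' credited back in the rate denominator. Sites lacking the statistics for a
#' test pass that test with p = 1. P-value computation is memoised over the
#' distinct statistic tuples present in the cohort.
#'
#' @param cohort A `trio_cohort`.
#' @param config A [filter_config()].
#' @return A data.frame with one row per site: `p_strand`, `p_position`,
#'   `pass`.
#' @export
site_filter <- function(cohort, config = filter_config()) {
  s <- cohort$sites
  n <- nrow(s)
  alphas <- config$site_test_alphas
  p_strand <- rep(1, n); p_position <- rep(1, n)
  if ("strand_bias" %in% names(alphas) && all(c("srf", "srr", "saf", "sar") %in% names(s))) {
    key <- paste(s$srf, s$srr, s$saf, s$sar)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i)
      strand_bias_p(s$srf[i], s$srr[i], s$saf[i], s$sar[i]), numeric(1))
    p_strand <- pv[match(key, key[uk])]
  }
  if ("read_position" %in% names(alphas) && all(c("rp_ref", "rp_alt") %in% names(s))) {
    key <- paste(s$rp_ref, s$rp_alt)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i)
      read_position_p(s$rp_ref[i], s$rp_alt[i]), numeric(1))
    p_position <- pv[match(key, key[uk])]
  }
  pass <- rep(TRUE, n)
  if ("strand_bias" %in% names(alphas))
    pass <- pass & p_strand >= alphas[["strand_bias"]]
  if ("read_position" %in% names(alphas))
    pass <- pass & p_position >= alphas[["read_position"]]
  data.frame(p_strand = p_strand, p_position = p_position, pass = pass)
}

#' Heterozygote individual filter
#'
#' A child's candidate heterozygous call passes when the genotype is Het, the
#' genotype quality is at least `gq_min` and the depth lies in
#' `[dp_min, dp_max]` (all bounds inclusive). Missing observations fail.
#'
#' @param gt Integer genotype codes (0 HomRef, 1 Het, 2 HomAlt, NA missing);
#'   vectorised.
#' @param gq,dp Genotype quality and depth, same length.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
heterozygote_filter <- function(gt, gq, dp, config = filter_config()) {
  ok <- gt == 1L & gq >= config$gq_min & dp >= config$dp_min & dp <= config$dp_max
  ok[is.na(ok)] <- FALSE
  ok
}

#' Homozygote individual filter
#'
#' A parent's homozygous-reference call passes when the genotype is HomRef,
#' genotype quality and depth satisfy the same bounds as the heterozygote
#' filter, and at most `hom_alt_reads_max` reads support the alternative
#' allele (AD2 = 0 by default). Missing observations fail.
#'
#' @inheritParams heterozygote_filter
#' @param ad_alt Alternative-supporting read count, same length.
#' @return Logical vector.
#' @export
homozygote_filter <- function(gt, gq, dp, ad_alt, config = filter_config()) {
  ok <- gt == 0L & gq >= config$gq_min & dp >= config$dp_min &
    dp <= config$dp_max & ad_alt <= config$hom_alt_reads_max
  ok[is.na(ok)] <- FALSE
  ok
}

#' Mendelian-violation de novo candidates for one family
#'
#' A site is a candidate in a family when the child is a heterozygote passing
#' the heterozygote filter, both parents are homozygous reference passing the
#' homozygote filter, and the variant is not called (no non-HomRef genotype)
#' in any sample outside the family. The cohort-level site filter is applied
#' separately (see [call_denovo()]); this predicate assumes the site already
#' passed it.
#'
#' @param cohort A `trio_cohort`.
#' @param family_id Family to test.
#' @param config A [filter_config()].
#' @return Logical vector over the cohort's sites.
#' @export
mendelian_violation_candidate <- function(cohort, family_id,
                                          config = filter_config()) {
  fam <- cohort$pedigrees[cohort$pedigrees$family_id == family_id, ]
  if (nrow(fam) != 1) stop("unknown family: ", family_id)
  ci <- fam$child_id; fi <- fam$father_id; mi <- fam$mother_id
  child_ok <- heterozygote_filter(cohort$gt[, ci], cohort$gq[, ci],
                                  cohort$dp[, ci], config)
  fa_ok <- homozygote_filter(cohort$gt[, fi], cohort$gq[, fi],
                             cohort$dp[, fi], cohort$ad_alt[, fi], config)
  mo_ok <- homozygote_filter(cohort$gt[, mi], cohort$gq[, mi],
                             cohort$dp[, mi], cohort$ad_alt[, mi], config)
  others <- setdiff(cohort$samples, c(ci, fi, mi))
  if (length(others)) {
    other_carrier <- rowSums(cohort$gt[, others, drop = FALSE] != 0L,
                             na.rm = TRUE) > 0
  } else {
    other_carrier <- rep(FALSE, nrow(cohort$sites))
  }
  child_ok & fa_ok & mo_ok & !other_carrier
}

#' Germline / somatic-candidate partition by allele balance
#'
#' Candidates whose allele balance falls inside the closed interval
#' `[ab_lo, ab_hi]` are considered genuine germline de novo mutations; the
#' rest (typically a low-balance mode around 0.18) are putative somatic
#' variants or artifacts.
#'
#' @param ab Allele balance value(s); must be defined (not NA/NaN).
#' @param config A [filter_config()].
#' @return Character vector, `"germline"` or `"somatic_candidate"`.
#' @export
classify_allele_balance <- function(ab, config = filter_config()) {
  if (any(!is.finite(ab)))
    stop("allele balance undefined (no informative reads): site uncallable")
  ifelse(ab >= config$ab_lo & ab <= config$ab_hi,
         "germline", "somatic_candidate")
}

#' Call de novo mutations in a trio cohort
#'
#' Runs the cohort-level site filter, the per-family Mendelian-violation
#' candidate logic and the allele-balance partition over all families.
#' Indels longer than `config$max_indel_len` are excluded from the indel
#' analysis.
#'
#' @param cohort A `trio_cohort`.
#' @param config A [filter_config()].
#' @return A data.frame of class `denovo_calls`: `family_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_type`, `ab`, `classification`, `child_gq`,
#'   `child_dp`.
#' @export
call_denovo <- function(cohort, config = filter_config()) {
  sp <- site_filter(cohort, config)$pass
  len_ok <- cohort$sites$variant_type == "SNV" |
    cohort$sites$indel_len <= config$max_indel_len
  ab <- allele_balance(cohort)
  out <- lapply(seq_len(nrow(cohort$pedigrees)), function(k) {
    fam <- cohort$pedigrees[k, ]
    cand <- mendelian_violation_candidate(cohort, fam$family_id, config) &
      sp & len_ok
    idx <- which(cand)
    if (!length(idx)) return(NULL)
    ab_c <- ab[idx, fam$child_id]
    data.frame(family_id = fam$family_id,
               chrom = cohort$sites$chrom[idx],
               pos = cohort$sites$pos[idx],
               ref = cohort$sites$ref[idx],
               alt = cohort$sites$alt[idx],
               variant_type = cohort$sites$variant_type[idx],
               ab = ab_c,
               classification = classify_allele_balance(ab_c, config),
               child_gq = cohort$gq[idx, fam$child_id],
               child_dp = cohort$dp[idx, fam$child_id],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(family_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      variant_type = character(0), ab = numeric(0),
                      classification = character(0), child_gq = numeric(0),
                      child_dp = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("denovo_calls", "data.frame")
  out
}

#' @export
print.denovo_calls <- function(x, ...) {
  cat(sprintf("%d de novo candidate(s): %d germline, %d somatic_candidate (%d SNV, %d indel)\n",
              nrow(x), sum(x$classification == "germline"),
              sum(x$classification == "somatic_candidate"),
              sum(x$variant_type == "SNV"), sum(x$variant_type == "indel")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
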