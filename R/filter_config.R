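#' Filter configuration for de novo mutation calling
#'
#' Bundles the individual-level and site-level filter thresholds used
#' throughout candidate calling and callability calibration. The defaults are
#' the conservative settings for high-depth (about 50x) trio sequencing:
#' genotype quality at least 50 for both the heterozygote and the homozygote
#' filter, read depth between 10 and 120 inclusive, zero alternative-allele
#' reads allowed for a homozygous-reference call, and an allele-balance window
#' of \[0.3, 0.7\] (closed) separating germline calls from putative somatic
#' candidates.
#'
#' @param gq_min Minimum phred-scaled genotype quality (applies to both the
#'   heterozygote and homozygote filter).
#' @param dp_min,dp_max Inclusive read-depth bounds.
#' @param hom_alt_reads_max Maximum alternative-supporting reads (AD2) allowed
#'   by the homozygote filter.
#' @param ab_lo,ab_hi Closed allele-balance interval for a germline call.
#' @param site_test_alphas Named numeric vector of per-test significance
#'   levels for the cohort-level site filter; a site is rejected when any
#'   test's p-value falls below its alpha. Names must be a subset of
#'   `c("strand_bias", "read_position")`.
#' @param max_indel_len Largest indel length (|len(alt) - len(ref)|, bp)
#'   admitted to de novo indel analysis; the default keeps indels under 40 bp.
#' @param min_trials Minimum number of calibration observations per depth bin
#'   before adjacent bins are pooled (see [calibrate_het_callability()]).
#' @return An object of class `filter_config` (a validated list).
#' @export
#' @examples
#' filter_config()
#' filter_config(site_test_alphas = c(strand_bias = 0.05))
filter_config <- function(gq_min = 50,
                          dp_min = 10, dp_max = 120,
                          hom_alt_reads_max = 0,
                          ab_lo = 0.3, ab_hi = 0.7,
                          site_test_alphas = c(strand_bias = 0.01,
                                               read_position = 0.01),
                          max_indel_len = 39,
                          min_trials = 100) {
  stopifnot(gq_min >= 0, dp_min >= 0, dp_min <= dp_max,
            hom_alt_reads_max >= 0,
            ab_lo >= 0, ab_lo < ab_hi, ab_hi <= 1,
            max_indel_len >= 1, min_trials >= 1)
  if (length(site_test_alphas)) {
    if (is.null(names(site_test_alphas)) ||
        !all(names(site_test_alphas) %in% c("strand_bias", "read_position")))
      stop("site_test_alphas must be named 'strand_bias' and/or 'read_position'")
    if (any(site_test_alphas < 0 | site_test_alphas >= 1))
      stop("site-test alphas must lie in [0, 1)")
  }
  structure(list(gq_min = gq_min, dp_min = dp_min, dp_max = dp_max,
                 hom_alt_reads_max = hom_alt_reads_max,
                 ab_lo = ab_lo, ab_hi = ab_hi,
                 site_test_alphas = site_test_alphas,
                 max_indel_len = max_indel_len,
                 min_trials = min_trials),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("de novo filter configuration\n")
  cat(sprintf("  GQ >= %g, DP in [%g; %g], homozygote AD2 <= %g\n",
              x$gq_min, x$dp_min, x$dp_max, x$hom_alt_reads_max))
  cat(sprintf("  germline allele balance in [%g; %g]\n", x$ab_lo, x$ab_hi))
  if (length(x$site_test_alphas))
    cat("  site-test alphas:",
        paste(sprintf("%s=%g", names(x$site_test_alphas), x$site_test_alphas),
              collapse = ", "), "\n")
  cat(sprintf("  indels <= %d bp, callability min trials per depth = %d\n",
              x$max_indel_len, x$min_trials))
  invisible(x)
}

#' Read a filter configuration from a key=value file
#'
#' One `key = value` pair per line; `#` starts a comment. Recognised keys
#' match the arguments of [filter_config()]; `site_test_alphas` is given as
#' the two keys `alpha_strand_bias` and `alpha_read_position`. Unknown keys
#' are an error so that typos cannot silently relax a filter.
#'
#' @param path Path to the configuration file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  ln <- trimws(sub("#.*", "", readLines(path)))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed line in filter config: ",
                                  ln[lengths(kv) != 2][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  known <- c("gq_min", "dp_min", "dp_max", "hom_alt_reads_max", "ab_lo",
             "ab_hi", "max_indel_len", "min_trials",
             "alpha_strand_bias", "alpha_read_position")
  if (any(!keys %in% known))
    stop("unknown filter config key: ", paste(setdiff(keys, known), collapse = ", "))
  args <- as.list(vals[!startsWith(keys, "alpha_")])
  names(args) <- keys[!startsWith(keys, "alpha_")]
  alphas <- vals[startsWith(keys, "alpha_")]
  names(alphas) <- sub("^alpha_", "", keys[startsWith(keys, "alpha_")])
  if (length(alphas)) args$site_test_alphas <- alphas
  do.call(filter_config, args)
}
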