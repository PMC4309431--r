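# In-code fixture builders shared across the test files.

# A hand-specified cohort: per-sample observation matrices with full control
# over every FORMAT value. `obs` matrices are sites x samples.
toy_cohort <- function(pedigrees, gt, gq, dp, ad_ref, ad_alt,
                       sites = NULL) {
  samples <- as.character(t(as.matrix(
    pedigrees[, c("child_id", "father_id", "mother_id")])))
  n <- nrow(gt)
  if (is.null(sites)) {
    sites <- data.frame(chrom = "1", pos = seq_len(n) * 100L,
                        ref = "A", alt = "G", variant_type = "SNV",
                        indel_len = 0L, known = FALSE,
                        srf = NA_real_, srr = NA_real_, saf = NA_real_,
                        sar = NA_real_, rp_ref = NA_character_,
                        rp_alt = NA_character_, stringsAsFactors = FALSE)
  }
  dnmrate:::new_trio_cohort(pedigrees, samples, sites,
                            gt = gt, gq = gq, dp = dp,
                            ad_ref = ad_ref, ad_alt = ad_alt)
}

toy_pedigree <- function(n_families = 2, ages = NULL) {
  fam <- sprintf("F%02d", seq_len(n_families))
  data.frame(family_id = fam,
             child_id = paste0(fam, "-C"),
             father_id = paste0(fam, "-F"),
             mother_id = paste0(fam, "-M"),
             father_age = if (is.null(ages)) NA_real_ else ages,
             stringsAsFactors = FALSE)
}

# Cohort where every observation is a clean high-quality call of the given
# genotype matrix (gq 99, dp 30, allele-consistent AD).
clean_cohort <- function(gt_matrix, pedigrees = NULL, sites = NULL) {
  if (is.null(pedigrees))
    pedigrees <- toy_pedigree(ncol(gt_matrix) / 3)
  dp <- matrix(30, nrow(gt_matrix), ncol(gt_matrix))
  gq <- matrix(99, nrow(gt_matrix), ncol(gt_matrix))
  ad_alt <- matrix(0, nrow(gt_matrix), ncol(gt_matrix))
  ad_alt[gt_matrix == 1L] <- 15
  ad_alt[gt_matrix == 2L] <- 30
  ad_ref <- dp - ad_alt
  toy_cohort(pedigrees, gt_matrix, gq, dp, ad_ref, ad_alt, sites = sites)
}

# Independent exact two-sided p-value for a 2x2 table by hypergeometric
# enumeration (probability-mass ordering), used as the oracle for the
# strand-bias test.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(xs, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Brute-force per-position depth lookup for histogram oracles.
brute_depth <- function(track, chrom, pos1) {
  vapply(pos1, function(p) {
    hit <- track$chrom == chrom & track$start < p & track$end >= p
    if (any(hit)) track$depth[which(hit)[1]] else 0L
  }, numeric(1))
}

# Exhaustive tandem-array oracle: enumerates every (start, unit-length)
# periodic extension directly, then applies the same reporting rules as the
# detector (min copies, minimal-period unit, containment suppression).
brute_tandem <- function(window) {
  s <- strsplit(toupper(window), "")[[1]]
  n <- length(s)
  hits <- list()
  for (k in seq_len(n %/% 2)) {
    a <- 1
    while (a + 2 * k - 1 <= n) {
      # extend the periodic stretch starting at a with period k
      b <- a + k - 1
      while (b + 1 <= n && s[b + 1] == s[b + 1 - k] && s[b + 1] != "N" &&
             s[b + 1 - k] != "N") b <- b + 1
      len <- b - a + 1
      copies <- len %/% k
      ok <- if (k == 1) copies >= 6 else copies >= 2
      if (ok && len >= 2 * k) {
        unit <- paste(s[a:(a + k - 1)], collapse = "")
        per <- dnmrate:::.min_period(unit)
        if (per == k)
          hits[[length(hits) + 1]] <- data.frame(
            unit = dnmrate:::.min_rotation(unit), unit_len = as.integer(k),
            copies = as.integer(copies), start = as.integer(a),
            end = as.integer(b), stringsAsFactors = FALSE)
      }
      a <- if (len >= 2 * k) b - k + 2 else a + 1
    }
    # dedupe identical maximal arrays found from different starts
  }
  if (!length(hits))
    return(data.frame(unit = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  # keep only maximal arrays per (unit_len): drop arrays contained in a
  # longer array of the same unit length
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    same <- out$unit_len == out$unit_len[i] &
      out$start <= out$start[i] & out$end >= out$end[i] &
      (out$end - out$start > out$end[i] - out$start[i])
    if (any(same)) keep[i] <- FALSE
    cont <- out$start <= out$start[i] & out$end >= out$end[i] &
      out$unit_len < out$unit_len[i] &
      (out$end - out$start) >= (out$end[i] - out$start[i])
    if (any(cont)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Write a minimal hand-rolled VCF for parser edge-case tests.
write_test_vcf <- function(path, body_lines,
                           samples = c("F01-C", "F01-F", "F01-M")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

write_test_ped <- function(path, pedigrees) {
  rows <- rbind(
    data.frame(f = pedigrees$family_id, id = pedigrees$child_id,
               fa = pedigrees$father_id, mo = pedigrees$mother_id, s = 0, p = -9),
    data.frame(f = pedigrees$family_id, id = pedigrees$father_id,
               fa = 0, mo = 0, s = 1, p = -9),
    data.frame(f = pedigrees$family_id, id = pedigrees$mother_id,
               fa = 0, mo = 0, s = 2, p = -9))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
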