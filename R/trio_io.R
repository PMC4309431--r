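#' @importFrom data.table data.table setDT setorder :=
NULL

.GT_CODE <- c("0/0" = 0L, "0|0" = 0L,
              "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
              "1/1" = 2L, "1|1" = 2L)

.SITE_STAT_COLS <- c("srf", "srr", "saf", "sar", "rp_ref", "rp_alt")

#' Read a pedigree of trios from a 6-column PED file
#'
#' Rows whose father and mother columns are both non-zero define the children;
#' each such row becomes one trio. Family ids must be unique (one child per
#' family) and the three members of a trio must be distinct samples.
#'
#' @param path Path to a whitespace-separated PED file
#'   (family, sample, father, mother, sex, phenotype).
#' @return A data.frame with columns `family_id`, `child_id`, `father_id`,
#'   `mother_id` and `father_age` (`NA` until ages are attached).
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  kids <- ped[ped$father_id != "0" & ped$mother_id != "0", , drop = FALSE]
  if (!nrow(kids)) stop("PED file contains no complete trios")
  if (anyDuplicated(kids$family_id))
    stop("duplicate family ids among trio children: ",
         paste(unique(kids$family_id[duplicated(kids$family_id)]), collapse = ", "))
  fam <- data.frame(family_id = kids$family_id, child_id = kids$sample_id,
                    father_id = kids$father_id, mother_id = kids$mother_id,
                    father_age = NA_real_, stringsAsFactors = FALSE)
  bad <- apply(fam[, c("child_id", "father_id", "mother_id")], 1,
               function(x) anyDuplicated(x) > 0)
  if (any(bad)) stop("trio members not distinct in family ",
                     paste(fam$family_id[bad], collapse = ", "))
  missing_parent <- setdiff(c(fam$father_id, fam$mother_id), ped$sample_id)
  if (length(missing_parent))
    stop("parents absent from PED: ", paste(missing_parent, collapse = ", "))
  fam
}

#' Attach paternal ages to a pedigree
#'
#' @param pedigree A pedigree data.frame from [read_ped()].
#' @param path Tab-separated file with header columns `family_id` and
#'   `father_age` (years at the child's birth).
#' @return The pedigree with `father_age` filled in.
#' @export
read_ages <- function(pedigree, path) {
  ages <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "father_age") %in% names(ages)))
    stop("ages file needs header columns family_id and father_age")
  if (any(ages$father_age <= 0, na.rm = TRUE))
    stop("father_age must be positive")
  idx <- match(pedigree$family_id, as.character(ages$family_id))
  pedigree$father_age <- ages$father_age[idx]
  pedigree
}

#' Read a known-variants site list
#'
#' Accepts either a VCF (`.vcf`/`.vcf.gz`) or a tab-separated table with
#' columns chrom, pos, ref, alt (header optional). Used as a dbSNP stand-in:
#' membership is keyed on the exact (chrom, pos, ref, alt) tuple.
#'
#' @param path Path to the site list.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_known_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- v@fix
    return(data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                      ref = fx[, "REF"], alt = fx[, "ALT"],
                      stringsAsFactors = FALSE))
  }
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.integer(first[2])))
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 4) stop("known-sites table needs 4 columns: chrom pos ref alt")
  names(tab)[1:4] <- c("chrom", "pos", "ref", "alt")
  tab$pos <- as.integer(tab$pos)
  tab[, 1:4]
}

.site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

.is_autosome <- function(chrom) grepl("^(chr)?[0-9]+$", chrom)

new_trio_cohort <- function(pedigrees, samples, sites, gt, gq, dp,
                            ad_ref, ad_alt, n_skipped = 0L,
                            skip_reasons = integer(0)) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(gt),
            ncol(gt) == length(samples),
            identical(dim(gt), dim(gq)), identical(dim(gt), dim(dp)),
            identical(dim(gt), dim(ad_ref)), identical(dim(gt), dim(ad_alt)))
  colnames(gt) <- colnames(gq) <- colnames(dp) <-
    colnames(ad_ref) <- colnames(ad_alt) <- samples
  need <- unlist(pedigrees[, c("child_id", "father_id", "mother_id")])
  if (!all(need %in% samples))
    stop("pedigree samples absent from genotype data: ",
         paste(setdiff(need, samples), collapse = ", "))
  structure(list(pedigrees = pedigrees, samples = samples, sites = sites,
                 gt = gt, gq = gq, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
                 n_skipped = as.integer(n_skipped), skip_reasons = skip_reasons),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio cohort: %d families (%d samples), %d bi-allelic sites (%d SNV, %d indel)\n",
              nrow(x$pedigrees), length(x$samples), nrow(x$sites),
              sum(x$sites$variant_type == "SNV"),
              sum(x$sites$variant_type == "indel")))
  if (x$n_skipped)
    cat(sprintf("  %d VCF records skipped (%s)\n", x$n_skipped,
                paste(sprintf("%s: %d", names(x$skip_reasons), x$skip_reasons),
                      collapse = ", ")))
  invisible(x)
}

#' Allele balance matrix of a cohort
#'
#' Fraction of informative reads supporting the alternative allele,
#' `ad_alt / (ad_ref + ad_alt)`; `NaN` where no informative reads exist.
#'
#' @param cohort A `trio_cohort`.
#' @return A numeric matrix, sites x samples.
#' @export
allele_balance <- function(cohort) {
  tot <- cohort$ad_ref + cohort$ad_alt
  ab <- cohort$ad_alt / tot
  ab[!is.finite(ab)] <- NaN
  ab
}

#' Read a trio cohort from VCF + PED (+ ages, known sites)
#'
#' Builds the in-memory cohort model every downstream step consumes. Only
#' bi-allelic SNV and indel records with parseable REF/ALT are kept;
#' multi-allelic, symbolic and malformed records are skipped and counted.
#' Genotype observations with a missing GT, GQ, DP or AD FORMAT value are set
#' to missing and never pass an individual filter. By default analysis is
#' restricted to autosomes (chromosome labels `1..22` / `chr1..chr22`).
#'
#' Site-level filter statistics, when present, are read from the INFO keys
#' `SRF`, `SRR`, `SAF`, `SAR` (reference/alternative forward/reverse strand
#' read counts summed over the cohort) and `RPR`, `RPA` (comma-separated
#' within-read positions of reference/alternative observations).
#'
#' @param vcf_path Multi-sample VCF 4.x with GT, GQ, DP and AD FORMAT fields
#'   for every pedigree sample. Must be coordinate-sorted.
#' @param ped_path PED file, see [read_ped()].
#' @param ages_path Optional paternal-ages TSV, see [read_ages()].
#' @param known_sites_path Optional known-variants list, see
#'   [read_known_sites()].
#' @param regions `NULL` (default) restricts to autosomes; `"all"` keeps every
#'   chromosome; or a data.frame with a `chrom` column naming chromosomes to
#'   keep.
#' @return A `trio_cohort` object.
#' @export
read_cohort <- function(vcf_path, ped_path, ages_path = NULL,
                        known_sites_path = NULL, regions = NULL) {
  ped <- read_ped(ped_path)
  if (!is.null(ages_path)) ped <- read_ages(ped, ages_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  samples <- as.character(t(as.matrix(ped[, c("child_id", "father_id", "mother_id")])))
  absent <- setdiff(samples, vcf_samples)
  if (length(absent))
    stop("pedigree samples absent from VCF header: ", paste(absent, collapse = ", "))

  fx <- v@fix
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  chrom <- fx[, "CHROM"]; pos <- as.integer(fx[, "POS"])
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]

  # sorted within contiguous chromosome runs, no interleaved chromosome blocks
  r <- rle(chrom)
  if (anyDuplicated(r$values)) stop("unsorted VCF: chromosome blocks interleaved")
  for (ch in r$values) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("unsorted VCF: positions out of order on ", ch)
  }

  skip <- character(0)
  ok_allele <- function(x) !is.na(x) & grepl("^[ACGTacgt]+$", x)
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  bad <- !ok_allele(ref) | (!ok_allele(alt) & !multi) | (!is.na(ref) & !is.na(alt) & ref == alt)
  keep <- !multi & !bad
  n_multi <- sum(multi); n_bad <- sum(bad & !multi)

  if (is.null(regions)) {
    off_region <- !.is_autosome(chrom)
  } else if (identical(regions, "all")) {
    off_region <- rep(FALSE, length(chrom))
  } else {
    off_region <- !(chrom %in% regions$chrom)
  }
  n_off <- sum(off_region & keep)
  keep <- keep & !off_region

  get_fmt <- function(el, fun = identity) {
    m <- vcfR::extract.gt(v, element = el)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
    m[, samples, drop = FALSE]
  }
  gt_raw <- get_fmt("GT")
  gq_raw <- suppressWarnings(apply(get_fmt("GQ"), 2, as.numeric))
  dp_raw <- suppressWarnings(apply(get_fmt("DP"), 2, as.numeric))
  ad_raw <- get_fmt("AD")
  if (is.null(dim(gq_raw))) gq_raw <- matrix(gq_raw, nrow = nrow(gt_raw))
  if (is.null(dim(dp_raw))) dp_raw <- matrix(dp_raw, nrow = nrow(gt_raw))
  split_ad <- function(k) {
    out <- suppressWarnings(
      vapply(strsplit(ifelse(is.na(ad_raw), "NA,NA", ad_raw), ",", fixed = TRUE),
             function(x) as.numeric(x[k]), numeric(1)))
    matrix(out, nrow = nrow(ad_raw))
  }
  ad_ref <- split_ad(1); ad_alt <- split_ad(2)

  gt <- matrix(.GT_CODE[gt_raw], nrow = nrow(gt_raw))
  miss <- is.na(gt) | is.na(gq_raw) | is.na(dp_raw) | is.na(ad_ref) | is.na(ad_alt)
  gt[miss] <- NA_integer_

  info_num <- function(key) suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
  info_chr <- function(key) {
    x <- vcfR::extract.info(v, key)
    if (is.null(x)) rep(NA_character_, length(chrom)) else as.character(x)
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  sites$variant_type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "indel")
  sites$indel_len <- abs(nchar(alt) - nchar(ref))
  sites$known <- FALSE
  sites$srf <- info_num("SRF"); sites$srr <- info_num("SRR")
  sites$saf <- info_num("SAF"); sites$sar <- info_num("SAR")
  sites$rp_ref <- info_chr("RPR"); sites$rp_alt <- info_chr("RPA")

  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  subm <- function(m) {
    m <- m[keep, , drop = FALSE]
    dimnames(m) <- list(NULL, samples)
    m
  }
  gt <- subm(gt); gq <- subm(gq_raw); dp <- subm(dp_raw)
  ad_ref <- subm(ad_ref); ad_alt <- subm(ad_alt)

  if (!is.null(known_sites_path)) {
    ks <- read_known_sites(known_sites_path)
    sites$known <- .site_key(sites$chrom, sites$pos, sites$ref, sites$alt) %in%
      .site_key(ks$chrom, ks$pos, ks$ref, ks$alt)
  }

  reasons <- c(multi_allelic = n_multi, malformed_allele = n_bad,
               off_region = n_off)
  reasons <- reasons[reasons > 0]
  new_trio_cohort(ped, samples, sites, gt, gq, dp, ad_ref, ad_alt,
                  n_skipped = n_multi + n_bad + n_off, skip_reasons = reasons)
}

#' Write a cohort back to VCF
#'
#' Emits a multi-sample VCF 4.2 with GT:GQ:DP:AD FORMAT fields and the
#' site-statistic INFO keys understood by [read_cohort()]. The file is
#' bgzip/gzip-compressed (give the path a `.vcf.gz` suffix).
#'
#' @param cohort A `trio_cohort`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  s <- cohort$sites
  info <- character(nrow(s))
  stat_ok <- !is.na(s$srf)
  info[stat_ok] <- sprintf("SRF=%g;SRR=%g;SAF=%g;SAR=%g",
                           s$srf[stat_ok], s$srr[stat_ok],
                           s$saf[stat_ok], s$sar[stat_ok])
  rp_ok <- !is.na(s$rp_ref)
  info[rp_ok] <- paste0(info[rp_ok],
                        ifelse(nzchar(info[rp_ok]), ";", ""),
                        "RPR=", s$rp_ref[rp_ok], ";RPA=", s$rp_alt[rp_ok])
  info[!nzchar(info)] <- "."
  fix <- cbind(CHROM = s$chrom, POS = as.character(s$pos), ID = ".",
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt_str <- c("0/0", "0/1", "1/1")[cohort$gt + 1L]
  cell <- sprintf("%s:%d:%d:%d,%d", gt_str,
                  as.integer(cohort$gq), as.integer(cohort$dp),
                  as.integer(cohort$ad_ref), as.integer(cohort$ad_alt))
  cell[is.na(cohort$gt)] <- "./.:.:.:.,."
  gt_mat <- cbind(FORMAT = rep("GT:GQ:DP:AD", nrow(s)),
                  matrix(cell, nrow = nrow(s),
                         dimnames = list(NULL, cohort$samples)))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Ref forward-strand reads, cohort\">",
            "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Ref reverse-strand reads, cohort\">",
            "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt forward-strand reads, cohort\">",
            "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reverse-strand reads, cohort\">",
            "##INFO=<ID=RPR,Number=.,Type=Integer,Description=\"Within-read positions, ref reads\">",
            "##INFO=<ID=RPA,Number=.,Type=Integer,Description=\"Within-read positions, alt reads\">")
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt_mat)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Read a BED-like per-sample depth track
#'
#' Four tab-separated columns, no header: chrom, start, end, depth.
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param path Path to the track.
#' @return A data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_depth_track <- function(path) {
  tr <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "depth"))
  tr$start <- as.numeric(tr$start); tr$end <- as.numeric(tr$end)
  tr$depth <- as.integer(tr$depth)
  tr
}

.clip_track <- function(track, ch, a, b) {
  iv <- track[track$chrom == ch & track$end > a & track$start < b, , drop = FALSE]
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop("overlapping intervals in depth track on ", ch)
  iv$start <- pmax(iv$start, a); iv$end <- pmin(iv$end, b)
  iv
}

#' Joint depth histogram of a trio over analysis regions
#'
#' Tallies, per family, the number of genomic positions at each observed
#' (child, father, mother) depth triple. Implemented as a breakpoint sweep
#' over the piecewise-constant depth tracks, so it is exact and never expands
#' per-position vectors. Positions not covered by a sample's track count as
#' depth 0 for that sample.
#'
#' @param tracks Named list of depth tracks (see [read_depth_track()]), named
#'   by sample id. A missing sample contributes depth 0 everywhere.
#' @param family One pedigree row (with `child_id`, `father_id`, `mother_id`).
#' @param regions data.frame of analysis regions: `chrom`, `start`, `end`,
#'   0-based half-open.
#' @return A `depth_histogram`: data.frame with columns `d_child`, `d_father`,
#'   `d_mother`, `count`, with attributes `total_positions` and `family_id`.
#' @export
build_depth_histogram <- function(tracks, family, regions) {
  ids <- c(family$child_id, family$father_id, family$mother_id)
  empty_track <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), depth = integer(0))
  trio_tracks <- lapply(ids, function(id)
    if (id %in% names(tracks)) tracks[[id]] else empty_track)
  pieces <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]; a <- regions$start[r]; b <- regions$end[r]
    if (b <= a) next
    ivs <- lapply(trio_tracks, .clip_track, ch = ch, a = a, b = b)
    bp <- sort(unique(c(a, b, unlist(lapply(ivs, function(x) c(x$start, x$end))))))
    st <- bp[-length(bp)]; len <- diff(bp)
    dep <- vapply(ivs, function(iv) {
      if (!nrow(iv)) return(rep(0L, length(st)))
      idx <- findInterval(st, iv$start)
      d <- ifelse(idx > 0 & st < iv$end[pmax(idx, 1)], iv$depth[pmax(idx, 1)], 0L)
      as.integer(d)
    }, integer(length(st)))
    if (is.null(dim(dep))) dep <- matrix(dep, nrow = length(st))
    pieces[[r]] <- data.table(d_child = dep[, 1], d_father = dep[, 2],
                              d_mother = dep[, 3], count = len)
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces)) {
    dt <- data.table::rbindlist(pieces)
    agg <- dt[, list(count = sum(count)),
              by = c("d_child", "d_father", "d_mother")]
    setorder(agg, d_child, d_father, d_mother)
    out <- as.data.frame(agg)
  } else {
    out <- data.frame(d_child = integer(0), d_father = integer(0),
                      d_mother = integer(0), count = numeric(0))
  }
  total <- if (nrow(regions)) sum(pmax(regions$end - regions$start, 0)) else 0
  stopifnot(isTRUE(all.equal(sum(out$count), total)))
  structure(out, total_positions = total, family_id = family$family_id,
            class = c("depth_histogram", "data.frame"))
}

#' Read a precomputed joint depth histogram
#'
#' Tab-separated with header columns `d_child`, `d_father`, `d_mother`,
#' `count` (and optionally `family_id` when several families share a file).
#'
#' @param path Path to the histogram TSV.
#' @param family_id Restrict to one family when the file has a `family_id`
#'   column.
#' @return A `depth_histogram`.
#' @export
read_depth_histogram <- function(path, family_id = NULL) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(family_id) && "family_id" %in% names(h))
    h <- h[h$family_id == family_id, , drop = FALSE]
  if (!all(c("d_child", "d_father", "d_mother", "count") %in% names(h)))
    stop("histogram needs columns d_child, d_father, d_mother, count")
  out <- h[, c("d_child", "d_father", "d_mother", "count")]
  rownames(out) <- NULL
  structure(out, total_positions = sum(out$count), family_id = family_id,
            class = c("depth_histogram", "data.frame"))
}
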