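#' Configuration for the synthetic trio-cohort simulator
#'
#' Defines the generative model for a cohort of father-mother-child trios on
#' a single synthetic autosome: piecewise-constant per-sample depth tracks,
#' background polymorphisms transmitted Mendelian-correctly (these populate
#' the callability calibration classes), seeded germline and somatic de novo
#' SNVs/indels with a linear paternal-age effect on the germline SNV rate, a
#' bimodal allele-balance model (germline component centred at 0.5, somatic
#' component centred near 0.18), depth-dependent call success, and a
#' site-filter false-rejection probability emulated directly.
#'
#' `mu` is the germline SNV rate at the reference paternal age `age_ref`;
#' family f mutates at `mu + age_slope * (age_f - age_ref)`. Genotype quality
#' is synthesised deterministically as
#' `GQ = min(99, round(5 * DP * (1 - 2 * |AB - E[AB]|)))`, so GQ thresholds
#' are exercised and callability genuinely depends on depth.
#'
#' @param n_families Number of trios.
#' @param genome_length Haploid length L of the simulated autosome (bp).
#' @param mu Germline SNV rate per nucleotide per generation at `age_ref`.
#' @param mu_indel Germline short-indel rate (age-independent).
#' @param somatic_ratio Somatic:germline seeding ratio for both types.
#' @param age_range,age_ref,age_slope Paternal ages are uniform on
#'   `age_range`; `age_slope` is extra mutations per nucleotide per year.
#' @param depth_mean,depth_size Negative-binomial depth per track segment.
#' @param depth_segment_length Mean length of constant-depth segments (bp).
#' @param het_success,hom_success Optional functions of depth giving the
#'   probability that a true Het / true homozygote is called at all
#'   (`NULL` means 1; filter-driven losses still apply on top).
#' @param miscall_to_missing Fraction of call failures emitted as missing
#'   genotypes; the rest are miscalls (Het failures become HomRef and vice
#'   versa).
#' @param germline_ab_shape,somatic_ab_shape Beta shape pairs for the true
#'   allele balance of germline and somatic de novo events.
#' @param calib_density Background polymorphic sites per bp.
#' @param indel_site_frac Fraction of background sites that are indels.
#' @param maf_range Uniform allele-frequency range of background sites.
#' @param known_prob,dnm_known_prob Probability a background / de novo site
#'   is in the known-variants list.
#' @param ad_error_rate Per-read probability that a homozygote shows a stray
#'   allele read (exercises the AD2 = 0 filter).
#' @param alpha_site Probability that a good site is emitted with statistics
#'   the site filter rejects; defaults to the loss implied by the default
#'   [filter_config()] alphas, `1 - 0.99^2`.
#' @param seed Mandatory RNG seed; the full output stream is a deterministic
#'   function of the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 10, genome_length = 1e7,
                       mu = 1e-7, mu_indel = mu / 8, somatic_ratio = 0.44,
                       age_range = c(22, 35), age_ref = 28.5,
                       age_slope = 3.88e-10,
                       depth_mean = 52, depth_size = 10,
                       depth_segment_length = 1000,
                       het_success = NULL, hom_success = NULL,
                       miscall_to_missing = 0.5,
                       germline_ab_shape = c(50, 50),
                       somatic_ab_shape = c(7.2, 32.8),
                       calib_density = 1e-3, indel_site_frac = 0.1,
                       maf_range = c(0.05, 0.95),
                       known_prob = 0.9, dnm_known_prob = 0.035,
                       ad_error_rate = 0.001,
                       alpha_site = 1 - (1 - 0.01)^2,
                       seed = 1) {
  stopifnot(n_families >= 1, genome_length >= 1, mu >= 0, mu_indel >= 0,
            somatic_ratio >= 0, length(age_range) == 2,
            age_range[1] <= age_range[2],
            depth_mean > 0, depth_size > 0, depth_segment_length >= 1,
            miscall_to_missing >= 0, miscall_to_missing <= 1,
            length(germline_ab_shape) == 2, all(germline_ab_shape > 0),
            length(somatic_ab_shape) == 2, all(somatic_ab_shape > 0),
            calib_density >= 0, indel_site_frac >= 0, indel_site_frac <= 1,
            known_prob >= 0, known_prob <= 1,
            ad_error_rate >= 0, ad_error_rate < 1,
            alpha_site >= 0, alpha_site < 1, length(seed) == 1)
  structure(as.list(environment()), class = "sim_config")
}

.sim_track <- function(L, seg_mean, depth_mean, depth_size) {
  n_guess <- ceiling(1.3 * L / seg_mean) + 10
  repeat {
    lens <- stats::rgeom(n_guess, 1 / seg_mean) + 1
    if (sum(lens) >= L) break
    n_guess <- n_guess * 2
  }
  ends <- cumsum(lens)
  k <- which(ends >= L)[1]
  ends <- pmin(ends[seq_len(k)], L)
  starts <- c(0, ends[-k])
  data.frame(chrom = "1", start = starts, end = ends,
             depth = stats::rnbinom(k, size = depth_size, mu = depth_mean),
             stringsAsFactors = FALSE)
}

.depth_at <- function(track, pos) {
  track$depth[findInterval(pos - 1, track$start)]
}

.rand_alleles <- function(n, is_indel) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  if (any(is_indel)) {
    for (i in which(is_indel)) {
      u <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) {         # deletion
        ref[i] <- paste0(ref[i], u); alt[i] <- substr(ref[i], 1, 1)
      } else {                             # insertion
        alt[i] <- paste0(ref[i], u)
      }
    }
  }
  list(ref = ref, alt = unname(alt))
}

.PASS_STATS <- list(srf = 50, srr = 50, saf = 25, sar = 25,
                    rp = "25,45,65,85")
.FAIL_STATS <- list(srf = 50, srr = 50, saf = 40, sar = 0,
                    rp = "25,45,65,85")

#' Simulate a trio cohort with known truth
#'
#' Generates a full synthetic cohort under a [sim_config()]: depth tracks,
#' background polymorphisms, seeded de novo mutations with truth labels, and
#' the VCF-level observations (GT, GQ, DP, AD plus site-filter statistics)
#' the calling pipeline consumes. With `out_dir` set, the exact file formats
#' read by [read_cohort()] and [build_depth_histogram()] are written
#' (`cohort.vcf.gz`, `trios.ped`, `ages.tsv`, `known_sites.tsv`,
#' `truth.tsv`, `<sample>.depth.bed`).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `trio_sim`: `cohort` (a `trio_cohort`), `truth`
#'   (data.frame of seeded de novo events: family_id, chrom, pos, ref, alt,
#'   variant_type, origin germline/somatic, true_ab, site_fail, child/father/
#'   mother depths), `tracks` (named list of depth tracks), `known_sites`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  L <- cf$genome_length
  nf <- cf$n_families
  fam_id <- sprintf("F%02d", seq_len(nf))
  ped <- data.frame(family_id = fam_id,
                    child_id = paste0(fam_id, "-C"),
                    father_id = paste0(fam_id, "-F"),
                    mother_id = paste0(fam_id, "-M"),
                    father_age = stats::runif(nf, cf$age_range[1], cf$age_range[2]),
                    stringsAsFactors = FALSE)
  samples <- as.character(t(as.matrix(ped[, c("child_id", "father_id", "mother_id")])))
  ns <- length(samples)
  mu_f <- pmax(0, cf$mu + cf$age_slope * (ped$father_age - cf$age_ref))

  tracks <- lapply(samples, function(s)
    .sim_track(L, cf$depth_segment_length, cf$depth_mean, cf$depth_size))
  names(tracks) <- samples

  # --- background polymorphic sites (calibration classes) ------------------
  n_bg <- round(L * cf$calib_density)
  pos_bg <- sort(sample.int(L, n_bg))
  is_indel_bg <- stats::runif(n_bg) < cf$indel_site_frac
  al_bg <- .rand_alleles(n_bg, is_indel_bg)
  f_bg <- stats::runif(n_bg, cf$maf_range[1], cf$maf_range[2])
  transmit <- function(g) ifelse(g == 2L, 1L,
                          ifelse(g == 0L, 0L,
                                 stats::rbinom(length(g), 1, 0.5)))
  g_bg <- matrix(0L, n_bg, ns, dimnames = list(NULL, samples))
  for (k in seq_len(nf)) {
    fa <- stats::rbinom(n_bg, 2, f_bg)
    mo <- stats::rbinom(n_bg, 2, f_bg)
    ch <- transmit(fa) + transmit(mo)
    g_bg[, ped$child_id[k]] <- ch
    g_bg[, ped$father_id[k]] <- fa
    g_bg[, ped$mother_id[k]] <- mo
  }

  # --- seeded de novo mutations -------------------------------------------
  dnm <- list()
  used <- pos_bg
  draw_pos <- function(n) {
    if (n == 0) return(integer(0))
    p <- integer(0)
    while (length(p) < n) {
      cand <- sample.int(L, n - length(p) + 5)
      cand <- setdiff(cand, c(used, p))
      p <- c(p, cand[seq_len(min(length(cand), n - length(p)))])
    }
    p
  }
  for (k in seq_len(nf)) {
    counts <- c(g_snv = stats::rpois(1, 2 * L * mu_f[k]),
                g_ind = stats::rpois(1, 2 * L * cf$mu_indel),
                s_snv = stats::rpois(1, 2 * L * cf$mu * cf$somatic_ratio),
                s_ind = stats::rpois(1, 2 * L * cf$mu_indel * cf$somatic_ratio))
    n_tot <- sum(counts)
    if (!n_tot) next
    p <- draw_pos(n_tot)
    used <- c(used, p)
    origin <- rep(c("germline", "germline", "somatic", "somatic"), counts)
    indel <- rep(c(FALSE, TRUE, FALSE, TRUE), counts)
    ab <- ifelse(origin == "germline",
                 stats::rbeta(n_tot, cf$germline_ab_shape[1], cf$germline_ab_shape[2]),
                 stats::rbeta(n_tot, cf$somatic_ab_shape[1], cf$somatic_ab_shape[2]))
    al <- .rand_alleles(n_tot, indel)
    dnm[[k]] <- data.frame(family_id = fam_id[k], pos = p,
                           ref = al$ref, alt = al$alt,
                           variant_type = ifelse(indel, "indel", "SNV"),
                           origin = origin, true_ab = ab,
                           stringsAsFactors = FALSE)
  }
  dnm <- if (length(dnm)) do.call(rbind, dnm) else
    data.frame(family_id = character(0), pos = integer(0), ref = character(0),
               alt = character(0), variant_type = character(0),
               origin = character(0), true_ab = numeric(0),
               stringsAsFactors = FALSE)
  n_dnm <- nrow(dnm)

  # --- combined site table -------------------------------------------------
  n_sites <- n_bg + n_dnm
  site_pos <- c(pos_bg, dnm$pos)
  site_ref <- c(al_bg$ref, dnm$ref)
  site_alt <- c(al_bg$alt, dnm$alt)
  site_known <- c(stats::runif(n_bg) < cf$known_prob,
                  stats::runif(n_dnm) < cf$dnm_known_prob)
  g_true <- rbind(g_bg, matrix(0L, n_dnm, ns, dimnames = list(NULL, samples)))
  ab_true <- matrix(NA_real_, n_sites, ns)
  ab_true[g_true == 1L] <- 0.5
  if (n_dnm) {
    for (i in seq_len(n_dnm)) {
      ci <- ped$child_id[match(dnm$family_id[i], fam_id)]
      g_true[n_bg + i, ci] <- 1L
      ab_true[n_bg + i, match(ci, samples)] <- dnm$true_ab[i]
    }
  }
  ord <- order(site_pos)
  site_pos <- site_pos[ord]; site_ref <- site_ref[ord]; site_alt <- site_alt[ord]
  site_known <- site_known[ord]
  g_true <- g_true[ord, , drop = FALSE]
  ab_true <- ab_true[ord, , drop = FALSE]
  dnm_row <- match(n_bg + seq_len(n_dnm), ord)

  site_fail <- stats::runif(n_sites) < cf$alpha_site
  st <- function(field) ifelse(site_fail, .FAIL_STATS[[field]], .PASS_STATS[[field]])

  # --- observation model ---------------------------------------------------
  d <- vapply(samples, function(s) .depth_at(tracks[[s]], site_pos),
              numeric(n_sites))
  if (is.null(dim(d))) d <- matrix(d, nrow = n_sites)
  colnames(d) <- samples
  p_keep <- matrix(1, n_sites, ns)
  if (!is.null(cf$het_success)) {
    i <- which(g_true == 1L); p_keep[i] <- cf$het_success(d[i])
  }
  if (!is.null(cf$hom_success)) {
    i <- which(g_true != 1L); p_keep[i] <- cf$hom_success(d[i])
  }
  keep <- matrix(stats::runif(n_sites * ns) < p_keep, n_sites, ns)
  to_missing <- matrix(stats::runif(n_sites * ns) < cf$miscall_to_missing,
                       n_sites, ns)
  obs_gt <- g_true
  obs_gt[!keep & !to_missing & g_true == 1L] <- 0L       # het miscalled hom-ref
  obs_gt[!keep & !to_missing & g_true != 1L] <- 1L       # hom miscalled het
  obs_gt[!keep & to_missing] <- NA_integer_
  obs_gt[d == 0] <- NA_integer_

  ad_alt <- matrix(NA_real_, n_sites, ns)
  i <- which(obs_gt == 1L & g_true == 1L)
  ad_alt[i] <- stats::rbinom(length(i), d[i], ab_true[i])
  i <- which(obs_gt == 1L & g_true != 1L)
  ad_alt[i] <- stats::rbinom(length(i), d[i], 0.25)
  i <- which(obs_gt == 0L)
  ad_alt[i] <- stats::rbinom(length(i), d[i], cf$ad_error_rate)
  i <- which(obs_gt == 2L)
  ad_alt[i] <- d[i] - stats::rbinom(length(i), d[i], cf$ad_error_rate)
  ad_ref <- d - ad_alt

  e_ab <- matrix(NA_real_, n_sites, ns)
  e_ab[obs_gt == 0L] <- 0; e_ab[obs_gt == 1L] <- 0.5; e_ab[obs_gt == 2L] <- 1
  ab_obs <- ad_alt / pmax(d, 1)
  margin <- pmax(0, 1 - 2 * abs(ab_obs - e_ab))
  gq <- pmin(round(5 * d * margin + 1e-9), 99)
  na_cells <- is.na(obs_gt)
  gq[na_cells] <- NA; ad_ref[na_cells] <- NA; ad_alt[na_cells] <- NA
  dp <- d; dp[na_cells] <- NA

  sites <- data.frame(chrom = "1", pos = site_pos, ref = site_ref,
                      alt = site_alt,
                      variant_type = ifelse(nchar(site_ref) == 1 &
                                              nchar(site_alt) == 1, "SNV", "indel"),
                      indel_len = abs(nchar(site_alt) - nchar(site_ref)),
                      known = site_known,
                      srf = st("srf"), srr = st("srr"),
                      saf = st("saf"), sar = st("sar"),
                      rp_ref = st("rp"), rp_alt = st("rp"),
                      stringsAsFactors = FALSE)
  cohort <- new_trio_cohort(ped, samples, sites,
                            gt = obs_gt, gq = gq, dp = dp,
                            ad_ref = ad_ref, ad_alt = ad_alt)

  truth <- if (n_dnm) {
    fam_idx <- match(dnm$family_id, fam_id)
    data.frame(family_id = dnm$family_id, chrom = "1", pos = dnm$pos,
               ref = dnm$ref, alt = dnm$alt, variant_type = dnm$variant_type,
               origin = dnm$origin, true_ab = dnm$true_ab,
               site_fail = site_fail[dnm_row],
               d_child = d[cbind(dnm_row, match(ped$child_id[fam_idx], samples))],
               d_father = d[cbind(dnm_row, match(ped$father_id[fam_idx], samples))],
               d_mother = d[cbind(dnm_row, match(ped$mother_id[fam_idx], samples))],
               stringsAsFactors = FALSE)
  } else {
    data.frame(family_id = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               variant_type = character(0), origin = character(0),
               true_ab = numeric(0), site_fail = logical(0),
               d_child = numeric(0), d_father = numeric(0),
               d_mother = numeric(0), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  known_sites <- sites[sites$known, c("chrom", "pos", "ref", "alt")]
  rownames(known_sites) <- NULL

  out <- structure(list(cohort = cohort, truth = truth, tracks = tracks,
                        known_sites = known_sites, config = cf),
                   class = "trio_sim")
  if (!is.null(out_dir)) write_sim(out, out_dir)
  out
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf("simulated trio cohort (seed %s): %d families, L = %g bp\n",
              format(x$config$seed), nrow(x$cohort$pedigrees),
              x$config$genome_length))
  cat(sprintf("  %d sites (%d seeded de novo: %d germline, %d somatic)\n",
              nrow(x$cohort$sites), nrow(x$truth),
              sum(x$truth$origin == "germline"),
              sum(x$truth$origin == "somatic")))
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param sim A `trio_sim`.
#' @param out_dir Output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$cohort$pedigrees
  paths <- c(vcf = file.path(out_dir, "cohort.vcf.gz"),
             ped = file.path(out_dir, "trios.ped"),
             ages = file.path(out_dir, "ages.tsv"),
             known = file.path(out_dir, "known_sites.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_cohort_vcf(sim$cohort, paths["vcf"])
  ped_rows <- rbind(
    data.frame(fam = ped$family_id, id = ped$child_id, fa = ped$father_id,
               mo = ped$mother_id, sex = 0, ph = -9),
    data.frame(fam = ped$family_id, id = ped$father_id, fa = 0, mo = 0,
               sex = 1, ph = -9),
    data.frame(fam = ped$family_id, id = ped$mother_id, fa = 0, mo = 0,
               sex = 2, ph = -9))
  utils::write.table(ped_rows, paths["ped"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(family_id = ped$family_id,
                                father_age = ped$father_age),
                     paths["ages"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$known_sites, paths["known"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in names(sim$tracks)) {
    p <- file.path(out_dir, paste0(s, ".depth.bed"))
    utils::write.table(sim$tracks[[s]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[paste0("track_", s)] <- p
  }
  invisible(paths)
}

#' Joint depth histograms for every simulated family
#'
#' Runs [build_depth_histogram()] over the simulator's depth tracks for each
#' family, covering the whole simulated autosome.
#'
#' @param sim A `trio_sim`.
#' @return Named list of `depth_histogram`s, keyed by family id.
#' @export
sim_depth_histograms <- function(sim) {
  regions <- data.frame(chrom = "1", start = 0,
                        end = sim$config$genome_length)
  ped <- sim$cohort$pedigrees
  out <- lapply(seq_len(nrow(ped)), function(k)
    build_depth_histogram(sim$tracks, ped[k, ], regions))
  names(out) <- ped$family_id
  out
}

#' Degrade a cohort's genotype calls with depth-dependent failures
#'
#' Treats the cohort's current calls as truth and retains each heterozygous
#' call with probability `het_success(depth)` and each homozygous call with
#' `hom_success(depth)`; failures become missing genotypes with probability
#' `miscall_to_missing` and miscalls otherwise (Het failures are written as
#' HomRef with zero alternative reads, homozygote failures as Het with an
#' allele balance around 0.25). GQ is re-synthesised for changed cells with
#' the simulator's GQ model.
#'
#' @param cohort A `trio_cohort`.
#' @param het_success,hom_success Functions of depth returning retention
#'   probabilities (`NULL` = 1).
#' @param miscall_to_missing Fraction of failures emitted as missing.
#' @param seed Optional seed for reproducibility.
#' @return The degraded `trio_cohort`.
#' @export
inject_genotype_errors <- function(cohort, het_success = NULL,
                                   hom_success = NULL,
                                   miscall_to_missing = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- cohort$gt
  d <- cohort$dp
  n <- length(gt)
  p_keep <- matrix(1, nrow(gt), ncol(gt))
  if (!is.null(het_success)) {
    i <- which(gt == 1L); p_keep[i] <- het_success(d[i])
  }
  if (!is.null(hom_success)) {
    i <- which(gt != 1L & !is.na(gt)); p_keep[i] <- hom_success(d[i])
  }
  fail <- !is.na(gt) & matrix(stats::runif(n) >= p_keep, nrow(gt))
  to_missing <- matrix(stats::runif(n) < miscall_to_missing, nrow(gt))

  i <- which(fail & !to_missing & gt == 1L)            # het -> hom-ref
  cohort$gt[i] <- 0L
  cohort$ad_alt[i] <- 0; cohort$ad_ref[i] <- d[i]
  cohort$gq[i] <- pmin(99, round(5 * d[i] + 1e-9))
  i <- which(fail & !to_missing & gt != 1L)            # hom -> het
  cohort$gt[i] <- 1L
  cohort$ad_alt[i] <- stats::rbinom(length(i), pmax(d[i], 0), 0.25)
  cohort$ad_ref[i] <- d[i] - cohort$ad_alt[i]
  cohort$gq[i] <- pmin(99, round(5 * d[i] *
    pmax(0, 1 - 2 * abs(cohort$ad_alt[i] / pmax(d[i], 1) - 0.5)) + 1e-9))
  i <- which(fail & to_missing)
  cohort$gt[i] <- NA_integer_
  cohort$gq[i] <- NA; cohort$dp[i] <- NA
  cohort$ad_ref[i] <- NA; cohort$ad_alt[i] <- NA
  cohort
}
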