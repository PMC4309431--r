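# A cohort tailored for het calibration: one informative family where the
# father is HomAlt, the mother HomRef, so the child must be Het.
het_calib_cohort <- function(child_gt, child_gq, child_dp) {
  n <- length(child_gt)
  gt <- cbind(child_gt, rep(2L, n), rep(0L, n),    # F01: informative
              rep(0L, n), rep(0L, n), rep(0L, n))  # F02: background
  dp <- matrix(30, n, 6); dp[, 1] <- child_dp
  gq <- matrix(99, n, 6); gq[, 1] <- child_gq
  ad_alt <- matrix(0, n, 6)
  ad_alt[, 2] <- 30
  ad_alt[, 1] <- ifelse(child_gt == 1L, round(child_dp / 2), 0)
  clean <- clean_cohort(gt)
  clean$dp <- `dimnames<-`(dp, dimnames(clean$dp))
  clean$gq <- `dimnames<-`(gq, dimnames(clean$gq))
  clean$ad_alt <- `dimnames<-`(ad_alt, dimnames(clean$ad_alt))
  clean$ad_ref <- clean$dp - clean$ad_alt
  clean
}

test_that("het callability is the fraction of qualifying children called Het", {
  cfg <- filter_config(min_trials = 1)
  co <- het_calib_cohort(rep(1L, 4), rep(99, 4), rep(30, 4))
  tab <- calibrate_het_callability(co, cfg)
  expect_equal(tab$trials[tab$depth == 30], 4)
  expect_equal(callability_at(tab, 30), 1.0)
  # 2 of 4 fail (one miscalled, one low GQ)
  co2 <- het_calib_cohort(c(1L, 1L, 0L, 1L), c(99, 99, 99, 40), rep(30, 4))
  tab2 <- calibrate_het_callability(co2, cfg)
  expect_equal(callability_at(tab2, 30), 0.5)
  expect_error(calibrate_het_callability(clean_cohort(matrix(0L, 2, 6)), cfg),
               "no qualifying")
})

test_that("homref calibration requires carrier families and known SNV sites", {
  cfg <- filter_config(min_trials = 1)
  # both parents of F01 HomRef, F02 child is a carrier
  gt <- rbind(c(0L, 0L, 0L, 1L, 1L, 0L),
              c(0L, 0L, 0L, 1L, 1L, 0L),
              c(0L, 0L, 0L, 0L, 0L, 0L))   # no carrier: must not qualify
  co <- clean_cohort(gt)
  co$sites$known <- c(TRUE, FALSE, TRUE)
  tab <- calibrate_homref_callability(co, cfg)
  expect_equal(sum(tab$trials), 1)          # only site 1 qualifies for F01
  expect_equal(callability_at(tab, 30), 1.0)
  # one stray alt read in the child breaks AD2=0 and lowers the estimate
  co2 <- co
  co2$ad_alt[1, "F01-C"] <- 1
  co2$sites$known <- TRUE
  tab2 <- calibrate_homref_callability(co2,  cfg)
  expect_equal(sum(tab2$trials), 2)
  expect_equal(callability_at(tab2, 30), 0.5)   # lowered by exactly 1/trials
  # indel calibration imposes no known-sites requirement: both carrier
  # sites now qualify even though neither is known
  co3 <- co
  co3$sites$known <- FALSE
  co3$sites$variant_type <- "indel"
  expect_equal(sum(calibrate_homref_callability(co3, cfg, "indel")$trials), 2)
})

test_that("sparse depth bins pool outward until the trial minimum is met", {
  pool <- dnmrate:::.pool_counts
  succ <- c(5, 100, 20, 10, 180)
  tri <- c(10, 200, 50, 30, 200)
  est <- pool(succ, tri, min_trials = 100)
  # bin 1 (10 trials) pools right into bin 2; bin 3 ties break toward lower
  # depth; bin 4 pools both neighbours
  expect_equal(est[1], (5 + 100) / (10 + 200))
  expect_equal(est[2], 100 / 200)
  expect_equal(est[3], (100 + 20) / (200 + 50))
  expect_equal(est[4], (20 + 10 + 180) / (50 + 30 + 200))
  expect_equal(est[5], 180 / 200)
  # independent oracle: replay the outward-expansion rule on random counts
  set.seed(19)
  for (rep in 1:20) {
    tri <- rpois(12, 40); succ <- rbinom(12, tri, 0.8)
    est <- pool(succ, tri, min_trials = 60)
    for (i in seq_along(tri)) {
      members <- i
      while (sum(tri[members]) < 60 && length(members) < length(tri)) {
        lo <- min(members); hi <- max(members)
        grow_left <- lo > 1 && (hi >= length(tri) || (i - (lo - 1)) <= ((hi + 1) - i))
        members <- if (grow_left) c(lo - 1, members) else c(members, hi + 1)
      }
      expect_equal(est[i], sum(succ[members]) / sum(tri[members]))
    }
  }
})

test_that("family site callability is the product of the member probabilities", {
  expect_equal(family_site_callability(0.9, 0.8, 0.7), 0.504)
  expect_equal(family_site_callability(0.9, 0, 0.7), 0)
  expect_equal(family_site_callability(1, 1, 1), 1)
  expect_error(family_site_callability(1.2, 1, 1), "probabilities")
})

make_flat_table <- function(p, dmax = 150, role = "het_child") {
  tri <- rep(1000, dmax + 1)
  dnmrate:::new_callability_table(0:dmax, round(p * tri), tri, role,
                                  min_trials = 1)
}

test_that("expected callable sites sums callability over the depth histogram", {
  het <- make_flat_table(0.9)
  hom <- make_flat_table(0.8, role = "homref_parent")
  fam <- toy_pedigree(1)[1, ]
  tr <- data.frame(chrom = "1", start = 0, end = 1000, depth = 40)
  tracks <- list(`F01-C` = tr, `F01-F` = tr, `F01-M` = tr)
  h <- build_depth_histogram(tracks, fam,
                             data.frame(chrom = "1", start = 0, end = 1000))
  expect_equal(expected_callable_sites(h, het, hom), 1000 * 0.9 * 0.8 * 0.8)
  empty <- build_depth_histogram(tracks, fam,
                                 data.frame(chrom = character(0),
                                            start = numeric(0), end = numeric(0)))
  expect_equal(expected_callable_sites(empty, het, hom), 0)
})

test_that("histogram-form callable sites equals the per-position brute force", {
  set.seed(77)
  # depth-varying tables so the test is sensitive to depth mix-ups
  dmax <- 60
  tri <- rep(500, dmax + 1)
  het <- dnmrate:::new_callability_table(0:dmax, rbinom(dmax + 1, 500, seq(0.2, 0.95, length.out = dmax + 1)),
                                         tri, "het_child", 1)
  hom <- dnmrate:::new_callability_table(0:dmax, rbinom(dmax + 1, 500, 0.9), tri,
                                         "homref_parent", 1)
  fam <- toy_pedigree(1)[1, ]
  mk_track <- function() {
    bp <- sort(sample(1:199, 12))
    data.frame(chrom = "1", start = c(0, bp), end = c(bp, 200),
               depth = sample(0:70, 13, replace = TRUE))
  }
  tracks <- list(`F01-C` = mk_track(), `F01-F` = mk_track(),
                 `F01-M` = mk_track())
  regions <- data.frame(chrom = "1", start = 3, end = 190)
  h <- build_depth_histogram(tracks, fam, regions)
  via_hist <- expected_callable_sites(h, het, hom)
  pos <- (regions$start + 1):regions$end
  brute <- sum(callability_at(het, brute_depth(tracks[["F01-C"]], "1", pos)) *
               callability_at(hom, brute_depth(tracks[["F01-F"]], "1", pos)) *
               callability_at(hom, brute_depth(tracks[["F01-M"]], "1", pos)))
  expect_equal(via_hist, brute, tolerance = 1e-9)
  # clamping: depths beyond the table range use the nearest calibrated bin
  expect_equal(callability_at(het, 1000), het$estimate[dmax + 1])
})

test_that("site-filter loss composes independent test alphas", {
  expect_equal(alpha_site_from_config(c(0, 0))$alpha_site, 0)
  expect_equal(alpha_site_from_config(c(0.01, 0.01))$alpha_site, 0.0199)
  expect_equal(alpha_site_from_config(0.05)$alpha_site, 0.05)
  expect_error(alpha_site_from_config(1), "0, 1")
})

test_that("calibration estimates stay within [0, 1] on simulated cohorts", {
  sim <- simulate_cohort(sim_config(n_families = 4, genome_length = 1e5,
                                    mu = 1e-5, calib_density = 2e-3, seed = 9))
  het <- calibrate_het_callability(sim$cohort)
  hom <- calibrate_homref_callability(sim$cohort)
  expect_true(all(het$estimate >= 0 & het$estimate <= 1))
  expect_true(all(hom$estimate >= 0 & hom$estimate <= 1))
  h <- sim_depth_histograms(sim)[[1]]
  cf <- expected_callable_sites(h, het, hom)
  expect_gte(cf, 0)
  expect_lte(cf, attr(h, "total_positions"))
})
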