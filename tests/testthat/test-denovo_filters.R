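test_that("individual filters apply the documented inclusive thresholds", {
  cfg <- filter_config()
  # heterozygote filter: (gt, gq, dp, expected)
  het_cases <- rbind(
    data.frame(gt = 1L, gq = 50, dp = 10, want = TRUE),   # bounds inclusive
    data.frame(gt = 1L, gq = 50, dp = 120, want = TRUE),
    data.frame(gt = 1L, gq = 49, dp = 30, want = FALSE),
    data.frame(gt = 1L, gq = 99, dp = 121, want = FALSE),
    data.frame(gt = 1L, gq = 99, dp = 9, want = FALSE),
    data.frame(gt = 0L, gq = 99, dp = 30, want = FALSE),
    data.frame(gt = NA_integer_, gq = 99, dp = 30, want = FALSE))
  expect_equal(heterozygote_filter(het_cases$gt, het_cases$gq, het_cases$dp, cfg),
               het_cases$want)
  # homozygote filter adds the AD2 = 0 requirement
  hom_cases <- rbind(
    data.frame(gt = 0L, gq = 60, dp = 30, ad = 0, want = TRUE),
    data.frame(gt = 0L, gq = 60, dp = 30, ad = 1, want = FALSE),
    data.frame(gt = 0L, gq = 60, dp = 9, ad = 0, want = FALSE),
    data.frame(gt = 0L, gq = 49, dp = 30, ad = 0, want = FALSE),
    data.frame(gt = 1L, gq = 99, dp = 30, ad = 15, want = FALSE),
    data.frame(gt = NA_integer_, gq = 60, dp = 30, ad = 0, want = FALSE))
  expect_equal(homozygote_filter(hom_cases$gt, hom_cases$gq, hom_cases$dp,
                                 hom_cases$ad, cfg),
               hom_cases$want)
})

test_that("strand-bias p-values agree with hypergeometric enumeration", {
  cases <- list(c(30, 30, 12, 0),    # all alt reads on one strand
                c(30, 30, 6, 6),     # balanced
                c(50, 50, 40, 0),    # the simulator's rejection statistics
                c(8, 3, 2, 7),
                c(0, 0, 5, 5))       # degenerate margin -> 1
  for (x in cases) {
    got <- strand_bias_p(x[1], x[2], x[3], x[4])
    want <- if ((x[1] + x[2]) == 0) 1 else
      enum_fisher_p(x[1], x[2], x[3], x[4])
    expect_equal(got, want, tolerance = 1e-9,
                 label = paste(x, collapse = ","))
  }
  expect_lt(strand_bias_p(30, 30, 12, 0), 0.05)
  expect_gt(strand_bias_p(30, 30, 6, 6), 0.9)
  expect_equal(strand_bias_p(NA, 1, 2, 3), 1)
})

test_that("read-position test passes central reads and flags skewed ones", {
  expect_equal(read_position_p("10,40,60,90", "12,38,62,88"), 1, tolerance = 0.5)
  skew <- read_position_p(paste(seq(30, 70, 2), collapse = ","),
                          paste(c(1, 2, 2, 3, 4, 5, 6), collapse = ","))
  expect_lt(skew, 0.05)
  expect_equal(read_position_p("", "10,20"), 1)   # no ref positions -> pass
  expect_equal(read_position_p("5,5", "5,5"), 1)  # all tied -> pass
})

test_that("site filter rejects exactly the sites below a configured alpha", {
  gt <- matrix(0L, 3, 6)
  co <- clean_cohort(gt)
  co$sites$srf <- c(30, 30, NA); co$sites$srr <- c(30, 30, NA)
  co$sites$saf <- c(12, 6, NA); co$sites$sar <- c(0, 6, NA)
  sf <- site_filter(co, filter_config(site_test_alphas = c(strand_bias = 0.05)))
  expect_equal(sf$pass, c(FALSE, TRUE, TRUE))   # NA stats pass with p = 1
  expect_equal(sf$p_strand[3], 1)
  # alpha = 0 has an empty rejection region
  sf0 <- site_filter(co, filter_config(site_test_alphas = c(strand_bias = 0,
                                                            read_position = 0)))
  expect_true(all(sf0$pass))
})

test_that("allele-balance partition uses the closed germline interval", {
  cfg <- filter_config()
  expect_equal(classify_allele_balance(c(0.5, 0.18, 0.3, 0.7, 0.29, 0.71), cfg),
               c("germline", "somatic_candidate", "germline", "germline",
                 "somatic_candidate", "somatic_candidate"))
  expect_error(classify_allele_balance(NaN, cfg), "uncallable")
})

test_that("Mendelian-violation candidates require clean trio genotypes and cohort exclusivity", {
  # two families, samples: F01-C F01-F F01-M F02-C F02-F F02-M
  gt <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),   # candidate in F01
              c(1L, 1L, 0L, 0L, 0L, 0L),   # father het -> not a violation
              c(1L, 0L, 0L, 1L, 0L, 0L),   # variant seen in the other family
              c(0L, 0L, 0L, 0L, 0L, 0L))   # no variant at all
  co <- clean_cohort(gt)
  expect_equal(mendelian_violation_candidate(co, "F01"),
               c(TRUE, FALSE, FALSE, FALSE))
  # a missing call outside the family is not a carrier call
  gt2 <- gt[1, , drop = FALSE]; gt2[1, 4] <- NA_integer_
  co2 <- clean_cohort(gt2)
  expect_true(mendelian_violation_candidate(co2, "F01")[1])
})

test_that("call_denovo returns the seeded truth on simulated cohorts", {
  cf <- sim_config(n_families = 4, genome_length = 2e5, mu = 4e-5,
                   calib_density = 1e-3, ad_error_rate = 0, alpha_site = 0,
                   seed = 41)
  sim <- simulate_cohort(cf)
  calls <- call_denovo(sim$cohort)
  # every call corresponds to a seeded event (no false positives without
  # genotype error), matched on family and position
  key_call <- paste(calls$family_id, calls$pos)
  key_truth <- paste(sim$truth$family_id, sim$truth$pos)
  expect_true(all(key_call %in% key_truth))
  # partition property: classes are exhaustive and exclusive
  expect_equal(sum(calls$classification == "germline") +
                 sum(calls$classification == "somatic_candidate"),
               nrow(calls))
  expect_false(any(duplicated(key_call)))
  # a cohort with no violations yields an empty call set
  co0 <- clean_cohort(matrix(0L, 5, 6))
  expect_equal(nrow(call_denovo(co0)), 0)
})

test_that("tightening individual filters never increases the call count", {
  sim <- simulate_cohort(sim_config(n_families = 4, genome_length = 2e5,
                                    mu = 4e-5, calib_density = 1e-3, seed = 5))
  base <- nrow(call_denovo(sim$cohort, filter_config()))
  for (cfg in list(filter_config(gq_min = 70),
                   filter_config(dp_min = 20, dp_max = 100),
                   filter_config(gq_min = 90, dp_min = 25, dp_max = 80))) {
    expect_lte(nrow(call_denovo(sim$cohort, cfg)), base)
  }
})

test_that("oversized indels are excluded from de novo calling", {
  ped <- toy_pedigree(2)
  gt <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L, 0L, 0L))
  sites <- data.frame(chrom = "1", pos = c(100L, 200L),
                      ref = c("A", paste0("A", strrep("CT", 20))),
                      alt = c(paste0("A", strrep("GA", 3)), "A"),
                      variant_type = "indel", indel_len = c(6L, 40L),
                      known = FALSE, srf = NA_real_, srr = NA_real_,
                      saf = NA_real_, sar = NA_real_,
                      rp_ref = NA_character_, rp_alt = NA_character_,
                      stringsAsFactors = FALSE)
  co <- clean_cohort(gt, ped, sites)
  calls <- call_denovo(co)
  expect_equal(calls$pos, 100L)   # the 40 bp deletion is out of scope
})
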