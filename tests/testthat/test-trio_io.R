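test_that("VCF records parse into genotype observations with skip accounting", {
  dir <- withr::local_tempdir()
  ped <- toy_pedigree(1)
  vcf <- write_test_vcf(file.path(dir, "t.vcf"), c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:32:32,0\t0/0:85:28:28,0",
    "1\t200\t.\tC\tA,T\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0",
    "1\t300\t.\tG\tT\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:.:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0"))
  pedf <- write_test_ped(file.path(dir, "t.ped"), ped)
  co <- read_cohort(vcf, pedf)
  expect_s3_class(co, "trio_cohort")
  expect_equal(nrow(co$sites), 2)            # multi-allelic row dropped
  expect_equal(co$n_skipped, 1L)
  expect_equal(unname(co$skip_reasons["multi_allelic"]), 1L)
  expect_equal(unname(co$gt[1, "F01-C"]), 1L)   # 0/1 -> Het
  expect_equal(unname(co$gt[1, "F01-F"]), 0L)
  expect_equal(unname(co$ad_ref[1, "F01-C"]), 15)
  # missing GQ makes the whole observation missing
  expect_true(is.na(co$gt[2, "F01-C"]))
  expect_false(is.na(co$gt[2, "F01-F"]))
})

test_that("pedigree samples absent from the VCF and unsorted VCFs are fatal", {
  dir <- withr::local_tempdir()
  ped <- toy_pedigree(1)
  pedf <- write_test_ped(file.path(dir, "t.ped"), ped)
  vcf1 <- write_test_vcf(file.path(dir, "bad_samples.vcf"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP:AD\t0/0:90:30:30,0\t0/0:90:30:30,0\t0/0:90:30:30,0",
    samples = c("X1", "X2", "X3"))
  expect_error(read_cohort(vcf1, pedf), "absent from VCF header")
  vcf2 <- write_test_vcf(file.path(dir, "unsorted.vcf"), c(
    "1\t300\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0",
    "1\t100\t.\tC\tT\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0"))
  expect_error(read_cohort(vcf2, pedf), "unsorted")
})

test_that("non-autosomal records are excluded by default and kept on request", {
  dir <- withr::local_tempdir()
  ped <- toy_pedigree(1)
  pedf <- write_test_ped(file.path(dir, "t.ped"), ped)
  vcf <- write_test_vcf(file.path(dir, "t.vcf"), c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0",
    "X\t100\t.\tC\tT\t.\tPASS\t.\tGT:GQ:DP:AD\t0/1:80:30:15,15\t0/0:90:30:30,0\t0/0:85:30:30,0"))
  expect_equal(nrow(read_cohort(vcf, pedf)$sites), 1)
  expect_equal(nrow(read_cohort(vcf, pedf, regions = "all")$sites), 2)
})

test_that("a simulated cohort round-trips through VCF identically", {
  sim <- simulate_cohort(sim_config(n_families = 3, genome_length = 5e4,
                                    mu = 5e-5, calib_density = 2e-3, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  co <- read_cohort(paths["vcf"], paths["ped"], paths["ages"], paths["known"])
  orig <- sim$cohort
  expect_equal(co$sites$chrom, orig$sites$chrom)
  expect_equal(co$sites$pos, orig$sites$pos)
  expect_equal(co$sites$ref, orig$sites$ref)
  expect_equal(co$sites$alt, orig$sites$alt)
  expect_equal(co$sites$known, orig$sites$known)
  expect_equal(co$sites$srf, orig$sites$srf)
  expect_equal(co$sites$rp_alt, orig$sites$rp_alt)
  for (m in c("gt", "gq", "dp", "ad_ref", "ad_alt"))
    expect_equal(unname(co[[m]]), unname(orig[[m]]), ignore_attr = TRUE,
                 label = m)
  expect_equal(co$pedigrees$father_age, orig$pedigrees$father_age)
  # and writing the re-read cohort again produces identical content
  p2 <- file.path(dir, "again.vcf.gz")
  write_cohort_vcf(co, p2)
  v1 <- vcfR::read.vcfR(paths["vcf"], verbose = FALSE)
  v2 <- vcfR::read.vcfR(p2, verbose = FALSE)
  expect_identical(v1@fix, v2@fix)
  expect_identical(v1@gt, v2@gt)
})

test_that("depth histogram handles constant depth and empty regions", {
  fam <- toy_pedigree(1)[1, ]
  tr <- data.frame(chrom = "1", start = 0, end = 100, depth = 30)
  tracks <- list(`F01-C` = tr, `F01-F` = tr, `F01-M` = tr)
  h <- build_depth_histogram(tracks, fam,
                             data.frame(chrom = "1", start = 0, end = 100))
  expect_equal(nrow(h), 1)
  expect_equal(h$count, 100)
  expect_equal(unlist(h[1, 1:3], use.names = FALSE), c(30, 30, 30))
  expect_equal(attr(h, "total_positions"), 100)

  h0 <- build_depth_histogram(tracks, fam,
                              data.frame(chrom = character(0),
                                         start = numeric(0), end = numeric(0)))
  expect_equal(nrow(h0), 0)
  expect_equal(attr(h0, "total_positions"), 0)
})

test_that("depth histogram matches a per-position brute-force tally", {
  fam <- toy_pedigree(1)[1, ]
  # offset breakpoints and a gap (positions 60-70 uncovered for the father)
  tracks <- list(
    `F01-C` = data.frame(chrom = "1", start = c(0, 13), end = c(13, 80),
                         depth = c(10, 35)),
    `F01-F` = data.frame(chrom = "1", start = c(0, 14, 70),
                         end = c(14, 60, 80), depth = c(12, 40, 22)),
    `F01-M` = data.frame(chrom = "1", start = c(5, 40), end = c(40, 90),
                         depth = c(28, 31)))
  regions <- data.frame(chrom = "1", start = 2, end = 78)
  h <- build_depth_histogram(tracks, fam, regions)
  pos <- (regions$start + 1):regions$end      # 1-based positions in region
  key <- paste(brute_depth(tracks[["F01-C"]], "1", pos),
               brute_depth(tracks[["F01-F"]], "1", pos),
               brute_depth(tracks[["F01-M"]], "1", pos))
  brute <- table(key)
  hk <- paste(h$d_child, h$d_father, h$d_mother)
  expect_setequal(hk, names(brute))
  expect_equal(h$count[match(names(brute), hk)], as.numeric(brute),
               ignore_attr = TRUE)
  # marginal over the child equals that sample's independent per-depth tally
  marg <- tapply(h$count, h$d_child, sum)
  brute_marg <- table(brute_depth(tracks[["F01-C"]], "1", pos))
  expect_equal(as.numeric(marg[names(brute_marg)]), as.numeric(brute_marg))
})

test_that("overlapping intervals within one depth track are fatal", {
  fam <- toy_pedigree(1)[1, ]
  bad <- data.frame(chrom = "1", start = c(0, 5), end = c(10, 15), depth = 9)
  tracks <- list(`F01-C` = bad, `F01-F` = bad[1, ], `F01-M` = bad[1, ])
  expect_error(build_depth_histogram(tracks, fam,
                                     data.frame(chrom = "1", start = 0, end = 15)),
               "overlapping")
})

test_that("precomputed histogram TSVs load with totals", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "h.tsv")
  utils::write.table(data.frame(family_id = "F01", d_child = c(30, 31),
                                d_father = 30, d_mother = 29,
                                count = c(70, 30)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- read_depth_histogram(p, "F01")
  expect_equal(attr(h, "total_positions"), 100)
  expect_equal(nrow(h), 2)
})
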