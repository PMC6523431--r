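test_that("call-rate filters use strict inequalities at the boundary", {
  # 100 SNPs; sample 1 has 95 calls (kept), sample 2 exactly 90 (removed)
  d <- matrix(1L, 4, 100)
  d[1, 1:5] <- NA
  d[2, 1:10] <- NA
  g <- tiny_genoset(d)
  out <- filter_individuals_by_callrate(g, 0.90)
  expect_setequal(out$sample_ids, c("s1", "s3", "s4"))
  expect_equal(attr(out, "n_removed"), 1)

  # SNP call rate: 96% kept, exactly 95% removed (20 samples)
  d2 <- matrix(1L, 20, 3)
  d2[1, 2] <- NA          # 95% call rate
  g2 <- tiny_genoset(d2)
  out2 <- filter_snps_by_callrate(g2, 0.95)
  expect_equal(nrow(out2$markers), 2)
})

test_that("engineered call-rate fixtures are counted exactly", {
  withr::with_seed(3, {
    d <- matrix(sample(0:2, 10 * 100, replace = TRUE), 10, 100)
    d[3, 1:15] <- NA   # 85% call rate
    d[7, 1:20] <- NA   # 80%
    g <- tiny_genoset(d)
    out <- filter_individuals_by_callrate(g, 0.90)
    expect_equal(length(out$sample_ids), 8)

    d <- matrix(sample(0:2, 50 * 100, replace = TRUE), 50, 100)
    for (j in 1:7) d[1:3, j] <- NA  # 94% call rate at 7 SNPs
    out <- filter_snps_by_callrate(tiny_genoset(d), 0.95)
    expect_equal(nrow(out$markers), 93)
  })
})

test_that("HWE exact p hits the landmark configurations", {
  expect_gt(hwe_exact_p(25, 50, 25), 0.9)        # near-perfect equilibrium
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)        # total heterozygote deficit
  expect_equal(hwe_exact_p(100, 0, 0), 1)        # monomorphic
})

test_that("HWE exact p agrees with an independent recurrence oracle", {
  for (n in c(5, 10, 25, 50)) {
    for (n_aa in seq(0, n, by = max(1, n %/% 5))) {
      for (n_ab in seq(0, n - n_aa, by = max(1, n %/% 5))) {
        n_bb <- n - n_aa - n_ab
        expect_equal(hwe_exact_p(n_aa, n_ab, n_bb),
                     hwe_recurrence_oracle(n_aa, n_ab, n_bb),
                     tolerance = 1e-12,
                     label = sprintf("(%d,%d,%d)", n_aa, n_ab, n_bb))
      }
    }
  }
})

test_that("MAF filter is strict at the 0.05 boundary", {
  # 20 samples: dosage sums give freq_a 0.051 -> impossible exactly; use 100
  d <- matrix(0L, 100, 3)
  d[1:11, 1] <- 1L   # freq_a = 11/200 = 0.055 > 0.05: kept
  d[1:10, 2] <- 1L   # freq_a = 0.05 exactly: removed
  d[1:2, 3] <- 1L    # freq_a = 0.01: removed
  out <- filter_maf(tiny_genoset(d), 0.05)
  expect_identical(out$markers$marker_id, "m1")
  expect_equal(attr(out, "n_removed"), 2)
})

test_that("run_qc attributes each SNP to the first removing filter", {
  withr::with_seed(9, {
    n <- 60
    d <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
    # SNPs 1-2: call rate 90% (< 95%), spread so no sample fails its filter
    d[1:6, 1] <- NA
    d[7:12, 2] <- NA
    # SNPs 3-4: extreme heterozygote deficit -> HWE failure
    d[, 3] <- rep(c(0L, 2L), n / 2)
    d[, 4] <- rep(c(0L, 2L), n / 2)
    # SNPs 5-6: rare (MAF < 0.05)
    d[, 5] <- 0L; d[1, 5] <- 1L
    d[, 6] <- 0L; d[2, 6] <- 1L
    g <- genotype_set(
      marker_map(paste0("m", 1:20),
                 c(rep("1", 18), "X", "19"),  # SNPs 19-20 non-autosomal
                 c(seq_len(18) * 1000, 1000, 1000),
                 rep("A", 20), rep("B", 20)),
      paste0("s", seq_len(n)), d)
    res <- run_qc(g)
    rep <- res$report
    expect_equal(rep$n_removed_snp_callrate, 2)
    expect_equal(rep$n_removed_hwe, 2)
    expect_equal(rep$n_removed_maf, 2)
    expect_equal(rep$n_removed_nonautosomal_or_unmapped, 2)
    expect_equal(rep$n_output_snps,
                 rep$n_input_snps - rep$n_removed_snp_callrate -
                   rep$n_removed_hwe - rep$n_removed_maf -
                   rep$n_removed_nonautosomal_or_unmapped)
  })
})

test_that("run_qc leaves a clean panel untouched", {
  withr::with_seed(2, {
    d <- matrix(rbinom(50 * 10, 2, 0.5), 50, 10)
    res <- run_qc(tiny_genoset(d))
    expect_equal(res$report$n_output_snps, 10)
    expect_equal(tidy(res$report)$n_removed, rep(0L, 5),
                 ignore_attr = TRUE)
  })
})

test_that("HWE and MAF filters commute when no SNP is removable by both", {
  withr::with_seed(13, {
    n <- 80
    d <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
    d[, 1] <- rep(c(0L, 2L), n / 2)          # HWE failure, common alleles
    d[, 2] <- 0L; d[1, 2] <- 1L              # rare, but monomorphic-ish HWE p = 1
    g <- tiny_genoset(d)
    a <- filter_maf(filter_hwe(g, 1e-6), 0.05)
    b <- filter_hwe(filter_maf(g, 0.05), 1e-6)
    expect_identical(a$markers$marker_id, b$markers$marker_id)
  })
})
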