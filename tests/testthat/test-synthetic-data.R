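test_that("a fixed seed reproduces the panel bit for bit", {
  cfg <- sim_config(n_samples = 30, n_chroms = 2, n_snps_per_chrom = 80,
                    seed = 123)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$haplotypes$alleles, b$haplotypes$alleles)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  c <- simulate_panel(sim_config(n_samples = 30, n_chroms = 2,
                                 n_snps_per_chrom = 80, seed = 124))
  expect_false(identical(a$haplotypes$alleles, c$haplotypes$alleles))
})

test_that("panel geometry matches the configured chip characteristics", {
  cfg <- sim_config(n_samples = 50, n_chroms = 4, n_snps_per_chrom = 400,
                    seed = 9)
  sim <- simulate_panel(cfg)
  map <- sim$haplotypes$markers
  expect_equal(length(unique(map$chromosome)), 4)
  expect_equal(nrow(map), 1600)
  gaps <- unlist(tapply(map$position_bp, map$chromosome, diff))
  expect_gt(mean(gaps), 0.8 * cfg$mean_spacing_bp)
  expect_lt(mean(gaps), 1.25 * cfg$mean_spacing_bp)
  expect_true(all(gaps > 0))
})

test_that("without QTL the phenotype is independent of every SNP", {
  cors <- vapply(1:8, function(s) {
    sim <- simulate_panel(sim_config(n_samples = 60, n_chroms = 1,
                                     n_snps_per_chrom = 200, seed = 300 + s))
    max(abs(suppressWarnings(
      cor(sim$phenotypes$BF1, sim$genotypes$dosage))), na.rm = TRUE)
  }, numeric(1))
  # max |cor| over 200 null SNPs at n = 60: far from 1, near the null envelope
  expect_lt(max(cors), 0.55)
  expect_gt(mean(cors), 0.2)  # and not degenerate either
})

test_that("realized variance explained lands near its target across seeds", {
  ves <- vapply(1:20, function(s) {
    cfg <- sim_config(n_samples = 150, n_chroms = 2, n_snps_per_chrom = 120,
                      seed = 500 + s,
                      qtl_spec = tibble::tibble(
                        chromosome = "1", position_bp = 3.7e6,
                        effect_size = qtl_effect_for_ve(0.3),
                        swept = FALSE, sweep_strength = 0))
    simulate_panel(cfg)$truth$realized_ve
  }, numeric(1))
  expect_true(all(ves > 0.2 & ves < 0.4))
})

test_that("missingness injection hits its targets and run_qc recovers them", {
  sim <- simulate_panel(sim_config(n_samples = 60, n_chroms = 2,
                                   n_snps_per_chrom = 150, seed = 31))
  g <- sim$genotypes
  expect_identical(inject_missingness_and_errors(g, 0, 0)$dosage, g$dosage)

  g2 <- inject_missingness_and_errors(g, 0.02, 0, seed = 77)
  rate <- mean(is.na(g2$dosage))
  expect_lt(abs(rate - 0.02), 3 * sqrt(0.02 * 0.98 / length(g2$dosage)) + 1e-3)

  g3 <- inject_missingness_and_errors(g, 0, 3, seed = 78)
  res <- run_qc(g3)
  expect_equal(res$report$n_removed_individual_callrate, 3)
  expect_setequal(setdiff(g$sample_ids, res$genotypes$sample_ids),
                  attr(g3, "failed_samples"))
})

test_that("swept QTL differentiate the extreme level-3 groups above the genome median", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 120, n_chroms = 2, n_snps_per_chrom = 150,
                      seed = 700 + s,
                      qtl_spec = tibble::tibble(
                        chromosome = "1", position_bp = 4.6e6,
                        effect_size = qtl_effect_for_ve(0.35),
                        swept = TRUE, sweep_strength = 0.9))
    sim <- simulate_panel(cfg)
    pr <- make_gradient_pairs(sim$phenotypes, "BF1")
    fst <- weir_cockerham_fst(sim$genotypes, pair_ids(pr, 3, "high"),
                              pair_ids(pr, 3, "low"))
    fst$theta[fst$marker_id == sim$truth$marker_id] >
      stats::median(fst$theta, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
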