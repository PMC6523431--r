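test_that("EHH is 1 at the core and follows pair counting at the next marker", {
  # 4 carriers of allele 1 splitting 2/2 at the next marker -> EHH = 2/6
  H <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
             c(0L, 0L), c(0L, 1L))
  h <- tiny_hapset(H, c(1000L, 2000L))
  cv <- ehh(h, "m1", 1, "downstream", cutoff = 0)
  expect_equal(cv$ehh[1], 1)
  expect_equal(cv$ehh[2], 1 / 3)
})

test_that("two identical carriers keep EHH at 1 and set the truncation flag", {
  H <- rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L),
             c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  h <- tiny_hapset(H, c(1L, 1000L, 2000L, 3000L))
  cv <- ehh(h, "m1", 1, "downstream")
  expect_true(all(cv$ehh == 1))
  expect_true(attr(cv, "truncated_at_chromosome_end"))
})

test_that("EHH is undefined with fewer than two carriers", {
  H <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  h <- tiny_hapset(H, c(100L, 200L))
  expect_warning(out <- ehh(h, "m1", 1, "downstream"), "fewer than 2")
  expect_null(out)
})

test_that("EHH curves are non-increasing, in [0,1], and match the pair oracle", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      H <- random_hap_matrix(16, 12)
      pos <- sort(sample.int(8e5, 12))
      h <- tiny_hapset(H, pos)
      core <- sample(3:10, 1)
      for (a in c(0L, 1L, NA)) {
        if (!is.na(a) && sum(H[, core] == a) < 2) next
        cv <- ehh(h, paste0("m", core), a, "downstream")
        if (is.null(cv)) next
        expect_true(all(diff(cv$ehh) <= 1e-12))
        expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
        orc <- ehh_pair_oracle(H, pos, core, a, +1L)
        expect_equal(cv$position_bp, orc$position)
        expect_equal(cv$ehh, orc$ehh, tolerance = 1e-12)
        expect_equal(attr(cv, "ihh"), orc$ihh, tolerance = 1e-9)
      }
    }
  })
})

test_that("iHH integrates trapezoids by hand and doubles for symmetric curves", {
  # EHH 1 over exactly 10,000 bp then 0 at a marker 1,000 bp further
  up <- tibble::tibble(position_bp = c(0, 10000, 11000), ehh = c(1, 1, 0))
  attr(up, "core_marker") <- "c"
  dn <- tibble::tibble(position_bp = 0, ehh = 1)
  attr(dn, "core_marker") <- "c"
  expect_equal(ihh(up, dn), 10000 + 500)
  dn2 <- up
  dn2$position_bp <- -dn2$position_bp
  expect_equal(ihh(up, dn2), 2 * 10500)
  expect_error(ihh(up, structure(dn, core_marker = "other")), "share a core")
})

test_that("iHS is zero under allele-exchange symmetry and negates on relabeling", {
  # a panel of complementary haplotype pairs is symmetric under allele
  # relabeling at every SNP: the two alleles' EHH curves coincide
  withr::with_seed(23, {
    A <- random_hap_matrix(10, 8)
    H <- rbind(A, 1L - A)
    pos <- sort(sample.int(4e5, 8))
    h <- tiny_hapset(H, pos)
    c0 <- ehh(h, "m4", 0, "downstream")
    c1 <- ehh(h, "m4", 1, "downstream")
    expect_equal(c0$ehh, c1$ehh, tolerance = 1e-12)

    # recoding alleles at one SNP leaves the scan invariant (minor stays
    # minor), while swapping the ancestral/derived roles negates the score
    H2 <- random_hap_matrix(24, 30)
    pos2 <- sort(sample.int(6e5, 30))
    h2 <- tiny_hapset(H2, pos2)
    s1 <- ihs_scan(h2, maf_floor = 0.05)
    expect_gt(nrow(s1), 0)
    flip <- H2
    flip[, 15] <- 1L - flip[, 15]
    s2 <- ihs_scan(tiny_hapset(flip, pos2), maf_floor = 0.05)
    expect_identical(s1$marker_id, s2$marker_id)
    expect_equal(s2$ihs_unstd, s1$ihs_unstd, tolerance = 1e-12)

    freq1 <- colMeans(H2)
    major_code <- as.integer(freq1 > 0.5)
    s_anc <- ihs_scan(h2, maf_floor = 0.05, ancestral = major_code)
    expect_equal(s_anc$ihs_unstd, s1$ihs_unstd, tolerance = 1e-12)
    s_der <- ihs_scan(h2, maf_floor = 0.05, ancestral = 1L - major_code)
    expect_equal(s_der$ihs_unstd, -s1$ihs_unstd, tolerance = 1e-12)
  })
})

test_that("iHS scan matches the exhaustive pair-counting oracle on a toy panel", {
  withr::with_seed(29, {
    H <- random_hap_matrix(20, 24)
    pos <- sort(sample.int(9e5, 24))
    h <- tiny_hapset(H, pos)
    tab <- ihs_scan(h, maf_floor = 0.05)
    expect_gt(nrow(tab), 0)
    for (i in seq_len(nrow(tab))) {
      core <- match(tab$marker_id[i], h$markers$marker_id)
      orc <- ihs_oracle_snp(H, pos, core)
      expect_false(is.null(orc))
      expect_equal(tab$ihh_major[i], orc$ihh_major, tolerance = 1e-9)
      expect_equal(tab$ihh_minor[i], orc$ihh_minor, tolerance = 1e-9)
      expect_equal(tab$ihs_unstd[i], orc$ihs, tolerance = 1e-9)
    }
    # SNPs the scan dropped must be undefined or truncated in the oracle too
    dropped <- setdiff(h$markers$marker_id, tab$marker_id)
    for (id in dropped) {
      core <- match(id, h$markers$marker_id)
      f1 <- mean(H[, core])
      if (min(f1, 1 - f1) < 0.05) next
      expect_null(ihs_oracle_snp(H, pos, core))
    }
  })
})

test_that("window averaging tiles the genome in 50 kb blocks", {
  t <- tibble::tibble(marker_id = c("a", "b", "c"), chromosome = "1",
                      position_bp = c(10000L, 60000L, 120000L),
                      abs_ihs = c(1, 3, 2))
  w <- window_average_abs_ihs(t)
  expect_equal(nrow(w), 3)
  expect_equal(w$start_bp, c(1, 50001, 100001))
  expect_equal(w$n_snps, c(1, 1, 1))

  t2 <- tibble::tibble(marker_id = c("a", "b"), chromosome = "1",
                       position_bp = c(10000L, 20000L), abs_ihs = c(1, 3))
  expect_equal(window_average_abs_ihs(t2)$mean_abs_ihs, 2)

  # tiling count: non-empty windows = distinct (chrom, pos %/% 50kb) pairs
  withr::with_seed(41, {
    t3 <- tibble::tibble(
      marker_id = paste0("s", 1:200),
      chromosome = as.character(sample(1:3, 200, replace = TRUE)),
      position_bp = sample.int(2e6, 200), abs_ihs = abs(rnorm(200)))
    w3 <- window_average_abs_ihs(t3)
    expect_equal(nrow(w3),
                 nrow(unique(cbind(t3$chromosome,
                                   (t3$position_bp - 1) %/% 50000))))
    expect_equal(sum(w3$n_snps), 200)
  })
})

test_that("XP-EHH is zero for identical panels and negates under swap", {
  sim <- simulate_panel(sim_config(n_samples = 24, n_chroms = 1,
                                   n_snps_per_chrom = 60, seed = 4))
  h <- sim$haplotypes
  ids <- h$sample_ids
  a <- gradscan:::subset_samples(h, ids[1:12])
  b <- gradscan:::subset_samples(h, ids[13:24])
  same <- xpehh_scan(a, a)
  expect_true(all(same$xpehh_unnorm == 0))
  ab <- xpehh_scan(a, b)
  ba <- xpehh_scan(b, a)
  expect_equal(ab$xpehh_unnorm, -ba$xpehh_unnorm, tolerance = 1e-12)
})

test_that("XP-EHH matches the brute-force oracle on a two-population toy panel", {
  withr::with_seed(37, {
    Ho <- random_hap_matrix(10, 8)
    Hr <- random_hap_matrix(10, 8)
    pos <- sort(sample.int(4e5, 8))
    xp <- xpehh_scan(tiny_hapset(Ho, pos), tiny_hapset(Hr, pos))
    for (i in seq_len(nrow(xp))) {
      core <- match(xp$marker_id[i], paste0("m", 1:8))
      orc <- xpehh_oracle_snp(Ho, Hr, pos, core)
      expect_equal(xp$ihh_observed[i], orc$ihh_obs, tolerance = 1e-9)
      expect_equal(xp$ihh_reference[i], orc$ihh_ref, tolerance = 1e-9)
      expect_equal(xp$xpehh_unnorm[i], orc$xpehh, tolerance = 1e-9)
      expect_equal(xp$truncated[i], orc$truncated)
    }
  })
})

test_that("a sweep toward low phenotype gives positive, outlying XP-EHH at the locus", {
  # favoured allele lowers the trait, so the swept background concentrates
  # in the observed (low) side of the level-3 pair; under the package's
  # role convention the locus scores positive and lands in the upper tail
  best <- q99 <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(seed = 900 + s,
                      qtl_spec = tibble::tibble(
                        chromosome = "7", position_bp = 6e7,
                        effect_size = -qtl_effect_for_ve(0.3),
                        swept = TRUE, sweep_strength = 0.9))
    sim <- simulate_panel(cfg)
    pr <- make_gradient_pairs(sim$phenotypes, "BF1")
    xp <- xpehh_scan(
      gradscan:::subset_samples(sim$haplotypes, pair_ids(pr, 3, "low")),
      gradscan:::subset_samples(sim$haplotypes, pair_ids(pr, 3, "high")))
    map <- sim$haplotypes$markers
    i <- match(xp$marker_id, map$marker_id)
    near <- map$chromosome[i] == sim$truth$chromosome &
      abs(map$position_bp[i] - sim$truth$position_bp) <= 2e5
    best[s] <- max(xp$xpehh_unnorm[near])
    q99[s] <- quantile(abs(xp$xpehh_unnorm), 0.99)
  }
  expect_true(all(best > 0))
  expect_gte(mean(best >= q99), 4 / 6)
})
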