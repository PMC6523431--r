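test_that("empirical p-values follow the rank/N rule with min-rank ties", {
  p <- empirical_p(c(5, 1, 3), tail = "upper")
  expect_equal(p, c(1 / 3, 1, 2 / 3))
  expect_equal(empirical_p(rep(2, 4), "upper"), rep(1 / 4, 4))
  # most extreme of N = 100 gets p = 0.01
  x <- c(100, seq_len(99))
  expect_equal(empirical_p(x, "upper")[1], 0.01)
  # absolute tail ranks by |x|
  expect_equal(empirical_p(c(-5, 1, 3), "absolute"), c(1 / 3, 1, 2 / 3))
  # sort-based oracle on a random vector
  withr::with_seed(5, {
    x <- rnorm(1000)
    p <- empirical_p(x, "upper")
    ord <- order(-x)
    expect_equal(p[ord], seq_len(1000) / 1000)
  })
})

test_that("NA statistics are excluded from the rank universe", {
  p <- empirical_p(c(5, NA, 1), "upper")
  expect_equal(p, c(0.5, NA, 1))
})

test_that("top-fraction counts reproduce the chip-scale threshold arithmetic", {
  expect_identical(top_fraction_count(37061), 370L)
  expect_identical(top_fraction_count(44559), 445L)
  expect_identical(top_fraction_count(99), 0L)
})

test_that("the trait-specific criterion enforces significance plus gradient", {
  ids <- paste0("m", 1:6)
  mk <- function(stat, p) tibble::tibble(marker_id = ids, statistic = stat,
                                         empirical_p = p)
  sig_p <- rep(0.005, 6)
  # reference score triples: a rising positive XP-EHH chain is called "low",
  # a falling negative chain "high"; a broken chain is not called
  s1 <- c(0.28, -0.34, 0.05, 0.33, 0.1, -0.2)
  s2 <- c(0.39, -0.48, 0.04, 0.50, 0.2, 0.3)
  s3 <- c(0.48, -0.68, 0.11, 0.13, 0.3, 0.4)
  xp <- call_trait_specific(list(mk(s1, sig_p), mk(s2, sig_p), mk(s3, sig_p)),
                            alpha = 0.01, method = "XPEHH", trait = "BF4")
  expect_setequal(xp$snps$marker_id, c("m1", "m2", "m5"))
  expect_equal(xp$snps$direction[xp$snps$marker_id == "m1"], "low")
  expect_equal(xp$snps$direction[xp$snps$marker_id == "m2"], "high")
  # m4 (0.33 < 0.50 < 0.13) breaks the gradient; m6 flips sign: neither called

  fst <- call_trait_specific(list(mk(abs(s1), sig_p), mk(abs(s2), sig_p),
                                  mk(abs(s3), sig_p)),
                             alpha = 0.01, method = "FST", trait = "BF4")
  expect_true(all(is.na(fst$snps$direction)))
  expect_true(!"m4" %in% fst$snps$marker_id)  # 0.33 < 0.50 > 0.13

  # significance must hold at every level
  p_mixed <- c(0.005, 0.02, rep(0.005, 4))
  xp2 <- call_trait_specific(list(mk(s1, p_mixed), mk(s2, sig_p),
                                  mk(s3, sig_p)), 0.01, "XPEHH")
  expect_false("m2" %in% xp2$snps$marker_id)
})

test_that("calling is permutation invariant and monotone in alpha", {
  withr::with_seed(205, {
    n <- 400
    ids <- paste0("m", 1:n)
    mk <- function(stat) tibble::tibble(marker_id = ids, statistic = stat,
                                        empirical_p = empirical_p(stat, "absolute"))
    base <- rnorm(n)
    scans <- list(mk(base), mk(base * 1.5 + rnorm(n, 0, 0.05)),
                  mk(base * 2 + rnorm(n, 0, 0.05)))
    called <- call_trait_specific(scans, 0.01, "XPEHH")
    perm <- sample(n)
    scans_p <- lapply(scans, function(s) s[perm, ])
    called_p <- call_trait_specific(scans_p, 0.01, "XPEHH")
    expect_setequal(called$snps$marker_id, called_p$snps$marker_id)

    strict <- call_trait_specific(scans, 0.005, "XPEHH")
    expect_true(all(strict$snps$marker_id %in% called$snps$marker_id))
  })
})

test_that("signature merging chains SNPs by pairwise 400 kb gaps", {
  map <- marker_map(paste0("m", 1:6), c(1, 1, 1, 1, 1, 2),
                    c(1.0e6, 1.35e6, 3.0e6, 3.3e6, 3.6e6, 1.0e6),
                    rep("A", 6), rep("B", 6))
  s <- structure(list(trait = "t", method = "FST", alpha = 0.01,
                      snps = tibble::tibble(marker_id = paste0("m", 1:6)),
                      regions = NULL), class = "signature_set")
  out <- merge_signatures(s, map, 400000)
  expect_equal(nrow(out$regions), 3)
  r1 <- out$regions[out$regions$start_bp == 1.0e6 & out$regions$chromosome == "1", ]
  expect_equal(r1$end_bp, 1.35e6)
  chain <- out$regions[out$regions$start_bp == 3.0e6, ]
  expect_equal(chain$end_bp, 3.6e6)   # 1.0/1.3/1.6-style pairwise chaining
  expect_equal(chain$n_snps, 3)

  # gap of exactly 500 kb splits
  map2 <- marker_map(c("a", "b"), c(1, 1), c(1.0e6, 1.5e6), "A", "B")
  s2 <- structure(list(trait = "t", method = "FST", alpha = 0.01,
                       snps = tibble::tibble(marker_id = c("a", "b")),
                       regions = NULL), class = "signature_set")
  expect_equal(nrow(merge_signatures(s2, map2, 400000)$regions), 2)
})

test_that("flanking extends 200 kb, floors at 1, and unions overlaps", {
  reg <- tibble::tibble(chromosome = c("1", "1", "2"),
                        start_bp = c(500000L, 850000L, 100000L),
                        end_bp = c(500000L, 850000L, 100000L))
  out <- flank_regions(reg, 200000)
  # the two chr1 singletons flank to [300k,700k] and [650k,1.05M]: unioned
  expect_equal(nrow(out), 2)
  expect_equal(out$start_bp[out$chromosome == "1"], 300000)
  expect_equal(out$end_bp[out$chromosome == "1"], 1050000)
  expect_equal(out$start_bp[out$chromosome == "2"], 1)  # floored
  expect_equal(out$end_bp[out$chromosome == "2"], 300000)
})

test_that("iHS window calling picks the 99th percentile and merges by 200 kb", {
  withr::with_seed(303, {
    n <- 2000
    w <- tibble::tibble(chromosome = "1",
                        start_bp = (seq_len(n) - 1L) * 50000L + 1L,
                        end_bp = seq_len(n) * 50000L,
                        mean_abs_ihs = runif(n), n_snps = 1L)
    w$empirical_p <- empirical_p(w$mean_abs_ihs, "upper")
    out <- call_ihs_regions(w, 99, 200000)
    expect_equal(nrow(out$significant), top_fraction_count(n, 0.01))
    expect_true(all(out$significant$mean_abs_ihs >=
                      sort(w$mean_abs_ihs, decreasing = TRUE)[20]))
  })
  # two significant windows 150 kb apart merge into one region
  w2 <- tibble::tibble(chromosome = "1",
                       start_bp = c(1L, 200001L), end_bp = c(50000L, 250000L),
                       mean_abs_ihs = c(5, 6), n_snps = 1L,
                       empirical_p = c(0.01, 0.005))
  out2 <- call_ihs_regions(w2, 99, 200000)
  expect_equal(nrow(out2$regions), 1)
  expect_equal(out2$regions$n_windows, 2)
  # 250 kb apart stays separate
  w3 <- w2
  w3$start_bp[2] <- 300001L
  w3$end_bp[2] <- 350000L
  expect_equal(nrow(call_ihs_regions(w3, 99, 200000)$regions), 2)
})

test_that("interval overlap honours half-open BED boundaries and a quadratic oracle", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "ann.bed")
  writeLines(c("1\t150\t300\tgeneA", "1\t200\t300\tgeneB"), bed)
  ann <- read_bed(bed)
  expect_equal(ann$start_bp, c(151L, 201L))
  reg <- tibble::tibble(chromosome = "1", start_bp = 101L, end_bp = 200L)
  ov <- overlap_annotation(reg, ann)
  # BED [150,300) overlaps [100,200); BED [200,300) does not (half-open)
  expect_equal(ov$annotation_name, "geneA")

  writeLines("1\t100", bed)
  expect_error(read_bed(bed), "line 1")

  withr::with_seed(99, {
    regions <- tibble::tibble(
      chromosome = as.character(sample(1:3, 100, replace = TRUE)),
      start_bp = sample.int(1e6, 100))
    regions$end_bp <- regions$start_bp + sample.int(5e4, 100)
    ann2 <- tibble::tibble(
      chromosome = as.character(sample(1:3, 100, replace = TRUE)),
      start_bp = sample.int(1e6, 100))
    ann2$end_bp <- ann2$start_bp + sample.int(5e4, 100)
    got <- overlap_annotation(regions, ann2)
    want <- overlap_quadratic_oracle(regions, ann2)
    key <- function(d) sort(paste(d$chromosome, d$region_start_bp,
                                  d$annotation_start_bp, d$overlap_bp))
    expect_equal(key(got), key(want))
    expect_equal(nrow(got), nrow(want))
  })
})

test_that("BED output converts back to 0-based half-open coordinates", {
  reg <- tibble::tibble(chromosome = "3", start_bp = 101L, end_bp = 200L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(reg, f)
  expect_equal(readLines(f), "3\t100\t200")
  rt <- read_bed(f)
  expect_equal(rt$start_bp, 101L)
  expect_equal(rt$end_bp, 200L)
})
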