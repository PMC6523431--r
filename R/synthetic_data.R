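# Founder-mosaic simulator of phased SNP panels with planted swept QTL and
# a quantitative phenotype.  The generator emulates a single-breed chip
# panel (by default 233 diploid samples, ~37k SNPs on 18 autosomes, mean
# marker spacing 62 kb): sample haplotypes are mosaics of a small founder
# pool with geometric recombination breakpoints, per-SNP founder allele
# frequencies follow a U-shaped (Beta(0.5, 0.5)) spectrum truncated to
# [0.05, 0.95] to mimic ascertained, MAF-filtered chip SNPs, and a hard
# sweep is planted by boosting one founder's local background among
# carriers of the favoured allele.  It is deliberately not a
# population-genetic (coalescent) null; it exists to give tunable LD and
# EHH contrast for end-to-end validation.

#' Simulation configuration
#'
#' @param n_samples Diploid samples (default 233).
#' @param n_chroms Autosomes (default 18).
#' @param n_snps_per_chrom SNPs per chromosome (default 2060, giving
#'   ~37k genome-wide).
#' @param mean_spacing_bp Mean inter-marker spacing (default 62,000).
#' @param n_founders Founder haplotypes per chromosome (default 40).
#' @param recomb_rate_per_bp Per-bp probability of a founder switch
#'   between adjacent markers (default 1e-6, ~1 Mb mosaic segments).
#' @param qtl_spec Tibble with columns `chromosome`, `position_bp`,
#'   `effect_size` (trait units per copy of the favoured allele),
#'   `swept` (logical) and `sweep_strength` (fraction of favoured-allele
#'   carriers put on the swept background); may be empty.
#' @param qtl_freq Founder frequency of the favoured allele at each QTL
#'   (default 0.3).
#' @param sweep_extent_bp Mean one-sided extent of the swept background
#'   (default 1 Mb).
#' @param h2_like_noise_sd SD of the Gaussian phenotype noise, trait
#'   units (default 1).
#' @param trait_name Name of the simulated trait column (default "BF1").
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 233, n_chroms = 18, n_snps_per_chrom = 2060,
                       mean_spacing_bp = 62000, n_founders = 40,
                       recomb_rate_per_bp = 1e-6, qtl_spec = NULL,
                       qtl_freq = 0.3, sweep_extent_bp = 1e6,
                       h2_like_noise_sd = 1, trait_name = "BF1", seed = 1) {
  if (is.null(qtl_spec))
    qtl_spec <- tibble(chromosome = character(), position_bp = integer(),
                       effect_size = numeric(), swept = logical(),
                       sweep_strength = numeric())
  stopifnot(n_samples > 1, n_chroms >= 1, n_snps_per_chrom > 1,
            mean_spacing_bp > 0, n_founders >= 2, recomb_rate_per_bp >= 0,
            h2_like_noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_chroms = as.integer(n_chroms),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 mean_spacing_bp = mean_spacing_bp,
                 n_founders = as.integer(n_founders),
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 qtl_spec = qtl_spec, qtl_freq = qtl_freq,
                 sweep_extent_bp = sweep_extent_bp,
                 h2_like_noise_sd = h2_like_noise_sd,
                 trait_name = trait_name, seed = as.integer(seed)),
            class = "sim_config")
}

#' Effect size giving a target variance explained
#'
#' Under Hardy-Weinberg the QTL dosage variance is `2 p (1 - p)`; the
#' per-copy effect that makes the QTL explain a fraction `ve` of the
#' phenotypic variance against noise SD `noise_sd` is
#' `noise_sd * sqrt(ve / ((1 - ve) * 2 p (1 - p)))`.
#'
#' @param ve Target variance explained, in (0, 1).
#' @param p Favoured-allele frequency.
#' @param noise_sd Phenotype noise SD.
#' @return Effect size in trait units per allele copy.
#' @export
qtl_effect_for_ve <- function(ve, p = 0.3, noise_sd = 1) {
  stopifnot(ve > 0, ve < 1, p > 0, p < 1)
  noise_sd * sqrt(ve / ((1 - ve) * 2 * p * (1 - p)))
}

#' Simulate a phased panel with planted QTL and phenotype
#'
#' See the package vignette for the generative model.  All randomness
#' flows through one seeded generator; a fixed seed gives bit-identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return A list: `haplotypes` ([haplotype_set()]), `genotypes`
#'   ([genotype_set()]), `phenotypes` (phenotype table), and `truth`
#'   (tibble of QTL marker ids, positions, effects, sweep settings and
#'   realized variance explained).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_panel_impl(cfg))
}

simulate_panel_impl <- function(cfg) {
  n <- cfg$n_samples
  n_haps <- 2L * n
  maps <- vector("list", cfg$n_chroms)
  hap_cols <- vector("list", cfg$n_chroms)
  qtl_rows <- list()

  for (ch in seq_len(cfg$n_chroms)) {
    m <- cfg$n_snps_per_chrom
    gaps <- pmax(1, round(rexp(m - 1, 1 / cfg$mean_spacing_bp)))
    pos <- as.integer(cumsum(c(round(runif(1, 1, cfg$mean_spacing_bp)), gaps)))
    # U-shaped founder allele-frequency spectrum, truncated like a
    # MAF-filtered chip
    u <- runif(m, stats::pbeta(0.05, 0.5, 0.5), stats::pbeta(0.95, 0.5, 0.5))
    f <- stats::qbeta(u, 0.5, 0.5)
    founders <- matrix(rbinom(cfg$n_founders * m, 1L, rep(f, each = cfg$n_founders)),
                       nrow = cfg$n_founders)

    qtl_here <- cfg$qtl_spec[cfg$qtl_spec$chromosome == as.character(ch), ]
    qtl_idx <- integer(0)
    if (nrow(qtl_here)) {
      qtl_idx <- vapply(qtl_here$position_bp,
                        function(p) which.min(abs(pos - p)), integer(1))
      # pin the favoured allele (coded 1) to frequency qtl_freq in founders
      for (k in seq_along(qtl_idx)) {
        n1 <- max(1L, round(cfg$qtl_freq * cfg$n_founders))
        founders[, qtl_idx[k]] <- 0L
        founders[sample(cfg$n_founders, n1), qtl_idx[k]] <- 1L
      }
    }

    switch_p <- pmin(1, cfg$recomb_rate_per_bp * gaps)
    H <- mosaic_chrom_cpp(founders, switch_p, n_haps)

    # plant hard sweeps: copy a donor founder background around the QTL
    # into a sweep_strength fraction of favoured-allele carriers
    if (nrow(qtl_here)) {
      for (k in seq_along(qtl_idx)) {
        if (!isTRUE(qtl_here$swept[k])) next
        j <- qtl_idx[k]
        donors <- which(founders[, j] == 1L)
        donor <- donors[sample.int(length(donors), 1)]
        carriers <- which(H[, j] == 1L)
        if (length(carriers) < 2)
          abort("infeasible sweep: favoured allele has < 2 carrier haplotypes")
        strength <- qtl_here$sweep_strength[k]
        chosen <- carriers[runif(length(carriers)) < strength]
        for (hrow in chosen) {
          left <- rgeom(1, 1 / (1 + cfg$sweep_extent_bp / cfg$mean_spacing_bp))
          right <- rgeom(1, 1 / (1 + cfg$sweep_extent_bp / cfg$mean_spacing_bp))
          lo <- max(1L, j - left)
          hi <- min(ncol(H), j + right)
          H[hrow, lo:hi] <- founders[donor, lo:hi]
        }
      }
      for (k in seq_along(qtl_idx)) {
        qtl_rows[[length(qtl_rows) + 1]] <- tibble(
          chromosome = as.character(ch), snp_index = qtl_idx[k],
          position_bp = pos[qtl_idx[k]],
          effect_size = qtl_here$effect_size[k],
          swept = isTRUE(qtl_here$swept[k]),
          sweep_strength = qtl_here$sweep_strength[k])
      }
    }

    maps[[ch]] <- tibble(
      marker_id = sprintf("snp_%d_%d", ch, seq_len(m)),
      chromosome = as.character(ch), position_bp = pos,
      allele_a = "A", allele_b = "B")
    hap_cols[[ch]] <- H
  }

  map_all <- bind_rows(maps)
  # haplotype code 1 = allele_b; favoured QTL allele is code 1
  alleles <- do.call(cbind, hap_cols)
  map <- marker_map(map_all$marker_id, map_all$chromosome, map_all$position_bp,
                    map_all$allele_a, map_all$allele_b)
  stopifnot(identical(map$marker_id, map_all$marker_id))
  sample_ids <- sprintf("ind_%03d", seq_len(n))
  h <- haplotype_set(map, sample_ids, alleles)
  g <- as_genotype_set(h)

  truth <- bind_rows(qtl_rows)
  y <- rnorm(n, 0, cfg$h2_like_noise_sd)
  if (nrow(truth)) {
    truth$marker_id <- vapply(seq_len(nrow(truth)), function(k) {
      sprintf("snp_%s_%d", truth$chromosome[k], truth$snp_index[k])
    }, character(1))
    genic <- rep(0, n)
    dos_b <- list()
    for (k in seq_len(nrow(truth))) {
      jj <- match(truth$marker_id[k], map$marker_id)
      d <- 2L - g$dosage[, jj]  # copies of allele_b = favoured allele
      genic <- genic + truth$effect_size[k] * d
      dos_b[[k]] <- d
    }
    y <- y + genic
    truth$realized_ve <- vapply(seq_len(nrow(truth)), function(k) {
      var(truth$effect_size[k] * dos_b[[k]]) / var(y)
    }, numeric(1))
  } else {
    truth <- tibble(chromosome = character(), snp_index = integer(),
                    position_bp = integer(), effect_size = numeric(),
                    swept = logical(), sweep_strength = numeric(),
                    marker_id = character(), realized_ve = numeric())
  }
  ph <- tibble(sample_id = sample_ids)
  ph[[cfg$trait_name]] <- y
  class(ph) <- c("phenotype_table", class(tibble()))

  list(haplotypes = h, genotypes = g, phenotypes = ph, truth = truth)
}

#' Inject missingness and failing samples into a genotype set
#'
#' Sets a random `miss_rate` fraction of calls to missing, then degrades
#' `fail_samples` randomly chosen samples to a call rate safely below the
#' 0.90 individual call-rate threshold (11% missing calls, rounded up).
#'
#' @param g A [genotype_set()].
#' @param miss_rate Background missing-call rate in `[0, 1)`.
#' @param fail_samples Number of samples to degrade (default 0).
#' @param seed Optional seed for reproducibility.
#' @return A [genotype_set()] with attribute `"failed_samples"` naming
#'   the degraded samples.
#' @export
inject_missingness_and_errors <- function(g, miss_rate, fail_samples = 0,
                                          seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate < 1, fail_samples >= 0,
            fail_samples <= length(g$sample_ids))
  run <- function() {
    d <- g$dosage
    if (miss_rate > 0)
      d[runif(length(d)) < miss_rate] <- NA_integer_
    failed <- character(0)
    if (fail_samples > 0) {
      rows <- sample(nrow(d), fail_samples)
      failed <- g$sample_ids[rows]
      n_miss <- ceiling(0.11 * ncol(d))
      for (r in rows) d[r, sample(ncol(d), n_miss)] <- NA_integer_
    }
    out <- genotype_set(g$markers, g$sample_ids, d)
    attr(out, "failed_samples") <- failed
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
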