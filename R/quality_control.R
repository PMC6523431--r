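# SNP-chip quality control.  All thresholds are strict inequalities: a
# sample or SNP sitting exactly on a cutoff is removed.  Filters run in a
# fixed order (individual call rate, SNP call rate, HWE, MAF,
# autosome/position) and each SNP is attributed to the first filter that
# removes it.

snp_callrate <- function(g) colMeans(!is.na(g$dosage))
ind_callrate <- function(g) rowMeans(!is.na(g$dosage))

#' Filter individuals by call rate
#'
#' Retains samples whose fraction of non-missing genotypes is strictly
#' greater than `min_rate`.
#'
#' @param g A [genotype_set()].
#' @param min_rate Minimum call rate (default 0.90).
#' @return Filtered [genotype_set()] with attribute `"n_removed"`.
#' @export
filter_individuals_by_callrate <- function(g, min_rate = 0.90) {
  stopifnot(min_rate > 0, min_rate <= 1)
  keep <- ind_callrate(g) > min_rate
  if (!any(keep)) abort("all samples fail the individual call-rate filter")
  out <- subset_samples(g, g$sample_ids[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter SNPs by call rate
#'
#' @param g A [genotype_set()].
#' @param min_rate Minimum SNP call rate (default 0.95); strict.
#' @return Filtered [genotype_set()] with attribute `"n_removed"`.
#' @export
filter_snps_by_callrate <- function(g, min_rate = 0.95) {
  stopifnot(min_rate > 0, min_rate <= 1)
  keep <- snp_callrate(g) > min_rate
  out <- subset_markers(g, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: enumerates every heterozygote count
#' consistent with the observed allele counts and sums the probabilities of
#' all configurations no more likely than the observed one (no mid-p
#' correction).  A monomorphic SNP returns 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (AA homozygote, heterozygote, BB
#'   homozygote).
#' @return The exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) abort("at least one genotyped individual required")
  na_ <- 2 * n_aa + n_ab
  nb_ <- 2 * n_bb + n_ab
  if (na_ == 0 || nb_ == 0) return(1)
  rare <- min(na_, nb_)
  k <- seq(rare %% 2, rare, by = 2)
  # log P(k heterozygotes | allele counts), Levene's conditional distribution
  logp <- k * log(2) + lfactorial(n) -
    lfactorial((na_ - k) / 2) - lfactorial(k) - lfactorial((nb_ - k) / 2) +
    lfactorial(na_) + lfactorial(nb_) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, k)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Filter SNPs by Hardy-Weinberg equilibrium
#'
#' Removes SNPs whose exact HWE p-value is not strictly greater than
#' `min_p` (default 1e-6), computed within the single panel.
#'
#' @param g A [genotype_set()].
#' @param min_p Significance cutoff; SNPs with `p <= min_p` are removed.
#' @return Filtered [genotype_set()] with attribute `"n_removed"`.
#' @export
filter_hwe <- function(g, min_p = 1e-6) {
  d <- g$dosage
  p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_p(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                sum(x == 0L, na.rm = TRUE))
  }, numeric(1))
  out <- subset_markers(g, p > min_p)
  attr(out, "n_removed") <- sum(p <= min_p)
  out
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `min_maf`, computed on
#' non-missing calls.
#'
#' @param g A [genotype_set()].
#' @param min_maf MAF cutoff (default 0.05); strict.
#' @return Filtered [genotype_set()] with attribute `"n_removed"`.
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  af <- allele_freq_and_maf(g)
  keep <- !is.na(af$maf) & af$maf > min_maf
  out <- subset_markers(g, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter to autosomal SNPs with known positions
#'
#' Keeps SNPs whose chromosome label parses as an integer in
#' `1:n_autosomes` (default 18, the pig autosomes) and whose position is a
#' known positive integer.
#'
#' @param g A [genotype_set()].
#' @param n_autosomes Number of autosomes.
#' @return Filtered [genotype_set()] with attribute `"n_removed"`.
#' @export
filter_autosomes <- function(g, n_autosomes = 18L) {
  num <- suppressWarnings(as.integer(g$markers$chromosome))
  keep <- !is.na(num) & num >= 1L & num <= n_autosomes &
    !is.na(g$markers$position_bp) & g$markers$position_bp >= 1L
  out <- subset_markers(g, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full quality-control cascade
#'
#' Applies, in order: (i) individual call rate > `ind_callrate`;
#' (ii) SNP call rate > `snp_callrate`; (iii) HWE exact p > `hwe_p`;
#' (iv) MAF > `maf`; (v) autosomal SNPs with known positions.  HWE and MAF
#' are recomputed after individual removal, and each SNP is counted under
#' the first filter that removes it.
#'
#' @param g A [genotype_set()].
#' @param ind_callrate,snp_callrate,hwe_p,maf,n_autosomes The five cutoffs.
#' @return A list with `genotypes` (filtered [genotype_set()]) and
#'   `report` (a `qc_report`).
#' @export
run_qc <- function(g, ind_callrate = 0.90, snp_callrate = 0.95,
                   hwe_p = 1e-6, maf = 0.05, n_autosomes = 18L) {
  n_input <- nrow(g$markers)
  g1 <- filter_individuals_by_callrate(g, ind_callrate)
  n_ind <- attr(g1, "n_removed")
  g2 <- filter_snps_by_callrate(g1, snp_callrate)
  g3 <- filter_hwe(g2, hwe_p)
  g4 <- filter_maf(g3, maf)
  g5 <- filter_autosomes(g4, n_autosomes)
  report <- structure(list(
    n_input_snps = n_input,
    n_removed_individual_callrate = n_ind,
    n_removed_snp_callrate = attr(g2, "n_removed"),
    n_removed_hwe = attr(g3, "n_removed"),
    n_removed_maf = attr(g4, "n_removed"),
    n_removed_nonautosomal_or_unmapped = attr(g5, "n_removed"),
    n_output_snps = nrow(g5$markers),
    thresholds = list(ind_callrate = ind_callrate,
                      snp_callrate = snp_callrate, hwe_p = hwe_p, maf = maf,
                      n_autosomes = n_autosomes)
  ), class = "qc_report")
  attr(g5, "n_removed") <- NULL
  list(genotypes = g5, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input SNPs:                   %d\n", x$n_input_snps))
  cat(sprintf("  individuals removed (call rate > %.2f): %d\n",
              x$thresholds$ind_callrate, x$n_removed_individual_callrate))
  cat(sprintf("  SNPs removed, call rate (> %.2f):  %d\n",
              x$thresholds$snp_callrate, x$n_removed_snp_callrate))
  cat(sprintf("  SNPs removed, HWE (p > %g):        %d\n",
              x$thresholds$hwe_p, x$n_removed_hwe))
  cat(sprintf("  SNPs removed, MAF (> %.2f):        %d\n",
              x$thresholds$maf, x$n_removed_maf))
  cat(sprintf("  SNPs removed, non-autosomal:       %d\n",
              x$n_removed_nonautosomal_or_unmapped))
  cat(sprintf("  output SNPs:                  %d\n", x$n_output_snps))
  invisible(x)
}

#' Tidy a QC report into one row per filter
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A tibble with columns `filter`, `n_removed`, `threshold`.
#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) {
  tibble(
    filter = c("individual_callrate", "snp_callrate", "hwe", "maf",
               "nonautosomal_or_unmapped"),
    n_removed = c(x$n_removed_individual_callrate, x$n_removed_snp_callrate,
                  x$n_removed_hwe, x$n_removed_maf,
                  x$n_removed_nonautosomal_or_unmapped),
    threshold = c(x$thresholds$ind_callrate, x$thresholds$snp_callrate,
                  x$thresholds$hwe_p, x$thresholds$maf,
                  x$thresholds$n_autosomes)
  )
}

#' One-row summary of a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble(n_input_snps = x$n_input_snps, n_output_snps = x$n_output_snps,
         n_removed_individuals = x$n_removed_individual_callrate)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(tidy(report), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
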