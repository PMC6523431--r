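# Per-SNP allele frequency / heterozygosity summaries and distance-binned
# linkage-disequilibrium decay.  r-squared is the squared Pearson
# correlation of genotype dosages (composite genotypic LD, the SNP-chip
# convention), not haplotype-EM r-squared.

#' Per-SNP allele frequency and minor allele frequency
#'
#' `freq_a` is the frequency of `allele_a` on non-missing calls;
#' `maf = min(freq_a, 1 - freq_a)`.  SNPs with no non-missing calls get
#' `NA` and are flagged.
#'
#' @param g A [genotype_set()].
#' @return A tibble: `marker_id`, `n_called`, `freq_a`, `maf`,
#'   `all_missing`.
#' @export
allele_freq_and_maf <- function(g) {
  d <- g$dosage
  n_called <- unname(colSums(!is.na(d)))
  freq_a <- unname(colSums(d, na.rm = TRUE)) / (2 * n_called)
  freq_a[n_called == 0] <- NA_real_
  tibble(marker_id = g$markers$marker_id, n_called = n_called,
         freq_a = freq_a, maf = pmin(freq_a, 1 - freq_a),
         all_missing = n_called == 0)
}

#' Expected heterozygosity
#'
#' `He = 2 p (1 - p)` for allele frequency `p`.
#'
#' @param freq_a Allele frequency in `[0, 1]` (vectorized).
#' @return Expected heterozygosity.
#' @export
expected_heterozygosity <- function(freq_a) {
  stopifnot(all(freq_a >= 0 & freq_a <= 1, na.rm = TRUE))
  2 * freq_a * (1 - freq_a)
}

#' Pairwise LD between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over samples non-missing
#' at both SNPs.  Undefined (NA) when either SNP has zero variance on the
#' shared samples or fewer than two shared samples exist.
#'
#' @param g A [genotype_set()].
#' @param snp_i,snp_j Marker ids or column indices.
#' @return r-squared, or `NA`.
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  ix <- if (is.character(snp_i)) match(snp_i, g$markers$marker_id) else snp_i
  jx <- if (is.character(snp_j)) match(snp_j, g$markers$marker_id) else snp_j
  if (is.na(ix) || is.na(jx)) abort("unknown marker id")
  x <- g$dosage[, ix]
  y <- g$dosage[, jx]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Distance-binned LD decay curve
#'
#' Every intra-chromosomal SNP pair at distance `<= max_dist_bp`
#' contributes its dosage r-squared to the half-open distance bin
#' `[k * bin_bp, (k+1) * bin_bp)`.  Bins with no pairs are omitted.
#' Monomorphic SNPs are excluded (their correlation is undefined).
#'
#' @param g A [genotype_set()], markers sorted by position.
#' @param max_dist_bp Maximum pair distance (default 1 Mb); the all-pairs
#'   computation is windowed to keep it tractable.
#' @param bin_bp Bin width in bp (default 1000).
#' @return A tibble: `bin_start_bp`, `bin_end_bp`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, max_dist_bp = 1e6, bin_bp = 1000) {
  map <- g$markers
  d <- g$dosage
  has_na <- anyNA(d)
  sums <- numeric(0)
  counts <- numeric(0)
  grow <- function(k) {
    if (k > length(sums)) {
      length(sums) <<- k
      length(counts) <<- k
      sums[is.na(sums)] <<- 0
      counts[is.na(counts)] <<- 0
    }
  }
  for (chrom in unique(map$chromosome)) {
    cols <- which(map$chromosome == chrom)
    if (length(cols) < 2) next
    pos <- map$position_bp[cols]
    x <- d[, cols, drop = FALSE]
    if (!has_na) {
      # standardize once; r(i, j) is then a scaled cross-product
      sdv <- apply(x, 2, sd)
      poly <- sdv > 0
      x <- scale(x[, poly, drop = FALSE])
      pos <- pos[poly]
      m <- ncol(x)
      if (m < 2) next
      nm1 <- nrow(x) - 1
      for (off in seq_len(m - 1)) {
        i <- seq_len(m - off)
        dist <- pos[i + off] - pos[i]
        keep <- dist <= max_dist_bp
        if (!any(keep)) {
          if (all(dist > max_dist_bp)) break else next
        }
        r <- colSums(x[, i[keep], drop = FALSE] *
                     x[, i[keep] + off, drop = FALSE]) / nm1
        bin <- dist[keep] %/% bin_bp + 1
        grow(max(bin))
        tb <- tapply(r^2, bin, sum)
        idx <- as.integer(names(tb))
        sums[idx] <- sums[idx] + tb
        counts[idx] <- counts[idx] + tabulate(bin, nbins = length(counts))[idx]
      }
    } else {
      m <- length(cols)
      for (a in seq_len(m - 1)) {
        for (b in (a + 1):m) {
          dist <- pos[b] - pos[a]
          if (dist > max_dist_bp) break
          r2 <- ld_r2(g, cols[a], cols[b])
          if (is.na(r2)) next
          bin <- dist %/% bin_bp + 1
          grow(bin)
          sums[bin] <- sums[bin] + r2
          counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  keep <- which(counts > 0)
  out <- tibble(bin_start_bp = (keep - 1) * bin_bp, bin_end_bp = keep * bin_bp,
                mean_r2 = sums[keep] / counts[keep], n_pairs = counts[keep])
  class(out) <- c("ld_decay_curve", class(tibble()))
  out
}

#' Write an LD decay curve as TSV
#'
#' @param curve An `ld_decay_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_decay <- function(curve, path) {
  utils::write.table(curve, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
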