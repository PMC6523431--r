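# Extended haplotype homozygosity statistics.  EHH(x) is the probability
# that two haplotypes drawn from the considered set are identical at every
# marker from the core SNP out to x; iHH is its trapezoidal integral
# against physical distance (bp), both directions summed, stopping at the
# first marker where EHH falls below the decay cutoff (that marker's
# trapezoid is included).  No genetic map is used.  Scores are left
# unstandardized throughout.

hap_chrom_split <- function(h) {
  split(seq_len(nrow(h$markers)), h$markers$chromosome)
}

#' EHH decay curve from a core SNP
#'
#' Computes extended haplotype homozygosity outward from a core marker for
#' carriers of one core allele (or for all haplotypes pooled: site-EHH).
#' The curve is 1 at the core, non-increasing with distance, and stops at
#' the first marker with EHH below `cutoff`, at the chromosome end, or at
#' an inter-marker gap larger than `max_gap_bp` (the last two set the
#' truncation flag).
#'
#' @param h A [haplotype_set()].
#' @param core Marker id of the core SNP.
#' @param core_allele 0, 1, or `NA` for pooled site-EHH.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap_bp Maximum tolerated inter-marker gap (default 200 kb).
#' @return A tibble of curve points (`position_bp`, `ehh`, starting at the
#'   core with ehh = 1) with attributes `ihh` (one-sided trapezoidal
#'   integral) and `truncated_at_chromosome_end`; `NULL` with a warning if
#'   fewer than two haplotypes carry the core allele.
#' @export
ehh <- function(h, core, core_allele = NA,
                direction = c("downstream", "upstream"),
                cutoff = 0.05, max_gap_bp = 2e5) {
  direction <- match.arg(direction)
  stopifnot(inherits(h, "haplotype_set"))
  j <- match(core, h$markers$marker_id)
  if (is.na(j)) abort(sprintf("unknown core marker '%s'", core))
  chrom <- h$markers$chromosome[j]
  cols <- which(h$markers$chromosome == chrom)
  res <- ehh_curve_cpp(h$alleles[, cols, drop = FALSE],
                       as.numeric(h$markers$position_bp[cols]),
                       match(j, cols) - 1L,
                       if (is.na(core_allele)) -1L else as.integer(core_allele),
                       if (direction == "downstream") 1L else -1L,
                       cutoff, max_gap_bp)
  if (is.null(res$ehh) && is.null(res$marker)) {
    warn(sprintf("fewer than 2 carriers of allele %s at %s; EHH undefined",
                 core_allele, core))
    return(NULL)
  }
  out <- tibble(
    position_bp = c(h$markers$position_bp[j],
                    h$markers$position_bp[cols][res$marker + 1L]),
    ehh = c(1, res$ehh)
  )
  attr(out, "core_marker") <- core
  attr(out, "core_allele") <- core_allele
  attr(out, "direction") <- direction
  attr(out, "ihh") <- res$ihh
  attr(out, "truncated_at_chromosome_end") <- res$truncated
  out
}

#' Integrated EHH from a pair of decay curves
#'
#' Trapezoidal integral of EHH against physical distance in bp, upstream
#' and downstream curves summed.  A degenerate single-point curve
#' contributes 0 for its direction.
#'
#' @param curve_up,curve_down Curves from [ehh()] sharing the same core.
#' @return The integrated EHH (bp x EHH units).
#' @export
ihh <- function(curve_up, curve_down) {
  one <- function(cv) {
    if (is.null(cv) || nrow(cv) < 2) return(0)
    sum(0.5 * (cv$ehh[-1] + cv$ehh[-nrow(cv)]) * abs(diff(cv$position_bp)))
  }
  if (!is.null(curve_up) && !is.null(curve_down) &&
      !identical(attr(curve_up, "core_marker"), attr(curve_down, "core_marker")))
    abort("curves do not share a core marker")
  one(curve_up) + one(curve_down)
}

#' Genome-wide unstandardized iHS scan
#'
#' For each retained SNP the EHH curve of each allele is integrated in
#' both directions; `ihs_unstd = log(ihh_minor / ihh_major)`, with the
#' major allele playing the ancestral role (chip data carries no ancestral
#' state; supply `ancestral` to override).  SNPs below the MAF floor, with
#' fewer than two carriers of an allele, or whose EHH is truncated by a
#' chromosome end or an oversized gap before reaching the cutoff are
#' dropped; the per-reason counts are returned as attribute `"skipped"`.
#'
#' @param h A [haplotype_set()].
#' @param maf_floor SNPs with MAF below this are excluded (default 0.05).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap_bp Maximum tolerated inter-marker gap (default 200 kb).
#' @param ancestral Optional vector (0/1, length = markers) of ancestral
#'   allele codes; when given it replaces the major allele in the
#'   denominator role.
#' @return A tibble: `marker_id`, `chromosome`, `position_bp`,
#'   `ihh_major`, `ihh_minor`, `ihs_unstd`, `abs_ihs`.
#' @export
ihs_scan <- function(h, maf_floor = 0.05, cutoff = 0.05, max_gap_bp = 2e5,
                     ancestral = NULL) {
  stopifnot(inherits(h, "haplotype_set"))
  map <- h$markers
  res <- vector("list", 0)
  skip_all <- integer(4)
  for (cols in hap_chrom_split(h)) {
    r <- ihs_chrom_cpp(h$alleles[, cols, drop = FALSE],
                       as.numeric(map$position_bp[cols]), cutoff, max_gap_bp,
                       maf_floor)
    ihh_major <- r$ihh_major
    ihh_minor <- r$ihh_minor
    if (!is.null(ancestral)) {
      anc <- ancestral[cols]
      major_is_1 <- r$freq1 > 0.5
      flip <- !is.na(anc) & (anc != as.integer(major_is_1))
      tmp <- ihh_major[flip]
      ihh_major[flip] <- ihh_minor[flip]
      ihh_minor[flip] <- tmp
    }
    skip_all <- skip_all + tabulate(r$skip, nbins = 4)[c(1, 2, 3, 4)]
    res[[length(res) + 1]] <- tibble(
      marker_id = map$marker_id[cols], chromosome = map$chromosome[cols],
      position_bp = map$position_bp[cols],
      ihh_major = ihh_major, ihh_minor = ihh_minor, skip = r$skip)
  }
  out <- bind_rows(res) %>%
    filter(.data$skip == 0L) %>%
    select(-"skip") %>%
    mutate(ihs_unstd = log(.data$ihh_minor / .data$ihh_major),
           abs_ihs = abs(.data$ihs_unstd))
  out <- out[order(chrom_order(out$chromosome), out$position_bp), ]
  attr(out, "skipped") <- c(maf_below_floor = skip_all[1],
                            too_few_carriers = skip_all[2],
                            truncated = skip_all[3])
  out
}

#' Average |iHS| in non-overlapping genomic windows
#'
#' Window `k` on each chromosome covers `[k * window_bp + 1,
#' (k + 1) * window_bp]` in 1-based coordinates; the mean `abs_ihs` of the
#' SNPs inside is reported and windows with no scored SNPs are absent.
#' Window scores get genome-wide empirical rank p-values (upper tail).
#'
#' @param t An iHS table from [ihs_scan()].
#' @param window_bp Window width (default 50,000).
#' @return A tibble: `chromosome`, `start_bp`, `end_bp`, `mean_abs_ihs`,
#'   `n_snps`, `empirical_p`.
#' @export
window_average_abs_ihs <- function(t, window_bp = 50000) {
  stopifnot(window_bp > 0)
  out <- t %>%
    mutate(win = (.data$position_bp - 1L) %/% as.integer(window_bp)) %>%
    group_by(.data$chromosome, .data$win) %>%
    summarise(mean_abs_ihs = mean(.data$abs_ihs), n_snps = n(),
              .groups = "drop") %>%
    mutate(start_bp = .data$win * as.integer(window_bp) + 1L,
           end_bp = (.data$win + 1L) * as.integer(window_bp)) %>%
    select("chromosome", "start_bp", "end_bp", "mean_abs_ihs", "n_snps")
  out$empirical_p <- empirical_p(out$mean_abs_ihs, tail = "upper")
  out <- out[order(chrom_order(out$chromosome), out$start_bp), ]
  class(out) <- c("window_score_table", class(tibble()))
  out
}

#' Genome-wide unnormalized XP-EHH scan between two populations
#'
#' At each SNP, site-EHH (both alleles pooled) is computed within the
#' observed and the reference population; the integration interval is set
#' where the EHH of the pooled two-population panel drops below `cutoff`,
#' so both populations integrate over the same interval.
#' `xpehh_unnorm = log(ihh_observed / ihh_reference)`; scores are not
#' normalized.  A positive score indicates selection in the observed
#' population.  Extensions truncated by a chromosome end or an oversized
#' gap are retained and flagged.
#'
#' @param h_obs,h_ref [haplotype_set()]s of the observed and reference
#'   populations, sharing an identical marker map.
#' @param cutoff Pooled-EHH decay cutoff (default 0.05).
#' @param max_gap_bp Maximum tolerated inter-marker gap (default 200 kb).
#' @return A tibble: `marker_id`, `chromosome`, `position_bp`,
#'   `ihh_observed`, `ihh_reference`, `xpehh_unnorm`, `truncated`.  SNPs
#'   with zero reference iHH are skipped (attribute `"n_skipped"`).
#' @export
xpehh_scan <- function(h_obs, h_ref, cutoff = 0.05, max_gap_bp = 2e5) {
  stopifnot(inherits(h_obs, "haplotype_set"), inherits(h_ref, "haplotype_set"))
  if (!identical(h_obs$markers$marker_id, h_ref$markers$marker_id) ||
      !identical(h_obs$markers$position_bp, h_ref$markers$position_bp))
    abort("observed and reference panels must share an identical marker map")
  map <- h_obs$markers
  res <- vector("list", 0)
  for (cols in hap_chrom_split(h_obs)) {
    r <- xpehh_chrom_cpp(h_obs$alleles[, cols, drop = FALSE],
                         h_ref$alleles[, cols, drop = FALSE],
                         as.numeric(map$position_bp[cols]), cutoff, max_gap_bp)
    res[[length(res) + 1]] <- tibble(
      marker_id = map$marker_id[cols], chromosome = map$chromosome[cols],
      position_bp = map$position_bp[cols], ihh_observed = r$ihh_obs,
      ihh_reference = r$ihh_ref, truncated = r$truncated, skip = r$skip)
  }
  out <- bind_rows(res)
  n_skip <- sum(out$skip != 0L)
  out <- out %>%
    filter(.data$skip == 0L) %>%
    select(-"skip") %>%
    mutate(xpehh_unnorm = log(.data$ihh_observed / .data$ihh_reference))
  out <- out[order(chrom_order(out$chromosome), out$position_bp), ]
  attr(out, "n_skipped") <- n_skip
  out
}
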