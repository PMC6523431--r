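# Per-SNP Weir & Cockerham (1984) fixation index between two populations:
# the two-level (population, individual) variance-component estimator with
# the observed-heterozygosity correction, computed per locus with no
# multi-locus ratio-of-sums averaging.  Negative estimates are retained as
# computed (not clipped to zero) so genome-wide ranking is untouched.

#' Per-SNP Weir-Cockerham F_ST between two populations
#'
#' Computes the among-population (`component_a`), among-individual
#' (`component_b`) and within-individual (`component_c`) variance
#' components and `theta = a / (a + b + c)` at every SNP.  Missing
#' genotypes are excluded per SNP per population; a SNP needs at least two
#' genotyped individuals in each population, and SNPs monomorphic across
#' both populations have undefined theta — both are excluded with a
#' reason column.
#'
#' @param g A [genotype_set()].
#' @param pop_a,pop_b Disjoint sample-id sets.
#' @return A tibble: `marker_id`, `chromosome`, `position_bp`, `theta`,
#'   `component_a`, `component_b`, `component_c`, `excluded`, `reason`.
#' @export
weir_cockerham_fst <- function(g, pop_a, pop_b) {
  stopifnot(inherits(g, "genotype_set"))
  pop_a <- as.character(pop_a)
  pop_b <- as.character(pop_b)
  if (length(intersect(pop_a, pop_b)))
    abort("pop_a and pop_b overlap")
  unknown <- setdiff(c(pop_a, pop_b), g$sample_ids)
  if (length(unknown))
    abort(sprintf("unknown sample id(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  da <- g$dosage[pop_a, , drop = FALSE]
  db <- g$dosage[pop_b, , drop = FALSE]

  stats_pop <- function(d) {
    n <- unname(colSums(!is.na(d)))
    p <- unname(colSums(d, na.rm = TRUE)) / (2 * n)
    h <- unname(colSums(d == 1L, na.rm = TRUE)) / n
    list(n = n, p = p, h = h)
  }
  sa <- stats_pop(da)
  sb <- stats_pop(db)

  r <- 2
  nbar <- (sa$n + sb$n) / r
  nc <- (r * nbar - (sa$n^2 + sb$n^2) / (r * nbar)) / (r - 1)
  pbar <- (sa$n * sa$p + sb$n * sb$p) / (r * nbar)
  s2 <- (sa$n * (sa$p - pbar)^2 + sb$n * (sb$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (sa$n * sa$h + sb$n * sb$h) / (r * nbar)

  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- ifelse(denom > 0, a / denom, NA_real_)

  too_few <- sa$n < 2 | sb$n < 2
  mono <- !too_few & (pbar <= 0 | pbar >= 1)
  reason <- rep(NA_character_, ncol(g$dosage))
  reason[mono] <- "monomorphic"
  reason[too_few] <- "fewer than 2 genotyped individuals in a population"
  excluded <- too_few | mono | is.na(theta)
  reason[excluded & is.na(reason)] <- "zero total variance"
  theta[excluded] <- NA_real_

  out <- tibble(marker_id = g$markers$marker_id,
                chromosome = g$markers$chromosome,
                position_bp = g$markers$position_bp,
                theta = theta, component_a = a, component_b = b,
                component_c = cc, excluded = excluded, reason = reason)
  class(out) <- c("fst_table", class(tibble()))
  out
}
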