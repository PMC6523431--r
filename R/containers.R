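# Matrix-backed containers for genotype and haplotype panels.  All result
# tables elsewhere in the package are tibbles; these two objects stay
# matrix-backed because per-SNP statistics need fast column access on
# panels of ~40k markers.

#' Build a marker map
#'
#' The marker map fixes the coordinate conventions used throughout the
#' package: one row per SNP with chromosome label, 1-based base-pair
#' position and the two allele labels.  `allele_a` is the first (REF)
#' allele of the source file; major/minor roles are always recomputed from
#' the data downstream, never taken from file order.
#'
#' @param marker_id Character vector of unique marker names.
#' @param chromosome Character (or coercible) chromosome labels; any
#'   `"chr"` prefix is stripped.
#' @param position_bp Positive integer positions, 1-based.
#' @param allele_a,allele_b Allele labels, distinct within each marker.
#' @return A tibble with class `marker_map`, sorted by (chromosome,
#'   position); chromosome labels that parse as integers sort numerically.
#' @export
marker_map <- function(marker_id, chromosome, position_bp, allele_a, allele_b) {
  chromosome <- sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
  map <- tibble(
    marker_id = as.character(marker_id),
    chromosome = chromosome,
    position_bp = as.integer(position_bp),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b)
  )
  if (anyDuplicated(map$marker_id))
    abort("duplicate marker_id in marker map")
  if (any(map$position_bp < 1L))
    abort("marker positions must be positive 1-based integers")
  if (any(map$allele_a == map$allele_b))
    abort("allele_a and allele_b must differ for every marker")
  map <- map[order(chrom_order(map$chromosome), map$position_bp), ]
  dup <- duplicated(map[, c("chromosome", "position_bp")])
  if (any(dup)) {
    d <- map[dup, ]
    abort(sprintf("duplicate position %s:%d in marker map",
                  d$chromosome[1], d$position_bp[1]))
  }
  class(map) <- c("marker_map", class(tibble()))
  map
}

# numeric-aware chromosome ordering ("2" before "10", non-numeric labels last)
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.integer(chrom))
  ord <- ifelse(is.na(num), rank(chrom) + 1e6, num)
  ord
}

#' Build a genotype set
#'
#' Holds a samples x markers dosage matrix counting copies of `allele_a`
#' (0, 1, 2 or `NA` for missing) together with its marker map.
#'
#' @param markers A [marker_map()].
#' @param sample_ids Unique sample identifiers.
#' @param dosage Integer matrix, `length(sample_ids)` rows and
#'   `nrow(markers)` columns, values in {0, 1, 2, NA}.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(markers, sample_ids, dosage) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) abort("sample ids must be unique")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(markers))
    abort("dosage dimensions must match sample and marker counts")
  if (any(dosage < 0L | dosage > 2L, na.rm = TRUE))
    abort("dosage values must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(sample_ids, markers$marker_id)
  structure(list(markers = markers, sample_ids = sample_ids, dosage = dosage),
            class = "genotype_set")
}

#' Build a haplotype set
#'
#' Phased panel: a (2 x samples) x markers binary matrix in which rows
#' `2i - 1` and `2i` are the two phased haplotypes of sample `i`; 0 codes
#' `allele_a`, 1 codes `allele_b`.  Phased data is complete: no missing
#' entries are allowed.
#'
#' @param markers A [marker_map()].
#' @param sample_ids Unique sample identifiers.
#' @param alleles Binary matrix with `2 * length(sample_ids)` rows.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(markers, sample_ids, alleles) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) abort("sample ids must be unique")
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids) ||
      ncol(alleles) != nrow(markers))
    abort("alleles matrix must be (2 x samples) x markers")
  if (anyNA(alleles)) abort("phased haplotypes cannot contain missing values")
  if (any(alleles != 0L & alleles != 1L)) abort("alleles must be 0/1")
  rownames(alleles) <- paste(rep(sample_ids, each = 2), 1:2, sep = "_")
  colnames(alleles) <- markers$marker_id
  structure(list(markers = markers, sample_ids = sample_ids, alleles = alleles),
            class = "haplotype_set")
}

#' Collapse a haplotype set to genotype dosages
#'
#' Sums the two phased haplotypes of each sample into a 0/1/2 dosage of
#' `allele_a` (haplotype code 0), reproducing the companion genotype set.
#'
#' @param h A [haplotype_set()].
#' @return A [genotype_set()].
#' @export
as_genotype_set <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  a <- h$alleles
  idx1 <- seq(1L, nrow(a), by = 2L)
  # code 0 = allele_a, so dosage of allele_a = 2 - (hap1 + hap2)
  dos <- 2L - (a[idx1, , drop = FALSE] + a[idx1 + 1L, , drop = FALSE])
  genotype_set(h$markers, h$sample_ids, dos)
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d samples x %d SNPs on %d chromosome(s); %d missing calls\n",
              length(x$sample_ids), nrow(x$markers),
              length(unique(x$markers$chromosome)), sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d samples (%d haplotypes) x %d SNPs on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$alleles), nrow(x$markers),
              length(unique(x$markers$chromosome))))
  invisible(x)
}

# subset helpers used across modules ---------------------------------------

subset_samples <- function(g, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, g$sample_ids)
  if (length(miss))
    abort(sprintf("unknown sample id(s): %s", paste(head(miss, 5), collapse = ", ")))
  if (inherits(g, "genotype_set")) {
    genotype_set(g$markers, ids, g$dosage[ids, , drop = FALSE])
  } else {
    rows <- as.vector(rbind(2L * match(ids, g$sample_ids) - 1L,
                            2L * match(ids, g$sample_ids)))
    haplotype_set(g$markers, ids, g$alleles[rows, , drop = FALSE])
  }
}

subset_markers <- function(g, keep) {
  map <- g$markers[keep, , drop = FALSE]
  class(map) <- class(g$markers)
  if (inherits(g, "genotype_set")) {
    genotype_set(map, g$sample_ids, g$dosage[, keep, drop = FALSE])
  } else {
    haplotype_set(map, g$sample_ids, g$alleles[, keep, drop = FALSE])
  }
}
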