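# Genotype, haplotype and phenotype I/O.  VCF parsing goes through vcfR;
# the PLINK binary trio (.bed/.bim/.fam) is read and written directly
# (SNP-major v1.00 layout).

#' Read a phased VCF into a haplotype set
#'
#' Retains biallelic SNP records only; multiallelic or non-SNP records are
#' dropped with a per-record report (attribute `"rejected"` and a message).
#' Any retained record with an unphased genotype (`/` separator) is an
#' error naming the offending `chromosome:position`.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A [haplotype_set()]; markers ordered by (chromosome, position).
#'   Attribute `"rejected"`: tibble of dropped records and reasons.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) abort("VCF contains no sample genotypes")
  samples <- colnames(gt)[-1]

  alt <- fix$ALT
  ref <- fix$REF
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  rejected <- tibble(
    chromosome = fix$CHROM[!snp], position_bp = as.integer(fix$POS[!snp]),
    reason = ifelse(grepl(",", alt[!snp]), "multiallelic", "not a SNP")
  )
  if (nrow(rejected))
    message(sprintf("read_phased_vcf: dropped %d non-biallelic-SNP record(s)",
                    nrow(rejected)))
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, -1, drop = FALSE]

  # GT is the first colon-separated field; sub/grepl drop dims, restore them
  gtf <- matrix(sub(":.*", "", gt), nrow = nrow(gt))
  unphased <- matrix(grepl("/", gtf, fixed = TRUE), nrow = nrow(gtf))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    abort(sprintf("unphased genotype at %s:%s (sample %s)",
                  fix$CHROM[i[1]], fix$POS[i[1]], samples[i[2]]))
  }
  bad <- matrix(!grepl("^[01]\\|[01]$", gtf), nrow = nrow(gtf))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed or missing phased genotype '%s' at %s:%s",
                  gtf[i[1], i[2]], fix$CHROM[i[1]], fix$POS[i[1]]))
  }

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  map <- marker_map(ids, fix$CHROM, as.integer(fix$POS), ref[snp], alt[snp])
  ord <- match(map$marker_id, ids)

  h1 <- substr(gtf, 1L, 1L) == "1"
  h2 <- substr(gtf, 3L, 3L) == "1"
  n <- length(samples)
  m <- nrow(fix)
  alleles <- matrix(0L, nrow = 2L * n, ncol = m)
  alleles[seq(1L, 2L * n, 2L), ] <- t(matrix(as.integer(h1), m, n))
  alleles[seq(2L, 2L * n, 2L), ] <- t(matrix(as.integer(h2), m, n))
  out <- haplotype_set(map, samples, alleles[, ord, drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

#' Write a haplotype set as a phased VCF
#'
#' @param h A [haplotype_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  stopifnot(inherits(h, "haplotype_set"))
  map <- h$markers
  n <- length(h$sample_ids)
  i1 <- seq(1L, 2L * n, 2L)
  gt <- matrix(paste0(t(h$alleles[i1, , drop = FALSE]), "|",
                      t(h$alleles[i1 + 1L, , drop = FALSE])),
               nrow = nrow(map))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=gradscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", h$sample_ids), collapse = "\t"),
    paste(map$chromosome, map$position_bp, map$marker_id, map$allele_a,
          map$allele_b, ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLINK binary fileset into a genotype set
#'
#' Reads the `.bed`/`.bim`/`.fam` trio (SNP-major v1.00 layout).  Dosage
#' counts copies of `allele_a`, defined as the A1 allele of the `.bim`
#' file; the PLINK missing code maps to `NA`.
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @return A [genotype_set()].
#' @export
read_plink_binary <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) abort(sprintf("missing PLINK file(s): %s",
                                  paste(miss, collapse = ", ")))
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    abort("not a PLINK .bed file (bad magic number)")
  if (raw[3] != as.raw(0x01))
    abort("only SNP-major .bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    abort(sprintf(".bed size does not match .bim/.fam dimensions (%d samples, %d SNPs)",
                  n, m))
  # decode 2-bit genotypes: 00 hom A1, 10 het, 11 hom A2, 01 missing
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)
  two_bit <- bits[seq(1L, 8L, 2L), , drop = FALSE] +
    2L * bits[seq(2L, 8L, 2L), , drop = FALSE]
  geno <- matrix(as.vector(two_bit), nrow = bytes_per_snp * 4L)[1:n, , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m)
  dosage[geno == 0L] <- 2L  # hom A1
  dosage[geno == 2L] <- 1L  # het
  dosage[geno == 3L] <- 0L  # hom A2
  map <- marker_map(bim$id, bim$chrom, bim$pos, bim$a1, bim$a2)
  ord <- match(map$marker_id, bim$id)
  genotype_set(map, fam[[2]], dosage[, ord, drop = FALSE])
}

#' Write a genotype set as a PLINK binary fileset
#'
#' @param g A [genotype_set()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_set"))
  map <- g$markers
  utils::write.table(
    data.frame(map$chromosome, map$marker_id, 0L, map$position_bp,
               map$allele_a, map$allele_b),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame("FAM", g$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  n <- length(g$sample_ids)
  bytes_per_snp <- ceiling(n / 4)
  code <- matrix(1L, nrow = bytes_per_snp * 4L, ncol = ncol(g$dosage))  # missing
  d <- g$dosage
  codes <- matrix(1L, nrow(d), ncol(d))
  codes[!is.na(d) & d == 2L] <- 0L
  codes[!is.na(d) & d == 1L] <- 2L
  codes[!is.na(d) & d == 0L] <- 3L
  code[1:n, ] <- codes
  lo <- code %% 2L
  hi <- code %/% 2L
  bits <- matrix(0L, nrow = 8L, ncol = bytes_per_snp * ncol(d))
  bits[seq(1L, 8L, 2L), ] <- matrix(as.vector(lo), nrow = 4L)
  bits[seq(2L, 8L, 2L), ] <- matrix(as.vector(hi), nrow = 4L)
  body <- packBits(as.logical(bits), type = "raw")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), body), paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read a sample-by-trait phenotype table
#'
#' The first column (or the column named by `id_col`) holds sample ids;
#' every other column is a quantitative trait.  Missing values use
#' `na` (default `"NA"`); any other non-numeric cell is an error naming
#' its row and column.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param id_col Name of the sample-id column; default: first column.
#' @param na Missing-value token.
#' @return A tibble with class `phenotype_table`: `sample_id` plus one
#'   numeric column per trait, names preserved verbatim.
#' @export
read_phenotypes <- function(path, id_col = NULL, na = "NA") {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) abort("phenotype table needs a sample-id column and >= 1 trait column")
  if (is.null(id_col)) id_col <- names(raw)[1]
  if (!id_col %in% names(raw)) abort(sprintf("no column named '%s'", id_col))
  traits <- setdiff(names(raw), id_col)
  out <- tibble(sample_id = as.character(raw[[id_col]]))
  for (tr in traits) {
    cell <- raw[[tr]]
    cell[cell == na] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      abort(sprintf("non-numeric phenotype value '%s' at row %d, column '%s'",
                    cell[bad[1]], bad[1], tr))
    out[[tr]] <- num
  }
  if (anyDuplicated(out$sample_id)) abort("duplicate sample ids in phenotype table")
  class(out) <- c("phenotype_table", class(tibble()))
  out
}

#' Write a phenotype table
#'
#' @param ph A phenotype table (tibble with `sample_id` first).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.table(ph, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Match phenotyped samples against a genotype or haplotype panel
#'
#' @param ph A phenotype table.
#' @param g A [genotype_set()] or [haplotype_set()].
#' @return A list with `matched` (ids in both) and `unmatched` (phenotyped
#'   ids absent from the panel).
#' @export
match_samples <- function(ph, g) {
  ids <- ph$sample_id
  list(matched = intersect(ids, g$sample_ids),
       unmatched = setdiff(ids, g$sample_ids))
}
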