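# Empirical-rank p-values, top-1% thresholding, the two-part
# trait-specific criterion across the three gradient pairs, direction
# labels, and genomic region arithmetic.  Interval merging, flanking and
# overlap run on IRanges; coordinates are 1-based inclusive internally and
# BED files are 0-based half-open.

#' Empirical rank p-values
#'
#' Ranks statistics genome-wide (upper tail, or by absolute value) and
#' returns `p = rank / N` with rank 1 the most extreme; ties share the
#' smallest rank of their block.  `NA` statistics get `NA` p-values and do
#' not count toward `N`.
#'
#' @param statistics Numeric vector of per-SNP (or per-window) statistics.
#' @param tail `"upper"` (large values extreme, e.g. F_ST) or
#'   `"absolute"` (both tails, e.g. XP-EHH and iHS).
#' @return Vector of empirical p-values in `(0, 1]`.
#' @export
empirical_p <- function(statistics, tail = c("upper", "absolute")) {
  tail <- match.arg(tail)
  s <- if (tail == "absolute") abs(statistics) else statistics
  ok <- !is.na(s)
  p <- rep(NA_real_, length(s))
  if (!any(ok)) return(p)
  p[ok] <- rank(-s[ok], ties.method = "min") / sum(ok)
  p
}

#' Number of items in the top fraction under the rank/N rule
#'
#' `floor(fraction * n)` is the count of items with `p <= fraction` when
#' `p = rank / N` and values are distinct.
#'
#' @param n Number of ranked items.
#' @param fraction Tail fraction (default 0.01, the top 1%).
#' @return Integer count.
#' @export
top_fraction_count <- function(n, fraction = 0.01) {
  stopifnot(n >= 1, fraction > 0, fraction <= 1)
  as.integer(floor(fraction * n + 1e-9))
}

#' Call trait-specific selection signatures across the three pairs
#'
#' A SNP is called when (a) its empirical p-value is `<= alpha` at all
#' three gradient levels and (b) the statistic follows a strict gradient:
#' for F_ST, `s1 < s2 < s3`; for XP-EHH, a constant sign with
#' `|s1| < |s2| < |s3|` (a sign flip would mean the selected population
#' changes between levels).  The direction of selection comes from the
#' XP-EHH sign — positive means the observed (low-phenotype) population,
#' labelled `"low"`; negative means the reference (high-phenotype)
#' population, labelled `"high"`.  F_ST carries no direction (`NA`).
#'
#' @param scans List of three tibbles (levels 1, 2, 3), each with
#'   `marker_id`, `statistic`, `empirical_p` over the same marker
#'   universe.  See [as_scan_table()].
#' @param alpha Significance level (default 0.01, the top 1%).
#' @param method `"FST"` or `"XPEHH"`.
#' @param trait Trait label carried into the result.
#' @return An object of class `signature_set`: list with `trait`,
#'   `method`, `alpha`, `snps` (tibble: `marker_id`, `s1`, `s2`, `s3`,
#'   `p1`, `p2`, `p3`, `direction`) and `regions` (`NULL` until
#'   [merge_signatures()]).
#' @export
call_trait_specific <- function(scans, alpha = 0.01,
                                method = c("FST", "XPEHH"), trait = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(scans) == 3)
  ids <- scans[[1]]$marker_id
  for (k in 2:3)
    if (!setequal(ids, scans[[k]]$marker_id))
      abort("the three scan tables must share a marker universe")
  m2 <- match(ids, scans[[2]]$marker_id)
  m3 <- match(ids, scans[[3]]$marker_id)
  s1 <- scans[[1]]$statistic
  s2 <- scans[[2]]$statistic[m2]
  s3 <- scans[[3]]$statistic[m3]
  p1 <- scans[[1]]$empirical_p
  p2 <- scans[[2]]$empirical_p[m2]
  p3 <- scans[[3]]$empirical_p[m3]
  sig <- !is.na(p1) & !is.na(p2) & !is.na(p3) &
    p1 <= alpha & p2 <= alpha & p3 <= alpha
  if (method == "FST") {
    grad <- s1 < s2 & s2 < s3
    direction <- NA_character_
  } else {
    grad <- sign(s1) == sign(s2) & sign(s2) == sign(s3) & sign(s1) != 0 &
      abs(s1) < abs(s2) & abs(s2) < abs(s3)
    direction <- ifelse(s3 > 0, "low", "high")
  }
  called <- sig & !is.na(grad) & grad
  snps <- tibble(marker_id = ids, s1 = s1, s2 = s2, s3 = s3,
                 p1 = p1, p2 = p2, p3 = p3,
                 direction = if (method == "FST") NA_character_ else direction)
  snps <- snps[called, ]
  structure(list(trait = trait, method = method, alpha = alpha,
                 snps = snps, regions = NULL),
            class = "signature_set")
}

#' Helper: package a statistic vector as a scan table
#'
#' @param marker_id Marker ids.
#' @param statistic Per-SNP statistic values.
#' @param tail Passed to [empirical_p()].
#' @return A tibble with `marker_id`, `statistic`, `empirical_p`.
#' @export
as_scan_table <- function(marker_id, statistic, tail = c("upper", "absolute")) {
  tibble(marker_id = marker_id, statistic = statistic,
         empirical_p = empirical_p(statistic, tail))
}

# internal: tibble of regions from positions clustered at pairwise gap <= merge_bp
cluster_positions <- function(chrom, pos, ids, merge_bp) {
  ord <- order(chrom_order(chrom), pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  ids <- ids[ord]
  new_region <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                          diff(pos) > merge_bp)
  region <- cumsum(new_region)
  tibble(chrom = chrom, pos = pos, marker_id = ids, region_id = region) %>%
    group_by(.data$region_id) %>%
    summarise(chromosome = .data$chrom[1], start_bp = min(.data$pos),
              end_bp = max(.data$pos), n_snps = n(),
              member_snps = list(.data$marker_id), .groups = "drop") %>%
    select("region_id", "chromosome", "start_bp", "end_bp", "n_snps",
           "member_snps")
}

#' Merge called SNPs into signature regions
#'
#' Same-chromosome called SNPs whose consecutive position gaps are
#' `<= merge_bp` chain into one region (single-linkage) spanning the
#' minimum to maximum member position.
#'
#' @param s A `signature_set` from [call_trait_specific()].
#' @param m A [marker_map()] providing SNP positions.
#' @param merge_bp Maximum chaining gap (default 400,000).
#' @return The `signature_set` with `regions` filled in and a `region_id`
#'   column added to `snps`.
#' @export
merge_signatures <- function(s, m, merge_bp = 400000) {
  stopifnot(inherits(s, "signature_set"))
  idx <- match(s$snps$marker_id, m$marker_id)
  if (anyNA(idx)) abort("called SNP missing from the marker map")
  if (nrow(s$snps) == 0) {
    s$regions <- tibble(region_id = integer(), chromosome = character(),
                        start_bp = integer(), end_bp = integer(),
                        n_snps = integer(), member_snps = list())
    return(s)
  }
  reg <- cluster_positions(m$chromosome[idx], m$position_bp[idx],
                           s$snps$marker_id, merge_bp)
  memb <- tidyr::unnest(reg[, c("region_id", "member_snps")],
                        "member_snps")
  s$snps$region_id <- memb$region_id[match(s$snps$marker_id,
                                           memb$member_snps)]
  s$regions <- reg
  s
}

#' Flank signature regions and union overlaps
#'
#' Extends every region by `flank_bp` on both sides (floored at position
#' 1) and unions overlapping or touching extended regions.
#'
#' @param s A `signature_set` with regions, or a region tibble
#'   (`chromosome`, `start_bp`, `end_bp`).
#' @param flank_bp Flank size (default 200,000).
#' @return A tibble of flanked regions: `chromosome`, `start_bp`,
#'   `end_bp`.
#' @export
flank_regions <- function(s, flank_bp = 200000) {
  reg <- if (inherits(s, "signature_set")) s$regions else s
  if (is.null(reg)) abort("regions not computed; run merge_signatures() first")
  if (nrow(reg) == 0)
    return(tibble(chromosome = character(), start_bp = integer(),
                  end_bp = integer()))
  out <- lapply(split(reg, reg$chromosome), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, as.integer(r$start_bp - flank_bp)),
      end = as.integer(r$end_bp + flank_bp)))
    tibble(chromosome = r$chromosome[1], start_bp = IRanges::start(ir),
           end_bp = IRanges::end(ir))
  })
  out <- bind_rows(out)
  out[order(chrom_order(out$chromosome), out$start_bp), ]
}

#' Call significant iHS windows and merge them into regions
#'
#' Windows whose mean |iHS| falls in the top `(100 - percentile)%` by
#' empirical rank (p `<= 0.01` for the 99th percentile) are significant;
#' significant windows within `merge_bp` of each other (edge gap) merge
#' into one region.
#'
#' @param w A window score table from [window_average_abs_ihs()].
#' @param percentile Significance percentile (default 99).
#' @param merge_bp Maximum merge gap between window edges (default
#'   200,000).
#' @return A list with `significant` (the significant window rows) and
#'   `regions` (tibble `chromosome`, `start_bp`, `end_bp`, `n_windows`).
#' @export
call_ihs_regions <- function(w, percentile = 99, merge_bp = 200000) {
  stopifnot(nrow(w) >= 1)
  alpha <- (100 - percentile) / 100
  sig <- w[!is.na(w$empirical_p) & w$empirical_p <= alpha, ]
  if (nrow(sig) == 0)
    return(list(significant = sig,
                regions = tibble(chromosome = character(),
                                 start_bp = integer(), end_bp = integer(),
                                 n_windows = integer())))
  out <- lapply(split(sig, sig$chromosome), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start_bp, end = r$end_bp),
                          min.gapwidth = merge_bp + 1)
    ov <- IRanges::findOverlaps(IRanges::IRanges(r$start_bp, r$end_bp), ir)
    tibble(chromosome = r$chromosome[1], start_bp = IRanges::start(ir),
           end_bp = IRanges::end(ir),
           n_windows = tabulate(S4Vectors::subjectHits(ov), length(ir)))
  })
  reg <- bind_rows(out)
  list(significant = sig,
       regions = reg[order(chrom_order(reg$chromosome), reg$start_bp), ])
}

#' Overlap regions with annotation intervals
#'
#' Reports every (region, annotation) pair sharing at least 1 bp, using
#' half-open arithmetic at BED boundaries (a region ending where an
#' interval starts does not overlap it).
#'
#' @param regions Tibble with `chromosome`, `start_bp`, `end_bp` (1-based
#'   inclusive).
#' @param annotation Tibble as returned by [read_bed()] (1-based
#'   inclusive internally), with `chromosome`, `start_bp`, `end_bp` and
#'   optionally `name`.
#' @return A tibble of overlapping pairs with overlap widths.
#' @export
overlap_annotation <- function(regions, annotation) {
  if (nrow(regions) == 0 || nrow(annotation) == 0)
    return(tibble(chromosome = character(), region_start_bp = integer(),
                  region_end_bp = integer(), annotation_start_bp = integer(),
                  annotation_end_bp = integer(), annotation_name = character(),
                  overlap_bp = integer()))
  ann_name <- if ("name" %in% names(annotation)) annotation$name
              else rep(NA_character_, nrow(annotation))
  out <- lapply(unique(regions$chromosome), function(ch) {
    r <- regions[regions$chromosome == ch, ]
    a_idx <- which(annotation$chromosome == ch)
    if (!length(a_idx)) return(NULL)
    a <- annotation[a_idx, ]
    hits <- IRanges::findOverlaps(IRanges::IRanges(r$start_bp, r$end_bp),
                                  IRanges::IRanges(a$start_bp, a$end_bp))
    if (!length(hits)) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble(chromosome = ch,
           region_start_bp = r$start_bp[qi], region_end_bp = r$end_bp[qi],
           annotation_start_bp = a$start_bp[si],
           annotation_end_bp = a$end_bp[si],
           annotation_name = ann_name[a_idx][si],
           overlap_bp = pmin(r$end_bp[qi], a$end_bp[si]) -
             pmax(r$start_bp[qi], a$start_bp[si]) + 1L)
  })
  bind_rows(out)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s, trait %s, alpha %g: %d SNP(s)%s\n",
              x$method, x$trait, x$alpha, nrow(x$snps),
              if (is.null(x$regions)) "" else
                sprintf(", %d region(s)", nrow(x$regions))))
  invisible(x)
}

#' Tidy a signature set into its SNP table
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return The called-SNP tibble.
#' @exportS3Method generics::tidy
tidy.signature_set <- function(x, ...) x$snps

#' One-row summary of a signature set
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return A one-row tibble with trait, method, alpha, SNP and region
#'   counts.
#' @exportS3Method generics::glance
glance.signature_set <- function(x, ...) {
  tibble(trait = x$trait, method = x$method, alpha = x$alpha,
         n_snps = nrow(x$snps),
         n_regions = if (is.null(x$regions)) NA_integer_ else nrow(x$regions),
         n_direction_low = sum(x$snps$direction == "low", na.rm = TRUE),
         n_direction_high = sum(x$snps$direction == "high", na.rm = TRUE))
}

# BED I/O -------------------------------------------------------------------

#' Read a BED file of annotation intervals
#'
#' BED is 0-based half-open; internally coordinates are 1-based
#' inclusive, so `start_bp = start0 + 1` and `end_bp = end0`.
#'
#' @param path Path to a 3+ column BED file.
#' @return A tibble: `chromosome`, `start_bp`, `end_bp`, `name` (when
#'   present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3)
  if (length(bad)) abort(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]))
  start0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad)) abort(sprintf("malformed BED line %d: bad coordinates", bad[1]))
  out <- tibble(
    chromosome = sub("^chr", "", vapply(parts, `[[`, "", 1), ignore.case = TRUE),
    start_bp = start0 + 1L, end_bp = end0)
  if (all(n_fields >= 4)) out$name <- vapply(parts, `[[`, "", 4)
  out
}

#' Write regions as a BED file
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions Tibble with `chromosome`, `start_bp`, `end_bp` and
#'   optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chromosome, regions$start_bp - 1L, regions$end_bp)
  if ("name" %in% names(regions)) df$name <- regions$name
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a signature set as TSV (plus optional BED of regions)
#'
#' @param s A `signature_set`.
#' @param path Output TSV path for the SNP table.
#' @param bed_path Optional BED path for the merged regions.
#' @param m Optional [marker_map()] to add chromosome/position columns.
#' @return `path`, invisibly.
#' @export
write_signature_set <- function(s, path, bed_path = NULL, m = NULL) {
  snps <- s$snps
  if (!is.null(m)) {
    idx <- match(snps$marker_id, m$marker_id)
    snps <- mutate(snps, chromosome = m$chromosome[idx],
                   position_bp = m$position_bp[idx], .after = "marker_id")
  }
  utils::write.table(snps, path, quote = FALSE, sep = "\t", row.names = FALSE)
  if (!is.null(bed_path) && !is.null(s$regions))
    write_bed(s$regions, bed_path)
  invisible(path)
}
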