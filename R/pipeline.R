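# End-to-end orchestration: QC on genotype files, then per-trait gradient
# pairs -> per-level F_ST and XP-EHH scans -> empirical p-values ->
# trait-specific calls -> region merging and flanking, plus one
# panel-wide iHS window scan.  The XP-EHH population roles follow the
# fixed pipeline convention: observed = low-phenotype subpopulation,
# reference = high-phenotype subpopulation, so positive scores mean
# selection toward the low phenotype.

#' Scan one trait across the three gradient pairs
#'
#' @param h A [haplotype_set()] (post-QC, phased).
#' @param ph A phenotype table covering the panel samples.
#' @param trait Trait column name.
#' @param sizes Optional per-side level sizes (default
#'   [gradient_sizes()]).
#' @param alpha Empirical significance level (default 0.01).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param max_gap_bp Maximum tolerated inter-marker gap (default 200 kb).
#' @param merge_bp Signature merge distance (default 400 kb).
#' @param flank_bp Region flank (default 200 kb).
#' @param g Optional companion [genotype_set()]; derived from `h` when
#'   absent.
#' @return A list of class `trait_scan`: `pairs` (`gradient_pairs`),
#'   `fst_scans`, `xpehh_scans` (per-level scan tibbles), `fst`, `xpehh`
#'   (`signature_set`s with regions), `fst_regions_flanked`,
#'   `xpehh_regions_flanked`, and `joint_regions` (flanked-region
#'   intersection of the two methods).
#' @export
scan_trait <- function(h, ph, trait, sizes = NULL, alpha = 0.01,
                       cutoff = 0.05, max_gap_bp = 2e5, merge_bp = 4e5,
                       flank_bp = 2e5, g = NULL) {
  stopifnot(inherits(h, "haplotype_set"))
  if (is.null(g)) g <- as_genotype_set(h)
  ph_use <- ph[ph$sample_id %in% h$sample_ids, ]
  pairs <- make_gradient_pairs(ph_use, trait, sizes)

  fst_scans <- list()
  xp_scans <- list()
  for (lev in 1:3) {
    hi <- pair_ids(pairs, lev, "high")
    lo <- pair_ids(pairs, lev, "low")
    fst <- weir_cockerham_fst(g, hi, lo)
    fst_scans[[lev]] <- tibble(marker_id = fst$marker_id,
                               statistic = fst$theta,
                               empirical_p = empirical_p(fst$theta, "upper"))
    xp <- xpehh_scan(subset_samples(h, lo), subset_samples(h, hi),
                     cutoff = cutoff, max_gap_bp = max_gap_bp)
    stat <- setNames(xp$xpehh_unnorm, xp$marker_id)[g$markers$marker_id]
    xp_scans[[lev]] <- tibble(marker_id = g$markers$marker_id,
                              statistic = unname(stat),
                              empirical_p = empirical_p(unname(stat), "absolute"))
  }

  fst_set <- merge_signatures(
    call_trait_specific(fst_scans, alpha, "FST", trait), h$markers, merge_bp)
  xp_set <- merge_signatures(
    call_trait_specific(xp_scans, alpha, "XPEHH", trait), h$markers, merge_bp)
  fst_fl <- flank_regions(fst_set, flank_bp)
  xp_fl <- flank_regions(xp_set, flank_bp)
  joint <- intersect_regions(fst_fl, xp_fl)

  structure(list(trait = trait, pairs = pairs, fst_scans = fst_scans,
                 xpehh_scans = xp_scans, fst = fst_set, xpehh = xp_set,
                 fst_regions_flanked = fst_fl, xpehh_regions_flanked = xp_fl,
                 joint_regions = joint),
            class = "trait_scan")
}

#' Intersect two region tables
#'
#' Returns the base-pair intersection of two region sets (used for loci
#' detected by both scan methods simultaneously).
#'
#' @param a,b Tibbles with `chromosome`, `start_bp`, `end_bp`.
#' @return A tibble of intersected regions.
#' @export
intersect_regions <- function(a, b) {
  ov <- overlap_annotation(a, b)
  if (nrow(ov) == 0)
    return(tibble(chromosome = character(), start_bp = integer(),
                  end_bp = integer()))
  tibble(chromosome = ov$chromosome,
         start_bp = pmax(ov$region_start_bp, ov$annotation_start_bp),
         end_bp = pmin(ov$region_end_bp, ov$annotation_end_bp)) %>%
    arrange(chrom_order(.data$chromosome), .data$start_bp)
}

#' @export
print.trait_scan <- function(x, ...) {
  cat(sprintf("<trait_scan> %s: %d FST and %d XPEHH trait-specific SNP(s), %d joint region(s)\n",
              x$trait, nrow(x$fst$snps), nrow(x$xpehh$snps),
              nrow(x$joint_regions)))
  invisible(x)
}

#' One-row summary of a trait scan
#'
#' @param x A `trait_scan`.
#' @param ... Unused.
#' @return A one-row tibble of call counts.
#' @exportS3Method generics::glance
glance.trait_scan <- function(x, ...) {
  tibble(trait = x$trait, n_fst_snps = nrow(x$fst$snps),
         n_xpehh_snps = nrow(x$xpehh$snps),
         n_fst_regions = nrow(x$fst$regions),
         n_xpehh_regions = nrow(x$xpehh$regions),
         n_joint_regions = nrow(x$joint_regions))
}

#' Run configuration
#'
#' Bundles every pipeline threshold, defaulted to the reference design's values,
#' with input/output paths.  Round-trips losslessly through YAML.
#'
#' @param vcf,plink_prefix,phenotypes,annotation_bed,out_dir Paths.
#' @param traits Character vector of trait columns to scan.
#' @param ind_callrate,snp_callrate,hwe_p,maf,n_autosomes QC cutoffs.
#' @param alpha Empirical significance level.
#' @param ehh_cutoff EHH decay cutoff.
#' @param max_gap_bp Maximum inter-marker gap.
#' @param window_bp iHS window width.
#' @param ihs_percentile iHS window significance percentile.
#' @param ihs_merge_bp iHS window merge distance.
#' @param merge_bp Signature merge distance.
#' @param flank_bp Region flank.
#' @param seed Seed for any randomized step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, plink_prefix = NULL, phenotypes = NULL,
                       annotation_bed = NULL, out_dir = ".",
                       traits = character(),
                       ind_callrate = 0.90, snp_callrate = 0.95,
                       hwe_p = 1e-6, maf = 0.05, n_autosomes = 18L,
                       alpha = 0.01, ehh_cutoff = 0.05, max_gap_bp = 2e5,
                       window_bp = 5e4, ihs_percentile = 99,
                       ihs_merge_bp = 2e5, merge_bp = 4e5, flank_bp = 2e5,
                       seed = 1L) {
  structure(list(vcf = vcf, plink_prefix = plink_prefix,
                 phenotypes = phenotypes, annotation_bed = annotation_bed,
                 out_dir = out_dir, traits = traits,
                 ind_callrate = ind_callrate, snp_callrate = snp_callrate,
                 hwe_p = hwe_p, maf = maf, n_autosomes = as.integer(n_autosomes),
                 alpha = alpha, ehh_cutoff = ehh_cutoff,
                 max_gap_bp = max_gap_bp, window_bp = window_bp,
                 ihs_percentile = ihs_percentile, ihs_merge_bp = ihs_merge_bp,
                 merge_bp = merge_bp, flank_bp = flank_bp,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' File-level QC command
#'
#' Reads genotypes (PLINK binary trio), runs the QC cascade, writes the
#' filtered fileset and a TSV report, and logs every threshold and count.
#'
#' @param config A `run_config` with `plink_prefix` and `out_dir` set.
#' @return The `qc_report`, invisibly.
#' @export
pipeline_qc <- function(config) {
  if (is.null(config$plink_prefix))
    abort("config$plink_prefix is required for QC")
  g <- read_plink_binary(config$plink_prefix)
  res <- run_qc(g, config$ind_callrate, config$snp_callrate, config$hwe_p,
                config$maf, config$n_autosomes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_plink_binary(res$genotypes, file.path(config$out_dir, "qc_filtered"))
  write_qc_report(res$report, file.path(config$out_dir, "qc_report.tsv"))
  message(sprintf(
    "QC: %d -> %d SNPs (call rate > %.2f / > %.2f, HWE p > %g, MAF > %.2f, %d autosomes); %d individual(s) removed",
    res$report$n_input_snps, res$report$n_output_snps, config$ind_callrate,
    config$snp_callrate, config$hwe_p, config$maf, config$n_autosomes,
    res$report$n_removed_individual_callrate))
  invisible(res$report)
}

#' File-level scan command
#'
#' Reads a phased VCF and phenotype table, scans every configured trait
#' (gradient pairs, F_ST, XP-EHH, trait-specific calls, merged and
#' flanked regions), runs the panel-wide iHS window scan, and writes TSV
#' and BED outputs into `out_dir`.  Deterministic given inputs and
#' config.
#'
#' @param config A `run_config` with `vcf`, `phenotypes`, `traits` set.
#' @return Invisibly, a list with per-trait `trait_scan`s and the iHS
#'   window table and regions.
#' @export
pipeline_scan <- function(config) {
  for (field in c("vcf", "phenotypes")) {
    if (is.null(config[[field]]))
      abort(sprintf("config$%s is required for the scan", field))
    if (!file.exists(config[[field]]))
      abort(sprintf("input file not found: %s", config[[field]]))
  }
  h <- read_phased_vcf(config$vcf)
  ph <- read_phenotypes(config$phenotypes)
  missing_traits <- setdiff(config$traits, names(ph))
  if (length(missing_traits))
    abort(sprintf("trait(s) not in phenotype table: %s",
                  paste(missing_traits, collapse = ", ")))
  unmatched <- match_samples(ph, h)$unmatched
  if (length(unmatched))
    message(sprintf("%d phenotyped sample(s) not in the genotype panel: %s",
                    length(unmatched), paste(head(unmatched, 5), collapse = ", ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ihs <- ihs_scan(h, cutoff = config$ehh_cutoff,
                  max_gap_bp = config$max_gap_bp)
  win <- window_average_abs_ihs(ihs, config$window_bp)
  ihs_reg <- call_ihs_regions(win, config$ihs_percentile, config$ihs_merge_bp)
  utils::write.table(win, file.path(config$out_dir, "ihs_windows.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  write_bed(ihs_reg$regions, file.path(config$out_dir, "ihs_regions.bed"))

  scans <- list()
  for (trait in config$traits) {
    ts <- scan_trait(h, ph, trait, alpha = config$alpha,
                     cutoff = config$ehh_cutoff,
                     max_gap_bp = config$max_gap_bp,
                     merge_bp = config$merge_bp, flank_bp = config$flank_bp)
    scans[[trait]] <- ts
    pre <- file.path(config$out_dir, trait)
    write_gradient_pairs(ts$pairs, paste0(pre, "_pairs.tsv"))
    write_signature_set(ts$fst, paste0(pre, "_fst_signatures.tsv"),
                        paste0(pre, "_fst_regions.bed"), h$markers)
    write_signature_set(ts$xpehh, paste0(pre, "_xpehh_signatures.tsv"),
                        paste0(pre, "_xpehh_regions.bed"), h$markers)
    write_bed(ts$joint_regions, paste0(pre, "_joint_regions.bed"))
    message(sprintf("trait %s: %d FST, %d XPEHH trait-specific SNP(s) at alpha %g",
                    trait, nrow(ts$fst$snps), nrow(ts$xpehh$snps),
                    config$alpha))
  }

  if (!is.null(config$annotation_bed)) {
    ann <- read_bed(config$annotation_bed)
    for (trait in names(scans)) {
      ov <- overlap_annotation(scans[[trait]]$joint_regions, ann)
      utils::write.table(ov,
        file.path(config$out_dir, paste0(trait, "_annotation_overlap.tsv")),
        quote = FALSE, sep = "\t", row.names = FALSE)
    }
  }
  invisible(list(traits = scans, ihs_windows = win,
                 ihs_regions = ihs_reg$regions))
}
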