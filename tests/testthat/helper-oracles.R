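# Independent oracles and fixture builders.  Each oracle re-derives the
# quantity through a different route than the package implementation so
# the two can disagree.

# small haplotype panel from an explicit matrix (rows = haplotypes)
tiny_hapset <- function(mat, pos, chrom = "1") {
  n <- nrow(mat) / 2
  haplotype_set(
    marker_map(paste0("m", seq_len(ncol(mat))), rep(chrom, ncol(mat)), pos,
               rep("A", ncol(mat)), rep("B", ncol(mat))),
    paste0("s", seq_len(n)), mat)
}

tiny_genoset <- function(dosage, pos = NULL, chrom = "1") {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_set(
    marker_map(paste0("m", seq_len(m)), rep(chrom, m), pos,
               rep("A", m), rep("B", m)),
    paste0("s", seq_len(nrow(dosage))), dosage)
}

random_hap_matrix <- function(n_haps, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  matrix(rbinom(n_haps * m, 1, rep(p, each = n_haps)), nrow = n_haps)
}

# --- Weir & Cockerham F_ST through the allele-level ANOVA route ----------
# (mean squares between populations / between individuals / within
# individuals; algebraically equivalent to the direct a, b, c formulas but
# coded independently)
fst_anova_oracle <- function(dos_a, dos_b) {
  dos_a <- dos_a[!is.na(dos_a)]
  dos_b <- dos_b[!is.na(dos_b)]
  r <- 2
  n1 <- length(dos_a); n2 <- length(dos_b)
  N <- n1 + n2
  p1 <- mean(dos_a) / 2; p2 <- mean(dos_b) / 2
  pbar <- (n1 * p1 + n2 * p2) / N
  # allele-copy means per individual are dosage/2
  ss_pop <- 2 * (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)
  ss_ind <- 2 * (sum((dos_a / 2 - p1)^2) + sum((dos_b / 2 - p2)^2))
  ss_within <- (sum(dos_a == 1) + sum(dos_b == 1)) / 2
  ms_pop <- ss_pop / (r - 1)
  ms_ind <- ss_ind / (N - r)
  ms_within <- ss_within / N
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  a <- (ms_pop - ms_ind) / (2 * nc)
  b <- (ms_ind - ms_within) / 2
  cc <- ms_within
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# --- EHH / iHH by exhaustive pair counting -------------------------------
# identity checked pair-by-pair over the inclusive marker interval
ehh_pair_oracle <- function(H, pos, core, allele, step, cutoff = 0.05,
                            max_gap = 2e5) {
  carriers <- if (is.na(allele)) seq_len(nrow(H)) else which(H[, core] == allele)
  nc <- length(carriers)
  if (nc < 2) return(NULL)
  denom <- nc * (nc - 1) / 2
  m <- ncol(H)
  out_pos <- pos[core]
  out_ehh <- 1
  truncated <- FALSE
  j <- core + step
  prev <- core
  repeat {
    if (j < 1 || j > m) { truncated <- TRUE; break }
    if (abs(pos[j] - pos[prev]) > max_gap) { truncated <- TRUE; break }
    rng <- min(core, j):max(core, j)
    same <- 0
    for (x in seq_len(nc - 1)) {
      for (y in (x + 1):nc) {
        if (all(H[carriers[x], rng] == H[carriers[y], rng])) same <- same + 1
      }
    }
    e <- same / denom
    out_pos <- c(out_pos, pos[j])
    out_ehh <- c(out_ehh, e)
    if (e < cutoff) break
    prev <- j
    j <- j + step
  }
  list(position = out_pos, ehh = out_ehh, truncated = truncated,
       ihh = if (length(out_pos) < 2) 0 else
         sum(0.5 * (out_ehh[-1] + out_ehh[-length(out_ehh)]) *
               abs(diff(out_pos))))
}

ihs_oracle_snp <- function(H, pos, core, cutoff = 0.05, max_gap = 2e5) {
  f1 <- mean(H[, core])
  major <- if (f1 > 0.5) 1L else 0L
  res <- lapply(c(0L, 1L), function(a) {
    up <- ehh_pair_oracle(H, pos, core, a, +1L, cutoff, max_gap)
    dn <- ehh_pair_oracle(H, pos, core, a, -1L, cutoff, max_gap)
    if (is.null(up) || is.null(dn)) return(NULL)
    list(ihh = up$ihh + dn$ihh, truncated = up$truncated || dn$truncated)
  })
  if (any(vapply(res, is.null, logical(1)))) return(NULL)
  if (res[[1]]$truncated || res[[2]]$truncated) return(NULL)
  ihh_major <- res[[major + 1]]$ihh
  ihh_minor <- res[[2 - major]]$ihh
  list(ihh_major = ihh_major, ihh_minor = ihh_minor,
       ihs = log(ihh_minor / ihh_major))
}

xpehh_oracle_snp <- function(Hobs, Href, pos, core, cutoff = 0.05,
                             max_gap = 2e5) {
  H <- rbind(Hobs, Href)
  n_obs <- nrow(Hobs)
  obs_rows <- seq_len(n_obs)
  ref_rows <- n_obs + seq_len(nrow(Href))
  one_dir <- function(step) {
    pooled <- ehh_pair_oracle(H, pos, core, NA, step, cutoff, max_gap)
    k <- length(pooled$position)
    sub_ehh <- function(rows) {
      nc <- length(rows)
      denom <- nc * (nc - 1) / 2
      vals <- 1
      if (k >= 2) {
        for (t in 2:k) {
          j <- which(pos == pooled$position[t])
          rng <- min(core, j):max(core, j)
          same <- 0
          for (x in seq_len(nc - 1)) {
            for (y in (x + 1):nc) {
              if (all(H[rows[x], rng] == H[rows[y], rng])) same <- same + 1
            }
          }
          vals <- c(vals, same / denom)
        }
      }
      vals
    }
    trapz <- function(v) {
      if (k < 2) return(0)
      sum(0.5 * (v[-1] + v[-k]) * abs(diff(pooled$position)))
    }
    list(obs = trapz(sub_ehh(obs_rows)), ref = trapz(sub_ehh(ref_rows)),
         truncated = pooled$truncated)
  }
  up <- one_dir(+1L)
  dn <- one_dir(-1L)
  list(ihh_obs = up$obs + dn$obs, ihh_ref = up$ref + dn$ref,
       truncated = up$truncated || dn$truncated,
       xpehh = log((up$obs + dn$obs) / (up$ref + dn$ref)))
}

# --- HWE exact p through the Wigginton-style recurrence ------------------
hwe_recurrence_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_ <- 2 * n_aa + n_ab
  nb_ <- 2 * n_bb + n_ab
  if (na_ == 0 || nb_ == 0) return(1)
  rare <- min(na_, nb_)
  ks <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(ks))
  mid <- which.min(abs(ks - rare * (na_ + nb_ - rare) / (na_ + nb_)))
  probs[mid] <- 1
  if (mid < length(ks)) {
    for (i in mid:(length(ks) - 1)) {
      k <- ks[i]
      # P(k+2) / P(k) = 4 * n_hom_rare(k) * n_hom_common(k) / ((k+2)(k+1))
      hr <- (rare - k) / 2
      hc <- (na_ + nb_ - rare - k) / 2
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((k + 2) * (k + 1))
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      k <- ks[i]
      hr <- (rare - k) / 2
      hc <- (na_ + nb_ - rare - k) / 2
      probs[i - 1] <- probs[i] * k * (k - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, ks)]
  sum(probs[probs <= obs * (1 + 1e-10)])
}

# --- quadratic interval-overlap oracle (1-based inclusive) ---------------
overlap_quadratic_oracle <- function(regions, annotation) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(annotation))) {
      if (regions$chromosome[i] != annotation$chromosome[j]) next
      lo <- max(regions$start_bp[i], annotation$start_bp[j])
      hi <- min(regions$end_bp[i], annotation$end_bp[j])
      if (hi >= lo) {
        hits[[length(hits) + 1]] <- data.frame(
          chromosome = regions$chromosome[i],
          region_start_bp = regions$start_bp[i],
          region_end_bp = regions$end_bp[i],
          annotation_start_bp = annotation$start_bp[j],
          annotation_end_bp = annotation$end_bp[j],
          overlap_bp = hi - lo + 1L)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}
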