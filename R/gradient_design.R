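# Nested phenotypic gradient differential population pairs: three nested
# high/low sample splits of shrinking size and growing phenotypic
# contrast.  With the defaults on a 233-sample panel the per-side level
# sizes are 116, 75 and 45; for other n the 75/116 and 45/116 ratios of
# the half-panel are scaled.

#' Default per-side sizes of the three gradient levels
#'
#' Level 1 takes `floor(n / 2)` per side (the median individual is dropped
#' when `n` is odd, keeping the pair balanced); levels 2 and 3 scale the
#' reference ratios 75/116 and 45/116 of the half-panel, giving exactly
#' (116, 75, 45) when `n = 233`.
#'
#' @param n Number of phenotyped samples.
#' @return Integer vector of three strictly decreasing per-side sizes.
#' @export
gradient_sizes <- function(n) {
  s1 <- n %/% 2L
  sizes <- c(s1, round(s1 * 75 / 116), round(s1 * 45 / 116))
  if (any(diff(sizes) >= 0) || sizes[3] < 1)
    abort(sprintf("panel too small for three nested gradient levels (n = %d)", n))
  as.integer(sizes)
}

#' Construct the three nested gradient population pairs for one trait
#'
#' Samples are ranked by phenotype (descending).  Level 1 pairs the top
#' `sizes[1]` (high) against the bottom `sizes[1]` (low); level 2 keeps
#' the most extreme `sizes[2]` of each side of level 1, and level 3 the
#' most extreme `sizes[3]` of level 2, so the sets nest and the contrast
#' grows.  Phenotype ties are broken by stable sample order; a warning is
#' emitted when a tie spans a split boundary.
#'
#' @param ph A phenotype table (tibble with `sample_id` and trait columns).
#' @param trait Trait column name.
#' @param sizes Three strictly decreasing per-side sizes; default
#'   [gradient_sizes()] of the number of non-missing phenotypes.
#' @return An object of class `gradient_pairs`: list with `trait`,
#'   `sizes`, and `membership`, a tibble (`sample_id`, `level`, `side`)
#'   with one row per (sample, level) membership.
#' @export
make_gradient_pairs <- function(ph, trait, sizes = NULL) {
  if (!trait %in% names(ph))
    abort(sprintf("trait '%s' not found in phenotype table", trait))
  y <- ph[[trait]]
  ok <- !is.na(y)
  ids <- ph$sample_id[ok]
  y <- y[ok]
  n <- length(y)
  if (is.null(sizes)) sizes <- gradient_sizes(n)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3 || any(diff(sizes) >= 0))
    abort("sizes must be three strictly decreasing integers")
  if (2L * sizes[1] > n)
    abort(sprintf("not enough phenotyped samples (%d) for level-1 size %d per side",
                  n, sizes[1]))
  if (length(unique(y)) == 1L)
    abort("phenotype is constant; no gradient split exists")

  ord <- order(y, decreasing = TRUE)  # ties keep stable sample order
  ids_sorted <- ids[ord]
  y_sorted <- y[ord]
  boundary_tie <- function(k_top, k_bot) {
    (k_top < n && y_sorted[k_top] == y_sorted[k_top + 1]) ||
      (k_bot > 1 && y_sorted[n - k_bot + 1] == y_sorted[n - k_bot])
  }
  rows <- list()
  for (lev in 1:3) {
    k <- sizes[lev]
    if (boundary_tie(k, k))
      warn(sprintf("phenotype tie spans the level-%d split boundary for trait %s; broken by sample order",
                   lev, trait))
    rows[[lev]] <- tibble(
      sample_id = c(head(ids_sorted, k), tail(ids_sorted, k)),
      level = lev, side = rep(c("high", "low"), each = k))
  }
  membership <- bind_rows(rows)
  hi3 <- min(y_sorted[seq_len(sizes[3])])
  lo3 <- max(y_sorted[seq(n - sizes[3] + 1, n)])
  if (hi3 <= lo3)
    warn(sprintf("high/low phenotype ranges touch at level 3 for trait %s", trait))
  structure(list(trait = trait, sizes = sizes, membership = membership),
            class = "gradient_pairs")
}

#' Ids of one side of one gradient level
#'
#' @param series A `gradient_pairs` object.
#' @param level Level 1, 2 or 3.
#' @param side `"high"` or `"low"`.
#' @return Character vector of sample ids.
#' @export
pair_ids <- function(series, level, side = c("high", "low")) {
  side <- match.arg(side)
  m <- series$membership
  m$sample_id[m$level == level & m$side == side]
}

#' Per-level phenotype means and high/low contrast tests
#'
#' For each level: mean phenotype of the high and low sides and a Welch
#' two-sample t test of their difference.
#'
#' @param series A `gradient_pairs` object.
#' @param ph The phenotype table it was built from.
#' @return A tibble: `level`, `n_per_side`, `mean_high`, `mean_low`,
#'   `t_statistic`, `p_value`.
#' @export
pair_summary <- function(series, ph) {
  y <- setNames(ph[[series$trait]], ph$sample_id)
  purrr::map_dfr(1:3, function(lev) {
    hi <- y[pair_ids(series, lev, "high")]
    lo <- y[pair_ids(series, lev, "low")]
    tt <- t.test(hi, lo)
    tibble(level = lev, n_per_side = length(hi), mean_high = mean(hi),
           mean_low = mean(lo), t_statistic = unname(tt$statistic),
           p_value = tt$p.value)
  })
}

#' @export
print.gradient_pairs <- function(x, ...) {
  cat(sprintf("<gradient_pairs> trait %s, per-side sizes %s\n", x$trait,
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Tidy gradient pair memberships
#'
#' @param x A `gradient_pairs` object.
#' @param ... Unused.
#' @return The membership tibble (`sample_id`, `level`, `side`).
#' @exportS3Method generics::tidy
tidy.gradient_pairs <- function(x, ...) x$membership

#' Write gradient pair memberships as TSV
#'
#' @param series A `gradient_pairs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gradient_pairs <- function(series, path) {
  m <- series$membership
  m$trait <- series$trait
  utils::write.table(m, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
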