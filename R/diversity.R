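# Windowed frequency statistics: nucleotide diversity, Tajima's D,
# Hudson FST, and pairwise LD. All computed from called genotypes with
# missing calls excluded pairwise, never imputed.

#' Per-site allele counts and frequencies
#'
#' @param gm a [genotype_matrix()].
#' @return data frame with one row per site: `pos`, `n_chrom` (genotyped
#'   chromosomes), `alt_count`, `p` (alternate-allele frequency; `NA` where
#'   no chromosome is genotyped).
#' @export
allele_freqs <- function(gm) {
  n_chrom <- 2 * colSums(!is.na(gm$geno))
  alt_count <- colSums(gm$geno, na.rm = TRUE)
  data.frame(pos = gm$variants$pos, n_chrom = n_chrom,
             alt_count = alt_count,
             p = ifelse(n_chrom > 0, alt_count / n_chrom, NA_real_))
}

# Half-open [start, end) windows in 0-based bp; a 1-based site position p
# falls in a window iff start < p <= end.
make_windows <- function(span_bp, width, step = width) {
  last_start <- max(0, floor((span_bp - 1) / step) * step)
  starts <- seq(0, last_start, by = step)
  data.frame(start = starts, end = starts + width)
}

sites_in_window <- function(pos, start, end) which(pos > start & pos <= end)

# Unbiased per-site nucleotide diversity 2*p*q*n/(n-1): the mean number of
# pairwise differences among the n genotyped chromosomes at the site.
site_pi <- function(p, n_chrom) {
  ifelse(n_chrom >= 2, 2 * p * (1 - p) * n_chrom / (n_chrom - 1), NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per window, the sum over genotyped sites of the unbiased per-site
#' heterozygosity \eqn{2pq\,n/(n-1)} (`value`), plus the per-bp density
#' (`density = value / window width`). Windows with no genotyped site are
#' flagged undefined (`NA`).
#'
#' @param gm a [genotype_matrix()].
#' @param width window width in bp (default 10000).
#' @param step window step in bp; default `width` (non-overlapping), 2000
#'   gives the sliding variant.
#' @param span_bp chromosome span; defaults to the last site position.
#' @return window-statistic data frame: `chrom`, `start`, `end`, `stat`,
#'   `value`, `density`, `n` (genotyped sites).
#' @export
pi_window <- function(gm, width = 1e4, step = width, span_bp = NULL) {
  af <- allele_freqs(gm)
  if (is.null(span_bp)) span_bp <- max(af$pos)
  w <- make_windows(span_bp, width, step)
  pis <- site_pi(af$p, af$n_chrom)
  rows <- lapply(seq_len(nrow(w)), function(i) {
    idx <- sites_in_window(af$pos, w$start[i], w$end[i])
    idx <- idx[!is.na(pis[idx])]
    data.frame(chrom = gm$variants$chrom[1], start = w$start[i],
               end = w$end[i], stat = "pi",
               value = if (length(idx)) sum(pis[idx]) else NA_real_,
               density = if (length(idx)) sum(pis[idx]) / width else NA_real_,
               n = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tajima's D from segregating sites and pairwise diversity
#'
#' The normalized difference between the pairwise-diversity and
#' segregating-sites estimators of the population mutation rate, with the
#' original normalizing constants. `S = 0` yields `NA` (undefined, not 0).
#'
#' @param S number of segregating sites.
#' @param pi_sum sum of per-site mean pairwise differences over the region.
#' @param n number of sampled chromosomes (>= 4).
#' @return Tajima's D, or `NA` if undefined.
#' @export
tajimas_d <- function(S, pi_sum, n) {
  if (is.na(S) || S < 1 || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed Tajima's D
#'
#' Computes per-window S and the pairwise-diversity sum from genotypes and
#' evaluates [tajimas_d()]. With missing data the chromosome count varies
#' across sites; the window uses the rounded mean count over its
#' segregating sites.
#'
#' @inheritParams pi_window
#' @return window-statistic data frame (`stat = "tajimas_d"`); `value` is
#'   `NA` where S = 0.
#' @export
tajima_window <- function(gm, width = 1e4, step = width, span_bp = NULL) {
  af <- allele_freqs(gm)
  if (is.null(span_bp)) span_bp <- max(af$pos)
  w <- make_windows(span_bp, width, step)
  pis <- site_pi(af$p, af$n_chrom)
  seg <- !is.na(af$p) & af$alt_count > 0 & af$alt_count < af$n_chrom
  rows <- lapply(seq_len(nrow(w)), function(i) {
    idx <- sites_in_window(af$pos, w$start[i], w$end[i])
    sidx <- idx[seg[idx]]
    S <- length(sidx)
    val <- if (S >= 1) {
      n_eff <- round(mean(af$n_chrom[sidx]))
      tajimas_d(S, sum(pis[sidx]), n_eff)
    } else NA_real_
    data.frame(chrom = gm$variants$chrom[1], start = w$start[i],
               end = w$end[i], stat = "tajimas_d", value = val, n = S,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Hudson per-site FST components (ratio-of-sums estimator).
hudson_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Windowed Hudson FST between two populations
#'
#' Ratio-of-sums Hudson estimator: per window,
#' \eqn{\sum_s \hat N_s / \sum_s \hat D_s} with
#' \eqn{\hat N = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' \eqn{\hat D = p_1(1-p_2) + p_2(1-p_1)}. Sites need at least two
#' genotyped chromosomes in each population. Windows with zero denominator
#' are flagged undefined.
#'
#' @param gm1,gm2 [genotype_matrix()] objects over the same sites.
#' @inheritParams pi_window
#' @return window-statistic data frame (`stat = "fst"`).
#' @export
hudson_fst_window <- function(gm1, gm2, width = 1e4, step = width,
                              span_bp = NULL) {
  if (ncol(gm1$geno) != ncol(gm2$geno)) stop("populations must share sites")
  a1 <- allele_freqs(gm1)
  a2 <- allele_freqs(gm2)
  usable <- a1$n_chrom >= 2 & a2$n_chrom >= 2
  comp <- hudson_components(a1$p, a1$n_chrom, a2$p, a2$n_chrom)
  if (is.null(span_bp)) span_bp <- max(a1$pos)
  w <- make_windows(span_bp, width, step)
  rows <- lapply(seq_len(nrow(w)), function(i) {
    idx <- sites_in_window(a1$pos, w$start[i], w$end[i])
    idx <- idx[usable[idx]]
    den <- sum(comp$den[idx])
    val <- if (length(idx) && den > 0) sum(comp$num[idx]) / den else NA_real_
    data.frame(chrom = gm1$variants$chrom[1], start = w$start[i],
               end = w$end[i], stat = "fst", value = val, n = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Whole-region Hudson FST
#'
#' Single ratio-of-sums estimate over all usable sites (see
#' [hudson_fst_window()]).
#'
#' @inheritParams hudson_fst_window
#' @return a single FST value (`NA` if undefined).
#' @export
hudson_fst <- function(gm1, gm2) {
  a1 <- allele_freqs(gm1)
  a2 <- allele_freqs(gm2)
  usable <- a1$n_chrom >= 2 & a2$n_chrom >= 2
  comp <- hudson_components(a1$p, a1$n_chrom, a2$p, a2$n_chrom)
  den <- sum(comp$den[usable])
  if (!any(usable) || den <= 0) return(NA_real_)
  sum(comp$num[usable]) / den
}

#' Pairwise linkage disequilibrium (r2) across a region
#'
#' Composite LD from genotype allele-dosage correlation across individuals
#' (pairwise-complete), squared. Sites must pass a minor-allele-frequency
#' gate (`maf_min`, inclusive) and a missing-data gate (`max_missing`,
#' inclusive).
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional site index vector restricting the region.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum missing-genotype fraction per site
#'   (default 0.2).
#' @return symmetric matrix of r2 values with site positions as dimnames;
#'   empty (0 x 0) with a warning when fewer than two sites qualify.
#' @export
ld_r2 <- function(gm, sites = NULL, maf_min = 0.05, max_missing = 0.2) {
  if (is.null(sites)) sites <- seq_len(ncol(gm$geno))
  g <- gm$geno[, sites, drop = FALSE]
  af <- allele_freqs(subset_genotypes(gm, sites = sites))
  maf <- pmin(af$p, 1 - af$p)
  miss <- colMeans(is.na(g))
  keep <- !is.na(maf) & maf >= maf_min & miss <= max_missing
  if (sum(keep) < 2) {
    warning("fewer than 2 SNPs pass the MAF/missingness gates")
    return(matrix(numeric(0), 0, 0))
  }
  g <- g[, keep, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- r^2
  dimnames(r2) <- list(af$pos[keep], af$pos[keep])
  r2
}
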