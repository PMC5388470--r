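# Haplotype-based sweep statistics: EHH decay, iHS with allele-frequency-bin
# standardization, window-iHS, and H12.

# Refine haplotype-identity group ids by one more SNP column.
# ids are small integers (<= n), so ids*2+allele cannot overflow.
refine_groups <- function(ids, alleles) {
  key <- ids * 2L + alleles
  match(key, unique(key))
}

ehh_value <- function(ids, n) {
  if (n < 2) return(NA_real_)
  counts <- tabulate(ids)
  sum(counts * (counts - 1) / 2) / (n * (n - 1) / 2)
}

#' Extended haplotype homozygosity decay around a core SNP
#'
#' EHH at distance d is the probability that two randomly drawn carrier
#' haplotypes of the core allele are identical at every SNP from the core
#' out to d. It equals 1 at the core and is nonincreasing outward on each
#' flank. The decay is traced site by site on both flanks until it falls
#' below `cutoff` or the chromosome ends.
#'
#' @param hm a [haplotype_matrix()].
#' @param core core SNP column index.
#' @param allele core allele, 0 (reference state) or 1 (alternate).
#' @param cutoff stop tracing once EHH drops below this value (default
#'   0.05); use 0 to trace the whole chromosome.
#' @return data frame with columns `side` ("left"/"right"/"core"), `site`,
#'   `pos_bp`, `distance_bp` (signed), `ehh`. Fewer than 2 carriers yields a
#'   zero-row result with attribute `undefined = TRUE`.
#' @export
ehh <- function(hm, core, allele, cutoff = 0.05) {
  carriers <- which(hm$haps[, core] == allele)
  n <- length(carriers)
  empty <- data.frame(side = character(), site = integer(),
                      pos_bp = numeric(), distance_bp = numeric(),
                      ehh = numeric(), stringsAsFactors = FALSE)
  if (n < 2) {
    attr(empty, "undefined") <- TRUE
    return(empty)
  }
  haps <- hm$haps[carriers, , drop = FALSE]
  walk <- function(sites, side) {
    ids <- rep(1L, n)
    out <- vector("list", length(sites))
    k <- 0
    for (j in sites) {
      ids <- refine_groups(ids, haps[, j])
      e <- ehh_value(ids, n)
      k <- k + 1
      out[[k]] <- c(j, e)
      if (e < cutoff) break
    }
    if (k == 0) return(empty)
    m <- do.call(rbind, out[seq_len(k)])
    data.frame(side = side, site = as.integer(m[, 1]),
               pos_bp = hm$positions_bp[m[, 1]],
               distance_bp = hm$positions_bp[m[, 1]] - hm$positions_bp[core],
               ehh = m[, 2], stringsAsFactors = FALSE)
  }
  left <- walk(rev(seq_len(core - 1)), "left")
  right <- walk(seq(core + 1, length.out = max(0, ncol(hm$haps) - core)), "right")
  core_row <- data.frame(side = "core", site = core,
                         pos_bp = hm$positions_bp[core],
                         distance_bp = 0, ehh = 1, stringsAsFactors = FALSE)
  res <- rbind(left[rev(seq_len(nrow(left))), ], core_row, right)
  rownames(res) <- NULL
  res
}

# Integrated EHH (iHH) for one allele class at one core: trapezoid area of
# the EHH curve over genetic distance (cM), walking outward on both flanks.
# The trapezoid into the first sub-cutoff point is included, then the walk
# stops. Running off the chromosome while EHH >= cutoff flags the side as
# "edge"; a physical gap > max_gap_bp between consecutive curve points
# flags "gap". The walk itself is compiled (src/ihh.cpp).
ihh_one <- function(haps, carriers, pos_bp, pos_cM, core, cutoff, max_gap_bp) {
  res <- ihh_walk_cpp(haps, carriers, pos_bp, pos_cM, core, cutoff, max_gap_bp)
  flag <- c("ok", "edge", "gap", "few_carriers")[res$flag + 1]
  ihh <- if (flag == "few_carriers") NA_real_ else res$ihh
  list(ihh = ihh, flag = flag)
}

#' Integrated haplotype score (iHS) scan
#'
#' For every SNP with minor allele frequency above `maf_min`, integrates the
#' EHH decay curves of the reference-state (0) and alternate-state (1)
#' carrier sets over genetic distance, truncating each curve once EHH drops
#' below `cutoff`. The unstandardized score is
#' \eqn{\ln(\mathrm{iHH}_{ref}/\mathrm{iHH}_{alt})}; scores are then
#' z-standardized within alternate-allele-frequency bins of width
#' `bin_width`. Curves that run off the chromosome before decaying are
#' flagged `"edge"`, physical gaps larger than `max_gap_bp` flag `"gap"`;
#' flagged sites are excluded from standardization.
#'
#' Alleles are polarized against the reference genome state (0), not an
#' inferred ancestral state, and binning therefore uses the
#' alternate-allele frequency.
#'
#' @param hm a [haplotype_matrix()].
#' @param maf_min minor-allele-frequency gate, strict (default 0.05).
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap_bp maximum tolerated physical gap between consecutive
#'   curve points (default 200000).
#' @param bin_width standardization bin width on alternate-allele frequency
#'   (default 0.05).
#' @param standardize set `FALSE` to skip the within-bin z-scoring.
#' @return data frame with one row per scanned SNP: `site`, `pos_bp`,
#'   `freq_alt`, `ihh_ref`, `ihh_alt`, `ihs_unstd`, `freq_bin`, `ihs_std`,
#'   `flag`.
#' @export
ihs <- function(hm, maf_min = 0.05, cutoff = 0.05, max_gap_bp = 2e5,
                bin_width = 0.05, standardize = TRUE) {
  haps <- hm$haps
  n <- nrow(haps)
  freq_alt <- col_freq_cpp(haps)
  maf <- pmin(freq_alt, 1 - freq_alt)
  sites <- which(maf > maf_min)
  k <- length(sites)
  ihh_ref <- ihh_alt <- unstd <- rep(NA_real_, k)
  flag <- character(k)
  for (idx in seq_len(k)) {
    s <- sites[idx]
    ref_rows <- which(haps[, s] == 0L)
    alt_rows <- which(haps[, s] == 1L)
    r <- ihh_one(haps, ref_rows, hm$positions_bp,
                 hm$positions_cM, s, cutoff, max_gap_bp)
    a <- ihh_one(haps, alt_rows, hm$positions_bp,
                 hm$positions_cM, s, cutoff, max_gap_bp)
    f <- if (r$flag != "ok") r$flag else a$flag
    u <- if (f %in% c("ok", "edge") &&
             isTRUE(r$ihh > 0) && isTRUE(a$ihh > 0)) {
      log(r$ihh / a$ihh)
    } else NA_real_
    if (f == "ok" && is.na(u)) f <- "degenerate"
    ihh_ref[idx] <- r$ihh
    ihh_alt[idx] <- a$ihh
    unstd[idx] <- u
    flag[idx] <- f
  }
  out <- data.frame(site = sites, pos_bp = hm$positions_bp[sites],
                    freq_alt = freq_alt[sites], ihh_ref = ihh_ref,
                    ihh_alt = ihh_alt, ihs_unstd = unstd, flag = flag,
                    stringsAsFactors = FALSE)
  out$freq_bin <- freq_bin_label(out$freq_alt, bin_width)
  out$ihs_std <- NA_real_
  if (standardize && nrow(out)) {
    usable <- out$flag == "ok" & !is.na(out$ihs_unstd)
    for (b in unique(out$freq_bin[usable])) {
      idx <- which(usable & out$freq_bin == b)
      if (length(idx) >= 2) {
        m <- mean(out$ihs_unstd[idx])
        s <- stats::sd(out$ihs_unstd[idx])
        if (s > 0) out$ihs_std[idx] <- (out$ihs_unstd[idx] - m) / s
      }
    }
  }
  attr(out, "chrom") <- hm$chrom
  out
}

freq_bin_label <- function(freq, bin_width = 0.05) {
  idx <- pmin(floor(freq / bin_width), ceiling(1 / bin_width) - 1)
  sprintf("[%.2f,%.2f)", idx * bin_width, (idx + 1) * bin_width)
}

#' Fraction of extreme iHS scores in nonoverlapping windows
#'
#' Per nonoverlapping window of `window_bp` physical span with strictly
#' more than `min_n` standardized scores, the fraction of scores with
#' \eqn{|iHS| >} `threshold`. Windows at or below `min_n` scores are
#' omitted.
#'
#' @param ihs_df output of [ihs()].
#' @param window_bp window width in bp (default 10000).
#' @param min_n minimum score count per window, strict (default 10).
#' @param threshold absolute-score threshold (default 2).
#' @param chrom chromosome label for the output (defaults to the scan's).
#' @return window-statistic data frame: `chrom`, `start`, `end` (half-open,
#'   0-based), `stat`, `value`, `n`.
#' @export
window_ihs <- function(ihs_df, window_bp = 1e4, min_n = 10, threshold = 2,
                       chrom = NULL) {
  if (is.null(chrom)) chrom <- attr(ihs_df, "chrom")
  if (is.null(chrom)) chrom <- "chr1"
  keep <- !is.na(ihs_df$ihs_std)
  df <- ihs_df[keep, , drop = FALSE]
  win <- floor((df$pos_bp - 1) / window_bp)
  stats_by <- split(df$ihs_std, win)
  rows <- lapply(names(stats_by), function(w) {
    v <- stats_by[[w]]
    if (length(v) <= min_n) return(NULL)
    w <- as.numeric(w)
    data.frame(chrom = chrom, start = w * window_bp,
               end = (w + 1) * window_bp, stat = "window_ihs",
               value = mean(abs(v) > threshold), n = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_windowstat()
  out[order(out$start), , drop = FALSE]
}

empty_windowstat <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stat = character(), value = numeric(), n = integer(),
             stringsAsFactors = FALSE)
}

#' Haplotype-spectrum H12 scan in fixed-SNP windows
#'
#' Haplotypes are compared as exact strings over consecutive windows of
#' `snps_per_window` SNPs (non-overlapping by default). With sorted
#' haplotype frequencies \eqn{p_1 \ge p_2 \ge \dots}, the statistic is
#' \eqn{H12 = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2}, which is elevated under
#' both hard and soft sweeps. A trailing partial window is omitted.
#'
#' @param hm a [haplotype_matrix()].
#' @param snps_per_window SNPs per window (default 81).
#' @param step window step in SNPs; defaults to `snps_per_window`
#'   (non-overlapping).
#' @return data frame with `window`, `snp_start`, `snp_end`, `start_bp`,
#'   `end_bp`, `center_bp`, `h12`, `h1`, `n_distinct`.
#' @export
h12_scan <- function(hm, snps_per_window = 81, step = snps_per_window) {
  m <- ncol(hm$haps)
  if (m < snps_per_window) stop("fewer SNPs than one window")
  starts <- seq(1, m - snps_per_window + 1, by = step)
  rows <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    e <- s + snps_per_window - 1
    ids <- rep(1L, nrow(hm$haps))
    for (j in s:e) ids <- refine_groups(ids, hm$haps[, j])
    p <- sort(tabulate(ids) / nrow(hm$haps), decreasing = TRUE)
    h1 <- sum(p^2)
    p2 <- if (length(p) >= 2) p[2] else 0
    data.frame(window = k, snp_start = s, snp_end = e,
               start_bp = hm$positions_bp[s], end_bp = hm$positions_bp[e],
               center_bp = (hm$positions_bp[s] + hm$positions_bp[e]) / 2,
               h12 = (p[1] + p2)^2 + sum(p[-(1:2)]^2),
               h1 = h1, n_distinct = length(p))
  })
  out <- do.call(rbind, rows)
  attr(out, "chrom") <- hm$chrom
  out
}
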