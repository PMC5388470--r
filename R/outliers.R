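# Recombination-binned empirical-quantile outlier calling and MAF-binned
# allele-frequency-change quantiles.

#' Recombination-rate bin labels
#'
#' Haplotype and diversity statistics are sensitive to the local
#' recombination rate, so outliers are called within rate bins. The default
#' edges partition the rate axis into <0.5, 0.5-2, 2-3.5, 3.5-5 and
#' >5 cM/Mb, left-closed/right-open at the printed edges (a rate of exactly
#' 2 falls in "2-3.5").
#'
#' @param rates local recombination rates in cM/Mb.
#' @param edges internal bin edges (default `c(0.5, 2, 3.5, 5)`).
#' @return factor of bin labels, one per rate; `NA` rates yield `NA`.
#' @export
recomb_bin <- function(rates, edges = c(0.5, 2, 3.5, 5)) {
  labels <- c(paste0("<", edges[1]),
              paste(edges[-length(edges)], edges[-1], sep = "-"),
              paste0(">", edges[length(edges)]))
  idx <- findInterval(rates, edges, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

#' Assign items to recombination-rate bins
#'
#' SNPs are binned at their own position, windows at their midpoint.
#'
#' @param pos physical positions (bp) of the items (for windows, pass
#'   `(start + end) / 2`).
#' @param map a [recombination_map()].
#' @param edges see [recomb_bin()].
#' @return data frame with `pos`, `rate` (cM/Mb), `bin`.
#' @export
assign_recomb_bins <- function(pos, map, edges = c(0.5, 2, 3.5, 5)) {
  rate <- local_recomb_rate(map, pos)
  data.frame(pos = pos, rate = rate, bin = recomb_bin(rate, edges))
}

#' Empirical-quantile outlier calls within recombination bins
#'
#' Per bin, the empirical `q` / `1 - q` quantile thresholds
#' (linear-interpolation, type-7) are computed and items strictly beyond
#' them are flagged. Tie rule for bounded or saturated statistics: when
#' the threshold coincides with the bin extreme (more than the nominal
#' tail mass is tied at the maximum/minimum), the tied extreme items are
#' flagged, since they are indistinguishably the most extreme set; a fully
#' degenerate bin (all values equal) still flags nothing. Bins with fewer
#' than `1/q` items are under-occupied: they flag nothing and a warning is
#' raised. Items with `NA` value or bin are excluded.
#'
#' @param values statistic values, one per item.
#' @param bins bin label per item (e.g. from [assign_recomb_bins()]); a
#'   single label recycles to pooled calling.
#' @param tail `"upper"`, `"lower"` or `"both"`.
#' @param q tail mass (default 0.001, i.e. the top 0.1%).
#' @return data frame with `value`, `bin`, `lower`, `upper` (thresholds,
#'   `NA` where not applicable), `is_outlier`.
#' @export
call_outliers <- function(values, bins, tail = c("upper", "lower", "both"),
                          q = 0.001) {
  tail <- match.arg(tail)
  if (length(bins) == 1) bins <- rep(bins, length(values))
  stopifnot(length(bins) == length(values))
  bins <- as.character(bins)
  out <- data.frame(value = values, bin = bins,
                    lower = NA_real_, upper = NA_real_,
                    is_outlier = FALSE, stringsAsFactors = FALSE)
  usable <- !is.na(values) & !is.na(bins)
  for (b in unique(bins[usable])) {
    idx <- which(usable & bins == b)
    if (length(idx) < 1 / q) {
      warning(sprintf("bin '%s' has %d items (< %g needed for q = %g); nothing flagged",
                      b, length(idx), 1 / q, q))
      next
    }
    v <- values[idx]
    spread <- max(v) > min(v)
    if (tail %in% c("upper", "both")) {
      thr <- stats::quantile(v, 1 - q, type = 7, names = FALSE)
      out$upper[idx] <- thr
      # tie rule: when the tail is saturated at the bin maximum (threshold
      # == max), the maximal items are the extreme set; a degenerate bin
      # (all values equal) still flags nothing
      out$is_outlier[idx] <- out$is_outlier[idx] | v > thr |
        (spread & thr == max(v) & v == max(v))
    }
    if (tail %in% c("lower", "both")) {
      thr <- stats::quantile(v, q, type = 7, names = FALSE)
      out$lower[idx] <- thr
      out$is_outlier[idx] <- out$is_outlier[idx] | v < thr |
        (spread & thr == min(v) & v == min(v))
    }
  }
  out
}

#' Allele-frequency change between source and transplant populations
#'
#' Per site, the frequency change `delta = p_transplant - p_source` and its
#' absolute value, binned by the source-population minor allele frequency
#' in bins of width `maf_bin_width`. Per-bin empirical quantiles of
#' `|delta|` (default 50/95/99%) are attached for genome-wide context.
#' Frequencies must refer to the same allele (alternate relative to the
#' reference genome) in both populations. Sites monomorphic in both
#' populations are excluded.
#'
#' @param p_source,p_transplant alternate-allele frequencies per site.
#' @param maf_bin_width source-MAF bin width (default 0.05).
#' @param probs quantile levels attached per bin.
#' @return data frame with `site`, `p_source`, `p_transplant`, `delta`,
#'   `abs_delta`, `maf_bin`, and one `q<level>` column per quantile level
#'   (per-bin empirical quantiles of `abs_delta`).
#' @export
af_change <- function(p_source, p_transplant, maf_bin_width = 0.05,
                      probs = c(0.5, 0.95, 0.99)) {
  stopifnot(length(p_source) == length(p_transplant))
  keep <- !(p_source %in% c(0, 1) & p_transplant %in% c(0, 1) &
              p_source == p_transplant)
  keep <- keep & !is.na(p_source) & !is.na(p_transplant)
  site <- which(keep)
  ps <- p_source[keep]
  pt <- p_transplant[keep]
  maf <- pmin(ps, 1 - ps)
  bin_idx <- pmin(floor(maf / maf_bin_width),
                  ceiling(0.5 / maf_bin_width) - 1)
  bin <- sprintf("[%.2f,%.2f)", bin_idx * maf_bin_width,
                 (bin_idx + 1) * maf_bin_width)
  out <- data.frame(site = site, p_source = ps, p_transplant = pt,
                    delta = pt - ps, abs_delta = abs(pt - ps),
                    maf_bin = bin, stringsAsFactors = FALSE)
  for (p in probs) out[[sprintf("q%02.0f", p * 100)]] <- NA_real_
  for (b in unique(bin)) {
    idx <- out$maf_bin == b
    qs <- stats::quantile(out$abs_delta[idx], probs, type = 7, names = FALSE)
    for (k in seq_along(probs)) {
      out[[sprintf("q%02.0f", probs[k] * 100)]][idx] <- qs[k]
    }
  }
  out
}
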