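# End-to-end orchestration of the analysis on one dataset: filters,
# partitions, sweep scans, windowed diversity, outlier calling,
# allele-frequency change, and selection-experiment estimates, with all
# outputs as plain TSV plus a JSON run manifest.

#' Write a window-statistic table as BED-like TSV
#'
#' @param ws window-statistic data frame (`chrom`, `start`, `end`, `stat`,
#'   `value`, `n`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windowstat <- function(ws, path) {
  utils::write.table(ws, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All statistic parameters at their standard values: 10 kb windows with
#' 2 kb sliding step, 81-SNP H12 bins, 5% MAF gate, 0.05-wide frequency
#' bins, 0.1% outlier tails, T400 threshold 74, 12.7 generations and
#' h = 0.5 for the selection-experiment estimators.
#'
#' @param seed integer seed echoed to every stochastic stage.
#' @param out_dir output directory.
#' @return named list of parameters.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("sweeplight_run_")) {
  list(seed = seed, out_dir = out_dir,
       window_bp = 1e4, step_bp = 2e3, h12_snps = 81,
       maf_min = 0.05, maf_bin_width = 0.05, outlier_q = 0.001,
       t400_threshold = 74, generations = 12.7, dominance = 0.5,
       source_pop = "MAYR", transplant_pop = "RDSP")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a radiation panel and a transplant experiment under the given
#' seed, then executes every stage: sweep scans (iHS, window-iHS, H12) on
#' the radiation haplotypes, recombination-binned outlier calls, windowed
#' diversity (pi, Tajima's D) per experiment population, Hudson FST between
#' them, allele-frequency change with MAF-binned quantiles, and the
#' evolutionary-rate and selection-coefficient estimates. Writes one TSV
#' per stage plus `manifest.json` echoing every parameter and the seed.
#'
#' @param cfg a [pipeline_config()].
#' @return the output directory, invisibly; stage results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  rad <- simulate_radiation(seed = cfg$seed)
  ihs_res <- ihs(rad$hm, maf_min = cfg$maf_min)
  utils::write.table(ihs_res, out("ihs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wihs <- window_ihs(ihs_res, window_bp = cfg$window_bp)
  write_windowstat(wihs, out("window_ihs.tsv"))
  h12 <- h12_scan(rad$hm, snps_per_window = cfg$h12_snps)
  utils::write.table(h12, out("h12.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bins <- assign_recomb_bins((wihs$start + wihs$end) / 2, rad$map)
  wihs_out <- call_outliers(wihs$value, bins$bin, tail = "upper",
                            q = cfg$outlier_q)
  utils::write.table(cbind(wihs[c("start", "end")], wihs_out),
                     out("window_ihs_outliers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  h12_bins <- assign_recomb_bins(h12$center_bp, rad$map)
  h12_out <- call_outliers(h12$h12, h12_bins$bin, tail = "upper",
                           q = cfg$outlier_q)
  utils::write.table(cbind(h12[c("start_bp", "end_bp")], h12_out),
                     out("h12_outliers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  trn <- simulate_transplant(seed = cfg$seed + 1L)
  for (nm in c("source", "transplant")) {
    gm <- trn[[paste0(nm, "_gm")]]
    write_windowstat(pi_window(gm, cfg$window_bp, cfg$step_bp),
                     out(paste0("pi_", nm, ".tsv")))
    write_windowstat(tajima_window(gm, cfg$window_bp, cfg$step_bp),
                     out(paste0("tajd_", nm, ".tsv")))
  }
  fst <- hudson_fst_window(trn$source_gm, trn$transplant_gm,
                           cfg$window_bp, cfg$step_bp)
  write_windowstat(fst, out("fst.tsv"))

  p_src <- allele_freqs(trn$source_gm)$p
  p_trn <- allele_freqs(trn$transplant_gm)$p
  afc <- af_change(p_src, p_trn, maf_bin_width = cfg$maf_bin_width)
  utils::write.table(afc, out("af_change.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  focal <- trn$truth$focal_site
  est <- list(
    haldanes = if (p_src[focal] > 0 && p_trn[focal] > 0 &&
                   p_src[focal] < 1 && p_trn[focal] < 1)
      haldanes(p_src[focal], p_trn[focal], g = cfg$generations)$haldanes
    else NA_real_,
    s = selection_coefficient(p_trn[focal] - p_src[focal],
                              g = cfg$generations, p_ref = max(p_src[focal], 1e-3),
                              h = cfg$dominance)$s
  )

  manifest <- c(cfg[setdiff(names(cfg), "out_dir")],
                list(package_version = as.character(utils::packageVersion("sweeplight")),
                     stages = c("simulate", "ihs", "window_ihs", "h12",
                                "outliers", "pi", "tajd", "fst",
                                "af_change", "selexp")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res <- list(radiation = rad, ihs = ihs_res, window_ihs = wihs, h12 = h12,
              window_ihs_outliers = wihs_out, h12_outliers = h12_out,
              transplant = trn, fst = fst, af_change = afc, estimates = est)
  structure(invisible(cfg$out_dir), results = res)
}
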