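#' Read a VCF file into variant and genotype tables
#'
#' Loads a VCF 4.x file (plain text or gzipped) and returns the per-site
#' metadata needed by the hard site filters together with the diploid
#' genotype matrix. Samples are kept in file order. Requires the GT format
#' field; per-sample DP and AD are used when present.
#'
#' @param path path to a VCF file.
#' @param populations optional named vector mapping sample name to
#'   population code; defaults to population `"pop1"` for every sample.
#' @return a [genotype_matrix()] whose `variants` element is the variant
#'   table (chrom, pos, ref, alt, qual, mean_depth, ref_reads, alt_reads,
#'   n_alleles, is_indel).
#' @export
read_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_site <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (n_site == 0) {
    variants <- data.frame(chrom = character(), pos = numeric(),
                           ref = character(), alt = character(),
                           qual = numeric(), mean_depth = numeric(),
                           ref_reads = numeric(), alt_reads = numeric(),
                           n_alleles = integer(), is_indel = logical(),
                           stringsAsFactors = FALSE)
    geno <- matrix(numeric(0), nrow = length(samples), ncol = 0)
    pops <- resolve_populations(samples, populations)
    return(genotype_matrix(geno, samples, pops, variants))
  }
  if (is.null(samples) || length(samples) == 0) {
    stop("VCF has no sample columns")
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1)))) {
    stop("VCF format error: GT field missing at one or more records")
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  # diploid dosage of the first alternate allele; half-missing -> missing
  alt1 <- function(a) ifelse(a %in% c(".", NA), NA_real_,
                             as.numeric(a != "0"))
  split_gt <- function(g) {
    parts <- strsplit(g, "[/|]")
    sapply(parts, function(p) {
      if (length(p) != 2) return(NA_real_)
      d <- alt1(p[1]) + alt1(p[2])
      d
    })
  }
  raw <- apply(gt, 1, split_gt)   # collapses when either dimension is 1
  geno <- matrix(raw, nrow = length(samples), ncol = n_site)
  rownames(geno) <- samples

  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  depths <- if (!is.null(dp) && !all(is.na(dp))) t(dp) else NULL

  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  ref_reads <- alt_reads <- rep(NA_real_, n_site)
  if (!is.null(ad) && !all(is.na(ad))) {
    ad_split <- apply(ad, 1, function(row) {
      mats <- strsplit(row, ",", fixed = TRUE)
      refs <- suppressWarnings(vapply(mats, function(x)
        as.numeric(x[1]), numeric(1)))
      alts <- suppressWarnings(vapply(mats, function(x)
        if (length(x) >= 2) as.numeric(x[2]) else NA_real_, numeric(1)))
      c(sum(refs, na.rm = TRUE), sum(alts, na.rm = TRUE))
    })
    ref_reads <- ad_split[1, ]
    alt_reads <- ad_split[2, ]
  }

  alt_field <- ifelse(is.na(fix$ALT), "", fix$ALT)
  n_alleles <- 1L + ifelse(alt_field == "" | alt_field == ".",
                           0L, lengths(strsplit(alt_field, ",", fixed = TRUE)))
  alleles <- strsplit(paste(fix$REF, alt_field, sep = ","), ",", fixed = TRUE)
  is_indel <- vapply(alleles, function(a) any(nchar(a[a != "."]) != 1), logical(1))

  mean_depth <- if (!is.null(depths)) colMeans(depths, na.rm = TRUE) else
    rep(NA_real_, n_site)

  variants <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = alt_field,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mean_depth = mean_depth,
    ref_reads = ref_reads, alt_reads = alt_reads,
    n_alleles = n_alleles, is_indel = is_indel,
    stringsAsFactors = FALSE
  )
  pops <- resolve_populations(samples, populations)
  genotype_matrix(geno, samples, pops, variants, depths)
}

resolve_populations <- function(samples, populations) {
  if (is.null(populations)) return(rep("pop1", length(samples)))
  if (!is.null(names(populations))) {
    miss <- setdiff(samples, names(populations))
    if (length(miss)) stop("no population given for sample(s): ",
                           paste(miss, collapse = ", "))
    return(unname(populations[samples]))
  }
  if (length(populations) != length(samples)) {
    stop("populations must be named or match the number of samples")
  }
  populations
}

#' Write a genotype matrix to a minimal VCF 4.2 file
#'
#' Emits GT (unphased "/" or phased "|" per `phased`) and, when available,
#' per-genotype DP.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param phased write `|`-separated genotypes (haplotype order is then the
#'   arbitrary but reproducible 0-before-1 split of heterozygotes).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  has_dp <- !is.null(gm$depths)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweeplight",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$individuals), collapse = "\t"), con)
  v <- gm$variants
  gt_code <- function(d) {
    ifelse(is.na(d), paste0(".", sep, "."),
           c(paste0("0", sep, "0"), paste0("0", sep, "1"),
             paste0("1", sep, "1"))[d + 1])
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  for (j in seq_len(ncol(gm$geno))) {
    cells <- gt_code(gm$geno[, j])
    if (has_dp) {
      dp <- gm$depths[, j]
      cells <- paste0(cells, ":", ifelse(is.na(dp), ".", dp))
    }
    qual <- if (is.na(v$qual[j])) "." else format(v$qual[j])
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       ".", v$ref[j],
                       if (v$alt[j] == "") "." else v$alt[j],
                       qual, "PASS", ".", fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Automatic mean-depth ceiling
#'
#' Dataset mean of per-site mean depths plus 1.5 times the interquartile
#' range of the mean-depth distribution (linear-interpolation, type-7
#' quantiles).
#'
#' @param mean_depths vector of per-site mean depths.
#' @return the depth ceiling.
#' @export
auto_depth_threshold <- function(mean_depths) {
  mean_depths <- mean_depths[!is.na(mean_depths)]
  mean(mean_depths) + 1.5 * stats::IQR(mean_depths, type = 7)
}

#' Hard site filters
#'
#' Retains biallelic SNPs with site quality >= `min_qual`, mean depth <=
#' `max_mean_depth`, and at least `min_allele_reads` reads supporting each
#' of the reference and alternate allele; indels and sites with more than
#' two alleles are removed. Sites with a missing annotation fail the
#' corresponding rule.
#'
#' @param gm a [genotype_matrix()] carrying the variant table.
#' @param min_qual minimum phred site quality (default 45).
#' @param max_mean_depth depth ceiling, or `"auto"` for
#'   [auto_depth_threshold()] on the dataset.
#' @param min_allele_reads minimum reads per allele (default 4).
#' @return the filtered [genotype_matrix()]; the applied depth ceiling is
#'   attached as attribute `"max_mean_depth"`.
#' @export
filter_sites <- function(gm, min_qual = 45, max_mean_depth = "auto",
                         min_allele_reads = 4) {
  v <- gm$variants
  if (identical(max_mean_depth, "auto")) {
    max_mean_depth <- auto_depth_threshold(v$mean_depth)
  }
  ok <- !is.na(v$qual) & v$qual >= min_qual
  ok <- ok & !is.na(v$mean_depth) & v$mean_depth <= max_mean_depth
  ok <- ok & !is.na(v$ref_reads) & v$ref_reads >= min_allele_reads &
    !is.na(v$alt_reads) & v$alt_reads >= min_allele_reads
  ok <- ok & v$n_alleles == 2L & !v$is_indel
  if (!any(ok)) warning("no sites retained by site filters")
  out <- subset_genotypes(gm, sites = which(ok))
  attr(out, "max_mean_depth") <- max_mean_depth
  out
}

#' Genotype-level filters
#'
#' Masks genotypes supported by fewer than `min_depth` reads as missing,
#' then drops sites whose missing-genotype fraction exceeds
#' `max_site_missing` (strictly greater; a site at exactly the bound is
#' kept). Missing genotypes are never imputed.
#'
#' @param gm a [genotype_matrix()] with per-genotype depths (sites without
#'   depth information are left untouched by the depth mask).
#' @param min_depth minimum reads per genotype (default 4).
#' @param max_site_missing maximum tolerated missing fraction per site
#'   (default 0.5).
#' @return the filtered [genotype_matrix()].
#' @export
filter_genotypes <- function(gm, min_depth = 4, max_site_missing = 0.5) {
  geno <- gm$geno
  if (!is.null(gm$depths)) {
    mask <- !is.na(gm$depths) & gm$depths < min_depth
    geno[mask] <- NA
  }
  miss_frac <- colMeans(is.na(geno))
  keep <- miss_frac <= max_site_missing
  out <- genotype_matrix(geno, gm$individuals, gm$populations,
                         gm$variants, gm$depths)
  subset_genotypes(out, sites = which(keep))
}

#' Split a dataset into adaptive-radiation and selection-experiment partitions
#'
#' The radiation partition holds one seeded-random individual per population,
#' excluding the transplant population. The experiment partition holds all
#' individuals of the designated source and transplant populations.
#'
#' @param gm a [genotype_matrix()].
#' @param source population code of the selection-experiment source
#'   population (default `"MAYR"`).
#' @param transplant population code of the transplant population
#'   (default `"RDSP"`).
#' @param seed integer seed for the per-population random pick.
#' @return list with elements `radiation` and `experiment`, both
#'   [genotype_matrix()] objects.
#' @export
partition_datasets <- function(gm, source = "MAYR", transplant = "RDSP",
                               seed = 1L) {
  pops <- gm$populations
  for (code in c(source, transplant)) {
    if (!code %in% pops) stop("unknown population code: ", code)
  }
  rng <- local_rng(seed)
  rad_pops <- setdiff(unique(pops), transplant)
  picks <- vapply(rad_pops, function(p) {
    idx <- which(pops == p)
    if (length(idx) == 1) idx else idx[rng$int(length(idx))]
  }, integer(1))
  radiation <- subset_genotypes(gm, individuals = sort(unname(picks)))
  experiment <- subset_genotypes(gm, individuals = which(pops %in% c(source, transplant)))
  list(radiation = radiation, experiment = experiment)
}

# Seeded RNG sandbox: runs draws under a private seed without touching the
# caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    int = function(n) run(function() sample.int(n, 1L)),
    runif = function(n, ...) run(function() stats::runif(n, ...)),
    run = run
  )
}
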