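#' Construct a phased haplotype matrix
#'
#' The substrate of all haplotype-based sweep statistics: a binary matrix of
#' phased haplotypes (rows, two per diploid individual) by SNP sites
#' (columns), with physical and genetic positions. Allele 0 is the reference
#' state, allele 1 the alternate.
#'
#' @param haps integer or numeric matrix of 0/1 alleles, one row per
#'   haplotype, one column per SNP.
#' @param positions_bp strictly increasing 1-based physical positions (bp),
#'   one per column.
#' @param positions_cM genetic positions in centimorgans, one per column.
#'   If `NULL`, a uniform 1 cM/Mb map is assumed.
#' @param sample_map optional data frame with one row per haplotype row,
#'   columns `individual` and `population`, mapping haplotypes back to
#'   diploid samples.
#' @param chrom chromosome label.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `haps`, `positions_bp`, `positions_cM`, `sample_map`, `chrom`.
#' @export
haplotype_matrix <- function(haps, positions_bp, positions_cM = NULL,
                             sample_map = NULL, chrom = "chr1") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (!all(haps %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1")
  }
  positions_bp <- as.numeric(positions_bp)
  if (length(positions_bp) != ncol(haps)) {
    stop("positions_bp must have one entry per SNP column")
  }
  if (ncol(haps) > 1 && any(diff(positions_bp) <= 0)) {
    stop("positions_bp must be strictly increasing")
  }
  if (is.null(positions_cM)) positions_cM <- positions_bp * 1e-6
  positions_cM <- as.numeric(positions_cM)
  if (length(positions_cM) != ncol(haps)) {
    stop("positions_cM must have one entry per SNP column")
  }
  if (!is.null(sample_map)) {
    sample_map <- as.data.frame(sample_map)
    if (nrow(sample_map) != nrow(haps)) {
      stop("sample_map must have one row per haplotype")
    }
  }
  structure(
    list(haps = haps, positions_bp = positions_bp,
         positions_cM = positions_cM, sample_map = sample_map,
         chrom = chrom),
    class = "haplotype_matrix"
  )
}

#' @exportS3Method base::print
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d SNPs (%s: %.0f-%.0f bp)\n",
              nrow(x$haps), ncol(x$haps), x$chrom,
              min(x$positions_bp), max(x$positions_bp)))
  invisible(x)
}

#' Number of haplotypes / SNPs in a haplotype matrix
#' @param hm a [haplotype_matrix()].
#' @return integer count.
#' @export
n_haplotypes <- function(hm) nrow(hm$haps)

#' @rdname n_haplotypes
#' @export
n_snps <- function(hm) ncol(hm$haps)

#' Collapse a haplotype matrix to diploid genotypes
#'
#' Pairs consecutive haplotype rows (1&2, 3&4, ...) into diploid individuals
#' and sums alleles into dosages 0/1/2.
#'
#' @param hm a [haplotype_matrix()].
#' @param individuals optional individual identifiers; defaults to the
#'   `sample_map` individuals or `ind1..indN`.
#' @param populations optional population codes per individual.
#' @return a [genotype_matrix()].
#' @export
haplotypes_to_genotypes <- function(hm, individuals = NULL, populations = NULL) {
  if (nrow(hm$haps) %% 2 != 0) stop("odd number of haplotypes cannot be paired")
  n_ind <- nrow(hm$haps) / 2
  odd <- seq(1, by = 2, length.out = n_ind)
  geno <- hm$haps[odd, , drop = FALSE] + hm$haps[odd + 1, , drop = FALSE]
  if (is.null(individuals)) {
    individuals <- if (!is.null(hm$sample_map)) {
      unique(hm$sample_map$individual)
    } else {
      paste0("ind", seq_len(n_ind))
    }
  }
  if (is.null(populations)) {
    populations <- if (!is.null(hm$sample_map)) {
      hm$sample_map$population[odd]
    } else {
      rep("pop1", n_ind)
    }
  }
  variants <- data.frame(
    chrom = hm$chrom, pos = hm$positions_bp,
    ref = "A", alt = "T", qual = NA_real_,
    mean_depth = NA_real_, ref_reads = NA_real_, alt_reads = NA_real_,
    n_alleles = 2L, is_indel = FALSE,
    stringsAsFactors = FALSE
  )
  genotype_matrix(geno, individuals = individuals,
                  populations = populations, variants = variants)
}

#' Construct a diploid genotype matrix
#'
#' Per-individual x per-site diploid allele counts in {0,1,2} with `NA` for
#' missing calls, carrying per-genotype read depths and per-site variant
#' metadata.
#'
#' @param geno numeric matrix, individuals x sites, values 0/1/2/NA.
#' @param individuals ordered sample identifiers.
#' @param populations population code per individual.
#' @param variants data frame of per-site metadata (columns `chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `mean_depth`, `ref_reads`, `alt_reads`,
#'   `n_alleles`, `is_indel`), one row per site.
#' @param depths optional matrix of per-genotype read depths, same shape as
#'   `geno`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, individuals, populations, variants,
                            depths = NULL) {
  geno <- as.matrix(geno)
  if (length(individuals) != nrow(geno)) {
    stop("individuals must match genotype rows")
  }
  if (length(populations) != nrow(geno)) {
    stop("populations must match genotype rows")
  }
  variants <- as.data.frame(variants)
  if (nrow(variants) != ncol(geno)) {
    stop("variants must have one row per genotype column")
  }
  if (!all(is.na(geno) | geno %in% c(0, 1, 2))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!all(dim(depths) == dim(geno))) stop("depths must match geno shape")
  }
  structure(
    list(geno = geno, individuals = as.character(individuals),
         populations = as.character(populations),
         variants = variants, depths = depths),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno)) * 100
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param individuals index or logical vector over individuals (optional).
#' @param sites index or logical vector over sites (optional).
#' @return the subsetted [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, individuals = NULL, sites = NULL) {
  geno <- gm$geno
  inds <- gm$individuals
  pops <- gm$populations
  variants <- gm$variants
  depths <- gm$depths
  if (!is.null(individuals)) {
    geno <- geno[individuals, , drop = FALSE]
    inds <- inds[individuals]
    pops <- pops[individuals]
    if (!is.null(depths)) depths <- depths[individuals, , drop = FALSE]
  }
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    variants <- variants[sites, , drop = FALSE]
    rownames(variants) <- NULL
    if (!is.null(depths)) depths <- depths[, sites, drop = FALSE]
  }
  genotype_matrix(geno, inds, pops, variants, depths)
}

#' Construct a recombination map
#'
#' A set of (physical position, cumulative genetic distance) anchors from
#' which local recombination rates are derived by finite differences on the
#' anchor intervals (a deliberately transparent smoother: rates are piecewise
#' constant between anchors, so they integrate back to the anchor cM
#' exactly).
#'
#' @param pos_bp anchor physical positions in bp (nondecreasing).
#' @param cum_cM cumulative genetic positions in cM (nondecreasing).
#' @param chrom chromosome label.
#' @return object of class `recombination_map` with `pos_bp`, `cum_cM` and
#'   per-interval `rate_cM_Mb`.
#' @export
recombination_map <- function(pos_bp, cum_cM, chrom = "chr1") {
  stopifnot(length(pos_bp) == length(cum_cM), length(pos_bp) >= 2)
  o <- order(pos_bp)
  pos_bp <- as.numeric(pos_bp[o])
  cum_cM <- as.numeric(cum_cM[o])
  if (any(diff(pos_bp) <= 0)) stop("anchor positions must be strictly increasing")
  if (any(diff(cum_cM) < 0)) stop("cumulative cM must be nondecreasing")
  rate <- diff(cum_cM) / diff(pos_bp) * 1e6   # cM per Mb on each interval
  structure(list(pos_bp = pos_bp, cum_cM = cum_cM,
                 rate_cM_Mb = rate, chrom = chrom),
            class = "recombination_map")
}

#' @exportS3Method base::print
print.recombination_map <- function(x, ...) {
  cat(sprintf("recombination_map: %d anchors, %.0f bp, %.2f cM (mean %.2f cM/Mb)\n",
              length(x$pos_bp), diff(range(x$pos_bp)), max(x$cum_cM) - min(x$cum_cM),
              (max(x$cum_cM) - min(x$cum_cM)) / diff(range(x$pos_bp)) * 1e6))
  invisible(x)
}

#' Local recombination rate at physical positions
#'
#' Evaluates the map's piecewise-constant finite-difference rate at each
#' query position. Queries outside the map span are clamped to the boundary
#' rate (with a warning).
#'
#' @param map a [recombination_map()].
#' @param pos physical positions (bp).
#' @return numeric vector of local rates in cM/Mb.
#' @export
local_recomb_rate <- function(map, pos) {
  pos <- as.numeric(pos)
  out_of_span <- pos < min(map$pos_bp) | pos > max(map$pos_bp)
  if (any(out_of_span)) {
    warning(sprintf("%d position(s) outside map span; boundary rate used",
                    sum(out_of_span)))
  }
  idx <- findInterval(pos, map$pos_bp, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(map$rate_cM_Mb))
  map$rate_cM_Mb[idx]
}

#' Interpolate genetic positions (cM) at physical positions
#'
#' Linear interpolation of cumulative genetic distance between anchors,
#' clamped outside the span.
#'
#' @inheritParams local_recomb_rate
#' @return numeric vector of genetic positions in cM.
#' @export
genetic_position <- function(map, pos) {
  stats::approx(map$pos_bp, map$cum_cM, xout = pos, rule = 2)$y
}

#' Construct / validate an environment table
#'
#' Per-population habitat covariates: habitat type, lake depth (m), lake
#' area (ha), percent light transmission at 400 nm (T400), a blackwater
#' flag, watershed and the number of sequenced individuals. T400 may be
#' missing only for marine or stream rows.
#'
#' @param df data frame with columns `abbreviation`, `habitat`, `depth_m`,
#'   `area_ha`, `t400`, `blackwater`, `watershed`, `n` (extra columns are
#'   kept).
#' @return the validated data frame with class `environment_table` prepended.
#' @export
environment_table <- function(df) {
  df <- as.data.frame(df)
  needed <- c("abbreviation", "habitat", "t400", "n")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("environment table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$n < 1)) stop("n must be >= 1 for every population")
  bad_t400 <- is.na(df$t400) & !(df$habitat %in% c("marine", "stream"))
  if (any(bad_t400)) {
    stop("T400 missing for non-marine, non-stream population(s): ",
         paste(df$abbreviation[bad_t400], collapse = ", "))
  }
  ok <- is.na(df$t400) | (df$t400 >= 0 & df$t400 <= 100)
  if (!all(ok)) stop("t400 must lie in [0, 100]")
  class(df) <- c("environment_table", class(df))
  df
}

#' Read an environment table from CSV
#'
#' @param path CSV file with the [environment_table()] schema.
#' @return an [environment_table()].
#' @export
read_environment <- function(path) {
  environment_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The Haida Gwaii population survey shipped with the package
#'
#' The 29 sampled stickleback populations (27 Haida Gwaii and coastal
#' British Columbia freshwater sites, one marine site, and the Roadside Pond
#' transplant population) with habitat type, lake depth and area, percent
#' light transmission at 400 nm (T400), blackwater flag, watershed and the
#' number of sequenced individuals.
#'
#' @return an [environment_table()] with 29 rows.
#' @export
haida_gwaii_populations <- function() {
  path <- system.file("extdata", "haida_gwaii_populations.csv",
                      package = "sweeplight", mustWork = TRUE)
  read_environment(path)
}

#' Read a recombination map from a 3-column text file
#'
#' @param path whitespace- or tab-separated file with columns chrom, pos
#'   (bp) and cumulative cM; a header line is detected and skipped.
#' @return a [recombination_map()].
#' @export
read_recomb_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\\s+\\d", first) ||
    is.na(suppressWarnings(as.numeric(strsplit(first, "\\s+")[[1]][2])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "pos", "cM")
  recombination_map(df$pos, df$cM, chrom = df$chrom[1])
}

#' Write a recombination map to a 3-column text file
#'
#' @param map a [recombination_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recomb_map <- function(map, path) {
  df <- data.frame(chrom = map$chrom, pos = map$pos_bp, cM = map$cum_cM)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
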