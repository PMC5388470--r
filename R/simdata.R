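# Synthetic-data generator emulating the study system's three data layers:
# a multi-population haplotype panel with a shared selective sweep, a
# source/transplant population pair descended from 100 founders, and
# per-population light-environment covariates.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv()))
  force(expr)
}

#' Simulate a neutral phased haplotype panel
#'
#' Coalescent-free mosaic-copying generative model: a small founder set
#' carries site alleles with a rare-skewed frequency spectrum
#' (founder-copy counts drawn with probability proportional to 1/i, the
#' neutral expectation); each output haplotype copies from the founders
#' with crossover switch points falling at exponential spacings along the
#' genetic map, plus fresh private mutations. Phased by construction.
#'
#' @param n_hap number of haplotypes (>= 4).
#' @param n_snp number of SNP sites.
#' @param chrom_length_bp chromosome length (default 1e6).
#' @param recomb_cM_Mb recombination rate of the emitted map in cM/Mb: a
#'   single value for a uniform map, or a vector of per-segment rates over
#'   equal-length chromosome segments (default 3).
#' @param n_founders founder haplotypes in the copying pool (default 80).
#' @param switches_per_cM expected mosaic switch points per cM, an
#'   effective ancestry depth (default 2).
#' @param mutation_prob per-haplotype probability that any given site
#'   receives a fresh private mutation (default 0.002).
#' @param seed integer seed; output is bit-reproducible under it.
#' @param chrom chromosome label.
#' @return list with `hm` (a [haplotype_matrix()]) and `map`
#'   (a [recombination_map()]).
#' @export
simulate_neutral_panel <- function(n_hap, n_snp, chrom_length_bp = 1e6,
                                   recomb_cM_Mb = 3, n_founders = 80,
                                   switches_per_cM = 2,
                                   mutation_prob = 0.002, seed = NULL,
                                   chrom = "chr1") {
  stopifnot(n_hap >= 4, n_snp >= 2)
  with_seed(seed, {
    pos <- sort(sample.int(chrom_length_bp - 1, n_snp)) + 0.0
    # a vector of rates describes equal-length chromosome segments
    k <- length(recomb_cM_Mb)
    anchors_bp <- seq(0, chrom_length_bp, length.out = k + 1)
    anchors_cM <- c(0, cumsum(recomb_cM_Mb * diff(anchors_bp) * 1e-6))
    cM <- stats::approx(anchors_bp, anchors_cM, xout = pos)$y
    total_cM <- anchors_cM[k + 1]
    # founder pool with 1/i-skewed founder-copy counts per site
    copies <- sample.int(n_founders - 1, n_snp, replace = TRUE,
                         prob = 1 / seq_len(n_founders - 1))
    founders <- matrix(0L, n_founders, n_snp)
    for (j in seq_len(n_snp)) {
      founders[sample.int(n_founders, copies[j]), j] <- 1L
    }
    haps <- matrix(0L, n_hap, n_snp)
    for (i in seq_len(n_hap)) {
      n_switch <- stats::rpois(1, switches_per_cM * total_cM)
      breaks <- sort(stats::runif(n_switch, 0, total_cM))
      seg <- findInterval(cM, breaks) + 1L
      donors <- sample.int(n_founders, n_switch + 1L, replace = TRUE)
      haps[i, ] <- founders[cbind(donors[seg], seq_len(n_snp))]
      mut <- stats::runif(n_snp) < mutation_prob
      haps[i, mut] <- 1L - haps[i, mut]
    }
    map <- recombination_map(anchors_bp, anchors_cM, chrom = chrom)
    list(hm = haplotype_matrix(haps, pos, cM, chrom = chrom), map = map)
  })
}

#' Inject a selective-sweep haplotype into a panel
#'
#' Copies one randomly chosen panel haplotype's alleles over a target
#' interval into a `carrier_freq` fraction of haplotypes, with
#' exponential-tailed breakpoints extending beyond the interval edges
#' (realistic EHH shoulders). Carrier rows and the donor are recorded as
#' ground truth.
#'
#' @param hm a [haplotype_matrix()].
#' @param interval `c(start_bp, end_bp)` of the swept segment.
#' @param carrier_freq fraction of haplotypes carrying the sweep
#'   (default 0.8).
#' @param shoulder_bp mean exponential extension beyond each edge
#'   (default 20000).
#' @param seed integer seed.
#' @return the modified [haplotype_matrix()] with attribute `sweep_truth`:
#'   list(`interval`, `carriers`, `donor`, `focal_site`).
#' @export
inject_sweep <- function(hm, interval, carrier_freq = 0.8,
                         shoulder_bp = 2e4, seed = NULL) {
  stopifnot(carrier_freq > 0, carrier_freq <= 1)
  with_seed(seed, {
    n <- nrow(hm$haps)
    donor <- sample.int(n, 1)
    n_carrier <- max(2L, round(carrier_freq * n))
    carriers <- sort(sample.int(n, n_carrier))
    pos <- hm$positions_bp
    for (i in carriers) {
      lo <- interval[1] - stats::rexp(1, 1 / shoulder_bp)
      hi <- interval[2] + stats::rexp(1, 1 / shoulder_bp)
      idx <- which(pos >= lo & pos <= hi)
      hm$haps[i, idx] <- hm$haps[donor, idx]
    }
    in_iv <- which(pos >= interval[1] & pos <= interval[2])
    focal <- if (length(in_iv)) in_iv[ceiling(length(in_iv) / 2)] else NA_integer_
    attr(hm, "sweep_truth") <- list(interval = interval,
                                    carriers = carriers, donor = donor,
                                    focal_site = focal)
    hm
  })
}

#' Configuration for a synthetic adaptive radiation
#'
#' Defaults mirror the sampled lake survey shipped with the package: its
#' population codes, per-population sample sizes and T400 values, a sweep
#' haplotype at high frequency in blackwater populations, and 7
#' nonsynonymous plus 4 synonymous coding variants riding on the swept
#' segment in near-perfect linkage (5% recombinant leakage).
#'
#' @param env an [environment_table()]; default
#'   [haida_gwaii_populations()].
#' @param n_snp SNPs on the simulated chromosome (default 1200).
#' @param chrom_length_bp chromosome length (default 1.2e6).
#' @param sweep_interval swept segment (default the central 150 kb).
#' @param association_strength 0..1: how strongly sweep-haplotype
#'   frequency tracks the blackwater flag (default 0.9; 0 gives a null
#'   radiation with frequency 0.5 everywhere).
#' @param n_nonsyn,n_syn linked coding variants on the swept segment
#'   (defaults 7 and 4).
#' @param leakage probability that a carrier haplotype recombines off a
#'   coding variant (default 0.05).
#' @param recomb_cM_Mb,n_founders,switches_per_cM,mutation_prob passed to
#'   [simulate_neutral_panel()].
#' @return a config list for [simulate_radiation()].
#' @export
radiation_config <- function(env = haida_gwaii_populations(),
                             n_snp = 1200, chrom_length_bp = 1.2e6,
                             sweep_interval = NULL,
                             association_strength = 0.9,
                             n_nonsyn = 7, n_syn = 4, leakage = 0.05,
                             recomb_cM_Mb = 3, n_founders = 80,
                             switches_per_cM = 2, mutation_prob = 0.002) {
  if (is.null(sweep_interval)) {
    mid <- chrom_length_bp / 2
    sweep_interval <- c(mid - 7.5e4, mid + 7.5e4)
  }
  list(env = env, n_snp = n_snp, chrom_length_bp = chrom_length_bp,
       sweep_interval = sweep_interval,
       association_strength = association_strength,
       n_nonsyn = n_nonsyn, n_syn = n_syn, leakage = leakage,
       recomb_cM_Mb = recomb_cM_Mb, n_founders = n_founders,
       switches_per_cM = switches_per_cM, mutation_prob = mutation_prob)
}

#' Simulate a multi-population adaptive radiation
#'
#' Builds a phased panel for all sequenced individuals of the configured
#' populations from a shared founder pool, then plants a sweep haplotype
#' whose per-population frequency tracks the blackwater flag with the
#' configured association strength: blackwater populations carry it at
#' frequency `0.5 + 0.45 * strength`, clearwater at `0.5 - 0.4 * strength`
#' (marine/stream intermediate at 0.5). Coding variants (nonsynonymous and
#' synonymous) sit on the swept segment: carriers show the reference state
#' (0), non-carriers the alternate (1), with recombinant leakage.
#'
#' @param cfg a [radiation_config()].
#' @param seed integer seed.
#' @return list with `hm` ([haplotype_matrix()] incl. sample map), `gm`
#'   ([genotype_matrix()]), `env`, `map`, and `truth` (sweep interval,
#'   per-population sweep frequency, carrier rows, coding-site indices and
#'   classes).
#' @export
simulate_radiation <- function(cfg = radiation_config(), seed = NULL) {
  with_seed(seed, {
    env <- cfg$env
    n_ind <- sum(env$n)
    n_hap <- 2 * n_ind
    panel <- simulate_neutral_panel(
      n_hap, cfg$n_snp, cfg$chrom_length_bp,
      recomb_cM_Mb = cfg$recomb_cM_Mb, n_founders = cfg$n_founders,
      switches_per_cM = cfg$switches_per_cM,
      mutation_prob = cfg$mutation_prob, seed = NULL
    )
    hm <- panel$hm
    pos <- hm$positions_bp
    iv <- cfg$sweep_interval
    in_iv <- which(pos >= iv[1] & pos <= iv[2])
    if (length(in_iv) < cfg$n_nonsyn + cfg$n_syn + 2) {
      stop("sweep interval contains too few SNPs for the coding variants")
    }
    # the sweep haplotype is a run of reference alleles over the interval
    donor_alleles <- rep(0L, length(in_iv))
    habitat <- blackwater_classify(env$t400)
    strength <- cfg$association_strength
    f_pop <- ifelse(is.na(habitat), 0.5,
                    ifelse(habitat == "blackwater",
                           0.5 + 0.45 * strength, 0.5 - 0.4 * strength))
    pop_of_hap <- rep(rep(env$abbreviation, env$n), each = 2)
    carriers <- stats::runif(n_hap) < f_pop[match(pop_of_hap, env$abbreviation)]
    for (i in which(carriers)) {
      lo <- iv[1] - stats::rexp(1, 1 / 2e4)
      hi <- iv[2] + stats::rexp(1, 1 / 2e4)
      idx <- which(pos >= lo & pos <= hi)
      hm$haps[i, idx] <- 0L
    }
    # coding variants inside the interval: carriers reference, others alt
    coding_idx <- sort(sample(in_iv, cfg$n_nonsyn + cfg$n_syn))
    coding_class <- sample(rep(c("nonsynonymous", "synonymous"),
                               c(cfg$n_nonsyn, cfg$n_syn)))
    for (k in coding_idx) {
      allele <- ifelse(carriers, 0L, 1L)
      flip <- stats::runif(n_hap) < cfg$leakage
      allele[flip] <- 1L - allele[flip]
      hm$haps[, k] <- allele
    }
    ind_ids <- paste0(rep(env$abbreviation, env$n), "_",
                      unlist(lapply(env$n, seq_len)))
    hm$sample_map <- data.frame(
      individual = rep(ind_ids, each = 2),
      population = pop_of_hap, stringsAsFactors = FALSE
    )
    gm <- haplotypes_to_genotypes(hm, individuals = ind_ids,
                                  populations = rep(env$abbreviation, env$n))
    truth <- list(sweep_interval = iv, sweep_freq = stats::setNames(f_pop, env$abbreviation),
                  carriers = which(carriers), coding_sites = coding_idx,
                  coding_class = coding_class)
    list(hm = hm, gm = gm, env = env, map = panel$map, truth = truth)
  })
}

#' Configuration for a synthetic transplant experiment
#'
#' Defaults mirror the study design: 100 founders, 13 generations, source
#' and transplant samples of 12 and 11 diploids, a focal allele starting
#' at frequency 0.13 that is favored in the new habitat, linked variants
#' hitchhiking with 5% leakage, and a genome-wide backdrop of unlinked
#' neutral SNPs that experience the same bottleneck.
#'
#' @param p0 founder frequency of the focal (favored) allele
#'   (default 0.13).
#' @param s selection coefficient (default 0.28).
#' @param h dominance (default 0.5).
#' @param n_founders census size (default 100).
#' @param generations generations of selection/drift (default 13).
#' @param n_source,n_transplant sampled diploids (defaults 12, 11).
#' @param n_unlinked unlinked neutral SNPs (default 2000).
#' @param n_linked hitchhiking linked SNPs (default 10).
#' @param leakage recombination leakage of linked SNPs off the focal
#'   haplotype (default 0.05).
#' @return a config list for [simulate_transplant()].
#' @export
transplant_config <- function(p0 = 0.13, s = 0.28, h = 0.5,
                              n_founders = 100, generations = 13,
                              n_source = 12, n_transplant = 11,
                              n_unlinked = 2000, n_linked = 10,
                              leakage = 0.05) {
  list(p0 = p0, s = s, h = h, n_founders = n_founders,
       generations = generations, n_source = n_source,
       n_transplant = n_transplant, n_unlinked = n_unlinked,
       n_linked = n_linked, leakage = leakage)
}

#' Simulate a source/transplant selection experiment
#'
#' The focal allele follows a selected Wright-Fisher trajectory
#' ([wf_simulate()]); linked SNPs ride the focal haplotype with
#' recombinant leakage; unlinked SNPs (starting frequencies drawn from a
#' rare-skewed spectrum) drift neutrally through the same
#' 100-founder bottleneck. Source genotypes are sampled at founder
#' frequencies, transplant genotypes after the trajectory.
#'
#' @param cfg a [transplant_config()].
#' @param seed integer seed.
#' @return list with `source_gm`, `transplant_gm` (genotype matrices over
#'   focal + linked + unlinked sites), and `truth` (site classes, founder
#'   and final population frequencies, the focal trajectory).
#' @export
simulate_transplant <- function(cfg = transplant_config(), seed = NULL) {
  with_seed(seed, {
    wf <- wf_simulate(cfg$p0, cfg$s, cfg$h, cfg$n_founders,
                      cfg$generations, cfg$n_source, cfg$n_transplant,
                      seed = NULL)
    # unlinked neutral SNPs: rare-skewed founder frequencies, pure drift
    two_n <- 2 * cfg$n_founders
    counts0 <- sample.int(two_n - 1, cfg$n_unlinked, replace = TRUE,
                          prob = 1 / seq_len(two_n - 1))
    p_un <- counts0 / two_n
    p_drift <- p_un
    for (t in seq_len(cfg$generations)) {
      p_drift <- stats::rbinom(cfg$n_unlinked, two_n, p_drift) / two_n
    }
    # linked SNPs: carried by the focal haplotype, with leakage both ways
    p_link0 <- rep(cfg$leakage + (1 - 2 * cfg$leakage) * cfg$p0, cfg$n_linked)
    p_linkT <- cfg$leakage + (1 - 2 * cfg$leakage) * wf$p_final
    sample_geno <- function(p_focal, p_link, p_unlink, n_ind) {
      probs <- c(p_focal, rep(p_link, length.out = cfg$n_linked), p_unlink)
      t(vapply(probs, function(p) stats::rbinom(n_ind, 2, p),
               numeric(n_ind)))
    }
    src <- sample_geno(cfg$p0, p_link0, p_un, cfg$n_source)
    trn <- sample_geno(wf$p_final, p_linkT, p_drift, cfg$n_transplant)
    n_site <- 1 + cfg$n_linked + cfg$n_unlinked
    variants <- data.frame(
      chrom = "chr1", pos = seq_len(n_site) * 1000,
      ref = "A", alt = "T", qual = NA_real_, mean_depth = NA_real_,
      ref_reads = NA_real_, alt_reads = NA_real_,
      n_alleles = 2L, is_indel = FALSE, stringsAsFactors = FALSE
    )
    mk_gm <- function(geno, prefix, n_ind, pop) {
      genotype_matrix(t(geno), paste0(prefix, seq_len(n_ind)),
                      rep(pop, n_ind), variants)
    }
    source_gm <- mk_gm(src, "src", cfg$n_source, "MAYR")
    transplant_gm <- mk_gm(trn, "trn", cfg$n_transplant, "RDSP")
    truth <- list(
      site_class = c("focal", rep("linked", cfg$n_linked),
                     rep("unlinked", cfg$n_unlinked)),
      focal_site = 1L,
      p_founder = c(cfg$p0, p_link0, p_un),
      p_final = c(wf$p_final, p_linkT, p_drift),
      trajectory = wf$trajectory
    )
    list(source_gm = source_gm, transplant_gm = transplant_gm, truth = truth)
  })
}
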