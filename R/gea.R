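# Genotype-environment association: per-gene MDS summaries, general linear
# models against light/depth/area, blackwater classification, and
# single-SNP chi-square association.

#' Blackwater / clearwater habitat classification
#'
#' Lakes transmitting at most 74% of 400 nm light are tannin-stained
#' blackwater; above 74% is clearwater. Missing T400 (marine/stream rows)
#' yields `NA` (unclassified).
#'
#' @param t400 percent light transmission at 400 nm.
#' @param threshold classification threshold (default 74).
#' @return character vector in `{"blackwater", "clearwater", NA}`.
#' @export
blackwater_classify <- function(t400, threshold = 74) {
  ifelse(is.na(t400), NA_character_,
         ifelse(t400 <= threshold, "blackwater", "clearwater"))
}

#' Collapse a gene's SNPs into a single MDS coordinate per individual
#'
#' Classical metric MDS (principal coordinates) on pairwise allele-sharing
#' distance: mean absolute dosage difference over pairwise-complete sites.
#' The first coordinate is returned, sign-fixed to correlate positively
#' with the individual's total alternate-allele dosage (the raw sign of an
#' MDS axis is arbitrary).
#'
#' @param gm a [genotype_matrix()].
#' @param sites site indices of the gene's SNPs (default: all sites).
#' @return numeric vector, one coordinate per individual (zeros with a
#'   warning when all individuals are identical).
#' @export
gene_mds <- function(gm, sites = NULL) {
  if (is.null(sites)) sites <- seq_len(ncol(gm$geno))
  g <- gm$geno[, sites, drop = FALSE]
  n <- nrow(g)
  if (n < 3) stop("need at least 3 individuals for an MDS coordinate")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- !is.na(g[i, ]) & !is.na(g[j, ])
      d[i, j] <- d[j, i] <- if (any(shared))
        mean(abs(g[i, shared] - g[j, shared])) else 0
    }
  }
  if (all(d == 0)) {
    warning("all individuals identical over the gene's SNPs; zero coordinate")
    return(stats::setNames(rep(0, n), gm$individuals))
  }
  coord <- suppressWarnings(stats::cmdscale(d, k = 1))[, 1]
  dosage <- rowSums(g, na.rm = TRUE)
  if (stats::sd(dosage) > 0 &&
      isTRUE(stats::cor(coord, dosage) < 0)) coord <- -coord
  stats::setNames(coord, gm$individuals)
}

#' General linear model of a gene coordinate against light, depth and area
#'
#' Ordinary least squares of a per-population response (individual MDS
#' coordinates are averaged per population by default, matching
#' population-level degrees of freedom) on three predictors: light
#' (T400 continuous, or the categorical blackwater/clearwater contrast),
#' lake depth (m), and log-transformed lake area. Rows with any missing
#' covariate are dropped.
#'
#' @param y named numeric vector: MDS coordinate per individual, names =
#'   individual ids.
#' @param individuals_pop population code per element of `y`.
#' @param env an [environment_table()].
#' @param light_mode `"continuous"` (T400) or `"categorical"`
#'   (blackwater vs clearwater).
#' @param level `"population"` (default: response averaged per population)
#'   or `"individual"`.
#' @return data frame with one row per predictor: `term`, `beta`, `t`,
#'   `p`, plus attributes `fit` (the `lm` object) and `n` (rows used).
#' @export
glm_fit <- function(y, individuals_pop, env,
                    light_mode = c("continuous", "categorical"),
                    level = c("population", "individual")) {
  light_mode <- match.arg(light_mode)
  level <- match.arg(level)
  stopifnot(length(y) == length(individuals_pop))
  df <- data.frame(y = y, pop = individuals_pop, stringsAsFactors = FALSE)
  if (level == "population") {
    df <- stats::aggregate(y ~ pop, df, mean)
  }
  m <- match(df$pop, env$abbreviation)
  if (anyNA(m)) stop("population code(s) not in environment table: ",
                     paste(unique(df$pop[is.na(m)]), collapse = ", "))
  df$t400 <- env$t400[m]
  df$depth <- env$depth_m[m]
  df$log_area <- log(env$area_ha[m] * 1e4)  # hectares to square meters
  df$habitat_class <- blackwater_classify(df$t400)
  df <- df[stats::complete.cases(df[c("y", "t400", "depth", "log_area")]), ]
  light <- if (light_mode == "continuous") "t400" else "habitat_class"
  if (light_mode == "categorical") {
    df$habitat_class <- factor(df$habitat_class,
                               levels = c("clearwater", "blackwater"))
  }
  form <- stats::as.formula(paste("y ~", light, "+ depth + log_area"))
  qrfit <- stats::lm(form, data = df)
  if (qrfit$rank < length(stats::coef(qrfit))) {
    aliased <- names(which(is.na(stats::coef(qrfit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(qrfit)$coefficients
  terms <- rownames(sm)[-1]   # drop intercept
  out <- data.frame(term = c("light", "depth", "log_area"),
                    beta = sm[-1, 1], t = sm[-1, 3], p = sm[-1, 4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- qrfit
  attr(out, "n") <- nrow(df)
  attr(out, "light_mode") <- light_mode
  out
}

#' Genotype-environment association scan over several genes
#'
#' Runs [gene_mds()] + [glm_fit()] per gene and applies Bonferroni
#' correction across the whole gene-by-predictor family.
#'
#' @param gm a [genotype_matrix()].
#' @param gene_sets named list of site-index vectors, one per gene.
#' @param env an [environment_table()].
#' @param light_mode,level passed to [glm_fit()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame with `gene`, `term`, `beta`, `t`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
gea_scan <- function(gm, gene_sets, env,
                     light_mode = c("continuous", "categorical"),
                     level = c("population", "individual"), alpha = 0.05) {
  light_mode <- match.arg(light_mode)
  level <- match.arg(level)
  rows <- lapply(names(gene_sets), function(gene) {
    coord <- gene_mds(gm, gene_sets[[gene]])
    fit <- glm_fit(coord, gm$populations, env, light_mode, level)
    fit$gene <- gene
    fit
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out[c("gene", "term", "beta", "t", "p", "p_bonferroni", "significant")]
}

#' Single-SNP chi-square association with habitat
#'
#' Per SNP, a 2x2 allele-count table (reference/alternate allele counts by
#' habitat class) is tested with Pearson's chi-square without continuity
#' correction; p-values are Bonferroni-corrected over the tested SNPs.
#' SNPs with an empty table margin are flagged undefined.
#'
#' @param gm a [genotype_matrix()].
#' @param habitat habitat class per individual (2 levels).
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame per SNP: `site`, `pos`, `chisq`, `p`,
#'   `p_bonferroni`, `significant`, `defined`.
#' @export
snp_chisq <- function(gm, habitat, alpha = 0.05) {
  habitat <- as.factor(habitat)
  stopifnot(length(habitat) == nrow(gm$geno), nlevels(habitat) == 2)
  lv <- levels(habitat)
  res <- lapply(seq_len(ncol(gm$geno)), function(j) {
    g <- gm$geno[, j]
    tab <- sapply(lv, function(h) {
      gh <- g[habitat == h & !is.na(g)]
      c(alt = sum(gh), ref = 2 * length(gh) - sum(gh))
    })
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(data.frame(site = j, pos = gm$variants$pos[j],
                        chisq = NA_real_, p = NA_real_, defined = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(site = j, pos = gm$variants$pos[j],
               chisq = unname(ct$statistic), p = unname(ct$p.value),
               defined = TRUE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * sum(out$defined))
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}
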