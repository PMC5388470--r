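# VCF round trips, hard site/genotype filters, dataset partitions, and
# recombination-map queries.

test_that("VCF round trip preserves genotypes, samples and missingness", {
  geno <- matrix(c(0, 1, 2, NA, 1,
                   2, 0, 1, 1, NA,
                   0, 0, 2, 1, 1), nrow = 3, byrow = TRUE)
  depths <- matrix(7, 3, 5)
  gm <- quick_gm(geno, depths = depths)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(dim(back$geno), c(3, 5))
  expect_equal(unname(back$geno), unname(gm$geno))
  expect_identical(back$individuals, gm$individuals)
  expect_equal(back$variants$pos, gm$variants$pos)
  # independent text parse of the file: count missing genotype cells
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  cells <- unlist(lapply(strsplit(lines, "\t"), function(x) x[10:12]))
  expect_equal(sum(grepl("^\\./\\.", cells)), 2)
  expect_equal(sum(is.na(back$geno)), 2)
})

test_that("empty VCF body loads as empty tables without error", {
  path <- tempfile(fileext = ".vcf")
  gm <- quick_gm(matrix(numeric(0), nrow = 3, ncol = 0))
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(ncol(back$geno), 0)
  expect_equal(nrow(back$variants), 0)
})

test_that("triallelic records load with n_alleles = 3", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "C,G", "50", "PASS", ".", "GT",
            "0/1", "1/2"), collapse = "\t")
  ), path)
  back <- read_vcf(path)
  expect_equal(back$variants$n_alleles, 3L)
})

test_that("single-sample VCFs keep the individuals-by-sites orientation", {
  gm <- quick_gm(matrix(c(0, 1, 2, NA), 1, 4))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(dim(back$geno), c(1, 4))
  expect_equal(unname(back$geno), unname(gm$geno))
})

test_that("site filters enforce each rule and keep clean records", {
  # 7 records: one violating each of the 5 rules + 2 clean
  variants <- data.frame(
    chrom = "chr1", pos = 1:7 * 100, ref = "A",
    alt = c("T", "T", "T", "T,G", "TT", "T", "T"),
    qual = c(44, rep(50, 6)),                 # record 1: quality < 45
    mean_depth = c(8, 12, 8, 8, 8, 8, 8),     # record 2: depth > 9.51
    ref_reads = c(10, 10, 3, 10, 10, 10, 10), # record 3: < 4 reads each allele
    alt_reads = rep(10, 7),
    n_alleles = c(2, 2, 2, 3, 2, 2, 2),       # record 4: triallelic
    is_indel = c(F, F, F, F, T, F, F),        # record 5: indel
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(matrix(1, 2, 7), c("a", "b"), c("p", "p"), variants)
  kept <- filter_sites(gm, max_mean_depth = 9.51)
  expect_equal(nrow(kept$variants), 2)
  expect_equal(kept$variants$pos, c(600, 700))
})

test_that("site filters retain identical clean records and warn on empty", {
  variants <- data.frame(chrom = "chr1", pos = 1:4 * 10, ref = "A", alt = "T",
                         qual = 50, mean_depth = 8, ref_reads = 9,
                         alt_reads = 9, n_alleles = 2L, is_indel = FALSE)
  gm <- genotype_matrix(matrix(1, 2, 4), c("a", "b"), c("p", "p"), variants)
  expect_equal(nrow(filter_sites(gm, max_mean_depth = 9.51)$variants), 4)
  expect_warning(out <- filter_sites(gm, min_qual = 99, max_mean_depth = 9.51),
                 "no sites")
  expect_equal(ncol(out$geno), 0)
})

test_that("auto depth ceiling is mean + 1.5 IQR with type-7 quantiles", {
  md <- c(5, 6, 7, 8)
  expect_equal(auto_depth_threshold(md),
               6.5 + 1.5 * (quantile(md, 0.75, type = 7) -
                              quantile(md, 0.25, type = 7)),
               ignore_attr = TRUE)
  expect_equal(auto_depth_threshold(md), 8.75)
})

test_that("genotype filters mask low-depth calls then drop high-missing sites", {
  geno <- matrix(1, 10, 3)
  depths <- matrix(10, 10, 3)
  depths[1:6, 1] <- 3       # site 1: 60% masked -> dropped
  depths[1:5, 2] <- 3       # site 2: exactly 50% -> retained
  gm <- quick_gm(geno, depths = depths)
  out <- filter_genotypes(gm)
  expect_equal(ncol(out$geno), 2)
  expect_equal(out$variants$pos, c(200, 300))
  expect_equal(sum(is.na(out$geno[, 1])), 5)
  # all depths >= 4: identity
  gm2 <- quick_gm(geno, depths = matrix(10, 10, 3))
  expect_identical(filter_genotypes(gm2)$geno, gm2$geno)
})

test_that("filtering is idempotent and its order is the canonical one", {
  set.seed(42)
  geno <- matrix(sample(c(0, 1, 2), 40, replace = TRUE), 8, 5)
  depths <- matrix(sample(2:10, 40, replace = TRUE), 8, 5)
  gm <- quick_gm(geno, depths = depths)
  once <- filter_genotypes(filter_sites(gm, max_mean_depth = 20))
  twice <- filter_genotypes(filter_sites(once, max_mean_depth = 20))
  expect_identical(once$geno, twice$geno)
  expect_identical(once$variants, twice$variants)

  # crafted site: 40% missing before depth masking, 60% after -> the
  # canonical order (mask, then site missingness) drops it, whereas
  # missingness-first would keep it
  geno2 <- matrix(1, 10, 1)
  geno2[1:4, 1] <- NA
  depths2 <- matrix(10, 10, 1)
  depths2[5:6, 1] <- 3
  gm2 <- quick_gm(geno2, depths = depths2)
  expect_equal(ncol(filter_genotypes(gm2)$geno), 0)    # canonical
  miss_first <- mean(is.na(gm2$geno[, 1])) > 0.5       # permuted order
  expect_false(miss_first)
})

test_that("dataset partition picks one individual per population, reproducibly", {
  env <- haida_gwaii_populations()
  n_ind <- sum(env$n)
  geno <- matrix(0, n_ind, 3)
  pops <- rep(env$abbreviation, env$n)
  gm <- quick_gm(geno, pops = pops)
  parts <- partition_datasets(gm, seed = 11)
  expect_equal(nrow(parts$radiation$geno), 28)
  expect_false("RDSP" %in% parts$radiation$populations)
  expect_equal(sort(unique(parts$experiment$populations)), c("MAYR", "RDSP"))
  expect_equal(nrow(parts$experiment$geno), 23)
  parts2 <- partition_datasets(gm, seed = 11)
  expect_identical(parts$radiation$individuals, parts2$radiation$individuals)
  expect_error(partition_datasets(gm, source = "NOPE", seed = 1), "NOPE")
})

test_that("single-population input yields a radiation partition of one", {
  gm <- quick_gm(matrix(0, 3, 2), pops = rep("MAYR", 3))
  parts <- partition_datasets(gm, transplant = "MAYR", source = "MAYR", seed = 1)
  # transplant population excluded -> empty radiation; use a second pop
  gm2 <- quick_gm(matrix(0, 4, 2), pops = c("AAAA", "AAAA", "AAAA", "MAYR"))
  parts2 <- partition_datasets(gm2, transplant = "MAYR", source = "MAYR", seed = 1)
  expect_equal(nrow(parts2$radiation$geno), 1)
})

test_that("local recombination rates derive from map anchors", {
  flat <- recombination_map(c(0, 1e6, 2e6), c(0, 1, 2))
  expect_equal(local_recomb_rate(flat, c(1e5, 1.5e6)), c(1, 1))
  two <- recombination_map(c(0, 1e6, 2e6), c(0, 2, 2))
  expect_equal(local_recomb_rate(two, 5e5), 2)
  expect_equal(local_recomb_rate(two, 1.5e6), 0)
  expect_warning(r <- local_recomb_rate(two, 3e6), "outside")
  expect_equal(r, 0)
  # rates integrate back to anchor cM
  seg_cm <- local_recomb_rate(two, c(5e5, 1.5e6)) * 1 # 1 Mb segments
  expect_equal(cumsum(seg_cm), c(2, 2))
  # genetic positions interpolate between anchors
  expect_equal(genetic_position(two, c(0, 5e5, 2e6)), c(0, 1, 2))
})

test_that("environment table validation enforces the schema", {
  env <- haida_gwaii_populations()
  expect_s3_class(env, "environment_table")
  expect_equal(nrow(env), 29)
  bad <- env
  bad$t400[bad$abbreviation == "MAYR"] <- NA
  expect_error(environment_table(bad), "MAYR")
})

test_that("recombination map text round trips", {
  map <- recombination_map(c(0, 5e5, 2e6), c(0, 1.2, 3.4), chrom = "chrX")
  path <- tempfile(fileext = ".txt")
  write_recomb_map(map, path)
  back <- read_recomb_map(path)
  expect_equal(back$pos_bp, map$pos_bp)
  expect_equal(back$cum_cM, map$cum_cM)
})
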