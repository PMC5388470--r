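# EHH decay, iHS, window-iHS and H12 against trivial cases and the
# brute-force pair-enumeration oracles.

test_that("EHH is 1 everywhere for identical carriers and at the core", {
  identical_carriers <- ehh(haplotype_matrix(matrix(1L, 4, 6), 1:6 * 100),
                            3, 1, cutoff = 0)
  expect_true(all(identical_carriers$ehh == 1))
  hm <- rand_panel(10, 12, 500)
  d <- ehh(hm, 5, hm$haps[1, 5], cutoff = 0)
  expect_equal(d$ehh[d$side == "core"], 1)
  # nonincreasing outward on each flank
  for (s in c("left", "right")) {
    v <- d$ehh[d$side == s]
    if (s == "left") v <- rev(v)
    expect_true(all(diff(c(1, v)) <= 1e-12))
  }
})

test_that("EHH matches the hand-derived 4-carrier case", {
  # carriers 0000, 0001, 0010, 0011 seen from core at site 1
  haps <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0), c(0, 0, 1, 1))
  hm <- haplotype_matrix(haps, c(100, 200, 300, 400))
  d <- ehh(hm, 1, 0, cutoff = 0)
  right <- d[d$side == "right", ]
  expect_equal(right$ehh[right$site == 2], 1)
  expect_equal(right$ehh[right$site == 3], 2 / 6)
  expect_equal(right$ehh[right$site == 4], 0)
})

test_that("EHH is flagged undefined with fewer than two carriers", {
  haps <- rbind(c(1, 0), c(0, 0), c(0, 1))
  hm <- haplotype_matrix(haps, c(10, 20))
  d <- ehh(hm, 1, 1)
  expect_equal(nrow(d), 0)
  expect_true(attr(d, "undefined"))
})

test_that("EHH equals the brute-force enumeration oracle on random panels", {
  for (seed in 1:40) {
    hm <- rand_panel(sample(6:32, 1), sample(10:64, 1), seed)
    core <- sample(ncol(hm$haps), 1)
    for (allele in 0:1) {
      if (sum(hm$haps[, core] == allele) < 2) next
      d <- ehh(hm, core, allele, cutoff = 0)
      for (r in sample(nrow(d), min(6, nrow(d)))) {
        expect_equal(d$ehh[r], oracle_ehh_at(hm$haps, core, allele, d$site[r]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("iHS negates under 0/1 relabeling and standardizes to z-scores", {
  hm <- rand_panel(20, 40, 99)
  mirror <- haplotype_matrix(1L - hm$haps, hm$positions_bp, hm$positions_cM)
  r1 <- ihs(hm)
  r2 <- ihs(mirror)
  ok <- r1$flag %in% c("ok", "edge") & r2$flag %in% c("ok", "edge")
  expect_equal(r1$ihs_unstd[ok], -r2$ihs_unstd[ok], tolerance = 1e-12)

  p <- simulate_neutral_panel(60, 1500, 1e6, seed = 5)
  r <- ihs(p$hm)
  usable <- !is.na(r$ihs_std)
  for (b in unique(r$freq_bin[usable])) {
    v <- r$ihs_std[usable & r$freq_bin == b]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-9)
      expect_lt(abs(sd(v) - 1), 1e-9)
    }
  }
})

test_that("iHH integration matches the brute-force oracle", {
  for (seed in 41:60) {
    hm <- rand_panel(sample(8:16, 1), sample(20:40, 1), seed)
    r <- ihs(hm, standardize = FALSE)
    pick <- r[r$flag %in% c("ok", "edge"), ]
    if (!nrow(pick)) next
    for (row in sample(nrow(pick), min(3, nrow(pick)))) {
      s <- pick$site[row]
      o_ref <- oracle_ihh(hm$haps, hm$positions_bp, hm$positions_cM, s, 0)
      o_alt <- oracle_ihh(hm$haps, hm$positions_bp, hm$positions_cM, s, 1)
      expect_equal(pick$ihh_ref[row], o_ref$ihh, tolerance = 1e-10)
      expect_equal(pick$ihh_alt[row], o_alt$ihh, tolerance = 1e-10)
    }
  }
})

test_that("iHS gap rule invalidates sites across large physical gaps", {
  haps <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  pos <- c(seq(1000, 15000, length.out = 15), seq(400000, 414000, length.out = 15))
  hm <- haplotype_matrix(haps, pos, pos * 1e-6)
  r <- ihs(hm, maf_min = 0)
  # sites adjacent to the 385 kb gap cannot integrate across it
  expect_true(any(r$flag == "gap"))
})

test_that("window-iHS computes exceedance fractions with the > 10 score rule", {
  df <- data.frame(pos_bp = c(rep(5000, 12), rep(15000, 10)),
                   ihs_std = c(c(2.5, -2.2, 3.0), rep(0.5, 9), rep(0.2, 10)))
  w <- window_ihs(df, window_bp = 1e4, chrom = "chr1")
  expect_equal(nrow(w), 1)   # second window has exactly 10 scores -> omitted
  expect_equal(w$value, 3 / 12)
  expect_equal(w$n, 12)
  expect_equal(c(w$start, w$end), c(0, 1e4))
})

test_that("window-iHS fraction approaches the two-sided normal tail mass", {
  set.seed(7)
  n <- 4e4
  df <- data.frame(pos_bp = sort(sample.int(2e7, n)), ihs_std = rnorm(n))
  w <- window_ihs(df, window_bp = 1e4)
  frac <- sum(w$value * w$n) / sum(w$n)
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.005)
  expect_true(all(w$value >= 0 & w$value <= 1))
})

test_that("H12 matches closed forms and the string-tabulation oracle", {
  # all identical
  hm <- haplotype_matrix(matrix(0L, 8, 81), 1:81 * 10)
  expect_equal(h12_scan(hm)$h12, 1)
  # n distinct singletons: (2/n)^2 + (n-2)/n^2
  set.seed(3)
  haps <- diag(10)[, rep(1:10, length.out = 81)]
  storage.mode(haps) <- "integer"
  hm2 <- haplotype_matrix(haps, 1:81 * 10)
  expect_equal(h12_scan(hm2)$h12, (2 / 10)^2 + (10 - 2) / 100)
  expect_equal(h12_scan(hm2)$h12, 0.12)
  # spectrum {0.5, 0.3, 0.2}
  base <- rbind(matrix(0L, 5, 81), matrix(1L, 3, 81),
                matrix(rep(c(0L, 1L), length.out = 81), 2, 81, byrow = TRUE))
  hm3 <- haplotype_matrix(base, 1:81 * 10)
  expect_equal(h12_scan(hm3)$h12, 0.8^2 + 0.04)
  # oracle on random panels, plus trailing-window omission
  for (seed in 61:80) {
    hm4 <- rand_panel(sample(6:20, 1), 200, seed)
    res <- h12_scan(hm4, snps_per_window = 81)
    expect_equal(nrow(res), 2)   # 200 %/% 81, trailing 38 SNPs dropped
    for (k in seq_len(nrow(res))) {
      expect_equal(res$h12[k],
                   oracle_h12(hm4$haps, res$snp_start[k], res$snp_end[k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("H12 is invariant to row permutation and 0/1 relabeling", {
  hm <- rand_panel(16, 162, 123)
  base <- h12_scan(hm)$h12
  perm <- haplotype_matrix(hm$haps[sample(16), ], hm$positions_bp,
                           hm$positions_cM)
  expect_equal(h12_scan(perm)$h12, base)
  flip <- haplotype_matrix(1L - hm$haps, hm$positions_bp, hm$positions_cM)
  expect_equal(h12_scan(flip)$h12, base)
})

test_that("iHS has directional power at an injected sweep", {
  p <- simulate_neutral_panel(60, 1500, 1e6, seed = 31)
  sw <- inject_sweep(p$hm, c(4e5, 6e5), 0.8, seed = 32)
  r <- ihs(sw)
  inside <- r$pos_bp > 4e5 & r$pos_bp < 6e5
  expect_gt(mean(abs(r$ihs_std[inside]), na.rm = TRUE),
            mean(abs(r$ihs_std), na.rm = TRUE))
})
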