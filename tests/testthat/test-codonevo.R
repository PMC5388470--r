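# NG86 pathway counting, mean pairwise dN/dS, sliding dS, key-site
# classification and minimum-spanning networks.

test_that("NG86 handles the trivial codon cases", {
  same <- ng86_pair("TTTGGG", "TTTGGG")
  expect_equal(same$Nd + same$Sd, 0)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  # TTT -> TTC is synonymous (Phe -> Phe)
  syn <- ng86_pair("TTT", "TTC")
  expect_equal(syn$Sd, 1)
  expect_equal(syn$Nd, 0)
  # nonsynonymous single change
  non <- ng86_pair("TTT", "GTT")
  expect_equal(non$Nd, 1)
  expect_equal(non$Sd, 0)
})

test_that("NG86 site/difference counts equal the pathway-enumeration oracle", {
  # 10-codon toy with multi-hit codons
  a <- "ATGTTTGGACCTAAAGAGTGCCTAATCGAA"
  b <- "ATGTTCGGTCCAAAGGAGTGTTTAATAGAT"
  got <- ng86_pair(a, b)
  want <- oracle_ng86(a, b)
  expect_equal(got$N, want$N, tolerance = 1e-10)
  expect_equal(got$S, want$S, tolerance = 1e-10)
  expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
  expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
  # symmetry and site conservation
  rev <- ng86_pair(b, a)
  expect_equal(got$Nd, rev$Nd)
  expect_equal(got$Sd, rev$Sd)
  expect_equal(got$N + got$S, 3 * nchar(a) / 3)
})

test_that("NG86 equals the oracle on random coding pairs", {
  for (seed in 1:30) {
    a <- rand_cds(sample(4:12, 1), seed)
    b <- mutate_cds(a, sample(1:5, 1), seed + 1000)
    got <- ng86_pair(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$N, want$N, tolerance = 1e-10)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
  }
})

test_that("Jukes-Cantor correction reduces to p in the small-p limit", {
  for (p in c(0.001, 0.01, 0.04)) {
    expect_lt(abs(jukes_cantor(p) - p), p^2)
  }
  expect_true(is.na(jukes_cantor(0.8)))
})

test_that("mean pairwise dN/dS averages defined pairs", {
  a <- rand_cds(30, 7)
  b <- mutate_cds(a, 3, 8)
  aln <- codon_alignment(c(h1 = a, h2 = b))
  res <- mean_pairwise_dnds(aln)
  expect_equal(res$n_pairs, 1)
  single <- ng86_pair(a, b)
  if (!is.na(single$dnds)) expect_equal(res$mean_dnds, single$dnds)
  # panel with only synonymous segregating differences -> mean 0
  syn_aln <- codon_alignment(c(x = "TTTGGACGA", y = "TTCGGACGA",
                               z = "TTTGGGCGA"))
  res_syn <- mean_pairwise_dnds(syn_aln)
  expect_equal(res_syn$mean_dnds, 0)
  # 5-haplotype mean equals averaging the 10 oracle pairs
  seqs <- c(a, b, mutate_cds(a, 2, 9), mutate_cds(a, 4, 10),
            mutate_cds(a, 1, 11))
  names(seqs) <- paste0("h", 1:5)
  aln5 <- codon_alignment(seqs)
  res5 <- mean_pairwise_dnds(aln5)
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- c(vals, ng86_pair(seqs[i], seqs[j])$dnds)
  }
  expect_equal(res5$n_pairs, 10)
  expect_equal(res5$mean_dnds, mean(vals, na.rm = TRUE))
  expect_equal(res5$n_undefined, sum(is.na(vals)))
})

test_that("sliding dS localizes synonymous differences", {
  a <- rand_cds(60, 12)   # 180 nt
  expect_true(all(sliding_ds(a, a)$dS == 0, na.rm = TRUE))
  # place a single synonymous difference: codon 34 TTT -> TTC (nt 102)
  chars <- strsplit(a, "")[[1]]
  chars[(34 * 3 - 2):(34 * 3)] <- c("T", "T", "T")
  a2 <- paste(chars, collapse = "")
  chars[34 * 3] <- "C"
  b2 <- paste(chars, collapse = "")
  win <- sliding_ds(a2, b2)
  hot <- win$start[!is.na(win$dS) & win$dS > 0]
  expect_equal(length(hot), 30)            # exactly the windows covering nt 102
  expect_true(all(hot >= 102 - 29 & hot <= 102))
  # windowed mean approximates global dS for scattered synonymous changes
  a3 <- paste(rep("TTT", 90), collapse = "")
  chars3 <- strsplit(a3, "")[[1]]
  idx <- seq(3, 270, by = 27)
  chars3[idx] <- "C"
  b3 <- paste(chars3, collapse = "")
  global <- ng86_pair(a3, b3)$dS
  win3 <- sliding_ds(a3, b3, window_nt = 30, step_nt = 3)
  expect_equal(mean(win3$dS, na.rm = TRUE), global, tolerance = 0.25 * global)
  expect_error(sliding_ds("TTT", "TTT", window_nt = 30), "longer")
})

test_that("key-site classification follows the two spectral-tuning residues", {
  # codon 1 = site 97, codon 2 = site 109
  key_map <- data.frame(rhodopsin_pos = c(97, 109), codon = c(1, 2))
  aln <- codon_alignment(c(
    red = "AGTGCTTTT",          # S97 + A109
    blue = "TGTGGTTTT",         # C97 + G109
    mixed = "AGTGGTTTT"         # S97 + G109
  ))
  calls <- classify_spectral(aln, key_map)
  expect_equal(calls$class, c("red-shifted", "blue-shifted", "intermediate"))
  # ambiguity classifies as intermediate with a warning
  aln2 <- codon_alignment(c(amb = "ANTGCTTTT"))
  expect_warning(calls2 <- classify_spectral(aln2, key_map), "ambiguity")
  expect_equal(calls2$class, "intermediate")
})

test_that("minimum-spanning haplotype networks keep tied alternatives", {
  # two haplotypes differing at 7 sites -> one edge of weight 7
  a <- paste(rep("TTT", 10), collapse = "")
  chars <- strsplit(a, "")[[1]]
  chars[c(1, 4, 7, 10, 13, 16, 19)] <- "C"
  b <- paste(chars, collapse = "")
  net <- haplotype_network(codon_alignment(c(h1 = a, h2 = b, h3 = a)))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$nodes$count, c(2, 1))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 7)
  # all identical -> single node, no edges
  one <- haplotype_network(codon_alignment(c(x = a, y = a)))
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
  # A-B:1, B-C:1, A-C:2 -> only the two weight-1 spanning edges
  A <- "TTTTTT"
  B <- "CTTTTT"
  C <- "CTTTTC"
  net3 <- haplotype_network(codon_alignment(c(A = A, B = B, C = C)))
  expect_equal(nrow(net3$edges), 2)
  expect_true(all(net3$edges$weight == 1))
  # tie: A-B:1, A-C:1, B-C:... star vs triangle with equal weights
  D1 <- "TTTTTT"; D2 <- "CTTTTT"; D3 <- "TCTTTT"
  netT <- haplotype_network(codon_alignment(c(a = D1, b = D2, c = D3)))
  # b-c distance is 2; the two weight-1 edges span, the weight-2 edge is
  # redundant at its level
  expect_equal(sort(netT$edges$weight), c(1, 1))
  g <- as_igraph(net3)
  expect_equal(igraph::vcount(g), 3)
})

test_that("codon alignments validate frame and flag internal stops", {
  expect_error(codon_alignment(c(a = "TTTG")), "divisible")
  expect_error(codon_alignment(c(a = "TTT", b = "TTTAAA")), "equal length")
  expect_warning(codon_alignment(c(a = "TAATTT")), "stop")
  # FASTA round trip
  aln <- codon_alignment(c(h1 = rand_cds(10, 3), h2 = rand_cds(10, 4)))
  path <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path)
  expect_equal(unclass(back)[, ], unclass(aln)[, ], ignore_attr = TRUE)
})
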