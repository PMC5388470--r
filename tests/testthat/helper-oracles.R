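# Brute-force oracles, independent of the package's incremental /
# compiled algorithms. Everything here works by explicit enumeration on
# small inputs.

# EHH among carriers of `allele` at `core`, at extension site `j`
# (inclusive), by direct string comparison of all carrier pairs.
oracle_ehh_at <- function(haps, core, allele, j) {
  carriers <- which(haps[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  span <- min(core, j):max(core, j)
  strs <- apply(haps[carriers, span, drop = FALSE], 1, paste, collapse = "")
  same <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      if (strs[a] == strs[b]) same <- same + 1
    }
  }
  same / choose(n, 2)
}

# Integrated EHH for one allele class: brute-force EHH at every step,
# trapezoid over cM, same truncation/edge/gap rules as the documented
# algorithm (but EHH values computed by pair enumeration, not incremental
# group refinement).
oracle_ihh <- function(haps, pos_bp, pos_cM, core, allele, cutoff = 0.05,
                       max_gap_bp = 2e5) {
  n_car <- sum(haps[, core] == allele)
  if (n_car < 2) return(list(ihh = NA_real_, flag = "few_carriers"))
  area <- 0
  flag <- "ok"
  for (dir in c(-1, 1)) {
    prev_e <- 1
    prev_cM <- pos_cM[core]
    prev_bp <- pos_bp[core]
    j <- core + dir
    repeat {
      if (j < 1 || j > ncol(haps)) {
        if (prev_e >= cutoff) flag <- "edge"
        break
      }
      if (abs(pos_bp[j] - prev_bp) > max_gap_bp) { flag <- "gap"; break }
      e <- oracle_ehh_at(haps, core, allele, j)
      area <- area + (prev_e + e) / 2 * abs(pos_cM[j] - prev_cM)
      if (e < cutoff) break
      prev_e <- e; prev_cM <- pos_cM[j]; prev_bp <- pos_bp[j]
      j <- j + dir
    }
    if (flag == "gap") break
  }
  list(ihh = area, flag = flag)
}

# H12 over an explicit SNP-index window by tabulating haplotype strings.
oracle_h12 <- function(haps, from, to) {
  strs <- apply(haps[, from:to, drop = FALSE], 1, paste, collapse = "")
  p <- sort(as.vector(table(strs)) / nrow(haps), decreasing = TRUE)
  p2 <- if (length(p) >= 2) p[2] else 0
  (p[1] + p2)^2 + sum(p[-(1:2)]^2)
}

# Per-site mean pairwise difference over genotyped chromosomes, by
# explicitly expanding genotypes into chromosomes and comparing all pairs.
oracle_pi_site <- function(geno_col) {
  g <- geno_col[!is.na(geno_col)]
  chroms <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(chroms)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) diffs <- diffs + (chroms[a] != chroms[b])
  }
  diffs / choose(n, 2)
}

# Tajima's D written out from the variance expression directly in n.
oracle_tajd <- function(S, pi_sum, n) {
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  # variance of (pi - S/a1) per the original derivation
  e1 <- ((n + 1) / (3 * (n - 1)) - 1 / a1) / a1
  e2 <- (2 * (n^2 + n + 3) / (9 * n * (n - 1)) - (n + 2) / (a1 * n) + a2 / a1^2) /
    (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Per-site Hudson FST components, hand-written, summed over a window.
oracle_fst <- function(p1, n1, p2, n2) {
  num <- den <- 0
  for (i in seq_along(p1)) {
    if (n1[i] >= 2 && n2[i] >= 2) {
      num <- num + (p1[i] - p2[i])^2 -
        p1[i] * (1 - p1[i]) / (n1[i] - 1) -
        p2[i] * (1 - p2[i]) / (n2[i] - 1)
      den <- den + p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
    }
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# ---- NG86 oracle: independent genetic code and recursive pathway walk ----

# Genetic code taken from Biostrings (independent of the package's
# hard-coded table).
oracle_code <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- as.character(Biostrings::GENETIC_CODE)
    tab
  }
})

oracle_aa <- function(codon) {
  code <- oracle_code()
  names(code) <- names(Biostrings::GENETIC_CODE)
  unname(code[codon])
}

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_aa(codon)
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_aa(alt) == "*") next
      valid <- valid + 1
      if (oracle_aa(alt) == aa0) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# Recursive enumeration of all shortest pathways between two codons,
# skipping pathways through stop codons (all pathways if every one is
# blocked).
oracle_path_diffs <- function(c1, c2) {
  walk <- function(cur, target, exclude_stops) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dpos)) return(list(c(syn = 0, nonsyn = 0)))
    res <- list()
    for (pos in dpos) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      if (exclude_stops && oracle_aa(nxt) == "*") next
      step <- if (oracle_aa(cur) == oracle_aa(nxt)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, target, exclude_stops)) {
        res[[length(res) + 1]] <- c(syn = step[1] + tail[["syn"]],
                                    nonsyn = step[2] + tail[["nonsyn"]])
      }
    }
    res
  }
  paths <- walk(c1, c2, TRUE)
  if (!length(paths)) paths <- walk(c1, c2, FALSE)
  m <- do.call(rbind, paths)
  c(syn = mean(m[, "syn"]), nonsyn = mean(m[, "nonsyn"]))
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- N <- Sd <- Nd <- 0
  for (k in seq_along(ca)) {
    if (oracle_aa(ca[k]) %in% c("*", NA) || oracle_aa(cb[k]) %in% c("*", NA)) next
    s_k <- (oracle_syn_sites(ca[k]) + oracle_syn_sites(cb[k])) / 2
    S <- S + s_k
    N <- N + 3 - s_k
    if (ca[k] != cb[k]) {
      d <- oracle_path_diffs(ca[k], cb[k])
      Sd <- Sd + d[["syn"]]
      Nd <- Nd + d[["nonsyn"]]
    }
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd)
}

# ---- small random fixtures ----

rand_panel <- function(n_hap, n_snp, seed) {
  set.seed(seed)
  haps <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.6)), n_hap, n_snp)
  pos <- sort(sample.int(n_snp * 1000, n_snp))
  haplotype_matrix(haps, pos, pos * 1e-6 * runif(1, 0.5, 5))
}

# random in-frame coding sequence without stop codons
rand_cds <- function(n_codon, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("T", "C", "A", "G")
  cods <- character(n_codon)
  for (k in seq_len(n_codon)) {
    repeat {
      c0 <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!c0 %in% stops) break
    }
    cods[k] <- c0
  }
  paste(cods, collapse = "")
}

# mutate a coding sequence at n_mut random positions, avoiding stops
mutate_cds <- function(cds, n_mut, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("T", "C", "A", "G")
  chars <- strsplit(cds, "")[[1]]
  positions <- sample(length(chars), n_mut)
  for (p in positions) {
    k <- ceiling(p / 3)
    repeat {
      b <- sample(setdiff(bases, chars[p]), 1)
      trial <- chars
      trial[p] <- b
      cod <- paste(trial[(3 * k - 2):(3 * k)], collapse = "")
      if (!cod %in% stops) { chars <- trial; break }
    }
  }
  paste(chars, collapse = "")
}

# quick genotype_matrix from a plain dosage matrix
quick_gm <- function(geno, pos = NULL, pops = NULL, depths = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100
  if (is.null(pops)) pops <- rep("pop1", nrow(geno))
  variants <- data.frame(chrom = rep("chr1", m), pos = pos,
                         ref = rep("A", m), alt = rep("T", m),
                         qual = rep(50, m), mean_depth = rep(8, m),
                         ref_reads = rep(10, m), alt_reads = rep(10, m),
                         n_alleles = rep(2L, m), is_indel = rep(FALSE, m))
  genotype_matrix(geno, paste0("ind", seq_len(nrow(geno))), pops, variants,
                  depths)
}
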