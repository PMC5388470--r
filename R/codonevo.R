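# Codon-level divergence: NG86-style pairwise dN/dS with equal-weight
# pathway averaging, gene-wide mean pairwise dN/dS, sliding synonymous
# divergence, spectral key-site classification, and minimum-spanning
# haplotype networks.

# Standard genetic code, codons in TCAG order (first base slowest).
GENETIC_CODE_STR <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  aa <- strsplit(GENETIC_CODE_STR, "")[[1]]
  stats::setNames(aa, codons)
}

.codon_env <- new.env()

translate_codon <- function(codon) {
  if (is.null(.codon_env$tab)) .codon_env$tab <- codon_table()
  aa <- .codon_env$tab[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Construct a codon alignment
#'
#' Equal-length, in-frame (length divisible by 3), gap-free aligned coding
#' sequences with haplotype labels. Internal stop codons are tolerated but
#' flagged with a warning.
#'
#' @param seqs named character vector of nucleotide strings, or a character
#'   matrix (rows = sequences).
#' @return object of class `codon_alignment`: a character matrix (rows =
#'   haplotypes, columns = nucleotide positions), uppercase.
#' @export
codon_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) stop("sequences must have equal length")
    mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) %% 3 != 0) stop("alignment length must be divisible by 3")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("hap", seq_len(nrow(mat)))
  n_codon <- ncol(mat) / 3
  for (i in seq_len(nrow(mat))) {
    cods <- codons_of(mat[i, ])
    internal <- cods[-length(cods)]
    if (any(translate_codon(internal) == "*")) {
      warning(sprintf("internal stop codon in sequence '%s'", rownames(mat)[i]))
    }
  }
  structure(mat, class = c("codon_alignment", "matrix"), n_codon = n_codon)
}

codons_of <- function(chars) {
  n <- length(chars) / 3
  vapply(seq_len(n), function(k)
    paste0(chars[3 * k - 2], chars[3 * k - 1], chars[3 * k]), character(1))
}

#' Read an aligned coding FASTA into a codon alignment
#'
#' @param path FASTA file of aligned, in-frame coding sequences.
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  dna <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  codon_alignment(toupper(dna))
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

is_valid_codon <- function(codon) {
  grepl("^[TCAG]{3}$", codon)
}

# Fractional synonymous site count of one codon: per position, the fraction
# of single-base changes (to non-stop codons) that preserve the amino acid.
# Changes producing stop codons are excluded from the denominator, so every
# position still contributes one full site and S + N = 3 per codon.
codon_syn_sites <- function(codon) {
  if (!is_valid_codon(codon) || translate_codon(codon) == "*") return(NA_real_)
  bases <- c("T", "C", "A", "G")
  aa0 <- translate_codon(codon)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    alts <- bases[bases != chars[pos]]
    alt_codons <- vapply(alts, function(b) {
      tmp <- chars; tmp[pos] <- b; paste(tmp, collapse = "")
    }, character(1))
    aas <- translate_codon(alt_codons)
    valid <- aas != "*"
    if (any(valid)) s <- s + sum(aas[valid] == aa0) / sum(valid)
  }
  s
}

# Enumerate all shortest mutational pathways between two codons, average
# synonymous/nonsynonymous step counts with equal weights. Pathways through
# stop codons are excluded; if every pathway is blocked, all pathways are
# used (degenerate fallback).
codon_path_diffs <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  orders <- perms(diff_pos)
  tally <- function(exclude_stops) {
    res <- matrix(NA_real_, nrow = nrow(orders), ncol = 2)
    for (r in seq_len(nrow(orders))) {
      cur <- strsplit(c1, "")[[1]]
      target <- strsplit(c2, "")[[1]]
      syn <- non <- 0
      blocked <- FALSE
      for (pos in orders[r, ]) {
        nxt <- cur
        nxt[pos] <- target[pos]
        aa_from <- translate_codon(paste(cur, collapse = ""))
        aa_to <- translate_codon(paste(nxt, collapse = ""))
        if (exclude_stops && aa_to == "*") { blocked <- TRUE; break }
        if (aa_from == aa_to) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      if (!blocked) res[r, ] <- c(syn, non)
    }
    res[!is.na(res[, 1]), , drop = FALSE]
  }
  ok <- tally(TRUE)
  if (nrow(ok) == 0) ok <- tally(FALSE)
  c(syn = mean(ok[, 1]), nonsyn = mean(ok[, 2]))
}

perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; returns `NA` for
#' proportions at or beyond the correction's domain (p >= 3/4).
#'
#' @param p proportion of differing sites.
#' @return corrected per-site distance.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise nonsynonymous/synonymous divergence by pathway counting
#'
#' NG86-style counting estimator for one pair of in-frame coding
#' sequences: fractional synonymous/nonsynonymous site counts per codon
#' (averaged between the two sequences), observed differences classified by
#' equal-weight averaging over all shortest mutational pathways through
#' each multi-hit codon (pathways through stop codons excluded), and
#' Jukes-Cantor correction of the per-site proportions. Codons containing a
#' gap or ambiguity in either sequence are skipped.
#'
#' @param a,b nucleotide strings, or row indices/labels into `aln`.
#' @param aln optional [codon_alignment()] from which `a` and `b` are
#'   taken.
#' @return one-row data frame: `N`, `S` (site counts), `Nd`, `Sd`
#'   (differences), `pN`, `pS`, `dN`, `dS`, `dnds` (`NA` when dS = 0),
#'   `n_codons_used`.
#' @export
ng86_pair <- function(a, b, aln = NULL) {
  if (!is.null(aln)) {
    a <- paste(aln[a, ], collapse = "")
    b <- paste(aln[b, ], collapse = "")
  }
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("sequence length must be divisible by 3")
  ca <- codons_of(strsplit(a, "")[[1]])
  cb <- codons_of(strsplit(b, "")[[1]])
  usable <- is_valid_codon(ca) & is_valid_codon(cb) &
    translate_codon(ca) != "*" & translate_codon(cb) != "*"
  S <- N <- Sd <- Nd <- 0
  for (k in which(usable)) {
    s_k <- (codon_syn_sites(ca[k]) + codon_syn_sites(cb[k])) / 2
    S <- S + s_k
    N <- N + 3 - s_k
    if (ca[k] != cb[k]) {
      d <- codon_path_diffs(ca[k], cb[k])
      Sd <- Sd + d["syn"]
      Nd <- Nd + d["nonsyn"]
    }
  }
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  dN <- jukes_cantor(pN)
  dS <- jukes_cantor(pS)
  dnds <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  data.frame(N = N, S = S, Nd = unname(Nd), Sd = unname(Sd),
             pN = pN, pS = pS, dN = dN, dS = dS, dnds = dnds,
             n_codons_used = sum(usable))
}

#' Mean pairwise dN/dS over all haplotype pairs of a gene
#'
#' Averages the defined pairwise dN/dS ratios over all C(n,2) haplotype
#' pairs; pairs with dS = 0 are undefined and excluded from the mean but
#' counted.
#'
#' @param aln a [codon_alignment()] with >= 2 haplotypes.
#' @return list with `mean_dnds` (`NA` when every pair is undefined),
#'   `n_pairs`, `n_undefined`, and the per-pair table `pairs`.
#' @export
mean_pairwise_dnds <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least two haplotypes")
  labs <- rownames(aln)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pd <- ng86_pair(i, j, aln = aln)
      pd$hap1 <- labs[i]
      pd$hap2 <- labs[j]
      rows[[length(rows) + 1]] <- pd
    }
  }
  pairs <- do.call(rbind, rows)
  defined <- !is.na(pairs$dnds)
  list(mean_dnds = if (any(defined)) mean(pairs$dnds[defined]) else NA_real_,
       n_pairs = nrow(pairs), n_undefined = sum(!defined), pairs = pairs)
}

#' Sliding-window synonymous divergence between two sequences
#'
#' Gene-conversion scan: dS between one sequence pair in short sliding
#' nucleotide windows. Each codon's synonymous site and difference counts
#' (pathway-averaged, as in [ng86_pair()]) are spread uniformly over its
#' three nucleotide positions; a window sums the per-nucleotide shares of
#' the positions it covers and Jukes-Cantor-corrects the ratio. Windows
#' without synonymous sites give `NA` (a gap in the series).
#'
#' @param a,b equal-length in-frame nucleotide strings.
#' @param window_nt window width in nucleotides (default 30).
#' @param step_nt step in nucleotides (default 1).
#' @return data frame with `start`, `end` (1-based inclusive nucleotide
#'   coordinates), `midpoint`, `S_sites`, `Sd`, `dS`.
#' @export
sliding_ds <- function(a, b, window_nt = 30, step_nt = 1) {
  a <- toupper(a); b <- toupper(b)
  L <- nchar(a)
  if (nchar(b) != L) stop("sequences must have equal length")
  if (window_nt > L) stop("window longer than alignment")
  achr <- strsplit(a, "")[[1]]
  bchr <- strsplit(b, "")[[1]]
  ca <- codons_of(achr)
  cb <- codons_of(bchr)
  n_codon <- length(ca)
  # synonymous site counts are spread over the codon's 3 nucleotides;
  # synonymous differences are placed on the exact differing nucleotides
  nt_s <- rep(NA_real_, L)
  nt_sd <- rep(0, L)
  for (k in seq_len(n_codon)) {
    idx <- (3 * k - 2):(3 * k)
    if (is_valid_codon(ca[k]) && is_valid_codon(cb[k]) &&
        translate_codon(ca[k]) != "*" && translate_codon(cb[k]) != "*") {
      nt_s[idx] <- (codon_syn_sites(ca[k]) + codon_syn_sites(cb[k])) / 2 / 3
      if (ca[k] != cb[k]) {
        syn <- codon_path_diffs(ca[k], cb[k])["syn"]
        diff_nt <- idx[achr[idx] != bchr[idx]]
        nt_sd[diff_nt] <- syn / length(diff_nt)
      }
    }
  }
  starts <- seq(1, L - window_nt + 1, by = step_nt)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window_nt - 1)
    Sw <- sum(nt_s[idx], na.rm = TRUE)
    Sdw <- sum(nt_sd[idx], na.rm = TRUE)
    ds <- if (Sw > 0) jukes_cantor(Sdw / Sw) else NA_real_
    data.frame(start = s, end = s + window_nt - 1,
               midpoint = s + (window_nt - 1) / 2,
               S_sites = Sw, Sd = Sdw, dS = ds)
  })
  do.call(rbind, rows)
}

#' Classify haplotypes by spectral-tuning key sites
#'
#' Spectral class is read off two key residues in bovine-rhodopsin
#' numbering: serine at 97 with alanine at 109 is the red-shifted state
#' (longer peak absorption wavelength), cysteine at 97 with glycine at 109
#' the blue-shifted state; any other combination is intermediate. Key
#' codons containing gaps or ambiguities classify as intermediate with a
#' warning. Residues at additional annotated positions are reported
#' alongside.
#'
#' @param aln a [codon_alignment()].
#' @param key_map data frame mapping bovine-rhodopsin residue numbers to
#'   alignment codon indices, columns `rhodopsin_pos` and `codon`; must
#'   cover positions 97 and 109.
#' @return data frame with one row per haplotype: `haplotype`, one
#'   `pos<k>` residue column per mapped position, `class` in
#'   red-shifted/blue-shifted/intermediate.
#' @export
classify_spectral <- function(aln, key_map) {
  key_map <- as.data.frame(key_map)
  if (!all(c(97, 109) %in% key_map$rhodopsin_pos)) {
    stop("key_map must cover rhodopsin positions 97 and 109")
  }
  if (any(key_map$codon > attr(aln, "n_codon"))) {
    stop("key_map codon index beyond alignment")
  }
  res <- data.frame(haplotype = rownames(aln), stringsAsFactors = FALSE)
  residues <- matrix("", nrow(aln), nrow(key_map))
  for (j in seq_len(nrow(key_map))) {
    cod_idx <- key_map$codon[j]
    for (i in seq_len(nrow(aln))) {
      codon <- paste(aln[i, (3 * cod_idx - 2):(3 * cod_idx)], collapse = "")
      residues[i, j] <- if (is_valid_codon(codon)) translate_codon(codon) else "X"
    }
    res[[paste0("pos", key_map$rhodopsin_pos[j])]] <- residues[, j]
  }
  if (any(residues == "X")) {
    warning("gap/ambiguity in key codon(s); affected haplotypes classify as intermediate")
  }
  s97 <- res$pos97
  a109 <- res$pos109
  res$class <- ifelse(s97 == "S" & a109 == "A", "red-shifted",
                      ifelse(s97 == "C" & a109 == "G", "blue-shifted",
                             "intermediate"))
  res
}

#' Minimum-spanning haplotype network
#'
#' Collapses identical sequences into nodes (sized by count) and connects
#' them with a minimum-spanning network over pairwise nucleotide (Hamming)
#' distances: an edge is retained iff it appears in some minimum spanning
#' tree, i.e. iff at its weight level it still joins two components of the
#' strictly-lighter edge graph. Tied alternative links are therefore kept
#' as parallel paths.
#'
#' @param aln a [codon_alignment()] (or any character matrix of equal-length
#'   sequences).
#' @return list with `nodes` (label of first representative, `count`,
#'   `members`) and `edges` (`from`, `to`, `weight` in nucleotide
#'   differences), class `haplotype_network`.
#' @export
haplotype_network <- function(aln) {
  seq_str <- apply(aln, 1, paste, collapse = "")
  uniq <- unique(seq_str)
  node_members <- lapply(uniq, function(u) rownames(aln)[seq_str == u])
  nodes <- data.frame(
    label = vapply(node_members, `[`, character(1), 1),
    count = lengths(node_members),
    stringsAsFactors = FALSE
  )
  nodes$members <- vapply(node_members, paste, character(1), collapse = ",")
  k <- length(uniq)
  edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  if (k >= 2) {
    um <- do.call(rbind, strsplit(uniq, ""))
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d[i, j] <- d[j, i] <- sum(um[i, ] != um[j, ])
      }
    }
    all_edges <- do.call(rbind, lapply(seq_len(k - 1), function(i)
      data.frame(from = i, to = seq(i + 1, k), weight = d[i, seq(i + 1, k)])))
    all_edges <- all_edges[order(all_edges$weight), , drop = FALSE]
    # union of all MSTs: process weights ascending; an edge is kept iff its
    # endpoints are in different components of the strictly-lighter graph
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(nrow(all_edges))
    for (w in unique(all_edges$weight)) {
      at_w <- which(all_edges$weight == w)
      roots <- cbind(vapply(all_edges$from[at_w], find, integer(1)),
                     vapply(all_edges$to[at_w], find, integer(1)))
      keep[at_w] <- roots[, 1] != roots[, 2]
      for (e in at_w[keep[at_w]]) {
        r1 <- find(all_edges$from[e]); r2 <- find(all_edges$to[e])
        if (r1 != r2) parent[r1] <- r2
      }
    }
    edges <- all_edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @exportS3Method base::print
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net a [haplotype_network()].
#' @return an igraph graph with node attribute `count` and edge attribute
#'   `weight`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(net$nodes)),
                          label = net$nodes$label, count = net$nodes$count)
  )
  g
}
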