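# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive re-derivations (enumeration, scalar arithmetic) and
# share no code with the package implementations they check.

# Build a genotype_matrix from a list of per-population dosage row lists.
make_gm <- function(dosage_rows, positions = NULL, contig = "chr1") {
  dos <- do.call(rbind, dosage_rows)
  rownames(dos) <- sprintf("s%02d", seq_len(nrow(dos)))
  L <- ncol(dos)
  loci <- data.frame(locus = sprintf("L%03d", seq_len(L)),
                     contig = contig,
                     position = positions %||% seq(1000, by = 1000, length.out = L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dos, loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# popmap with ni samples in each of length(ni) populations, ecotype labels
# recycled over populations.
make_popmap <- function(ni, ecotypes = NULL) {
  pops <- sprintf("P%d", seq_along(ni))
  ecotypes <- ecotypes %||% pops
  population_map(sprintf("s%02d", seq_len(sum(ni))),
                 rep(pops, ni), rep(ecotypes, ni))
}

# Longhand Weir & Cockerham (1984) theta for one locus, scalar arithmetic.
wc_longhand <- function(pops) {
  r <- length(pops)
  n <- sapply(pops, length)
  p <- sapply(pops, function(d) sum(d) / (2 * length(d)))
  h <- sapply(pops, function(d) mean(d == 1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  a / (a + b + hbar / 2)
}

# Brute-force mean pairwise Manhattan distance matrices over all
# individual pairs.
allelic_diff_oracle <- function(dos, pop) {
  pops <- unique(pop)
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    ri <- which(pop == pops[i]); rj <- which(pop == pops[j])
    if (i == j) {
      if (length(ri) < 2) next
      prs <- utils::combn(ri, 2)
      m[i, i] <- mean(apply(prs, 2, function(pr)
        sum(abs(dos[pr[1], ] - dos[pr[2], ]))))
    } else {
      vals <- outer(ri, rj, Vectorize(function(a, b)
        sum(abs(dos[a, ] - dos[b, ]))))
      m[i, j] <- mean(vals)
    }
  }
  m
}

# Exhaustive Poisson-binomial upper tail: enumerate all 2^n outcomes.
pb_tail_oracle <- function(probs, k) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# Two-tailed Fisher p by hypergeometric enumeration: sum over all tables
# with the margins whose probability does not exceed the observed one.
fisher_oracle <- function(k, n, K, N) {
  kk <- max(0, K - (N - n)):min(n, K)
  probs <- stats::dhyper(kk, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact Mann-Whitney two-sided p by enumeration of all group assignments.
mw_oracle <- function(set1, set2) {
  m <- length(set1); n <- length(set2)
  vals <- c(set1, set2)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  asn <- utils::combn(m + n, m)
  U_all <- apply(asn, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Brute-force interval linkage: at most `window` bases separate the SNP
# from the gene span (gap = start - pos - 1 to the right, pos - end - 1 to
# the left, 0 when covered).
linkage_oracle <- function(loci, genes, window) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    pos <- loci$position[i]
    gap <- ifelse(genes$start > pos, genes$start - pos - 1,
                  ifelse(genes$end < pos, pos - genes$end - 1, 0))
    genes$gene[genes$contig == loci$contig[i] & gap <= window]
  })
  names(out) <- loci$locus
  out
}

# Small VCF text fixture with GT:DP:GQ fields.
write_toy_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
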