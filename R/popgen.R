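#' Per-locus and pairwise differentiation statistics
#'
#' Weir & Cockerham (1984) variance-components estimator of FST (theta),
#' pooled heterozygosity, and mean pairwise allelic differences, computed on
#' a complete-case dosage matrix.
#'
#' @name popgen_stats
NULL

# Weir-Cockerham (1984) variance components from per-population summaries.
# n: diploid sample sizes (length r); p, h: r x L matrices of alt-allele
# frequency and observed heterozygote proportion. Returns per-locus
# components a (among populations), b (among individuals within populations)
# and c (within individuals); theta = a / (a + b + c).
wc_components <- function(n, p, h) {
  r <- length(n)
  stopifnot(r >= 2, nrow(p) == r, all(dim(p) == dim(h)))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, pbar = pbar)
}

# Per-population allele frequencies and heterozygote proportions for a
# genotype matrix, in the population order given.
pop_freq_het <- function(gm, popmap, populations = NULL) {
  populations <- populations %||% unique(popmap$population)
  dos <- gm$dosage
  if (anyNA(dos)) stop("complete-case matrix required (missing dosages present)")
  n <- integer(length(populations))
  p <- matrix(0, length(populations), ncol(dos))
  h <- matrix(0, length(populations), ncol(dos))
  for (k in seq_along(populations)) {
    rows <- match(samples_of_pop(popmap, populations[k]), rownames(dos))
    if (anyNA(rows)) stop("popmap samples absent from matrix")
    sub <- dos[rows, , drop = FALSE]
    n[k] <- nrow(sub)
    p[k, ] <- colSums(sub) / (2 * n[k])
    h[k, ] <- colSums(sub == 1) / n[k]
  }
  list(n = n, p = p, h = h, populations = populations)
}

#' Per-locus summaries: pooled frequency, heterozygosity and theta
#'
#' For every locus, the pooled alternate-allele frequency over all mapped
#' samples, expected heterozygosity He = 2p(1-p), the multi-population
#' Weir-Cockerham theta across the map's populations, and the raw variance
#' components used for multi-locus ratio-of-sums combination.
#'
#' @param gm a complete-case `genotype_matrix`.
#' @param popmap a `population_map` covering all samples of `gm`.
#' @param locus_set optional character vector of locus ids (default: all).
#' @return data.frame with columns `locus`, `p_hat`, `he`, `theta`, `wc_a`,
#'   `wc_d` (= a + b + c).
#' @export
locus_summaries <- function(gm, popmap, locus_set = NULL) {
  if (!is.null(locus_set)) gm <- subset_loci(gm, locus_set)
  if (ncol(gm$dosage) == 0) stop("empty locus set")
  fh <- pop_freq_het(gm, popmap)
  comp <- wc_components(fh$n, fh$p, fh$h)
  ntot <- sum(fh$n)
  p_hat <- colSums(gm$dosage) / (2 * ntot)
  d <- comp$a + comp$b + comp$c
  data.frame(locus = gm$loci$locus,
             p_hat = p_hat,
             he = 2 * p_hat * (1 - p_hat),
             theta = ifelse(d == 0, NA_real_, comp$a / d),
             wc_a = comp$a,
             wc_d = d,
             stringsAsFactors = FALSE)
}

# Multi-locus ratio-of-sums theta from per-locus components.
multilocus_theta <- function(wc_a, wc_d) {
  keep <- is.finite(wc_a) & is.finite(wc_d)
  sum(wc_a[keep]) / sum(wc_d[keep])
}

#' Pairwise-population layer container
#'
#' A symmetric population-by-population matrix of one statistic (pairwise
#' FST or mean allelic differences) computed on a named locus set.
#'
#' @param values symmetric numeric matrix with population dimnames.
#' @param label locus-set label, e.g. "neutral", "outlier", "all".
#' @param diagonal_defined logical; whether the diagonal carries a
#'   within-population value.
#' @return An object of class `pairwise_layer`.
#' @export
pairwise_layer <- function(values, label = "all", diagonal_defined = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  off <- values; diag(off) <- 0
  if (max(abs(off - t(off)), na.rm = TRUE) > 1e-12) stop("matrix not symmetric")
  structure(list(values = values,
                 populations = rownames(values),
                 label = label,
                 diagonal_defined = diagonal_defined),
            class = "pairwise_layer")
}

#' @export
print.pairwise_layer <- function(x, ...) {
  cat(sprintf("pairwise_layer (%s) over %d populations\n",
              x$label, length(x$populations)))
  print(round(x$values, 4))
  invisible(x)
}

# Look up the layer value for one unordered population pair.
layer_value <- function(layer, a, b) layer$values[a, b]

#' Pairwise Weir-Cockerham FST between all population pairs
#'
#' Multi-locus theta (ratio of sums over loci of the among-population
#' variance component to the total) for each population pair, computed by
#' restricting the two-level Weir-Cockerham components to the pair. An
#' optional permutation test shuffles individuals between the two
#' populations.
#'
#' @inheritParams locus_summaries
#' @param label locus-set label recorded in the returned layer.
#' @param permutations number of permutations for a one-sided p-value per
#'   pair (0 disables).
#' @param seed RNG seed for the permutation test.
#' @return A `pairwise_layer` of pairwise theta; when permutations > 0 the
#'   p-value matrix is attached as `$p_values`.
#' @export
pairwise_fst <- function(gm, popmap, locus_set = NULL, label = "all",
                         permutations = 0, seed = NULL) {
  if (!is.null(locus_set)) gm <- subset_loci(gm, locus_set)
  pops <- unique(popmap$population)
  if (length(pops) < 2) stop("need at least two populations")
  sizes <- attr(popmap, "pop_sizes")[pops]
  if (any(sizes == 0)) stop("population with zero samples")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  pair_theta <- function(rowsA, rowsB) {
    dos <- gm$dosage
    n <- c(length(rowsA), length(rowsB))
    p <- rbind(colSums(dos[rowsA, , drop = FALSE]) / (2 * n[1]),
               colSums(dos[rowsB, , drop = FALSE]) / (2 * n[2]))
    h <- rbind(colSums(dos[rowsA, , drop = FALSE] == 1) / n[1],
               colSums(dos[rowsB, , drop = FALSE] == 1) / n[2])
    comp <- wc_components(n, p, h)
    multilocus_theta(comp$a, comp$a + comp$b + comp$c)
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i >= j) next
    rowsA <- match(samples_of_pop(popmap, pops[i]), rownames(gm$dosage))
    rowsB <- match(samples_of_pop(popmap, pops[j]), rownames(gm$dosage))
    obs <- pair_theta(rowsA, rowsB)
    m[i, j] <- m[j, i] <- obs
    if (permutations > 0) {
      pool <- c(rowsA, rowsB)
      exceed <- with_seed(if (is.null(seed)) NULL else seed + i * 1000L + j, {
        sum(vapply(seq_len(permutations), function(rep) {
          idx <- sample(pool)
          pair_theta(idx[seq_along(rowsA)], idx[-seq_along(rowsA)]) >= obs
        }, logical(1)))
      })
      pmat[i, j] <- pmat[j, i] <- (exceed + 1) / (permutations + 1)
    }
  }
  layer <- pairwise_layer(m, label = label)
  if (permutations > 0) layer$p_values <- pmat
  layer
}

#' Mean pairwise allelic differences within and between populations
#'
#' Entry (A, B) is the mean over all cross-population individual pairs of
#' the Manhattan distance between their dosage vectors restricted to the
#' locus set; the diagonal is the mean over distinct within-population
#' pairs (NA, with a flag, for populations of size 1).
#'
#' @inheritParams pairwise_fst
#' @param normalize divide by the number of loci in the set (per-locus
#'   mean difference) instead of reporting the raw summed distance.
#' @return A `pairwise_layer` with `diagonal_defined = TRUE`; populations of
#'   size 1 are listed in the layer's `undefined_within` field.
#' @export
allelic_difference_matrix <- function(gm, popmap, locus_set = NULL,
                                      label = "all", normalize = FALSE) {
  if (!is.null(locus_set)) gm <- subset_loci(gm, locus_set)
  if (anyNA(gm$dosage)) stop("complete-case matrix required")
  pops <- unique(popmap$population)
  L <- ncol(gm$dosage)
  # per-population dosage-class counts per locus
  cnt <- lapply(pops, function(pp) {
    rows <- match(samples_of_pop(popmap, pp), rownames(gm$dosage))
    sub <- gm$dosage[rows, , drop = FALSE]
    list(n = nrow(sub),
         c0 = colSums(sub == 0), c1 = colSums(sub == 1), c2 = colSums(sub == 2))
  })
  names(cnt) <- pops
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    A <- cnt[[i]]; B <- cnt[[j]]
    if (i == j) {
      if (A$n < 2) next
      tot <- sum(A$c0 * A$c1 + A$c1 * A$c2 + 2 * A$c0 * A$c2)
      m[i, i] <- tot / (A$n * (A$n - 1) / 2)
    } else if (i < j) {
      tot <- sum(A$c0 * B$c1 + A$c1 * B$c0 + A$c1 * B$c2 + A$c2 * B$c1 +
                 2 * (A$c0 * B$c2 + A$c2 * B$c0))
      m[i, j] <- m[j, i] <- tot / (A$n * B$n)
    }
  }
  if (normalize) m <- m / L
  layer <- pairwise_layer(m, label = label, diagonal_defined = TRUE)
  layer$undefined_within <- pops[vapply(cnt, function(x) x$n < 2, logical(1))]
  layer
}
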