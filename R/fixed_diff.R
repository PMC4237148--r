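#' Reciprocally fixed differences and their sampling null
#'
#' A locus is a fixed difference between two population samples when one is
#' monomorphic for the reference allele and the other for the alternate.
#' The chance of observing such reciprocal monomorphism from finite samples
#' of a single panmictic pool is computed per locus from the pooled allele
#' frequency, and the count over loci is tested against a Poisson-binomial
#' null.
#'
#' @name fixed_diff
NULL

#' Find reciprocally fixed loci between two populations
#'
#' @param gm a complete-case `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param popA,popB population labels.
#' @param locus_set optional character vector of locus ids.
#' @return Character vector of fixed-difference locus ids (order as in the
#'   matrix); symmetric in A and B.
#' @export
find_fixed <- function(gm, popmap, popA, popB, locus_set = NULL) {
  if (!is.null(locus_set)) gm <- subset_loci(gm, locus_set)
  rowsA <- match(samples_of_pop(popmap, popA), rownames(gm$dosage))
  rowsB <- match(samples_of_pop(popmap, popB), rownames(gm$dosage))
  if (!length(rowsA) || !length(rowsB)) stop("empty population")
  dA <- gm$dosage[rowsA, , drop = FALSE]
  dB <- gm$dosage[rowsB, , drop = FALSE]
  a0 <- colSums(dA) == 0
  a2 <- colSums(dA == 2) == nrow(dA)
  b0 <- colSums(dB) == 0
  b2 <- colSums(dB == 2) == nrow(dB)
  gm$loci$locus[(a0 & b2) | (a2 & b0)]
}

#' Null probability of reciprocal fixation under panmixia
#'
#' With pooled alternate-allele frequency p = k / total, the probability
#' that a sample of nA diploids is monomorphic for one allele while a
#' sample of nB diploids is monomorphic for the other:
#' p^(2nA) (1-p)^(2nB) + (1-p)^(2nA) p^(2nB).
#'
#' @param pooled_alt_count alternate-allele count in the pooled sample.
#' @param total_alleles total allele count (2 x diploids).
#' @param nA,nB diploid sample sizes of the two populations.
#' @return The reciprocal-fixation probability; 0 for a monomorphic pool.
#' @export
fixation_null_probability <- function(pooled_alt_count, total_alleles, nA, nB) {
  stopifnot(total_alleles > 0, nA >= 1, nB >= 1,
            pooled_alt_count >= 0, pooled_alt_count <= total_alleles)
  p <- pooled_alt_count / total_alleles
  ifelse(p <= 0 | p >= 1, 0,
         p^(2 * nA) * (1 - p)^(2 * nB) + (1 - p)^(2 * nA) * p^(2 * nB))
}

#' Poisson-binomial upper-tail probability
#'
#' P(X >= k) for X a sum of independent Bernoulli trials with success
#' probabilities `probs`. Exact dynamic programming up to 10^4 trials, a
#' Poisson approximation (rate = sum of probs) beyond that.
#'
#' @param probs vector of success probabilities.
#' @param k observed count.
#' @return Upper-tail probability.
#' @export
poisson_binomial_tail <- function(probs, k) {
  stopifnot(all(probs >= 0), all(probs <= 1), k >= 0)
  if (k == 0) return(1)
  if (k > length(probs)) return(0)
  if (length(probs) > 1e4) {
    return(stats::ppois(k - 1, sum(probs), lower.tail = FALSE))
  }
  f <- 1
  for (p in probs) f <- c(f * (1 - p), 0) + c(0, f * p)
  sum(f[(k + 1):length(f)])
}

#' Test the fixed-difference count between two populations
#'
#' Observed reciprocally fixed loci are compared with the expectation under
#' a panmictic pooling null: each locus contributes its reciprocal-fixation
#' probability (computed from the pooled frequency and the two sample
#' sizes), the expected count is their sum, and the upper-tail probability
#' of the observed count is Poisson-binomial.
#'
#' @inheritParams find_fixed
#' @param alpha significance level for the `significant` flag.
#' @return A list of class `fixed_diff_report`: populations, fixed locus
#'   ids, observed and expected counts, per-locus null probabilities, tail
#'   probability and significance flag.
#' @export
test_fixed_pair <- function(gm, popmap, popA, popB, locus_set = NULL,
                            alpha = 0.05) {
  if (!is.null(locus_set)) gm <- subset_loci(gm, locus_set)
  fixed <- find_fixed(gm, popmap, popA, popB)
  rowsA <- match(samples_of_pop(popmap, popA), rownames(gm$dosage))
  rowsB <- match(samples_of_pop(popmap, popB), rownames(gm$dosage))
  sub <- gm$dosage[c(rowsA, rowsB), , drop = FALSE]
  pooled <- colSums(sub)
  total <- 2 * nrow(sub)
  probs <- fixation_null_probability(pooled, total,
                                     length(rowsA), length(rowsB))
  observed <- length(fixed)
  tail_p <- poisson_binomial_tail(probs, observed)
  structure(list(populations = c(popA, popB),
                 fixed_loci = fixed,
                 observed = observed,
                 expected = sum(probs),
                 null_probabilities = stats::setNames(probs, gm$loci$locus),
                 tail_probability = tail_p,
                 alpha = alpha,
                 significant = tail_p <= alpha),
            class = "fixed_diff_report")
}

#' @export
print.fixed_diff_report <- function(x, ...) {
  cat(sprintf("fixed differences %s vs %s: observed %d, expected %.3f, P(X>=obs) = %.4g%s\n",
              x$populations[1], x$populations[2], x$observed, x$expected,
              x$tail_probability, if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise fixed-difference count matrix over a locus set
#'
#' @inheritParams test_fixed_pair
#' @param label locus-set label for the layer.
#' @return A `pairwise_layer` of counts; significance flags (from the
#'   Poisson-binomial test) are attached as `$significant`.
#' @export
fixed_diff_matrix <- function(gm, popmap, locus_set = NULL, label = "all",
                              alpha = 0.05) {
  pops <- unique(popmap$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  sig <- matrix(FALSE, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i >= j) next
    rep_ <- test_fixed_pair(gm, popmap, pops[i], pops[j], locus_set, alpha)
    m[i, j] <- m[j, i] <- rep_$observed
    sig[i, j] <- sig[j, i] <- rep_$significant
  }
  layer <- pairwise_layer(m, label = label)
  layer$significant <- sig
  layer
}

#' Group-averaged fixed-difference percentage
#'
#' Averages the pairwise fixed-difference counts over all (A, B) population
#' pairs and expresses the mean as a percentage of the number of SNPs
#' scored.
#'
#' @param layer a `pairwise_layer` of fixed-difference counts.
#' @param groupA,groupB population label vectors (disjoint).
#' @param n_snps total number of SNPs scored.
#' @return Mean percentage of loci fixed between the groups' populations.
#' @export
group_fixed_percent <- function(layer, groupA, groupB, n_snps) {
  stopifnot(!length(intersect(groupA, groupB)))
  pairs <- expand.grid(a = groupA, b = groupB, stringsAsFactors = FALSE)
  counts <- mapply(function(a, b) layer_value(layer, a, b), pairs$a, pairs$b)
  mean(counts) / n_snps * 100
}
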