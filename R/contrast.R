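#' Between- versus within-ecotype differentiation contrasts
#'
#' The headline comparison: for a pairwise FST layer, the set of ratios
#' FST(between-ecotype pair) / FST(within-ecotype pair) over the full
#' Cartesian product of between- and within-ecotype population pairs,
#' compared across locus sets by a Mann-Whitney rank test; and 2x2
#' chi-square contrasts of allelic-difference magnitudes.
#'
#' @name ecotype_contrast
NULL

# All unordered population pairs within a set.
pairs_within <- function(pops) {
  if (length(pops) < 2) return(data.frame(a = character(), b = character()))
  cmb <- utils::combn(pops, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Ratio set of between- to within-ecotype FST
#'
#' Between pairs are every (population of ecotype A, population of ecotype
#' B) pair; within pairs are every same-ecotype pair inside A plus inside
#' B. The ratio set is the full Cartesian product between/within.
#'
#' @param fst_layer a `pairwise_layer` of pairwise FST.
#' @param popmap a `population_map` assigning the layer's populations to
#'   ecotypes (populations absent from the layer are ignored).
#' @param ecotypeA,ecotypeB ecotype labels to contrast.
#' @return A list of class `ratio_contrast`: `ratios`, `n`, `mean`, `min`,
#'   `max`, and the between/within pair tables.
#' @export
ratio_set <- function(fst_layer, popmap, ecotypeA, ecotypeB) {
  popsA <- intersect(pops_of_ecotype(popmap, ecotypeA), fst_layer$populations)
  popsB <- intersect(pops_of_ecotype(popmap, ecotypeB), fst_layer$populations)
  if (!length(popsA) || !length(popsB)) stop("ecotype with no populations in layer")
  between <- expand.grid(a = popsA, b = popsB, stringsAsFactors = FALSE)
  within <- rbind(pairs_within(popsA), pairs_within(popsB))
  if (!nrow(within)) stop("no within-ecotype population pair exists; ratio undefined")
  bvals <- mapply(function(a, b) layer_value(fst_layer, a, b), between$a, between$b)
  wvals <- mapply(function(a, b) layer_value(fst_layer, a, b), within$a, within$b)
  ratios <- as.vector(outer(bvals, wvals, "/"))
  structure(list(ecotypes = c(ecotypeA, ecotypeB),
                 between_pairs = cbind(between, fst = bvals),
                 within_pairs = cbind(within, fst = wvals),
                 ratios = ratios,
                 n = length(ratios),
                 mean = mean(ratios),
                 min = min(ratios),
                 max = max(ratios),
                 label = fst_layer$label),
            class = "ratio_contrast")
}

#' @export
print.ratio_contrast <- function(x, ...) {
  cat(sprintf("ratio_contrast (%s): N = %d, mean = %.2f, range = %.2f-%.2f\n",
              x$label, x$n, x$mean, x$min, x$max))
  invisible(x)
}

#' Mann-Whitney U test of two value sets
#'
#' U by rank summation with midranks for ties; Z from the tie-corrected
#' normal approximation with continuity correction, negative when `set1` is
#' stochastically smaller than `set2`. When m*n <= 400 and there are no
#' ties, the two-sided p-value comes from the exact U distribution;
#' otherwise from the normal approximation.
#'
#' @param set1,set2 numeric vectors (non-empty).
#' @return A list of class `rank_test`: `U` (wins of set1 over set2), `z`,
#'   `p`, and the method used.
#' @export
mann_whitney <- function(set1, set2) {
  stopifnot(length(set1) > 0, length(set2) > 0)
  m <- length(set1); n <- length(set2)
  r <- rank(c(set1, set2))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  tie_tab <- table(r)
  has_ties <- any(tie_tab > 1)
  tie_corr <- sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1))
  sigma <- sqrt(m * n / 12 * ((m + n + 1) - tie_corr))
  if (sigma == 0) {
    return(structure(list(U = U, z = 0, p = 1, method = "degenerate"),
                     class = "rank_test"))
  }
  z <- (U - mu - 0.5 * sign(U - mu)) / sigma
  if (!has_ties && m * n <= 400) {
    p <- min(1, 2 * stats::pwilcox(min(U, m * n - U), m, n))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(U = U, z = z, p = p, method = method), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, Z = %.2f, two-sided p = %.4g (%s)\n",
              x$U, x$z, x$p, x$method))
  invisible(x)
}

# Sum of layer values over all cross pairs of two population sets.
sum_between <- function(layer, popsA, popsB) {
  pairs <- expand.grid(a = popsA, b = popsB, stringsAsFactors = FALSE)
  sum(mapply(function(a, b) layer_value(layer, a, b), pairs$a, pairs$b))
}

# Sum over all within-set unordered pairs (off-diagonal only).
sum_within <- function(layer, pops) {
  w <- pairs_within(pops)
  if (!nrow(w)) return(0)
  sum(mapply(function(a, b) layer_value(layer, a, b), w$a, w$b))
}

yates_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1)
}

#' 2x2 chi-square contrast of allelic-difference magnitudes
#'
#' Builds the table rows = \{neutral, outlier\} locus sets, columns =
#' \{between-ecotype, within-ecotype\}, from summed mean allelic-difference
#' totals rounded to counts, and reports per-row fold-ratios
#' (between / within) and the Yates-corrected chi-square.
#'
#' @param diff_layer_neutral,diff_layer_outlier `pairwise_layer`s of mean
#'   allelic differences on the neutral and outlier locus sets.
#' @param popmap a `population_map`.
#' @param ecotypeA,ecotypeB ecotype labels.
#' @return A list of class `contingency_result`: `table`, `fold_ratios`,
#'   `statistic`, `p_value`, `df`.
#' @export
chi2_contrast <- function(diff_layer_neutral, diff_layer_outlier, popmap,
                          ecotypeA, ecotypeB) {
  popsA <- intersect(pops_of_ecotype(popmap, ecotypeA),
                     diff_layer_neutral$populations)
  popsB <- intersect(pops_of_ecotype(popmap, ecotypeB),
                     diff_layer_neutral$populations)
  cells <- function(layer) {
    c(between = sum_between(layer, popsA, popsB),
      within = sum_within(layer, popsA) + sum_within(layer, popsB))
  }
  raw <- rbind(neutral = cells(diff_layer_neutral),
               outlier = cells(diff_layer_outlier))
  tab <- round(raw)
  yt <- yates_2x2(tab)
  structure(list(table = tab,
                 fold_ratios = raw[, "between"] / raw[, "within"],
                 statistic = yt$statistic, p_value = yt$p_value, df = yt$df),
            class = "contingency_result")
}

#' Ecotypes-versus-outgroup 2x2 contrast
#'
#' Columns are total allelic differences of resident-vs-outgroup and
#' transient-vs-outgroup population pairs; rows are the neutral and outlier
#' locus sets. Yates-corrected chi-square tests whether the two locus sets
#' apportion differentiation to the two ecotype-outgroup contrasts
#' differently.
#'
#' @inheritParams chi2_contrast
#' @param residents,transients,outgroups ecotype labels of three disjoint
#'   groups.
#' @return A `contingency_result` with fold-ratios resident/transient per
#'   row.
#' @export
outgroup_contrast <- function(diff_layer_neutral, diff_layer_outlier, popmap,
                              residents, transients, outgroups) {
  popsR <- pops_of_ecotype(popmap, residents)
  popsT <- pops_of_ecotype(popmap, transients)
  popsO <- pops_of_ecotype(popmap, outgroups)
  stopifnot(!length(intersect(popsR, popsT)), !length(intersect(popsR, popsO)),
            !length(intersect(popsT, popsO)))
  cells <- function(layer) {
    c(resident_vs_outgroup = sum_between(layer, popsR, popsO),
      transient_vs_outgroup = sum_between(layer, popsT, popsO))
  }
  raw <- rbind(neutral = cells(diff_layer_neutral),
               outlier = cells(diff_layer_outlier))
  tab <- round(raw)
  yt <- yates_2x2(tab)
  structure(list(table = tab,
                 fold_ratios = raw[, 1] / raw[, 2],
                 statistic = yt$statistic, p_value = yt$p_value, df = yt$df),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("fold-ratios: %s; Yates chi-square = %.2f, df = %d, p = %.4g\n",
              paste(sprintf("%s %.2f", names(x$fold_ratios), x$fold_ratios),
                    collapse = ", "),
              x$statistic, x$df, x$p_value))
  invisible(x)
}
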