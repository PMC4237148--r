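#' Worked-example tables from a killer whale RAD SNP survey
#'
#' Two small published summary tables over nine killer whale populations
#' (four North Pacific resident populations SR, AR, BS, RU; two transient
#' populations AT, CT; and three outgroup populations OS, IC, MI) ship with
#' the package as plain-text fixtures. Both are square matrices whose upper
#' triangle was computed on the positive-outlier locus set and whose lower
#' triangle on the neutral set; the accessors unfold them into two
#' symmetric `pairwise_layer`s plus the matching `population_map`.
#'
#' @name example_tables
NULL

# Split a printed square table (outlier upper / neutral lower) into two
# symmetric layers.
unfold_layers <- function(m) {
  pops <- rownames(m)
  outlier <- neutral <- matrix(NA_real_, nrow(m), ncol(m),
                               dimnames = dimnames(m))
  diag(outlier) <- diag(neutral) <- 0
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i < j) {
      outlier[i, j] <- outlier[j, i] <- m[i, j]
      neutral[i, j] <- neutral[j, i] <- m[j, i]
    }
  }
  list(outlier = pairwise_layer(outlier, label = "outlier"),
       neutral = pairwise_layer(neutral, label = "neutral"))
}

orca_popmap <- function(pops) {
  eco <- c(SR = "resident", AR = "resident", BS = "resident", RU = "resident",
           AT = "transient", CT = "transient",
           OS = "outgroup", IC = "outgroup", MI = "outgroup")
  # one placeholder sample per population: layer-level contrasts only need
  # the population -> ecotype assignment
  population_map(paste0(pops, "_1"), pops, unname(eco[pops]))
}

#' Pairwise FST layers among six killer whale populations
#'
#' Pairwise FST among the populations with more than ten samples (SR, AR,
#' BS, AT, CT, MI), computed separately on positive-outlier and neutral
#' locus sets.
#'
#' @return list with `outlier` and `neutral` `pairwise_layer`s and a
#'   `popmap` assigning SR/AR/BS to the resident ecotype, AT/CT to the
#'   transient ecotype and MI to the outgroup.
#' @export
orca_fst_layers <- function() {
  path <- system.file("extdata", "orca_pairwise_fst.tsv", package = "ecoscan")
  df <- read_tsv(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$pop
  c(unfold_layers(m), list(popmap = orca_popmap(df$pop)))
}

#' Pairwise fixed-difference counts among nine killer whale populations
#'
#' Counts of reciprocally fixed SNPs per population pair, on the
#' positive-outlier (upper triangle of the printed table) and neutral
#' (lower triangle) locus sets, out of 3,281 SNPs scored in 115 samples.
#'
#' @return list with `outlier` and `neutral` count `pairwise_layer`s, the
#'   per-population diploid `sample_sizes`, `n_snps` (3281), and a
#'   `popmap`.
#' @export
orca_fixed_diff_layers <- function() {
  path <- system.file("extdata", "orca_fixed_diff_counts.tsv",
                      package = "ecoscan")
  df <- read_tsv(path)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$pop
  c(unfold_layers(m),
    list(sample_sizes = stats::setNames(df$n, df$pop),
         n_snps = 3281L,
         popmap = orca_popmap(df$pop)))
}
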