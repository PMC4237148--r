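#' Genotype matrix container
#'
#' A light container for a diploid allele-dosage matrix over biallelic SNP
#' loci. Rows are samples, columns are loci; entries count copies of the
#' alternate allele (0, 1, 2) or are `NA` where the call is missing. Locus
#' metadata (contig, 1-based position, ref/alt alleles, indel and
#' multi-allelic flags, optional mean coverage) travels alongside, together
#' with an optional per-genotype quality matrix.
#'
#' @param dosage integer matrix, samples x loci, values in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns `locus`, `contig`, `position`, `ref`,
#'   `alt` and optionally `is_indel`, `is_multiallelic`, `mean_dp`.
#' @param gq optional numeric matrix of genotype qualities, same shape as
#'   `dosage`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, gq = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(loci), nrow(loci) == ncol(dosage),
            all(c("locus", "contig", "position", "ref", "alt") %in% names(loci)))
  if (anyDuplicated(loci$locus)) stop("duplicate locus ids")
  if (anyDuplicated(paste(loci$contig, loci$position))) {
    stop("duplicate contig/position pairs")
  }
  if (is.null(rownames(dosage))) stop("dosage matrix must have sample rownames")
  colnames(dosage) <- loci$locus
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    stopifnot(all(dim(gq) == dim(dosage)))
    dimnames(gq) <- dimnames(dosage)
  }
  loci$is_indel <- loci$is_indel %||% rep(FALSE, nrow(loci))
  loci$is_multiallelic <- loci$is_multiallelic %||% rep(FALSE, nrow(loci))
  rownames(loci) <- NULL
  structure(list(dosage = dosage, loci = loci, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing calls)\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by locus
#'
#' @param gm a `genotype_matrix`.
#' @param loci locus ids (character) or a logical/integer index over columns.
#' @return A `genotype_matrix` restricted to the requested loci.
#' @export
subset_loci <- function(gm, loci) {
  idx <- if (is.character(loci)) match(loci, gm$loci$locus) else loci
  if (is.character(loci) && anyNA(idx)) {
    stop("unknown locus ids: ", paste(loci[is.na(idx)], collapse = ", "))
  }
  genotype_matrix(gm$dosage[, idx, drop = FALSE],
                  gm$loci[idx, , drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[, idx, drop = FALSE])
}

#' Population map
#'
#' Maps each sample to a population and each population to an ecotype
#' grouping (e.g. resident, transient, outgroup).
#'
#' @param sample character vector of sample ids.
#' @param population character vector, one population label per sample.
#' @param ecotype character vector, one ecotype label per sample; must be
#'   constant within each population.
#' @return A data.frame of class `population_map` with one row per sample and
#'   attributes `pop_sizes` (diploid samples per population) and
#'   `pop_ecotype` (population -> ecotype lookup).
#' @export
population_map <- function(sample, population, ecotype) {
  stopifnot(length(sample) == length(population),
            length(sample) == length(ecotype))
  if (anyDuplicated(sample)) {
    stop("duplicate sample rows: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  eco_by_pop <- tapply(ecotype, population, function(e) length(unique(e)))
  if (any(eco_by_pop > 1)) {
    stop("populations with conflicting ecotype labels: ",
         paste(names(eco_by_pop)[eco_by_pop > 1], collapse = ", "))
  }
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   ecotype = as.character(ecotype),
                   stringsAsFactors = FALSE)
  sizes <- table(df$population)
  attr(df, "pop_sizes") <- stats::setNames(as.integer(sizes), names(sizes))
  eco <- df$ecotype[!duplicated(df$population)]
  attr(df, "pop_ecotype") <- stats::setNames(eco, df$population[!duplicated(df$population)])
  class(df) <- c("population_map", "data.frame")
  df
}

# Populations belonging to an ecotype label.
pops_of_ecotype <- function(popmap, ecotype) {
  pe <- attr(popmap, "pop_ecotype")
  names(pe)[pe %in% ecotype]
}

# Sample ids of one population.
samples_of_pop <- function(popmap, pop) {
  if (!pop %in% popmap$population) stop("unknown population label: ", pop)
  popmap$sample[popmap$population == pop]
}
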