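#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into an alt-allele dosage matrix. Indel and
#' multi-allelic records are retained but flagged for [filter_snps()];
#' missing genotypes (`./.`) become `NA` dosages. Per-locus mean coverage is
#' taken from the FORMAT `DP` field when present (otherwise from INFO `DP`
#' divided by the sample count), and per-genotype qualities from FORMAT
#' `GQ`; both are optional.
#'
#' @param path path to a VCF (v4.x) file with GT fields.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  alt1 <- vapply(strsplit(fix$ALT, ","), `[`, character(1), 1)
  is_multi <- grepl(",", fix$ALT)
  is_indel <- nchar(fix$REF) != 1 |
    vapply(strsplit(fix$ALT, ","), function(a) any(nchar(a) != 1), logical(1))
  # dosage: count of non-reference alleles in the GT string
  alleles <- gsub("[|/]", "", gt)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & !grepl("\\.", gt)
  dosage[called] <- nchar(gsub("0", "", alleles[called]))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, sep = "_"), fix$ID)
  loci <- data.frame(locus = ids,
                     contig = fix$CHROM,
                     position = as.integer(fix$POS),
                     ref = fix$REF,
                     alt = alt1,
                     is_indel = is_indel,
                     is_multiallelic = is_multi,
                     stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (!is.null(dp) && !all(is.na(dp))) {
    loci$mean_dp <- rowMeans(dp, na.rm = TRUE)
  } else {
    info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
    if (!all(is.na(info_dp))) loci$mean_dp <- info_dp / ncol(gt)
  }
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  if (!is.null(gq) && all(is.na(gq))) gq <- NULL
  genotype_matrix(t(dosage), loci, gq = if (!is.null(gq)) t(gq))
}

#' Filter SNP loci to the analysis-ready complete-case set
#'
#' Applies, in order: removal of indel and multi-allelic records; a per-site
#' mean-coverage floor; a per-genotype quality floor (a locus is dropped if
#' any genotype falls below it); removal of loci with any missing genotype;
#' removal of loci monomorphic across all samples. Filters whose supporting
#' annotation (coverage, quality) is absent are skipped with a warning. A
#' removal ledger (counts per rule, attributed sequentially) is attached as
#' attribute `removal_ledger`.
#'
#' @param gm a `genotype_matrix` from [read_vcf()].
#' @param min_mean_coverage per-site mean depth floor (x), default 20.
#' @param min_genotype_quality per-genotype GQ floor (phred), default 20.
#' @param drop_missing drop loci with any missing genotype (default TRUE).
#' @return The filtered `genotype_matrix`; errors if nothing survives.
#' @export
filter_snps <- function(gm, min_mean_coverage = 20, min_genotype_quality = 20,
                        drop_missing = TRUE) {
  keep <- rep(TRUE, ncol(gm$dosage))
  ledger <- c(indel = 0L, multiallelic = 0L, coverage = 0L, quality = 0L,
              missing = 0L, monomorphic = 0L)
  drop_rule <- function(bad, rule) {
    bad <- bad & keep
    ledger[rule] <<- sum(bad)
    keep[bad] <<- FALSE
  }
  drop_rule(gm$loci$is_indel, "indel")
  drop_rule(gm$loci$is_multiallelic, "multiallelic")
  if (!is.null(min_mean_coverage)) {
    if (is.null(gm$loci$mean_dp)) {
      warning("no coverage annotation present; coverage filter skipped")
    } else {
      drop_rule(gm$loci$mean_dp < min_mean_coverage, "coverage")
    }
  }
  if (!is.null(min_genotype_quality)) {
    if (is.null(gm$gq)) {
      warning("no genotype-quality annotation present; quality filter skipped")
    } else {
      min_gq <- suppressWarnings(apply(gm$gq, 2, min, na.rm = TRUE))
      drop_rule(is.finite(min_gq) & min_gq < min_genotype_quality, "quality")
    }
  }
  if (drop_missing) {
    drop_rule(colSums(is.na(gm$dosage)) > 0, "missing")
  }
  tot <- colSums(gm$dosage, na.rm = TRUE)
  n_called <- colSums(!is.na(gm$dosage))
  drop_rule(tot == 0 | tot == 2 * n_called, "monomorphic")
  if (!any(keep)) stop("all loci removed by filtering")
  out <- subset_loci(gm, which(keep))
  attr(out, "removal_ledger") <- ledger
  out
}

#' Read and validate a population map
#'
#' @param path TSV with header columns `sample`, `population`, `ecotype`.
#' @param gm a `genotype_matrix`; every sample of `gm` must be mapped and
#'   every mapped sample must exist in `gm`.
#' @return A `population_map` ordered as the matrix's samples.
#' @export
read_popmap <- function(path, gm) {
  if (file.size(path) == 0) stop("empty popmap file: ", path)
  df <- read_tsv(path)
  need <- c("sample", "population", "ecotype")
  if (!all(need %in% names(df))) {
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty popmap file: ", path)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample rows in popmap: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  extra <- setdiff(df$sample, rownames(gm$dosage))
  if (length(extra)) {
    stop("popmap samples absent from the genotype matrix: ",
         paste(extra, collapse = ", "))
  }
  unmapped <- setdiff(rownames(gm$dosage), df$sample)
  if (length(unmapped)) {
    stop("samples missing from the popmap: ", paste(unmapped, collapse = ", "))
  }
  df <- df[match(rownames(gm$dosage), df$sample), ]
  population_map(df$sample, df$population, df$ecotype)
}

#' Read an annotation track from gene-span and gene-term TSVs
#'
#' @param genes_path TSV with columns `gene`, `contig`, `start`, `end`
#'   (1-based inclusive spans).
#' @param terms_path TSV with columns `gene`, `term`.
#' @return An `annotation_track`.
#' @export
read_annotation <- function(genes_path, terms_path) {
  annotation_track(read_tsv(genes_path), read_tsv(terms_path))
}
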