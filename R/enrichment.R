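#' Gene annotation and functional-term enrichment
#'
#' Candidate loci are linked to genes whose span intersects a +/- 5 kb
#' window around the SNP; term overrepresentation in a candidate gene list
#' against a background list is tested per term with a two-tailed Fisher's
#' exact test and Benjamini-Hochberg correction; random neutral gene lists
#' of matched length serve as a negative control.
#'
#' @name annotation_enrichment
NULL

#' Annotation track container
#'
#' @param genes data.frame with columns `gene`, `contig`, `start`, `end`
#'   (1-based inclusive).
#' @param gene_terms data.frame with columns `gene`, `term`.
#' @return A list of class `annotation_track`.
#' @export
annotation_track <- function(genes, gene_terms) {
  stopifnot(all(c("gene", "contig", "start", "end") %in% names(genes)),
            all(c("gene", "term") %in% names(gene_terms)))
  if (anyDuplicated(genes$gene)) stop("duplicate gene ids")
  if (nrow(genes) && any(genes$start > genes$end)) stop("gene span with start > end")
  structure(list(genes = genes, gene_terms = gene_terms),
            class = "annotation_track")
}

#' Link SNP loci to genes within a window
#'
#' A locus links to a gene iff at most `window` bases separate the SNP
#' position from the gene span on the same contig (zero separation when
#' the span covers the SNP). With 1-based inclusive coordinates, a SNP at
#' 10,000 and a gene starting at 15,001 are separated by exactly 5,000
#' intervening bases and are linked at the default window; a gene starting
#' at 15,002 is not.
#'
#' @param loci data.frame with columns `locus`, `contig`, `position`, or a
#'   `genotype_matrix`.
#' @param track an `annotation_track`.
#' @param window half-width of the linkage window in bp (default 5000).
#' @return Named list: per locus, the character vector of linked gene ids
#'   (possibly empty).
#' @export
link_snps_to_genes <- function(loci, track, window = 5000) {
  if (inherits(loci, "genotype_matrix")) loci <- loci$loci
  stopifnot(all(c("locus", "contig", "position") %in% names(loci)))
  out <- stats::setNames(vector("list", nrow(loci)), loci$locus)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (!nrow(track$genes) || !nrow(loci)) return(out)
  # expand by window + 1 so that spans separated from the SNP by exactly
  # `window` intervening bases still intersect; shared seqlevels keep
  # findOverlaps quiet when a contig appears on only one side
  lv <- union(unique(loci$contig), unique(track$genes$contig))
  query <- GenomicRanges::GRanges(
    factor(loci$contig, levels = lv),
    IRanges::IRanges(pmax(1L, loci$position - as.integer(window) - 1L),
                     loci$position + as.integer(window) + 1L))
  subject <- GenomicRanges::GRanges(
    factor(track$genes$contig, levels = lv),
    IRanges::IRanges(track$genes$start, track$genes$end))
  hits <- GenomicRanges::findOverlaps(query, subject)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    out[[i]] <- track$genes$gene[sh[qh == i]]
  }
  out
}

#' Fisher exact enrichment of functional terms
#'
#' For each term, the 2x2 table is (candidate genes with/without the term)
#' versus (background-only genes with/without the term); the two-tailed p
#' sums all tables at most as probable as the observed one. BH correction
#' is applied across terms.
#'
#' @param candidate_genes character vector (deduplicated internally); must
#'   be a subset of `background_genes`.
#' @param background_genes character vector of the background gene list.
#' @param gene_terms data.frame with columns `gene`, `term` (or an
#'   `annotation_track`).
#' @return data.frame of class `enrichment_result`, sorted by adjusted p:
#'   term, k (candidate hits), n (candidate size), K (background hits),
#'   N (background size), p, p_adjusted.
#' @export
fisher_enrichment <- function(candidate_genes, background_genes, gene_terms) {
  if (inherits(gene_terms, "annotation_track")) gene_terms <- gene_terms$gene_terms
  candidate_genes <- unique(candidate_genes)
  background_genes <- unique(background_genes)
  if (!length(candidate_genes)) stop("empty candidate gene list")
  if (length(setdiff(candidate_genes, background_genes))) {
    stop("candidate genes must be a subset of the background")
  }
  n <- length(candidate_genes)
  N <- length(background_genes)
  terms <- unique(gene_terms$term[gene_terms$gene %in% background_genes])
  res <- lapply(terms, function(tm) {
    with_term <- unique(gene_terms$gene[gene_terms$term == tm])
    k <- sum(candidate_genes %in% with_term)
    K <- sum(background_genes %in% with_term)
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), 2, 2)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p_adjusted, out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Random neutral gene lists of matched length
#'
#' Seed-reproducible uniform samples without replacement from the
#' neutral-locus gene pool, each of the same length as the candidate list.
#'
#' @param neutral_genes pool of genes linked to neutral loci.
#' @param list_length length of each random list.
#' @param n_lists number of lists (default 10).
#' @param seed RNG seed.
#' @return List of character vectors.
#' @export
random_neutral_control <- function(neutral_genes, list_length, n_lists = 10,
                                   seed = 1) {
  neutral_genes <- unique(neutral_genes)
  if (length(neutral_genes) < list_length) {
    stop("neutral gene pool smaller than requested list length")
  }
  with_seed(seed, lapply(seq_len(n_lists),
                         function(i) sample(neutral_genes, list_length)))
}

#' Run the enrichment negative control
#'
#' Applies [fisher_enrichment()] to each random neutral list and reports
#' how many lists yield any term significant at the adjusted-p threshold.
#'
#' @inheritParams random_neutral_control
#' @inheritParams fisher_enrichment
#' @param threshold adjusted-p significance threshold (default 0.05).
#' @return List with `n_significant_lists`, `n_lists`, and the per-list
#'   minimum adjusted p-values.
#' @export
control_enrichment <- function(neutral_genes, list_length, background_genes,
                               gene_terms, n_lists = 10, seed = 1,
                               threshold = 0.05) {
  lists <- random_neutral_control(neutral_genes, list_length, n_lists, seed)
  min_adj <- vapply(lists, function(gl) {
    res <- fisher_enrichment(gl, background_genes, gene_terms)
    if (nrow(res)) min(res$p_adjusted) else 1
  }, numeric(1))
  list(n_significant_lists = sum(min_adj <= threshold),
       n_lists = n_lists,
       min_adjusted_p = min_adj)
}
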