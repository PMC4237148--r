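#' Configuration for the hierarchical genotype simulator
#'
#' Defines a two-level (ecotype, population) Balding-Nichols drift design
#' with planted locus classes. The default configuration mirrors a
#' killer-whale-style survey: nine populations in three ecotype groups
#' (four resident, two transient, three outgroup populations) with diploid
#' sample sizes (13, 17, 13, 9, 21, 16, 7, 6, 13) and ~3,000 biallelic SNPs
#' split into neutral, positively selected (elevated between-ecotype
#' differentiation), balancing (suppressed differentiation) and reciprocally
#' fixed classes.
#'
#' @param n_ecotypes number of ecotype groups.
#' @param populations_per_ecotype scalar or vector (length `n_ecotypes`).
#' @param samples_per_population scalar or vector over all populations, in
#'   ecotype order.
#' @param n_neutral,n_positive,n_balancing,n_fixed locus counts per class.
#' @param f_ecotype_neutral drift parameter between ecotypes for neutral
#'   loci, in [0, 1).
#' @param f_ecotype_positive drift parameter for positively selected loci;
#'   must exceed `f_ecotype_neutral`.
#' @param f_population within-ecotype (population-level) drift, in [0, 1).
#' @param f_balancing near-zero drift used at both levels for balancing loci.
#' @param ancestral_bounds lower/upper bound of the uniform ancestral-
#'   frequency distribution, inside (0, 1).
#' @param fixed_ecotype index of the ecotype fixed for the reference allele
#'   at "fixed" loci (all other ecotypes are fixed for the alternate).
#' @param bp_per_locus average spacing used to size the synthetic contig.
#' @param seed integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_ecotypes = 3,
                              populations_per_ecotype = c(4, 2, 3),
                              samples_per_population = c(13, 17, 13, 9, 21, 16, 7, 6, 13),
                              n_neutral = 2670,
                              n_positive = 150,
                              n_balancing = 150,
                              n_fixed = 30,
                              f_ecotype_neutral = 0.05,
                              f_ecotype_positive = 0.5,
                              f_population = 0.02,
                              f_balancing = 0.001,
                              ancestral_bounds = c(0.05, 0.95),
                              fixed_ecotype = 1,
                              bp_per_locus = 10000,
                              seed = 1) {
  if (length(populations_per_ecotype) == 1) {
    populations_per_ecotype <- rep(populations_per_ecotype, n_ecotypes)
  }
  stopifnot(length(populations_per_ecotype) == n_ecotypes,
            all(populations_per_ecotype >= 1))
  n_pops <- sum(populations_per_ecotype)
  if (length(samples_per_population) == 1) {
    samples_per_population <- rep(samples_per_population, n_pops)
  }
  stopifnot(length(samples_per_population) == n_pops,
            all(samples_per_population >= 1))
  fs <- c(f_ecotype_neutral, f_ecotype_positive, f_population, f_balancing)
  if (any(fs < 0) || any(fs >= 1)) stop("all F parameters must lie in [0, 1)")
  if (f_ecotype_positive <= f_ecotype_neutral) {
    stop("f_ecotype_positive must exceed f_ecotype_neutral")
  }
  counts <- c(n_neutral, n_positive, n_balancing, n_fixed)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid locus counts")
  stopifnot(length(ancestral_bounds) == 2,
            ancestral_bounds[1] > 0, ancestral_bounds[2] < 1,
            ancestral_bounds[1] < ancestral_bounds[2],
            fixed_ecotype >= 1, fixed_ecotype <= n_ecotypes)
  structure(list(n_ecotypes = n_ecotypes,
                 populations_per_ecotype = populations_per_ecotype,
                 samples_per_population = samples_per_population,
                 n_neutral = n_neutral, n_positive = n_positive,
                 n_balancing = n_balancing, n_fixed = n_fixed,
                 f_ecotype_neutral = f_ecotype_neutral,
                 f_ecotype_positive = f_ecotype_positive,
                 f_population = f_population,
                 f_balancing = f_balancing,
                 ancestral_bounds = ancestral_bounds,
                 fixed_ecotype = fixed_ecotype,
                 bp_per_locus = bp_per_locus,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Balding-Nichols draw: frequencies around p with drift parameter f.
# Beta(p(1-f)/f, (1-p)(1-f)/f); f = 0 degenerates to p itself.
rbalding_nichols <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a structured genotype dataset with planted locus classes
#'
#' Ancestral frequencies are uniform within the configured bounds; ecotype
#' frequencies are Balding-Nichols draws around the ancestral value
#' (class-specific drift), population frequencies are Balding-Nichols draws
#' around their ecotype value, and genotypes are two binomial allele draws
#' per diploid individual. Balancing loci pin the ancestral frequency near
#' 0.5 with near-zero drift; fixed loci deterministically assign the
#' reference allele to the designated ecotype and the alternate to all
#' others. Loci that come out monomorphic across the whole sample are
#' redrawn (at most 100 times each).
#'
#' @param config a `simulation_config`.
#' @return A list with elements `genotypes` (a `genotype_matrix`), `popmap`
#'   (a `population_map`), `truth` (data.frame locus, class) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  n_pops <- sum(config$populations_per_ecotype)
  pop_labels <- sprintf("pop%02d", seq_len(n_pops))
  eco_of_pop <- rep(sprintf("ecotype%d", seq_len(config$n_ecotypes)),
                    config$populations_per_ecotype)
  n_k <- config$samples_per_population
  sample_ids <- sprintf("s%03d", seq_len(sum(n_k)))
  popmap <- population_map(sample_ids,
                           rep(pop_labels, n_k),
                           rep(eco_of_pop, n_k))

  L <- config$n_neutral + config$n_positive + config$n_balancing + config$n_fixed
  classes <- sample(rep(c("neutral", "positive", "balancing", "fixed"),
                        c(config$n_neutral, config$n_positive,
                          config$n_balancing, config$n_fixed)))

  draw_locus_block <- function(class, m) {
    # population frequencies (n_pops x m) for m loci of one class
    if (class == "balancing") {
      p <- stats::runif(m, 0.45, 0.55)
      f_eco <- config$f_balancing
      f_pop <- config$f_balancing
    } else {
      p <- stats::runif(m, config$ancestral_bounds[1], config$ancestral_bounds[2])
      f_eco <- if (class == "positive") config$f_ecotype_positive else config$f_ecotype_neutral
      f_pop <- config$f_population
    }
    q_eco <- vapply(seq_len(config$n_ecotypes),
                    function(e) rbalding_nichols(p, f_eco), numeric(m))
    if (m == 1) q_eco <- matrix(q_eco, nrow = 1)
    q_pop <- matrix(0, n_pops, m)
    for (k in seq_len(n_pops)) {
      e <- match(eco_of_pop[k], sprintf("ecotype%d", seq_len(config$n_ecotypes)))
      q_pop[k, ] <- rbalding_nichols(q_eco[, e], f_pop)
    }
    q_pop
  }

  draw_genotypes <- function(q_pop) {
    # q_pop: n_pops x m; returns sum(n_k) x m dosage matrix
    m <- ncol(q_pop)
    dos <- matrix(0L, sum(n_k), m)
    row0 <- 0
    for (k in seq_len(n_pops)) {
      dos[row0 + seq_len(n_k[k]), ] <-
        matrix(stats::rbinom(n_k[k] * m, 2, rep(q_pop[k, ], each = n_k[k])),
               n_k[k], m)
      row0 <- row0 + n_k[k]
    }
    dos
  }

  dosage <- matrix(0L, sum(n_k), L)
  for (cls in c("neutral", "positive", "balancing")) {
    idx <- which(classes == cls)
    if (!length(idx)) next
    dos <- draw_genotypes(draw_locus_block(cls, length(idx)))
    # redraw monomorphic loci individually, bounded retries
    tot <- colSums(dos)
    mono <- which(tot == 0 | tot == 2 * sum(n_k))
    for (j in mono) {
      ok <- FALSE
      for (try in seq_len(100)) {
        redraw <- draw_genotypes(draw_locus_block(cls, 1))
        if (sum(redraw) > 0 && sum(redraw) < 2 * sum(n_k)) {
          dos[, j] <- redraw
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("locus persisted monomorphic after 100 redraws")
    }
    dosage[, idx] <- dos
  }
  fixed_idx <- which(classes == "fixed")
  if (length(fixed_idx)) {
    ref_rows <- popmap$ecotype == sprintf("ecotype%d", config$fixed_ecotype)
    dosage[ref_rows, fixed_idx] <- 0L
    dosage[!ref_rows, fixed_idx] <- 2L
  }

  positions <- sort(sample.int(config$bp_per_locus * L, L))
  loci <- data.frame(locus = sprintf("snp%05d", seq_len(L)),
                     contig = "contig_1",
                     position = positions,
                     ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  rownames(dosage) <- sample_ids
  gm <- genotype_matrix(dosage, loci)
  truth <- data.frame(locus = loci$locus, class = classes,
                      stringsAsFactors = FALSE)
  list(genotypes = gm, popmap = popmap, truth = truth, config = config)
}

#' Simulate an annotation track matched to a genotype dataset
#'
#' Places gene spans so that a known, seed-reproducible subset of loci fall
#' within the linkage window of a gene, assigns background functional terms
#' to every gene, and preferentially tags genes near positively selected or
#' fixed loci with designated "enriched" terms.
#'
#' @param gm a `genotype_matrix` with locus coordinates.
#' @param truth truth-label data.frame from [simulate_dataset()].
#' @param fraction_near_gene proportion of loci that receive a gene within
#'   the window.
#' @param terms_per_gene number of background terms drawn per gene.
#' @param enriched_terms term ids planted preferentially on selected-locus
#'   genes.
#' @param prob_enriched_selected,prob_enriched_background probability that a
#'   gene near a selected (positive/fixed) versus other locus carries an
#'   enriched term.
#' @param n_background_terms size of the background term pool.
#' @param gene_halfwidth half-width of each gene span around its locus (bp).
#' @param seed RNG seed.
#' @return An `annotation_track` (see [annotation_track()]).
#' @export
simulate_annotation <- function(gm, truth,
                                fraction_near_gene = 0.6,
                                terms_per_gene = 3,
                                enriched_terms = sprintf("TERM_ENR%d", 1:3),
                                prob_enriched_selected = 0.8,
                                prob_enriched_background = 0.1,
                                n_background_terms = 20,
                                gene_halfwidth = 2000,
                                seed = 1) {
  stopifnot(fraction_near_gene >= 0, fraction_near_gene <= 1,
            terms_per_gene >= 1)
  with_seed(seed, {
    L <- nrow(gm$loci)
    n_genes <- round(fraction_near_gene * L)
    if (n_genes == 0) {
      return(annotation_track(
        genes = data.frame(gene = character(), contig = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE),
        gene_terms = data.frame(gene = character(), term = character(),
                                stringsAsFactors = FALSE)))
    }
    host <- sort(sample.int(L, n_genes))
    genes <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                        contig = gm$loci$contig[host],
                        start = pmax(1L, gm$loci$position[host] - as.integer(gene_halfwidth)),
                        end = gm$loci$position[host] + as.integer(gene_halfwidth),
                        stringsAsFactors = FALSE)
    pool <- sprintf("TERM%02d", seq_len(n_background_terms))
    selected_host <- truth$class[host] %in% c("positive", "fixed")
    term_rows <- lapply(seq_len(n_genes), function(i) {
      terms <- sample(pool, terms_per_gene)
      p_enr <- if (selected_host[i]) prob_enriched_selected else prob_enriched_background
      if (stats::runif(1) < p_enr) terms <- c(terms, sample(enriched_terms, 1))
      data.frame(gene = genes$gene[i], term = terms, stringsAsFactors = FALSE)
    })
    annotation_track(genes, do.call(rbind, term_rows))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits a VCFv4.2 genotype file, a sample/population/ecotype TSV, gene-span
#' and gene-term TSVs, and the truth-label TSV. The files round-trip through
#' [read_vcf()] / [read_popmap()] exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param annotation an `annotation_track` or NULL.
#' @param truth truth-label data.frame or NULL.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(gm, popmap, annotation = NULL, truth = NULL, out_dir) {
  if (nrow(gm$dosage) == 0) stop("dataset has zero samples")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             popmap = file.path(out_dir, "popmap.tsv"))
  write_vcf(gm, paths[["vcf"]])
  write_tsv(as.data.frame(popmap)[, c("sample", "population", "ecotype")],
            paths[["popmap"]])
  if (!is.null(annotation)) {
    paths[["genes"]] <- file.path(out_dir, "genes.tsv")
    paths[["gene_terms"]] <- file.path(out_dir, "gene_terms.tsv")
    write_tsv(annotation$genes, paths[["genes"]])
    write_tsv(annotation$gene_terms, paths[["gene_terms"]])
  }
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(out_dir, "truth.tsv")
    write_tsv(truth, paths[["truth"]])
  }
  invisible(paths)
}

# Emit a genotype matrix as a minimal VCFv4.2 file (GT-only FORMAT).
write_vcf <- function(gm, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- gm$dosage
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(gm$loci$contig)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  gt <- matrix(ifelse(is.na(dos), "./.", gt_code[as.character(dos)]),
               nrow = nrow(dos))
  body <- apply(cbind(gm$loci$contig, gm$loci$position, gm$loci$locus,
                      gm$loci$ref, gm$loci$alt, ".", "PASS", ".", "GT",
                      t(gt)),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
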