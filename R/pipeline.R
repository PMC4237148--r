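#' End-to-end analysis pipeline
#'
#' Runs filtering, the iterated outlier scan, neutral/outlier
#' differentiation layers, fixed-difference testing, ecotype contrasts and
#' (when an annotation is available) term enrichment, writing plain-text
#' reports plus a checksum manifest. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' Either `sim_config` (a [simulation_config()]; the dataset is simulated
#' and written into the output directory) or `vcf` + `popmap_path` must be
#' given. Annotation inputs are optional; without them the enrichment stage
#' is skipped with a notice.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master integer seed; all stage seeds derive from it.
#' @param sim_config optional `simulation_config`.
#' @param vcf,popmap_path optional input paths.
#' @param genes_path,terms_path optional annotation TSV paths.
#' @param min_mean_coverage,min_genotype_quality filter thresholds.
#' @param n_sims,fdr,n_bins outlier-scan parameters.
#' @param ecotype_a,ecotype_b the two focal ecotype labels for the
#'   contrasts.
#' @param outgroup outgroup ecotype label (optional contrast).
#' @param window enrichment linkage window (bp).
#' @param enrichment_threshold adjusted-p threshold for reporting.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, sim_config = NULL, vcf = NULL,
                       popmap_path = NULL, genes_path = NULL,
                       terms_path = NULL, min_mean_coverage = 20,
                       min_genotype_quality = 20, n_sims = 50000, fdr = 0.1,
                       n_bins = 50, ecotype_a = "ecotype1",
                       ecotype_b = "ecotype2", outgroup = "ecotype3",
                       window = 5000, enrichment_threshold = 0.05) {
  if (is.null(sim_config) && (is.null(vcf) || is.null(popmap_path))) {
    stop("either sim_config or vcf + popmap_path must be supplied")
  }
  for (p in c(vcf, popmap_path, genes_path, terms_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim_config = sim_config, vcf = vcf,
                 popmap_path = popmap_path, genes_path = genes_path,
                 terms_path = terms_path,
                 min_mean_coverage = min_mean_coverage,
                 min_genotype_quality = min_genotype_quality,
                 n_sims = n_sims, fdr = fdr, n_bins = n_bins,
                 ecotype_a = ecotype_a, ecotype_b = ecotype_b,
                 outgroup = outgroup, window = window,
                 enrichment_threshold = enrichment_threshold),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest of written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(...) if (!quiet) message(...)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(x, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) {
        manifest <- data.frame(file = basename(written),
                               md5 = unname(tools::md5sum(written)))
        write_tsv(manifest, file.path(config$out_dir, "manifest_partial.tsv"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- input ----------------------------------------------------------
  annotation <- NULL; truth <- NULL
  stage("input", {
    if (!is.null(config$sim_config)) {
      sim <- simulate_dataset(config$sim_config)
      gm <- sim$genotypes; popmap <- sim$popmap; truth <- sim$truth
      annotation <- simulate_annotation(gm, truth,
                                        seed = config$seed + 101L)
      write_dataset(gm, popmap, annotation, truth,
                    file.path(config$out_dir, "data"))
    } else {
      gm <- read_vcf(config$vcf)
      popmap <- read_popmap(config$popmap_path, gm)
      if (!is.null(config$genes_path) && !is.null(config$terms_path)) {
        annotation <- read_annotation(config$genes_path, config$terms_path)
      }
    }
  })

  # -- filter ---------------------------------------------------------
  gm_f <- stage("filter", suppressWarnings(
    filter_snps(gm, config$min_mean_coverage, config$min_genotype_quality)))
  ledger <- attr(gm_f, "removal_ledger")
  emit(data.frame(rule = names(ledger), removed = as.integer(ledger)),
       "filter_ledger.tsv")
  note(sprintf("filter: %d -> %d loci", ncol(gm$dosage), ncol(gm_f$dosage)))

  # -- outlier scan ---------------------------------------------------
  scan <- stage("outlier_scan",
                iterate_baseline(gm_f, popmap, fdr = config$fdr,
                                 n_sims = config$n_sims,
                                 seed = config$seed,
                                 n_bins = config$n_bins))
  cls <- scan$classification
  emit(as.data.frame(cls), "classification.tsv")
  note(sprintf("scan: baseline %.4f; %d positive, %d balancing, %d neutral",
               scan$baseline, sum(cls$label == "positive"),
               sum(cls$label == "balancing"), sum(cls$label == "neutral")))
  neutral_ids <- cls$locus[cls$label == "neutral"]
  outlier_ids <- cls$locus[cls$label == "positive"]

  # -- differentiation layers ----------------------------------------
  layers <- stage("layers", {
    out <- list(fst_neutral = pairwise_fst(gm_f, popmap, neutral_ids, "neutral"),
                diff_neutral = allelic_difference_matrix(gm_f, popmap,
                                                         neutral_ids, "neutral"))
    if (length(outlier_ids) >= 2) {
      out$fst_outlier <- pairwise_fst(gm_f, popmap, outlier_ids, "outlier")
      out$diff_outlier <- allelic_difference_matrix(gm_f, popmap,
                                                    outlier_ids, "outlier")
    }
    out
  })
  for (nm in names(layers)) {
    emit(data.frame(pop = rownames(layers[[nm]]$values),
                    layers[[nm]]$values, check.names = FALSE),
         paste0(nm, ".tsv"))
  }

  # -- fixed differences ---------------------------------------------
  fixed <- stage("fixed_diff", {
    out <- list(neutral = fixed_diff_matrix(gm_f, popmap, neutral_ids, "neutral"))
    if (length(outlier_ids)) {
      out$outlier <- fixed_diff_matrix(gm_f, popmap, outlier_ids, "outlier")
    }
    out
  })
  for (nm in names(fixed)) {
    counts <- fixed[[nm]]$values
    starred <- matrix(paste0(counts, ifelse(fixed[[nm]]$significant, "*", "")),
                      nrow(counts), dimnames = dimnames(counts))
    emit(data.frame(pop = rownames(starred), starred, check.names = FALSE),
         paste0("fixed_diff_", nm, ".tsv"))
  }

  # -- ecotype contrasts ---------------------------------------------
  contrast <- stage("contrast", {
    if (is.null(layers$fst_outlier)) {
      note("contrast: fewer than 2 outlier loci; stage skipped")
      NULL
    } else {
      rn <- ratio_set(layers$fst_neutral, popmap, config$ecotype_a, config$ecotype_b)
      ro <- ratio_set(layers$fst_outlier, popmap, config$ecotype_a, config$ecotype_b)
      mw <- mann_whitney(rn$ratios, ro$ratios)
      x2 <- chi2_contrast(layers$diff_neutral, layers$diff_outlier, popmap,
                          config$ecotype_a, config$ecotype_b)
      og <- if (!is.null(config$outgroup) &&
                length(pops_of_ecotype(popmap, config$outgroup))) {
        outgroup_contrast(layers$diff_neutral, layers$diff_outlier, popmap,
                          config$ecotype_a, config$ecotype_b, config$outgroup)
      }
      list(ratio_neutral = rn, ratio_outlier = ro, mann_whitney = mw,
           chi2 = x2, outgroup = og)
    }
  })
  if (!is.null(contrast)) {
    emit(data.frame(
      quantity = c("neutral_ratio_mean", "neutral_ratio_min", "neutral_ratio_max",
                   "outlier_ratio_mean", "outlier_ratio_min", "outlier_ratio_max",
                   "ratio_n", "mann_whitney_U", "mann_whitney_Z", "mann_whitney_p",
                   "chi2_between_within", "chi2_p",
                   "chi2_outgroup", "chi2_outgroup_p"),
      value = c(contrast$ratio_neutral$mean, contrast$ratio_neutral$min,
                contrast$ratio_neutral$max, contrast$ratio_outlier$mean,
                contrast$ratio_outlier$min, contrast$ratio_outlier$max,
                contrast$ratio_neutral$n, contrast$mann_whitney$U,
                contrast$mann_whitney$z, contrast$mann_whitney$p,
                contrast$chi2$statistic, contrast$chi2$p_value,
                contrast$outgroup$statistic %||% NA,
                contrast$outgroup$p_value %||% NA)),
      "contrast.tsv")
  }

  # -- enrichment -----------------------------------------------------
  enrich <- stage("enrichment", {
    if (is.null(annotation)) {
      note("enrichment: no annotation supplied; stage skipped")
      NULL
    } else {
      links <- link_snps_to_genes(gm_f, annotation, window = config$window)
      # candidates: best-supported positive outliers plus loci fixed for
      # any population pair
      candidate_ids <- cls$locus[cls$label == "positive" & cls$best_supported]
      pops <- unique(popmap$population)
      for (i in seq_along(pops)) for (j in seq_along(pops)) {
        if (i < j) candidate_ids <- union(candidate_ids,
                                          find_fixed(gm_f, popmap, pops[i], pops[j]))
      }
      candidate_genes <- unique(unlist(links[candidate_ids]))
      background_genes <- unique(unlist(links))
      if (!length(candidate_genes)) {
        note("enrichment: no candidate locus links to a gene; stage skipped")
        NULL
      } else {
        res <- fisher_enrichment(candidate_genes, background_genes, annotation)
        neutral_genes <- setdiff(unique(unlist(links[neutral_ids])), candidate_genes)
        ctrl <- if (length(neutral_genes) >= length(candidate_genes)) {
          control_enrichment(neutral_genes, length(candidate_genes),
                             background_genes, annotation,
                             seed = config$seed + 202L,
                             threshold = config$enrichment_threshold)
        }
        list(result = res, control = ctrl)
      }
    }
  })
  if (!is.null(enrich)) emit(as.data.frame(enrich$result), "enrichment.tsv")

  # -- manifest -------------------------------------------------------
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(genotypes = gm_f, popmap = popmap, scan = scan,
                 layers = layers, fixed = fixed, contrast = contrast,
                 enrichment = enrich, truth = truth, manifest = manifest))
}
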