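test_that("simulation is reproducible and respects dosage/frequency bounds", {
  cfg <- simulation_config(n_neutral = 100, n_positive = 10, n_balancing = 10,
                           n_fixed = 5, samples_per_population = 6, seed = 42)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$genotypes$dosage, sim2$genotypes$dosage)
  expect_identical(sim1$genotypes$loci, sim2$genotypes$loci)
  expect_identical(sim1$truth, sim2$truth)
  expect_true(all(sim1$genotypes$dosage %in% 0:2))
  expect_false(anyDuplicated(sim1$genotypes$loci$position) > 0)
  # no locus monomorphic across the whole sample
  tot <- colSums(sim1$genotypes$dosage)
  expect_true(all(tot > 0 & tot < 2 * nrow(sim1$genotypes$dosage)))
  # every locus has exactly one truth class
  expect_setequal(sim1$truth$locus, sim1$genotypes$loci$locus)
  expect_true(all(sim1$truth$class %in% c("neutral", "positive", "balancing", "fixed")))
})

test_that("zero drift gives allele frequencies equal across populations up to sampling", {
  cfg <- simulation_config(n_ecotypes = 3, populations_per_ecotype = 3,
                           samples_per_population = 25,
                           n_neutral = 500, n_positive = 0, n_balancing = 0,
                           n_fixed = 0, f_ecotype_neutral = 0,
                           f_population = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  summ <- locus_summaries(sim$genotypes, sim$popmap)
  expect_lt(abs(ecoscan:::multilocus_theta(summ$wc_a, summ$wc_d)), 0.01)
})

test_that("realized FST matches the Balding-Nichols drift parameter", {
  # single-level drift: 8 ecotypes of one population each at F = 0.05
  cfg <- simulation_config(n_ecotypes = 8, populations_per_ecotype = 1,
                           samples_per_population = 25,
                           n_neutral = 800, n_positive = 0, n_balancing = 0,
                           n_fixed = 0, f_ecotype_neutral = 0.05,
                           f_population = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  summ <- locus_summaries(sim$genotypes, sim$popmap)
  expect_lt(abs(ecoscan:::multilocus_theta(summ$wc_a, summ$wc_d) - 0.05), 0.012)
})

test_that("Balding-Nichols draws have variance F p (1 - p)", {
  p <- 0.3; f <- 0.15
  draws <- ecoscan:::with_seed(3, ecoscan:::rbalding_nichols(rep(p, 2e5), f))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - p), 0.005)
  expect_lt(abs(stats::var(draws) - f * p * (1 - p)) / (f * p * (1 - p)), 0.03)
})

test_that("fixed loci are reciprocally monomorphic between the designated ecotypes", {
  cfg <- simulation_config(n_neutral = 50, n_positive = 0, n_balancing = 0,
                           n_fixed = 10, samples_per_population = 5, seed = 13)
  sim <- simulate_dataset(cfg)
  fixed_ids <- sim$truth$locus[sim$truth$class == "fixed"]
  expect_length(fixed_ids, 10)
  eco1 <- sim$popmap$sample[sim$popmap$ecotype == "ecotype1"]
  eco2 <- sim$popmap$sample[sim$popmap$ecotype == "ecotype2"]
  dos <- sim$genotypes$dosage[, fixed_ids, drop = FALSE]
  expect_true(all(dos[eco1, ] == 0))
  expect_true(all(dos[eco2, ] == 2))
  # and no other locus is reciprocally fixed between complete ecotypes
  p1 <- sim$popmap$population[match(eco1[1], sim$popmap$sample)]
  p2 <- sim$popmap$population[match(eco2[1], sim$popmap$sample)]
  found <- find_fixed(sim$genotypes, sim$popmap, p1, p2)
  expect_true(all(fixed_ids %in% found))
})

test_that("positive-class loci realize higher FST than neutral loci", {
  cfg <- simulation_config(n_neutral = 400, n_positive = 100, n_balancing = 100,
                           n_fixed = 0, samples_per_population = 10, seed = 21)
  sim <- simulate_dataset(cfg)
  summ <- locus_summaries(sim$genotypes, sim$popmap)
  mt <- function(cls) {
    idx <- sim$truth$class == cls
    ecoscan:::multilocus_theta(summ$wc_a[idx], summ$wc_d[idx])
  }
  expect_gt(mt("positive"), mt("neutral") + 0.2)
  expect_lt(mt("balancing"), mt("neutral"))
})

test_that("written datasets round-trip bit-exactly through the readers", {
  cfg <- simulation_config(n_neutral = 60, n_positive = 10, n_balancing = 5,
                           n_fixed = 5, samples_per_population = 4, seed = 33)
  sim <- simulate_dataset(cfg)
  ann <- simulate_annotation(sim$genotypes, sim$truth, seed = 33)
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim$genotypes, sim$popmap, ann, sim$truth, dir)
  gm2 <- read_vcf(paths[["vcf"]])
  expect_identical(unname(gm2$dosage), unname(sim$genotypes$dosage))
  expect_identical(gm2$loci$position, sim$genotypes$loci$position)
  pm2 <- read_popmap(paths[["popmap"]], gm2)
  expect_identical(pm2$population, sim$popmap$population)
  truth2 <- read.table(paths[["truth"]], sep = "\t", header = TRUE)
  expect_equal(nrow(truth2), ncol(sim$genotypes$dosage))
  ann2 <- read_annotation(paths[["genes"]], paths[["gene_terms"]])
  expect_equal(ann2$genes, ann$genes)
})

test_that("writing an empty dataset errors", {
  cfg <- simulation_config(n_neutral = 5, n_positive = 0, n_balancing = 0,
                           n_fixed = 0, samples_per_population = 2, seed = 1)
  sim <- simulate_dataset(cfg)
  gm0 <- sim$genotypes
  gm0$dosage <- gm0$dosage[integer(0), , drop = FALSE]
  expect_error(write_dataset(gm0, sim$popmap, out_dir = tempfile()),
               "zero samples")
})

test_that("annotation placement controls linkage and enrichment structure", {
  cfg <- simulation_config(n_neutral = 80, n_positive = 20, n_balancing = 0,
                           n_fixed = 0, samples_per_population = 4, seed = 5)
  sim <- simulate_dataset(cfg)
  ann0 <- simulate_annotation(sim$genotypes, sim$truth,
                              fraction_near_gene = 0, seed = 5)
  links0 <- link_snps_to_genes(sim$genotypes, ann0, window = 5000)
  expect_true(all(lengths(links0) == 0))
  ann1 <- simulate_annotation(sim$genotypes, sim$truth,
                              fraction_near_gene = 1, seed = 5)
  links1 <- link_snps_to_genes(sim$genotypes, ann1, window = 5000)
  expect_true(all(lengths(links1) >= 1))
  # same seed, same track
  ann1b <- simulate_annotation(sim$genotypes, sim$truth,
                               fraction_near_gene = 1, seed = 5)
  expect_identical(ann1, ann1b)
})
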