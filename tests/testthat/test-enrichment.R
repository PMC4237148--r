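test_that("the 5 kb window uses closed-interval boundaries", {
  loci <- data.frame(locus = "L1", contig = "c1", position = 10000)
  near <- annotation_track(data.frame(gene = "g1", contig = "c1",
                                      start = 15001, end = 20000),
                           data.frame(gene = "g1", term = "T1"))
  far <- annotation_track(data.frame(gene = "g1", contig = "c1",
                                     start = 15002, end = 20000),
                          data.frame(gene = "g1", term = "T1"))
  expect_equal(link_snps_to_genes(loci, near, 5000)$L1, "g1")
  expect_length(link_snps_to_genes(loci, far, 5000)$L1, 0)
  # different contig never links
  off <- annotation_track(data.frame(gene = "g1", contig = "c2",
                                     start = 9000, end = 11000),
                          data.frame(gene = "g1", term = "T1"))
  expect_length(link_snps_to_genes(loci, off, 5000)$L1, 0)
})

test_that("linkage matches the brute-force interval oracle and grows with the window", {
  set.seed(17)
  loci <- data.frame(locus = sprintf("L%02d", 1:40),
                     contig = sample(c("c1", "c2"), 40, replace = TRUE),
                     position = sample.int(2e5, 40))
  start <- sample.int(2e5, 25)
  genes <- data.frame(gene = sprintf("g%02d", 1:25),
                      contig = sample(c("c1", "c2"), 25, replace = TRUE),
                      start = start, end = start + sample.int(8000, 25))
  track <- annotation_track(genes, data.frame(gene = "g01", term = "T1"))
  got <- link_snps_to_genes(loci, track, 5000)
  want <- linkage_oracle(loci, genes, 5000)
  for (l in loci$locus) expect_setequal(got[[l]], want[[l]])
  wide <- link_snps_to_genes(loci, track, 20000)
  for (l in loci$locus) expect_true(all(got[[l]] %in% wide[[l]]))
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  genes <- sprintf("g%03d", 1:100)
  terms <- data.frame(gene = genes[1:10], term = "T_A")
  res <- fisher_enrichment(genes[1:10][c(1:5)] |> c(genes[50:54]),
                           genes, terms)
  row <- res[res$term == "T_A", ]
  expect_equal(row$k, 5); expect_equal(row$n, 10)
  expect_equal(row$K, 10); expect_equal(row$N, 100)
  expect_equal(row$p, fisher_oracle(5, 10, 10, 100), tolerance = 1e-9)
  # equal proportional representation -> p = 1
  terms_all <- data.frame(gene = genes, term = "T_B")
  res_b <- fisher_enrichment(genes[1:10], genes, terms_all)
  expect_equal(res_b$p[res_b$term == "T_B"], 1)
  # random tables against the oracle
  set.seed(23)
  for (rep in 1:5) {
    N <- 60; n <- 15; K <- sample(5:30, 1)
    cand <- sample(genes[1:N], n)
    tg <- sample(genes[1:N], K)
    res_r <- fisher_enrichment(cand, genes[1:N],
                               data.frame(gene = tg, term = "T_R"))
    k <- sum(cand %in% tg)
    expect_equal(res_r$p[res_r$term == "T_R"], fisher_oracle(k, n, K, N),
                 tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(character(0), genes, terms), "empty candidate")
  expect_error(fisher_enrichment("nope", genes, terms), "subset")
})

test_that("enrichment is invariant to gene-list order and adjusted p >= p", {
  genes <- sprintf("g%03d", 1:80)
  set.seed(3)
  terms <- data.frame(gene = sample(genes, 120, replace = TRUE),
                      term = sample(sprintf("T%02d", 1:8), 120, replace = TRUE))
  cand <- sample(genes, 20)
  r1 <- fisher_enrichment(cand, genes, terms)
  r2 <- fisher_enrichment(rev(cand), sample(genes), terms)
  expect_equal(r1, r2)
  expect_true(all(r1$p_adjusted >= r1$p - 1e-12))
})

test_that("planted enrichment is detected and the neutral control stays clean", {
  cfg <- simulation_config(n_neutral = 300, n_positive = 60, n_balancing = 0,
                           n_fixed = 0, samples_per_population = 4, seed = 71)
  sim <- simulate_dataset(cfg)
  ann <- simulate_annotation(sim$genotypes, sim$truth, fraction_near_gene = 0.8,
                             seed = 71)
  links <- link_snps_to_genes(sim$genotypes, ann)
  cand <- unique(unlist(links[sim$truth$locus[sim$truth$class == "positive"]]))
  bg <- unique(unlist(links))
  res <- fisher_enrichment(cand, bg, ann)
  top <- res$term[1]
  expect_true(top %in% sprintf("TERM_ENR%d", 1:3))
  expect_lt(res$p_adjusted[1], 0.05)
  # random neutral lists of matched length: no significant term
  neutral_pool <- setdiff(unique(unlist(links[sim$truth$locus[sim$truth$class == "neutral"]])),
                          cand)
  ctrl <- control_enrichment(neutral_pool, length(cand), bg, ann,
                             n_lists = 10, seed = 72)
  expect_lte(ctrl$n_significant_lists, 1)
})

test_that("random neutral lists are reproducible and bounded by the pool", {
  pool <- sprintf("g%02d", 1:12)
  l1 <- random_neutral_control(pool, 5, n_lists = 3, seed = 9)
  l2 <- random_neutral_control(pool, 5, n_lists = 3, seed = 9)
  expect_identical(l1, l2)
  expect_true(all(lengths(l1) == 5))
  full <- random_neutral_control(pool, 12, n_lists = 2, seed = 9)
  expect_setequal(full[[1]], pool)
  expect_setequal(full[[2]], pool)
  expect_error(random_neutral_control(pool, 13, seed = 9), "smaller")
})
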