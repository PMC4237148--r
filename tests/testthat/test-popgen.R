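test_that("heterozygosity and theta match hand-derived cases", {
  # pooled frequency 0.5 -> He = 0.5; reciprocal fixation -> theta = 1
  gm <- make_gm(list(c(0, 0), c(2, 0), c(1, 2), c(1, 2)))
  pm <- make_popmap(c(2, 2))
  summ <- locus_summaries(gm, pm)
  expect_equal(summ$p_hat[1], 0.5)
  expect_equal(summ$he[1], 0.5)
  expect_equal(summ$theta[2], 1)
})

test_that("theta equals the longhand Weir-Cockerham evaluation", {
  # frozen from an independent scalar transcription of the 1984 components
  pops <- list(c(0, 1, 1, 1), c(1, 1, 1, 2))
  dos <- matrix(c(0, 1, 1, 1, 1, 1, 1, 2), ncol = 1)
  rownames(dos) <- sprintf("s%02d", 1:8)
  gm <- genotype_matrix(dos, data.frame(locus = "L1", contig = "c",
                                        position = 1, ref = "A", alt = "G"))
  pm <- make_popmap(c(4, 4))
  expect_equal(locus_summaries(gm, pm)$theta, 0.0588235294, tolerance = 1e-9)
  expect_equal(wc_longhand(pops), 0.0588235294, tolerance = 1e-9)
  # three unequal populations
  pops3 <- list(c(0, 1, 2, 1), c(2, 2, 1), c(0, 0, 1, 1, 0))
  dos3 <- matrix(unlist(pops3), ncol = 1)
  rownames(dos3) <- sprintf("s%02d", 1:12)
  gm3 <- genotype_matrix(dos3, data.frame(locus = "L1", contig = "c",
                                          position = 1, ref = "A", alt = "G"))
  pm3 <- make_popmap(c(4, 3, 5))
  expect_equal(locus_summaries(gm3, pm3)$theta, 0.2483815656, tolerance = 1e-9)
})

test_that("pairwise theta equals the multi-population formula on two populations", {
  set.seed(8)
  dos <- matrix(sample(0:2, 30 * 12, replace = TRUE), 12, 30)
  rownames(dos) <- sprintf("s%02d", 1:12)
  gm <- genotype_matrix(dos, data.frame(locus = sprintf("L%03d", 1:30),
                                        contig = "c", position = 1:30,
                                        ref = "A", alt = "G"))
  pm3 <- make_popmap(c(4, 4, 4))
  layer <- pairwise_fst(gm, pm3)
  # restrict popmap to P1/P2 and recompute via the multi-population path
  pm2 <- population_map(rownames(dos)[1:8], rep(c("P1", "P2"), each = 4),
                        rep(c("P1", "P2"), each = 4))
  gm2 <- gm; gm2$dosage <- gm$dosage[1:8, , drop = FALSE]
  summ <- locus_summaries(gm2, pm2)
  expect_equal(layer$values["P1", "P2"],
               ecoscan:::multilocus_theta(summ$wc_a, summ$wc_d))
  expect_equal(layer$values, t(layer$values))
})

test_that("statistics are invariant to ref/alt relabeling", {
  set.seed(4)
  dos <- matrix(sample(0:2, 20 * 9, replace = TRUE), 9, 20)
  rownames(dos) <- sprintf("s%02d", 1:9)
  loci <- data.frame(locus = sprintf("L%03d", 1:20), contig = "c",
                     position = 1:20, ref = "A", alt = "G")
  gm <- genotype_matrix(dos, loci)
  flipped <- dos; flipped[, 5] <- 2L - flipped[, 5]
  gmf <- genotype_matrix(flipped, loci)
  pm <- make_popmap(c(3, 3, 3))
  s1 <- locus_summaries(gm, pm); s2 <- locus_summaries(gmf, pm)
  expect_equal(s1$he, s2$he)
  expect_equal(s1$theta, s2$theta)
  expect_equal(allelic_difference_matrix(gm, pm)$values,
               allelic_difference_matrix(gmf, pm)$values)
  expect_equal(pairwise_fst(gm, pm)$values, pairwise_fst(gmf, pm)$values)
})

test_that("allelic differences match hand cases and the brute-force oracle", {
  # identical individuals -> 0; (0,2) vs (2,0) -> 4
  gm <- make_gm(list(c(0, 2), c(0, 2), c(2, 0), c(2, 0)))
  pm <- make_popmap(c(2, 2))
  layer <- allelic_difference_matrix(gm, pm)
  expect_equal(layer$values["P1", "P1"], 0)
  expect_equal(layer$values["P1", "P2"], 4)
  # random instances vs exhaustive pair enumeration
  set.seed(11)
  for (rep in 1:3) {
    ni <- sample(2:5, 3, replace = TRUE)
    dos <- matrix(sample(0:2, sum(ni) * 8, replace = TRUE), sum(ni), 8)
    rownames(dos) <- sprintf("s%02d", seq_len(sum(ni)))
    gm <- genotype_matrix(dos, data.frame(locus = sprintf("L%03d", 1:8),
                                          contig = "c", position = 1:8,
                                          ref = "A", alt = "G"))
    pm <- make_popmap(ni)
    got <- allelic_difference_matrix(gm, pm)$values
    want <- allelic_diff_oracle(dos, rep(sprintf("P%d", 1:3), ni))
    expect_equal(got, want)
  }
})

test_that("size-one populations flag an undefined within-population value", {
  gm <- make_gm(list(c(0, 1), c(1, 2), c(2, 0)))
  pm <- make_popmap(c(2, 1))
  layer <- allelic_difference_matrix(gm, pm)
  expect_true(is.na(layer$values["P2", "P2"]))
  expect_equal(layer$undefined_within, "P2")
})

test_that("splitting one population into two pseudo-populations gives theta near 0", {
  set.seed(19)
  dos <- matrix(rbinom(40 * 200, 2, 0.4), 40, 200)
  rownames(dos) <- sprintf("s%02d", 1:40)
  gm <- genotype_matrix(dos, data.frame(locus = sprintf("L%03d", 1:200),
                                        contig = "c", position = 1:200,
                                        ref = "A", alt = "G"))
  pm <- make_popmap(c(20, 20))
  layer <- pairwise_fst(gm, pm, permutations = 49, seed = 2)
  expect_lt(abs(layer$values["P1", "P2"]), 0.02)
  expect_gt(layer$p_values["P1", "P2"], 0.1)
})

test_that("per-locus normalization divides by the locus count", {
  gm <- make_gm(list(c(0, 2), c(0, 2), c(2, 0), c(2, 0)))
  pm <- make_popmap(c(2, 2))
  raw <- allelic_difference_matrix(gm, pm)$values
  norm <- allelic_difference_matrix(gm, pm, normalize = TRUE)$values
  expect_equal(norm, raw / 2)
})
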