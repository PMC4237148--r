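toy_vcf <- function() {
  samples <- c("a", "b", "c")
  rec <- function(pos, ref, alt, gts, id = ".") {
    paste(c("chr1", pos, id, ref, alt, ".", "PASS", ".", "GT:DP:GQ", gts),
          collapse = "\t")
  }
  g <- function(gt, dp = 30, gq = 99) sprintf("%s:%d:%d", gt, dp, gq)
  records <- c(
    # 5 clean biallelic SNPs
    rec(100, "A", "G", c(g("0/0"), g("0/1"), g("1/1"))),
    rec(200, "C", "T", c(g("0/1"), g("0/1"), g("0/0"))),
    rec(300, "G", "A", c(g("1/1"), g("0/1"), g("0/0"))),
    rec(400, "T", "C", c(g("0/0"), g("0/0"), g("0/1"))),
    rec(500, "A", "C", c(g("0/1"), g("1/1"), g("0/1"))),
    # 2 indels
    rec(600, "A", "AT", c(g("0/1"), g("0/0"), g("0/0"))),
    rec(700, "CTT", "C", c(g("0/0"), g("0/1"), g("0/0"))),
    # 1 below mean coverage 20 (DP 15 in all samples)
    rec(800, "G", "T", c(g("0/1", dp = 15), g("0/0", dp = 15), g("0/1", dp = 15))),
    # 1 with one genotype below Q20
    rec(900, "A", "G", c(g("0/1"), g("0/1", gq = 12), g("0/0"))),
    # 1 with a missing call
    rec(1000, "C", "G", c(g("0/1"), "./.:.:.", g("0/0")))
  )
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, records, samples)
  path
}

test_that("VCF parsing yields dosages, flags and missing calls", {
  gm <- read_vcf(toy_vcf())
  expect_equal(dim(gm$dosage), c(3, 10))
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(sum(gm$loci$is_indel), 2)
  expect_true(gm$loci$is_indel[6] && gm$loci$is_indel[7])
  expect_true(is.na(gm$dosage["b", 10]))
  expect_equal(gm$loci$mean_dp[8], 15)
})

test_that("filtering applies each rule and ledgers the removals", {
  gm <- read_vcf(toy_vcf())
  filtered <- filter_snps(gm)
  expect_equal(ncol(filtered$dosage), 5)
  ledger <- attr(filtered, "removal_ledger")
  expect_equal(ledger[["indel"]], 2L)
  expect_equal(ledger[["coverage"]], 1L)
  expect_equal(ledger[["quality"]], 1L)
  expect_equal(ledger[["missing"]], 1L)
  expect_equal(sum(ledger), ncol(gm$dosage) - ncol(filtered$dosage))
  # idempotence
  again <- filter_snps(filtered)
  expect_identical(again$dosage, filtered$dosage)
  expect_equal(sum(attr(again, "removal_ledger")), 0L)
})

test_that("monomorphic loci are removed as non-variable", {
  dos <- rbind(c(0, 1), c(0, 0), c(0, 2))
  rownames(dos) <- c("a", "b", "c")
  gm <- genotype_matrix(dos, data.frame(locus = c("m", "v"), contig = "c",
                                        position = c(1, 2), ref = "A", alt = "G"))
  filtered <- suppressWarnings(filter_snps(gm))
  expect_equal(filtered$loci$locus, "v")
  expect_equal(attr(filtered, "removal_ledger")[["monomorphic"]], 1L)
})

test_that("filters lacking their annotation are skipped with a warning", {
  dos <- rbind(c(0, 1), c(1, 0))
  rownames(dos) <- c("a", "b")
  gm <- genotype_matrix(dos, data.frame(locus = c("x", "y"), contig = "c",
                                        position = 1:2, ref = "A", alt = "G"))
  expect_warning(filter_snps(gm, min_genotype_quality = NULL), "coverage")
  expect_warning(filter_snps(gm, min_mean_coverage = NULL), "quality")
})

test_that("an all-removed filter errors explicitly", {
  dos <- rbind(c(0, 0), c(0, 0))
  rownames(dos) <- c("a", "b")
  gm <- genotype_matrix(dos, data.frame(locus = c("x", "y"), contig = "c",
                                        position = 1:2, ref = "A", alt = "G"))
  expect_error(suppressWarnings(filter_snps(gm)), "all loci removed")
})

test_that("popmap validation catches structural problems", {
  gm <- read_vcf(toy_vcf())
  write_pm <- function(df) {
    p <- tempfile(fileext = ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  good <- data.frame(sample = c("a", "b", "c"),
                     population = c("P1", "P1", "P2"),
                     ecotype = c("e1", "e1", "e2"))
  pm <- read_popmap(write_pm(good), gm)
  expect_s3_class(pm, "population_map")
  expect_equal(unname(attr(pm, "pop_sizes")), c(2L, 1L))
  expect_error(read_popmap(write_pm(good[1:2, ]), gm), "missing from the popmap: c")
  bad_extra <- rbind(good, data.frame(sample = "zz", population = "P3", ecotype = "e3"))
  expect_error(read_popmap(write_pm(bad_extra), gm), "absent from the genotype matrix: zz")
  dup <- rbind(good, good[1, ])
  expect_error(read_popmap(write_pm(dup), gm), "duplicate sample rows")
  empty <- tempfile(); file.create(empty)
  expect_error(read_popmap(empty, gm), "empty popmap")
})

test_that("study-scale popmaps recover the per-population sample sizes", {
  sizes <- c(SR = 13, AR = 17, BS = 13, RU = 9, OS = 7, AT = 21, CT = 16,
             IC = 6, MI = 13)
  eco <- c(SR = "resident", AR = "resident", BS = "resident", RU = "resident",
           OS = "outgroup", AT = "transient", CT = "transient",
           IC = "outgroup", MI = "outgroup")
  pm <- population_map(sprintf("ind%03d", seq_len(sum(sizes))),
                       rep(names(sizes), sizes),
                       rep(unname(eco), sizes))
  expect_equal(sum(attr(pm, "pop_sizes")), 115)
  expect_equal(unname(attr(pm, "pop_sizes")[names(sizes)]), unname(sizes))
  expect_setequal(ecoscan:::pops_of_ecotype(pm, "resident"),
                  c("SR", "AR", "BS", "RU"))
})
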