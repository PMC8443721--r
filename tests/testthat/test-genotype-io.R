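write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1,length=100000>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B"), collapse = "\t"))

test_that("read_vcf imports biallelic SNPs and maps genotype codes", {
  p <- write_test_vcf(c(vcf_header,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\trs1\tC\tG\t.\tPASS\t.\tGT\t1|1\t./.",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./1\t0/0"))
  out <- read_vcf(p)
  g <- out$genotypes
  expect_equal(dim(g$calls), c(3L, 2L))
  expect_equal(g$sample_ids, c("A", "B"))
  expect_equal(unname(g$calls[1, ]), c(0L, 1L))
  expect_equal(unname(g$calls[2, ]), c(2L, NA))   # phased accepted, missing NA
  expect_equal(unname(g$calls[3, ]), c(NA, 0L))   # half-call becomes missing
  expect_equal(g$id[2], "rs1")
  expect_equal(attr(g, "chrom_lengths"), c(chr1 = 100000))
})

test_that("multiallelic and non-SNP records are dropped and counted", {
  p <- write_test_vcf(c(vcf_header,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tA\tA,T\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0"))
  out <- read_vcf(p)
  expect_equal(n_sites(out$genotypes), 1L)
  expect_equal(out$report$sites_in, 3L)
  expect_equal(unname(out$report$removed["multiallelic"]), 1L)
  expect_equal(unname(out$report$removed["non_snp"]), 1L)
  expect_equal(out$report$sites_out, 1L)
})

test_that("malformed VCF lines error with the line number", {
  p <- write_test_vcf(c(vcf_header,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/0"))
  expect_error(read_vcf(p), "line 6")
  p2 <- write_test_vcf(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT"), collapse = "\t")))
  expect_error(read_vcf(p2), "zero sample")
})

test_that("write_vcf / read_vcf round-trips the calls matrix", {
  g <- random_gm(80, 6, miss = 0.1, seed = 42)
  p <- tempfile(fileext = ".vcf")
  write_vcf(g, p)
  back <- read_vcf(p)$genotypes
  expect_identical(unname(back$calls), unname(g$calls))
  expect_identical(back$pos, g$pos)
  expect_identical(back$ref, g$ref)
  # field-by-field file identity ignoring the date line
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(back, p2)
  l1 <- grep("^##fileDate", readLines(p), value = TRUE, invert = TRUE)
  l2 <- grep("^##fileDate", readLines(p2), value = TRUE, invert = TRUE)
  expect_identical(l1, l2)
})

test_that("filter_sites applies strict MAF and missingness rules", {
  # site 1: alt freq 0.03 < = fails MAF; site 2: 25% missing fails missingness
  n <- 20
  calls <- rbind(c(rep(0L, 19), 1L),                    # freq 0.025
                 c(rep(NA, 5), rep(1L, 15)),            # 25% missing
                 rep(c(0L, 1L), 10))                    # freq 0.25, clean
  g <- make_gm(calls)
  out <- filter_sites(g, maf_min = 0.05, missing_max = 0.2)
  expect_equal(n_sites(out$genotypes), 1L)
  expect_equal(out$genotypes$pos, g$pos[3])
  expect_equal(unname(out$report$removed["maf"]), 1L)
  expect_equal(unname(out$report$removed["missingness"]), 1L)
})

test_that("filter_sites matches an independent per-site tally and is idempotent", {
  g <- random_gm(1000, 20, miss = 0.15, seed = 9)
  out <- filter_sites(g, 0.05, 0.2)
  # independent recount
  keep <- logical(n_sites(g))
  for (s in seq_len(n_sites(g))) {
    gt <- g$calls[s, ]
    nc <- sum(!is.na(gt))
    f <- sum(gt, na.rm = TRUE) / (2 * nc)
    keep[s] <- min(f, 1 - f) > 0.05 && (1 - nc / 20) < 0.2
  }
  expect_equal(out$genotypes$pos, g$pos[keep])
  # conservation and idempotence
  expect_equal(out$report$sites_in,
               out$report$sites_out + sum(out$report$removed))
  again <- filter_sites(out$genotypes, 0.05, 0.2)
  expect_identical(again$genotypes$calls, out$genotypes$calls)
  expect_equal(sum(again$report$removed), 0L)
})

test_that("all sites removed yields an empty matrix with a warning", {
  g <- make_gm(rbind(c(0L, 0L, 0L, 1L)))  # freq 0.125 > 0.05? no: 1/8 = 0.125
  expect_warning(out <- filter_sites(g, maf_min = 0.4, missing_max = 1),
                 "all sites removed")
  expect_equal(n_sites(out$genotypes), 0L)
})

test_that("batch_effect_filter reproduces the 2x2 chi-square", {
  # balanced alleles: 10 ref / 10 alt in each batch -> chi2 = 0, kept
  g1 <- make_gm(rbind(rep(1L, 20)))  # every sample het: 10/10 split per batch
  out1 <- batch_effect_filter(g1, rep(c("b1", "b2"), each = 10), alpha = 0.05)
  expect_equal(out1$p[1], 1)
  expect_equal(n_sites(out1$genotypes), 1L)
  # batch1 all ref-hom, batch2 all alt-hom: table [[10,0],[0,10]], chi2 = 20
  g2 <- make_gm(rbind(c(rep(0L, 5), rep(2L, 5))))
  out2 <- batch_effect_filter(g2, rep(c("b1", "b2"), each = 5), alpha = 0.01)
  chi2 <- 20 * (10 * 10 - 0)^2 / (10 * 10 * 10 * 10)
  expect_equal(chi2, 20)
  expect_equal(out2$p[1], pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(out2$p[1], 1e-5)
  expect_equal(n_sites(out2$genotypes), 0L)
  # agreement with stats::chisq.test without continuity correction
  g3 <- make_gm(rbind(c(0L, 1L, 2L, 1L, 0L, 0L, 1L, 2L)))
  b <- rep(c("b1", "b2"), 4)
  out3 <- batch_effect_filter(g3, b, alpha = 0.01)
  ref1 <- sum(2 - g3$calls[1, b == "b1"]); alt1 <- sum(g3$calls[1, b == "b1"])
  ref2 <- sum(2 - g3$calls[1, b == "b2"]); alt2 <- sum(g3$calls[1, b == "b2"])
  ct <- suppressWarnings(stats::chisq.test(matrix(c(ref1, alt1, ref2, alt2),
                                                  2, byrow = TRUE),
                                           correct = FALSE))
  expect_equal(out3$p[1], unname(ct$p.value), tolerance = 1e-12)
})

test_that("batch filter boundary behavior: alpha = 0 and empty batches", {
  g <- random_gm(50, 10, seed = 3)
  out <- batch_effect_filter(g, rep(c("b1", "b2"), 5), alpha = 0)
  expect_equal(n_sites(out$genotypes), 50L)
  # a site where batch 2 is entirely missing is kept, untested
  calls <- rbind(c(1L, 1L, NA, NA))
  g2 <- make_gm(calls)
  out2 <- batch_effect_filter(g2, c("b1", "b1", "b2", "b2"), alpha = 0.99)
  expect_true(is.na(out2$p[1]))
  expect_equal(n_sites(out2$genotypes), 1L)
})

test_that("batch_effect_filter type-I error is calibrated under the null", {
  g <- random_gm(20000, 40, seed = 77)
  out <- batch_effect_filter(g, rep(c("b1", "b2"), 20), alpha = 0.05)
  rate <- 1 - n_sites(out$genotypes) / 20000
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("ld_prune removes duplicated SNPs and keeps independent ones", {
  set.seed(4)
  base <- rbinom(30, 2, 0.5)
  calls <- rbind(base, base, rbinom(30, 2, 0.5))
  g <- make_gm(calls)
  pruned <- ld_prune(g, window_snps = 10, step = 5, r2_max = 0.2)
  expect_equal(n_sites(pruned), 2L)
  # mutually independent SNPs survive
  g2 <- random_gm(40, 200, seed = 5)
  pruned2 <- ld_prune(g2, window_snps = 20, step = 5, r2_max = 0.5)
  expect_equal(n_sites(pruned2), 40L)
})

test_that("ld_prune leaves no within-window pair above the threshold", {
  # blocky LD: 20 blocks of 10 correlated SNPs
  withr::with_seed(8, {
    blocks <- lapply(1:20, function(b) {
      anchor <- rbinom(60, 2, 0.5)
      t(sapply(1:10, function(i) {
        flip <- runif(60) < 0.05
        ifelse(flip, rbinom(60, 2, 0.5), anchor)
      }))
    })
    calls <- do.call(rbind, blocks)
  })
  g <- make_gm(calls)
  pruned <- ld_prune(g, window_snps = 100, step = 10, r2_max = 0.2)
  expect_lt(n_sites(pruned), n_sites(g))
  # exhaustive all-pairs verification within the window span
  d <- t(pruned$calls)
  r2 <- suppressWarnings(cor(d))^2
  diag(r2) <- 0
  for (i in seq_len(nrow(r2))) {
    jmax <- min(nrow(r2), i + 99)
    if (i + 1 <= jmax)
      expect_true(all(r2[i, (i + 1):jmax] <= 0.2 + 1e-12))
  }
})

test_that("prune_related_samples enforces the distance cutoff greedily", {
  # all pairs distant: everyone retained
  d1 <- matrix(0.5, 4, 4); diag(d1) <- 0
  dimnames(d1) <- list(letters[1:4], letters[1:4])
  expect_equal(prune_related_samples(d1, 0.06), letters[1:4])
  # identical pair: exactly one retained, the lexicographically smaller id
  d2 <- d1; d2["a", "b"] <- d2["b", "a"] <- 0
  kept <- prune_related_samples(d2, 0.06)
  expect_equal(sort(kept), c("a", "c", "d"))
  # clique below cutoff: post-condition holds
  set.seed(10)
  d3 <- matrix(runif(100, 0.2, 0.5), 10, 10)
  d3 <- (d3 + t(d3)) / 2; diag(d3) <- 0
  ids <- paste0("s", 1:10)
  dimnames(d3) <- list(ids, ids)
  d3[1:3, 1:3] <- 0.01; diag(d3) <- 0
  kept3 <- prune_related_samples(d3, 0.06)
  sub <- d3[kept3, kept3]
  expect_true(all(sub[upper.tri(sub)] >= 0.06))
  expect_equal(sum(c("s1", "s2", "s3") %in% kept3), 1L)
})
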