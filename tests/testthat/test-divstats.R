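test_that("theta-pi matches hand counts and the all-pairs oracle", {
  # one SNP, both samples het: 4 alleles, 2 ref + 2 alt -> pi = 4/6
  g <- make_gm(rbind(c(1L, 1L)), pos = 500L, chrom_lengths = c(chr1 = 100000))
  tr <- window_theta_pi(g, span = 100000)
  expect_equal(tr$value, (2 * 2 * 2 / (4 * 3)) / 1e5, tolerance = 1e-12)
  expect_equal(tr$value, 6.667e-6, tolerance = 1e-4)
  # monomorphic window
  g0 <- make_gm(rbind(c(0L, 0L)), pos = 500L, chrom_lengths = c(chr1 = 1000))
  expect_equal(window_theta_pi(g0, span = 1000)$value, 0)
  # oracle equivalence on random data with missingness
  g2 <- random_gm(120, 8, miss = 0.1, seed = 31,
                  chrom_lengths = c(chr1 = 50000))
  tr2 <- window_theta_pi(g2, span = 10000)
  or <- oracle_theta_pi(g2, 10000, c(chr1 = 50000))
  expect_equal(tr2$value, or$value, tolerance = 1e-10)
})

test_that("Watterson's theta follows the harmonic-sum formula", {
  # 3 segregating sites, 2 samples (k = 4), 100-kb window
  g <- make_gm(rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L)),
               pos = c(10L, 20L, 30L), chrom_lengths = c(chr1 = 100000))
  tr <- window_theta_w(g, span = 100000)
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_equal(tr$value, 3 / a1 / 1e5, tolerance = 1e-12)
  expect_equal(tr$value, 1.636e-5, tolerance = 1e-3)
  # S = 0
  g0 <- make_gm(rbind(c(2L, 2L)), pos = 10L, chrom_lengths = c(chr1 = 1000))
  expect_equal(window_theta_w(g0, span = 1000)$value, 0)
  # oracle equivalence with varying per-site k
  g2 <- random_gm(150, 10, miss = 0.15, seed = 32,
                  chrom_lengths = c(chr1 = 60000))
  tr2 <- window_theta_w(g2, span = 20000)
  or <- oracle_theta_w(g2, 20000, c(chr1 = 60000))
  expect_equal(tr2$value, or$value, tolerance = 1e-10)
})

test_that("Tajima's D reproduces the independent constant evaluation", {
  # k = 4 alleles, S = 3, summed pi = 2.0
  expect_equal(tajimas_d_from_counts(3, 2.0, 4), oracle_tajimas_d(3, 2.0, 4),
               tolerance = 1e-12)
  expect_equal(tajimas_d_from_counts(3, 2.0, 4), 2.01, tolerance = 1e-2)
  # numerator vanishes when pi_sum = S / a1
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_equal(tajimas_d_from_counts(3, 3 / a1, 4), 0, tolerance = 1e-12)
  # S = 0 is undefined, not zero
  expect_true(is.na(tajimas_d_from_counts(0, 0, 10)))
  g0 <- make_gm(rbind(c(2L, 2L, 2L)), pos = 10L, chrom_lengths = c(chr1 = 1000))
  expect_true(is.na(window_tajimas_d(g0, span = 1000)$value))
})

test_that("windowed Tajima's D agrees with the oracle and is near 0 under neutrality", {
  g <- random_gm(200, 10, seed = 33, chrom_lengths = c(chr1 = 100000))
  tr <- window_tajimas_d(g, span = 10000)
  for (w in seq_len(nrow(tr))) {
    sel <- g$pos >= tr$start[w] & g$pos <= tr$end[w]
    gt <- g$calls[sel, , drop = FALSE]
    seg <- apply(gt, 1, function(x) {
      alt <- sum(x, na.rm = TRUE); k <- 2 * sum(!is.na(x))
      alt > 0 && alt < k
    })
    S <- sum(seg)
    if (S == 0) { expect_true(is.na(tr$value[w])); next }
    pis <- apply(gt[seg, , drop = FALSE], 1, function(x) {
      k <- 2 * sum(!is.na(x)); alt <- sum(x, na.rm = TRUE)
      2 * alt * (k - alt) / (k * (k - 1))
    })
    expect_equal(tr$value[w], oracle_tajimas_d(S, sum(pis), 20),
                 tolerance = 1e-10)
  }
  # frequencies drawn from the 1/i neutral spectrum: mean D near 0
  withr::with_seed(34, {
    n <- 20; k <- 2 * n
    wts <- 1 / (1:(k - 1))
    vals <- replicate(200, {
      m <- 40
      cnt <- sample(1:(k - 1), m, replace = TRUE, prob = wts)
      calls <- t(sapply(cnt, function(cc) {
        slots <- sample(k, cc)
        tabulate((slots - 1) %/% 2 + 1, nbins = n) |> pmin(2)
      }))
      calls <- matrix(as.integer(calls), m, n)
      pis <- apply(calls, 1, function(x) {
        alt <- sum(x); 2 * alt * (k - alt) / (k * (k - 1))
      })
      tajimas_d_from_counts(m, sum(pis), k)
    })
  })
  expect_lt(abs(mean(vals)), 0.3)
})

test_that("Weir-Cockerham F_ST matches direct component evaluation", {
  # fixed difference: F_ST = 1
  g <- make_gm(cbind(matrix(0L, 1, 10), matrix(2L, 1, 10)),
               chrom_lengths = c(chr1 = 1000))
  pops <- rep(c("p1", "p2"), each = 10)
  expect_equal(window_fst(g, pops, span = 1000)$value, 1)
  # printed toy counts: pop1 6 hom-ref + 2 het, pop2 2 hom-ref + 6 het
  g2 <- make_gm(rbind(c(rep(0L, 6), rep(1L, 2), rep(0L, 2), rep(1L, 6))),
                chrom_lengths = c(chr1 = 1000))
  pops2 <- rep(c("p1", "p2"), each = 8)
  got <- site_fst(g2, pops2)
  or <- oracle_wc_site(list(g2$calls[1, 1:8], g2$calls[1, 9:16]))
  expect_equal(got$a, or$a, tolerance = 1e-12)
  expect_equal(got$b, or$b, tolerance = 1e-12)
  expect_equal(got$c, or$c, tolerance = 1e-12)
  expect_equal(got$fst, or$fst, tolerance = 1e-12)
  # single-site window: ratio-of-sums equals the per-site estimate
  expect_equal(window_fst(g2, pops2, span = 1000)$value, or$fst,
               tolerance = 1e-12)
})

test_that("F_ST is near zero for populations drawn from identical frequencies", {
  g <- random_gm(2000, 40, seed = 35, chrom_lengths = c(chr1 = 2000 * 1000))
  pops <- rep(c("p1", "p2"), 20)
  res <- global_fst(g, pops)
  expect_lt(abs(res$fst), 0.02)
})

test_that("windowed F_ST equals the oracle over multi-population data", {
  g <- random_gm(300, 18, miss = 0.1, seed = 36,
                 chrom_lengths = c(chr1 = 30000))
  pops <- rep(c("p1", "p2", "p3"), each = 6)
  comp <- site_fst(g, pops)
  for (s in sample(300, 40)) {
    or <- oracle_wc_site(split(g$calls[s, ], pops))
    if (is.na(comp$fst[s])) next
    expect_equal(comp$fst[s], or$fst, tolerance = 1e-10)
  }
})

test_that("outgroup polarization defines ancestral state and DAF", {
  # outgroup hom-ref; ingroup {0/1, 1/1, 0/0} -> DAF = 3/6
  g <- make_gm(rbind(c(1L, 2L, 0L, 0L),
                     c(2L, 2L, 2L, 2L),
                     c(1L, 1L, 0L, 1L)),
               chrom_lengths = c(chr1 = 1000))
  colnames(g$calls) <- g$sample_ids <- c("a", "b", "c", "OG1")
  res <- polarize_and_daf(g, "OG1", span = 1000)
  expect_equal(res$sites$daf[1], 0.5)          # ancestral = ref
  expect_equal(res$sites$daf[2], 0)            # outgroup alt-hom, ingroup fixed alt
  expect_false(res$sites$polarizable[3])       # het outgroup excluded
  expect_equal(res$track$n, 2L)
  expect_equal(res$track$value, mean(c(0.5, 0)))
})

test_that("DAF is zero when the ingroup is fixed for the outgroup allele", {
  g <- make_gm(rbind(c(0L, 0L, 0L, 0L), c(2L, 2L, 2L, 2L)),
               chrom_lengths = c(chr1 = 1000))
  colnames(g$calls) <- g$sample_ids <- c("a", "b", "c", "OG1")
  res <- polarize_and_daf(g, "OG1", span = 1000)
  expect_equal(res$sites$daf, c(0, 0))
})

test_that("top-quantile region calling uses order-statistic cutoffs with ties", {
  tr <- window_track("chr1", (0:99) * 1000 + 1, (1:100) * 1000,
                     as.numeric(1:100), rep(1L, 100))
  res <- top_quantile_regions(tr, 0.01)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 99 * 1000 + 1)
  expect_equal(attr(res, "cutoff"), 100)
  # all equal: ties at the cutoff all qualify
  tr2 <- window_track("chr1", (0:9) * 1000 + 1, (1:10) * 1000,
                      rep(5, 10), rep(1L, 10))
  res2 <- top_quantile_regions(tr2, 0.1)
  expect_equal(sum(res2$n_windows), 10L)
  # sort-and-slice oracle on random values
  set.seed(37)
  v <- rnorm(500)
  tr3 <- window_track("chr1", (0:499) * 1000 + 1, (1:500) * 1000, v,
                      rep(1L, 500))
  res3 <- top_quantile_regions(tr3, 0.05)
  # oracle: sort descending, keep the top ceil(f * n) plus ties at the cutoff
  cutoff <- sort(v, decreasing = TRUE)[ceiling(0.05 * 500)]
  qual_oracle <- which(v >= cutoff)
  got <- unlist(lapply(seq_len(nrow(res3)), function(i)
    which(tr3$start >= res3$start[i] & tr3$end <= res3$end[i])))
  expect_equal(sort(got), qual_oracle)
  # count property: |qualifying| ~ ceil(fraction * n) up to ties
  expect_gte(length(qual_oracle), ceiling(0.05 * 500))
})

test_that("gene-region overlap matches the quadratic oracle", {
  regions <- data.frame(chrom = "chr1", start = 6000, end = 7000)
  genes <- data.frame(chrom = "chr1", start = c(5000, 5000), end = c(6000, 5999),
                      gene_id = c("g1", "g2"))
  got <- genes_overlapping_regions(regions, genes, flank = 0)
  expect_equal(got[[1]], "g1")   # shared bp at 6000; g2 misses by 1 bp
  # random layout, both chroms
  set.seed(38)
  regions2 <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                         start = sample.int(100000, 40))
  regions2$end <- regions2$start + sample.int(5000, 40)
  genes2 <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                       start = sample.int(100000, 200))
  genes2$end <- genes2$start + sample.int(3000, 200)
  genes2$gene_id <- sprintf("g%03d", 1:200)
  got2 <- genes_overlapping_regions(regions2, genes2, flank = 250)
  or2 <- oracle_overlap(regions2, genes2, flank = 250)
  expect_equal(lapply(got2, sort), lapply(or2, sort))
})
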