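# windowed diversity / differentiation / derived-allele-frequency statistics

# per-site pairwise diversity: expected heterozygosity of a random allele
# pair drawn without replacement from the called alleles
site_pi <- function(g) {
  ac <- allele_counts(g)
  k <- ac$k
  pi <- rep(NA_real_, n_sites(g))
  ok <- k >= 2
  pi[ok] <- 2 * ac$c_ref[ok] * ac$c_alt[ok] / (k[ok] * (k[ok] - 1))
  list(pi = pi, k = k, segregating = ac$c_ref > 0 & ac$c_alt > 0 & ok)
}

window_stat_frame <- function(g, span, chrom_lengths) {
  cl <- infer_chrom_lengths(g, chrom_lengths)
  win <- tile_windows(cl, span)
  idx <- site_window_index(g$chrom, g$pos, win, span)
  list(win = win, idx = idx)
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per site, pairwise diversity is the probability that two called alleles
#' drawn without replacement differ. Window theta-pi is the sum of per-site
#' diversities divided by the window span in bp (fixed-span denominator, as
#' in the usual windowed-pi convention). Sites with fewer than two called
#' alleles are skipped.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param span window span in bp (default 100 kb).
#' @param chrom_lengths optional chromosome lengths for the tiling.
#' @return window track with \code{value} = theta-pi per bp and \code{n} =
#'   SNP sites used.
#' @export
window_theta_pi <- function(g, span = 100000, chrom_lengths = NULL) {
  ws <- window_stat_frame(g, span, chrom_lengths)
  sp <- site_pi(g)
  ok <- !is.na(ws$idx) & !is.na(sp$pi)
  sums <- tapply(sp$pi[ok], ws$idx[ok], sum)
  cnts <- tapply(sp$pi[ok], ws$idx[ok], length)
  value <- rep(0, nrow(ws$win))
  n <- rep(0L, nrow(ws$win))
  at <- as.integer(names(sums))
  spans <- ws$win$end - ws$win$start + 1
  value[at] <- sums / spans[at]
  n[at] <- cnts
  window_track(ws$win$chrom, ws$win$start, ws$win$end, value, n)
}

#' Windowed Watterson's theta
#'
#' theta-w = S / (a1 * span) with a1 the harmonic number over k - 1, where k
#' is the number of called alleles. Because k can vary across sites (missing
#' genotypes), each segregating site contributes 1/a1(k_site), so a window is
#' the sum of per-site Watterson contributions divided by the span.
#'
#' @inheritParams window_theta_pi
#' @return window track with \code{value} = theta-w per bp and \code{n} =
#'   segregating sites.
#' @export
window_theta_w <- function(g, span = 100000, chrom_lengths = NULL) {
  ws <- window_stat_frame(g, span, chrom_lengths)
  sp <- site_pi(g)
  seg <- sp$segregating & sp$k >= 2
  contrib <- ifelse(seg, 1 / harmonic_a1(sp$k), 0)
  ok <- !is.na(ws$idx) & seg
  sums <- tapply(contrib[ok], ws$idx[ok], sum)
  cnts <- tapply(contrib[ok], ws$idx[ok], length)
  value <- rep(0, nrow(ws$win))
  n <- rep(0L, nrow(ws$win))
  at <- as.integer(names(sums))
  spans <- ws$win$end - ws$win$start + 1
  value[at] <- sums / spans[at]
  n[at] <- cnts
  window_track(ws$win$chrom, ws$win$start, ws$win$end, value, n)
}

# a1 = sum_{i=1}^{k-1} 1/i, vectorized over allele counts k
harmonic_a1 <- function(k) {
  mx <- max(k, 2)
  cs <- cumsum(1 / seq_len(mx - 1))
  out <- rep(NA_real_, length(k))
  ok <- k >= 2
  out[ok] <- cs[k[ok] - 1]
  out
}

# Tajima (1989) normalization constants for k sampled alleles
tajima_constants <- function(k) {
  a1 <- sum(1 / seq_len(k - 1))
  a2 <- sum(1 / seq_len(k - 1)^2)
  b1 <- (k + 1) / (3 * (k - 1))
  b2 <- 2 * (k^2 + k + 3) / (9 * k * (k - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (k + 2) / (a1 * k) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) statistic per window: the difference between the
#' summed pairwise diversity and S/a1, normalized by the usual variance
#' estimate built from e1 and e2. The allele count k used for the constants
#' is the per-window mode of the number of called alleles; windows with no
#' segregating site or fewer than 4 called alleles are undefined (\code{NA}),
#' not zero.
#'
#' @inheritParams window_theta_pi
#' @return window track with \code{value} = Tajima's D and \code{n} =
#'   segregating sites.
#' @export
window_tajimas_d <- function(g, span = 100000, chrom_lengths = NULL) {
  ws <- window_stat_frame(g, span, chrom_lengths)
  sp <- site_pi(g)
  value <- rep(NA_real_, nrow(ws$win))
  n <- rep(0L, nrow(ws$win))
  for (w in unique(ws$idx[!is.na(ws$idx)])) {
    sel <- which(ws$idx == w & sp$segregating)
    S <- length(sel)
    n[w] <- S
    if (S < 1) next
    k <- as.integer(names(which.max(table(sp$k[sel]))))
    if (k < 4) next
    value[w] <- tajimas_d_from_counts(S, sum(sp$pi[sel]), k)
  }
  window_track(ws$win$chrom, ws$win$start, ws$win$end, value, n)
}

#' Tajima's D from summary counts
#'
#' @param S number of segregating sites.
#' @param pi_sum summed per-site pairwise diversity over the same sites.
#' @param k number of sampled alleles.
#' @return Tajima's D (\code{NA} when undefined).
#' @export
tajimas_d_from_counts <- function(S, pi_sum, k) {
  if (S < 1 || k < 4) return(NA_real_)
  ct <- tajima_constants(k)
  v <- ct$e1 * S + ct$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / ct$a1) / sqrt(v)
}

#' Per-site Weir-Cockerham F_ST variance components
#'
#' Computes the Weir & Cockerham (1984) a (among-population), b
#' (among-individual) and c (within-individual) components per site for two
#' or more populations, from called genotypes only. The per-site estimator is
#' a/(a+b+c).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param pop_labels vector of population labels, one per sample.
#' @return data frame with \code{chrom}, \code{pos}, \code{a}, \code{b},
#'   \code{c}, \code{fst} (\code{NA} where undefined).
#' @export
site_fst <- function(g, pop_labels) {
  pops <- as.factor(pop_labels)
  if (length(pops) != n_samples(g)) stop("one population label per sample required")
  r <- nlevels(pops)
  if (r < 2) stop("need at least two populations")
  cl <- g$calls
  ni <- pi_ <- hi <- matrix(0, n_sites(g), r)
  for (j in seq_len(r)) {
    sub <- cl[, pops == levels(pops)[j], drop = FALSE]
    ni[, j] <- rowSums(!is.na(sub))
    alt <- rowSums(sub, na.rm = TRUE)
    pi_[, j] <- ifelse(ni[, j] > 0, alt / (2 * ni[, j]), NA)
    hi[, j] <- ifelse(ni[, j] > 0, rowSums(sub == 1L, na.rm = TRUE) / ni[, j], NA)
  }
  use <- rowSums(ni > 0) == r & rowSums(ni) > r  # every pop called, nbar > 1
  nbar <- rowSums(ni) / r
  nc <- (r * nbar - rowSums(ni^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(ni * pi_) / (r * nbar)
  s2 <- rowSums(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  ok <- use & poly & (a + b + cc) != 0
  a[!use | !poly] <- NA; b[!use | !poly] <- NA; cc[!use | !poly] <- NA
  fst <- ifelse(ok, a / (a + b + cc), NA_real_)
  data.frame(chrom = g$chrom, pos = g$pos, a = a, b = b, c = cc, fst = fst)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Ratio-of-sums (weighted) Weir-Cockerham estimator per window:
#' sum(a) / sum(a + b + c) over usable polymorphic sites. Windows without a
#' polymorphic site are undefined.
#'
#' @inheritParams window_theta_pi
#' @param pop_labels population label per sample.
#' @return window track with \code{value} = F_ST and \code{n} = sites used.
#' @export
window_fst <- function(g, pop_labels, span = 100000, chrom_lengths = NULL) {
  ws <- window_stat_frame(g, span, chrom_lengths)
  comp <- site_fst(g, pop_labels)
  ok <- !is.na(ws$idx) & !is.na(comp$a) & !is.na(comp$fst)
  A <- tapply(comp$a[ok], ws$idx[ok], sum)
  Tt <- tapply((comp$a + comp$b + comp$c)[ok], ws$idx[ok], sum)
  cnt <- tapply(comp$a[ok], ws$idx[ok], length)
  value <- rep(NA_real_, nrow(ws$win))
  n <- rep(0L, nrow(ws$win))
  at <- as.integer(names(A))
  value[at] <- A / Tt
  n[at] <- cnt
  window_track(ws$win$chrom, ws$win$start, ws$win$end, value, n)
}

#' Genome-wide Weir-Cockerham F_ST (ratio of sums)
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param pop_labels population label per sample.
#' @return list with \code{fst} (ratio-of-sums over all usable sites),
#'   \code{fst_sitemean} (mean of per-site estimates) and \code{n_sites}.
#' @export
global_fst <- function(g, pop_labels) {
  comp <- site_fst(g, pop_labels)
  ok <- !is.na(comp$fst)
  list(fst = sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok]),
       fst_sitemean = mean(comp$fst[ok]),
       n_sites = sum(ok))
}

#' Outgroup polarization and windowed derived allele frequency
#'
#' A site is polarizable iff the outgroup sample carries a called homozygous
#' genotype there; that allele is taken as ancestral and the derived allele
#' frequency (DAF) is the frequency of the other allele among called ingroup
#' alleles. Heterozygous or missing outgroup genotypes exclude the site.
#' Window DAF is the unweighted mean over polarizable sites.
#'
#' @param g a \code{\link{genotype_matrix}} including the outgroup sample.
#' @param outgroup_sample sample id of the outgroup.
#' @param span window span in bp (default 100 kb).
#' @param chrom_lengths optional chromosome lengths.
#' @return list with \code{sites} (data frame: chrom, pos, polarizable, daf)
#'   and \code{track} (window track of mean DAF; \code{n} = polarizable
#'   sites).
#' @export
polarize_and_daf <- function(g, outgroup_sample, span = 100000,
                             chrom_lengths = NULL) {
  oi <- match(outgroup_sample, g$sample_ids)
  if (is.na(oi)) stop("outgroup sample not found: ", outgroup_sample)
  og <- g$calls[, oi]
  ing <- g$calls[, -oi, drop = FALSE]
  n_called <- rowSums(!is.na(ing))
  alt <- rowSums(ing, na.rm = TRUE)
  polarizable <- !is.na(og) & og != 1L & n_called > 0
  daf <- rep(NA_real_, n_sites(g))
  anc_ref <- polarizable & og == 0L
  anc_alt <- polarizable & og == 2L
  daf[anc_ref] <- alt[anc_ref] / (2 * n_called[anc_ref])
  daf[anc_alt] <- 1 - alt[anc_alt] / (2 * n_called[anc_alt])
  ws <- window_stat_frame(g, span, chrom_lengths)
  ok <- !is.na(ws$idx) & polarizable
  sums <- tapply(daf[ok], ws$idx[ok], sum)
  cnts <- tapply(daf[ok], ws$idx[ok], length)
  value <- rep(NA_real_, nrow(ws$win))
  n <- rep(0L, nrow(ws$win))
  at <- as.integer(names(sums))
  value[at] <- sums / cnts
  n[at] <- cnts
  list(sites = data.frame(chrom = g$chrom, pos = g$pos,
                          polarizable = polarizable, daf = daf),
       track = window_track(ws$win$chrom, ws$win$start, ws$win$end, value, n))
}

#' Call top-quantile regions from any window track
#'
#' The cutoff is the empirical (1 - upper_fraction) order-statistic quantile
#' over defined windows (no interpolation); windows at or above the cutoff
#' qualify (ties included) and adjacent qualifying windows are merged into
#' regions.
#'
#' @param track a window track data frame.
#' @param upper_fraction fraction of windows to call, in (0, 1).
#' @return data frame of regions (\code{chrom}, \code{start}, \code{end},
#'   \code{n_windows}, \code{max_value}) with attributes \code{cutoff} and
#'   \code{upper_fraction}.
#' @export
top_quantile_regions <- function(track, upper_fraction = 0.01) {
  stopifnot(upper_fraction > 0, upper_fraction < 1)
  v <- track$value
  vv <- v[!is.na(v)]
  k <- ceiling(upper_fraction * length(vv))
  cutoff <- sort(vv, decreasing = TRUE)[k]
  qual <- !is.na(v) & v >= cutoff
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    q <- qual[track$chrom == ch][order(track$start[track$chrom == ch])]
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i1 <- starts[j]; i2 <- ends[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = tr$start[i1], end = tr$end[i2],
        n_windows = i2 - i1 + 1L, max_value = max(tr$value[i1:i2], na.rm = TRUE))
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), max_value = numeric())
  attr(res, "cutoff") <- cutoff
  attr(res, "upper_fraction") <- upper_fraction
  res
}

#' Genes overlapping regions
#'
#' Reports, for every region, the gene intervals intersecting it after
#' symmetric expansion of the gene by \code{flank} bp. Intersection is on
#' closed 1-based intervals.
#'
#' @param regions data frame with \code{chrom}, \code{start}, \code{end}.
#' @param genes data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @param flank bp added on both sides of each gene before testing overlap.
#' @return list (one element per region row) of overlapping gene ids.
#' @export
genes_overlapping_regions <- function(regions, genes, flank = 0) {
  if (!nrow(regions) || !nrow(genes))
    return(rep(list(character(0)), nrow(regions)))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start, regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1, genes$start - flank),
                                                  genes$end + flank))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  out <- rep(list(character(0)), nrow(regions))
  if (length(hits)) {
    sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) out[[as.integer(q)]] <- unname(sp[[q]])
  }
  out
}
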