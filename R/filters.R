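#' Site filter report
#'
#' Book-keeping for site QC: every removed site is attributed to exactly one
#' rule, so \code{sites_in = sites_out + sum(removed)} always holds.
#'
#' @param sites_in number of sites before filtering.
#' @param removed named integer vector of per-rule removal counts.
#' @param samples_in,samples_out sample counts, when a step touches samples.
#' @return object of class \code{filter_report}.
#' @export
filter_report <- function(sites_in, removed = integer(0),
                          samples_in = NA_integer_, samples_out = NA_integer_) {
  structure(list(sites_in = as.integer(sites_in),
                 removed = removed,
                 sites_out = as.integer(sites_in - sum(removed)),
                 samples_in = samples_in, samples_out = samples_out),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", x$sites_in, " sites in, ", x$sites_out, " out\n", sep = "")
  if (length(x$removed))
    for (r in names(x$removed))
      cat("  removed by ", r, ": ", x$removed[[r]], "\n", sep = "")
  if (!is.na(x$samples_in))
    cat("  samples: ", x$samples_in, " in, ", x$samples_out, " out\n", sep = "")
  invisible(x)
}

#' Filter sites on minor allele frequency and missingness
#'
#' A site is kept iff its minor-allele frequency (over called alleles) is
#' strictly greater than \code{maf_min} and its missing-genotype fraction is
#' strictly below \code{missing_max}. Sites failing both rules are counted
#' under missingness.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param maf_min minor-allele frequency threshold in [0, 0.5).
#' @param missing_max maximum tolerated missing fraction in [0, 1].
#' @return list with \code{genotypes} (filtered matrix) and \code{report}.
#' @export
filter_sites <- function(g, maf_min = 0.05, missing_max = 0.2) {
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max >= 0, missing_max <= 1)
  ac <- allele_counts(g)
  miss_frac <- 1 - ac$n_called / n_samples(g)
  f <- ifelse(ac$k > 0, ac$c_alt / ac$k, 0)
  maf <- pmin(f, 1 - f)
  fail_miss <- !(miss_frac < missing_max)
  fail_maf <- !(maf > maf_min) & !fail_miss
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) warning("all sites removed by filters")
  list(genotypes = subset_genotypes(g, sites = keep),
       report = filter_report(n_sites(g),
                              c(missingness = sum(fail_miss),
                                maf = sum(fail_maf))))
}

#' Remove sites showing a sequencing batch effect
#'
#' Per site, allele counts (2 x hom + het) are cross-tabulated against two
#' batch labels and tested with a 1-df Pearson chi-square (no continuity
#' correction). Sites with p below \code{alpha} are removed. A site where one
#' batch has zero called alleles cannot be tested and is kept.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param batches vector of batch labels, one per sample (exactly 2 levels).
#' @param alpha removal threshold on the chi-square p-value.
#' @return list with \code{genotypes}, \code{report}, and \code{p} (per-site
#'   p-values, \code{NA} where untestable).
#' @export
batch_effect_filter <- function(g, batches, alpha = 0.01) {
  batches <- as.factor(batches)
  if (nlevels(batches) != 2) stop("exactly two batch labels are required")
  if (length(batches) != n_samples(g)) stop("one batch label per sample required")
  cl <- g$calls
  b1 <- batches == levels(batches)[1]
  alt1 <- rowSums(cl[, b1, drop = FALSE], na.rm = TRUE)
  n1 <- 2 * rowSums(!is.na(cl[, b1, drop = FALSE]))
  alt2 <- rowSums(cl[, !b1, drop = FALSE], na.rm = TRUE)
  n2 <- 2 * rowSums(!is.na(cl[, !b1, drop = FALSE]))
  # 2x2 table per site: rows = batch, cols = ref/alt allele counts
  a <- n1 - alt1; b <- alt1; c <- n2 - alt2; d <- alt2
  N <- n1 + n2
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  testable <- n1 > 0 & n2 > 0 & denom > 0
  chi2 <- rep(NA_real_, n_sites(g))
  chi2[testable] <- (N * (a * d - b * c)^2 / denom)[testable]
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  remove <- !is.na(p) & p < alpha
  list(genotypes = subset_genotypes(g, sites = !remove),
       report = filter_report(n_sites(g), c(batch_effect = sum(remove))),
       p = p)
}

#' LD pruning on genotype-dosage correlation
#'
#' Within sliding windows of \code{window_snps} SNPs advanced by \code{step}
#' SNPs (per chromosome), pairs with squared dosage correlation above
#' \code{r2_max} are resolved by greedily removing the SNP involved in the
#' most offending pairs (ties broken toward the later position). The scan is
#' repeated until no window contains an offending pair. Genotypes are treated
#' as unphased; r^2 is the composite (dosage) correlation.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param window_snps window size in SNPs.
#' @param step step size in SNPs.
#' @param r2_max maximum tolerated pairwise r^2.
#' @return the pruned \code{genotype_matrix}.
#' @export
ld_prune <- function(g, window_snps = 100, step = 10, r2_max = 0.2) {
  stopifnot(window_snps >= step, step >= 1)
  d <- dosage(g)
  keep <- rep(TRUE, n_sites(g))
  chroms <- unique(g$chrom)
  repeat {
    changed <- FALSE
    for (ch in chroms) {
      repeat {
        idx <- which(keep & g$chrom == ch)
        if (length(idx) < 2) break
        removed_this_pass <- FALSE
        starts <- seq.int(1L, max(1L, length(idx) - 1L), by = step)
        for (s in starts) {
          w <- idx[s:min(s + window_snps - 1L, length(idx))]
          w <- w[keep[w]]
          if (length(w) < 2) next
          drop <- prune_window(d[w, , drop = FALSE], r2_max)
          if (length(drop)) {
            keep[w[drop]] <- FALSE
            removed_this_pass <- TRUE
            changed <- TRUE
          }
        }
        if (!removed_this_pass) break
      }
    }
    if (!changed) break
  }
  subset_genotypes(g, sites = keep)
}

# greedy within-window pruning; returns local indices to drop
prune_window <- function(dw, r2_max) {
  r2 <- suppressWarnings(cor(t(dw), use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 0
  drop <- integer(0)
  repeat {
    offend <- r2 > r2_max
    cnt <- rowSums(offend)
    if (!any(cnt > 0)) break
    worst <- which(cnt == max(cnt))
    victim <- worst[length(worst)]  # later position on ties
    drop <- c(drop, victim)
    r2[victim, ] <- 0
    r2[, victim] <- 0
  }
  drop
}

#' Greedy pruning of closely related samples
#'
#' While any retained pair of samples is closer than \code{cutoff}, the
#' closest pair is located and the member with more sub-cutoff neighbours is
#' dropped (ties broken toward the lexicographically larger sample id). The
#' returned set has all pairwise distances at or above \code{cutoff}.
#'
#' @param d a symmetric distance matrix with zero diagonal and sample ids as
#'   dimnames (e.g. from \code{\link{ibs_distance}}).
#' @param cutoff minimum tolerated pairwise distance.
#' @return character vector of retained sample ids.
#' @export
prune_related_samples <- function(d, cutoff = 0.06) {
  m <- as.matrix(d)
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  stopifnot(nrow(m) == ncol(m))
  keep <- rep(TRUE, nrow(m))
  repeat {
    mm <- m[keep, keep, drop = FALSE]
    diag(mm) <- Inf
    if (min(mm) >= cutoff) break
    cur <- which(keep)
    w <- which(mm == min(mm), arr.ind = TRUE)[1, ]
    pair <- cur[as.integer(w)]
    nbr <- rowSums(mm < cutoff)
    n1 <- nbr[w[1]]; n2 <- nbr[w[2]]
    victim <- if (n1 > n2) pair[1]
      else if (n2 > n1) pair[2]
      else pair[order(ids[pair], decreasing = TRUE)[1]]
    keep[victim] <- FALSE
  }
  ids[keep]
}
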