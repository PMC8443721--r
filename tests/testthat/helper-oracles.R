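# brute-force / closed-form oracles, written independently of the package
# implementations they check

# theta-pi per window by explicit all-pairs allele comparison
oracle_theta_pi <- function(g, span, chrom_lengths) {
  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = span)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + span - 1, chrom_lengths[[ch]]))
  }))
  vals <- numeric(nrow(win))
  for (w in seq_len(nrow(win))) {
    sel <- which(g$chrom == win$chrom[w] & g$pos >= win$start[w] &
                   g$pos <= win$end[w])
    tot <- 0
    for (s in sel) {
      gt <- g$calls[s, ]
      alleles <- unlist(lapply(gt[!is.na(gt)],
                               function(x) switch(x + 1, c(0, 0), c(0, 1), c(1, 1))))
      k <- length(alleles)
      if (k < 2) next
      diffs <- 0
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        diffs <- diffs + (alleles[i] != alleles[j])
      tot <- tot + diffs / choose(k, 2)
    }
    vals[w] <- tot / (win$end[w] - win$start[w] + 1)
  }
  cbind(win, value = vals)
}

# Watterson's theta per window from the harmonic-sum formula, per-site k
oracle_theta_w <- function(g, span, chrom_lengths) {
  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = span)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + span - 1, chrom_lengths[[ch]]))
  }))
  vals <- numeric(nrow(win))
  for (w in seq_len(nrow(win))) {
    sel <- which(g$chrom == win$chrom[w] & g$pos >= win$start[w] &
                   g$pos <= win$end[w])
    tot <- 0
    for (s in sel) {
      gt <- g$calls[s, ]
      k <- 2 * sum(!is.na(gt))
      alt <- sum(gt, na.rm = TRUE)
      if (k >= 2 && alt > 0 && alt < k)
        tot <- tot + 1 / sum(1 / seq_len(k - 1))
    }
    vals[w] <- tot / (win$end[w] - win$start[w] + 1)
  }
  cbind(win, value = vals)
}

# Tajima's D from S, summed pi and k, constants evaluated from scratch
oracle_tajimas_d <- function(S, pi_sum, k) {
  a1 <- sum(1 / (1:(k - 1)))
  a2 <- sum(1 / (1:(k - 1))^2)
  b1 <- (k + 1) / (3 * (k - 1))
  b2 <- 2 * (k * k + k + 3) / (9 * k * (k - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (k + 2) / (a1 * k) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site Weir & Cockerham (1984) a, b, c by scalar loops
oracle_wc_site <- function(gt_by_pop) {
  r <- length(gt_by_pop)
  ni <- pi <- hi <- numeric(r)
  for (j in seq_len(r)) {
    gt <- gt_by_pop[[j]]
    gt <- gt[!is.na(gt)]
    ni[j] <- length(gt)
    pi[j] <- if (ni[j] > 0) sum(gt) / (2 * ni[j]) else NA
    hi[j] <- if (ni[j] > 0) mean(gt == 1) else NA
  }
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, fst = a / (a + b + c))
}

# IBS distance by per-pair per-site shared-allele tally
oracle_ibs <- function(g, normalize = TRUE) {
  shared <- function(x, y) {
    if (is.na(x) || is.na(y)) return(NA)
    if (x == y) return(2)
    if (x == 1 || y == 1) return(1)
    0
  }
  n <- ncol(g$calls)
  D <- matrix(0, n, n, dimnames = list(g$sample_ids, g$sample_ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- 0
    for (s in seq_len(nrow(g$calls))) {
      sh <- shared(g$calls[s, i], g$calls[s, j])
      if (!is.na(sh)) tot <- tot + (2 - sh)   # missing: contributes zero
    }
    D[i, j] <- if (normalize) tot / (2 * nrow(g$calls)) else tot
  }
  D
}

# transitive closure of the <= gap relation via union-find
oracle_merge <- function(chrom, pos, gap) {
  n <- length(pos)
  parent <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || chrom[i] != chrom[j]) next
      if (abs(pos[i] - pos[j]) <= gap) {
        ri <- find2(parent, i); rj <- find2(parent, j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); changed <- TRUE }
      }
    }
    if (!changed) break
  }
  root <- vapply(seq_len(n), function(i) find2(parent, i), integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(ix) {
    data.frame(chrom = chrom[ix[1]], start = min(pos[ix]), end = max(pos[ix]),
               n_snps = length(ix))
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

find2 <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }

# exact hypergeometric upper tail by enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# quadratic closed-interval overlap scan
oracle_overlap <- function(regions, genes, flank = 0) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] != genes$chrom[j]) next
      gs <- genes$start[j] - flank
      ge <- genes$end[j] + flank
      if (gs <= regions$end[i] && ge >= regions$start[i])
        hits <- c(hits, genes$gene_id[j])
    }
    out[[i]] <- hits
  }
  out
}

# exact Mantel permutation distribution over all relabelings
oracle_mantel_exact <- function(x, y) {
  ut <- upper.tri(x)
  perms <- as.matrix(expand.grid(rep(list(1:nrow(x)), nrow(x))))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  r_obs <- cor(x[ut], y[ut])
  r_all <- apply(perms, 1, function(p) cor(x[p, p][ut], y[ut]))
  list(r = r_obs, p_exact = mean(r_all >= r_obs))
}
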