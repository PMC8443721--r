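# in-code fixtures shared across test files

# quick genotype matrix from a calls matrix (sites x samples)
make_gm <- function(calls, chrom = NULL, pos = NULL, chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  m <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  genotype_matrix(chrom, pos, rep("A", m), rep("T", m), calls,
                  sample_ids = colnames(calls) %||%
                    sprintf("S%02d", seq_len(ncol(calls))),
                  chrom_lengths = chrom_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal track constructor, convenient for hand-built tracks in tests
window_track <- clonalscape:::window_track

# random biallelic genotypes with HWE sites and optional missingness
random_gm <- function(n_sites, n_samples, miss = 0, seed = 1,
                      chrom_lengths = c(chr1 = n_sites * 1000)) {
  withr::with_seed(seed, {
    p <- runif(n_sites, 0.05, 0.95)
    calls <- matrix(rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
                    n_sites, n_samples)
    if (miss > 0) calls[runif(length(calls)) < miss] <- NA
    pos <- sort(sample.int(chrom_lengths[[1]], n_sites))
    make_gm(calls, pos = pos, chrom_lengths = chrom_lengths)
  })
}

# small config without planted regions, for fast simulator runs
fast_config <- function(...) {
  args <- utils::modifyList(
    list(chrom_lengths = c(chr1 = 4e6),
         planted_high_lchr = NULL, planted_low_lchr = NULL,
         n_samples = 30, n_groups = 2, n_causal = 0),
    list(...))
  do.call(sim_config, args)
}

# jaccard overlap between two interval sets on the same chromosome set
interval_jaccard <- function(a, b) {
  cover <- function(df, chroms) {
    out <- list()
    for (ch in chroms) {
      d <- df[df$chrom == ch, , drop = FALSE]
      out[[ch]] <- if (nrow(d)) unlist(mapply(seq, d$start, d$end,
                                              SIMPLIFY = FALSE)) else integer(0)
    }
    out
  }
  chroms <- union(unique(a$chrom), unique(b$chrom))
  # compare at kb resolution to keep the sets small
  ak <- cover(transform(a, start = ceiling(start / 1000), end = end %/% 1000),
              chroms)
  bk <- cover(transform(b, start = ceiling(start / 1000), end = end %/% 1000),
              chroms)
  inter <- sum(mapply(function(x, y) length(intersect(x, y)), ak, bk))
  uni <- sum(mapply(function(x, y) length(union(x, y)), ak, bk))
  if (uni == 0) return(NA_real_)
  inter / uni
}
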