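#' Site-level heterozygous genotype frequency
#'
#' For each SNP site, the number of heterozygous genotypes divided by the
#' number of called genotypes. Sites with no called genotype get \code{NA}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return data frame with columns \code{chrom}, \code{pos}, \code{n_het},
#'   \code{n_called}, \code{h}.
#' @export
site_het_frequency <- function(g) {
  cl <- g$calls
  n_het <- rowSums(cl == 1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(cl))
  h <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  data.frame(chrom = g$chrom, pos = g$pos, n_het = n_het,
             n_called = n_called, h = h)
}

#' Classify sites into heterozygosity frequency classes
#'
#' A site is \code{low} when at most \code{low_max} of called individuals are
#' heterozygous (the somatic-mutation regime), \code{high} when at least
#' \code{high_min} are (the clonally fixed founder regime), otherwise
#' \code{intermediate}. Both boundaries are inclusive.
#'
#' @param h numeric vector of site heterozygous-genotype frequencies (or the
#'   data frame from \code{\link{site_het_frequency}}).
#' @param low_max inclusive upper bound of the low class.
#' @param high_min inclusive lower bound of the high class.
#' @return factor with levels \code{low}, \code{intermediate}, \code{high}
#'   (\code{NA} where \code{h} is undefined).
#' @export
classify_het_class <- function(h, low_max = 0.10, high_min = 0.90) {
  if (is.data.frame(h)) h <- h$h
  stopifnot(low_max < high_min)
  out <- rep(NA_character_, length(h))
  out[!is.na(h) & h <= low_max] <- "low"
  out[!is.na(h) & h >= high_min] <- "high"
  out[!is.na(h) & h > low_max & h < high_min] <- "intermediate"
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Window-level heterozygous genotype frequency
#'
#' Tiles each chromosome with non-overlapping windows from position 1 and
#' averages the site-level heterozygous-genotype frequency over the SNP sites
#' in each window (unweighted). Windows without SNP sites carry \code{NA} and
#' are excluded from downstream mean/SD computations. The trailing partial
#' window is kept with its true span.
#'
#' @param stats output of \code{\link{site_het_frequency}}.
#' @param span window span in bp (default 200 kb).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last SNP position per chromosome.
#' @return a window track data frame: \code{chrom}, \code{start}, \code{end}
#'   (1-based closed), \code{value} (mean site h), \code{n} (SNP sites).
#' @export
window_het_frequency <- function(stats, span = 200000, chrom_lengths = NULL) {
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(stats$pos, stats$chrom, max)[unique(stats$chrom)]
  win <- tile_windows(unlist(chrom_lengths), span)
  idx <- site_window_index(stats$chrom, stats$pos, win, span)
  ok <- !is.na(idx) & !is.na(stats$h)
  sums <- tapply(stats$h[ok], idx[ok], sum)
  cnts <- tapply(stats$h[ok], idx[ok], length)
  value <- rep(NA_real_, nrow(win))
  n <- rep(0L, nrow(win))
  at <- as.integer(names(sums))
  value[at] <- sums / cnts
  n[at] <- cnts
  window_track(win$chrom, win$start, win$end, value, n)
}

#' Heterozygosity landscape thresholds (mean +/- one SD)
#'
#' Computes the mean and (n-1) standard deviation of a window-level
#' heterozygous-genotype frequency track over defined windows, and returns
#' one-SD-above and one-SD-below thresholds used to call high- and
#' low-heterozygosity regions.
#'
#' @param track a window track from \code{\link{window_het_frequency}}.
#' @return list with \code{mean}, \code{sd}, \code{t_high = mean + sd},
#'   \code{t_low = mean - sd}.
#' @export
het_thresholds <- function(track) {
  v <- track$value[!is.na(track$value)]
  if (length(v) < 2) stop("need at least two defined windows")
  m <- mean(v)
  s <- sd(v)
  list(mean = m, sd = s, t_high = m + s, t_low = m - s)
}

#' Detect long continuous heterozygous regions (LCHRs)
#'
#' Scans a window-level heterozygosity track for maximal runs of consecutive
#' defined windows whose value stays strictly above \code{t_high} (class
#' \code{high}) or strictly below \code{t_low} (class \code{low}). A run's
#' length is the summed span of its member windows; runs strictly longer than
#' \code{min_run_bp} are reported. An undefined (SNP-free) window breaks a
#' run.
#'
#' @param track window track (see \code{\link{window_het_frequency}}).
#' @param t_high,t_low thresholds, typically from \code{\link{het_thresholds}}.
#' @param min_run_bp minimum run length in bp (strict; default 5 Mb).
#' @return data frame of intervals: \code{chrom}, \code{start}, \code{end}
#'   (1-based closed), \code{class}, \code{length_bp}, \code{n_windows}.
#' @export
detect_lchr <- function(track, t_high, t_low, min_run_bp = 5e6) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    state <- rep("none", nrow(tr))
    state[!is.na(tr$value) & tr$value > t_high] <- "high"
    state[!is.na(tr$value) & tr$value < t_low] <- "low"
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values %in% c("high", "low"))) {
      i1 <- starts[j]; i2 <- ends[j]
      len <- sum(tr$end[i1:i2] - tr$start[i1:i2] + 1)
      if (len > min_run_bp)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = tr$start[i1], end = tr$end[i2],
          class = r$values[j], length_bp = len, n_windows = i2 - i1 + 1L)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      class = character(), length_bp = numeric(),
                      n_windows = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Per-individual heterozygosity statistics
#'
#' Among each sample's variant loci (sites where the sample carries at least
#' one alternate allele), the fraction that are heterozygous and the ratio of
#' heterozygous to homozygous-alternate calls. The ratio is \code{Inf} for a
#' sample without homozygous-alternate calls; both are \code{NA} for a sample
#' without variant loci.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return data frame with \code{sample_id}, \code{n_het}, \code{n_hom_alt},
#'   \code{het_fraction}, \code{het_hom_ratio}.
#' @export
individual_het_stats <- function(g) {
  cl <- g$calls
  n_het <- colSums(cl == 1L, na.rm = TRUE)
  n_hom <- colSums(cl == 2L, na.rm = TRUE)
  tot <- n_het + n_hom
  frac <- ifelse(tot > 0, n_het / tot, NA_real_)
  ratio <- ifelse(tot > 0, n_het / n_hom, NA_real_)
  data.frame(sample_id = g$sample_ids, n_het = n_het, n_hom_alt = n_hom,
             het_fraction = frac, het_hom_ratio = ratio, row.names = NULL)
}
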