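# shared internal helpers

# tile [1, len] into non-overlapping windows of `span` bp; the trailing
# partial window keeps its true (shorter) span
tile_windows <- function(chrom_lengths, span) {
  stopifnot(span >= 1, all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = span)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + span - 1, len))
  })
  do.call(rbind, out)
}

# empirical order-statistic quantile (no interpolation), matching the
# documented tie rule: the cutoff itself qualifies
quantile_type1 <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 1, names = FALSE, na.rm = TRUE))
}

# assign sites to windows of a `span`-bp tiling; returns the row index into
# `win` per site, NA for sites outside the tiling
site_window_index <- function(chrom, pos, win, span) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    si <- which(chrom == ch)
    if (!length(si)) next
    j <- (pos[si] - 1) %/% span + 1
    j[j < 1 | j > length(wi)] <- NA
    idx[si] <- wi[j]
  }
  idx
}

# chromosome lengths for a genotype matrix: stored attribute, else max pos
infer_chrom_lengths <- function(g, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(unlist(chrom_lengths))
  cl <- attr(g, "chrom_lengths")
  if (!is.null(cl)) return(unlist(cl))
  tapply(g$pos, g$chrom, max)[unique(g$chrom)]
}

# new-style window track container
window_track <- function(chrom, start, end, value, n) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       value = value, n = n),
            class = c("window_track", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
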