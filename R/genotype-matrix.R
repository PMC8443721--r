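#' Biallelic SNP genotype matrix
#'
#' Container for multi-sample biallelic SNP calls. Genotypes are coded per
#' site (rows) and sample (columns) as 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, and \code{NA} = missing.
#' Positions are 1-based and strictly increasing within each chromosome.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character alleles per site.
#' @param calls integer matrix, sites x samples, values in \{0, 1, 2, NA\}.
#' @param sample_ids unique sample identifiers (column names of \code{calls}).
#' @param id optional site identifiers; defaults to \code{chrom_pos}.
#' @param chrom_lengths optional named vector of chromosome lengths in bp,
#'   carried along for window tiling and VCF contig headers.
#'
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{id},
#'   \code{calls}, \code{sample_ids} and attribute \code{chrom_lengths}.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, calls, sample_ids = colnames(calls),
                            id = NULL, chrom_lengths = NULL) {
  n <- length(pos)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(calls) == n)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(calls)))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (ncol(calls) != length(sample_ids)) stop("calls/sample_ids dimension mismatch")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  colnames(calls) <- sample_ids
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         id = as.character(id), calls = calls,
         sample_ids = as.character(sample_ids)),
    chrom_lengths = chrom_lengths,
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_sites(x), "biallelic SNP sites x",
      n_samples(x), "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of SNP sites / samples
#' @param g a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_sites <- function(g) length(g$pos)

#' @rdname n_sites
#' @export
n_samples <- function(g) ncol(g$calls)

#' Alternate-allele dosage matrix
#'
#' @param g a \code{genotype_matrix}.
#' @return numeric matrix (sites x samples) of alt-allele dosages 0/1/2 with
#'   \code{NA} for missing calls.
#' @export
dosage <- function(g) {
  d <- g$calls
  storage.mode(d) <- "double"
  d
}

#' Subset a genotype matrix by site and/or sample
#'
#' @param g a \code{genotype_matrix}.
#' @param sites logical or integer index over sites.
#' @param samples logical, integer or character index over samples.
#' @return a \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(g))
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  if (is.character(samples)) samples <- match(samples, g$sample_ids)
  genotype_matrix(g$chrom[sites], g$pos[sites], g$ref[sites], g$alt[sites],
                  g$calls[sites, samples, drop = FALSE],
                  sample_ids = g$sample_ids[samples], id = g$id[sites],
                  chrom_lengths = attr(g, "chrom_lengths"))
}

# per-site allele counts over called genotypes: ref count, alt count, called n
allele_counts <- function(g) {
  cl <- g$calls
  n_called <- rowSums(!is.na(cl))
  alt <- rowSums(cl, na.rm = TRUE)
  list(n_called = n_called, c_alt = as.numeric(alt),
       c_ref = 2 * n_called - as.numeric(alt), k = 2 * n_called)
}

#' Per-site alternate allele frequency
#' @param g a \code{genotype_matrix}.
#' @return numeric vector of alt-allele frequencies over called alleles
#'   (\code{NaN} where no genotype is called).
#' @export
alt_freq <- function(g) {
  ac <- allele_counts(g)
  ac$c_alt / ac$k
}
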