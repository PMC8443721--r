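#' Read a multi-sample VCF into a genotype matrix
#'
#' Imports biallelic SNP records from a VCF v4.x file. Multiallelic records,
#' indels and other non-SNP records are dropped and counted in the filter
#' report. Genotypes are mapped to 0/1/2 dosage codes; half-calls (e.g.
#' \code{./1}) and missing genotypes become \code{NA}. Phase separators
#' (\code{|}) are accepted but phase is discarded.
#'
#' @param path path to an (optionally gzipped) VCF file.
#' @return list with elements \code{genotypes} (a
#'   \code{\link{genotype_matrix}}) and \code{report} (a
#'   \code{\link{filter_report}} with per-rule dropped-record counts).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has zero sample columns")
  fix <- v@fix
  n_in <- nrow(fix)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- !multi & snp
  removed <- c(multiallelic = sum(multi), non_snp = sum(!snp & !multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  calls <- gt_to_code(gt)
  meta <- v@meta
  clen <- parse_contig_lengths(meta)
  ids <- fix[keep, "ID"]
  fill <- is.na(ids) | ids == "."
  ids[fill] <- paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = "_")[fill]
  g <- genotype_matrix(chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       ref = ref[keep], alt = alt[keep],
                       calls = calls, sample_ids = colnames(gt),
                       id = ids, chrom_lengths = clen)
  list(genotypes = g,
       report = filter_report(sites_in = n_in, removed = removed))
}

# map GT strings to dosage codes; anything containing "." is missing
gt_to_code <- function(gt) {
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt2 <- gsub("|", "/", gt, fixed = TRUE)
  code[gt2 %in% c("0/0", "0")] <- 0L
  code[gt2 %in% c("0/1", "1/0")] <- 1L
  code[gt2 %in% c("1/1", "1")] <- 2L
  code
}

# column-count sanity check so malformed lines are reported by line number
validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  ncol_expected <- NULL
  i <- 0L
  repeat {
    chunk <- readLines(con, n = 5000L)
    if (!length(chunk)) break
    for (line in chunk) {
      i <- i + 1L
      if (startsWith(line, "##")) next
      nf <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
      if (startsWith(line, "#CHROM")) {
        if (nf < 10) stop("VCF has zero sample columns (line ", i, ")")
        ncol_expected <- nf
      } else {
        if (is.null(ncol_expected)) stop("malformed VCF: data before #CHROM header (line ", i, ")")
        if (nf != ncol_expected)
          stop("malformed VCF line ", i, ": expected ", ncol_expected,
               " fields, found ", nf)
      }
    }
  }
  invisible(TRUE)
}

parse_contig_lengths <- function(meta) {
  ct <- grep("^##contig=", meta, value = TRUE)
  if (!length(ct)) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", ct)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", ct)))
  if (all(is.na(lens))) return(NULL)
  setNames(lens, ids)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits unphased \code{0/1}-style GT fields and contig header lines taken
#' from the matrix's chromosome lengths (falling back to the last observed
#' position per chromosome).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output file path; \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(g, path) {
  clen <- infer_chrom_lengths(g)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
           "##source=clonalscape",
           sprintf("##contig=<ID=%s,length=%d>", names(clen), as.integer(clen)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L], nrow = n_sites(g))
  gt[is.na(gt)] <- "./."
  body <- paste(g$chrom, g$pos, ifelse(is.na(g$id), ".", g$id), g$ref, g$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Converts 1-based closed intervals to the BED convention (0-based,
#' half-open).
#'
#' @param regions data frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based closed) and optionally a name column.
#' @param path output path.
#' @param name_col column to place in the BED name field, if present.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path, name_col = NULL) {
  df <- data.frame(chrom = regions$chrom,
                   start = regions$start - 1L,
                   end = regions$end)
  if (!is.null(name_col) && name_col %in% names(regions))
    df$name <- regions[[name_col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene intervals as GFF3
#'
#' @param genes data frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based closed) and \code{gene_id}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "clonalscape", "gene", genes$start, genes$end,
                   ".", "+", ".", paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a window track as BedGraph-style TSV
#'
#' Columns are chrom, 0-based start, end, value, n; internal representation
#' stays 1-based closed.
#'
#' @param track a window track data frame (\code{chrom}, \code{start},
#'   \code{end}, \code{value}, \code{n}; 1-based closed).
#' @param path file path.
#' @return \code{read_track}: a window track; \code{write_track}:
#'   \code{path}, invisibly.
#' @export
write_track <- function(track, path) {
  df <- data.frame(chrom = track$chrom, start0 = track$start - 1L,
                   end0 = track$end, value = track$value, n = track$n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  window_track(df$chrom, df$start0 + 1L, df$end0, df$value, df$n)
}
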