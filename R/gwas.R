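# covariates, single-variant association, multi-method consensus, MTAs,
# gene assignment and enrichment

#' Principal-component covariates from environmental factors
#'
#' Standardizes each environmental factor (mean 0, SD 1), drops
#' zero-variance factors with a warning, mean-imputes missing entries with a
#' message, and extracts the leading principal components of the correlation
#' structure.
#'
#' @param env data frame or matrix of numeric environmental factors
#'   (samples x factors).
#' @param n_pcs number of components to return (default 3).
#' @return list with \code{scores} (samples x n_pcs), \code{var_explained}
#'   (fractions per returned PC) and \code{dropped} (names of zero-variance
#'   factors).
#' @export
env_covariates <- function(env, n_pcs = 3) {
  X <- as.matrix(env)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    message("mean-imputing ", sum(is.na(X)), " missing environmental values")
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped))
    warning("dropping zero-variance factors: ", paste(dropped, collapse = ", "))
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < n_pcs) stop("fewer usable factors than requested PCs")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve[seq_len(n_pcs)],
       dropped = dropped)
}

#' Covariate-adjusted single-variant linear association
#'
#' Ordinary least squares of the phenotype on alt-allele dosage plus
#' covariates, one SNP at a time; reports the two-sided p-value of the dosage
#' coefficient. This is the package's stand-in association generator used to
#' exercise the consensus machinery; mixed-model and multi-locus methods are
#' consumed from their result tables instead.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param phenotype numeric vector, one value per sample.
#' @param covariates optional numeric matrix (samples x covariates).
#' @param method label recorded in the output table.
#' @return an association table: data frame with \code{method}, \code{chrom},
#'   \code{pos}, \code{id}, \code{beta}, \code{stat} (t), \code{p},
#'   \code{stat_type = "p"} and significance \code{rank} (ties broken by
#'   chrom, pos).
#' @export
associate_linear <- function(g, phenotype, covariates = NULL,
                             method = "ols_linear") {
  y <- as.numeric(phenotype)
  n <- n_samples(g)
  stopifnot(length(y) == n)
  Z <- cbind(intercept = rep(1, n), covariates)
  X <- t(dosage(g))  # samples x sites
  beta <- tvec <- pvec <- rep(NA_real_, n_sites(g))
  complete <- !anyNA(X)
  miss_cols <- if (complete) integer(0) else which(colSums(is.na(X)) > 0)
  full_cols <- setdiff(seq_len(ncol(X)), miss_cols)
  qz <- qr(Z)
  df <- n - ncol(Z) - 1
  if (df < 1) stop("not enough samples for the covariate model")
  if (length(full_cols)) {
    yr <- qr.resid(qz, y)
    Xr <- qr.resid(qz, X[, full_cols, drop = FALSE])
    sxx <- colSums(Xr^2)
    sxy <- colSums(Xr * yr)
    ok <- sxx > 1e-12
    b <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- sum(yr^2) - b^2 * sxx
    rss <- pmax(rss, 0)
    tt <- b * sqrt(sxx) / sqrt(rss / df)
    beta[full_cols] <- b
    tvec[full_cols] <- ifelse(ok, tt, NA_real_)
  }
  for (j in miss_cols) {
    use <- !is.na(X[, j])
    dfj <- sum(use) - ncol(Z) - 1
    if (dfj < 1) next
    fit <- stats::lm.fit(cbind(Z[use, , drop = FALSE], X[use, j]), y[use])
    cf <- fit$coefficients
    if (anyNA(cf)) next
    rss <- sum(fit$residuals^2)
    R <- qr.R(fit$qr)
    xv <- chol2inv(R)[ncol(Z) + 1, ncol(Z) + 1]
    beta[j] <- cf[ncol(Z) + 1]
    tvec[j] <- cf[ncol(Z) + 1] / sqrt(rss / dfj * xv)
  }
  miss_df <- ifelse(seq_len(n_sites(g)) %in% miss_cols,
                    colSums(!is.na(X)) - ncol(Z) - 1, df)
  pvec <- 2 * pt(-abs(tvec), df = pmax(miss_df, 1))
  ord <- order(pvec, g$chrom, g$pos, na.last = TRUE)
  rank <- integer(n_sites(g))
  rank[ord] <- seq_len(n_sites(g))
  association_table(method, g$chrom, g$pos, g$id, stat = tvec, p_or_lod = pvec,
                    stat_type = "p", beta = beta, rank = rank)
}

#' Construct an association table
#'
#' Normalized per-variant association results from one named method. P-value
#' tables are ranked by ascending p; LOD tables by descending LOD. Duplicated
#' (chrom, pos) entries are an error.
#'
#' @param method method name.
#' @param chrom,pos variant coordinates.
#' @param id variant ids (defaults to \code{chrom_pos}).
#' @param stat raw test statistic (optional).
#' @param p_or_lod p-value (\code{stat_type = "p"}) or LOD score
#'   (\code{stat_type = "lod"}).
#' @param stat_type \code{"p"} or \code{"lod"}.
#' @param beta optional effect estimates.
#' @param rank optional precomputed significance rank.
#' @return data frame of class \code{association_table}.
#' @export
association_table <- function(method, chrom, pos, id = NULL, stat = NA_real_,
                              p_or_lod, stat_type = c("p", "lod"),
                              beta = NA_real_, rank = NULL) {
  stat_type <- match.arg(stat_type)
  chrom <- rep_len(as.character(chrom), length(pos))
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicated (chrom, pos) in association table for method ", method)
  if (is.null(id)) id <- paste(chrom, pos, sep = "_")
  if (is.null(rank)) {
    key <- if (stat_type == "p") p_or_lod else -p_or_lod
    ord <- order(key, chrom, pos, na.last = TRUE)
    rank <- integer(length(pos))
    rank[ord] <- seq_along(pos)
  }
  structure(data.frame(method = method, chrom = as.character(chrom),
                       pos = as.integer(pos), id = as.character(id),
                       beta = beta, stat = stat, p_or_lod = p_or_lod,
                       stat_type = stat_type, rank = as.integer(rank)),
            class = c("association_table", "data.frame"))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of (effective) independent tests; for SNP-level GWAS this
#'   is typically the effective SNP number from an external estimator, for
#'   gene-level analysis the number of genes tested.
#' @return per-test p-value threshold \code{alpha / m}.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Multi-method candidate SNP consensus
#'
#' A SNP is a candidate iff (a) it passes its method's significance threshold
#' in at least one table (p below the method's Bonferroni threshold, or LOD
#' above \code{lod_min} for LOD tables), or (b) it ranks within the top
#' \code{top_n} most significant variants in at least \code{min_methods}
#' tables (ties at the boundary rank included). Provenance records which rule
#' fired and which methods support each candidate.
#'
#' @param tables list of \code{\link{association_table}} objects.
#' @param p_thresholds single p threshold or named vector (by method) for
#'   p-value tables, e.g. from \code{\link{bonferroni_threshold}}.
#' @param lod_min suggestive LOD threshold for LOD tables (default 3).
#' @param top_n per-method rank cutoff for the consensus rule (default 500).
#' @param min_methods minimum number of methods for rule (b) (default 2;
#'   set 3 for the stricter reading of "more than two").
#' @return data frame of candidate SNPs: \code{chrom}, \code{pos}, \code{id},
#'   \code{by_threshold}, \code{by_consensus}, \code{methods_significant},
#'   \code{methods_top}, \code{n_methods_top}.
#' @export
candidate_snps <- function(tables, p_thresholds, lod_min = 3, top_n = 500,
                           min_methods = 2) {
  if (inherits(tables, "association_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  per <- lapply(tables, function(tb) {
    meth <- tb$method[1]
    if (anyDuplicated(paste(tb$chrom, tb$pos)))
      stop("duplicated (chrom, pos) in association table for method ", meth)
    if (tb$stat_type[1] == "lod") {
      sig <- !is.na(tb$p_or_lod) & tb$p_or_lod > lod_min
    } else {
      thr <- if (length(p_thresholds) > 1 || !is.null(names(p_thresholds)))
        p_thresholds[[meth]] else p_thresholds
      if (is.null(thr) || is.na(thr)) stop("no p threshold for method ", meth)
      sig <- !is.na(tb$p_or_lod) & tb$p_or_lod < thr
    }
    key <- if (tb$stat_type[1] == "lod") -tb$p_or_lod else tb$p_or_lod
    top <- if (nrow(tb) <= top_n) rep(TRUE, nrow(tb)) else {
      boundary <- sort(key, na.last = NA)[top_n]
      !is.na(key) & key <= boundary  # ties at the boundary included
    }
    data.frame(key = paste(tb$chrom, tb$pos, sep = "\r"), chrom = tb$chrom,
               pos = tb$pos, id = tb$id, method = meth, sig = sig, top = top)
  })
  all <- do.call(rbind, per)
  agg_sig <- tapply(ifelse(all$sig, all$method, NA), all$key,
                    function(x) sort(unique(x[!is.na(x)])))
  agg_top <- tapply(ifelse(all$top, all$method, NA), all$key,
                    function(x) sort(unique(x[!is.na(x)])))
  keys <- unique(all$key)
  first <- all[!duplicated(all$key), c("key", "chrom", "pos", "id")]
  rownames(first) <- first$key
  n_top <- vapply(agg_top[keys], length, integer(1))
  by_thr <- vapply(agg_sig[keys], length, integer(1)) > 0
  by_cons <- n_top >= min_methods
  cand <- by_thr | by_cons
  res <- data.frame(chrom = first[keys, "chrom"], pos = first[keys, "pos"],
                    id = first[keys, "id"],
                    by_threshold = by_thr, by_consensus = by_cons,
                    methods_significant = I(unname(agg_sig[keys])),
                    methods_top = I(unname(agg_top[keys])),
                    n_methods_top = n_top)[cand, , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge candidate SNPs into marker-trait associations (MTAs)
#'
#' Single-linkage chaining: consecutive candidates on one chromosome whose
#' positions differ by at most \code{merge_gap} bp join the same MTA. The MTA
#' interval spans the first to the last member SNP (a single candidate gives
#' a zero-length interval).
#'
#' @param candidates data frame with \code{chrom}, \code{pos} (and optionally
#'   \code{id}), e.g. from \code{\link{candidate_snps}}.
#' @param merge_gap maximum chaining distance in bp (default 10 kb).
#' @return data frame: \code{chrom}, \code{start}, \code{end}, \code{n_snps},
#'   \code{snps} (list column of member ids or positions).
#' @export
merge_mtas <- function(candidates, merge_gap = 10000) {
  if (!nrow(candidates))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      snps = I(list())))
  cand <- candidates[order(candidates$chrom, candidates$pos), , drop = FALSE]
  ids <- cand$id %||% paste(cand$chrom, cand$pos, sep = "_")
  new_block <- c(TRUE, cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                   diff(cand$pos) > merge_gap)
  block <- cumsum(new_block)
  res <- data.frame(
    chrom = tapply(cand$chrom, block, `[`, 1),
    start = as.integer(tapply(cand$pos, block, min)),
    end = as.integer(tapply(cand$pos, block, max)),
    n_snps = as.integer(tapply(cand$pos, block, length)),
    snps = I(unname(split(ids, block))))
  rownames(res) <- NULL
  res
}

#' Assign candidate genes to MTAs
#'
#' A gene is assigned to an MTA when the gene interval intersects the MTA
#' expanded by \code{flank} bp up- and downstream (closed 1-based
#' intersection).
#'
#' @param mtas data frame from \code{\link{merge_mtas}}.
#' @param genes data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}.
#' @param flank expansion in bp (default 5 kb).
#' @return list of gene-id vectors, one per MTA row.
#' @export
assign_genes <- function(mtas, genes, flank = 5000) {
  if (!nrow(mtas)) return(list())
  expanded <- data.frame(chrom = mtas$chrom,
                         start = pmax(1, mtas$start - flank),
                         end = mtas$end + flank)
  genes_overlapping_regions(expanded, genes, flank = 0)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For every term, tests over-representation of the selected genes among the
#' background with the hypergeometric upper tail P(X >= k), then applies the
#' Benjamini-Hochberg adjustment across tested terms.
#'
#' @param selected character vector of selected gene ids (subset of
#'   background).
#' @param background character vector of background gene ids.
#' @param term_map data frame with columns \code{gene_id}, \code{term_id}.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data frame per term: \code{term_id}, \code{k} (selected in term),
#'   \code{K} (background in term), \code{n} (selected), \code{N}
#'   (background), \code{p}, \code{p_adj}, \code{significant}.
#' @export
enrichment <- function(selected, background, term_map, alpha = 0.05) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background")
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  if (!nrow(tm))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  N <- length(background)
  n <- length(selected)
  K <- tapply(tm$gene_id, tm$term_id, function(x) length(unique(x)))
  sel_tm <- tm[tm$gene_id %in% selected, , drop = FALSE]
  k <- setNames(integer(length(K)), names(K))
  if (nrow(sel_tm)) {
    kk <- tapply(sel_tm$gene_id, sel_tm$term_id, function(x) length(unique(x)))
    k[names(kk)] <- kk
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- p.adjust(p, method = "BH")
  res <- data.frame(term_id = names(K), k = as.integer(k), K = as.integer(K),
                    n = n, N = N, p = as.numeric(p), p_adj = as.numeric(p_adj),
                    significant = as.numeric(p_adj) < alpha)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
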