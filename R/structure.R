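# pairwise distances, relatedness networks, isolation by distance

#' Identity-by-state and Hamming genetic distances
#'
#' For each sample pair and site, the number of shared alleles s is 2 minus
#' the absolute dosage difference (same homozygote or both heterozygous: 2;
#' heterozygote vs homozygote: 1; opposite homozygotes: 0). The IBS distance
#' is sum(2 - s) over sites divided by twice the total number of sites; the
#' Hamming distance is the unnormalized sum. Sites where either genotype is
#' missing contribute zero to the numerator while the denominator stays fixed
#' at the total site count (the "flat missing" convention).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param normalize if \code{TRUE} (IBS) divide by \code{2 * n_sites};
#'   otherwise return the raw Hamming distance.
#' @return symmetric distance matrix with sample ids as dimnames and
#'   attribute \code{kind} (\code{"ibs"} or \code{"hamming"}).
#' @export
ibs_distance <- function(g, normalize = TRUE) {
  X <- dosage(g)
  M <- !is.na(X)
  X[!M] <- 0
  storage.mode(M) <- "double"
  X2 <- X^2
  # sum over sites of (x - y)^2, counting only sites called in both samples
  S1 <- crossprod(X2, M) + crossprod(M, X2) - 2 * crossprod(X)
  # |x - y| = (x - y)^2 - 2 * [opposite homozygotes]
  A0 <- (g$calls == 0L) & M; A2 <- (g$calls == 2L) & M
  storage.mode(A0) <- "double"; storage.mode(A2) <- "double"
  opp <- crossprod(A0, A2) + crossprod(A2, A0)
  D <- S1 - 2 * opp
  D <- (D + t(D)) / 2  # enforce exact symmetry
  diag(D) <- 0
  if (normalize) D <- D / (2 * n_sites(g))
  dimnames(D) <- list(g$sample_ids, g$sample_ids)
  attr(D, "kind") <- if (normalize) "ibs" else "hamming"
  D
}

#' Lowest-quantile relatedness edges
#'
#' Takes the empirical \code{fraction}-quantile (order statistic, no
#' interpolation) of the upper-triangle pairwise distances as cutoff and
#' returns all pairs at or below it (ties at the cutoff included), with node
#' degrees.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param fraction lower-tail fraction in (0, 1); 0.005 and 0.01 are the
#'   presets used for relatedness networks.
#' @return data frame of edges (\code{i}, \code{j}, \code{distance}) with
#'   \code{i < j} lexical order of indices, plus attributes \code{cutoff} and
#'   \code{degree} (named vector over all samples).
#' @export
lowest_quantile_edges <- function(d, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 1)
  m <- as.matrix(d)
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  ut <- upper.tri(m)
  vals <- m[ut]
  cutoff <- quantile_type1(vals, fraction)
  sel <- which(ut & m <= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = ids[sel[, 1]], j = ids[sel[, 2]],
                      distance = m[sel])
  edges <- edges[order(edges$distance, edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- setNames(numeric(length(ids)), ids)
  tab <- table(c(edges$i, edges$j))
  deg[names(tab)] <- tab
  attr(edges, "cutoff") <- cutoff
  attr(edges, "degree") <- deg
  edges
}

#' Mantel test of isolation by distance
#'
#' Correlates linearized genetic differentiation, F_ST / (1 - F_ST), with
#' geographic distance across location pairs and assesses significance by
#' jointly permuting the rows and columns of one matrix. The one-sided
#' p-value uses the add-one rule, (1 + #\{r_perm >= r_obs\}) / (1 + n_perm),
#' so it can never be exactly zero.
#'
#' @param fst_matrix symmetric matrix of pairwise F_ST values (or already
#'   linearized distances if \code{transform = FALSE}).
#' @param geo_matrix symmetric matrix of geographic distances (same order).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed for the permutation stream.
#' @param transform apply the F_ST / (1 - F_ST) linearization (default).
#' @return list with \code{r} (Pearson correlation of off-diagonal entries),
#'   \code{p} (one-sided permutation p-value), \code{n_perm}, \code{n}.
#' @export
mantel_ibd <- function(fst_matrix, geo_matrix, n_perm = 9999, seed = NULL,
                       transform = TRUE) {
  x <- as.matrix(fst_matrix)
  y <- as.matrix(geo_matrix)
  stopifnot(nrow(x) == ncol(x), all(dim(x) == dim(y)))
  if (transform) {
    if (any(x[upper.tri(x)] >= 1)) stop("F_ST values must be < 1 for linearization")
    x <- x / (1 - x)
  }
  ut <- upper.tri(x)
  xv <- x[ut]
  if (sd(xv) == 0 || sd(y[ut]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- cor(xv, y[ut])
  run <- function() {
    n <- nrow(x)
    r_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      r_perm[b] <- cor(x[p, p][ut], y[ut])
    }
    r_perm
  }
  r_perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  list(r = r_obs, p = p, n_perm = n_perm, n = nrow(x))
}

#' Great-circle distance matrix
#'
#' Haversine distances in km on a sphere of radius 6371.0088 km.
#'
#' @param lat,lon decimal-degree coordinates.
#' @param ids optional location ids for dimnames.
#' @return symmetric matrix of distances in km.
#' @export
great_circle <- function(lat, lon, ids = NULL) {
  stopifnot(length(lat) == length(lon),
            all(abs(lat) <= 90), all(abs(lon) <= 360))
  R <- 6371.0088
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  h <- pmin(pmax(h, 0), 1)
  D <- 2 * R * asin(sqrt(h))
  diag(D) <- 0
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(d, path) {
  m <- as.matrix(d)
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  lines <- c(sprintf("%5d", nrow(m)),
             paste(formatC(substr(ids, 1, 10), width = -10),
                   apply(m, 1, function(r) paste(formatC(r, format = "g"),
                                                 collapse = " "))))
  writeLines(lines, path)
  invisible(path)
}
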