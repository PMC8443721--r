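# synthetic clonal-population generator
#
# Site classes emitted:
#   founder    - heterozygous in ~96% of samples (clonally fixed founder
#                heterozygosity); strongly enriched inside planted high-LCHRs
#   somatic    - a mutation on one edge of a random clonal genealogy,
#                heterozygous in exactly that clade (<= 10% of samples);
#                enriched inside planted low-LCHRs
#   background - ordinary standing variants, HWE within groups, group allele
#                frequencies perturbed around an ancestral frequency so that
#                the expected Weir-Cockerham F_ST matches the configured
#                target, with spatially correlated deviations (isolation by
#                distance)

# region enrichment multipliers (site intensity relative to background bp)
.region_weights <- list(
  founder = c(high = 6, low = 0.05),
  somatic = c(high = 0.3, low = 4),
  background = c(high = 1, low = 1))

#' Simulate a clonal diploid SNP population with known ground truth
#'
#' Generates a biallelic SNP genotype matrix, a sample metadata table
#' (groups, coordinates, batches, 12 correlated environmental factors) and a
#' ground-truth record, from a \code{\link{sim_config}}. Output is
#' deterministic given \code{config$seed}. Monomorphic sites (no alternate
#' allele called) are not retained.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{clonal_sim}: \code{genotypes}
#'   (\code{\link{genotype_matrix}}, outgroup sample last when enabled),
#'   \code{samples} (data frame), \code{truth} (list: per-site class,
#'   planted regions, causal SNPs, group assignment, lineage depth, latent
#'   environmental factors).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  n <- cfg$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  L <- sum(cfg$chrom_lengths)

  ## clonal genealogy and somatic-eligible clades
  tree <- ape::rtree(n, tip.label = ids)
  clades <- edge_clades(tree)
  depth <- tip_edge_depth(tree)
  # cap somatic clades at 10% of samples; with missingness on, stay one
  # sample clear of the boundary so observed carrier frequencies (over
  # called genotypes) remain at or below 10% despite masked calls
  max_clade <- max(1L, floor(0.10 * n) - (cfg$missing_rate > 0))
  eligible <- which(lengths(clades) <= max_clade)

  ## groups and geography
  group <- sample(rep_len(seq_len(cfg$n_groups), n))
  centers <- data.frame(group = seq_len(cfg$n_groups),
                        lat = runif(cfg$n_groups, 24, 32),
                        lon = runif(cfg$n_groups, 105, 122))
  lat <- centers$lat[group] + runif(n, -0.5, 0.5)
  lon <- centers$lon[group] + runif(n, -0.5, 0.5)

  ## site positions per class (piecewise-constant intensity over regions)
  pos_f <- draw_class_positions(cfg, cfg$founder_het_density, "founder")
  pos_s <- draw_class_positions(cfg, cfg$somatic_mut_rate * n, "somatic")
  pos_b <- draw_class_positions(cfg, cfg$background_site_density, "background")
  sites <- rbind(
    if (nrow(pos_f)) cbind(pos_f, class = "founder"),
    if (nrow(pos_s)) cbind(pos_s, class = "somatic"),
    if (nrow(pos_b)) cbind(pos_b, class = "background"))
  if (is.null(sites) || !nrow(sites)) {
    g <- genotype_matrix(character(0), integer(0), character(0), character(0),
                         matrix(NA_integer_, 0, n + cfg$outgroup),
                         sample_ids = c(ids, if (cfg$outgroup) "OG1"),
                         chrom_lengths = cfg$chrom_lengths)
    return(empty_sim(cfg, g, ids, group, lat, lon, depth, centers))
  }
  sites <- sites[order(match(sites$chrom, names(cfg$chrom_lengths)), sites$pos), ]
  dup <- duplicated(paste(sites$chrom, sites$pos))
  sites <- sites[!dup, , drop = FALSE]
  m <- nrow(sites)

  ## genotypes per class
  calls <- matrix(0L, m, n)
  i_f <- which(sites$class == "founder")
  if (length(i_f)) {
    het <- matrix(runif(length(i_f) * n) < 0.96, length(i_f), n)
    gt <- matrix(0L, length(i_f), n)
    gt[het] <- 1L
    gt[!het] <- ifelse(runif(sum(!het)) < 0.5, 0L, 2L)
    calls[i_f, ] <- gt
  }
  i_s <- which(sites$class == "somatic")
  if (length(i_s)) {
    edge_of <- sample(eligible, length(i_s), replace = TRUE)
    for (e in unique(edge_of)) {
      rows <- i_s[edge_of == e]
      calls[rows, clades[[e]]] <- 1L
    }
  }
  i_b <- which(sites$class == "background")
  p_group <- NULL
  if (length(i_b)) {
    p_group <- background_group_freqs(length(i_b), cfg, centers)
    pg <- p_group[, group, drop = FALSE]  # sites x samples expansion
    calls[i_b, ] <- matrix(rbinom(length(pg), 2L, pg), nrow(pg), ncol(pg))
  }

  ## outgroup: homozygous at >= 99% of sites; mostly ancestral (ref)
  if (cfg$outgroup) {
    u <- runif(m)
    og <- ifelse(u < 0.90, 0L, ifelse(u < 0.995, 2L, 1L))
    calls <- cbind(calls, og)
    ids_all <- c(ids, "OG1")
  } else ids_all <- ids

  ## causal SNPs from background sites with usable frequencies
  causal <- empty_causal()
  causal_dosage <- NULL
  if (cfg$n_causal > 0 && length(i_b)) {
    f_real <- rowMeans(calls[i_b, seq_len(n), drop = FALSE]) / 2
    pool <- i_b[f_real >= 0.2 & f_real <= 0.8]
    n_c <- min(cfg$n_causal, length(pool))
    if (n_c > 0) {
      pick <- sort(sample(pool, n_c))
      causal <- data.frame(
        id = paste(sites$chrom[pick], sites$pos[pick], sep = "_"),
        chrom = sites$chrom[pick], pos = sites$pos[pick],
        trait = paste0("trait_", (seq_len(n_c) - 1L) %% 9L + 1L),
        effect = cfg$effect_size)
      causal_dosage <- t(calls[pick, seq_len(n), drop = FALSE])
      colnames(causal_dosage) <- causal$id
      rownames(causal_dosage) <- ids
    }
  }

  ## missingness, uniform and genotype-independent
  if (cfg$missing_rate > 0) {
    mask <- runif(length(calls)) < cfg$missing_rate
    calls[mask] <- NA_integer_
  }

  ## drop sites with no called alternate allele
  keep <- rowSums(calls, na.rm = TRUE) > 0 & rowSums(!is.na(calls)) > 0
  calls <- calls[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]

  ## environmental latent factors (leading factor follows latitude)
  latent <- cbind(scale(lat)[, 1], scale(lon)[, 1])
  if (cfg$env_latent_dim > 2)
    latent <- cbind(latent, matrix(rnorm(n * (cfg$env_latent_dim - 2)), n))
  latent <- latent[, seq_len(cfg$env_latent_dim), drop = FALSE]
  colnames(latent) <- paste0("latent_", seq_len(ncol(latent)))
  samples <- sample_table(cfg, ids, group, lat, lon, latent, centers)

  g <- genotype_matrix(sites$chrom, sites$pos,
                       ref = rep("A", nrow(sites)), alt = rep("T", nrow(sites)),
                       calls = calls, sample_ids = ids_all,
                       chrom_lengths = cfg$chrom_lengths)
  truth <- list(site_class = sites$class,
                planted_high = cfg$planted_high_lchr,
                planted_low = cfg$planted_low_lchr,
                causal = causal, causal_dosage = causal_dosage,
                group = setNames(group, ids),
                lineage_depth = depth,
                latent = latent,
                group_centers = centers,
                tree = tree)
  structure(list(genotypes = g, samples = samples, truth = truth,
                 config = cfg),
            class = "clonal_sim")
}

empty_causal <- function() {
  data.frame(id = character(0), chrom = character(0), pos = integer(0),
             trait = character(0), effect = numeric(0))
}

empty_sim <- function(cfg, g, ids, group, lat, lon, depth, centers) {
  n <- cfg$n_samples
  latent <- cbind(scale(lat)[, 1], scale(lon)[, 1])
  if (cfg$env_latent_dim > 2)
    latent <- cbind(latent, matrix(rnorm(n * (cfg$env_latent_dim - 2)), n))
  latent <- latent[, seq_len(cfg$env_latent_dim), drop = FALSE]
  colnames(latent) <- paste0("latent_", seq_len(ncol(latent)))
  structure(list(genotypes = g,
                 samples = sample_table(cfg, ids, group, lat, lon, latent,
                                        centers),
                 truth = list(site_class = character(0),
                              planted_high = cfg$planted_high_lchr,
                              planted_low = cfg$planted_low_lchr,
                              causal = empty_causal(), causal_dosage = NULL,
                              group = setNames(group, ids),
                              lineage_depth = depth, latent = latent,
                              group_centers = centers, tree = NULL),
                 config = cfg),
            class = "clonal_sim")
}

#' @export
print.clonal_sim <- function(x, ...) {
  cat("clonal_sim:", n_sites(x$genotypes), "SNP sites x",
      n_samples(x$genotypes), "samples (seed", x$config$seed, ")\n")
  if (length(x$truth$site_class))
    print(table(x$truth$site_class))
  invisible(x)
}

# Poisson positions with region-dependent intensity for one site class
draw_class_positions <- function(cfg, base_rate, class) {
  w <- .region_weights[[class]]
  out <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    segs <- region_segments(len,
                            cfg$planted_high_lchr[cfg$planted_high_lchr$chrom == ch, , drop = FALSE],
                            cfg$planted_low_lchr[cfg$planted_low_lchr$chrom == ch, , drop = FALSE])
    pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      rate <- base_rate * switch(segs$kind[i], high = w[["high"]],
                                 low = w[["low"]], 1)
      nbp <- segs$end[i] - segs$start[i] + 1
      cnt <- rpois(1, rate * nbp)
      if (cnt == 0) return(integer(0))
      sort(sample.int(nbp, min(cnt, nbp)) + segs$start[i] - 1L)
    }))
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = as.integer(pos))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(0), pos = integer(0)) else out
}

# partition [1, len] into segments labelled none/high/low
region_segments <- function(len, high, low) {
  marks <- data.frame(pos = c(1, len + 1), kind = NA)
  brk <- sort(unique(c(1, len + 1, high$start, high$end + 1,
                       low$start, low$end + 1)))
  brk <- brk[brk >= 1 & brk <= len + 1]
  segs <- data.frame(start = brk[-length(brk)], end = brk[-1] - 1)
  segs$kind <- "none"
  for (i in seq_len(nrow(high)))
    segs$kind[segs$start >= high$start[i] & segs$end <= high$end[i]] <- "high"
  for (i in seq_len(nrow(low)))
    segs$kind[segs$start >= low$start[i] & segs$end <= low$end[i]] <- "low"
  segs
}

# group allele frequencies around an ancestral frequency, calibrated so the
# expected Weir-Cockerham F_ST equals the target; deviations are spatially
# correlated across group centers (exponential decay) to create isolation by
# distance, standardized so the mean pairwise variance matches independent
# (Balding-Nichols-like) draws
background_group_freqs <- function(n_sites, cfg, centers) {
  K <- cfg$n_groups
  p <- runif(n_sites, 0.1, 0.9)
  Fst <- cfg$group_fst_target
  if (Fst <= 0 || K < 2)
    return(matrix(p, n_sites, K))
  C <- diag(K)
  if (K > 1) {
    D <- great_circle(centers$lat, centers$lon)
    C <- exp(-D / cfg$group_corr_range)
    rb <- mean(C[upper.tri(C)])
    # rescale so mean pairwise E[(z_g - z_h)^2] / 2 = 1
    Z <- matrix(rnorm(n_sites * K), n_sites, K) %*% chol(C)
    Z <- Z / sqrt(max(1 - rb, .Machine$double.eps))
  }
  pg <- p + sqrt(Fst * p * (1 - p)) * Z
  pmin(pmax(pg, 0.005), 0.995)
}

sample_table <- function(cfg, ids, group, lat, lon, latent, centers) {
  n <- length(ids)
  env_names <- c("altitude", "soil_type", "precip_annual", "temp_annual",
                 "N", "P", "K", "Mg", "B", "Zn")
  B <- matrix(rnorm(length(env_names) * ncol(latent)), length(env_names))
  env <- latent %*% t(B) + matrix(rnorm(n * length(env_names), sd = 0.4), n)
  colnames(env) <- env_names
  df <- data.frame(sample_id = ids,
                   group = paste0("G", group),
                   latitude = lat, longitude = lon,
                   batch = paste0("B", sample(1:2, n, replace = TRUE)),
                   env, check.names = FALSE)
  if (cfg$outgroup) {
    og_env <- as.list(colMeans(env))
    og <- c(list(sample_id = "OG1", group = "outgroup",
                 latitude = 23.0, longitude = 108.0, batch = "B1"), og_env)
    df <- rbind(df, as.data.frame(og, check.names = FALSE))
  }
  rownames(df) <- NULL
  df
}

# tip sets per edge of the clonal genealogy
edge_clades <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1]; child <- po$edge[r, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) sort(desc[[tree$edge[r, 2]]]))
}

# number of edges from the root to each tip
tip_edge_depth <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  dep <- rep(NA_integer_, n + tree$Nnode)
  dep[root] <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[r, 1]; child <- po$edge[r, 2]
    dep[child] <- dep[par] + 1L
  }
  setNames(dep[seq_len(n)], tree$tip.label)
}

#' Simulate phenotypes from causal SNPs and the environment
#'
#' Nine trait columns; each causal SNP contributes its effect times the true
#' (pre-missingness) alt-allele dosage to the trait it is assigned to, plus a
#' shared environmental term (the leading latent factor times
#' \code{env_weight}) and Gaussian noise of SD \code{noise_sd}. Deterministic
#' given \code{config$seed}.
#'
#' @param truth truth component of a \code{\link{simulate_population}} result
#'   (or the \code{clonal_sim} object itself).
#' @param genotypes the matching \code{\link{genotype_matrix}} (used for
#'   sample ids; dosages come from the truth record).
#' @param config the \code{\link{sim_config}} used for the simulation.
#' @return data frame: \code{sample_id} plus \code{trait_1} ... \code{trait_9}
#'   (outgroup excluded).
#' @export
simulate_phenotypes <- function(truth, genotypes, config) {
  if (inherits(truth, "clonal_sim")) {
    genotypes <- truth$genotypes
    config <- truth$config
    truth <- truth$truth
  }
  ids <- names(truth$group)
  n <- length(ids)
  withr::with_seed(config$seed + 1L, {
    Y <- matrix(rnorm(n * 9L, sd = config$noise_sd), n, 9L,
                dimnames = list(ids, paste0("trait_", 1:9)))
    Y <- Y + config$env_weight * truth$latent[, 1]
    if (nrow(truth$causal)) {
      if (!all(truth$causal$id %in% genotypes$id))
        stop("causal SNP absent from the genotype matrix")
      for (i in seq_len(nrow(truth$causal))) {
        tr <- truth$causal$trait[i]
        Y[, tr] <- Y[, tr] +
          truth$causal$effect[i] * truth$causal_dosage[, truth$causal$id[i]]
      }
    }
    data.frame(sample_id = ids, Y, row.names = NULL)
  })
}

#' Simulate gene annotation and a gene-to-term mapping
#'
#' Genes are tiled along each chromosome at a fixed pitch, optionally with a
#' random jitter of the start inside its slot, giving
#' \code{floor(length / pitch)} genes per chromosome. Each gene is mapped to
#' 1-5 terms; term popularity is heavy-tailed (Zipf weights), so term sizes
#' span a wide range as in real functional catalogs.
#'
#' @param config a \code{\link{sim_config}}.
#' @param pitch distance between gene slots in bp (default 10 kb).
#' @param gene_length gene length in bp (default 3 kb).
#' @param n_genes optional cap: keep a random subset of this many genes
#'   (0 gives an empty annotation).
#' @param n_terms number of terms in the catalog (default 50).
#' @param jitter randomize gene starts within their slots (default TRUE).
#' @return list with \code{genes} (data frame: \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id}; 1-based closed) and \code{term_map} (data
#'   frame: \code{gene_id}, \code{term_id}).
#' @export
simulate_annotation <- function(config, pitch = 10000, gene_length = 3000,
                                n_genes = NULL, n_terms = 50, jitter = TRUE) {
  stopifnot(gene_length <= pitch)
  withr::with_seed(config$seed + 2L, {
    genes <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      cnt <- floor(len / pitch)
      if (cnt < 1) return(NULL)
      slot <- (seq_len(cnt) - 1) * pitch + 1
      off <- if (jitter) sample.int(pitch - gene_length + 1, cnt,
                                    replace = TRUE) - 1L else 0L
      data.frame(chrom = ch, start = as.integer(slot + off),
                 end = as.integer(slot + off + gene_length - 1))
    }))
    if (is.null(genes)) genes <- data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0))
    if (!is.null(n_genes)) {
      n_genes <- min(n_genes, nrow(genes))
      genes <- genes[sort(sample.int(nrow(genes), n_genes)), , drop = FALSE]
    }
    if (nrow(genes)) {
      genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
      rownames(genes) <- NULL
      w <- 1 / seq_len(n_terms)  # Zipf popularity
      tm <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
        k <- sample(1:5, 1)
        data.frame(gene_id = genes$gene_id[i],
                   term_id = sprintf("term%03d",
                                     sample.int(n_terms, k, prob = w)))
      }))
    } else {
      genes$gene_id <- character(0)
      tm <- data.frame(gene_id = character(0), term_id = character(0))
    }
    list(genes = genes, term_map = tm)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text artifacts for a simulation: VCF v4.2
#' genotypes, sample metadata TSV, phenotype TSV, gene annotation as BED
#' (0-based half-open) and GFF3 (1-based closed), the gene-to-term TSV and a
#' ground-truth JSON.
#'
#' @param sim a \code{clonal_sim} from \code{\link{simulate_population}}.
#' @param dir output directory (created if needed).
#' @param annotation optional result of \code{\link{simulate_annotation}}.
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, paths[["vcf"]])
  utils::write.table(sim$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ph <- simulate_phenotypes(sim)
  utils::write.table(ph, paths[["phenotypes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- sim$truth
  truth$tree <- if (!is.null(truth$tree)) ape::write.tree(truth$tree) else NULL
  truth$latent <- NULL
  truth$causal_dosage <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  if (!is.null(annotation)) {
    paths <- c(paths, genes_bed = file.path(dir, "genes.bed"),
               genes_gff3 = file.path(dir, "genes.gff3"),
               terms = file.path(dir, "terms.tsv"))
    write_bed(annotation$genes, paths[["genes_bed"]], name_col = "gene_id")
    write_gff3(annotation$genes, paths[["genes_gff3"]])
    utils::write.table(annotation$term_map, paths[["terms"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
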