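#' Configuration for the clonal-population simulator
#'
#' Bundles and validates all simulator parameters. The defaults describe the
#' data regime the package targets: a low-diversity clonal diploid population
#' in which most SNP sites are either founder heterozygous sites fixed
#' through clonal propagation (heterozygous in nearly all individuals) or
#' recent somatic mutations confined to one small clade of the clonal
#' genealogy (heterozygous in few individuals), with a minority of ordinary
#' standing variants carrying very weak group structure, plus planted
#' high/low heterozygosity regions and one homozygous-rich outgroup sample.
#'
#' @param n_samples number of ingroup samples.
#' @param n_groups number of geographic groups.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param founder_het_density expected founder-heterozygous sites per bp.
#' @param somatic_mut_rate expected new somatic heterozygous mutations per
#'   sample lineage per bp (total somatic site count scales with
#'   \code{n_samples}).
#' @param background_site_density expected ordinary (intermediate-frequency,
#'   group-structured) SNP sites per bp.
#' @param planted_high_lchr,planted_low_lchr data frames (\code{chrom},
#'   \code{start}, \code{end}; 1-based closed) of regions where founder
#'   (high) or somatic (low) sites are strongly enriched, to plant detectable
#'   LCHRs.
#' @param group_fst_target expected Weir-Cockerham F_ST among groups at
#'   background sites, in [0, 1).
#' @param group_corr_range spatial range (km) of the exponential correlation
#'   between group allele-frequency deviations; produces isolation by
#'   distance among groups.
#' @param outgroup append one outgroup sample (\code{"OG1"}) homozygous at
#'   almost all sites, for allele polarization.
#' @param n_causal number of phenotype-causal SNPs (drawn from background
#'   sites).
#' @param effect_size per-allele phenotype shift, in phenotype SD units.
#' @param env_weight weight of the leading latent environmental factor in the
#'   phenotype model.
#' @param noise_sd phenotype residual SD.
#' @param env_latent_dim number of latent factors generating the 12
#'   environmental variables.
#' @param missing_rate fraction of genotypes masked as missing, in [0, 1).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 100,
                       n_groups = 5,
                       chrom_lengths = c(chr1 = 50e6, chr2 = 30e6),
                       founder_het_density = 1.7e-4,
                       somatic_mut_rate = 2.3e-6,
                       background_site_density = 1e-4,
                       planted_high_lchr = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(10000001, 5000001),
                         end = c(16000000, 11000000)),
                       planted_low_lchr = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(30000001, 20000001),
                         end = c(36000000, 26000000)),
                       group_fst_target = 0.001,
                       group_corr_range = 400,
                       outgroup = TRUE,
                       n_causal = 9,
                       effect_size = 0.8,
                       env_weight = 0.3,
                       noise_sd = 1,
                       env_latent_dim = 3,
                       missing_rate = 0.02,
                       seed = 1) {
  stopifnot(n_samples >= 2, n_groups >= 1, length(chrom_lengths) >= 1,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            founder_het_density >= 0, somatic_mut_rate >= 0,
            background_site_density >= 0,
            group_fst_target >= 0, group_fst_target < 1,
            missing_rate >= 0, missing_rate < 1,
            n_causal >= 0, env_latent_dim >= 1, noise_sd >= 0)
  check_planted <- function(df, what) {
    if (is.null(df) || !nrow(df)) return(invisible())
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    if (!all(df$chrom %in% names(chrom_lengths)))
      stop(what, " interval on unknown chromosome")
    if (any(df$start < 1) || any(df$end > chrom_lengths[df$chrom]))
      stop(what, " interval exceeds chromosome length")
    if (any(df$end < df$start)) stop(what, " interval with end < start")
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
        stop(what, " intervals overlap on ", ch)
    }
  }
  empty_regions <- data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0))
  planted_high_lchr <- planted_high_lchr %||% empty_regions
  planted_low_lchr <- planted_low_lchr %||% empty_regions
  check_planted(planted_high_lchr, "planted high-LCHR")
  check_planted(planted_low_lchr, "planted low-LCHR")
  structure(list(n_samples = as.integer(n_samples),
                 n_groups = as.integer(n_groups),
                 chrom_lengths = chrom_lengths,
                 founder_het_density = founder_het_density,
                 somatic_mut_rate = somatic_mut_rate,
                 background_site_density = background_site_density,
                 planted_high_lchr = planted_high_lchr,
                 planted_low_lchr = planted_low_lchr,
                 group_fst_target = group_fst_target,
                 group_corr_range = group_corr_range,
                 outgroup = isTRUE(outgroup),
                 n_causal = as.integer(n_causal),
                 effect_size = effect_size,
                 env_weight = env_weight,
                 noise_sd = noise_sd,
                 env_latent_dim = as.integer(env_latent_dim),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples in", x$n_groups, "groups,",
      length(x$chrom_lengths), "chromosome(s),",
      sprintf("%.1f Mb", sum(x$chrom_lengths) / 1e6), "\n")
  cat("  densities/bp: founder", x$founder_het_density,
      "somatic/lineage", x$somatic_mut_rate,
      "background", x$background_site_density, "\n")
  cat("  F_ST target:", x$group_fst_target,
      " outgroup:", x$outgroup, " seed:", x$seed, "\n")
  invisible(x)
}
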