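# divergence-based mutation rate and coalescent trajectory scaling

#' Mutation rate from interspecific divergence
#'
#' mu = D * g / (2 * T): the per-site per-generation mutation rate implied by
#' an observed pairwise sequence divergence D between two species, a
#' generation time g (years) and a divergence time T (years), assuming
#' divergence accumulates at 2 * mu * T / g substitutions per site along the
#' two lineages. When a vector (e.g. per-window divergences from a
#' whole-genome alignment) is supplied, its median is used.
#'
#' @param D observed frequency of pairwise differences per site (scalar or
#'   per-window vector, in which case the median is taken).
#' @param generation_time generation time g in years.
#' @param divergence_time divergence time T in years.
#' @return list with \code{mu} (per site per generation), \code{D} (the
#'   divergence actually used), \code{generation_time}, \code{divergence_time}.
#' @export
mutation_rate <- function(D, generation_time, divergence_time) {
  if (length(D) > 1) D <- median(D, na.rm = TRUE)
  if (!is.finite(divergence_time) || divergence_time <= 0)
    stop("divergence time must be positive")
  if (generation_time <= 0) stop("generation time must be positive")
  if (D < 0 || D >= 1) stop("divergence D must be in [0, 1)")
  list(mu = D * generation_time / (2 * divergence_time),
       D = D, generation_time = generation_time,
       divergence_time = divergence_time)
}

#' Scale a coalescent trajectory to years and individuals
#'
#' Converts the scaled output of sequential-coalescent inference (times in
#' units of 2 * N0 generations, sizes relative to N0) into years and diploid
#' individuals, with N0 = theta0 / (4 * mu * bin_size).
#'
#' @param traj data frame with columns \code{time} (units of 2 N0
#'   generations) and \code{size} (relative to N0).
#' @param theta0 scaled mutation rate per bin from the inference.
#' @param mu mutation rate per site per generation.
#' @param generation_time generation time in years.
#' @param bin_size bp per bin of the input (default 100).
#' @return data frame with \code{time_years} and \code{ne} plus attribute
#'   \code{scaling = list(N0, mu, generation_time)}.
#' @export
scale_coalescent_output <- function(traj, theta0, mu, generation_time,
                                    bin_size = 100) {
  stopifnot(mu > 0, generation_time > 0, theta0 > 0, bin_size > 0)
  if (is.unsorted(traj$time)) stop("trajectory times must be non-decreasing")
  if (any(traj$time < 0)) stop("trajectory times must be non-negative")
  N0 <- theta0 / (4 * mu * bin_size)
  out <- data.frame(time_years = traj$time * 2 * N0 * generation_time,
                    ne = traj$size * N0)
  attr(out, "scaling") <- list(N0 = N0, mu = mu,
                               generation_time = generation_time)
  out
}

#' @rdname scale_coalescent_output
#' @param scaled output of \code{scale_coalescent_output}.
#' @return \code{unscale_coalescent_output}: the original scaled trajectory.
#' @export
unscale_coalescent_output <- function(scaled, theta0, mu, generation_time,
                                      bin_size = 100) {
  N0 <- theta0 / (4 * mu * bin_size)
  data.frame(time = scaled$time_years / (2 * N0 * generation_time),
             size = scaled$ne / N0)
}
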