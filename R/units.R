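#' Demographic unit constants
#'
#' Constants for converting diffusion-scaled demographic parameters to
#' natural units: a nuclear mutation rate of 2.34e-8 substitutions per
#' nucleotide per generation, an analysed sequence length of 1.45 Mb, a
#' generation time of 25.7 years, a killer whale / bottlenose dolphin
#' divergence time of 10 million years, and (for context) a 2.3 Gb genome.
#'
#' @param mu mutation rate (substitutions/nucleotide/generation).
#' @param seq_length analysed sequence length (bp).
#' @param generation_time generation time (years).
#' @param t_div_years species divergence time (years).
#' @param genome_size genome size (bp), context only.
#' @return A validated list of class `unit_constants`.
#' @export
unit_constants <- function(mu = 2.34e-8, seq_length = 1.45e6,
                           generation_time = 25.7, t_div_years = 1e7,
                           genome_size = 2.3e9) {
  vals <- c(mu, seq_length, generation_time, t_div_years, genome_size)
  if (any(vals <= 0)) stop("all unit constants must be positive")
  structure(list(mu = mu, seq_length = seq_length,
                 generation_time = generation_time,
                 t_div_years = t_div_years, genome_size = genome_size),
            class = "unit_constants")
}

#' Reference effective population size from scaled theta
#'
#' Ne = theta / (4 mu L), the ancestral reference size implied by the
#' population-scaled mutation parameter over the analysed sequence.
#'
#' @param theta scaled mutation parameter (> 0).
#' @param constants a `unit_constants` object.
#' @return Reference Ne (diploid individuals).
#' @export
reference_ne <- function(theta, constants = unit_constants()) {
  if (any(theta <= 0)) stop("theta must be positive")
  theta / (4 * constants$mu * constants$seq_length)
}

# Inverse of reference_ne; used to check conversion round trips.
theta_from_ne <- function(ne, constants = unit_constants()) {
  4 * constants$mu * constants$seq_length * ne
}

#' Convert a diffusion-scaled time to years
#'
#' years = 2 Ne_ref * T_scaled * g (times are scaled by 2 Ne_ref
#' generations).
#'
#' @param t_scaled scaled time (>= 0).
#' @param ne_ref reference effective size (> 0).
#' @param constants a `unit_constants` object.
#' @return Time in years.
#' @export
scaled_time_to_years <- function(t_scaled, ne_ref,
                                 constants = unit_constants()) {
  if (any(t_scaled < 0) || any(ne_ref <= 0)) stop("non-positive inputs")
  2 * ne_ref * t_scaled * constants$generation_time
}

#' Scaled symmetric migration to migrants per generation
#'
#' Under the diffusion scaling M = 2 Ne_ref m, the expected number of
#' migrant individuals entering a population of relative size nu each
#' generation is nu * M / 2.
#'
#' @param m_scaled scaled migration rate M.
#' @param nu relative size of the receiving population (default 1).
#' @return Migrants per generation.
#' @export
migrants_per_generation <- function(m_scaled, nu = 1) {
  if (any(m_scaled < 0) || any(nu <= 0)) stop("non-positive inputs")
  nu * m_scaled / 2
}

#' Expected sequence divergence between two species
#'
#' Twice the per-generation mutation rate times the number of generations
#' since the split (mutations accumulate on both lineages):
#' divergence = 2 mu T_div / g.
#'
#' @param constants a `unit_constants` object.
#' @return Expected divergence as a proportion (e.g. 0.0182 = 1.82%).
#' @export
expected_divergence <- function(constants = unit_constants()) {
  2 * constants$mu * (constants$t_div_years / constants$generation_time)
}
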