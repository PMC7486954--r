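#' Effective population size from synonymous diversity
#'
#' For a diploid population at neutral equilibrium, `pi_s = 4 Ne mu`, so
#' `Ne = pi_s / (4 mu)`.
#'
#' @param pi_s synonymous nucleotide diversity (per site).
#' @param mu per-site per-generation mutation rate.
#' @export
ne_from_diversity <- function(pi_s, mu) {
  if (mu <= 0) stopf("mu must be positive")
  if (pi_s < 0) stopf("pi_s must be non-negative")
  pi_s / (4 * mu)
}

#' Divergence-calibrated yearly mutation rate
#'
#' From the synonymous divergence `d_s` between two lineages and their
#' divergence time `T` (years), the per-year rate along one lineage is
#' `mu_year = d_s / (2 T)`.
#'
#' @param d_s synonymous divergence (substitutions per site).
#' @param T_years divergence time in years.
#' @export
clock_rate <- function(d_s, T_years) {
  if (T_years <= 0) stopf("divergence time must be positive")
  if (d_s < 0) stopf("divergence must be non-negative")
  d_s / (2 * T_years)
}

#' Generations per year implied by the molecular clock
#'
#' Dividing the divergence-calibrated yearly rate by the per-generation
#' (per-division) rate measured in the lab gives the number of generations
#' per year in the wild, and hence the days per generation (365-day year).
#'
#' @param mu_year per-year mutation rate (e.g. from [clock_rate()]).
#' @param mu_gen per-generation mutation rate.
#' @return list with `generations_per_year`, `days_per_generation`, and
#'   rounded `generations_per_year_int`, `days_per_generation_int`.
#' @export
generations_per_year <- function(mu_year, mu_gen) {
  if (mu_gen <= 0) stopf("per-generation rate must be positive")
  if (mu_year <= 0) stopf("per-year rate must be positive")
  g <- mu_year / mu_gen
  list(generations_per_year = g, days_per_generation = 365 / g,
       generations_per_year_int = round(g),
       days_per_generation_int = round(365 / g))
}

#' Lower bound on the per-generation rate in the wild
#'
#' With at most `max_gen_per_year` generations per year, the yearly rate
#' implies at least `mu_year / max_gen_per_year` mutations per site per
#' generation.
#'
#' @param mu_year per-year mutation rate.
#' @param max_gen_per_year maximal generations per year (default 300).
#' @export
min_per_generation_rate <- function(mu_year, max_gen_per_year = 300) {
  if (max_gen_per_year <= 0) stopf("max generations per year must be positive")
  mu_year / max_gen_per_year
}

#' Cell divisions from a bottleneck census
#'
#' A culture founded by a single cell that reaches `count` cells in
#' `days` days has undergone `log2(count)` divisions, i.e.
#' `log2(count)/days` divisions per day.
#'
#' @param count cell count at transfer (>= 1).
#' @param days interval length in days.
#' @return list with `divisions`, `divisions_per_day`.
#' @export
estimate_generations <- function(count, days) {
  if (any(count < 1)) stopf("cell count must be >= 1")
  if (days <= 0) stopf("interval must be positive")
  d <- log2(count)
  list(divisions = d, divisions_per_day = d / days)
}

#' Harmonic-mean effective population size of a bottlenecked culture
#'
#' The effective size of a population whose census fluctuates is the
#' harmonic mean of the per-generation (here per-day) census sizes:
#' `H = n / sum(1/N_i)` over all sampled days of all cycles, including the
#' founding single cell of each cycle.
#'
#' @param counts numeric vector of daily cell counts (all >= 1).
#' @export
harmonic_mean_popsize <- function(counts) {
  if (!length(counts)) stopf("empty cell-count input")
  if (any(counts < 1)) stopf("cell counts must be >= 1")
  length(counts) / sum(1 / counts)
}

#' Trend in division rate over the course of the experiment
#'
#' Spearman rank correlation of per-interval divisions/day against the
#' interval index; a proxy for a fitness change during the MA experiment.
#' Ties are handled by mid-ranks.
#'
#' @param rates per-interval divisions per day.
#' @param index interval index (defaults to 1..n).
#' @return list with `rho`, `p_value` (`rho` NA for a constant series,
#'   flagged via `constant`).
#' @export
fitness_trend <- function(rates, index = seq_along(rates)) {
  if (length(rates) < 3L) stopf("need at least 3 intervals")
  if (length(unique(rates)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, constant = TRUE))
  ct <- suppressWarnings(cor.test(index, rates, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, constant = FALSE)
}

#' Cross-species correlation between Ne and mutation rate
#'
#' Pearson correlation of `log10(mu)` on `log10(Ne)` across a species
#' compilation (both axes span orders of magnitude); a raw-scale mode is
#' available.
#'
#' @param species data.frame with columns `ne`, `mu` (>= 4 species).
#' @param log10_scale correlate on log10 scale (default) or raw values.
#' @return list with `rho`, `p_value`, `n`.
#' @export
ne_mu_correlation <- function(species, log10_scale = TRUE) {
  if (nrow(species) < 4L) stopf("need at least 4 species")
  x <- species$ne; y <- species$mu
  if (log10_scale) { x <- log10(x); y <- log10(y) }
  ct <- cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(species))
}
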