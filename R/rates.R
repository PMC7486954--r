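#' Poisson rate estimate with exact (Garwood) confidence interval
#'
#' Point rate `mu = count / exposure` with a confidence interval on the
#' Poisson mean.  The default exact (Garwood) interval uses chi-square
#' quantiles: `low = qchisq(alpha/2, 2*count)/2 / exposure` (0 when the
#' count is 0) and `high = qchisq(1 - alpha/2, 2*(count+1))/2 / exposure`.
#' A normal (Wald) approximation is available via `method = "normal"`.
#'
#' @param count non-negative integer number of events.
#' @param exposure positive denominator in site-divisions (for a nuclear
#'   MA experiment: ploidy x sum over lines of callable_sites x
#'   generations).
#' @param level confidence level.
#' @param method `"garwood"` (exact) or `"normal"`.
#' @param compartment optional label carried along.
#' @return object of class `rate_estimate` with fields `count`, `exposure`,
#'   `mu`, `level`, `ci` (length-2), `method`, `compartment`.
#' @export
rate_estimate <- function(count, exposure, level = 0.95,
                          method = c("garwood", "normal"),
                          compartment = NULL) {
  method <- match.arg(method)
  if (!is_count(count)) stopf("count must be a non-negative integer")
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure <= 0)
    stopf("exposure must be positive")
  if (level <= 0 || level >= 1) stopf("level must be in (0,1)")
  a <- 1 - level
  mu <- count / exposure
  if (method == "garwood") {
    lo <- if (count == 0) 0 else qchisq(a / 2, 2 * count) / 2 / exposure
    hi <- qchisq(1 - a / 2, 2 * (count + 1)) / 2 / exposure
  } else {
    z <- stats::qnorm(1 - a / 2)
    se <- sqrt(count) / exposure
    lo <- max(0, mu - z * se); hi <- mu + z * se
  }
  structure(list(count = count, exposure = exposure, mu = mu, level = level,
                 ci = c(lo, hi), method = method,
                 compartment = compartment %||% "nuclear"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s mutation rate: %s per site per division\n",
              x$compartment, format(x$mu, digits = 3)))
  cat(sprintf("  %d mutations / %s site-divisions\n", x$count,
              format(x$exposure, digits = 6, big.mark = ",")))
  cat(sprintf("  %d%% CI (%s): %s - %s\n", round(100 * x$level), x$method,
              format(x$ci[1], digits = 3), format(x$ci[2], digits = 3)))
  invisible(x)
}

#' @export
confint.rate_estimate <- function(object, parm, level, ...) object$ci

#' Fit the mutation-rate model of an MA experiment
#'
#' The central estimator: given the per-line experiment table (generations,
#' callable sites, accepted mutation counts), estimates the per-site
#' per-division mutation rate `mu = n / (ploidy * sum_i callable_i *
#' gen_i)` with an exact Poisson confidence interval, the per-haploid-
#' genome rates `U = genome_size * mu` and `U_cds = cds_size * mu`,
#' per-line rates, and the among-line heterogeneity chi-square.
#'
#' @param experiment an [experiment_table()] (or data.frame with columns
#'   `line`, `generations`, `callable_sites`, `n_mut`).
#' @param count total mutation count; defaults to `sum(n_mut)`.
#' @param ploidy ploidy of the MA lines (2 for a diploid strain: each site
#'   carries two mutable copies).
#' @param genome_size,cds_size optional sizes in bp for `U` and `U_cds`.
#' @param level confidence level.
#' @param ci_method `"garwood"` or `"normal"`.
#' @param het_expectation expected per-line counts for the heterogeneity
#'   test: `"exposure"` (proportional to callable x generations) or
#'   `"equal"`.
#' @return object of class `ma_fit`.
#' @seealso [rate_estimate()], [per_line_rates()]
#' @export
ma_fit <- function(experiment, count = NULL, ploidy = 2,
                   genome_size = NULL, cds_size = NULL, level = 0.95,
                   ci_method = c("garwood", "normal"),
                   het_expectation = c("exposure", "equal")) {
  ci_method <- match.arg(ci_method)
  het_expectation <- match.arg(het_expectation)
  ex <- experiment_table(as.data.frame(experiment))
  if (is.null(count)) {
    if (is.null(ex$n_mut)) stopf("no mutation counts: supply count= or n_mut")
    count <- sum(ex$n_mut)
  }
  if (ploidy < 1) stopf("ploidy must be >= 1")
  exposure <- ploidy * sum(as.numeric(ex$callable_sites) * ex$generations)
  rate <- rate_estimate(count, exposure, level = level, method = ci_method)
  per_line <- if (!is.null(ex$n_mut) && nrow(ex) >= 2L)
    per_line_rates(ex, ploidy = ploidy, expectation = het_expectation)
  else NULL
  fit <- structure(list(
    experiment = ex, ploidy = ploidy, rate = rate,
    genome_size = genome_size, cds_size = cds_size,
    U = if (!is.null(genome_size)) genome_size * rate$mu else NULL,
    U_cds = if (!is.null(cds_size)) cds_size * rate$mu else NULL,
    per_line = per_line), class = "ma_fit")
  ma_log("ma_fit: mu = %.3e on %d lines", rate$mu, nrow(ex))
  fit
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("MA experiment fit: %d lines, %s generations total, ploidy %d\n",
              nrow(x$experiment), format(sum(x$experiment$generations),
                                         big.mark = ","), x$ploidy))
  print(x$rate)
  if (!is.null(x$U))
    cat(sprintf("  U (per haploid genome per division)     = %.3g\n", x$U))
  if (!is.null(x$U_cds))
    cat(sprintf("  U_cds (per haploid coding complement)   = %.3g\n", x$U_cds))
  if (!is.null(x$per_line))
    cat(sprintf("  per-line counts: mean %.2f, SD %.2f; heterogeneity X2 = %.2f (df %d, p = %.3g, %s expectation)\n",
                x$per_line$mean_count, x$per_line$sd_count,
                x$per_line$chisq, x$per_line$df, x$per_line$p_value,
                x$per_line$expectation))
  invisible(x)
}

#' @export
summary.ma_fit <- function(object, ...) {
  out <- c(mu = object$rate$mu, ci_low = object$rate$ci[1],
           ci_high = object$rate$ci[2], count = object$rate$count,
           exposure = object$rate$exposure)
  if (!is.null(object$U)) out <- c(out, U = object$U)
  if (!is.null(object$U_cds)) out <- c(out, U_cds = object$U_cds)
  if (!is.null(object$per_line))
    out <- c(out, mean_count = object$per_line$mean_count,
             sd_count = object$per_line$sd_count,
             het_chisq = object$per_line$chisq,
             het_p = object$per_line$p_value)
  out
}

#' @export
coef.ma_fit <- function(object, ...) c(mu = object$rate$mu)

#' @export
confint.ma_fit <- function(object, parm, level, ...) object$rate$ci

#' Per-line rates and among-line heterogeneity
#'
#' Per-line rates `mu_i = n_i / (ploidy * callable_i * gen_i)`, the mean
#' and sample SD (n-1 denominator) of per-line counts, and a Pearson
#' chi-square for rate heterogeneity across lines.  Expected counts are
#' either proportional to each line's exposure (`"exposure"`) or equal
#' across lines (`"equal"`); df = n - 1.
#'
#' @inheritParams ma_fit
#' @param expectation `"exposure"` or `"equal"`.
#' @return list with `rates` (data.frame line, n_mut, exposure, mu),
#'   `mean_count`, `sd_count`, `chisq`, `df`, `p_value`, `expectation`.
#' @export
per_line_rates <- function(experiment, ploidy = 2,
                           expectation = c("exposure", "equal")) {
  expectation <- match.arg(expectation)
  ex <- as.data.frame(experiment)
  if (nrow(ex) < 2L) stopf("need at least 2 lines")
  if (is.null(ex$n_mut)) stopf("experiment table lacks n_mut")
  w <- as.numeric(ex$callable_sites) * ex$generations
  if (any(w <= 0)) stopf("line with zero exposure")
  mu_i <- ex$n_mut / (ploidy * w)
  total <- sum(ex$n_mut)
  E <- if (expectation == "exposure") total * w / sum(w)
       else rep(total / nrow(ex), nrow(ex))
  chisq <- sum((ex$n_mut - E)^2 / E)
  df <- nrow(ex) - 1L
  list(rates = data.frame(line = ex$line, n_mut = ex$n_mut,
                          exposure = ploidy * w, mu = mu_i),
       mean_count = mean(ex$n_mut), sd_count = sd(ex$n_mut),
       chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE),
       expectation = expectation)
}

#' Organelle mutation rate
#'
#' Exposure for an organelle genome is `copy_number x organelle_length x
#' sum of generations`, where the copy number is the average number of
#' organelle genome copies per cell (see [estimate_copy_number()]).
#'
#' @param count organelle mutation count.
#' @param organelle_length organelle genome length in bp.
#' @param copy_number organelle genome copies per cell.
#' @param generations per-line generation counts (summed internally), or a
#'   single total.
#' @param level,method as in [rate_estimate()].
#' @param compartment label for the estimate.
#' @export
organelle_rate <- function(count, organelle_length, copy_number, generations,
                           level = 0.95, method = "garwood",
                           compartment = "organelle") {
  if (missing(copy_number) || is.null(copy_number) || !is.numeric(copy_number))
    stopf("copy number required")
  if (copy_number <= 0) stopf("copy number must be positive")
  exposure <- copy_number * organelle_length * sum(generations)
  rate_estimate(count, exposure, level = level, method = method,
                compartment = compartment)
}

#' Organelle genome copy number from relative coverage
#'
#' `copies = nuclear_ploidy * organelle_coverage / nuclear_coverage`.
#'
#' @param organelle_coverage,nuclear_coverage mean read coverages.
#' @param nuclear_ploidy nuclear ploidy (2 for a diploid).
#' @export
estimate_copy_number <- function(organelle_coverage, nuclear_coverage,
                                 nuclear_ploidy = 2) {
  if (nuclear_coverage <= 0) stopf("nuclear coverage must be positive")
  if (organelle_coverage <= 0) stopf("organelle coverage must be positive")
  nuclear_ploidy * organelle_coverage / nuclear_coverage
}

#' Compare two Poisson rates by 2x2 contingency chi-square
#'
#' Pearson chi-square without continuity correction on the table
#' `[[countA, exposureA - countA], [countB, exposureB - countB]]`, df = 1.
#'
#' @param a,b [rate_estimate()] objects.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
compare_rates <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  m <- rbind(c(a$count, a$exposure - a$count),
             c(b$count, b$exposure - b$count))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopf("degenerate 2x2 table (zero margin)")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
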