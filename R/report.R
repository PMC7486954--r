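#' Run the full MA analysis on an experiment's inputs
#'
#' Convenience driver tying the modules together: filters candidates (when
#' supplied), fits the mutation-rate model, summarises the spectrum and
#' derives the GC equilibrium, and computes the diversity-based effective
#' population size when `pi_s` is given.
#'
#' @param experiment an [experiment_table()]; when candidates are
#'   filtered, `n_mut` is recomputed from the accepted calls.
#' @param genome an `ma_genome` (used for spectrum site counts and effect
#'   classes), or a numeric GC fraction.
#' @param mutations data.frame of accepted mutations (`line`, `contig`,
#'   `pos`, `ref`, `alt`), or `NULL` to derive them from `calls`.
#' @param calls an `ma_calls` object (see [sim_variant_calls()]) to
#'   filter, or `NULL`.
#' @param params [filter_params()] used when filtering.
#' @param ploidy,genome_size,cds_size,level passed to [ma_fit()].
#' @param pi_s optional synonymous diversity for [ne_from_diversity()].
#' @return list of class `ma_analysis` with elements `fit`, `spectrum`,
#'   `gc_eq`, `effects`, `mutations`, `rejected`, `ne`.
#' @export
ma_analysis <- function(experiment, genome, mutations = NULL, calls = NULL,
                        params = filter_params(), ploidy = 2,
                        genome_size = NULL, cds_size = NULL, level = 0.95,
                        pi_s = NULL) {
  rejected <- NULL
  if (is.null(mutations)) {
    if (is.null(calls)) stopf("supply mutations or calls")
    fl <- filter_candidates(calls$candidates, params = params,
                            pileup = calls$pileup)
    mutations <- fl$accepted
    rejected <- fl$rejected
  }
  # the accepted calls are the counts the fit uses
  experiment$n_mut <- vapply(experiment$line,
                             function(l) sum(mutations$line == l), 1L)
  ann <- inherits(genome, "ma_genome") && !is.null(genome$annotation)
  mut_ann <- if (inherits(genome, "ma_genome"))
    annotate_mutations(mutations, genome) else mutations
  fit <- ma_fit(experiment, ploidy = ploidy, genome_size = genome_size,
                cds_size = cds_size, level = level)
  spec <- mutation_spectrum(mutations, genome)
  structure(list(fit = fit, spectrum = spec, gc_eq = spec$gc_eq,
                 effects = if (ann) effect_table(mut_ann) else NULL,
                 mutations = mut_ann, rejected = rejected,
                 ne = if (!is.null(pi_s))
                   ne_from_diversity(pi_s, fit$rate$mu) else NULL),
            class = "ma_analysis")
}

#' @export
print.ma_analysis <- function(x, ...) {
  print(x$fit)
  print(x$spectrum)
  if (!is.null(x$ne))
    cat(sprintf("  Ne (pi_s / 4 mu) = %s\n", format(x$ne, big.mark = ",")))
  invisible(x)
}

# scientific notation with 3 significant digits, e.g. 5.55e-10
fmt_rate <- function(x) formatC(x, format = "e", digits = 2)

#' Write the analysis report
#'
#' Writes a TSV of the headline quantities (deterministic column order,
#' rates in scientific notation with 3 significant digits) and a
#' human-readable summary alongside it (same path with extension
#' `.summary.txt`).
#'
#' @param results an `ma_analysis` (or a named list of numbers).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "ma_analysis")) {
    r <- results$fit$rate
    vals <- list(
      n_mutations = r$count,
      exposure_site_divisions = r$exposure,
      mu = fmt_rate(r$mu),
      ci_low = fmt_rate(r$ci[1]), ci_high = fmt_rate(r$ci[2]),
      U = if (!is.null(results$fit$U)) signif(results$fit$U, 2) else NA,
      U_cds = if (!is.null(results$fit$U_cds))
        signif(results$fit$U_cds, 2) else NA,
      n_at_gc = results$spectrum$n_at_gc,
      n_gc_at = results$spectrum$n_gc_at,
      bias_ratio = if (is.na(results$spectrum$ratio)) NA else
        signif(results$spectrum$ratio, 4),
      gc_eq_percent = if (is.na(results$gc_eq)) NA else
        round(100 * results$gc_eq, 2),
      k = if (is.na(results$spectrum$k)) NA else
        signif(results$spectrum$k, 3),
      ne = if (!is.null(results$ne)) signif(results$ne, 3) else NA)
    if (!is.null(results$effects))
      vals <- c(vals, as.list(setNames(as.integer(results$effects),
                                       paste0("effect_",
                                              names(results$effects)))))
  } else vals <- results
  df <- data.frame(quantity = names(vals),
                   value = vapply(vals, function(v) as.character(v %||% NA),
                                  ""))
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stopf("cannot write report to %s: %s", path,
                              conditionMessage(e)))
  txt <- sub("\\.tsv$", "", path)
  txt <- paste0(txt, ".summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(sprintf("%-26s %s", df$quantity, df$value), con)
  ma_log("write_report: %d quantities to %s", nrow(df), path)
  invisible(path)
}
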