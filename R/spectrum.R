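#' The six strand-symmetric mutation classes
#'
#' Pooled classes in the fixed order used throughout the package:
#' `AT_GC` (A:T->G:C, transition), `GC_AT` (G:C->A:T, transition),
#' `AT_TA`, `AT_CG`, `GC_TA`, `GC_CG` (transversions).
#' @export
spectrum_classes <- function() {
  c("AT_GC", "GC_AT", "AT_TA", "AT_CG", "GC_TA", "GC_CG")
}

# strand-symmetric folding: mutation ref>alt -> pooled class
fold_class <- function(ref, alt) {
  key <- paste0(ref, alt)
  map <- c(AG = "AT_GC", TC = "AT_GC", GA = "GC_AT", CT = "GC_AT",
           AT = "AT_TA", TA = "AT_TA", AC = "AT_CG", TG = "AT_CG",
           GT = "GC_TA", CA = "GC_TA", GC = "GC_CG", CG = "GC_CG")
  unname(map[key])
}

#' Summarise the mutation spectrum
#'
#' Classifies every mutation into one of the six pooled strand-symmetric
#' classes, counts G:C and A:T sites in the reference space, and derives
#' the conditional rates R1 (GC->AT) and R2 (AT->GC), the equilibrium GC
#' content and the transition/transversion ratio k.  Mutations with
#' ambiguous ref or alt bases are skipped with a warning count.
#'
#' @param mutations data.frame with columns `ref`, `alt`.
#' @param genome an `ma_genome`, or a numeric GC fraction of the reference
#'   space (callable masks refine the site counts without changing the
#'   formula).
#' @return object of class `spectrum_summary`: `counts` (6 classes),
#'   `n_skipped`, `gc_n`, `at_n`, `R1`, `R2`, `ratio` (R1/R2), `gc_eq`
#'   (fraction), `k` (NA when no transversions).
#' @export
mutation_spectrum <- function(mutations, genome) {
  ok <- mutations$ref %in% c("A", "C", "G", "T") &
    mutations$alt %in% c("A", "C", "G", "T") &
    mutations$ref != mutations$alt
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(sprintf("skipped %d records with ambiguous bases", n_skipped))
  m <- mutations[ok, , drop = FALSE]
  cls <- factor(fold_class(m$ref, m$alt), levels = spectrum_classes())
  counts <- setNames(as.integer(table(cls)), spectrum_classes())
  if (inherits(genome, "ma_genome")) {
    f <- base_counts(genome$seq)
    gc_n <- f[["G"]] + f[["C"]]; at_n <- f[["A"]] + f[["T"]]
  } else {
    gc <- as.numeric(genome)
    if (is.na(gc) || gc <= 0 || gc >= 1) stopf("GC fraction must be in (0,1)")
    gc_n <- gc; at_n <- 1 - gc
  }
  n_gc_at <- counts[["GC_AT"]] + counts[["GC_TA"]]
  n_at_gc <- counts[["AT_GC"]] + counts[["AT_CG"]]
  R1 <- n_gc_at / gc_n
  R2 <- n_at_gc / at_n
  ts <- counts[["AT_GC"]] + counts[["GC_AT"]]
  tv <- sum(counts) - ts
  structure(list(counts = counts, n_skipped = n_skipped,
                 gc_n = gc_n, at_n = at_n,
                 n_gc_at = n_gc_at, n_at_gc = n_at_gc,
                 R1 = R1, R2 = R2,
                 ratio = if (R2 > 0) R1 / R2 else NA_real_,
                 gc_eq = if (R1 + R2 > 0) R2 / (R1 + R2) else NA_real_,
                 k = if (tv > 0) ts / tv else NA_real_),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum (pooled strand-symmetric classes):\n")
  print(x$counts)
  cat(sprintf("  GC->AT: %d, AT->GC: %d\n", x$n_gc_at, x$n_at_gc))
  cat(sprintf("  R1/R2 = %s, GC_eq = %s, k (ts/tv) = %s\n",
              format(x$ratio, digits = 4),
              if (is.na(x$gc_eq)) "NA" else sprintf("%.2f%%", 100 * x$gc_eq),
              if (is.na(x$k)) "undefined (no transversions)"
              else format(x$k, digits = 3)))
  if (x$n_skipped) cat(sprintf("  (%d ambiguous records skipped)\n",
                               x$n_skipped))
  invisible(x)
}

#' Exact binomial test for GC bias of the mutation spectrum
#'
#' Two-sided exact binomial test of `n_at_gc` vs `n_gc_at` at probability
#' 0.5 (the two-sided p sums the probabilities of all outcomes no more
#' likely than the observed one).
#'
#' @param n_at_gc,n_gc_at pooled AT->GC and GC->AT mutation counts.
#' @return list with `p_value`, `estimate` (AT->GC fraction).
#' @export
gc_bias_test <- function(n_at_gc, n_gc_at) {
  if (n_at_gc < 0 || n_gc_at < 0 || n_at_gc + n_gc_at == 0)
    stopf("need non-negative counts, not both zero")
  bt <- binom.test(n_at_gc, n_at_gc + n_gc_at, p = 0.5)
  list(p_value = bt$p.value, estimate = unname(bt$estimate))
}

#' Conditional mutation rates R1 and R2
#'
#' `R1` is the GC->AT rate per G:C site and `R2` the AT->GC rate per A:T
#' site: `R1 = n_gc_at / gc`, `R2 = n_at_gc / (1 - gc)` (up to a common
#' proportionality constant that cancels from every downstream quantity).
#'
#' @param n_gc_at,n_at_gc pooled mutation counts.
#' @param gc genomic GC fraction, in (0,1).
#' @return list with `R1`, `R2`, `ratio` = R1/R2 (unrounded).
#' @export
conditional_rates <- function(n_gc_at, n_at_gc, gc) {
  if (gc <= 0 || gc >= 1) stopf("GC fraction must be in (0,1)")
  R1 <- n_gc_at / gc
  R2 <- n_at_gc / (1 - gc)
  list(R1 = R1, R2 = R2, ratio = if (R2 > 0) R1 / R2 else NA_real_)
}

#' Equilibrium GC content
#'
#' The GC fraction at which GC->AT and AT->GC mutation fluxes balance:
#' `GC_eq = R2 / (R1 + R2)`.
#'
#' @param R1,R2 conditional rates from [conditional_rates()].
#' @return equilibrium GC fraction in `[0, 1]`.
#' @export
equilibrium_gc <- function(R1, R2) {
  if (R1 < 0 || R2 < 0 || R1 + R2 <= 0) stopf("need R1 + R2 > 0")
  R2 / (R1 + R2)
}

#' Forward-simulate GC content under conditional rates
#'
#' Evolves the G:C site count of a sequence of `length` sites through
#' `n_events` single-site mutation events, each event flipping a G:C site
#' to A:T with probability proportional to `gc_sites * R1` and an A:T site
#' to G:C with probability proportional to `at_sites * R2`.  The realized
#' GC fraction converges to [equilibrium_gc()].
#'
#' @param R1,R2 conditional rates (any common scale).
#' @param length number of sites.
#' @param n_events number of mutation events.
#' @param gc0 starting GC fraction.
#' @return final GC fraction.
#' @export
evolve_gc <- function(R1, R2, length = 1e5, n_events = 1e6, gc0 = 0.5) {
  x <- round(gc0 * length)
  u <- runif(n_events)
  for (i in seq_len(n_events)) {
    p_loss <- x * R1 / (x * R1 + (length - x) * R2)
    x <- if (u[i] < p_loss) x - 1L else x + 1L
  }
  x / length
}

#' CpG dinucleotide and CpG-mutation analysis
#'
#' Counts CpG dinucleotides over all overlapping dinucleotide positions per
#' contig (no wrap-around) and compares the observed fraction with the
#' expectation `(GC/2)^2` under base independence with equal C and G
#' frequencies.  At the mutation level, compares the fraction of G:C-site
#' mutations occurring in CpG context (the mutated base is the C of a CG
#' dinucleotide on either strand, i.e. destroys a CpG) with the fraction
#' of genomic G:C sites in CpG context.  Both comparisons are chi-square
#' tests with df = 1.
#'
#' @param genome an `ma_genome`.
#' @param mutations optional annotated mutations ([annotate_mutations()]);
#'   omit for the genome-level analysis only.
#' @return list with `cpg_fraction`, `expected_fraction`, `chisq_genome`,
#'   `p_genome`, and (with mutations) `mut_cpg_fraction`,
#'   `mut_expected_fraction`, `chisq_mut`, `p_mut`.
#' @export
cpg_analysis <- function(genome, mutations = NULL) {
  seqs <- genome$seq
  din_total <- 0; n_cpg <- 0
  gc_sites <- 0; gc_in_cpg <- 0
  for (s in seqs) {
    L <- nchar(s)
    if (L < 2L) next
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    nxt <- c(b[-1L], "N"); prv <- c("N", b[-L])
    is_cg <- b == "C" & nxt == "G"
    din_total <- din_total + (L - 1L)
    n_cpg <- n_cpg + sum(is_cg)
    in_ctx <- (b == "C" & nxt == "G") | (b == "G" & prv == "C")
    gc_sites <- gc_sites + sum(b %in% c("C", "G"))
    gc_in_cpg <- gc_in_cpg + sum(in_ctx)
  }
  gc <- gc_content(genome)
  p0 <- (gc / 2)^2
  obs <- n_cpg / din_total
  chi_g <- (n_cpg - din_total * p0)^2 / (din_total * p0) +
    ((din_total - n_cpg) - din_total * (1 - p0))^2 / (din_total * (1 - p0))
  out <- list(cpg_fraction = obs, expected_fraction = p0,
              chisq_genome = chi_g,
              p_genome = pchisq(chi_g, 1, lower.tail = FALSE))
  if (!is.null(mutations) && nrow(mutations)) {
    m <- mutations[mutations$ref %in% c("C", "G"), , drop = FALSE]
    n_mut_cpg <- sum(m$cpg)
    p_site <- gc_in_cpg / gc_sites
    n <- nrow(m)
    chi_m <- if (n > 0) {
      (n_mut_cpg - n * p_site)^2 / (n * p_site) +
        ((n - n_mut_cpg) - n * (1 - p_site))^2 / (n * (1 - p_site))
    } else NA_real_
    out$mut_cpg_fraction <- if (n > 0) n_mut_cpg / n else NA_real_
    out$mut_expected_fraction <- p_site
    out$chisq_mut <- chi_m
    out$p_mut <- if (is.na(chi_m)) NA_real_
                 else pchisq(chi_m, 1, lower.tail = FALSE)
  }
  out
}

#' Binomial test of coding vs noncoding mutation counts
#'
#' Exact binomial test of the observed number of coding mutations against
#' the expectation given the proportion of callable coding sites.
#'
#' @param n_coding,n_total observed coding and total mutation counts.
#' @param coding_sites,noncoding_sites callable site counts.
#' @return list with `p_value`, `expected` (expected coding count), `p0`.
#' @export
coding_noncoding_test <- function(n_coding, n_total, coding_sites,
                                  noncoding_sites) {
  if (n_coding < 0 || n_total < n_coding) stopf("invalid counts")
  p0 <- coding_sites / (coding_sites + noncoding_sites)
  bt <- binom.test(n_coding, n_total, p = p0)
  list(p_value = bt$p.value, expected = n_total * p0, p0 = p0)
}
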