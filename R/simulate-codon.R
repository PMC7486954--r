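#' Simulate codon usage and expression under mutation-selection-drift
#'
#' Generates CDS sequences whose synonymous-codon usage follows the
#' two-state mutation-selection-drift equilibrium: within each synonymous
#' family the preferred (GC-ending) codon is used with probability `P`
#' satisfying `P/(1-P) = exp(S)/b`, where `b` is the GC->AT / AT->GC
#' mutation-bias ratio.  Genes in the highly expressed stratum use
#' `S = S_true`; the rest use `S = 0` (mutation bias only).  Expression
#' values are log-normal with a higher location for the high stratum, so
#' ranking genes by expression recovers it.
#'
#' @param config a [sim_config()]; uses `S_true`, `bias_ratio`,
#'   `high_frac`, `n_genes`, `mean_cds_length`.
#' @param n_genes,n_codons optional overrides of gene number and
#'   per-gene codon count.
#' @return list of class `ma_codon_sim`: `cds` (named character vector),
#'   `expression` (data.frame gene_id, fpkm, high), `preferred` (planted
#'   preferred-codon map), `p_high`, `p_low`.
#' @export
sim_codon_usage <- function(config = sim_config(), n_genes = NULL,
                            n_codons = NULL) {
  sim_seed(config, 5L)
  if (!is.finite(config$S_true)) stopf("S_true must be finite")
  if (config$bias_ratio <= 0) stopf("bias ratio must be positive")
  n_genes <- n_genes %||% config$n_genes
  n_codons <- n_codons %||% max(10L, round(config$mean_cds_length / 3))
  b <- config$bias_ratio
  odds <- function(S) exp(S) / b
  p_high <- odds(config$S_true) / (1 + odds(config$S_true))
  p_low <- odds(0) / (1 + odds(0))
  ids <- sprintf("g%03d", seq_len(n_genes))
  n_high <- max(1L, round(config$high_frac * n_genes))
  high <- c(rep(TRUE, n_high), rep(FALSE, n_genes - n_high))
  cds <- setNames(character(n_genes), ids)
  for (i in seq_len(n_genes)) {
    body <- sample_codons(n_codons - 2L,
                          S = if (high[i]) config$S_true else 0, b = b)
    cds[i] <- paste0("ATG", paste(body, collapse = ""),
                     sample(c("TAA", "TAG", "TGA"), 1L))
  }
  fpkm <- rlnorm(n_genes, meanlog = ifelse(high, 5, 1), sdlog = 1)
  expression <- data.frame(gene_id = ids, fpkm = fpkm, high = high,
                           stringsAsFactors = FALSE)
  structure(list(cds = cds, expression = expression,
                 preferred = preferred_codon_map(),
                 p_high = p_high, p_low = p_low),
            class = "ma_codon_sim")
}
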