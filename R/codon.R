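# standard genetic code helpers -------------------------------------------

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

# amino acid of each sense codon
codon_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  code[code != "*"]
}

# synonymous-family degeneracy per amino acid (standard code):
# 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold; Met/Trp single
aa_degeneracy <- function() {
  aa <- codon_aa()
  tab <- table(aa)
  setNames(as.integer(tab), names(tab))
}

#' The eight two-codon amino acids used for selection-strength estimation
#'
#' Phe, Tyr, His, Gln, Asn, Lys, Asp, Glu: the two-fold degenerate amino
#' acids (excluding Cys) whose synonym pairs differ only at a GC-vs-AT
#' third position, so their codon usage responds directly to the
#' GC-AT mutation bias.
#' @export
twofold_aa_set <- function() c("F", "Y", "H", "Q", "N", "K", "D", "E")

#' Per-gene codon usage from CDS sequences
#'
#' Counts the 61 sense codons of each start-to-stop reading frame (the
#' terminal stop codon is excluded) and computes GC3s, the GC fraction at
#' third positions of codons belonging to synonymous families (Met, Trp
#' and stop codons excluded).  Genes containing an internal stop codon are
#' flagged and excluded from ENC averaging.
#'
#' @param cds named character vector (or `DNAStringSet`) of CDS sequences;
#'   each length must be divisible by 3.
#' @return object of class `codon_usage`: `counts` (gene x 61 matrix),
#'   `gc3s` (per gene), `gc3s_pooled`, `n_codons`, `internal_stop`.
#' @export
codon_usage <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  cds <- toupper(cds)
  if (is.null(names(cds))) names(cds) <- paste0("g", seq_along(cds))
  bad <- nchar(cds) %% 3L != 0L
  if (any(bad))
    stopf("CDS length of '%s' is not divisible by 3", names(cds)[bad][1L])
  code <- Biostrings::GENETIC_CODE
  sc <- sense_codons()
  aa <- codon_aa()
  deg <- aa_degeneracy()
  syn_codons <- sc[deg[aa] >= 2L]       # codons of synonymous families
  counts <- matrix(0L, length(cds), length(sc),
                   dimnames = list(names(cds), sc))
  gc3s <- n_codons <- numeric(length(cds))
  internal_stop <- logical(length(cds))
  g3 <- g3n <- 0
  for (i in seq_along(cds)) {
    s <- cds[[i]]
    cod <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                     seq(3L, nchar(s), by = 3L))
    is_stop <- code[cod] == "*"
    is_stop[is.na(is_stop)] <- FALSE    # codons with N: not counted below
    if (any(is_stop[-length(cod)])) {
      internal_stop[i] <- TRUE
      warning(sprintf("internal stop codon in gene '%s'; excluded from ENC",
                      names(cds)[i]))
    }
    cod <- cod[!is_stop]
    cod <- cod[cod %in% sc]
    t <- table(factor(cod, levels = sc))
    counts[i, ] <- as.integer(t)
    n_codons[i] <- length(cod)
    syn <- cod[cod %in% syn_codons]
    third <- substr(syn, 3L, 3L)
    gc3s[i] <- if (length(third)) mean(third %in% c("G", "C")) else NA_real_
    g3 <- g3 + sum(third %in% c("G", "C")); g3n <- g3n + length(third)
  }
  structure(list(counts = counts, gc3s = gc3s,
                 gc3s_pooled = if (g3n > 0) g3 / g3n else NA_real_,
                 n_codons = n_codons, internal_stop = internal_stop),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage: %d genes, %s codons, pooled GC3s = %.1f%%\n",
              nrow(x$counts), format(sum(x$n_codons), big.mark = ","),
              100 * x$gc3s_pooled))
  invisible(x)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC per gene.  For an amino acid with `k` synonyms and `n`
#' observed codons with frequencies `p_i`, the homozygosity estimate is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` (defined for `n >= 2`).  ENC is
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with `Fk` the mean of `F` over amino
#' acids of degeneracy `k`; a missing three-fold average (Ile unobserved)
#' is imputed as the mean of the two-fold and four-fold averages.  The
#' result is capped at 61; genes where any family average is undefined and
#' unimputable get `NA`.  A gene observed at fewer than `min_codons`
#' codons is flagged low-confidence via the `"low_confidence"` attribute.
#'
#' @param usage a [codon_usage()] object or a gene x 61 count matrix.
#' @param min_codons threshold for the low-confidence flag.
#' @return named numeric vector of per-gene ENC values in `[20, 61]`
#'   (NA for genes with internal stops or undefined families).
#' @export
enc <- function(usage, min_codons = 100L) {
  counts <- if (inherits(usage, "codon_usage")) usage$counts else usage
  if (is.null(dim(counts))) counts <- matrix(counts, 1L,
                                             dimnames = list("g1", names(counts)))
  aa <- codon_aa()[colnames(counts)]
  deg <- aa_degeneracy()
  skip <- if (inherits(usage, "codon_usage")) usage$internal_stop
          else rep(FALSE, nrow(counts))
  out <- setNames(rep(NA_real_, nrow(counts)), rownames(counts))
  for (i in seq_len(nrow(counts))) {
    if (skip[i]) next
    Fhat <- c()
    for (a in names(deg)[deg >= 2L]) {
      n_a <- counts[i, aa == a]
      n <- sum(n_a)
      if (n >= 2L) {
        p <- n_a / n
        Fhat[a] <- (n * sum(p^2) - 1) / (n - 1)
      }
    }
    fam_mean <- function(k) {
      v <- Fhat[names(Fhat) %in% names(deg)[deg == k]]
      v <- v[v > 0]
      if (length(v)) mean(v) else NA_real_
    }
    F2 <- fam_mean(2L); F3 <- fam_mean(3L)
    F4 <- fam_mean(4L); F6 <- fam_mean(6L)
    if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- mean(c(F2, F4))
    if (anyNA(c(F2, F3, F4, F6))) next
    out[i] <- min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
  }
  n_cod <- if (inherits(usage, "codon_usage")) usage$n_codons
           else rowSums(counts)
  attr(out, "low_confidence") <- n_cod < min_codons
  out
}

#' Identify preferred codons from codon-usage contrast
#'
#' Genes are ranked by ENC (ascending: most biased first); the top and
#' bottom `tail` fractions form the high- and low-bias gene sets.  For
#' each amino acid with >= 2 synonyms, a two-way chi-square contingency
#' test (codon x set) is run on the pooled counts; when significant at
#' `alpha`, the codon enriched in the high-bias set is called preferred.
#' Amino acids without a significant or unique winner get no preferred
#' codon.
#'
#' @param usage a [codon_usage()] object.
#' @param tail fraction of genes in each tail.
#' @param alpha significance level for the contingency test.
#' @return named character vector mapping amino acid (one-letter) to its
#'   preferred codon.
#' @export
identify_preferred_codons <- function(usage, tail = 0.05, alpha = 0.01) {
  e <- enc(usage)
  ok <- !is.na(e)
  if (sum(ok) < 20L) stopf("need at least 20 genes with defined ENC")
  e <- e[ok]
  counts <- usage$counts[ok, , drop = FALSE]
  n_tail <- max(1L, floor(length(e) * tail))
  ord <- order(e)
  hi <- counts[ord[seq_len(n_tail)], , drop = FALSE]           # most biased
  lo <- counts[ord[seq(length(e) - n_tail + 1L, length(e))], , drop = FALSE]
  aa <- codon_aa()[colnames(counts)]
  pref <- character(0)
  for (a in unique(aa)) {
    if (sum(aa == a) < 2L) next
    h <- colSums(hi[, aa == a, drop = FALSE])
    l <- colSums(lo[, aa == a, drop = FALSE])
    if (sum(h) == 0 || sum(l) == 0) next
    tab <- rbind(h, l)
    keep <- colSums(tab) > 0
    if (sum(keep) < 2L) next
    p <- suppressWarnings(chisq.test(tab[, keep, drop = FALSE])$p.value)
    if (is.na(p) || p >= alpha) next
    dprop <- h / sum(h) - l / sum(l)
    best <- which(dprop == max(dprop))
    if (length(best) != 1L) next
    pref[a] <- names(h)[best]
  }
  pref
}

#' Frequency of optimal codons (Fop)
#'
#' `Fop` is the number of codons that are the preferred synonym divided by
#' the number of codons of amino acids that have a preferred codon, pooled
#' over a gene subset.
#'
#' @param usage a [codon_usage()] object.
#' @param preferred named character vector from
#'   [identify_preferred_codons()] (names: amino acids, values: codons).
#' @param genes optional character vector of gene ids (e.g. the top-N
#'   genes by expression); default all genes.
#' @param expression optional expression table (`gene_id`, `fpkm`) used
#'   with `top_n` to select the most expressed genes.
#' @param top_n number of top-expression genes when `expression` is given.
#' @return Fop in `[0, 1]`.
#' @export
fop <- function(usage, preferred, genes = NULL, expression = NULL,
                top_n = 500L) {
  if (!length(preferred)) stopf("preferred codon set is empty")
  if (!is.null(expression)) {
    expression <- expression[order(-expression$fpkm), ]
    genes <- head(expression$gene_id, top_n)
  }
  counts <- usage$counts
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(counts))
    if (!length(genes)) stopf("gene subset is empty")
    counts <- counts[genes, , drop = FALSE]
  }
  aa <- codon_aa()[colnames(counts)]
  in_family <- aa %in% names(preferred)
  denom <- sum(counts[, in_family])
  if (denom == 0) stopf("no codons in amino acids with a preferred codon")
  num <- sum(counts[, colnames(counts) %in% preferred, drop = FALSE])
  num / denom
}

#' Strength of selected codon usage bias (S)
#'
#' Under the mutation-selection-drift equilibrium for a two-codon amino
#' acid whose preferred codon is GC-ending, the equilibrium frequency P of
#' the preferred codon satisfies `P/(1-P) = exp(S) / b`, where
#' `b = mu_GC->AT / mu_AT->GC` is the mutation-bias ratio (R1/R2) and
#' `S = 4 Ne s` is the scaled selection coefficient.  Inverting:
#' `S = log( (Fop/(1-Fop)) * b )`.
#'
#' @param fop pooled frequency of optimal codons, in (0,1).
#' @param bias_ratio the unrounded conditional-rate ratio R1/R2 from
#'   [conditional_rates()].
#' @return S (dimensionless).
#' @export
selection_strength <- function(fop, bias_ratio) {
  if (!is.numeric(fop) || fop <= 0 || fop >= 1)
    stopf("Fop must be strictly between 0 and 1")
  if (bias_ratio <= 0) stopf("bias ratio must be positive")
  log(fop / (1 - fop) * bias_ratio)
}

#' Long-term effective population size from codon bias
#'
#' `Ne = S / (4 s)` given the selective advantage `s` of preferred over
#' unpreferred codons (typically assumed of the order 1e-6 to 1e-7).
#'
#' @param S strength of selected codon usage bias.
#' @param s selective advantage per codon.
#' @export
ne_from_codon_bias <- function(S, s) {
  if (s <= 0) stopf("s must be positive")
  S / (4 * s)
}
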