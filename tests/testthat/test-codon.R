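# Codon usage, ENC, preferred codons, Fop and selection strength

test_that("codon counting excludes stops and computes GC3s over synonymous families", {
  u <- codon_usage(c(g1 = "ATGTTTTAA"))
  expect_equal(unname(u$counts["g1", "ATG"]), 1L)
  expect_equal(unname(u$counts["g1", "TTT"]), 1L)
  expect_equal(sum(u$counts), 2L)          # TAA not counted
  expect_equal(u$n_codons, 2)
  expect_equal(u$gc3s, 0)                  # only TTT is in a synonymous family
  # all-GC-ending synonymous codons
  u2 <- codon_usage(c(g1 = codon_cds(rep(c("TTC", "GGC", "CTG"), 5))))
  expect_equal(u2$gc3s, 1)
  expect_error(codon_usage(c(g1 = "ATGT")), "divisible")
})

test_that("internal stop codons flag the gene and exclude it from ENC", {
  expect_warning(u <- codon_usage(c(g1 = "ATGTAATTTTAA")), "internal stop")
  expect_true(u$internal_stop[1])
  expect_true(is.na(enc(u)[1]))
})

test_that("ENC is 20 for single-codon usage and approaches 61 for uniform usage", {
  # two copies of one codon per amino acid: F = 1 in every family
  one_per_aa <- c("TTT", "TAT", "CAT", "CAA", "AAT", "AAA", "GAT", "GAA",
                  "TGT", "ATT", "GTT", "CCT", "ACT", "GCT", "GGT", "CTT",
                  "TCT", "CGT")
  u <- codon_usage(c(g1 = codon_cds(rep(one_per_aa, 2))))
  expect_equal(unname(enc(u)["g1"]), 20)
  # uniform usage across all 61 sense codons, large n
  sc <- mutacc:::sense_codons()
  u61 <- codon_usage(c(g1 = codon_cds(rep(sc[sc != "ATG"], 170), "ATG")))
  e61 <- enc(u61)
  expect_gt(unname(e61["g1"]), 60.5)
  expect_lte(unname(e61["g1"]), 61)
})

test_that("ENC matches an independent transcription of Wright's formula", {
  set.seed(14)
  cs <- sim_codon_usage(sim_config(seed = 14), n_genes = 6, n_codons = 150)
  u <- codon_usage(cs$cds)
  code <- Biostrings::GENETIC_CODE
  aa_of <- code[code != "*"]
  oracle <- vapply(rownames(u$counts), function(g) {
    x <- u$counts[g, ]
    fam <- split(x, aa_of[names(x)])
    deg <- vapply(fam, length, 1L)
    Fh <- vapply(fam, function(v) {
      n <- sum(v)
      if (n < 2) return(NA_real_)
      (n * sum((v / n)^2) - 1) / (n - 1)
    }, 1)
    avg <- function(k) {
      v <- Fh[deg[names(Fh)] == k]
      v <- v[!is.na(v) & v > 0]
      if (!length(v)) NA_real_ else mean(v)
    }
    F2 <- avg(2); F3 <- avg(3); F4 <- avg(4); F6 <- avg(6)
    if (is.na(F3)) F3 <- mean(c(F2, F4))
    min(2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6, 61)
  }, 1)
  expect_equal(unname(enc(u)), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ENC stays within [20, 61] and flags short genes", {
  set.seed(15)
  cs <- sim_codon_usage(sim_config(seed = 15), n_genes = 10, n_codons = 500)
  u <- codon_usage(cs$cds)
  e <- enc(u)
  expect_true(all(e[!is.na(e)] >= 20 & e[!is.na(e)] <= 61))
  expect_false(any(attr(e, "low_confidence")))
  short <- codon_usage(c(g1 = codon_cds(rep("TTC", 8))))
  expect_true(attr(enc(short), "low_confidence")[1])
})

test_that("preferred codons are recovered exactly from planted usage", {
  cfg <- sim_config(S_true = 1.5, bias_ratio = 0.4, high_frac = 0.5,
                    seed = 16)
  cs <- sim_codon_usage(cfg, n_genes = 300, n_codons = 300)
  u <- codon_usage(cs$cds)
  pref <- identify_preferred_codons(u)
  planted <- cs$preferred
  expect_identical(pref[order(names(pref))],
                   planted[order(names(planted))])
  # recovered preferred codons end in G or C
  expect_true(all(substr(pref, 3, 3) %in% c("G", "C")))
})

test_that("identical usage in both tails yields no preferred codons", {
  one <- codon_cds(rep(c("TTT", "TTC", "AAA", "AAG", "GGC", "GGA",
                         "ATT", "ATC", "CTG", "CTA"), 15))
  u <- codon_usage(setNames(rep(one, 25), paste0("g", 1:25)))
  expect_length(identify_preferred_codons(u), 0)
  expect_error(identify_preferred_codons(
    codon_usage(setNames(rep(one, 5), paste0("g", 1:5)))), "20 genes")
})

test_that("Fop obeys its boundary cases and is invariant to gene order", {
  pref <- c(F = "TTC", K = "AAG")
  all_pref <- codon_usage(c(g1 = codon_cds(rep(c("TTC", "AAG"), 10))))
  expect_equal(fop(all_pref, pref), 1)
  half <- codon_usage(c(g1 = codon_cds(rep(c("TTC", "TTT", "AAG", "AAA"), 10))))
  expect_equal(fop(half, pref), 0.5)
  set.seed(17)
  cs <- sim_codon_usage(sim_config(seed = 17), n_genes = 30, n_codons = 100)
  u <- codon_usage(cs$cds)
  ids <- rownames(u$counts)
  expect_equal(fop(u, pref, genes = ids), fop(u, pref, genes = rev(ids)))
  expect_error(fop(u, character(0)), "empty")
})

test_that("selection strength inverts the equilibrium odds", {
  cr <- conditional_rates(151, 207, 0.657)
  expect_equal(round(selection_strength(0.8859, cr$ratio), 3), 1.084)
  # neutrality: odds equal to 1/b gives S = 0
  b <- 0.4
  expect_equal(selection_strength(1 / (1 + b), b), 0, tolerance = 1e-12)
  expect_error(selection_strength(1, 0.4), "between 0 and 1")
  expect_error(selection_strength(0.5, 0), "positive")
})

test_that("simulation and estimation of S are mutual inverses", {
  cfg <- sim_config(S_true = 1.5, bias_ratio = 0.4, high_frac = 1, seed = 18)
  cs <- sim_codon_usage(cfg, n_genes = 40, n_codons = 1500)
  u <- codon_usage(cs$cds)
  f <- fop(u, cs$preferred[twofold_aa_set()])
  S_hat <- selection_strength(f, 0.4)
  expect_lt(abs(S_hat - 1.5), 0.1)   # ~24k two-fold codons of Monte-Carlo error
})

test_that("Ne from codon bias is S over 4s", {
  expect_equal(ne_from_codon_bias(1.084, 1e-7), 2710000)
  expect_equal(ne_from_codon_bias(1.084, 1e-6), 271000)
  expect_equal(ne_from_codon_bias(0, 1e-7), 0)
  expect_error(ne_from_codon_bias(1, 0), "positive")
})
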