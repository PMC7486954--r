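# Synthetic MA-experiment generator

test_that("genome generation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 2e4, n_genes = 3, seed = 1)
  g1 <- sim_genome(cfg)
  g2 <- sim_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$annotation$features, g2$annotation$features)
})

test_that("realized GC is within half a percentage point of target at 100 kb", {
  cfg <- sim_config(genome_length = 1e5, gc = 0.657, n_genes = 0, seed = 2)
  g <- sim_genome(cfg)
  expect_gte(gc_content(g), 0.652)
  expect_lte(gc_content(g), 0.662)
})

test_that("a zero-gene genome has no annotation and analyses still run", {
  cfg <- sim_config(genome_length = 1e4, n_genes = 0, mu = 1e-5,
                    n_lines = 3, seed = 3)
  g <- sim_genome(cfg)
  expect_null(g$annotation)
  tr <- sim_ma_lines(g, cfg)
  m <- annotate_mutations(tr$mutations, g)
  expect_true(all(m$effect == "intergenic"))
})

test_that("gene models that cannot be placed raise a sizing error", {
  cfg <- sim_config(genome_length = 3e3, n_genes = 3,
                    mean_cds_length = 3000, seed = 1)
  expect_error(sim_genome(cfg), "cannot place")
})

test_that("mutation counts are Poisson with mean ploidy x L x gen x mu", {
  cfg <- sim_config(genome_length = 1e6, n_genes = 0, n_lines = 15,
                    generations = 200, mu = 1e-7, seed = 4)
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  # expected total 2 * 1e6 * 200 * 15 * 1e-7 = 600, sd sqrt(600)
  expect_lt(abs(nrow(tr$mutations) - 600), 3 * sqrt(600))
  expect_equal(sum(tr$experiment$n_mut), nrow(tr$mutations))
  # positions unique within a line, ref matches genome
  by_line <- split(tr$mutations$pos, tr$mutations$line)
  expect_true(all(vapply(by_line, anyDuplicated, 1L) == 0L))
  expect_identical(base_at(g, tr$mutations$contig, tr$mutations$pos),
                   tr$mutations$ref)
})

test_that("mu = 0 yields no mutations and saturation triggers a warning", {
  cfg0 <- sim_config(genome_length = 1e4, n_genes = 0, mu = 0, seed = 5)
  g <- sim_genome(cfg0)
  expect_equal(nrow(sim_ma_lines(g, cfg0)$mutations), 0L)

  cfg_sat <- sim_config(genome_length = 1e4, n_genes = 0, mu = 1e-3,
                        n_lines = 5, seed = 5)
  expect_warning(sim_ma_lines(g, cfg_sat), "infinite-sites")
})

test_that("spectrum weights condition on the ref base", {
  # zero weight on all G:C-origin classes: no mutations at G/C sites
  cfg <- sim_config(genome_length = 5e4, n_genes = 0, mu = 2e-6,
                    spectrum = c(AT_GC = 2, GC_AT = 0, AT_TA = 1,
                                 AT_CG = 1, GC_TA = 0, GC_CG = 0),
                    seed = 6)
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  expect_gt(nrow(tr$mutations), 50)
  expect_true(all(tr$mutations$ref %in% c("A", "T")))
})

test_that("pooled class counts converge to the configured weights", {
  cfg <- sim_config(genome_length = 2e5, n_genes = 0, mu = 1e-6, seed = 7)
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  sp <- mutation_spectrum(tr$mutations, g)
  expect_gt(sum(sp$counts), 500)
  p <- cfg$spectrum / sum(cfg$spectrum)
  gof <- chisq.test(sp$counts, p = p)
  expect_gt(gof$p.value, 0.01)
  # conditional-rate ratio near the configured reference value
  expect_lt(abs(sp$ratio - 0.381), 0.12)
})

test_that("variant synthesis reproduces truth and labels artifacts", {
  cfg <- sim_config(genome_length = 3e4, n_genes = 0, n_lines = 5,
                    mu = 1e-6, seed = 8,
                    artifact_rates = c(low_mapping_quality = 5, low_depth = 5,
                                       high_depth = 5, low_alt_fraction = 5,
                                       near_indel = 5, ancestral_allele = 5))
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  calls <- sim_variant_calls(g, tr, cfg)
  # every true mutation is a candidate with alt support in its line
  key <- function(d) paste(d$contig, d$pos, d$alt)
  s <- calls$candidates$sites
  idx <- match(key(tr$mutations), key(s))
  expect_false(anyNA(idx))
  for (i in seq_len(nrow(tr$mutations))) {
    ln <- tr$mutations$line[i]
    expect_gt(calls$candidates$ad[idx[i], ln], 0)
  }
  # audit table classes are Poisson around their configured means
  tab <- table(factor(calls$audit$class, levels = names(cfg$artifact_rates)))
  expect_true(all(abs(tab - 5) <= 3 * sqrt(5) + 1))
  # byte-identical VCF under the same seed
  calls2 <- sim_variant_calls(g, tr, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf_candidates(calls$candidates, f1, indels = calls$indels)
  write_vcf_candidates(calls2$candidates, f2, indels = calls2$indels)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("codon-usage generator hits the closed-form equilibrium", {
  # S = 0, b = 1: preferred and unpreferred equally likely
  cfg0 <- sim_config(S_true = 0, bias_ratio = 1, seed = 9)
  cs0 <- sim_codon_usage(cfg0, n_genes = 5, n_codons = 50)
  expect_equal(cs0$p_high, 0.5)
  # published-scale check: S = 1.084 with b = 0.38083 gives P = 0.8859
  cfg1 <- sim_config(S_true = 1.084, bias_ratio = 0.38083, seed = 9)
  cs1 <- sim_codon_usage(cfg1, n_genes = 40, n_codons = 500)
  expect_equal(cs1$p_high, exp(1.084) / 0.38083 / (1 + exp(1.084) / 0.38083))
  expect_equal(round(cs1$p_high, 4), 0.8859)
  # empirical preferred-codon frequency in the high stratum matches P
  u <- codon_usage(cs1$cds)
  high <- cs1$expression$gene_id[cs1$expression$high]
  f <- fop(u, cs1$preferred[twofold_aa_set()], genes = high)
  expect_lt(abs(f - cs1$p_high), 0.02)
})

test_that("growth trajectories follow bottlenecked exponential doubling", {
  cfg <- sim_config(n_lines = 2, cycles = 3, divisions_per_day = 1.17,
                    division_sd = 0, seed = 10)
  cc <- sim_cell_counts(cfg)
  one <- cc[cc$line == "L01" & cc$cycle == 1, ]
  expect_equal(one$count, 2^(1.17 * (0:13)))
  # every cycle restarts from a single founding cell
  expect_true(all(cc$count[cc$day == 0] == 1))
  # transfer-count census recovers the division rate
  est <- estimate_generations(2^(1.17 * 14), days = 14)
  expect_equal(est$divisions_per_day, 1.17)
  # jittered rates recover the planted mean
  cfg2 <- sim_config(n_lines = 15, cycles = 14, division_sd = 0.02, seed = 10)
  cc2 <- sim_cell_counts(cfg2)
  expect_lt(abs(mean(attr(cc2, "rates")$rate) - 1.17), 0.01)
})
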