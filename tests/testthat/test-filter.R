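# Callable-site definition, acceptance criteria and effect classification

test_that("callable sites require MQ >= 20 and depth within [20, 150] in both samples", {
  depth <- cbind(anc = c(30, 30, 30, 30, 19, 150, 151),
                 L1  = c(30, 19, 151, 150, 30, 150, 30))
  mq <- c(60, 60, 60, 60, 60, 20, 19)
  pu <- ma_pileup(list(c1 = mq), list(c1 = depth), ancestor = "anc")
  m <- callable_mask(pu, "L1")
  expect_identical(unname(m$c1),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(m, "callable"), 3)
  expect_equal(unname(callable_counts(pu)), 3)
})

test_that("acceptance boundaries are exact: alt fraction 1/3 in, indel gap 5 out, depth 150 in", {
  cand <- make_candidates(data.frame(
    line = "L1",
    pos = c(10, 20, 30, 40, 50, 60, 70),
    ref = "A", alt = "G",
    dp = c(30, 30, 150, 30, 30, 30, 30),
    ad = c(10, 9, 50, 15, 15, 15, 15),
    indel_dist = c(Inf, Inf, Inf, 5, 6, Inf, Inf),
    anc_ad = c(0, 0, 0, 0, 0, 4, 0),
    other_ad = c(0, 0, 0, 0, 0, 0, 4)))
  fl <- filter_candidates(cand)
  expect_equal(sort(fl$accepted$pos), c(10, 30, 50))
  rej <- fl$rejected[fl$rejected$line == "L1", ]
  rej <- rej[order(rej$pos), ]
  expect_equal(rej$pos, c(20, 40, 60, 70))
  expect_equal(rej$reason, c("low_alt_fraction", "near_indel",
                             "ancestral_allele", "shared_across_lines"))
})

test_that("rejection reasons follow the criterion order", {
  # a candidate failing several criteria reports only the first
  cand <- make_candidates(data.frame(
    line = "L1", pos = 10, ref = "A", alt = "G",
    dp = 10, ad = 2, indel_dist = 2, anc_ad = 3, mq = 10))
  expect_equal(filter_candidates(cand)$rejected$reason, "low_mapping_quality")
  cand2 <- make_candidates(data.frame(
    line = "L1", pos = 10, ref = "A", alt = "G",
    dp = 10, ad = 2, indel_dist = 2, anc_ad = 3))
  expect_equal(filter_candidates(cand2)$rejected$reason, "low_depth")
})

test_that("on artifact-free synthetic data the filter recovers truth exactly", {
  cfg <- sim_config(genome_length = 3e4, n_genes = 0, n_lines = 5,
                    mu = 1e-6, seed = 31)
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  calls <- sim_variant_calls(g, tr, cfg)
  fl <- filter_candidates(calls$candidates, params = filter_params(),
                          pileup = calls$pileup)
  key <- function(d) sort(paste(d$line, d$pos, d$alt))
  expect_gt(nrow(tr$mutations), 30)
  expect_identical(key(fl$accepted), key(tr$mutations))  # sensitivity 1, FP 0
  expect_equal(nrow(fl$rejected), 0L)
})

test_that("every audit-labelled artifact is rejected for its labelled reason", {
  cfg <- sim_config(genome_length = 3e4, n_genes = 0, n_lines = 5,
                    mu = 1e-6, seed = 32,
                    artifact_rates = c(low_mapping_quality = 6, low_depth = 6,
                                       high_depth = 6, low_alt_fraction = 6,
                                       near_indel = 6, ancestral_allele = 6))
  g <- sim_genome(cfg)
  tr <- sim_ma_lines(g, cfg)
  calls <- sim_variant_calls(g, tr, cfg)
  fl <- filter_candidates(calls$candidates, params = filter_params(),
                          pileup = calls$pileup)
  expect_gt(nrow(calls$audit), 20)
  for (i in seq_len(nrow(calls$audit))) {
    a <- calls$audit[i, ]
    hit <- fl$rejected[fl$rejected$pos == a$pos & fl$rejected$alt == a$alt, ]
    expect_gt(nrow(hit), 0)
    expect_true(all(hit$reason == a$class),
                info = sprintf("pos %d labelled %s got %s", a$pos, a$class,
                               paste(unique(hit$reason), collapse = ",")))
  }
  # nothing accepted that is an artifact
  expect_false(any(paste(fl$accepted$pos, fl$accepted$alt) %in%
                     paste(calls$audit$pos, calls$audit$alt)))
})

test_that("candidates at unknown coordinates raise structural errors", {
  cand <- make_candidates(data.frame(line = "L1", pos = 10, ref = "A",
                                     alt = "G", dp = 30, ad = 15))
  depth <- cbind(anc = rep(30, 5), L1 = rep(30, 5), L2 = rep(30, 5),
                 L3 = rep(30, 5))
  pu <- ma_pileup(list(c2 = rep(60, 5)), list(c2 = depth), "anc")
  expect_error(filter_candidates(cand, pileup = pu), "unknown contig")
  pu2 <- ma_pileup(list(c1 = rep(60, 5)), list(c1 = depth), "anc")
  expect_error(filter_candidates(cand, pileup = pu2), "bounds")
})

test_that("effect classification matches hand-worked codon changes", {
  g <- tiny_genome()
  cases <- data.frame(
    pos = c(22, 23, 23, 18, 27, 30, 35, 12, 55, 5, 94, 84),
    ref = c("T", "C", "C", "T", "A", "T", "T", "T", "T", "T", "A", "A"),
    alt = c("C", "T", "G", "C", "C", "A", "A", "A", "A", "A", "G", "C"),
    effect = c("synonymous",     # TTT -> TTC, Phe
               "stop_gained",    # CAA -> TAA
               "missense",       # CAA -> GAA, Gln -> Glu
               "start_lost",     # ATG -> ACG in codon 1
               "splice_region",  # within 3 bp of the exon1/intron junction
               "splice_region",  # first intronic bases
               "intron",
               "UTR", "UTR",
               "intergenic",
               "synonymous",     # minus strand GCT -> GCC, Ala
               "missense"))      # minus strand TCG -> GCG, Ser -> Ala
  m <- data.frame(contig = "c1", pos = cases$pos, ref = cases$ref,
                  alt = cases$alt)
  expect_identical(classify_effects(m, g), cases$effect)
})

test_that("annotated mutation records carry context, CpG flag and compartment", {
  g <- ma_genome(c(c1 = "TTCGAA"), compartment = c(c1 = "mitochondrial"))
  m <- annotate_mutations(data.frame(line = "L1", contig = "c1",
                                     pos = c(3L, 4L, 1L),
                                     ref = c("C", "G", "T"),
                                     alt = c("T", "A", "A")), g)
  expect_equal(m$cpg, c(TRUE, TRUE, FALSE))
  expect_equal(m$ctx5, c("T", "C", "N"))
  expect_equal(m$ctx3, c("G", "A", "T"))
  expect_true(all(m$compartment == "mitochondrial"))
  expect_error(annotate_mutations(data.frame(line = "a", contig = "c1",
                                             pos = 2L, ref = "A", alt = "G"),
                                  g),
               "mismatch")
})

test_that("effect tabulation conserves the mutation count", {
  g <- tiny_genome()
  set.seed(42)
  pos <- sample(nchar(g$seq[[1]]), 60, replace = TRUE)
  ref <- base_at(g, rep("c1", 60), pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  m <- annotate_mutations(unique(data.frame(line = "L1", contig = "c1",
                                            pos = pos, ref = ref, alt = alt)),
                          g)
  tab <- effect_table(m)
  expect_equal(sum(tab), nrow(m))
  expect_named(tab, c("UTR", "intergenic", "intron", "missense",
                      "splice_region", "start_lost", "stop_gained",
                      "synonymous"))
})

test_that("annotation invariants reject frame-breaking CDS", {
  genes <- data.frame(gene_id = "g1", contig = "c1", strand = "+")
  feats <- data.frame(gene_id = "g1", type = "CDS", start = 1, end = 10)
  expect_error(annotation(genes, feats), "divisible by 3")
})
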