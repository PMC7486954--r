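---
title: "Estimating spontaneous mutation rates from mutation accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous mutation rates from mutation accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## The model

A mutation accumulation (MA) experiment propagates replicate lines of a
clonal organism through repeated single-cell bottlenecks. With an
effective population size of only a handful of cells between transfers,
selection is nearly powerless and essentially all non-lethal mutations
drift to fixation within a line. Sequencing each line against the
ancestor therefore observes the mutation process directly.

The count model is Poisson. If a diploid line `i` was propagated for
`gen_i` cell divisions and `callable_i` of its sites could be genotyped
confidently, its accepted substitution count is

    n_i ~ Poisson( ploidy * callable_i * gen_i * mu )

and the pooled estimator is `mu = sum(n_i) / E` with exposure
`E = ploidy * sum(callable_i * gen_i)` site-divisions. The ploidy factor
matters: a diploid site carries two mutable copies, so omitting it
doubles the rate. `ma_fit()` is the entry point; it returns the point
rate, the per-haploid-genome rates `U = genome_size * mu` and `U_cds`,
per-line rates and an among-line heterogeneity chi-square.

```{r}
fit <- ma_fit(ehux_ma_lines(), genome_size = 167e6, cds_size = 39635709)
fit
```

### Exact Poisson intervals

Confidence intervals use the exact (Garwood) construction from
chi-square quantiles,

    low  = qchisq(alpha/2, 2n) / 2 / E      (0 when n = 0)
    high = qchisq(1 - alpha/2, 2(n+1)) / 2 / E

rather than a normal approximation, because MA counts are often small
(organelle compartments may yield fewer than ten mutations) and the
exact interval keeps its coverage guarantee there. A Wald interval is
available via `ci_method = "normal"`. The test suite checks the Garwood
bounds against `stats::poisson.test()` and verifies >= 93% empirical
coverage at means 3, 30 and 455.

### Heterogeneity between lines

`per_line_rates()` compares per-line counts with their expectation by a
Pearson chi-square on `df = n_lines - 1`. Two expectations are offered:
proportional to each line's exposure (`"exposure"`, the default — lines
with more callable site-divisions expect more mutations) and `"equal"`
(the same count for every line). They answer slightly different
questions and neither is uniformly standard in the MA literature, so
both are exposed and the mode is printed with the statistic.

## Mutation calling

`filter_candidates()` implements the acceptance criteria used across MA
resequencing studies, with every threshold a `filter_params()` field:

* callable site: mapping quality >= 20 and coverage within [20, 150] in
  the MA line **and** the ancestor (both bounds inclusive; the upper cap
  excludes repetitive, collapsed regions). The caps are applied to both
  samples symmetrically — the callable-site definition does not
  distinguish them.
* alt-allele fraction >= 1/3 of total coverage, inclusive: a diploid de
  novo mutation is heterozygous, expected at fraction 0.5, and 1/3 is
  the conventional lower guard. A read fraction at exactly the bound
  passes.
* distance to the nearest indel record > 5 bp (alignment artifacts
  cluster around indels); exactly 5 bp is rejected.
* the alt allele absent from the ancestor and from every other line.
  This operationalises the manual cross-sample inspection of pileup
  files as an automatic rule: a variant shared across lines cannot be a
  set of independent de novo events and is, in practice, an ancestral
  heterozygous site or a systematic artifact.

Each rejected candidate records exactly one reason — the first failing
criterion in the order mapping quality, low depth, high depth, alt
fraction, indel proximity, ancestral presence, cross-line sharing — so
filter behaviour is auditable class by class.

The effect classifier translates the annotated reading frame on the
coding strand (standard genetic code) and applies the precedence
splice_region > start_lost > stop_gained > missense > synonymous > UTR >
intron > intergenic. The splice region is any site within 3 bp of an
exon–intron junction on either side; 3 bp is the conventional core
window and is a parameter (`splice_window`).

## Spectrum and GC equilibrium

Substitutions are pooled into six strand-symmetric classes. With `GCn`
and `ATn` the numbers of G:C and A:T sites in the reference space, the
conditional rates are `R1 = n(GC->AT)/GCn` and `R2 = n(AT->GC)/ATn`, and
the GC content at which the two fluxes balance is
`GC_eq = R2/(R1 + R2)`. Both rates carry an arbitrary common
proportionality constant (per-generation scaling) that cancels from
`GC_eq` and from the bias ratio `b = R1/R2`; the package keeps them as
count-per-site-fraction quantities. When callable masks are supplied the
site counts come from the callable space, otherwise from the whole
genome — the formula is unchanged.

`evolve_gc()` forward-simulates single-site mutation events under R1/R2
and is used in the tests to confirm that the realized GC fraction
converges to the analytic `GC_eq` within one percentage point after 1e6
events on 5e4 sites.

The CpG analysis uses two nulls. Genome level: the CpG dinucleotide
fraction is compared with `(GC/2)^2`, i.e. independence with equal C and
G frequencies. Mutation level: among mutations at G:C sites, the
fraction occurring in CpG context (the mutated base is the C of a CG on
either strand) is compared with the fraction of genomic G:C sites in CpG
context. Both are df-1 chi-squares; an excess at CpG sites would point
to methylation-driven deamination.

## Codon bias and selection strength

ENC follows Wright: per amino acid with `n` observed codons and usage
frequencies `p_i`, the homozygosity is `F = (n * sum(p_i^2) - 1)/(n-1)`,
and `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` over the degeneracy-class
averages, capped at 61, with an unobserved three-fold average imputed as
the mean of the two- and four-fold averages. Note that the `n`-corrected
`F` makes ENC exactly scale-dependent at small counts (it is only
asymptotically invariant to multiplying all counts by a constant);
genes observed at fewer than 100 codons are flagged low-confidence.

Preferred codons are identified by contrasting the 5% most and least
biased genes (ENC ranks), calling per amino acid the codon significantly
enriched in the biased tail by a two-way chi-square at alpha = 0.01.
This replaces a full correspondence analysis: the contingency criterion
is what defines the preferred/unpreferred split, and on data with a real
high-expression stratum the ENC ranking selects the same tails the first
correspondence axis would.

For a two-codon amino acid whose preferred codon is GC-ending, the
mutation–selection–drift equilibrium frequency `P` of the preferred
codon satisfies `P/(1-P) = exp(S)/b`: mutation toward the preferred
codon runs at the AT->GC rate and away from it at the GC->AT rate, so
the mutational odds are `1/b`, tilted by `exp(S)` with `S = 4*Ne*s`.
Inverting at the pooled frequency of optimal codons gives
`S = ln[(Fop/(1-Fop)) * b]`. `S` is computed from the pooled Fop of the
eight two-codon amino acids (Phe, Tyr, His, Gln, Asn, Lys, Asp, Glu) —
a single pooled `P`, not a per-amino-acid average — and `b` is used
unrounded from `conditional_rates()`. Long-term
`Ne = S/(4s)` then only needs an assumed selective advantage `s` per
preferred codon, conventionally 1e-6 to 1e-7.

```{r}
cr <- conditional_rates(151, 207, 0.657)
c(ratio = cr$ratio, gc_eq = equilibrium_gc(cr$R1, cr$R2),
  S = selection_strength(0.8859, cr$ratio))
```

## Clock and population-size syntheses

`clock_rate()` converts synonymous divergence and a fossil-calibrated
split time into a per-year rate, `mu_year = d_s/(2T)`; dividing by the
per-division rate measured in the lab gives generations per year (365
days fixed). The growth module counts divisions as `log2(cell count)`
from a single founding cell and summarises bottlenecked censuses by
their harmonic mean — the quantity that governs drift across cycles; the
founding cell of each cycle is included in the census. The cross-species
correlation between `Ne` and `mu` is computed on log10 scales on both
axes, since the compiled values span many orders of magnitude (a
raw-scale mode exists).

## The synthetic experiment generator

`sim_config()` fixes the study conditions the package is tested under:
15 diploid lines, 14-day bottleneck cycles for 14 cycles at 1.17
divisions/day (229 generations per line), genomic GC 65.7%, and a
6-class spectrum with weights (150, 89, 49, 57, 62, 48) for
(A:T→G:C, G:C→A:T, A:T→T:A, A:T→C:G, G:C→T:A, G:C→C:G). Those weights
are the package's calibration of the observed experiment: they
reproduce the published pooled constraints — 207 AT→GC vs 151 GC→AT,
455 total, transition/transversion ratio ≈ 1.11 — while the individual
transition/transversion split within each flux direction, which is not
published at class resolution, was fixed once to plausible values. The
genome is scaled to 1 Mb and the true rate raised to 1e-7 so a single
simulated experiment yields a few hundred mutations — the same counting
regime as the full-genome study at a fraction of the cost; rate-recovery
tests use 200 replicate experiments at this scale.

Two deliberate idealisations matter for interpreting green tests:

* **Detectability of true calls.** Depths are drawn from the truncated
  negative-binomial coverage model within the callable range, and alt
  depths are binomial(depth, 1/2) conditioned to meet the 1/3 bound.
  True mutations are therefore detectable by construction, which makes
  the sensitivity-1.0 property exact. Real experiments lose mutations in
  uncallable regions; the denominator (callable sites) absorbs that loss
  in the rate, but the generator does not emulate it.
* **Infinite sites.** Mutations are placed without replacement across
  the whole experiment, so no site is hit twice in any line — the
  appropriate approximation when a few hundred mutations fall on
  megabases (455 over 167 Mb in the real experiment), and necessary for
  the cross-line uniqueness criterion to be exactly consistent with the
  truth set at desk scale. The generator warns when the expected count
  exceeds a tenth of the genome.

Artifacts of all six audited classes are injected at Poisson counts at
positions distinct from true mutations, each labelled with the rejection
reason it must trigger, so filter specificity is checked class by class
and per seed. Codon usage, expression strata and daily cell counts are
generated from the same equilibrium and growth models the estimators
invert, making generator and estimator mutual inverses — a property the
test suite exercises (S recovered within 0.05 from 1e5 codons; planted
preferred-codon sets recovered exactly; 1.17 divisions/day recovered
from censuses).

What the generator does **not** emulate: read-level errors and mapping,
coverage autocorrelation along the genome, selection during propagation,
mutation-rate variation along the genome, and context effects beyond the
base-conditioned spectrum. Passing tests validate the estimators and the
filter logic under the stated statistical model, not the upstream
bioinformatics.

## Numerical choices and degenerate inputs

* Alt-fraction comparison uses `>=` with a 1e-9 guard against binary
  rounding of `depth * 1/3`.
* `k` (ts/tv) is reported as `NA` when no transversions were observed,
  never as infinity; ambiguous bases skip a record with a warning count.
* A zero mutation count yields `mu = 0` with CI `[0, qchisq(0.975, 2)/2/E]`.
* ENC is `NA` for genes with internal stop codons or with an entire
  degeneracy class unobserved (after the three-fold imputation).
* Organelle copy number is treated as fixed and known
  (`estimate_copy_number()` is simple coverage proportionality); no
  error propagation into the organelle CI.
* Seeds: every generator stage reseeds deterministically from
  `config$seed` plus a stage offset, so a configured run is bit-for-bit
  reproducible while unconfigured runs follow the caller's RNG stream.

## Known limitations

Candidate tables must carry DP, AD and MQ; other VCF fields are ignored,
and structural variants are out of scope (indels enter only as exclusion
zones). The heterogeneity chi-square treats lines as independent Poisson
draws; overdispersion from shared culture history is not modelled. The
preferred-codon caller needs a genuine bias contrast between expression
strata — on uniformly unbiased genomes it correctly returns an empty
set, and `Fop`/`S` are then undefined by design.
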