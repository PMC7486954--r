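#' Configuration of a synthetic MA experiment
#'
#' Defaults emulate, at desk scale, a serial-bottleneck mutation
#' accumulation experiment in a diploid unicellular phytoplankton: 15 MA
#' lines bottlenecked to one cell every 14 days for 14 cycles at 1.17
#' divisions/day (229 generations per line), a GC-rich genome (65.7% GC),
#' and a GC-biased, transition-enriched mutation spectrum.  The spectrum
#' weights are pooled class counts observed at the reference GC content
#' `spectrum_gc_ref`; the per-site class rates are conditioned on the ref
#' base so that pooled counts reproduce the weights on a genome at that GC.
#' The genome is scaled to 1 Mb and the true rate raised to 1e-7 per site
#' per division so that a single simulated experiment yields a few hundred
#' mutations, the same counting regime as a full-genome experiment.
#'
#' @param genome_length genome length in bp.
#' @param gc target GC fraction, in (0,1).
#' @param n_genes,mean_cds_length gene models to place (CDS length in bp,
#'   rounded to whole codons).
#' @param n_lines number of MA lines.
#' @param cycles,cycle_days,divisions_per_day bottleneck design; the
#'   per-line generation count is `round(cycles * cycle_days *
#'   divisions_per_day)` unless `generations` is given.
#' @param generations per-line generations override.
#' @param mu true per-site per-division mutation rate.
#' @param ploidy ploidy (2: two mutable copies per site).
#' @param spectrum named 6-vector of pooled class weights (see
#'   [spectrum_classes()]).
#' @param spectrum_gc_ref GC content at which the spectrum weights were
#'   observed.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   model (mean and size).
#' @param mq site mapping quality assigned to clean sites.
#' @param artifact_rates named vector of expected artifact counts
#'   (Poisson means) per class: `low_mapping_quality`, `low_depth`,
#'   `high_depth`, `low_alt_fraction`, `near_indel`, `ancestral_allele`.
#' @param S_true codon-selection strength of highly expressed genes.
#' @param bias_ratio mutation-bias ratio b = mu_GC->AT / mu_AT->GC used by
#'   the codon-usage generator; default derived from `spectrum` at
#'   `spectrum_gc_ref`.
#' @param high_frac fraction of genes in the highly expressed stratum.
#' @param division_sd per-interval SD of divisions/day in the growth
#'   simulator.
#' @param seed integer seed; when set, each generator operation is
#'   bit-for-bit reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc = 0.657,
                       n_genes = 40L, mean_cds_length = 900L,
                       n_lines = 15L, cycles = 14L, cycle_days = 14L,
                       divisions_per_day = 1.17, generations = NULL,
                       mu = 1e-7, ploidy = 2L,
                       spectrum = c(AT_GC = 150, GC_AT = 89, AT_TA = 49,
                                    AT_CG = 57, GC_TA = 62, GC_CG = 48),
                       spectrum_gc_ref = 0.657,
                       coverage_mean = 60, coverage_dispersion = 10,
                       mq = 60,
                       artifact_rates = c(low_mapping_quality = 0,
                                          low_depth = 0, high_depth = 0,
                                          low_alt_fraction = 0,
                                          near_indel = 0,
                                          ancestral_allele = 0),
                       S_true = 1.084, bias_ratio = NULL,
                       high_frac = 0.25, division_sd = 0.02,
                       seed = NULL) {
  if (gc <= 0 || gc >= 1) stopf("GC fraction must be in (0,1)")
  if (mu < 0) stopf("mu must be non-negative")
  if (!all(spectrum_classes() %in% names(spectrum)))
    stopf("spectrum needs weights for %s",
          paste(spectrum_classes(), collapse = ", "))
  spectrum <- spectrum[spectrum_classes()]
  if (any(spectrum < 0) || sum(spectrum) <= 0)
    stopf("spectrum weights must be >= 0 and sum > 0")
  if (is.null(generations))
    generations <- round(cycles * cycle_days * divisions_per_day)
  if (is.null(bias_ratio)) {
    cr <- conditional_rates(spectrum[["GC_AT"]] + spectrum[["GC_TA"]],
                            spectrum[["AT_GC"]] + spectrum[["AT_CG"]],
                            spectrum_gc_ref)
    bias_ratio <- cr$ratio
  }
  structure(list(genome_length = genome_length, gc = gc, n_genes = n_genes,
                 mean_cds_length = mean_cds_length, n_lines = n_lines,
                 cycles = cycles, cycle_days = cycle_days,
                 divisions_per_day = divisions_per_day,
                 generations = generations, mu = mu, ploidy = ploidy,
                 spectrum = spectrum, spectrum_gc_ref = spectrum_gc_ref,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion, mq = mq,
                 artifact_rates = artifact_rates, S_true = S_true,
                 bias_ratio = bias_ratio, high_frac = high_frac,
                 division_sd = division_sd, seed = seed),
            class = "sim_config")
}

# reseed deterministically per generator stage, leaving the caller's RNG
# stream alone when no seed is configured
sim_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
  invisible(NULL)
}

# preferred (GC-ending) codon per degenerate amino acid, used by the
# codon-usage generator; remaining synonyms share the complement
preferred_codon_map <- function() {
  c(F = "TTC", Y = "TAC", H = "CAC", Q = "CAG", N = "AAC", K = "AAG",
    D = "GAC", E = "GAG", C = "TGC", I = "ATC", V = "GTC", P = "CCC",
    T = "ACC", A = "GCC", G = "GGC", L = "CTG", S = "TCC", R = "CGC")
}

# sample n amino acids' worth of sense codons under the two-state
# preferred/unpreferred equilibrium P/(1-P) = exp(S)/b
sample_codons <- function(n, S, b) {
  sc <- sense_codons(); aa <- codon_aa()
  pref <- preferred_codon_map()
  p <- exp(S) / b / (1 + exp(S) / b)
  aas <- sample(unique(aa), n, replace = TRUE)
  out <- character(n)
  for (a in unique(aas)) {
    i <- which(aas == a)
    syn <- sc[aa == a]
    if (length(syn) == 1L) { out[i] <- syn; next }
    pc <- pref[[a]]
    others <- setdiff(syn, pc)
    pick <- runif(length(i)) < p
    out[i][pick] <- pc
    out[i][!pick] <- sample(others, sum(!pick), replace = TRUE)
  }
  out
}

#' Generate a synthetic annotated genome
#'
#' Draws an i.i.d. nucleotide background at the target GC content, then
#' places non-overlapping gene models (5'UTR, 1-3 exons with >= 60 bp
#' introns, 3'UTR; random strand) whose CDS is a start-to-stop codon
#' sequence drawn from the neutral codon equilibrium.  For genomes of
#' 100 kb and more the realized GC lies within half a percentage point of
#' the target.
#'
#' @param config a [sim_config()].
#' @return an `ma_genome` with annotation; attribute `cds_fraction`.
#' @export
sim_genome <- function(config = sim_config()) {
  sim_seed(config, 1L)
  L <- as.integer(config$genome_length)
  gc <- config$gc
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genes <- features <- list()
  n_genes <- config$n_genes
  if (n_genes > 0L) {
    block <- L %/% n_genes
    for (gi in seq_len(n_genes)) {
      n_cod <- max(10L, round(config$mean_cds_length *
                                runif(1, 0.7, 1.3) / 3))
      n_ex <- sample(1:3, 1L)
      # split CDS bp across exons (codon-boundary-free splits allowed)
      cds_len <- 3L * n_cod
      cuts <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
      ex_len <- diff(c(0L, cuts, cds_len))
      utr <- 60L; intron <- 100L
      span <- 2L * utr + cds_len + (n_ex - 1L) * intron
      if (span + 2L > block)
        stopf("cannot place %d genes of span %d in %d bp", n_genes, span, L)
      start <- (gi - 1L) * block +
        sample.int(block - span - 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("g%03d", gi)
      # genomic layout: utr5' | exon1 .. intron .. exonN | utr3'
      pos <- start
      f <- list()
      f[[1]] <- data.frame(gene_id = gid, type = "five_prime_UTR",
                           start = pos, end = pos + utr - 1L)
      pos <- pos + utr
      cds_iv <- list()
      for (e in seq_len(n_ex)) {
        cds_iv[[e]] <- data.frame(gene_id = gid, type = "CDS",
                                  start = pos, end = pos + ex_len[e] - 1L)
        pos <- pos + ex_len[e] + (if (e < n_ex) intron else 0L)
      }
      f[[2]] <- do.call(rbind, cds_iv)
      f[[3]] <- data.frame(gene_id = gid, type = "three_prime_UTR",
                           start = pos, end = pos + utr - 1L)
      # exons: UTRs merged with flanking CDS
      ex <- do.call(rbind, cds_iv)
      ex$type <- "exon"
      ex$start[1L] <- f[[1]]$start
      ex$end[nrow(ex)] <- f[[3]]$end
      # CDS sequence in coding orientation: ATG + body + stop
      body <- sample_codons(n_cod - 2L, S = 0, b = config$bias_ratio)
      cds_seq <- paste0("ATG", paste(body, collapse = ""),
                        sample(c("TAA", "TAG", "TGA"), 1L))
      if (strand == "-") cds_seq <- revcomp(cds_seq)
      cdsg <- do.call(rbind, cds_iv)       # genomic order
      chars <- strsplit(cds_seq, "")[[1L]]
      off <- 0L
      for (e in seq_len(nrow(cdsg))) {
        w <- cdsg$end[e] - cdsg$start[e] + 1L
        base[cdsg$start[e]:cdsg$end[e]] <- chars[(off + 1L):(off + w)]
        off <- off + w
      }
      genes[[gi]] <- data.frame(gene_id = gid, contig = "chr1",
                                strand = strand)
      features[[gi]] <- rbind(f[[1]], f[[2]], ex, f[[3]])
    }
  }
  ann <- if (n_genes > 0L)
    annotation(do.call(rbind, genes), do.call(rbind, features))
  else NULL
  g <- ma_genome(setNames(paste(base, collapse = ""), "chr1"),
                 annotation = ann)
  cds_bp <- if (is.null(ann)) 0L else sum(cds_lengths(ann))
  attr(g, "cds_fraction") <- cds_bp / L
  ma_log("sim_genome: %d bp, GC %.3f, %d genes (CDS fraction %.3f)",
         L, gc_content(g), n_genes, attr(g, "cds_fraction"))
  g
}

# per-ref-class per-site rates and conditional class probabilities implied
# by the pooled spectrum weights at the reference GC
spectrum_site_model <- function(config, f_at, f_gc) {
  w <- config$spectrum / sum(config$spectrum)
  g0 <- config$spectrum_gc_ref
  at_cls <- c("AT_GC", "AT_TA", "AT_CG"); gc_cls <- c("GC_AT", "GC_TA", "GC_CG")
  s_at <- sum(w[at_cls]) / (1 - g0)      # relative per-site rate, A/T site
  s_gc <- sum(w[gc_cls]) / g0
  Z <- f_at * s_at + f_gc * s_gc
  list(mu_at = config$mu * s_at / Z, mu_gc = config$mu * s_gc / Z,
       p_at = w[at_cls] / sum(w[at_cls]), p_gc = w[gc_cls] / sum(w[gc_cls]))
}

# alt base for a ref base and pooled class
alt_for <- function(ref, class) {
  m <- list(A = c(AT_GC = "G", AT_TA = "T", AT_CG = "C"),
            T = c(AT_GC = "C", AT_TA = "A", AT_CG = "G"),
            G = c(GC_AT = "A", GC_TA = "T", GC_CG = "C"),
            C = c(GC_AT = "T", GC_TA = "A", GC_CG = "G"))
  vapply(seq_along(ref), function(i) m[[ref[i]]][[class[i]]], "")
}

#' Simulate de novo mutations of the MA lines
#'
#' Each line accumulates `Poisson(ploidy x L x generations x mu)`
#' mutations; a mutation's pooled class is drawn from the spectrum
#' conditioned on the ref base (A/T sites and G/C sites carry different
#' per-site rates so that pooled class counts reproduce the configured
#' weights), and its position is uniform among sites of that base class,
#' without replacement across the whole experiment (infinite-sites
#' approximation: no site is hit twice in any line; a warning is raised
#' when the expected count exceeds a tenth of the genome).
#'
#' @param genome an `ma_genome` from [sim_genome()].
#' @param config a [sim_config()].
#' @return list of class `ma_truth`: `mutations` (line, contig, pos, ref,
#'   alt), `experiment` (an [experiment_table()] whose callable sites are
#'   the full genome), `mu_true`.
#' @export
sim_ma_lines <- function(genome, config = sim_config()) {
  sim_seed(config, 2L)
  b <- strsplit(genome$seq[[1L]], "")[[1L]]
  contig <- names(genome$seq)[1L]
  at_idx <- which(b %in% c("A", "T")); gc_idx <- which(b %in% c("G", "C"))
  L <- length(b)
  mod <- spectrum_site_model(config, length(at_idx) / L, length(gc_idx) / L)
  gens <- rep(config$generations, config$n_lines)
  lambda <- config$ploidy * L * gens * config$mu
  if (sum(lambda) > L / 10)
    warning("expected mutation count exceeds a tenth of the genome; infinite-sites approximation violated")
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  out <- list()
  taken_at <- taken_gc <- integer(0)   # sites already hit, per base class
  for (i in seq_along(lines)) {
    n <- rpois(1L, lambda[i])
    if (n == 0L) next
    # ref class of each mutation
    p_at_total <- length(at_idx) * mod$mu_at /
      (length(at_idx) * mod$mu_at + length(gc_idx) * mod$mu_gc)
    n_at <- rbinom(1L, n, p_at_total)
    avail_at <- setdiff(at_idx, taken_at)
    avail_gc <- setdiff(gc_idx, taken_gc)
    n_at <- min(n_at, length(avail_at))                  # saturation guard
    n <- n_at + min(n - n_at, length(avail_gc))
    if (n == 0L) next
    pos_at <- if (n_at > 0) sample(avail_at, n_at)
    pos_gc <- if (n - n_at > 0) sample(avail_gc, n - n_at)
    taken_at <- c(taken_at, pos_at); taken_gc <- c(taken_gc, pos_gc)
    pos <- c(pos_at, pos_gc)
    cls <- c(if (n_at > 0) sample(names(mod$p_at), n_at, replace = TRUE,
                                  prob = mod$p_at),
             if (n - n_at > 0) sample(names(mod$p_gc), n - n_at,
                                      replace = TRUE, prob = mod$p_gc))
    ref <- b[pos]
    out[[i]] <- data.frame(line = lines[i], contig = contig, pos = pos,
                           ref = ref, alt = alt_for(ref, cls),
                           stringsAsFactors = FALSE)
  }
  muts <- if (length(out)) do.call(rbind, out) else
    data.frame(line = character(0), contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  rownames(muts) <- NULL
  n_mut <- vapply(lines, function(l) sum(muts$line == l), 1L)
  exp_tab <- experiment_table(data.frame(
    line = lines, generations = gens, callable_sites = L,
    n_mut = as.integer(n_mut)))
  ma_log("sim_ma_lines: %d mutations across %d lines", nrow(muts),
         length(lines))
  structure(list(mutations = muts, experiment = exp_tab,
                 mu_true = config$mu), class = "ma_truth")
}

# truncated negative-binomial coverage draw in [lo, hi]
rcov <- function(n, mean, size, lo = 20L, hi = 150L) {
  x <- rnbinom(n, mu = mean, size = size)
  for (k in 1:20) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- rnbinom(length(bad), mu = mean, size = size)
  }
  pmin(pmax(x, lo), hi)
}

# binomial alt-depth draw conditioned on passing the alt-fraction bound
r_alt_depth <- function(dp, frac = 1/3) {
  ad <- rbinom(length(dp), dp, 0.5)
  for (k in 1:50) {
    bad <- which(ad < ceiling(dp * frac))
    if (!length(bad)) break
    ad[bad] <- rbinom(length(bad), dp[bad], 0.5)
  }
  pmax(ad, ceiling(dp * frac))
}

#' Synthesize variant calls (and artifacts) from true mutations
#'
#' Builds the candidate table and per-site pileup statistics a variant
#' caller would produce.  Every true mutation appears as a heterozygous
#' candidate whose depth follows the coverage model truncated to the
#' callable range and whose alt depth is binomial(depth, 1/2) conditioned
#' to meet the alt-fraction bound, so that on artifact-free input the
#' acceptance criteria recover the truth exactly.  Artifacts of the six
#' audited classes are injected at Poisson-distributed counts
#' (`config$artifact_rates`) at positions distinct from true mutations,
#' each labelled in the audit table with the rejection reason it must
#' trigger.
#'
#' @param genome an `ma_genome`.
#' @param truth an `ma_truth` from [sim_ma_lines()].
#' @param config a [sim_config()].
#' @param pileup build per-site pileup matrices (memory ~ L x lines);
#'   disable for large genomes.
#' @return list of class `ma_calls`: `candidates` ([ma_candidates()]),
#'   `pileup` ([ma_pileup()] or NULL), `indels`, `audit` (contig, pos,
#'   alt, line, class).
#' @export
sim_variant_calls <- function(genome, truth, config = sim_config(),
                              pileup = TRUE) {
  sim_seed(config, 3L)
  contig <- names(genome$seq)[1L]
  L <- nchar(genome$seq[[1L]])
  lines <- truth$experiment$line
  smp <- c("ancestor", lines)
  b <- NULL
  pl <- NULL
  if (pileup) {
    depth <- matrix(rcov(L * length(smp), config$coverage_mean,
                         config$coverage_dispersion),
                    L, length(smp), dimnames = list(NULL, smp))
    mqv <- rep(config$mq, L)
    pl <- list(mq = setNames(list(mqv), contig),
               depth = setNames(list(depth), contig))
  }
  used <- truth$mutations$pos
  rand_pos <- function(n) {
    p <- sample.int(L, n + length(used))
    p <- setdiff(p, used)[seq_len(n)]
    used <<- c(used, p)
    p
  }
  site_depth <- function(pos, s) {
    if (!is.null(pl)) pl$depth[[contig]][pos, s]
    else rcov(length(pos), config$coverage_mean, config$coverage_dispersion)
  }
  rows <- list(); dp_l <- list(); ad_l <- list()
  audit <- list(); indels <- list()
  add <- function(contig, pos, ref, alt, mq, dp, ad) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, pos = pos, ref = ref, alt = alt, mq = mq,
      stringsAsFactors = FALSE)
    dp_l[[length(dp_l) + 1L]] <<- dp
    ad_l[[length(ad_l) + 1L]] <<- ad
  }
  # true mutations: het in their line, absent elsewhere
  tm <- truth$mutations
  if (nrow(tm)) {
    for (i in seq_len(nrow(tm))) {
      dp <- vapply(smp, function(s) site_depth(tm$pos[i], s), 1)
      ad <- setNames(numeric(length(smp)), smp)
      ad[tm$line[i]] <- r_alt_depth(dp[tm$line[i]])
      add(tm$contig[i], tm$pos[i], tm$ref[i], tm$alt[i], config$mq, dp, ad)
    }
  }
  mutate_base <- function(ref) vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  art <- config$artifact_rates
  n_art <- setNames(rpois(length(art), art), names(art))
  for (class in names(n_art)) {
    n <- n_art[[class]]
    if (n == 0L) next
    pos <- rand_pos(n)
    ref <- base_at(genome, rep(contig, n), pos)
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; ref <- ref[keep]
    if (!length(pos)) next
    alt <- mutate_base(ref)
    ln <- sample(lines, length(pos), replace = TRUE)
    for (i in seq_along(pos)) {
      dp <- vapply(smp, function(s) site_depth(pos[i], s), 1)
      ad <- setNames(numeric(length(smp)), smp)
      mq <- config$mq
      switch(class,
        low_mapping_quality = {
          mq <- sample(5:19, 1L)
          if (!is.null(pl)) pl$mq[[contig]][pos[i]] <- mq
          ad[ln[i]] <- r_alt_depth(dp[ln[i]])
        },
        low_depth = {
          dp[ln[i]] <- sample(5:19, 1L)
          if (!is.null(pl)) pl$depth[[contig]][pos[i], ln[i]] <- dp[ln[i]]
          ad[ln[i]] <- max(1, round(dp[ln[i]] / 2))
        },
        high_depth = {
          dp[ln[i]] <- sample(151:300, 1L)
          if (!is.null(pl)) pl$depth[[contig]][pos[i], ln[i]] <- dp[ln[i]]
          ad[ln[i]] <- round(dp[ln[i]] / 2)
        },
        low_alt_fraction = {
          ad[ln[i]] <- max(1, floor(dp[ln[i]] / 3) - 1L)
        },
        near_indel = {
          ad[ln[i]] <- r_alt_depth(dp[ln[i]])
          ipos <- pos[i] + sample(c(-5:-1, 1:5), 1L)
          ipos <- min(max(ipos, 1L), L)
          iref <- base_at(genome, contig, ipos)
          indels[[length(indels) + 1L]] <- data.frame(
            contig = contig, pos = ipos, ref = iref,
            alt = paste0(iref, "T"), stringsAsFactors = FALSE)
        },
        ancestral_allele = {
          ad[smp] <- r_alt_depth(dp[smp])   # het in ancestor and all lines
        })
      add(contig, pos[i], ref[i], alt[i], mq, dp, ad)
      audit[[length(audit) + 1L]] <- data.frame(
        contig = contig, pos = pos[i], alt = alt[i],
        line = if (class == "ancestral_allele") NA_character_ else ln[i],
        class = class, stringsAsFactors = FALSE)
    }
  }
  empty_sites <- data.frame(contig = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            mq = numeric(0), indel_dist = numeric(0))
  ind <- if (length(indels)) do.call(rbind, indels) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  if (length(rows)) {
    sites <- do.call(rbind, rows)
    sites$indel_dist <- vapply(seq_len(nrow(sites)), function(r) {
      p <- ind$pos[ind$contig == sites$contig[r]]
      if (length(p)) min(abs(p - sites$pos[r])) else Inf
    }, 1)
    dp <- do.call(rbind, dp_l); ad <- do.call(rbind, ad_l)
    colnames(dp) <- colnames(ad) <- smp
  } else {
    sites <- empty_sites
    dp <- ad <- matrix(numeric(0), 0, length(smp),
                       dimnames = list(NULL, smp))
  }
  cand <- ma_candidates(sites, dp, ad, ancestor = "ancestor")
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(contig = character(0), pos = integer(0), alt = character(0),
               line = character(0), class = character(0))
  pu <- if (!is.null(pl)) ma_pileup(pl$mq, pl$depth, "ancestor") else NULL
  ma_log("sim_variant_calls: %d candidates (%d artifacts), %d indels",
         nrow(sites), nrow(audit), nrow(ind))
  structure(list(candidates = cand, pileup = pu, indels = ind,
                 audit = audit), class = "ma_calls")
}

#' Simulate daily cell counts of the bottleneck cycles
#'
#' Each cycle starts from one cell and grows exponentially at the
#' configured divisions/day (jittered per interval by `division_sd`),
#' resetting every `cycle_days` days.  Day 0 of each cycle is the founding
#' single cell.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `line`, `cycle`, `day`, `count`, and
#'   attribute `rates` (per line x cycle divisions/day).
#' @export
sim_cell_counts <- function(config = sim_config()) {
  sim_seed(config, 4L)
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  out <- list(); rates <- list()
  for (l in lines) {
    for (cy in seq_len(config$cycles)) {
      r <- config$divisions_per_day + rnorm(1L, 0, config$division_sd)
      d <- 0:(config$cycle_days - 1L)
      out[[length(out) + 1L]] <- data.frame(
        line = l, cycle = cy, day = d, count = 2^(r * d),
        stringsAsFactors = FALSE)
      rates[[length(rates) + 1L]] <- data.frame(line = l, cycle = cy,
                                                rate = r)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "rates") <- do.call(rbind, rates)
  res
}
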