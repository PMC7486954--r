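#' Classify the functional effect of de novo point mutations
#'
#' A minimal effect classifier over gene-model annotation.  Codon effects
#' are computed by translating the annotated reading frame on the coding
#' strand (standard genetic code).  When several classes apply the
#' precedence is: splice_region > start_lost > stop_gained > missense >
#' synonymous > UTR > intron > intergenic.  The splice region is any site
#' within `splice_window` bp of an exon-intron junction, on either side.
#'
#' @param mutations data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @param genome an `ma_genome` whose `annotation` is set (an empty
#'   annotation classifies everything intergenic).
#' @param splice_window bp on each side of an exon-intron junction.
#' @return character vector of effect classes, one per mutation.
#' @export
classify_effects <- function(mutations, genome, splice_window = 3L) {
  ann <- genome$annotation
  n <- nrow(mutations)
  out <- rep("intergenic", n)
  if (is.null(ann) || nrow(ann$genes) == 0L || n == 0L) return(out)
  # per-gene span index
  f <- ann$features
  span <- do.call(rbind, lapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    fi <- f[f$gene_id == g$gene_id, ]
    data.frame(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
               start = min(fi$start), end = max(fi$end))
  }))
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (k in seq_len(n)) {
    ct <- mutations$contig[k]; p <- mutations$pos[k]
    if (is.null(genome$seq[[ct]]))
      stopf("mutation on unknown contig '%s'", ct)
    if (p < 1L || p > nchar(genome$seq[[ct]]))
      stopf("mutation outside contig '%s' bounds", ct)
    hit <- span[span$contig == ct & span$start <= p & span$end >= p, ]
    if (nrow(hit) == 0L) next
    cls <- character(0)
    for (gi in seq_len(nrow(hit))) {
      gid <- hit$gene_id[gi]; strand <- hit$strand[gi]
      introns <- gene_introns(ann, gid)
      splice <- FALSE
      if (nrow(introns)) {
        jl <- introns$start - 1L   # last exonic base before each intron
        jr <- introns$end          # last intronic base before next exon
        splice <- any(p >= jl - (splice_window - 1L) & p <= jl + splice_window) ||
          any(p >= jr - (splice_window - 1L) & p <= jr + splice_window)
      }
      if (splice) cls <- c(cls, "splice_region")
      cdsiv <- gene_intervals(ann, gid, "CDS")
      in_cds <- nrow(cdsiv) > 0L && any(p >= cdsiv$start & p <= cdsiv$end)
      if (in_cds) {
        cds <- gene_cds_seq(genome, ann, gid)
        # offset of p within the spliced CDS, transcription order, 0-based
        off <- 0L
        if (strand == "+") {
          for (r in seq_len(nrow(cdsiv))) {
            if (p >= cdsiv$start[r] && p <= cdsiv$end[r]) {
              off <- off + (p - cdsiv$start[r]); break
            }
            off <- off + (cdsiv$end[r] - cdsiv$start[r] + 1L)
          }
          alt_c <- mutations$alt[k]
        } else {
          for (r in rev(seq_len(nrow(cdsiv)))) {
            if (p >= cdsiv$start[r] && p <= cdsiv$end[r]) {
              off <- off + (cdsiv$end[r] - p); break
            }
            off <- off + (cdsiv$end[r] - cdsiv$start[r] + 1L)
          }
          alt_c <- comp[[mutations$alt[k]]]
        }
        ci <- off %/% 3L; cp <- off %% 3L
        ref_codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
        alt_codon <- ref_codon
        substr(alt_codon, cp + 1L, cp + 1L) <- alt_c
        ref_aa <- unname(code[ref_codon]); if (is.na(ref_aa)) ref_aa <- "X"
        alt_aa <- unname(code[alt_codon]); if (is.na(alt_aa)) alt_aa <- "X"
        if (ci == 0L && ref_codon == "ATG" && alt_codon != "ATG")
          cls <- c(cls, "start_lost")
        else if (alt_aa == "*" && ref_aa != "*")
          cls <- c(cls, "stop_gained")
        else if (alt_aa != ref_aa)
          cls <- c(cls, "missense")
        else
          cls <- c(cls, "synonymous")
      } else {
        utr <- rbind(gene_intervals(ann, gid, "five_prime_UTR"),
                     gene_intervals(ann, gid, "three_prime_UTR"))
        if (nrow(utr) && any(p >= utr$start & p <= utr$end))
          cls <- c(cls, "UTR")
        else if (nrow(introns) && any(p >= introns$start & p <= introns$end))
          cls <- c(cls, "intron")
      }
    }
    prec <- c("splice_region", "start_lost", "stop_gained", "missense",
              "synonymous", "UTR", "intron", "intergenic")
    hit_cls <- prec[prec %in% cls]
    if (length(hit_cls)) out[k] <- hit_cls[1L]
  }
  out
}

#' Annotate accepted mutations into full mutation records
#'
#' Adds the genomic compartment, trinucleotide context, CpG flag (the site
#' is the C of a CG dinucleotide on either strand) and functional effect
#' class, and checks that each ref allele matches the genome.
#'
#' @param mutations data.frame with columns `line`, `contig`, `pos`, `ref`,
#'   `alt`.
#' @param genome an `ma_genome`.
#' @param splice_window passed to [classify_effects()].
#' @return the input data.frame with columns `compartment`, `ctx5`, `ctx3`,
#'   `cpg`, `effect` appended; class `ma_mutations`.
#' @export
annotate_mutations <- function(mutations, genome, splice_window = 3L) {
  m <- as.data.frame(mutations)
  if (nrow(m)) {
    refs <- base_at(genome, m$contig, m$pos)
    bad <- which(refs != m$ref)
    if (length(bad))
      stopf("ref allele mismatch at %s:%d (genome %s, record %s)",
            m$contig[bad[1L]], m$pos[bad[1L]], refs[bad[1L]], m$ref[bad[1L]])
    if (any(m$ref == m$alt)) stopf("ref == alt in a mutation record")
    m$compartment <- unname(genome$compartment[m$contig])
    m$ctx5 <- base_at(genome, m$contig, pmax(m$pos - 1L, 1L))
    m$ctx5[m$pos == 1L] <- "N"
    len <- nchar(genome$seq)[m$contig]
    m$ctx3 <- base_at(genome, m$contig, pmin(m$pos + 1L, len))
    m$ctx3[m$pos == len] <- "N"
    m$cpg <- (m$ref == "C" & m$ctx3 == "G") | (m$ref == "G" & m$ctx5 == "C")
    m$effect <- classify_effects(m, genome, splice_window)
  } else {
    m$compartment <- m$ctx5 <- m$ctx3 <- m$effect <- character(0)
    m$cpg <- logical(0)
  }
  class(m) <- c("ma_mutations", "data.frame")
  m
}

#' Tabulate mutations by functional effect class
#'
#' @param mutations output of [annotate_mutations()] (or any data.frame
#'   with an `effect` column).
#' @return named integer vector over all eight effect classes; the counts
#'   sum to the number of input mutations.
#' @export
effect_table <- function(mutations) {
  classes <- c("UTR", "intergenic", "intron", "missense", "splice_region",
               "start_lost", "stop_gained", "synonymous")
  out <- setNames(integer(length(classes)), classes)
  if (nrow(mutations)) {
    t <- table(factor(mutations$effect, levels = classes))
    out[names(t)] <- as.integer(t)
  }
  out
}
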