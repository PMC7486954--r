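#' Gene-model annotation
#'
#' A light-weight gene-model container: one row per gene plus a feature
#' table of CDS/exon/UTR intervals.  Introns are derived as the gaps
#' between exons of a gene and are not stored.  Coordinates are 1-based
#' inclusive, as in GFF3.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`).
#' @param features data.frame with columns `gene_id`, `type` (one of
#'   `CDS`, `exon`, `five_prime_UTR`, `three_prime_UTR`), `start`, `end`.
#' @return an object of class `ma_annotation`.
#' @export
annotation <- function(genes, features) {
  need <- c("gene_id", "contig", "strand")
  if (!all(need %in% names(genes)))
    stopf("genes must have columns %s", paste(need, collapse = ", "))
  need <- c("gene_id", "type", "start", "end")
  if (!all(need %in% names(features)))
    stopf("features must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene id '%s'", genes$gene_id[duplicated(genes$gene_id)][1L])
  if (!all(genes$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  ok_types <- c("CDS", "exon", "five_prime_UTR", "three_prime_UTR")
  if (!all(features$type %in% ok_types))
    stopf("unknown feature type '%s'", setdiff(features$type, ok_types)[1L])
  if (!all(features$gene_id %in% genes$gene_id))
    stopf("feature for unknown gene '%s'",
          setdiff(features$gene_id, genes$gene_id)[1L])
  if (any(features$end < features$start))
    stopf("feature with end < start")
  genes <- as.data.frame(genes)[, c("gene_id", "contig", "strand")]
  features <- as.data.frame(features)[, c("gene_id", "type", "start", "end")]
  features <- features[order(match(features$gene_id, genes$gene_id),
                             features$start), ]
  rownames(genes) <- rownames(features) <- NULL
  ann <- structure(list(genes = genes, features = features),
                   class = "ma_annotation")
  validate_annotation(ann)
  ann
}

#' @export
print.ma_annotation <- function(x, ...) {
  cat(sprintf("Gene-model annotation: %d genes, %d features\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}

# invariants: CDS length divisible by 3; within-gene intervals of one type
# non-overlapping; with a genome, intervals within contig bounds.
validate_annotation <- function(ann, genome = NULL) {
  f <- ann$features
  cds_len <- cds_lengths(ann)
  bad <- names(cds_len)[cds_len %% 3L != 0L]
  if (length(bad))
    stopf("CDS length of gene '%s' is not divisible by 3", bad[1L])
  for (ty in unique(f$type)) {
    fi <- f[f$type == ty, ]
    sp <- split(fi, fi$gene_id)
    for (g in sp) {
      if (nrow(g) > 1L) {
        g <- g[order(g$start), ]
        if (any(g$start[-1L] <= g$end[-nrow(g)]))
          stopf("overlapping %s intervals in gene '%s'", ty, g$gene_id[1L])
      }
    }
  }
  if (!is.null(genome)) {
    ctg <- ann$genes$contig[match(f$gene_id, ann$genes$gene_id)]
    len <- nchar(genome$seq)[ctg]
    if (anyNA(len)) stopf("gene on unknown contig '%s'", ctg[is.na(len)][1L])
    if (any(f$start < 1L | f$end > len))
      stopf("feature outside contig bounds in gene '%s'",
            f$gene_id[f$start < 1L | f$end > len][1L])
  }
  invisible(ann)
}

#' Per-gene CDS lengths
#' @param ann an `ma_annotation`.
#' @return named integer vector.
#' @export
cds_lengths <- function(ann) {
  f <- ann$features[ann$features$type == "CDS", ]
  v <- tapply(f$end - f$start + 1L, f$gene_id, sum)
  out <- setNames(integer(nrow(ann$genes)), ann$genes$gene_id)
  out[names(v)] <- as.integer(v)
  out
}

# intervals of one type for one gene, in genomic order
gene_intervals <- function(ann, gene_id, type) {
  f <- ann$features
  f <- f[f$gene_id == gene_id & f$type == type, c("start", "end")]
  f[order(f$start), , drop = FALSE]
}

#' Intron intervals derived from exon gaps
#' @param ann an `ma_annotation`.
#' @param gene_id one gene id.
#' @return data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
gene_introns <- function(ann, gene_id) {
  ex <- gene_intervals(ann, gene_id, "exon")
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' Extract the spliced CDS of one gene on its coding strand
#'
#' Concatenates CDS intervals in genomic order and reverse-complements for
#' minus-strand genes, yielding the start-to-stop reading frame.
#'
#' @param genome an `ma_genome` with sequences covering the gene.
#' @param ann an `ma_annotation`.
#' @param gene_id one gene id.
#' @return a character string (possibly `""` for a gene without CDS).
#' @export
gene_cds_seq <- function(genome, ann, gene_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (nrow(g) == 0L) stopf("unknown gene '%s'", gene_id)
  iv <- gene_intervals(ann, gene_id, "CDS")
  if (nrow(iv) == 0L) return("")
  sq <- genome$seq[[g$contig]]
  parts <- substring(sq, iv$start, iv$end)
  s <- paste(parts, collapse = "")
  if (g$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Read GFF3 gene-model annotation
#'
#' Honours feature types gene, mRNA, CDS, exon, five_prime_UTR and
#' three_prime_UTR; all other types are ignored.  CDS/exon/UTR features are
#' attached to their gene through the mRNA `Parent` chain.
#'
#' @param path path to a GFF3 file.
#' @return an `ma_annotation`.
#' @export
read_annotation_gff3 <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  keep <- ty %in% c("gene", "mRNA", "CDS", "exon",
                    "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]; ty <- ty[keep]
  id <- gr$ID
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))
  gi <- ty == "gene"
  genes <- data.frame(gene_id = id[gi],
                      contig = as.character(GenomicRanges::seqnames(gr)[gi]),
                      strand = as.character(GenomicRanges::strand(gr)[gi]))
  # mRNA id -> gene id (features may also point directly at the gene)
  mrna <- setNames(parent[ty == "mRNA"], id[ty == "mRNA"])
  fi <- ty %in% c("CDS", "exon", "five_prime_UTR", "three_prime_UTR")
  fparent <- parent[fi]
  fgene <- ifelse(fparent %in% names(mrna), mrna[fparent], fparent)
  features <- data.frame(gene_id = fgene, type = ty[fi],
                         start = GenomicRanges::start(gr)[fi],
                         end = GenomicRanges::end(gr)[fi])
  ma_log("read_annotation_gff3: %d genes, %d features from %s",
         nrow(genes), nrow(features), path)
  annotation(genes, features)
}

#' Write gene-model annotation to GFF3
#'
#' Emits gene, mRNA (one per gene, id `<gene>.t1`), exon, CDS and UTR
#' records.  Round-trips through [read_annotation_gff3()].
#'
#' @param ann an `ma_annotation`.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @export
write_annotation_gff3 <- function(ann, path, source = "mutacc") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    f <- ann$features[ann$features$gene_id == g$gene_id, ]
    lo <- min(f$start); hi <- max(f$end)
    mid <- paste0(g$gene_id, ".t1")
    ln <- function(type, start, end, attr, phase = ".")
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$contig, source, type, start, end, g$strand, phase, attr)
    out <- c(ln("gene", lo, hi, paste0("ID=", g$gene_id)),
             ln("mRNA", lo, hi, sprintf("ID=%s;Parent=%s", mid, g$gene_id)))
    # phase: 0 for the first CDS interval in transcription order, then
    # carried over remaining length
    cds <- f[f$type == "CDS", ]
    cds <- cds[order(cds$start, decreasing = (g$strand == "-")), ]
    phase <- 0L
    cds$phase <- NA_integer_
    for (k in seq_len(nrow(cds))) {
      cds$phase[k] <- phase
      phase <- (3L - ((cds$end[k] - cds$start[k] + 1L - phase) %% 3L)) %% 3L
    }
    for (k in seq_len(nrow(f))) {
      fe <- f[k, ]
      ph <- if (fe$type == "CDS")
        as.character(cds$phase[cds$start == fe$start]) else "."
      out <- c(out, ln(fe$type, fe$start, fe$end,
                       paste0("Parent=", mid), ph))
    }
    writeLines(out, con)
  }
  invisible(path)
}
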