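#' Genome container
#'
#' A genome is a set of contig sequences with per-contig compartment labels
#' (nuclear, mitochondrial or chloroplast) and, optionally, gene-model
#' annotation.  Sequences are stored as upper-case character strings over
#' the alphabet A/C/G/T/N; all coordinates exposed to users are 1-based
#' inclusive.
#'
#' @param sequences named character vector of contig sequences.
#' @param compartment named character vector mapping contig ids to one of
#'   `"nuclear"`, `"mitochondrial"`, `"chloroplast"`.  Contigs not named
#'   default to nuclear.
#' @param annotation an [annotation()] object, or `NULL`.
#' @return an object of class `ma_genome`.
#' @seealso [read_genome_fasta()], [annotation()]
#' @export
ma_genome <- function(sequences, compartment = NULL, annotation = NULL) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stopf("all sequences must be named by contig id")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate contig id: %s",
          names(sequences)[duplicated(names(sequences))][1L])
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stopf("contig '%s' contains non-ACGTN characters", names(sequences)[bad][1L])
  comp <- setNames(rep("nuclear", length(sequences)), names(sequences))
  if (!is.null(compartment)) {
    unknown <- setdiff(names(compartment), names(sequences))
    if (length(unknown))
      stopf("compartment label for unknown contig '%s'", unknown[1L])
    if (!all(compartment %in% c("nuclear", "mitochondrial", "chloroplast")))
      stopf("compartment must be nuclear, mitochondrial or chloroplast")
    comp[names(compartment)] <- compartment
  }
  g <- structure(list(seq = sequences, compartment = comp,
                      annotation = annotation),
                 class = "ma_genome")
  if (!is.null(annotation)) validate_annotation(annotation, g)
  g
}

#' @export
print.ma_genome <- function(x, ...) {
  n <- length(x$seq)
  L <- genome_length(x)
  cat(sprintf("MA genome: %d contig%s, %s bp, GC %.1f%%\n",
              n, if (n == 1) "" else "s", format(L, big.mark = ","),
              100 * gc_content(x)))
  tab <- table(x$compartment)
  cat("  compartments:", paste(sprintf("%s (%d)", names(tab), tab),
                               collapse = ", "), "\n")
  if (!is.null(x$annotation))
    cat(sprintf("  annotation: %d gene models\n", nrow(x$annotation$genes)))
  invisible(x)
}

#' Total genome length in bp
#' @param genome an `ma_genome`.
#' @param compartment optional compartment to restrict to.
#' @export
genome_length <- function(genome, compartment = NULL) {
  s <- genome$seq
  if (!is.null(compartment)) s <- s[genome$compartment == compartment]
  sum(nchar(s))
}

#' GC fraction of a genome or sequence set
#'
#' N bases are excluded from the denominator.
#' @param genome an `ma_genome` or a character vector of sequences.
#' @export
gc_content <- function(genome) {
  s <- if (inherits(genome, "ma_genome")) genome$seq else toupper(genome)
  f <- base_counts(s)
  (f[["G"]] + f[["C"]]) / sum(f[c("A", "C", "G", "T")])
}

# counts of A/C/G/T/N pooled over a character vector of sequences
base_counts <- function(s) {
  x <- Biostrings::DNAStringSet(s)
  colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T", "N"),
                                           drop = FALSE])
}

#' Extract bases at genomic positions
#' @param genome an `ma_genome`.
#' @param contig,pos parallel vectors of contig ids and 1-based positions.
#' @return character vector of single bases (`""` outside contig bounds).
#' @export
base_at <- function(genome, contig, pos) {
  out <- character(length(pos))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    sq <- genome$seq[[ct]]
    if (is.null(sq)) stopf("unknown contig '%s'", ct)
    out[i] <- substring(sq, pos[i], pos[i])
  }
  out
}

#' Read a genome from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are case-normalised to upper.  Malformed headers, non-IUPAC
#' characters and duplicate ids raise a format error naming the offending
#' line.
#'
#' @param path path to a FASTA file.
#' @param compartment optional named compartment labels (see [ma_genome()]).
#' @return an `ma_genome` (without annotation).
#' @export
read_genome_fasta <- function(path, compartment = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stopf("empty FASTA: %s", path)
  first <- which(keep)[1L]
  if (!startsWith(lines[first], ">"))
    stopf("malformed FASTA %s: line %d does not start a record", path, first)
  is_seq <- keep & !startsWith(lines, ">")
  bad <- which(is_seq & grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv.-]", lines))
  if (length(bad))
    stopf("malformed FASTA %s: non-IUPAC characters on line %d", path, bad[1L])
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA record id '%s' in %s", ids[duplicated(ids)][1L], path)
  seqs <- setNames(toupper(as.character(x)), ids)
  # collapse non-ACGTN ambiguity codes to N: downstream treats them as uncallable
  seqs <- gsub("[^ACGTN]", "N", seqs)
  ma_log("read_genome_fasta: %d contigs, %d bp from %s",
         length(seqs), sum(nchar(seqs)), path)
  ma_genome(seqs, compartment = compartment)
}

#' Write a genome to FASTA
#' @param genome an `ma_genome`.
#' @param path output path.
#' @param width line width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
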