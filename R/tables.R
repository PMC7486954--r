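#' Read / write an MA experiment table
#'
#' The experiment table has one row per MA line: line id, number of
#' generations, number of callable sites, and (optionally) the number of
#' accepted de novo nucleotide substitutions `n_mut`.
#'
#' @param path TSV path with columns `line`, `generations`,
#'   `callable_sites` and optionally `n_mut`.
#' @param genome_size optional genome size used to check
#'   `callable_sites <= genome_size`.
#' @return data.frame of class `ma_experiment`.
#' @export
read_experiment_table <- function(path, genome_size = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  experiment_table(x, genome_size = genome_size)
}

#' @param x data.frame with the columns listed above.
#' @rdname read_experiment_table
#' @export
experiment_table <- function(x, genome_size = NULL) {
  need <- c("line", "generations", "callable_sites")
  if (!all(need %in% names(x)))
    stopf("experiment table needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(x$line))
    stopf("duplicate line id '%s'", x$line[duplicated(x$line)][1L])
  if (any(x$generations <= 0)) stopf("generations must be positive")
  if (any(x$callable_sites <= 0)) stopf("callable sites must be positive")
  if (!is.null(x$n_mut) && any(x$n_mut < 0))
    stopf("mutation counts must be non-negative")
  if (!is.null(genome_size) && any(x$callable_sites > genome_size))
    stopf("callable sites exceed genome size")
  x <- as.data.frame(x)
  rownames(x) <- NULL
  class(x) <- c("ma_experiment", "data.frame")
  x
}

#' @param tab an experiment table.
#' @rdname read_experiment_table
#' @export
write_experiment_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#' @param path TSV with columns `gene_id`, `fpkm`.
#' @export
read_expression_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(x)))
    stopf("expression table needs columns gene_id, fpkm")
  x
}

#' Read a species compilation table
#'
#' Used for the cross-species effective-population-size vs mutation-rate
#' correlation; columns `species`, `ne`, `mu` and optionally `group`.
#' @param path TSV path.
#' @export
read_species_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "ne", "mu") %in% names(x)))
    stopf("species table needs columns species, ne, mu")
  if (any(x$ne <= 0) || any(x$mu <= 0)) stopf("ne and mu must be positive")
  x
}

#' The Emiliania huxleyi MA experiment table
#'
#' Published per-line summary of the 15 E. huxleyi (strain RCC1242,
#' diploid) mutation accumulation lines: MA generations, nuclear callable
#' sites and accepted de novo single-nucleotide substitutions per line.
#' These numbers are the denominators and counts behind the headline
#' nuclear mutation-rate estimate.
#'
#' @return an [experiment_table()] with 15 rows.
#' @export
ehux_ma_lines <- function() {
  experiment_table(data.frame(
    line = c("Eh_mut_A", "Eh_mut_E", "Eh_mut_G", "Eh_mut_H", "Eh_mut_J",
             "Eh_mut_M", "Eh_mut_N", "Eh_mut_O", "Eh_mut_R", "Eh_mut_S",
             "Eh_mut_T", "Eh_mut_U", "Eh_mut_X", "Eh_mut_Y", "Eh_mut_Z"),
    generations = c(210L, 209L, 209L, 221L, 267L, 285L, 273L, 291L, 202L,
                    214L, 209L, 200L, 232L, 240L, 218L),
    callable_sites = c(118881543, 119008226, 120234404, 117447180, 117688670,
                       120186108, 117776564, 116961626, 120132427, 116500955,
                       119224148, 117252421, 104532863, 120278083, 119602275),
    n_mut = c(34L, 22L, 40L, 44L, 40L, 19L, 30L, 26L, 21L, 52L, 47L, 20L,
              23L, 25L, 12L)))
}

#' Reference genome summary statistics for Emiliania huxleyi
#'
#' Published summary constants of the E. huxleyi RCC1242 reference genome
#' and population used throughout the analysis: genome and annotated-CDS
#' size, GC content (total, coding, noncoding, third synonymous codon
#' positions), callable coding/noncoding site counts, and synonymous
#' nucleotide diversity.
#'
#' @return a named list.
#' @export
ehux_genome_stats <- function() {
  list(genome_size = 167e6,
       cds_size = 39635709,
       gc = 0.657,
       gc_coding = 0.691,
       gc_noncoding = 0.630,
       gc3s = 0.842,
       callable_coding = 30362830,
       callable_noncoding = 87351003,
       pi_s = 0.006,
       ploidy = 2L)
}
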