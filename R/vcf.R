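#' Variant-candidate set
#'
#' Container for SNV candidates awaiting the de novo acceptance criteria:
#' one row per (site, alt allele) with the site mapping quality and the
#' distance to the nearest indel record, plus per-sample total depth and
#' alt-allele depth matrices covering the ancestor and every MA line.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `mq`, `indel_dist` (`Inf` when no indel on the contig).
#' @param dp,ad numeric matrices, rows parallel to `sites`, columns named
#'   by sample: total depth and alt-allele depth.
#' @param ancestor name of the ancestor sample.
#' @return an object of class `ma_candidates`.
#' @export
ma_candidates <- function(sites, dp, ad, ancestor) {
  need <- c("contig", "pos", "ref", "alt", "mq", "indel_dist")
  if (!all(need %in% names(sites)))
    stopf("sites needs columns %s", paste(need, collapse = ", "))
  if (nrow(sites) != nrow(dp) || nrow(sites) != nrow(ad))
    stopf("dp/ad rows must parallel sites")
  if (is.null(colnames(dp)) || !identical(colnames(dp), colnames(ad)))
    stopf("dp and ad must share sample column names")
  if (!ancestor %in% colnames(dp))
    stopf("ancestor sample '%s' not among samples", ancestor)
  if (ncol(dp) < 2L) stopf("need the ancestor plus at least one MA line")
  rownames(sites) <- NULL
  structure(list(sites = as.data.frame(sites), dp = dp, ad = ad,
                 samples = colnames(dp), ancestor = ancestor),
            class = "ma_candidates")
}

#' @export
print.ma_candidates <- function(x, ...) {
  cat(sprintf("%d SNV candidates across %d samples (ancestor: %s)\n",
              nrow(x$sites), length(x$samples), x$ancestor))
  invisible(x)
}

#' Lines (non-ancestor samples) of a candidate set
#' @param x an `ma_candidates`.
#' @export
candidate_lines <- function(x) setdiff(x$samples, x$ancestor)

#' Read SNV candidates from a VCF
#'
#' Accepts VCF v4.1-4.3 with per-sample FORMAT fields `DP` and `AD` and the
#' site INFO key `MQ`; every other field is ignored.  Indel records are not
#' returned as candidates but populate each SNV's distance to the nearest
#' indel (REF-anchored positions, strand-agnostic).  Multiallelic records
#' are split into one candidate per alt allele.
#'
#' @param path path to a VCF file.
#' @param ancestor name of the ancestor sample; defaults to the first
#'   sample column.
#' @return an [ma_candidates()] object.
#' @export
read_vcf_candidates <- function(path, ancestor = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  smp <- colnames(v)
  if (length(smp) < 2L)
    stopf("VCF %s must carry one ancestor plus at least one MA line", path)
  ancestor <- ancestor %||% smp[1L]
  if (!ancestor %in% smp) stopf("ancestor sample '%s' not in VCF", ancestor)
  gen <- VariantAnnotation::geno(v)
  if (!all(c("DP", "AD") %in% names(gen)))
    stopf("VCF %s lacks FORMAT fields DP and/or AD", path)
  if (!"MQ" %in% names(VariantAnnotation::info(v)))
    stopf("VCF %s lacks INFO key MQ", path)
  rr <- SummarizedExperiment::rowRanges(v)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  alts <- lapply(seq_along(altl), function(i) as.character(altl[[i]]))
  mq <- as.numeric(VariantAnnotation::info(v)$MQ)
  dp <- gen$DP
  adl <- gen$AD

  n <- length(pos)
  rec_id <- sprintf("%s:%d %s>%s", contig, pos, ref,
                    vapply(alts, paste, "", collapse = ","))
  # usability check: every record must carry DP, AD and MQ
  ad_ok <- vapply(seq_len(n), function(i)
    all(vapply(seq_along(smp), function(j)
      length(adl[[i, j]]) >= 2L && !anyNA(adl[[i, j]]), logical(1))),
    logical(1))
  bad <- which(is.na(mq) | apply(is.na(dp), 1L, any) | !ad_ok)
  if (length(bad))
    stopf("unusable VCF record (missing DP/AD/MQ): %s",
          paste(rec_id[bad], collapse = "; "))

  is_indel_alt <- function(r, a) nchar(r) != 1L || nchar(a) != 1L
  rows <- list(); k <- 0L
  indel_pos <- list()
  for (i in seq_len(n)) {
    for (j in seq_along(alts[[i]])) {
      a <- alts[[i]][j]
      if (is_indel_alt(ref[i], a)) {
        indel_pos[[length(indel_pos) + 1L]] <- c(contig[i], pos[i])
      } else {
        k <- k + 1L
        rows[[k]] <- list(contig = contig[i], pos = pos[i],
                          ref = substr(ref[i], 1L, 1L), alt = a,
                          mq = mq[i], rec = i, alt_idx = j)
      }
    }
  }
  if (k == 0L) {
    sites <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        mq = numeric(0), indel_dist = numeric(0))
    m <- matrix(numeric(0), 0, length(smp), dimnames = list(NULL, smp))
    return(ma_candidates(sites, m, m, ancestor))
  }
  sites <- data.frame(contig = vapply(rows, `[[`, "", "contig"),
                      pos = vapply(rows, function(r) as.integer(r$pos), 1L),
                      ref = vapply(rows, `[[`, "", "ref"),
                      alt = vapply(rows, `[[`, "", "alt"),
                      mq = vapply(rows, function(r) as.numeric(r$mq), 1))
  # distance to nearest indel, per contig
  ind <- if (length(indel_pos)) {
    data.frame(contig = vapply(indel_pos, `[`, "", 1L),
               pos = as.integer(vapply(indel_pos, `[`, "", 2L)))
  } else data.frame(contig = character(0), pos = integer(0))
  sites$indel_dist <- vapply(seq_len(nrow(sites)), function(r) {
    p <- ind$pos[ind$contig == sites$contig[r]]
    if (length(p)) min(abs(p - sites$pos[r])) else Inf
  }, 1)

  ridx <- vapply(rows, function(r) r$rec, 1L)
  aidx <- vapply(rows, function(r) r$alt_idx, 1L)
  dpm <- dp[ridx, , drop = FALSE]
  adm <- matrix(0, nrow(sites), length(smp), dimnames = list(NULL, smp))
  for (r in seq_len(nrow(sites)))
    for (j in seq_along(smp))
      adm[r, j] <- adl[[ridx[r], j]][aidx[r] + 1L]
  dimnames(dpm) <- list(NULL, smp)
  ma_log("read_vcf_candidates: %d SNV candidates, %d indel records from %s",
         nrow(sites), nrow(ind), path)
  ma_candidates(sites, dpm, adm, ancestor)
}

#' Write a candidate set as VCF v4.2
#'
#' Emits the minimal VCF subset the pipeline consumes (FORMAT `GT:DP:AD`,
#' INFO `MQ`), plus any indel records supplied so that indel proximity
#' round-trips through [read_vcf_candidates()].
#'
#' @param cand an [ma_candidates()] object.
#' @param path output path.
#' @param indels optional data.frame with columns `contig`, `pos`, `ref`,
#'   `alt` of indel records to interleave.
#' @export
write_vcf_candidates <- function(cand, path, indels = NULL) {
  smp <- cand$samples
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutacc",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", smp), collapse = "\t"))
  s <- cand$sites
  recs <- data.frame(contig = s$contig, pos = s$pos, ref = s$ref, alt = s$alt,
                     mq = s$mq, snv = TRUE, idx = seq_len(nrow(s)))
  if (!is.null(indels) && nrow(indels)) {
    recs <- rbind(recs, data.frame(contig = indels$contig, pos = indels$pos,
                                   ref = indels$ref, alt = indels$alt,
                                   mq = 60, snv = FALSE, idx = NA))
  }
  recs <- recs[order(recs$contig, recs$pos, !recs$snv), ]
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    if (r$snv) {
      dp <- cand$dp[r$idx, ]; ad <- cand$ad[r$idx, ]
      gt <- ifelse(ad > 0, "0/1", "0/0")
      fld <- sprintf("%s:%d:%d,%d", gt, as.integer(dp),
                     as.integer(dp - ad), as.integer(ad))
    } else {
      fld <- rep(sprintf("0/0:%d:%d,%d", 30L, 30L, 0L), length(smp))
    }
    paste(c(r$contig, r$pos, ".", r$ref, r$alt, "50", "PASS",
            sprintf("MQ=%g", r$mq), "GT:DP:AD", fld), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
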