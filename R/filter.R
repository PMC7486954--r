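#' Acceptance-criteria parameters for de novo mutation calling
#'
#' Defaults follow the standard MA-resequencing criteria: callable sites
#' require mapping quality >= 20 and coverage between 20 and 150 (inclusive)
#' in both the MA line and the ancestor; the alternative allele must be
#' supported by at least 1/3 of the total coverage; candidates within 5 bp
#' of an indel are removed; and the alt allele must be absent from the
#' ancestor and from every other line (shared variants cannot be
#' independent de novo events).
#'
#' @param min_mq minimum site mapping quality.
#' @param min_depth,max_depth coverage bounds, applied to line and ancestor
#'   symmetrically; both bounds inclusive.
#' @param min_alt_frac minimum alt-allele fraction (inclusive).
#' @param indel_window bp; candidates at distance <= `indel_window` from an
#'   indel record are rejected.
#' @param unique_across_lines require the alt allele to be absent from the
#'   ancestor and all other lines.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(min_mq = 20, min_depth = 20, max_depth = 150,
                          min_alt_frac = 1/3, indel_window = 5,
                          unique_across_lines = TRUE) {
  if (min_depth <= 0 || min_depth > max_depth)
    stopf("need 0 < min_depth <= max_depth")
  if (min_alt_frac <= 0 || min_alt_frac > 1)
    stopf("need 0 < min_alt_frac <= 1")
  structure(list(min_mq = min_mq, min_depth = min_depth,
                 max_depth = max_depth, min_alt_frac = min_alt_frac,
                 indel_window = indel_window,
                 unique_across_lines = unique_across_lines),
            class = "filter_params")
}

#' Per-site pileup statistics
#'
#' Site-level mapping quality and per-sample depth over a contiguous
#' coordinate space, used to define callable sites.
#'
#' @param mq named list (by contig) of per-site mapping-quality vectors.
#' @param depth named list (by contig) of site x sample depth matrices.
#' @param ancestor ancestor sample name.
#' @return an object of class `ma_pileup`.
#' @export
ma_pileup <- function(mq, depth, ancestor) {
  if (!identical(names(mq), names(depth)))
    stopf("mq and depth must cover identical contigs")
  smp <- colnames(depth[[1L]])
  for (ct in names(mq)) {
    if (length(mq[[ct]]) != nrow(depth[[ct]]))
      stopf("mq/depth length mismatch on contig '%s'", ct)
    if (!identical(colnames(depth[[ct]]), smp))
      stopf("inconsistent samples across contigs")
  }
  if (!ancestor %in% smp) stopf("ancestor '%s' not among samples", ancestor)
  structure(list(mq = mq, depth = depth, samples = smp, ancestor = ancestor),
            class = "ma_pileup")
}

#' Callable-site mask for one MA line
#'
#' A site is callable iff its mapping quality is >= `min_mq` and the depth
#' in both the MA line and the ancestor lies within
#' `[min_depth, max_depth]`.
#'
#' @param pileup an [ma_pileup()].
#' @param line line sample name.
#' @param params a [filter_params()].
#' @return named list (by contig) of logical vectors, with attribute
#'   `callable` giving the total count.
#' @export
callable_mask <- function(pileup, line, params = filter_params()) {
  if (!line %in% pileup$samples) stopf("unknown line '%s'", line)
  anc <- pileup$ancestor
  masks <- lapply(names(pileup$mq), function(ct) {
    d <- pileup$depth[[ct]]
    pileup$mq[[ct]] >= params$min_mq &
      d[, line] >= params$min_depth & d[, line] <= params$max_depth &
      d[, anc] >= params$min_depth & d[, anc] <= params$max_depth
  })
  names(masks) <- names(pileup$mq)
  attr(masks, "callable") <- sum(vapply(masks, sum, 1))
  masks
}

#' Callable-site counts for every line
#' @inheritParams callable_mask
#' @return named numeric vector of callable-site counts.
#' @export
callable_counts <- function(pileup, params = filter_params()) {
  ln <- setdiff(pileup$samples, pileup$ancestor)
  vapply(ln, function(l) attr(callable_mask(pileup, l, params), "callable"), 1)
}

#' Apply the de novo acceptance criteria to variant candidates
#'
#' A candidate (site, alt allele) is evaluated in every line carrying alt
#' reads.  It is accepted iff the site is callable in that line, the alt
#' depth is at least `min_alt_frac` of the total depth (inclusive), the
#' distance to the nearest indel exceeds `indel_window`, and the alt allele
#' is absent from the ancestor and from every other line.  Rejected
#' candidates carry exactly one rejection reason: the first failing
#' criterion in the order mapping quality, low depth, high depth, alt
#' fraction, indel proximity, ancestral presence, cross-line sharing.
#'
#' @param cand an [ma_candidates()].
#' @param masks named list (by line) of callable masks from
#'   [callable_mask()]; `NULL` treats every site as callable.
#' @param params a [filter_params()].
#' @param pileup optional [ma_pileup()] used to attribute granular
#'   callability reasons (mapping quality vs depth) when `masks` come from
#'   it; if supplied, masks are computed from it.
#' @return list with data.frames `accepted` (columns line, contig, pos,
#'   ref, alt) and `rejected` (same plus `reason`).
#' @export
filter_candidates <- function(cand, masks = NULL, params = filter_params(),
                              pileup = NULL) {
  if (!is.null(pileup))
    masks <- lapply(setNames(nm = candidate_lines(cand)),
                    function(l) callable_mask(pileup, l, params))
  s <- cand$sites
  anc <- cand$ancestor
  lines <- candidate_lines(cand)
  acc <- rej <- list()
  eps <- 1e-9
  for (ln in lines) {
    has_alt <- which(cand$ad[, ln] > 0)
    for (i in has_alt) {
      dp <- cand$dp[i, ln]; ad <- cand$ad[i, ln]
      reason <- NULL
      if (s$mq[i] < params$min_mq) {
        reason <- "low_mapping_quality"
      } else if (!is.null(pileup)) {
        d <- pileup$depth[[s$contig[i]]]
        if (is.null(d)) stopf("candidate on unknown contig '%s'", s$contig[i])
        if (s$pos[i] < 1L || s$pos[i] > nrow(d))
          stopf("candidate outside contig '%s' bounds", s$contig[i])
        dl <- d[s$pos[i], ln]; da <- d[s$pos[i], anc]
        if (dl < params$min_depth || da < params$min_depth)
          reason <- "low_depth"
        else if (dl > params$max_depth || da > params$max_depth)
          reason <- "high_depth"
      } else {
        da <- cand$dp[i, anc]
        if (dp < params$min_depth || da < params$min_depth)
          reason <- "low_depth"
        else if (dp > params$max_depth || da > params$max_depth)
          reason <- "high_depth"
        if (!is.null(masks)) {
          m <- masks[[ln]][[s$contig[i]]]
          if (is.null(m)) stopf("candidate on unknown contig '%s'", s$contig[i])
          if (s$pos[i] < 1L || s$pos[i] > length(m))
            stopf("candidate outside contig '%s' bounds", s$contig[i])
          if (is.null(reason) && !m[s$pos[i]]) reason <- "low_mapping_quality"
        }
      }
      if (is.null(reason) && ad < dp * params$min_alt_frac - eps)
        reason <- "low_alt_fraction"
      if (is.null(reason) && s$indel_dist[i] <= params$indel_window)
        reason <- "near_indel"
      if (is.null(reason) && params$unique_across_lines &&
          cand$ad[i, anc] > 0)
        reason <- "ancestral_allele"
      if (is.null(reason) && params$unique_across_lines &&
          any(cand$ad[i, setdiff(lines, ln)] > 0))
        reason <- "shared_across_lines"
      rec <- data.frame(line = ln, contig = s$contig[i], pos = s$pos[i],
                        ref = s$ref[i], alt = s$alt[i],
                        stringsAsFactors = FALSE)
      if (is.null(reason)) acc[[length(acc) + 1L]] <- rec
      else { rec$reason <- reason; rej[[length(rej) + 1L]] <- rec }
    }
  }
  empty <- data.frame(line = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  accepted <- if (length(acc)) do.call(rbind, acc) else empty
  rejected <- if (length(rej)) do.call(rbind, rej) else
    cbind(empty, data.frame(reason = character(0)))
  rownames(accepted) <- rownames(rejected) <- NULL
  ma_log("filter_candidates: %d accepted, %d rejected",
         nrow(accepted), nrow(rejected))
  list(accepted = accepted, rejected = rejected)
}
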