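#' Derive the copy-neutral LOH minor-allele-fraction cutoff
#'
#' For each normal reference sample, takes the 10th percentile of its
#' minor allele fraction values (linear interpolation between order
#' statistics, quantile type 7); the cutoff is the mean of these
#' per-sample percentiles minus three sample standard deviations
#' (n - 1 denominator), clamped to \[0, 0.5\]. A copy-neutral segment
#' whose minor allele fraction falls below this value is considered to
#' show allelic imbalance.
#'
#' @param normalMafs named list of numeric vectors, one per normal
#'   sample, each the segment minor allele fractions of that sample.
#' @param quantileType passed to [stats::quantile()] (default 7).
#' @return a [CnlohCutoff-class].
#' @examples
#' deriveCnlohCutoff(replicate(7, rep(0.47, 5), simplify = FALSE))
#' @export
deriveCnlohCutoff <- function(normalMafs, quantileType = 7) {
  if (!is.list(normalMafs) || length(normalMafs) < 2L)
    stop("at least 2 normal samples are required (the SD of a single ",
         "sample's percentile is undefined)", call. = FALSE)
  if (any(!vapply(normalMafs, length, integer(1))))
    stop("every normal sample needs at least one MAF value", call. = FALSE)
  p10 <- vapply(normalMafs, function(x)
    unname(stats::quantile(x, probs = 0.10, type = quantileType,
                           names = FALSE)), numeric(1))
  if (is.null(names(normalMafs)))
    names(p10) <- paste0("normal", seq_along(p10))
  value <- mean(p10) - 3 * stats::sd(p10)
  value <- min(0.5, max(0, value))
  new("CnlohCutoff", value = value, nNormals = length(p10),
      perSampleP10 = p10)
}

.classifySegment <- function(ratio, maf, gainCutoff, lossCutoff, cutoffVal) {
  if (ratio > gainCutoff) return("GAIN")
  if (ratio < lossCutoff) return("LOSS")
  if (maf < cutoffVal) return("CNLOH")
  NA_character_
}

#' Call copy-number and copy-neutral-LOH events from segments
#'
#' Per segment: copy ratio strictly above `gainCutoff` is a gain,
#' strictly below `lossCutoff` a loss; a ratio inside the closed neutral
#' band with minor allele fraction below the CN-LOH cutoff is
#' copy-neutral LOH; anything else is no event. Adjacent same-type
#' events of one sample on one chromosome are merged into a single
#' event.
#'
#' @param segmentTable segment data.frame (may span samples and cases).
#' @param cnlohCutoff a [CnlohCutoff-class] (or numeric threshold).
#' @param gainCutoff,lossCutoff copy-ratio cutoffs, defaults 1.1 / 0.9;
#'   `lossCutoff < 1 < gainCutoff` is required.
#' @return event data.frame (case_id, sample_id, chrom, start, end,
#'   event_type, affected_haplotype = NA).
#' @examples
#' cut <- deriveCnlohCutoff(replicate(3, rep(0.47, 5), simplify = FALSE))
#' seg <- data.frame(case_id = "c1", sample_id = "G1", chrom = "chr1",
#'                   start = 1, end = 100, copy_ratio = 1.2,
#'                   minor_allele_fraction = 0.48, n_probes = 50)
#' callCnaEvents(seg, cut)$event_type  # "GAIN"
#' @export
callCnaEvents <- function(segmentTable, cnlohCutoff,
                          gainCutoff = 1.1, lossCutoff = 0.9) {
  if (!(lossCutoff < 1 && 1 < gainCutoff))
    stop("cutoffs must satisfy lossCutoff < 1 < gainCutoff", call. = FALSE)
  cutoffVal <- if (is(cnlohCutoff, "CnlohCutoff"))
    cutoffValue(cnlohCutoff) else as.numeric(cnlohCutoff)
  .validateSegments(segmentTable)
  empty <- data.frame(case_id = character(), sample_id = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), event_type = character(),
                      affected_haplotype = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(segmentTable)) return(empty)
  type <- vapply(seq_len(nrow(segmentTable)), function(i)
    .classifySegment(segmentTable$copy_ratio[i],
                     segmentTable$minor_allele_fraction[i],
                     gainCutoff, lossCutoff, cutoffVal), character(1))
  hit <- segmentTable[!is.na(type), , drop = FALSE]
  hit$event_type <- type[!is.na(type)]
  if (!nrow(hit)) return(empty)
  out <- lapply(split(hit, list(hit$case_id, hit$sample_id,
                                hit$event_type), drop = TRUE),
                function(h) {
    gr <- GenomicRanges::GRanges(h$chrom,
                                 IRanges::IRanges(h$start, h$end))
    red <- GenomicRanges::reduce(gr)  # merges adjacent same-type runs
    data.frame(case_id = h$case_id[1], sample_id = h$sample_id[1],
               chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               event_type = h$event_type[1],
               affected_haplotype = NA_integer_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$case_id, res$sample_id, res$chrom, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign the affected haplotype of a copy-number event
#'
#' Majority vote over phased heterozygous variants overlapping the
#' event. For a loss or copy-neutral LOH, a variant whose phased allele
#' shows VAF below 0.5 votes that its haplotype was lost; for a gain,
#' an elevated VAF votes that its haplotype was gained. The convention:
#' `affected_haplotype` is the LOST haplotype for LOSS/CNLOH and the
#' GAINED haplotype for GAIN. Ties or absence of informative variants
#' yield NA (unknown).
#'
#' @param event one event row (as from [callCnaEvents()]).
#' @param phasedVariants variant data.frame of the same sample; only
#'   rows overlapping the event with a phase label and VAF strictly
#'   inside (0, 1) and away from 0.5 are informative.
#' @return the event row with `affected_haplotype` filled in.
#' @export
assignHaplotype <- function(event, phasedVariants) {
  stopifnot(nrow(event) == 1L)
  event$affected_haplotype <- NA_integer_
  if (!nrow(phasedVariants)) return(event)
  v <- phasedVariants
  ok <- !is.na(v$phase) & v$chrom == event$chrom &
    v$pos >= event$start & v$pos <= event$end &
    v$vaf > 0 & v$vaf < 1 & v$vaf != 0.5
  v <- v[ok, , drop = FALSE]
  if (!nrow(v)) return(event)
  if (event$event_type %in% c("LOSS", "CNLOH")) {
    affected <- ifelse(v$vaf < 0.5, v$phase, 1L - v$phase)
  } else {
    affected <- ifelse(v$vaf > 0.5, v$phase, 1L - v$phase)
  }
  n0 <- sum(affected == 0L); n1 <- sum(affected == 1L)
  if (n0 == n1) return(event)
  event$affected_haplotype <- if (n0 > n1) 0L else 1L
  event
}

#' Assign affected haplotypes for a whole event table
#'
#' Applies [assignHaplotype()] to each event using the phased variants
#' of the matching sample. Variants should be the unsubtracted sample
#' table (phased heterozygous germline variants carry the allelic
#' imbalance signal).
#'
#' @param eventTable events from [callCnaEvents()].
#' @param variantTable cohort variant data.frame with a `phase` column.
#' @return the event table with `affected_haplotype` filled where
#'   resolvable.
#' @export
assignHaplotypes <- function(eventTable, variantTable) {
  if (!nrow(eventTable)) return(eventTable)
  for (i in seq_len(nrow(eventTable))) {
    sv <- variantTable[variantTable$sample_id == eventTable$sample_id[i], ,
                       drop = FALSE]
    eventTable[i, ] <- assignHaplotype(eventTable[i, , drop = FALSE], sv)
  }
  eventTable
}

#' Find mutual copy-number events between two samples
#'
#' Pairs events of the same type whose intervals overlap reciprocally
#' by at least `minReciprocalOverlap` of each event's length. Both
#' event sets must come from the same case.
#'
#' @param eventsA,eventsB event data.frames of two samples of one case.
#' @param minReciprocalOverlap fraction in (0, 1\], default 0.5.
#' @return data.frame of matched pairs with both intervals and the two
#'   overlap fractions.
#' @export
mutualEvents <- function(eventsA, eventsB, minReciprocalOverlap = 0.5) {
  empty <- data.frame(case_id = character(), event_type = character(),
                      chrom = character(),
                      start_a = numeric(), end_a = numeric(),
                      start_b = numeric(), end_b = numeric(),
                      overlap_frac_a = numeric(),
                      overlap_frac_b = numeric(), stringsAsFactors = FALSE)
  if (!nrow(eventsA) || !nrow(eventsB)) return(empty)
  ca <- unique(eventsA$case_id); cb <- unique(eventsB$case_id)
  if (!identical(ca, cb))
    stop("mutual events require two samples of the same case", call. = FALSE)
  lev <- union(eventsA$chrom, eventsB$chrom)
  gra <- GenomicRanges::GRanges(factor(eventsA$chrom, levels = lev),
                                IRanges::IRanges(eventsA$start, eventsA$end))
  grb <- GenomicRanges::GRanges(factor(eventsB$chrom, levels = lev),
                                IRanges::IRanges(eventsB$start, eventsB$end))
  ov <- GenomicRanges::findOverlaps(gra, grb)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  keepType <- eventsA$event_type[qi] == eventsB$event_type[si]
  inter <- GenomicRanges::pintersect(gra[qi], grb[si])
  w <- GenomicRanges::width(inter)
  fa <- w / GenomicRanges::width(gra[qi])
  fb <- w / GenomicRanges::width(grb[si])
  keep <- keepType & fa >= minReciprocalOverlap & fb >= minReciprocalOverlap
  if (!any(keep)) return(empty)
  data.frame(case_id = ca,
             event_type = eventsA$event_type[qi[keep]],
             chrom = eventsA$chrom[qi[keep]],
             start_a = eventsA$start[qi[keep]],
             end_a = eventsA$end[qi[keep]],
             start_b = eventsB$start[si[keep]],
             end_b = eventsB$end[si[keep]],
             overlap_frac_a = fa[keep], overlap_frac_b = fb[keep],
             stringsAsFactors = FALSE)
}
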