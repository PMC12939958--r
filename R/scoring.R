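QUALIFYING_SV_CLASSES <- c("exonic_nonsyn", "stopgain", "frameshift",
                           "nonframeshift")

#' Does a short variant qualify for driver scoring?
#'
#' A variant qualifies when it is exonic and not synonymous
#' (nonsynonymous SNV, stopgain, frameshift or non-frameshift indel)
#' and is rare in the East Asian reference population: population
#' allele frequency below 0.01, or unregistered (missing) — i.e. likely
#' somatic.
#'
#' @param funcClass functional-class value(s).
#' @param popAfEas population allele frequency value(s), NA = absent.
#' @param maxPopAf rarity threshold (default 0.01).
#' @return logical vector.
#' @export
qualifyShortVariant <- function(funcClass, popAfEas, maxPopAf = 0.01) {
  funcClass %in% QUALIFYING_SV_CLASSES &
    (is.na(popAfEas) | popAfEas < maxPopAf)
}

#' Short-variant points per gene
#'
#' One point per case with at least one qualifying variant in the gene,
#' counted on carcinoma (`G` role) samples only; multiple qualifying
#' variants of a gene within one case still contribute a single point.
#'
#' @param somaticTable filtered somatic cohort variant data.frame.
#' @param carcinomaRole role whose samples are scored (default "G").
#' @return named integer vector of points per gene (genes with 0 points
#'   omitted).
#' @export
scoreShortVariants <- function(somaticTable, carcinomaRole = "G") {
  g <- somaticTable[somaticTable$role == carcinomaRole &
                      !is.na(somaticTable$gene), , drop = FALSE]
  if (!nrow(g)) return(stats::setNames(integer(0), character(0)))
  q <- qualifyShortVariant(g$func_class, g$pop_af_eas)
  g <- g[q, , drop = FALSE]
  if (!nrow(g)) return(stats::setNames(integer(0), character(0)))
  tab <- unique(g[, c("gene", "case_id")])
  counts <- table(tab$gene)
  stats::setNames(as.integer(counts), names(counts))
}

#' Does a gene's copy-number evidence qualify in one case?
#'
#' Biologically plausible combinations only: gain over an oncogene,
#' loss over a tumor-suppressor (genes annotated as both accept
#' either), and copy-neutral LOH only when a loss-of-function variant
#' (stopgain, frameshift or splicing) of the gene lies on the retained
#' haplotype; CN-LOH with unknown affected haplotype, or without an
#' interpretable variant, is never scored.
#'
#' @param geneRow one row of the gene table (gene, chrom, start, end).
#' @param role the gene's role: ONCOGENE, TSG, BOTH or UNKNOWN.
#' @param events event data.frame of one case's carcinoma sample, with
#'   `affected_haplotype` filled by [assignHaplotypes()].
#' @param geneVariants the same case/sample's somatic variants in the
#'   gene (used for the CN-LOH loss-of-function arm).
#' @return TRUE or FALSE.
#' @export
qualifyCna <- function(geneRow, role, events, geneVariants) {
  if (!nrow(events)) return(FALSE)
  ov <- events$chrom == geneRow$chrom & events$start <= geneRow$end &
    events$end >= geneRow$start
  ev <- events[ov, , drop = FALSE]
  if (!nrow(ev)) return(FALSE)
  if (role %in% c("ONCOGENE", "BOTH") && any(ev$event_type == "GAIN"))
    return(TRUE)
  if (role %in% c("TSG", "BOTH") && any(ev$event_type == "LOSS"))
    return(TRUE)
  cnloh <- ev[ev$event_type == "CNLOH", , drop = FALSE]
  if (nrow(cnloh) && nrow(geneVariants)) {
    lof <- geneVariants[geneVariants$func_class %in% LOF_CLASSES &
                          !is.na(geneVariants$phase), , drop = FALSE]
    for (i in seq_len(nrow(cnloh))) {
      if (is.na(cnloh$affected_haplotype[i])) next  # unknown: not scored
      retained <- 1L - cnloh$affected_haplotype[i]
      inEvent <- lof$chrom == cnloh$chrom[i] &
        lof$pos >= cnloh$start[i] & lof$pos <= cnloh$end[i]
      if (any(inEvent & lof$phase == retained)) return(TRUE)
    }
  }
  FALSE
}

#' Score a cohort and rank candidate driver genes
#'
#' The per-gene total is the sum of short-variant points (cases with a
#' qualifying rare non-synonymous variant, [scoreShortVariants()]) and
#' copy-number points (cases with biologically plausible copy-number
#' evidence, [qualifyCna()]), computed on carcinoma samples. Genes
#' reaching `threshold` points (default 2) are candidates; the
#' sensitivity analysis re-emits the candidate set at thresholds 2-5,
#' which are nested by construction.
#'
#' @param somaticTable filtered somatic cohort variant data.frame.
#' @param eventTable called events with haplotypes
#'   ([assignHaplotypes()]).
#' @param genes gene table with columns gene, chrom, start, end.
#' @param roles data.frame gene/role (default: `role` column of
#'   `genes`).
#' @param threshold candidate threshold (default 2).
#' @param thresholds sensitivity thresholds (default 2:5).
#' @param carcinomaRole role scored (default "G").
#' @param carcinomaSamples sample ids whose events are scored; defaults
#'   to the sample ids carrying `carcinomaRole` in `somaticTable`.
#' @return list with `scores` (data.frame gene, sv_points, cna_points,
#'   total, evidence; sorted by total descending, ties alphabetical),
#'   `candidates` (genes at `threshold`) and `candidatesByThreshold`.
#' @export
scoreCohort <- function(somaticTable, eventTable, genes, roles = NULL,
                        threshold = 2L, thresholds = 2:5,
                        carcinomaRole = "G", carcinomaSamples = NULL) {
  if (is.null(roles)) {
    if (!"role" %in% names(genes))
      stop("supply a roles table or a role column in genes", call. = FALSE)
    roles <- genes[, c("gene", "role")]
  }
  roleOf <- stats::setNames(roles$role, roles$gene)
  sv <- scoreShortVariants(somaticTable, carcinomaRole)
  if (is.null(carcinomaSamples))
    carcinomaSamples <- unique(somaticTable$sample_id[
      somaticTable$role == carcinomaRole])
  carEvents <- eventTable[eventTable$sample_id %in% carcinomaSamples, ,
                          drop = FALSE]
  cases <- sort(unique(c(somaticTable$case_id, eventTable$case_id)))
  cnaPoints <- stats::setNames(integer(nrow(genes)), genes$gene)
  evidence <- stats::setNames(vector("list", nrow(genes)), genes$gene)
  for (cs in cases) {
    ev <- carEvents[carEvents$case_id == cs, , drop = FALSE]
    if (!nrow(ev)) next
    vs <- somaticTable[somaticTable$case_id == cs &
                         somaticTable$role == carcinomaRole, , drop = FALSE]
    # restrict to genes whose interval is touched by any event
    touched <- vapply(seq_len(nrow(genes)), function(i)
      any(ev$chrom == genes$chrom[i] & ev$start <= genes$end[i] &
            ev$end >= genes$start[i]), logical(1))
    for (i in which(touched)) {
      gname <- genes$gene[i]
      role <- roleOf[[gname]]
      if (is.null(role) || is.na(role)) role <- "UNKNOWN"
      gv <- vs[!is.na(vs$gene) & vs$gene == gname, , drop = FALSE]
      if (qualifyCna(genes[i, ], role, ev, gv)) {
        cnaPoints[gname] <- cnaPoints[gname] + 1L  # capped at 1/case
        evidence[[gname]] <- c(evidence[[gname]], paste0(cs, ":cna"))
      }
    }
  }
  for (gname in names(sv)) {
    if (!gname %in% names(cnaPoints))
      cnaPoints[gname] <- 0L
  }
  svCases <- somaticTable[somaticTable$role == carcinomaRole &
                            !is.na(somaticTable$gene), , drop = FALSE]
  if (nrow(svCases)) {
    q <- qualifyShortVariant(svCases$func_class, svCases$pop_af_eas)
    tab <- unique(svCases[q, c("gene", "case_id")])
    for (j in seq_len(nrow(tab)))
      evidence[[tab$gene[j]]] <- c(evidence[[tab$gene[j]]],
                                   paste0(tab$case_id[j], ":sv"))
  }
  allGenes <- union(names(cnaPoints), names(sv))
  svFull <- stats::setNames(integer(length(allGenes)), allGenes)
  svFull[names(sv)] <- sv
  cnaFull <- stats::setNames(integer(length(allGenes)), allGenes)
  cnaFull[names(cnaPoints)] <- cnaPoints
  scores <- data.frame(gene = allGenes,
                       sv_points = as.integer(svFull),
                       cna_points = as.integer(cnaFull),
                       total = as.integer(svFull + cnaFull),
                       stringsAsFactors = FALSE)
  scores$evidence <- vapply(scores$gene, function(g) {
    e <- evidence[[g]]
    if (is.null(e)) "" else paste(sort(unique(e)), collapse = ",")
  }, character(1))
  scores <- scores[scores$total > 0L, , drop = FALSE]
  scores <- scores[order(-scores$total, scores$gene), , drop = FALSE]
  rownames(scores) <- NULL
  byThresh <- lapply(thresholds, function(t)
    scores$gene[scores$total >= t])
  names(byThresh) <- paste0(">=", thresholds)
  list(scores = scores,
       candidates = scores$gene[scores$total >= threshold],
       candidatesByThreshold = byThresh)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric tail probability of observing at least the
#' candidate/set overlap given the universe, per gene set, with
#' Benjamini-Hochberg adjustment across sets; sets with q < `alpha`
#' are flagged. This generic over-representation test stands in for
#' external pathway services.
#'
#' @param candidates candidate gene symbols (must lie in `universe`).
#' @param geneSets named list of gene vectors (e.g. from [readGmt()]).
#' @param universe background gene symbols.
#' @param alpha significance level on the adjusted values (default
#'   0.05).
#' @return data.frame: set, overlap, set_size, p, q, significant.
#' @export
enrichmentTest <- function(candidates, geneSets, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  if (!all(candidates %in% universe))
    stop("candidates must be a subset of the universe", call. = FALSE)
  candidates <- unique(candidates)
  n <- length(candidates); N <- length(universe)
  res <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    k <- length(intersect(candidates, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out$significant <- out$q < alpha
  out
}
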