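.variantKey <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Subtract germline variants using the matched myometrium reference
#'
#' Removes from a lesion sample's variant table every variant whose
#' `(chrom, pos, ref, alt)` key is present in the matched reference
#' (role `Nm`) sample of the same case; such variants are treated as
#' germline. Genotype, VAF and phase are deliberately not part of the
#' key. Row order is preserved.
#'
#' @param lesionVariants variant data.frame of one or more lesion
#'   samples of a single case.
#' @param referenceVariants variant data.frame of the matched `Nm`
#'   sample.
#' @return the lesion rows whose key is absent from the reference.
#' @examples
#' les <- data.frame(case_id = "c1", chrom = "chr1", pos = c(1, 2, 3),
#'                   ref = "A", alt = "T")
#' ref <- data.frame(case_id = "c1", chrom = "chr1", pos = 2,
#'                   ref = "A", alt = "T")
#' subtractGermline(les, ref)$pos  # 1 3
#' @export
subtractGermline <- function(lesionVariants, referenceVariants) {
  if (nrow(lesionVariants) && nrow(referenceVariants)) {
    lc <- unique(lesionVariants$case_id)
    rc <- unique(referenceVariants$case_id)
    if (length(lc) > 1L || length(rc) > 1L || !identical(lc, rc))
      stop("germline subtraction requires lesion and reference variants ",
           "from the same single case (got '",
           paste(lc, collapse = ","), "' vs '",
           paste(rc, collapse = ","), "')", call. = FALSE)
  }
  if (!nrow(lesionVariants)) return(lesionVariants)
  keep <- !(.variantKey(lesionVariants) %in%
              .variantKey(referenceVariants))
  lesionVariants[keep, , drop = FALSE]
}

#' Quality-filter a variant table
#'
#' Applies the row-wise quality predicate: mean base quality at least
#' `minMeanBaseQuality` (rows lacking the field pass this criterion),
#' depth at least `minDepth`, VAF at least `minVaf`, and — when
#' `dropUnplacedAndMito` — removal of variants on mitochondrial or
#' unplaced/unknown contigs (anything outside the canonical
#' autosome/sex-chromosome naming).
#'
#' @param variantTable variant data.frame.
#' @param minMeanBaseQuality Phred floor (default 20).
#' @param minDepth read-depth floor (default 10).
#' @param minVaf VAF floor (default 0.05).
#' @param dropUnplacedAndMito logical (default TRUE).
#' @return the filtered data.frame, input order preserved.
#' @export
qualityFilter <- function(variantTable, minMeanBaseQuality = 20,
                          minDepth = 10, minVaf = 0.05,
                          dropUnplacedAndMito = TRUE) {
  if (any(c(minMeanBaseQuality, minDepth, minVaf) < 0))
    stop("filter thresholds must be >= 0", call. = FALSE)
  if (!nrow(variantTable)) return(variantTable)
  keep <- variantTable$depth >= minDepth & variantTable$vaf >= minVaf
  if ("mean_base_quality" %in% names(variantTable)) {
    bq <- variantTable$mean_base_quality
    keep <- keep & (is.na(bq) | bq >= minMeanBaseQuality)
  }
  if (dropUnplacedAndMito) {
    canonical <- grepl("^(chr)?([0-9]{1,2}|X|Y)$", variantTable$chrom)
    keep <- keep & canonical
  }
  variantTable[keep, , drop = FALSE]
}

#' Partition variants into exonic and non-exonic classes
#'
#' Exonic: nonsynonymous, synonymous, stopgain, frameshift and
#' non-frameshift coding changes. Non-exonic: splicing, intronic,
#' intergenic and UTR. The partition is exhaustive and disjoint; an
#' unknown functional class aborts, naming the value.
#'
#' @param variantTable variant data.frame with `func_class` populated.
#' @return named list with data.frames `exonic` and `nonExonic`.
#' @export
classifyExonic <- function(variantTable) {
  fc <- variantTable$func_class
  unknown <- setdiff(unique(fc), FUNC_CLASSES)
  if (length(unknown))
    stop("unknown func_class value(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  isEx <- fc %in% EXONIC_CLASSES
  list(exonic = variantTable[isEx, , drop = FALSE],
       nonExonic = variantTable[!isEx, , drop = FALSE])
}

#' Somatic mutation rate per megabase
#'
#' @param variantTable variant data.frame (one sample's somatic set).
#' @param targetSizeMb callable-territory size in megabases.
#' @return mutations per Mb.
#' @examples
#' mutationRate(data.frame(pos = 1:60), 50)  # 1.2
#' @export
mutationRate <- function(variantTable, targetSizeMb) {
  if (!is.numeric(targetSizeMb) || targetSizeMb <= 0)
    stop("targetSizeMb must be positive", call. = FALSE)
  nrow(variantTable) / targetSizeMb
}

#' Run germline subtraction and quality filtering for a whole cohort
#'
#' Convenience wrapper: for each case, subtracts the `Nm` variant keys
#' from every lesion sample and applies [qualityFilter()].
#'
#' @param variantTable cohort variant data.frame (all cases, all roles).
#' @param ... passed to [qualityFilter()].
#' @return somatic, quality-passing variant data.frame.
#' @export
somaticVariants <- function(variantTable, ...) {
  out <- lapply(split(variantTable, variantTable$case_id), function(cv) {
    ref <- cv[cv$role == "Nm", , drop = FALSE]
    les <- cv[cv$role != "Nm", , drop = FALSE]
    subtractGermline(les, ref)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  qualityFilter(res, ...)
}
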